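# Strand-specific single-nucleotide end coverage: construction from
# fragment intervals, bedGraph I/O, and window counting.

#' Create an empty stranded coverage object
#'
#' Per-chromosome dense integer vectors, one per strand, holding the number
#' of fragment ends at each base. Dense vectors keep window sums bit-exact
#' and are cheap at the genome sizes this package targets.
#'
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param sample_id sample label carried in metadata.
#' @param end_convention which fragment end is counted: `"3prime"`
#'   (default) or `"5prime"`.
#' @return An object of class `stranded_coverage`.
#' @export
stranded_coverage <- function(chrom_sizes, sample_id = "sample",
                              end_convention = c("3prime", "5prime")) {
  end_convention <- match.arg(end_convention)
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "")) {
    stopf("chrom_sizes must be a named vector")
  }
  chrom_sizes <- setNames(as.integer(chrom_sizes), names(chrom_sizes))
  zero <- lapply(chrom_sizes, function(n) integer(n))
  structure(
    list(plus = zero, minus = zero, chrom_sizes = chrom_sizes,
         sample_id = sample_id, end_convention = end_convention),
    class = "stranded_coverage"
  )
}

#' @export
print.stranded_coverage <- function(x, ...) {
  cat(sprintf(
    "stranded_coverage '%s' (%s ends): %d chromosome(s), total signal %s\n",
    x$sample_id, x$end_convention, length(x$chrom_sizes),
    format(total_signal(x))))
  invisible(x)
}

#' Total signal in a coverage object
#'
#' Sum over both strands of all per-base counts; equals the number of
#' fragments when the coverage was built by [fragments_to_end_coverage()].
#'
#' @param cov a `stranded_coverage`.
#' @param strand optionally restrict to `"+"` or `"-"`.
#' @export
total_signal <- function(cov, strand = NULL) {
  p <- sum(vapply(cov$plus, sum, numeric(1)))
  m <- sum(vapply(cov$minus, sum, numeric(1)))
  if (is.null(strand)) p + m else if (strand == "+") p else m
}

strand_slot <- function(strand) if (strand == "+") "plus" else "minus"

#' Reduce stranded fragments to single-base end coverage
#'
#' Each fragment contributes exactly one unit at its 3'-most (or 5'-most)
#' base on its transcript strand, the standard reduction that makes
#' promoter window counting insensitive to fragment length. With a
#' reverse-stranded library (the default, as for dUTP-based protocols) the
#' transcript strand is the opposite of the recorded fragment strand; with
#' a forward library they coincide.
#'
#' @param fragments `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open) and `strand` (fragment orientation).
#' @param chrom_sizes named integer vector.
#' @param end_convention `"3prime"` (default) or `"5prime"`.
#' @param library_strandness `"reverse"` (default) or `"forward"`.
#' @param sample_id metadata label.
#' @return A `stranded_coverage` whose total signal equals `nrow(fragments)`.
#' @export
fragments_to_end_coverage <- function(fragments, chrom_sizes,
                                      end_convention = c("3prime", "5prime"),
                                      library_strandness = c("reverse",
                                                             "forward"),
                                      sample_id = "sample") {
  end_convention <- match.arg(end_convention)
  library_strandness <- match.arg(library_strandness)
  cov <- stranded_coverage(chrom_sizes, sample_id, end_convention)
  if (nrow(fragments) == 0) return(cov)
  check_strand(fragments$strand, "fragment")
  bad_chrom <- !fragments$chrom %in% names(chrom_sizes)
  if (any(bad_chrom)) {
    i <- which(bad_chrom)[1]
    stopf("fragment %d on unknown chromosome '%s'", i, fragments$chrom[i])
  }
  len <- chrom_sizes[fragments$chrom]
  out_of_bounds <- fragments$start < 0 | fragments$end > len |
    fragments$start >= fragments$end
  if (any(out_of_bounds)) {
    i <- which(out_of_bounds)[1]
    stopf("fragment %d (%s:%d-%d, %s) outside chromosome bounds or empty",
          i, fragments$chrom[i], fragments$start[i], fragments$end[i],
          fragments$strand[i])
  }
  tstrand <- if (library_strandness == "forward") {
    fragments$strand
  } else {
    ifelse(fragments$strand == "+", "-", "+")
  }
  # 3' end of a + fragment is its rightmost base; of a - fragment its
  # leftmost. 5' is the mirror.
  right_end <- (tstrand == "+") == (end_convention == "3prime")
  pos <- ifelse(right_end, fragments$end - 1L, fragments$start)
  for (chrom in unique(fragments$chrom)) {
    n <- chrom_sizes[[chrom]]
    for (s in c("+", "-")) {
      sel <- fragments$chrom == chrom & tstrand == s
      if (!any(sel)) next
      slot <- strand_slot(s)
      cov[[slot]][[chrom]] <- cov[[slot]][[chrom]] +
        tabulate(pos[sel] + 1L, nbins = n)
    }
  }
  cov
}

#' Write one strand of a coverage object as bedGraph
#'
#' Run-length encodes the per-base vector; zero runs are omitted, so an
#' all-zero strand produces an empty file. Output is 0-based half-open and
#' sorted by (chromosome, start).
#'
#' @param cov a `stranded_coverage`.
#' @param strand `"+"` or `"-"`.
#' @param path output path.
#' @export
write_bedgraph <- function(cov, strand, path) {
  check_strand(strand, "strand argument")
  vecs <- cov[[strand_slot(strand)]]
  lines <- character(0)
  for (chrom in sort(names(vecs))) {
    r <- rle(vecs[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", chrom, starts[keep],
                              ends[keep], format(r$values[keep],
                                                 scientific = FALSE,
                                                 trim = TRUE)))
  }
  writeLines(lines, path)
  invisible(path)
}

# Parse a bedGraph into per-chromosome dense vectors, validating bounds,
# chromosome names and interval disjointness.
bedgraph_to_vectors <- function(path, chrom_sizes) {
  vecs <- lapply(chrom_sizes, function(n) numeric(n))
  if (!file.exists(path)) stopf("bedGraph not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) stopf("failed to parse bedGraph %s: %s",
                                           path, conditionMessage(e)))
  if (length(gr) == 0) return(vecs)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  unknown <- !chrom %in% names(chrom_sizes)
  if (any(unknown)) {
    stopf("bedGraph %s: unknown chromosome '%s'", path,
          chrom[which(unknown)[1]])
  }
  if (any(GenomicRanges::end(gr) > chrom_sizes[chrom])) {
    stopf("bedGraph %s: interval beyond chromosome end", path)
  }
  self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  if (length(self) > 0) stopf("bedGraph %s: overlapping intervals", path)
  score <- S4Vectors::mcols(gr)$score
  for (i in seq_along(gr)) {
    vecs[[chrom[i]]][GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <-
      score[i]
  }
  vecs
}

#' Read a bedGraph into one strand of a coverage object
#'
#' Inverse of [write_bedgraph()]: the write/read round trip reproduces the
#' per-base vector exactly. Overlapping intervals or unknown chromosomes
#' are errors.
#'
#' @param path bedGraph path.
#' @param chrom_sizes named integer vector.
#' @param strand which strand the file holds.
#' @param into optional existing `stranded_coverage` to fill (so a
#'   plus/minus pair can be assembled); a fresh object is created otherwise.
#' @inheritParams stranded_coverage
#' @export
read_bedgraph <- function(path, chrom_sizes, strand, into = NULL,
                          sample_id = "sample",
                          end_convention = "3prime") {
  check_strand(strand, "strand argument")
  cov <- into %||% stranded_coverage(chrom_sizes, sample_id, end_convention)
  cov[[strand_slot(strand)]] <- bedgraph_to_vectors(path, cov$chrom_sizes)
  cov
}

#' Read a plus/minus bedGraph pair
#'
#' @param plus_path,minus_path per-strand bedGraph files of one sample.
#' @inheritParams read_bedgraph
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, chrom_sizes,
                               sample_id = "sample",
                               end_convention = "3prime") {
  cov <- read_bedgraph(plus_path, chrom_sizes, "+", sample_id = sample_id,
                       end_convention = end_convention)
  read_bedgraph(minus_path, chrom_sizes, "-", into = cov)
}

#' Sum coverage in a window
#'
#' @param cov a `stranded_coverage`.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 0-based half-open window, inside the chromosome (the
#'   caller clips explicitly; out-of-bounds windows are errors).
#' @export
count_window <- function(cov, chrom, strand, start, end) {
  if (!chrom %in% names(cov$chrom_sizes)) {
    stopf("unknown chromosome '%s'", chrom)
  }
  n <- cov$chrom_sizes[[chrom]]
  if (start < 0 || end > n || start >= end) {
    stopf("window [%d,%d) outside chromosome %s (length %d)",
          start, end, chrom, n)
  }
  check_strand(strand, "strand argument")
  sum(cov[[strand_slot(strand)]][[chrom]][(start + 1L):end])
}

#' Count sense and antisense promoter-window signal
#'
#' For a `+` strand gene with TSS `t`, the sense window is `[t, t+window)`
#' on the coding strand and the antisense (divergent) window `[t-window, t)`
#' on the opposite strand — nucleotide positions +1..+500 and -1..-500
#' relative to the TSS at the default window of 500. Minus-strand genes are
#' the exact mirror. Windows truncated at chromosome edges are computed
#' over the truncated span and flagged.
#'
#' @param genes a gene table (normally the tandem subset from
#'   [classify_promoters()]).
#' @param cov a `stranded_coverage`.
#' @param window window length in bases.
#' @return `data.frame` with `gene_id`, `sense`, `antisense`, `clipped`.
#' @export
count_promoter_windows <- function(genes, cov, window = 500L) {
  stopifnot(window > 0)
  n <- nrow(genes)
  sense <- antisense <- numeric(n)
  clipped <- logical(n)
  for (i in seq_len(n)) {
    chrom <- genes$chrom[i]
    if (!chrom %in% names(cov$chrom_sizes)) {
      stopf("gene %s on unknown chromosome '%s'", genes$gene_id[i], chrom)
    }
    len <- cov$chrom_sizes[[chrom]]
    t <- genes$tss[i]
    if (genes$strand[i] == "+") {
      s_win <- c(t, t + window)
      a_win <- c(t - window, t)
      s_strand <- "+"; a_strand <- "-"
    } else {
      s_win <- c(t - window + 1L, t + 1L)
      a_win <- c(t + 1L, t + window + 1L)
      s_strand <- "-"; a_strand <- "+"
    }
    wins <- rbind(s_win, a_win)
    lo <- pmax(wins[, 1], 0L)
    hi <- pmin(wins[, 2], len)
    clipped[i] <- any(lo != wins[, 1]) || any(hi != wins[, 2])
    wins <- cbind(lo, hi)
    sense[i] <- if (wins[1, 1] < wins[1, 2]) {
      count_window(cov, chrom, s_strand, wins[1, 1], wins[1, 2])
    } else 0
    antisense[i] <- if (wins[2, 1] < wins[2, 2]) {
      count_window(cov, chrom, a_strand, wins[2, 1], wins[2, 2])
    } else 0
  }
  data.frame(gene_id = genes$gene_id, sense = sense, antisense = antisense,
             clipped = clipped, stringsAsFactors = FALSE)
}

#' Count signal around anchor points, per strand
#'
#' Counts coverage in `[pos - flank, pos + flank)` around each anchor (for
#' example a set of transcription-factor binding sites), separately for the
#' Watson and Crick strands, yielding exactly `2 * n` rows for `n` anchors.
#'
#' @param anchors `data.frame` with `chrom` and `pos` (0-based); an
#'   optional `name` column is carried through.
#' @param cov a `stranded_coverage`.
#' @param flank half-width in bases.
#' @return `data.frame` with `name`, `chrom`, `pos`, `strand`, `count`.
#' @export
count_anchored_intervals <- function(anchors, cov, flank = 100L) {
  stopifnot(flank > 0)
  n <- nrow(anchors)
  name <- anchors$name %||% sprintf("anchor_%d", seq_len(n))
  out <- data.frame(
    name = rep(name, each = 2L),
    chrom = rep(anchors$chrom, each = 2L),
    pos = rep(anchors$pos, each = 2L),
    strand = rep(c("+", "-"), times = n),
    count = NA_real_, stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    chrom <- anchors$chrom[i]
    if (!chrom %in% names(cov$chrom_sizes)) {
      stopf("anchor %d on unknown chromosome '%s'", i, chrom)
    }
    len <- cov$chrom_sizes[[chrom]]
    lo <- anchors$pos[i] - flank
    hi <- anchors$pos[i] + flank
    if (lo < 0 || hi > len) {
      stopf("anchor %d interval [%d,%d) outside chromosome %s", i, lo, hi,
            chrom)
    }
    out$count[2L * i - 1L] <- count_window(cov, chrom, "+", lo, hi)
    out$count[2L * i] <- count_window(cov, chrom, "-", lo, hi)
  }
  out
}
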