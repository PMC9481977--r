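# Promoter motif scanning, positional profiles around the TSS, and
# group-wise enrichment.

#' Define a motif
#'
#' Patterns are strings over A/C/G/T with single-position alternatives in
#' brackets, e.g. `"AAAAAAA"` (the A-track associated with RSC recruitment
#' and nucleosome exclusion) or `"CG[CG]G"` / `"CG[C/G]G"` (the GC-rich
#' motif). `scan_strand` chooses whether the pattern is matched on the
#' given (sense/coding) strand or on its reverse complement, with match
#' coordinates always reported on the input sequence.
#'
#' @param name motif label.
#' @param pattern pattern string; `/` separators inside brackets are
#'   ignored.
#' @param scan_strand `"sense"` or `"antisense"`.
#' @return A `motif_spec` object (list with `name`, `sets`, `iupac`,
#'   `length`, `scan_strand`).
#' @export
motif_spec <- function(name, pattern,
                       scan_strand = c("sense", "antisense")) {
  scan_strand <- match.arg(scan_strand)
  clean <- gsub("/", "", pattern, fixed = TRUE)
  toks <- regmatches(clean,
                     gregexpr("\\[[ACGT]+\\]|[ACGT]", clean))[[1]]
  if (length(toks) == 0 || sum(nchar(gsub("[^ACGT\\[\\]]", "", toks))) <
        nchar(gsub("[^ACGT\\[\\]]", "", clean))) {
    stopf("cannot parse motif pattern '%s'", pattern)
  }
  sets <- lapply(toks, function(t) {
    sort(unique(strsplit(gsub("\\[|\\]", "", t), "")[[1]]))
  })
  iupac <- paste(vapply(sets, function(s) {
    Biostrings::mergeIUPACLetters(paste(s, collapse = ""))
  }, character(1)), collapse = "")
  structure(list(name = name, sets = sets, iupac = iupac,
                 length = length(sets), scan_strand = scan_strand),
            class = "motif_spec")
}

#' The A-track motif (AAAAAAA)
#' @inheritParams motif_spec
#' @export
motif_atrack <- function(scan_strand = "sense") {
  motif_spec("A-track", "AAAAAAA", scan_strand)
}

#' The GC-rich motif CG(C/G)G
#' @inheritParams motif_spec
#' @export
motif_gc <- function(scan_strand = "sense") {
  motif_spec("CG(C/G)G", "CG[CG]G", scan_strand)
}

#' Scan a sequence for motif matches
#'
#' Returns all 0-based start positions, overlapping matches included, in
#' ascending order. `N` bases never match. Antisense scanning matches the
#' reverse complement of the sequence and maps each hit back to the
#' leftmost base of its footprint in input coordinates.
#'
#' @param sequence a character string or `DNAString` over A/C/G/T/N.
#' @param motif a `motif_spec`.
#' @return Integer vector of 0-based match start positions.
#' @export
scan_motif <- function(sequence, motif) {
  subject <- if (inherits(sequence, "DNAString")) sequence else {
    Biostrings::DNAString(sequence)
  }
  L <- length(subject)
  if (L < motif$length) return(integer(0))
  if (motif$scan_strand == "antisense") {
    subject <- Biostrings::reverseComplement(subject)
  }
  # Pattern ambiguities are IUPAC-expanded; subject letters stay literal,
  # so N in the sequence matches nothing.
  m <- Biostrings::matchPattern(motif$iupac, subject,
                                fixed = c(pattern = FALSE, subject = TRUE))
  starts <- IRanges::start(m) - 1L
  if (motif$scan_strand == "antisense") {
    starts <- sort(L - starts - motif$length)
  }
  as.integer(starts)
}

# Extract the strand-oriented promoter sequence covering TSS offsets
# [-flank, flank): for a minus-strand gene the genomic span is
# [tss-flank+1, tss+flank+1) reverse-complemented, so position i of the
# result is always TSS offset i - flank in the coding direction.
promoter_sequence <- function(gene, genome, flank) {
  chrom <- gene$chrom
  if (!chrom %in% names(genome)) {
    stopf("genome lacks chromosome '%s'", chrom)
  }
  len <- length(genome[[chrom]])
  if (gene$strand == "+") {
    lo <- gene$tss - flank
    hi <- gene$tss + flank
  } else {
    lo <- gene$tss - flank + 1L
    hi <- gene$tss + flank + 1L
  }
  if (lo < 0 || hi > len) return(NULL)
  s <- Biostrings::subseq(genome[[chrom]], lo + 1L, hi)
  if (gene$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet")) {
    stopf("genome must be a named DNAStringSet or character vector")
  }
  if (is.null(names(genome))) stopf("genome sequences must be named")
  genome
}

#' Positional motif profile around TSSs
#'
#' For each offset `p` in `[-flank, flank)` relative to the TSS (TSS = 0),
#' the fraction of promoters with a motif match starting at `p` in the
#' strand-oriented promoter sequence (minus-strand promoters are
#' reverse-complemented first, so "sense" always means the coding strand).
#' Promoters whose window overhangs a chromosome end are skipped and
#' counted in the `n_skipped` attribute. Matches must fit inside the
#' window.
#'
#' @param genes a gene table.
#' @param genome named `DNAStringSet` (or named character vector).
#' @param motif a `motif_spec`.
#' @param flank half-width of the window (default 500).
#' @return `data.frame` with `offset` and `fraction`; attributes `n_genes`
#'   (used) and `n_skipped`.
#' @export
motif_profile <- function(genes, genome, motif, flank = 500L) {
  genome <- as_genome(genome)
  width <- 2L * flank
  counts <- integer(width)
  used <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    s <- promoter_sequence(genes[i, ], genome, flank)
    if (is.null(s)) {
      skipped <- skipped + 1L
      next
    }
    used <- used + 1L
    starts <- scan_motif(s, motif)
    if (length(starts) > 0) {
      counts[starts + 1L] <- counts[starts + 1L] + 1L
    }
  }
  if (skipped > 0) {
    log_info("motif_profile: skipped %d promoter(s) overhanging chromosome ends",
             skipped)
  }
  out <- data.frame(
    offset = seq.int(-flank, flank - 1L),
    fraction = if (used > 0) counts / used else rep(NA_real_, width)
  )
  attr(out, "n_genes") <- used
  attr(out, "n_skipped") <- skipped
  out
}

# Per-promoter motif match counts in the oriented [-flank, flank) window.
promoter_match_counts <- function(genes, genome, motif, flank) {
  genome <- as_genome(genome)
  vapply(seq_len(nrow(genes)), function(i) {
    s <- promoter_sequence(genes[i, ], genome, flank)
    if (is.null(s)) return(NA_integer_)
    length(scan_motif(s, motif))
  }, integer(1))
}

#' Motif enrichment between two promoter groups
#'
#' Compares per-promoter match counts in the `[-flank, flank)` window
#' between two gene groups: fold enrichment is the ratio of pseudocounted
#' group means, `(mean_A + 0.5) / (mean_B + 0.5)`, and the p-value comes
#' from a two-sided Mann-Whitney rank-sum test on the per-promoter counts.
#'
#' @param groupA_genes,groupB_genes nonempty gene tables.
#' @inheritParams motif_profile
#' @return A list with `fold_enrichment`, `p_value`, `higher_group`
#'   (`"A"`, `"B"` or `"none"`), `mean_A`, `mean_B`, `n_A`, `n_B`.
#' @export
motif_enrichment <- function(groupA_genes, groupB_genes, genome, motif,
                             flank = 500L) {
  if (nrow(groupA_genes) == 0 || nrow(groupB_genes) == 0) {
    stopf("both promoter groups must be nonempty")
  }
  cA <- promoter_match_counts(groupA_genes, genome, motif, flank)
  cB <- promoter_match_counts(groupB_genes, genome, motif, flank)
  cA <- cA[!is.na(cA)]
  cB <- cB[!is.na(cB)]
  if (length(cA) == 0 || length(cB) == 0) {
    stopf("all promoters in a group overhang chromosome ends")
  }
  enrichment_test(cA, cB)
}

#' Rank-sum enrichment test on per-promoter counts
#'
#' The statistical core of [motif_enrichment()], usable on any pair of
#' per-promoter count vectors: fold enrichment
#' `(mean_A + 0.5) / (mean_B + 0.5)` and a two-sided Mann-Whitney p-value.
#' Two all-zero groups yield fold 1 and p 1.
#'
#' @param countsA,countsB non-negative per-promoter match counts.
#' @return A list with `fold_enrichment`, `p_value`, `higher_group`,
#'   `mean_A`, `mean_B`, `n_A`, `n_B`.
#' @export
enrichment_test <- function(countsA, countsB) {
  stopifnot(length(countsA) > 0, length(countsB) > 0)
  mA <- mean(countsA)
  mB <- mean(countsB)
  if (all(countsA == 0) && all(countsB == 0)) {
    p <- 1
    fold <- 1
  } else {
    fold <- (mA + 0.5) / (mB + 0.5)
    p <- suppressWarnings(
      wilcox.test(countsA, countsB, alternative = "two.sided",
                  exact = FALSE)$p.value)
    # all-tie degenerate case: the normal approximation yields 0/0
    if (is.na(p)) p <- 1
  }
  list(
    fold_enrichment = fold,
    p_value = p,
    higher_group = if (mA > mB) "A" else if (mB > mA) "B" else "none",
    mean_A = mA, mean_B = mB, n_A = length(countsA), n_B = length(countsB)
  )
}
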