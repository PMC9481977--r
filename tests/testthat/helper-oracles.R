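# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-fragment / per-position loops, character-level
# motif comparison) so they are independent of the implementation paths
# they check.

# Per-fragment loop tally of end coverage.
naive_end_tally <- function(fragments, chrom_sizes,
                            end_convention = "3prime",
                            library_strandness = "forward") {
  vecs <- list(
    plus = lapply(chrom_sizes, function(n) integer(n)),
    minus = lapply(chrom_sizes, function(n) integer(n))
  )
  for (i in seq_len(nrow(fragments))) {
    s <- fragments$strand[i]
    ts <- if (library_strandness == "forward") s else setdiff(c("+", "-"), s)
    pos <- if ((ts == "+") == (end_convention == "3prime")) {
      fragments$end[i] - 1L
    } else {
      fragments$start[i]
    }
    slot <- if (ts == "+") "plus" else "minus"
    chrom <- fragments$chrom[i]
    vecs[[slot]][[chrom]][pos + 1L] <- vecs[[slot]][[chrom]][pos + 1L] + 1L
  }
  vecs
}

# Position-by-position window sum.
naive_window_sum <- function(vec, start, end) {
  total <- 0
  for (p in seq.int(start, end - 1L)) total <- total + vec[p + 1L]
  total
}

# Character-level sliding-window motif scan; sets = list of allowed bases
# per position; antisense via explicit reverse complement.
naive_scan <- function(sequence, sets, scan_strand = "sense") {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(sequence, "")[[1]]
  if (scan_strand == "antisense") chars <- rev(unname(comp[chars]))
  L <- length(chars)
  k <- length(sets)
  hits <- integer(0)
  if (L >= k) {
    for (p in 0:(L - k)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!chars[p + j] %in% sets[[j]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) hits <- c(hits, p)
    }
  }
  if (scan_strand == "antisense" && length(hits) > 0) {
    hits <- sort(L - hits - k)
  }
  hits
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_fragments <- function(n, chrom_sizes, max_len = 80L) {
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(chrom_sizes[[chrom[i]]] - len[i], 1L) - 1L
  }, integer(1))
  data.frame(chrom = chrom, start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Mirror a gene set: flip strands and reflect coordinates through the
# chromosome length, preserving every pairwise geometric relation.
mirror_genes <- function(genes, chrom_len) {
  gene_table(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    strand = ifelse(genes$strand == "+", "-", "+"),
    start = chrom_len - genes$end,
    end = chrom_len - genes$start
  )
}

# Small deterministic two-gene fixture on one chromosome.
demo_genes <- function() {
  gene_table(
    gene_id = c("gA", "gB"),
    chrom = "chr1",
    strand = c("+", "-"),
    start = c(2000L, 6000L),
    end = c(3500L, 7500L)
  )
}
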