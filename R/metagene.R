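# TSS-anchored metagene matrices and profiles for unstranded per-base
# tracks (MNase-seq / CUT&RUN-style occupancy).

#' Read an unstranded per-base track from bedGraph
#'
#' @param path bedGraph path.
#' @param chrom_sizes named integer vector.
#' @return A named list of per-chromosome numeric vectors (a "track").
#' @export
read_track <- function(path, chrom_sizes) {
  chrom_sizes <- setNames(as.integer(chrom_sizes), names(chrom_sizes))
  bedgraph_to_vectors(path, chrom_sizes)
}

#' Sum-normalize and log-transform a track
#'
#' Divides every value by the track's total signal (so samples of
#' different depth become comparable) and applies
#' `log2(value + pseudocount)`. Doubling every input value leaves the
#' output unchanged.
#'
#' @param track named list of non-negative per-chromosome vectors.
#' @param pseudocount small positive value added before the log
#'   (default 1e-6).
#' @export
normalize_track <- function(track, pseudocount = 1e-6) {
  total <- sum(vapply(track, sum, numeric(1)))
  if (!is.finite(total) || total <= 0) {
    stopf("track has zero (or non-finite) total signal")
  }
  lapply(track, function(v) log2(v / total + pseudocount))
}

#' TSS-anchored signal matrix
#'
#' One row per gene, one column per offset in `[-upstream, downstream)`
#' relative to the TSS at single-base resolution, oriented so transcription
#' runs left to right: for a `+` gene column `j` (1-based) holds the signal
#' at `tss - upstream + (j-1)`; for a `-` gene, at
#' `tss + upstream - (j-1)`. Positions off the chromosome are `NA`
#' (missing, distinct from 0). With `skip_zeros`, all-zero rows are
#' dropped and their number logged.
#'
#' @param genes a gene table.
#' @param track named list of per-chromosome numeric vectors.
#' @param upstream,downstream bases before/after the TSS (defaults 500).
#' @param skip_zeros drop rows whose observed values are all zero.
#' @return Numeric matrix with rownames `gene_id` and colnames the
#'   offsets.
#' @export
matrix_at_tss <- function(genes, track, upstream = 500L, downstream = 500L,
                          skip_zeros = FALSE) {
  width <- upstream + downstream
  offsets <- seq.int(-upstream, downstream - 1L)
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = width,
                dimnames = list(genes$gene_id, offsets))
  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chrom[i]
    if (!chrom %in% names(track)) {
      stopf("track lacks chromosome '%s'", chrom)
    }
    v <- track[[chrom]]
    len <- length(v)
    pos <- if (genes$strand[i] == "+") {
      genes$tss[i] + offsets
    } else {
      genes$tss[i] - offsets
    }
    inside <- pos >= 0 & pos < len
    mat[i, inside] <- v[pos[inside] + 1L]
  }
  if (skip_zeros) {
    all_zero <- apply(mat, 1, function(r) {
      obs <- r[!is.na(r)]
      length(obs) > 0 && all(obs == 0)
    })
    if (any(all_zero)) {
      log_info("matrix_at_tss: dropped %d all-zero row(s)", sum(all_zero))
      mat <- mat[!all_zero, , drop = FALSE]
    }
  }
  mat
}

#' Column-wise mean profile of a signal matrix
#'
#' Per-offset mean across genes, ignoring missing values; offsets with no
#' observations are `NA`.
#'
#' @param matrix output of [matrix_at_tss()] (at least one row).
#' @return `data.frame` with `offset`, `mean`, `n`.
#' @export
mean_profile <- function(matrix) {
  if (nrow(matrix) == 0) stopf("matrix has no rows")
  n <- colSums(!is.na(matrix))
  m <- suppressWarnings(colMeans(matrix, na.rm = TRUE))
  m[n == 0] <- NA_real_
  data.frame(offset = as.integer(colnames(matrix)), mean = as.numeric(m),
             n = as.integer(n))
}
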