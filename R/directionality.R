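# Directionality scores, spike-in size factors, condition-wise changes and
# quintile stratification.

#' Promoter directionality score
#'
#' For one promoter, a pseudocount is added to every replicate count, the
#' replicates are averaged, and the score is
#' `D = log10(S / A)` with `S` and `A` the pseudocounted mean sense and
#' antisense signals. The pseudocount is applied per replicate *before*
#' averaging, which matters at low counts; with the default pseudocount of
#' 1, `S >= 1` and `A >= 1`, so `D` is always finite and positive exactly
#' when sense signal exceeds antisense signal.
#'
#' @param sense_reps,antisense_reps non-negative per-replicate window
#'   counts, equal length.
#' @param pseudocount value added to every count (default 1).
#' @return A list with `S`, `A` and `D`.
#' @export
directionality_score <- function(sense_reps, antisense_reps,
                                 pseudocount = 1) {
  if (length(sense_reps) == 0) stopf("at least one replicate required")
  if (length(sense_reps) != length(antisense_reps)) {
    stopf("sense and antisense must have the same number of replicates")
  }
  stopifnot(all(sense_reps >= 0), all(antisense_reps >= 0))
  S <- mean(sense_reps + pseudocount)
  A <- mean(antisense_reps + pseudocount)
  list(S = S, A = A, D = log10(S / A))
}

#' Per-gene directionality table from replicate count matrices
#'
#' Vectorised form of [directionality_score()] over a gene-by-replicate
#' pair of matrices (rows = genes, columns = biological replicates).
#'
#' @param sense_mat,antisense_mat numeric matrices with identical
#'   dimensions and rownames (gene ids).
#' @inheritParams directionality_score
#' @return `data.frame` with `gene_id`, `S`, `A`, `D`, `n_replicates`.
#' @export
directionality_table <- function(sense_mat, antisense_mat, pseudocount = 1) {
  sense_mat <- as.matrix(sense_mat)
  antisense_mat <- as.matrix(antisense_mat)
  stopifnot(identical(dim(sense_mat), dim(antisense_mat)))
  if (ncol(sense_mat) == 0) stopf("at least one replicate required")
  if (nrow(sense_mat) == 0) {
    return(data.frame(gene_id = character(), S = numeric(), A = numeric(),
                      D = numeric(), n_replicates = integer(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(rownames(sense_mat))) stopf("count matrices need gene rownames")
  S <- rowMeans(sense_mat + pseudocount)
  A <- rowMeans(antisense_mat + pseudocount)
  reset_rownames(data.frame(
    gene_id = rownames(sense_mat), S = S, A = A, D = log10(S / A),
    n_replicates = ncol(sense_mat), stringsAsFactors = FALSE
  ))
}

#' Spike-in median-of-ratios size factors
#'
#' DESeq2-style median-of-ratios normalisation restricted to spike-in
#' genes, so that a global shift in the main genome's transcription does
#' not distort the scale: for sample `j`,
#' `sf_j = median_i( count_ij / geomean_i )` over spike-in genes `i` with
#' nonzero counts in every sample, where `geomean_i` is the across-sample
#' geometric mean of gene `i`.
#'
#' @param count_matrix non-negative gene-by-sample count matrix with
#'   rownames.
#' @param spikein_ids rownames designating spike-in genes.
#' @return A list with `size_factors` (named, one per sample, all > 0) and
#'   `spikein_used` (ids that entered the median).
#' @export
spikein_size_factors <- function(count_matrix, spikein_ids) {
  count_matrix <- as.matrix(count_matrix)
  if (is.null(rownames(count_matrix))) stopf("count matrix needs rownames")
  missing <- setdiff(spikein_ids, rownames(count_matrix))
  if (length(missing) > 0) {
    stopf("spike-in ids absent from count matrix (e.g. '%s')", missing[1])
  }
  sub <- count_matrix[spikein_ids, , drop = FALSE]
  usable <- rowSums(sub > 0) == ncol(sub)
  if (!any(usable)) {
    stopf("no spike-in gene has nonzero counts in all samples")
  }
  sub <- sub[usable, , drop = FALSE]
  log_geomean <- rowMeans(log(sub))
  sf <- apply(sub, 2, function(cnt) exp(median(log(cnt) - log_geomean)))
  sf <- setNames(as.numeric(sf), colnames(count_matrix))
  list(size_factors = sf, spikein_used = rownames(sub))
}

#' Log2 fold change of normalized, pseudocounted counts
#'
#' `log2( ((count_t / sf_t) + pseudocount) / ((count_c / sf_c) + pseudocount) )`.
#' A plain ratio, not a shrunken estimate. Vectorised.
#'
#' @param count_t,count_c non-negative counts (treatment, control).
#' @param sf_t,sf_c positive size factors.
#' @param pseudocount added after normalization.
#' @export
log2fc <- function(count_t, count_c, sf_t = 1, sf_c = 1, pseudocount = 1) {
  stopifnot(all(count_t >= 0), all(count_c >= 0), all(sf_t > 0),
            all(sf_c > 0))
  log2((count_t / sf_t + pseudocount) / (count_c / sf_c + pseudocount))
}

#' Change in directionality score on the log2 scale
#'
#' Directionality scores live on the log10 scale; condition-wise changes
#' are conventionally reported as log2 fold changes, so the difference is
#' converted exactly: `delta = (D_t - D_c) * log2(10)`. When both scores
#' derive from the same pseudocounted means,
#' `delta == log2FC_sense - log2FC_antisense`.
#'
#' @param D_t,D_c finite directionality scores (log10).
#' @export
directionality_change <- function(D_t, D_c) {
  (D_t - D_c) * log2(10)
}

#' Condition-wise change table
#'
#' Combines two per-condition directionality tables (same genes, same
#' order) into per-gene log2 fold changes of divergent (antisense) and
#' sense signal plus the directionality change, all computed from the
#' pseudocounted means so that
#' `delta_directionality == log2FC_sense - log2FC_divergent` holds exactly.
#' Size factors, when supplied, rescale the means before the ratio.
#'
#' @param dir_t,dir_c outputs of [directionality_table()] for treatment and
#'   control.
#' @param sf_t,sf_c positive size factors applied to the respective
#'   condition's means.
#' @return `data.frame` with `gene_id`, `log2FC_divergent`, `log2FC_sense`,
#'   `delta_directionality`.
#' @export
change_table <- function(dir_t, dir_c, sf_t = 1, sf_c = 1) {
  if (!identical(dir_t$gene_id, dir_c$gene_id)) {
    stopf("condition tables must cover the same genes in the same order")
  }
  stopifnot(sf_t > 0, sf_c > 0)
  l2_sense <- log2((dir_t$S / sf_t) / (dir_c$S / sf_c))
  l2_div <- log2((dir_t$A / sf_t) / (dir_c$A / sf_c))
  data.frame(
    gene_id = dir_t$gene_id,
    log2FC_divergent = l2_div,
    log2FC_sense = l2_sense,
    delta_directionality = l2_sense - l2_div,
    stringsAsFactors = FALSE
  )
}

#' Stratify genes into quintiles by score
#'
#' Equal-count stratification: genes are stably sorted by
#' `(score, gene_id)` ascending and split into `n_groups` contiguous
#' groups whose sizes differ by at most one, remainders going to the low
#' end. `Q1` holds the lowest scores, `Q5` the highest.
#'
#' @param scores named numeric vector (names = gene ids) of finite scores.
#' @param n_groups number of strata (default 5).
#' @return A list with `assignment` (`gene_id`, `score`, `quintile`) and
#'   `summary` (`quintile`, `min`, `max`, `size`).
#' @export
stratify_quintiles <- function(scores, n_groups = 5L) {
  if (is.null(names(scores))) stopf("scores must be named by gene id")
  if (!all(is.finite(scores))) stopf("scores must be finite")
  n <- length(scores)
  if (n < n_groups) stopf("need at least %d genes, got %d", n_groups, n)
  ord <- order(scores, names(scores))
  base <- n %/% n_groups
  rem <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, rem), rep(0L, n_groups - rem))
  labels <- sprintf("Q%d", seq_len(n_groups))
  quintile <- rep(labels, times = sizes)
  assignment <- data.frame(
    gene_id = names(scores)[ord],
    score = as.numeric(scores[ord]),
    quintile = quintile,
    stringsAsFactors = FALSE
  )
  summ <- do.call(rbind, lapply(labels, function(q) {
    s <- assignment$score[assignment$quintile == q]
    data.frame(quintile = q, min = min(s), max = max(s), size = length(s),
               stringsAsFactors = FALSE)
  }))
  list(assignment = reset_rownames(assignment), summary = reset_rownames(summ))
}
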