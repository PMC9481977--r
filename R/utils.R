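# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

log_info <- function(fmt, ...) message(sprintf(paste0("INFO: ", fmt), ...))

# Strand symbols accepted everywhere; anything else is an input error.
check_strand <- function(strand, where = "record") {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stopf("unknown strand symbol '%s' in %s %d",
          strand[which(bad)[1]], where, which(bad)[1])
  }
  invisible(strand)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Sort a gene table deterministically by (chrom, start, gene_id).
sort_genes <- function(genes) {
  genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
}

reset_rownames <- function(df) {
  rownames(df) <- NULL
  df
}
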