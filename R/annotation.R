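# Gene annotation handling: parsing, TSS curation and promoter
# classification. All coordinates are 0-based half-open internally; GFF3 is
# converted at parse time, BED is native.

#' Construct a gene table
#'
#' The gene table is the package's central annotation structure: one row per
#' gene with a single TSS. Coordinates are 0-based half-open. The TSS
#' defaults to the strand-appropriate gene boundary (`start` on `+`,
#' `end - 1` on `-`) and is flagged `annotation` until replaced by a curated
#' entry (see [apply_curated_tss()]).
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param start,end 0-based half-open gene body coordinates, `start < end`.
#' @param tss optional 0-based TSS positions; defaults to the boundary
#'   implied by the strand.
#' @param tss_source `"annotation"` or `"curated"`, recycled.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `tss`, `tss_source`, sorted by `(chrom, start,
#'   gene_id)`.
#' @export
gene_table <- function(gene_id, chrom, strand, start, end,
                       tss = NULL, tss_source = "annotation") {
  gene_id <- as.character(gene_id)
  n <- length(gene_id)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  check_strand(strand, "gene")
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start >= end)) {
    stopf("gene %s has start >= end", gene_id[which(start >= end)[1]])
  }
  if (anyDuplicated(gene_id)) {
    stopf("duplicated gene_id '%s'", gene_id[duplicated(gene_id)][1])
  }
  if (is.null(tss)) {
    tss <- ifelse(strand == "+", start, end - 1L)
  }
  df <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start, end = end, tss = as.integer(tss),
    tss_source = rep_len(as.character(tss_source), n),
    stringsAsFactors = FALSE
  )
  reset_rownames(sort_genes(df))
}

# Light line-level validation so parse errors can name the offending line.
validate_annotation_lines <- function(lines, format) {
  n_fields <- if (format == "gff3") 9L else 6L
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "track")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < n_fields) {
      stopf("malformed %s line %d: expected %d tab-separated fields, got %d",
            toupper(format), i, n_fields, length(fields))
    }
    coord_idx <- if (format == "gff3") c(4L, 5L) else c(2L, 3L)
    if (anyNA(suppressWarnings(as.integer(fields[coord_idx])))) {
      stopf("malformed %s line %d: non-numeric coordinates", toupper(format), i)
    }
    strand_idx <- if (format == "gff3") 7L else 6L
    if (!fields[strand_idx] %in% c("+", "-")) {
      stopf("unknown strand symbol '%s' on line %d", fields[strand_idx], i)
    }
  }
  invisible(TRUE)
}

#' Read a gene annotation
#'
#' Reads GFF3 (1-based inclusive, converted) or BED6 (native 0-based
#' half-open) into a gene table. Gene identifiers come from the GFF3 `ID`
#' (falling back to `Name`) attribute or the BED name field. Malformed lines
#' raise an error naming the line number; unknown strand symbols are errors.
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed6"`.
#' @return A gene table (see [gene_table()]); empty input yields a
#'   zero-row table.
#' @export
read_annotation <- function(path, format = c("gff3", "bed6")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path)
  validate_annotation_lines(lines, format)
  body <- lines[!(lines == "" | startsWith(lines, "#") |
                    startsWith(lines, "track"))]
  if (length(body) == 0) {
    return(gene_table(character(), character(), character(),
                      integer(), integer())[0, ])
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    ids <- as.character(S4Vectors::mcols(gr)$ID %||% rep(NA, length(gr)))
    if ("Name" %in% names(S4Vectors::mcols(gr))) {
      nm <- as.character(S4Vectors::mcols(gr)$Name)
      ids[is.na(ids)] <- nm[is.na(ids)]
    }
    if (anyNA(ids)) stopf("GFF3 record without ID or Name attribute")
    gene_table(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,  # 1-based -> 0-based
      end = GenomicRanges::end(gr)
    )
  } else {
    fields <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    gene_table(
      gene_id = fields[, 4],
      chrom = fields[, 1],
      strand = fields[, 6],
      start = as.integer(fields[, 2]),
      end = as.integer(fields[, 3])
    )
  }
}

#' Write a gene annotation
#'
#' Inverse of [read_annotation()]: GFF3 gets 1-based inclusive coordinates
#' and an `ID` attribute, BED6 is written natively. Curated TSS positions
#' are not representable in either format and are dropped on write.
#'
#' @param genes a gene table.
#' @param path output path.
#' @param format `"gff3"` or `"bed6"`.
#' @export
write_annotation <- function(genes, path, format = c("gff3", "bed6")) {
  format <- match.arg(format)
  genes <- sort_genes(genes)
  if (format == "gff3") {
    gr <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(genes$start + 1L, genes$end),
      strand = genes$strand
    )
    S4Vectors::mcols(gr)$source <- "promdir"
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- genes$gene_id
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    out <- data.frame(genes$chrom, genes$start, genes$end,
                      genes$gene_id, 0L, genes$strand)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a curated TSS table
#'
#' Two-column TSV with a header: `gene_id`, `tss_1based` (an optional third
#' `chrom` column enables chromosome checking). Positions are converted to
#' the internal 0-based convention.
#'
#' @param path TSV path.
#' @return `data.frame` with `gene_id`, `tss` (0-based) and optionally
#'   `chrom`.
#' @export
read_curated_tss <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("gene_id", "tss_1based") %in% names(tab))) {
    stopf("curated TSS table needs columns gene_id and tss_1based")
  }
  out <- data.frame(gene_id = as.character(tab$gene_id),
                    tss = as.integer(tab$tss_1based) - 1L,
                    stringsAsFactors = FALSE)
  if ("chrom" %in% names(tab)) out$chrom <- as.character(tab$chrom)
  out
}

#' Apply curated TSS positions
#'
#' Curated TSS positions (e.g. from TSS sequencing) are primary; the
#' annotation-derived TSS is the fallback for genes missing from the curated
#' table. A curated entry on the wrong chromosome is an error; an entry
#' downstream of the gene end (past `end` on `+`, before `start` on `-`) is
#' ignored with a warning, as is an unknown gene id.
#'
#' @param genes a gene table.
#' @param tss_table output of [read_curated_tss()] or a `data.frame` with
#'   `gene_id` and 0-based `tss` (optionally `chrom`).
#' @return The gene table with curated rows updated and
#'   `tss_source = "curated"`.
#' @export
apply_curated_tss <- function(genes, tss_table) {
  idx <- match(tss_table$gene_id, genes$gene_id)
  unknown <- is.na(idx)
  if (any(unknown)) {
    warnf("%d curated TSS entries with unknown gene ids ignored (e.g. '%s')",
          sum(unknown), tss_table$gene_id[unknown][1])
  }
  for (k in which(!unknown)) {
    i <- idx[k]
    pos <- tss_table$tss[k]
    if (!is.null(tss_table$chrom) && !is.na(tss_table$chrom[k]) &&
        tss_table$chrom[k] != genes$chrom[i]) {
      stopf("curated TSS for %s on chromosome %s but gene is on %s",
            genes$gene_id[i], tss_table$chrom[k], genes$chrom[i])
    }
    downstream_of_end <- if (genes$strand[i] == "+") {
      pos >= genes$end[i]
    } else {
      pos < genes$start[i]
    }
    if (downstream_of_end) {
      warnf("curated TSS for %s at %d lies downstream of the gene end; ignored",
            genes$gene_id[i], pos)
      next
    }
    genes$tss[i] <- as.integer(pos)
    genes$tss_source[i] <- "curated"
  }
  genes
}

#' Classify promoter orientation
#'
#' Labels each gene `overlapping` (its body intersects any other gene body,
#' either strand), else `divergent` (another gene's body or TSS on the
#' opposite strand intrudes into the `window` bases upstream of its TSS, in
#' the divergent direction), else `tandem`. The upstream window matches the
#' antisense quantification window so that a tandem gene's divergent window
#' can never contain another gene's coding transcription. Both members of a
#' divergent pair are labelled divergent (unless one is overlapping, which
#' takes precedence).
#'
#' @param genes a gene table.
#' @param window upstream window length in bases (default 500, the
#'   antisense quantification window).
#' @return `data.frame` with `gene_id` and `label`.
#' @export
classify_promoters <- function(genes, window = 500L) {
  stopifnot(window > 0)
  n <- nrow(genes)
  if (n == 0) {
    return(data.frame(gene_id = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  body <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(body, drop.self = TRUE,
                                    drop.redundant = FALSE)
  overlapping <- unique(S4Vectors::queryHits(ov))

  plus <- genes$strand == "+"
  us_start <- ifelse(plus, pmax(0L, genes$tss - window), genes$tss + 1L)
  us_end <- ifelse(plus, genes$tss, genes$tss + window + 1L)
  ok <- us_start < us_end
  win <- GenomicRanges::GRanges(
    genes$chrom[ok], IRanges::IRanges(us_start[ok] + 1L, us_end[ok]))
  hits <- GenomicRanges::findOverlaps(win, body)
  qi <- which(ok)[S4Vectors::queryHits(hits)]
  si <- S4Vectors::subjectHits(hits)
  keep <- qi != si & genes$strand[qi] != genes$strand[si]
  divergent <- union(qi[keep], si[keep])  # both members of a pair
  divergent <- setdiff(divergent, overlapping)

  label <- rep("tandem", n)
  label[divergent] <- "divergent"
  label[overlapping] <- "overlapping"
  data.frame(gene_id = genes$gene_id, label = label,
             stringsAsFactors = FALSE)
}

#' Filter noncoding intervals by length
#'
#' Keeps intervals strictly longer than `min_length` (the conventional
#' > 200 nt filter for CUT/SUT/XUT/NUT noncoding transcript annotations).
#' Input order is preserved.
#'
#' @param intervals `data.frame` with `start` and `end` (half-open).
#' @param min_length minimum length, exclusive.
#' @export
filter_noncoding_by_length <- function(intervals, min_length = 200L) {
  stopifnot(all(intervals$start < intervals$end))
  reset_rownames(intervals[(intervals$end - intervals$start) > min_length, ,
                           drop = FALSE])
}
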