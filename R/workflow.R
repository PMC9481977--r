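# Workflow layer: run configuration, end-to-end commands and run
# manifests. All outputs are headered TSVs with deterministic row order so
# runs are diffable; INFO logging reports the surviving record count at
# each filtering step.

default_parameters <- function() {
  list(window = 500L, pseudocount = 1, flank = 500L,
       end_convention = "3prime", library_strandness = "reverse",
       quintiles = 5L)
}

#' Read and validate a run configuration
#'
#' YAML file with `paths` (annotation, genome, chrom_sizes, curated_tss,
#' track...), `parameters` (defaults: window 500, pseudocount 1, flank 500,
#' end_convention 3prime, library_strandness reverse, quintiles 5),
#' `motifs` (list of name/pattern/scan_strand) and `samples` (sample_id,
#' condition, replicate, plus, minus). Validation collects every violation
#' and reports them together.
#'
#' @param path YAML config path.
#' @return A validated `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  cfg$parameters <- utils::modifyList(default_parameters(),
                                      cfg$parameters %||% list())
  validate_run_config(cfg, dir = dirname(path))
}

#' @rdname read_run_config
#' @param cfg a config list (as from `yaml::read_yaml`).
#' @param dir directory against which relative paths are resolved.
#' @export
validate_run_config <- function(cfg, dir = ".") {
  problems <- character(0)
  need <- function(field) {
    if (is.null(cfg[[field]])) {
      problems <<- c(problems, sprintf("missing required field '%s'", field))
      FALSE
    } else TRUE
  }
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(dir, p)
  }
  for (f in c("annotation", "chrom_sizes")) {
    if (need(f)) {
      cfg[[f]] <- resolve(cfg[[f]])
      if (!file.exists(cfg[[f]])) {
        problems <- c(problems, sprintf("file for '%s' not found: %s", f,
                                        cfg[[f]]))
      }
    }
  }
  for (f in c("genome", "curated_tss", "track")) {
    if (!is.null(cfg[[f]])) {
      cfg[[f]] <- resolve(cfg[[f]])
      if (!file.exists(cfg[[f]])) {
        problems <- c(problems, sprintf("file for '%s' not found: %s", f,
                                        cfg[[f]]))
      }
    }
  }
  if (is.null(cfg$samples) || length(cfg$samples) == 0) {
    problems <- c(problems, "empty sample sheet: at least one sample required")
  } else {
    for (i in seq_along(cfg$samples)) {
      s <- cfg$samples[[i]]
      for (f in c("sample_id", "condition", "replicate", "plus", "minus")) {
        if (is.null(s[[f]])) {
          problems <- c(problems,
                        sprintf("sample %d: missing field '%s'", i, f))
        }
      }
      for (f in c("plus", "minus")) {
        if (!is.null(s[[f]])) {
          cfg$samples[[i]][[f]] <- resolve(s[[f]])
          if (!file.exists(cfg$samples[[i]][[f]])) {
            problems <- c(problems,
                          sprintf("sample %d: file not found: %s", i, s[[f]]))
          }
        }
      }
    }
  }
  pp <- cfg$parameters
  if (!pp$end_convention %in% c("3prime", "5prime")) {
    problems <- c(problems, "parameters.end_convention must be 3prime or 5prime")
  }
  if (!pp$library_strandness %in% c("forward", "reverse")) {
    problems <- c(problems,
                  "parameters.library_strandness must be forward or reverse")
  }
  if (!is.numeric(pp$window) || pp$window <= 0) {
    problems <- c(problems, "parameters.window must be a positive number")
  }
  if (length(problems) > 0) {
    stopf("invalid run configuration:\n%s",
          paste0("  - ", problems, collapse = "\n"))
  }
  class(cfg) <- "run_config"
  cfg
}

read_chrom_sizes <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  setNames(as.integer(tab[[2]]), tab[[1]])
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(dir, seed = NA) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE),
                        "MANIFEST.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(md5sum(file.path(dir, files))),
    seed = seed, stringsAsFactors = FALSE
  )
  write_tsv(manifest, file.path(dir, "MANIFEST.tsv"))
}

#' Simulate a full run directory
#'
#' Writes genome FASTA, GFF3 annotation, chrom.sizes, ground-truth TSV,
#' per-condition/replicate fragment BED and plus/minus bedGraph pairs,
#' a spike-in count matrix, the parameters as YAML, and a manifest with
#' per-file md5 checksums. Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @param out_dir output directory (created).
#' @param conditions conditions to simulate.
#' @param distortions per-sample depth distortions for the spike-in matrix.
#' @return `out_dir`, invisibly.
#' @export
cmd_simulate <- function(params, out_dir,
                         conditions = c("control", "depleted"),
                         distortions = c(control = 1, depleted = 2)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(params)
  Biostrings::writeXStringSet(sim$genome, file.path(out_dir, "genome.fa"))
  write_annotation(sim$genes, file.path(out_dir, "genes.gff3"), "gff3")
  writeLines(sprintf("%s\t%d", names(sim$chrom_sizes),
                     unname(sim$chrom_sizes)),
             file.path(out_dir, "chrom.sizes"))
  write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
  for (cond in conditions) {
    for (r in seq_len(params$n_replicates)) {
      rep_out <- simulate_coverage(sim, cond, r)
      stem <- file.path(out_dir, sprintf("%s_rep%d", cond, r))
      write_tsv_bed6(rep_out$fragments, paste0(stem, ".fragments.bed"))
      write_bedgraph(rep_out$coverage, "+", paste0(stem, ".plus.bedGraph"))
      write_bedgraph(rep_out$coverage, "-", paste0(stem, ".minus.bedGraph"))
    }
  }
  sp <- simulate_spikein_counts(params, distortions)
  counts <- data.frame(gene_id = rownames(sp$counts),
                       spikein = rownames(sp$counts) %in% sp$spikein_ids,
                       sp$counts, check.names = FALSE)
  write_tsv(counts, file.path(out_dir, "spikein_counts.tsv"))
  writable <- params
  writable$motif$prob <- NULL  # closures are not serialisable config
  yaml::write_yaml(writable[setdiff(names(writable), "class")],
                   file.path(out_dir, "params.yaml"))
  write_manifest(out_dir, seed = params$seed)
  log_info("cmd_simulate: wrote %d genes, %d condition(s) x %d replicate(s) to %s",
           nrow(sim$genes), length(conditions), params$n_replicates, out_dir)
  invisible(out_dir)
}

write_tsv_bed6 <- function(df, path) {
  write.table(df[, c("chrom", "start", "end", "name", "score", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

sample_sheet <- function(cfg) {
  do.call(rbind, lapply(cfg$samples, function(s) {
    data.frame(sample_id = s$sample_id, condition = s$condition,
               replicate = as.integer(s$replicate), plus = s$plus,
               minus = s$minus, stringsAsFactors = FALSE)
  }))
}

# Gene-by-replicate window count matrices for one condition.
condition_window_counts <- function(genes, sheet, cond, chrom_sizes, cfg) {
  rows <- sheet[sheet$condition == cond, , drop = FALSE]
  rows <- rows[order(rows$replicate), , drop = FALSE]
  sense <- antisense <- matrix(
    NA_real_, nrow = nrow(genes), ncol = nrow(rows),
    dimnames = list(genes$gene_id, rows$sample_id))
  for (k in seq_len(nrow(rows))) {
    cov <- read_bedgraph_pair(rows$plus[k], rows$minus[k], chrom_sizes,
                              sample_id = rows$sample_id[k],
                              end_convention = cfg$parameters$end_convention)
    wc <- count_promoter_windows(genes, cov, cfg$parameters$window)
    sense[wc$gene_id, k] <- wc$sense
    antisense[wc$gene_id, k] <- wc$antisense
  }
  list(sense = sense, antisense = antisense)
}

#' Score promoters end-to-end
#'
#' Runs annotation -> promoter classification -> tandem filtering ->
#' window counting -> directionality scoring for every condition in the
#' sample sheet, then the condition contrast (when a `conditions` mapping
#' with `treatment` and `control` is present) and quintile stratification
#' of the control-condition scores. Writes `directionality_<cond>.tsv`,
#' `changes.tsv` and `quintiles.tsv` to `out_dir`.
#'
#' @param cfg a validated `run_config`.
#' @param out_dir output directory.
#' @return Invisibly, a list with the per-condition directionality tables,
#'   the change table and the quintile assignment.
#' @export
cmd_score <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- cfg$annotation_format %||% "gff3"
  genes <- read_annotation(cfg$annotation, fmt)
  log_info("cmd_score: %d genes read from annotation", nrow(genes))
  if (!is.null(cfg$curated_tss)) {
    genes <- apply_curated_tss(genes, read_curated_tss(cfg$curated_tss))
    log_info("cmd_score: %d genes with curated TSS",
             sum(genes$tss_source == "curated"))
  }
  classes <- classify_promoters(genes, cfg$parameters$window)
  tandem <- genes[genes$gene_id %in%
                    classes$gene_id[classes$label == "tandem"], ,
                  drop = FALSE]
  log_info("cmd_score: %d tandem non-overlapping genes retained (of %d)",
           nrow(tandem), nrow(genes))
  if (nrow(tandem) == 0) {
    warnf("no tandem genes survive filtering; writing empty tables")
  }
  chrom_sizes <- read_chrom_sizes(cfg$chrom_sizes)
  sheet <- sample_sheet(cfg)
  conds <- unique(sheet$condition)
  dirtabs <- list()
  for (cond in conds) {
    wc <- condition_window_counts(tandem, sheet, cond, chrom_sizes, cfg)
    dirtabs[[cond]] <- directionality_table(wc$sense, wc$antisense,
                                            cfg$parameters$pseudocount)
    write_tsv(dirtabs[[cond]],
              file.path(out_dir, sprintf("directionality_%s.tsv", cond)))
  }
  changes <- NULL
  if (!is.null(cfg$conditions) &&
        all(c(cfg$conditions$treatment, cfg$conditions$control) %in% conds)) {
    changes <- change_table(dirtabs[[cfg$conditions$treatment]],
                            dirtabs[[cfg$conditions$control]])
    write_tsv(changes, file.path(out_dir, "changes.tsv"))
  }
  quintiles <- NULL
  ref <- cfg$conditions$control %||% conds[1]
  dref <- dirtabs[[ref]]
  if (nrow(dref) >= cfg$parameters$quintiles) {
    quintiles <- stratify_quintiles(setNames(dref$D, dref$gene_id),
                                    cfg$parameters$quintiles)
    write_tsv(quintiles$assignment, file.path(out_dir, "quintiles.tsv"))
    write_tsv(quintiles$summary, file.path(out_dir, "quintile_summary.tsv"))
  }
  invisible(list(directionality = dirtabs, changes = changes,
                 quintiles = quintiles, tandem = tandem))
}

# Load two promoter groups (e.g. Q1 vs Q5) from a quintile assignment TSV.
quintile_groups <- function(genes, quintile_tsv, a = "Q5", b = "Q1") {
  q <- read.table(quintile_tsv, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  list(
    a = genes[genes$gene_id %in% q$gene_id[q$quintile == a], , drop = FALSE],
    b = genes[genes$gene_id %in% q$gene_id[q$quintile == b], , drop = FALSE]
  )
}

#' Motif profiles and enrichment for configured promoter groups
#'
#' For every motif in the config, writes a positional profile TSV per
#' group and one enrichment TSV comparing group A to group B (groups come
#' from a quintile assignment file via `cfg$groups`:
#' `file`, `a` (default Q5), `b` (default Q1)).
#'
#' @inheritParams cmd_score
#' @export
cmd_motifs <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cfg$genome)) stopf("cmd_motifs requires a genome FASTA")
  if (is.null(cfg$groups$file)) {
    stopf("cmd_motifs requires groups: {file, a, b}")
  }
  genome <- Biostrings::readDNAStringSet(cfg$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- read_annotation(cfg$annotation, cfg$annotation_format %||% "gff3")
  grp <- quintile_groups(genes, cfg$groups$file,
                         cfg$groups$a %||% "Q5", cfg$groups$b %||% "Q1")
  if (nrow(grp$a) == 0 || nrow(grp$b) == 0) {
    stopf("empty promoter group (a: %d, b: %d genes)", nrow(grp$a),
          nrow(grp$b))
  }
  flank <- cfg$parameters$flank
  enrich <- list()
  for (m in cfg$motifs %||% list(list(name = "A-track",
                                      pattern = "AAAAAAA",
                                      scan_strand = "sense"))) {
    motif <- motif_spec(m$name, m$pattern, m$scan_strand %||% "sense")
    tag <- gsub("[^A-Za-z0-9]+", "_", motif$name)
    for (g in c("a", "b")) {
      prof <- motif_profile(grp[[g]], genome, motif, flank)
      write_tsv(prof, file.path(out_dir,
                                sprintf("profile_%s_group_%s.tsv", tag, g)))
    }
    e <- motif_enrichment(grp$a, grp$b, genome, motif, flank)
    enrich[[length(enrich) + 1L]] <- data.frame(
      motif = motif$name, scan_strand = motif$scan_strand,
      fold_enrichment = e$fold_enrichment, p_value = e$p_value,
      higher_group = e$higher_group, mean_A = e$mean_A, mean_B = e$mean_B,
      n_A = e$n_A, n_B = e$n_B, stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, enrich), file.path(out_dir, "enrichment.tsv"))
  invisible(out_dir)
}

#' TSS metagene matrix and profile from a per-base track
#'
#' Reads the configured bedGraph track, sum-normalizes and log-transforms
#' it, builds the strand-oriented TSS matrix over `[-flank, flank)` and
#' writes both the matrix (`metagene_matrix.tsv`, offsets as header) and
#' its per-offset mean profile (`metagene_profile.tsv`).
#'
#' @inheritParams cmd_score
#' @export
cmd_metagene <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cfg$track)) stopf("cmd_metagene requires a track bedGraph")
  chrom_sizes <- read_chrom_sizes(cfg$chrom_sizes)
  track <- normalize_track(read_track(cfg$track, chrom_sizes))
  genes <- read_annotation(cfg$annotation, cfg$annotation_format %||% "gff3")
  flank <- cfg$parameters$flank
  mat <- matrix_at_tss(genes, track, flank, flank)
  out <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write_tsv(out, file.path(out_dir, "metagene_matrix.tsv"))
  write_tsv(mean_profile(mat), file.path(out_dir, "metagene_profile.tsv"))
  invisible(out_dir)
}
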