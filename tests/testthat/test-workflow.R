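# End-to-end workflow: config validation, run directories, and the
# scoring pipeline against an independently computed reference.

sim_run_dir <- function(seed = 1, n_genes = 40L) {
  p <- sim_params(seed = seed, n_genes = n_genes)
  dir <- tempfile("run")
  cmd_simulate(p, dir)
  dir
}

run_config_for <- function(dir) {
  samples <- list()
  for (cond in c("control", "depleted")) {
    for (r in 1:3) {
      stem <- file.path(dir, sprintf("%s_rep%d", cond, r))
      samples[[length(samples) + 1L]] <- list(
        sample_id = sprintf("%s_%d", cond, r), condition = cond,
        replicate = r, plus = paste0(stem, ".plus.bedGraph"),
        minus = paste0(stem, ".minus.bedGraph"))
    }
  }
  cfg <- list(
    annotation = file.path(dir, "genes.gff3"),
    genome = file.path(dir, "genome.fa"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    parameters = list(library_strandness = "forward"),
    conditions = list(treatment = "depleted", control = "control"),
    samples = samples
  )
  cfg$parameters <- utils::modifyList(promdir:::default_parameters(),
                                      cfg$parameters)
  validate_run_config(cfg)
}

test_that("config validation reports every violation at once", {
  cfg <- list(parameters = promdir:::default_parameters())
  err <- tryCatch(validate_run_config(cfg), error = conditionMessage)
  expect_match(err, "missing required field 'annotation'")
  expect_match(err, "missing required field 'chrom_sizes'")
  expect_match(err, "empty sample sheet")

  cfg2 <- list(
    annotation = tempfile(), chrom_sizes = tempfile(),
    parameters = utils::modifyList(promdir:::default_parameters(),
                                   list(end_convention = "mid")),
    samples = list(list(sample_id = "s1"))
  )
  err2 <- tryCatch(validate_run_config(cfg2), error = conditionMessage)
  expect_match(err2, "end_convention")
  expect_match(err2, "sample 1: missing field 'plus'")
  expect_match(err2, "not found")
})

test_that("simulated run directories are manifest-identical across runs", {
  d1 <- sim_run_dir(seed = 7, n_genes = 15L)
  d2 <- sim_run_dir(seed = 7, n_genes = 15L)
  m1 <- read.table(file.path(d1, "MANIFEST.tsv"), header = TRUE, sep = "\t")
  m2 <- read.table(file.path(d2, "MANIFEST.tsv"), header = TRUE, sep = "\t")
  expect_identical(m1$file, m2$file)
  expect_identical(m1$md5, m2$md5)
  expect_true("genome.fa" %in% m1$file)
  d3 <- sim_run_dir(seed = 8, n_genes = 15L)
  m3 <- read.table(file.path(d3, "MANIFEST.tsv"), header = TRUE, sep = "\t")
  expect_false(identical(m1$md5, m3$md5))
})

test_that("cmd_score reproduces an independent per-fragment reference bit-for-bit", {
  dir <- sim_run_dir(seed = 3, n_genes = 30L)
  cfg <- run_config_for(dir)
  out1 <- file.path(dir, "out1")
  res <- suppressMessages(cmd_score(cfg, out1))

  # independent reference: naive tally of the fragment BEDs
  genes <- read_annotation(file.path(dir, "genes.gff3"), "gff3")
  cls <- classify_promoters(genes)
  tandem <- genes[genes$gene_id %in% cls$gene_id[cls$label == "tandem"], ]
  cs <- promdir:::read_chrom_sizes(file.path(dir, "chrom.sizes"))
  ref_counts <- function(cond) {
    sense <- antisense <- NULL
    for (r in 1:3) {
      bed <- read.table(file.path(dir, sprintf("%s_rep%d.fragments.bed",
                                               cond, r)), sep = "\t")
      frags <- data.frame(chrom = bed$V1, start = bed$V2, end = bed$V3,
                          strand = bed$V6, stringsAsFactors = FALSE)
      vecs <- naive_end_tally(frags, cs, "3prime", "forward")
      s <- a <- numeric(nrow(tandem))
      for (i in seq_len(nrow(tandem))) {
        t <- tandem$tss[i]
        if (tandem$strand[i] == "+") {
          s[i] <- naive_window_sum(vecs$plus[[tandem$chrom[i]]], t, t + 500L)
          a[i] <- naive_window_sum(vecs$minus[[tandem$chrom[i]]], t - 500L, t)
        } else {
          s[i] <- naive_window_sum(vecs$minus[[tandem$chrom[i]]],
                                   t - 499L, t + 1L)
          a[i] <- naive_window_sum(vecs$plus[[tandem$chrom[i]]],
                                   t + 1L, t + 501L)
        }
      }
      sense <- cbind(sense, s)
      antisense <- cbind(antisense, a)
    }
    rownames(sense) <- rownames(antisense) <- tandem$gene_id
    list(sense = sense, antisense = antisense)
  }
  refc <- ref_counts("control")
  ref_dir <- directionality_table(refc$sense, refc$antisense)
  got <- read.table(file.path(out1, "directionality_control.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(got$gene_id, ref_dir$gene_id)
  expect_equal(got$S, ref_dir$S, tolerance = 1e-12)
  expect_equal(got$D, ref_dir$D, tolerance = 1e-12)

  # re-run -> byte-identical outputs
  out2 <- file.path(dir, "out2")
  suppressMessages(cmd_score(cfg, out2))
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("cmd_score warns and writes empty tables when no tandem genes survive", {
  dir <- tempfile("ovl")
  dir.create(dir)
  genes <- gene_table(c("g1", "g2"), "chrS", c("+", "-"),
                      start = c(1000L, 1500L), end = c(2000L, 2600L))
  write_annotation(genes, file.path(dir, "genes.gff3"), "gff3")
  writeLines("chrS\t5000", file.path(dir, "chrom.sizes"))
  cov <- stranded_coverage(c(chrS = 5000L))
  write_bedgraph(cov, "+", file.path(dir, "s.plus.bedGraph"))
  write_bedgraph(cov, "-", file.path(dir, "s.minus.bedGraph"))
  cfg <- validate_run_config(list(
    annotation = file.path(dir, "genes.gff3"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    parameters = promdir:::default_parameters(),
    samples = list(list(sample_id = "s", condition = "wt", replicate = 1,
                        plus = file.path(dir, "s.plus.bedGraph"),
                        minus = file.path(dir, "s.minus.bedGraph")))
  ))
  expect_warning(res <- suppressMessages(cmd_score(cfg, file.path(dir, "o"))),
                 "no tandem")
  got <- read.table(file.path(dir, "o", "directionality_wt.tsv"),
                    header = TRUE, sep = "\t")
  expect_equal(nrow(got), 0L)
})

test_that("cmd_motifs and cmd_metagene produce deterministic grouped outputs", {
  dir <- sim_run_dir(seed = 13, n_genes = 30L)
  cfg <- run_config_for(dir)
  out <- file.path(dir, "score")
  suppressMessages(cmd_score(cfg, out))
  cfg$groups <- list(file = file.path(out, "quintiles.tsv"),
                     a = "Q5", b = "Q1")
  cfg$motifs <- list(list(name = "A-track", pattern = "AAAAAAA",
                          scan_strand = "sense"))
  mo <- file.path(dir, "motifs")
  suppressMessages(cmd_motifs(cfg, mo))
  enr <- read.table(file.path(mo, "enrichment.tsv"), header = TRUE,
                    sep = "\t")
  expect_equal(nrow(enr), 1L)
  expect_true(enr$fold_enrichment > 0)
  expect_true(file.exists(file.path(mo, "profile_A_track_group_a.tsv")))

  # metagene over one replicate's plus-strand signal as a generic track
  cfg$track <- cfg$samples[[1]]$plus
  mg <- file.path(dir, "metagene")
  suppressMessages(cmd_metagene(cfg, mg))
  prof <- read.table(file.path(mg, "metagene_profile.tsv"), header = TRUE,
                     sep = "\t")
  expect_equal(nrow(prof), 1000L)
  mg2 <- file.path(dir, "metagene2")
  suppressMessages(cmd_metagene(cfg, mg2))
  expect_identical(readLines(file.path(mg, "metagene_profile.tsv")),
                   readLines(file.path(mg2, "metagene_profile.tsv")))
})
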