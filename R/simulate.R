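# Synthetic-data generator: genomes, tandem gene annotations, stranded
# 3'-end coverage with a divergent-transcription component, spike-in
# counts, and the ground truth needed for recovery tests. Every output is
# a pure function of (params, seed).

#' Simulation parameters
#'
#' Defaults describe a compact nascent-transcription experiment: genes of
#' realistic length separated by intergenic gaps wide enough that every
#' promoter classifies as tandem; per-promoter sense initiation rates
#' log-normal with mean 50 fragment 3' ends per 500-base window (a depth at
#' which divergent signal is comfortably above the pseudocount); true
#' directionality `delta` normal with mean 0.8 and sd 0.5 on the log10
#' scale, so divergent rates span roughly 2-25 with sense at 50; divergent
#' transcripts short (geometric, mean 150 bases, capped at 500, so their 3'
#' ends always fall in the antisense window); three biological replicates;
#' and a "depleted" condition that multiplies the antisense rate of a
#' quarter of promoters by 4.
#'
#' The motif-planting rule puts an A-track at a fixed upstream offset with
#' probability increasing in `delta` (logistic around the `delta` mean), so
#' strongly directional promoters carry the motif more often — mirroring
#' the association between A-tracks and directional promoters that the
#' enrichment analysis is meant to detect. Pass `prob = 1` (or any
#' constant / function of delta) to override.
#'
#' @param seed integer seed; every generator output is reproducible
#'   given it.
#' @param n_genes number of genes.
#' @param n_replicates biological replicates per condition.
#' @param gene_length list: `meanlog`, `sdlog`, `min` (log-normal, floored).
#' @param spacing list: `min`, `max` intergenic gap (uniform integer);
#'   `min` must exceed the promoter window for guaranteed-tandem layouts.
#' @param lambda_sense list: `meanlog`, `sdlog` of the per-promoter sense
#'   rate (expected fragment ends per window per replicate). The default
#'   `meanlog` is offset by `-sdlog^2/2` so the mean rate is exactly 50.
#' @param delta list: `mean`, `sd` of true log10 directionality; the
#'   antisense rate is `lambda_sense / 10^delta`.
#' @param divergent_length list: `mean`, `max` of the geometric divergent
#'   transcript length.
#' @param effect list: `fraction` of promoters affected and antisense-rate
#'   `multiplier` in the depleted condition.
#' @param spikein list: `n` genes, `meanlog`, `sdlog` of their rates.
#' @param fragment_length simulated fragment length in bases.
#' @param background_rate expected background fragments per base per strand
#'   (default 0).
#' @param motif list: `pattern`, `offset` (upstream, relative to TSS) and
#'   `prob` (NULL for the default delta-dependent rule, a constant, or a
#'   function of delta).
#' @param chrom name of the simulated chromosome.
#' @param margin bases of gene-free sequence at each chromosome end.
#' @return A `sim_params` list.
#' @export
sim_params <- function(seed = 1L,
                       n_genes = 2000L,
                       n_replicates = 3L,
                       gene_length = list(meanlog = log(1200), sdlog = 0.25,
                                          min = 500L),
                       spacing = list(min = 600L, max = 2000L),
                       lambda_sense = list(meanlog = log(50) - 0.125,
                                           sdlog = 0.5),
                       delta = list(mean = 0.8, sd = 0.5),
                       divergent_length = list(mean = 150, max = 500L),
                       effect = list(fraction = 0.25, multiplier = 4),
                       spikein = list(n = 50L, meanlog = log(100) - 0.125,
                                      sdlog = 0.5),
                       fragment_length = 50L,
                       background_rate = 0,
                       motif = list(pattern = "AAAAAAA", offset = -100L,
                                    prob = NULL),
                       chrom = "chrSim",
                       margin = 1000L) {
  p <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
            n_replicates = as.integer(n_replicates),
            gene_length = gene_length, spacing = spacing,
            lambda_sense = lambda_sense, delta = delta,
            divergent_length = divergent_length, effect = effect,
            spikein = spikein, fragment_length = as.integer(fragment_length),
            background_rate = background_rate, motif = motif,
            chrom = chrom, margin = as.integer(margin))
  stopifnot(p$n_genes >= 0, p$n_replicates >= 1,
            p$effect$fraction >= 0, p$effect$fraction <= 1,
            p$effect$multiplier > 0, p$spacing$min <= p$spacing$max,
            p$margin >= 500L, p$background_rate >= 0)
  if (is.null(p$motif$prob)) {
    d0 <- p$delta$mean
    p$motif$prob <- function(delta) stats::plogis(2 * (delta - d0))
  } else if (is.numeric(p$motif$prob)) {
    p0 <- p$motif$prob
    p$motif$prob <- function(delta) rep(p0, length(delta))
  }
  class(p) <- "sim_params"
  p
}

# Deterministic sub-seed per (stage, condition, replicate) so stages can be
# re-run independently; kept well below 2^31.
sub_seed <- function(params, stage, replicate = 0L) {
  offsets <- c(genome = 0L, control = 100000L, depleted = 200000L,
               spikein = 300000L)
  (params$seed %% 100000000L) + offsets[[stage]] + 101L * replicate
}

#' Simulate a genome with tandem genes and ground truth
#'
#' Generates an i.i.d. uniform background sequence, places `n_genes`
#' non-overlapping genes on random strands separated by gaps of at least
#' `spacing$min` (> 500, so every promoter is tandem under the default
#' classification window), draws per-gene true rates and condition
#' effects, and plants the motif per the planting rule on the coding
#' strand at the configured upstream offset.
#'
#' @param params a [sim_params()] object.
#' @return A list with `genome` (named `DNAStringSet`), `genes` (gene
#'   table), `truth` (per-gene `data.frame`: rates, `delta`, `affected`,
#'   `motif_planted`), `chrom_sizes`, and `params`.
#' @export
simulate_genome <- function(params) {
  set.seed(sub_seed(params, "genome"))
  n <- params$n_genes
  gl <- pmax(params$gene_length$min,
             round(rlnorm(n, params$gene_length$meanlog,
                          params$gene_length$sdlog)))
  gaps <- if (n > 0) {
    sample(params$spacing$min:params$spacing$max, n, replace = TRUE)
  } else integer(0)
  start <- integer(n)
  cursor <- params$margin
  for (i in seq_len(n)) {
    start[i] <- cursor
    cursor <- cursor + gl[i] + gaps[i]
  }
  chrom_length <- cursor + params$margin
  strand <- if (n > 0) sample(c("+", "-"), n, replace = TRUE) else character(0)
  base <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE)

  lambda_sense <- rlnorm(n, params$lambda_sense$meanlog,
                         params$lambda_sense$sdlog)
  delta <- rnorm(n, params$delta$mean, params$delta$sd)
  lambda_antisense <- lambda_sense / 10^delta
  affected <- runif(n) < params$effect$fraction
  plant <- runif(n) < params$motif$prob(delta)

  genes <- if (n > 0) {
    gene_table(
      gene_id = sprintf("gene_%04d", seq_len(n)),
      chrom = params$chrom, strand = strand,
      start = start, end = start + gl
    )
  } else {
    gene_table(character(), character(), character(), integer(), integer())[0, ]
  }

  # Plant the motif on the coding strand at the configured upstream offset
  # (on the reference strand this means the complement for minus genes).
  pat <- strsplit(gsub("[^ACGT]", "", params$motif$pattern), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  off <- params$motif$offset
  tss <- ifelse(strand == "+", start, start + gl - 1L)
  for (i in which(plant)) {
    if (strand[i] == "+") {
      at <- tss[i] + off + seq_along(pat)  # 1-based indices
      base[at] <- pat
    } else {
      at <- tss[i] - off - seq_along(pat) + 2L
      base[at] <- comp[pat]
    }
  }
  genome <- Biostrings::DNAStringSet(setNames(paste(base, collapse = ""),
                                              params$chrom))
  truth <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n)),
    strand = strand, tss = tss,
    lambda_sense = lambda_sense,
    lambda_antisense = lambda_antisense,
    lambda_antisense_depleted = lambda_antisense *
      ifelse(affected, params$effect$multiplier, 1),
    delta = delta, affected = affected, motif_planted = plant,
    stringsAsFactors = FALSE
  )
  list(genome = genome, genes = genes, truth = truth,
       chrom_sizes = setNames(chrom_length, params$chrom),
       params = params)
}

#' Simulate stranded fragments and end coverage for one replicate
#'
#' Per gene: the number of sense fragments is Poisson with the gene's
#' sense rate, their 3' ends uniform over the +1..+500 sense window on the
#' coding strand; the number of divergent fragments is Poisson with the
#' antisense rate (times the effect multiplier for affected genes in the
#' depleted condition), their 3' ends at `TSS - (1 + g)` on the opposite
#' strand with `g` geometric (mean `divergent_length$mean`, capped so every
#' end stays inside the -1..-500 antisense window). Optional uniform
#' background fragments are added on both strands. Fragments carry their
#' transcript strand, so coverage is built with a forward library
#' convention.
#'
#' @param sim output of [simulate_genome()].
#' @param condition `"control"` or `"depleted"`.
#' @param replicate replicate number (1-based); determines the sub-seed.
#' @return A list with `fragments` (BED-like `data.frame`) and `coverage`
#'   (a `stranded_coverage` of 3' ends).
#' @export
simulate_coverage <- function(sim, condition = c("control", "depleted"),
                              replicate = 1L) {
  condition <- match.arg(condition)
  params <- sim$params
  set.seed(sub_seed(params, condition, as.integer(replicate)))
  truth <- sim$truth
  chrom_len <- unname(sim$chrom_sizes[[params$chrom]])
  flen <- params$fragment_length
  cap <- as.integer(params$divergent_length$max)
  gmean <- params$divergent_length$mean

  end_chunks <- vector("list", nrow(truth) + 1L)
  strand_chunks <- vector("list", nrow(truth) + 1L)
  for (i in seq_len(nrow(truth))) {
    tss <- truth$tss[i]
    plus_gene <- truth$strand[i] == "+"
    ns <- rpois(1, truth$lambda_sense[i])
    la <- if (condition == "depleted") {
      truth$lambda_antisense_depleted[i]
    } else {
      truth$lambda_antisense[i]
    }
    na <- rpois(1, la)
    # sense 3' ends uniform in the +1..+500 window
    se <- if (ns > 0) {
      if (plus_gene) tss + sample.int(500L, ns, replace = TRUE) - 1L
      else tss - sample.int(500L, ns, replace = TRUE) + 1L
    } else integer(0)
    # divergent 3' ends at TSS -/+ (1 + g), g geometric capped in-window
    g <- if (na > 0) pmin(rgeom(na, 1 / gmean), cap - 1L) else integer(0)
    ae <- if (plus_gene) tss - 1L - g else tss + 1L + g
    end_chunks[[i]] <- c(se, ae)
    strand_chunks[[i]] <- c(rep(if (plus_gene) "+" else "-", ns),
                            rep(if (plus_gene) "-" else "+", na))
  }
  if (params$background_rate > 0) {
    nb <- rpois(1, params$background_rate * chrom_len * 2)
    end_chunks[[nrow(truth) + 1L]] <-
      sample.int(chrom_len, nb, replace = TRUE) - 1L
    strand_chunks[[nrow(truth) + 1L]] <- sample(c("+", "-"), nb,
                                                replace = TRUE)
  }
  end3 <- as.integer(unlist(end_chunks))
  ends <- data.frame(
    chrom = rep_len(params$chrom, length(end3)),
    end3 = end3,
    strand = as.character(unlist(strand_chunks)),
    stringsAsFactors = FALSE
  )
  # Expand each 3' end into a fragment interval of fixed length, clipped
  # at chromosome bounds (the end base itself is never clipped away).
  plus <- ends$strand == "+"
  start <- ifelse(plus, pmax(0L, ends$end3 - flen + 1L), ends$end3)
  end <- ifelse(plus, ends$end3 + 1L, pmin(chrom_len, ends$end3 + flen))
  fragments <- data.frame(
    chrom = ends$chrom, start = as.integer(start), end = as.integer(end),
    name = if (nrow(ends) > 0) sprintf("frag_%06d", seq_len(nrow(ends)))
           else character(0),
    score = if (nrow(ends) > 0) 0L else integer(0),
    strand = ends$strand, stringsAsFactors = FALSE
  )
  cov <- fragments_to_end_coverage(
    fragments, sim$chrom_sizes, end_convention = "3prime",
    library_strandness = "forward",
    sample_id = sprintf("%s_rep%d", condition, replicate)
  )
  list(fragments = fragments, coverage = cov)
}

#' Replicate-wise promoter window counts for one condition
#'
#' Convenience wrapper: simulates each replicate's coverage and reduces it
#' to sense/antisense promoter-window count matrices (genes x replicates),
#' discarding the dense coverage between replicates.
#'
#' @param sim output of [simulate_genome()].
#' @param condition `"control"` or `"depleted"`.
#' @param window promoter window length.
#' @return A list with matrices `sense` and `antisense`.
#' @export
simulate_window_counts <- function(sim, condition = c("control", "depleted"),
                                   window = 500L) {
  condition <- match.arg(condition)
  n_rep <- sim$params$n_replicates
  sense <- antisense <- matrix(
    NA_real_, nrow = nrow(sim$genes), ncol = n_rep,
    dimnames = list(sim$genes$gene_id, sprintf("rep%d", seq_len(n_rep))))
  for (r in seq_len(n_rep)) {
    cov <- simulate_coverage(sim, condition, r)$coverage
    wc <- count_promoter_windows(sim$genes, cov, window)
    sense[wc$gene_id, r] <- wc$sense
    antisense[wc$gene_id, r] <- wc$antisense
  }
  list(sense = sense, antisense = antisense)
}

#' Simulate spike-in (and optional main-gene) count matrices
#'
#' Spike-in gene counts are Poisson with gene-specific rates scaled by a
#' per-sample depth distortion, emulating exogenous spike-in material
#' added in fixed proportion and sequenced at sample-specific depth. Main
#' genes, when requested, get rates scaled additionally by a per-sample
#' global shift (to mimic a genuine global change in transcription that
#' spike-in normalization should expose).
#'
#' @param params a [sim_params()] object.
#' @param distortions positive per-sample depth distortions (named vector
#'   names become column names).
#' @param n_main number of main (non-spike-in) genes to include.
#' @param main_shift per-sample multiplier on main-gene rates (default 1).
#' @return A list with `counts` (gene x sample integer matrix) and
#'   `spikein_ids`.
#' @export
simulate_spikein_counts <- function(params, distortions, n_main = 0L,
                                    main_shift = 1) {
  stopifnot(all(distortions > 0))
  set.seed(sub_seed(params, "spikein"))
  n_sp <- params$spikein$n
  n_samp <- length(distortions)
  sp_rates <- rlnorm(n_sp, params$spikein$meanlog, params$spikein$sdlog)
  main_rates <- if (n_main > 0) {
    rlnorm(n_main, params$lambda_sense$meanlog + log(10),
           params$lambda_sense$sdlog)
  } else numeric(0)
  main_shift <- rep_len(main_shift, n_samp)
  rates <- rbind(
    outer(sp_rates, distortions),
    if (n_main > 0) outer(main_rates, distortions * main_shift)
  )
  counts <- matrix(rpois(length(rates), rates), nrow = nrow(rates))
  spikein_ids <- sprintf("spike_%03d", seq_len(n_sp))
  rownames(counts) <- c(spikein_ids,
                        if (n_main > 0) sprintf("main_%04d", seq_len(n_main)))
  colnames(counts) <- names(distortions) %||%
    sprintf("sample_%d", seq_len(n_samp))
  list(counts = counts, spikein_ids = spikein_ids)
}
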