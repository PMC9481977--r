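test_that("fragment ends land on the strand-appropriate terminal base", {
  cs <- c(chr1 = 1000L)
  plus_frag <- data.frame(chrom = "chr1", start = 100L, end = 150L,
                          strand = "+")
  minus_frag <- data.frame(chrom = "chr1", start = 100L, end = 150L,
                           strand = "-")
  cov <- fragments_to_end_coverage(plus_frag, cs, "3prime", "forward")
  expect_equal(which(cov$plus$chr1 == 1L), 150L)  # 0-based 149
  expect_equal(total_signal(cov), 1)
  cov <- fragments_to_end_coverage(minus_frag, cs, "3prime", "forward")
  expect_equal(which(cov$minus$chr1 == 1L), 101L)  # 0-based 100
  # 5' convention mirrors within each strand
  cov <- fragments_to_end_coverage(plus_frag, cs, "5prime", "forward")
  expect_equal(which(cov$plus$chr1 == 1L), 101L)
  # reverse-stranded library flips the transcript strand
  cov <- fragments_to_end_coverage(plus_frag, cs, "3prime", "reverse")
  expect_equal(sum(cov$plus$chr1), 0)
  expect_equal(which(cov$minus$chr1 == 1L), 101L)  # 3' end of a - transcript
})

test_that("end coverage equals a per-fragment brute-force tally and conserves units", {
  set.seed(7)
  cs <- c(chrA = 400L, chrB = 250L)
  for (conv in c("3prime", "5prime")) {
    for (strd in c("forward", "reverse")) {
      frags <- random_fragments(1000L, cs)
      cov <- fragments_to_end_coverage(frags, cs, conv, strd)
      oracle <- naive_end_tally(frags, cs, conv, strd)
      expect_equal(cov$plus, oracle$plus)
      expect_equal(cov$minus, oracle$minus)
      expect_equal(total_signal(cov), 1000)
    }
  }
})

test_that("fragments outside chromosome bounds are rejected with the record named", {
  cs <- c(chr1 = 100L)
  bad <- data.frame(chrom = "chr1", start = 90L, end = 120L, strand = "+")
  expect_error(fragments_to_end_coverage(bad, cs), "fragment 1")
  unk <- data.frame(chrom = "chrX", start = 0L, end = 10L, strand = "+")
  expect_error(fragments_to_end_coverage(unk, cs), "unknown chromosome")
})

test_that("bedGraph writing run-length encodes and round-trips exactly", {
  cs <- c(chr1 = 5L)
  cov <- stranded_coverage(cs)
  cov$plus$chr1 <- c(0L, 0L, 3L, 3L, 0L)
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(cov, "+", path)
  expect_equal(readLines(path), "chr1\t2\t4\t3")

  # empty strand -> empty file -> all-zero vector back
  path0 <- tempfile()
  write_bedgraph(cov, "-", path0)
  expect_equal(length(readLines(path0)), 0L)
  back <- read_bedgraph(path0, cs, "-")
  expect_equal(back$minus$chr1, numeric(5))

  set.seed(13)
  cs2 <- c(chr1 = 300L, chr2 = 120L)
  for (rep in 1:10) {
    cov <- fragments_to_end_coverage(random_fragments(200L, cs2), cs2,
                                     library_strandness = "forward")
    for (s in c("+", "-")) {
      p <- tempfile()
      write_bedgraph(cov, s, p)
      rt <- read_bedgraph(p, cs2, s)
      slot <- if (s == "+") "plus" else "minus"
      expect_equal(lapply(rt[[slot]], as.integer), cov[[slot]])
    }
  }
})

test_that("bedGraph reading rejects overlaps and unknown chromosomes", {
  cs <- c(chr1 = 100L)
  p <- tempfile()
  writeLines(c("chr1\t0\t10\t2", "chr1\t5\t15\t1"), p)
  expect_error(read_bedgraph(p, cs, "+"), "overlapping")
  writeLines("chrZ\t0\t10\t2", p)
  expect_error(read_bedgraph(p, cs, "+"), "unknown chromosome")
})

test_that("window counting matches a naive positional sum", {
  cs <- c(chr1 = 1000L)
  cov <- stranded_coverage(cs)
  cov$plus$chr1[101L] <- 1L  # unit at 0-based 100
  expect_equal(count_window(cov, "chr1", "+", 50L, 550L), 1)
  expect_equal(count_window(cov, "chr1", "-", 50L, 550L), 0)
  expect_error(count_window(cov, "chr1", "+", 900L, 1100L), "outside")

  set.seed(3)
  cov <- fragments_to_end_coverage(random_fragments(500L, cs), cs,
                                   library_strandness = "forward")
  for (rep in 1:50) {
    lo <- sample.int(990L, 1L) - 1L
    hi <- lo + sample.int(1000L - lo, 1L)
    expect_equal(count_window(cov, "chr1", "+", lo, hi),
                 naive_window_sum(cov$plus$chr1, lo, hi))
  }
})

test_that("promoter windows follow the +1..+500 / -1..-500 convention and mirror by strand", {
  cs <- c(chr1 = 10000L)
  genes <- gene_table("g1", "chr1", "+", 1000L, 3000L)
  cov <- stranded_coverage(cs)
  cov$plus$chr1[1251L] <- 1L   # 0-based 1250, sense window [1000,1500)
  cov$minus$chr1[801L] <- 1L   # 0-based 800, antisense window [500,1000)
  wc <- count_promoter_windows(genes, cov)
  expect_equal(wc$sense, 1)
  expect_equal(wc$antisense, 1)
  expect_false(wc$clipped)

  # exact strand mirror: same counts
  L <- 10000L
  mg <- mirror_genes(genes, L)
  mcov <- stranded_coverage(cs)
  mcov$minus$chr1[L - 1250L] <- 1L  # mirrored position, flipped strand
  mcov$plus$chr1[L - 800L] <- 1L
  mwc <- count_promoter_windows(mg, mcov)
  expect_equal(mwc$sense, wc$sense)
  expect_equal(mwc$antisense, wc$antisense)

  # zero coverage
  wc0 <- count_promoter_windows(genes, stranded_coverage(cs))
  expect_equal(wc0$sense, 0)
  expect_equal(wc0$antisense, 0)

  # window truncated at the chromosome start is flagged
  edge <- gene_table("g2", "chr1", "+", 200L, 900L)
  expect_true(count_promoter_windows(edge, cov)$clipped)
})

test_that("strand-mirroring a random fragment set swaps nothing in the window counts", {
  set.seed(21)
  L <- 20000L
  cs <- c(chr1 = L)
  start <- c(3000L, 9000L, 15000L)
  genes <- gene_table(sprintf("g%d", 1:3), "chr1", c("+", "-", "+"),
                      start, start + 2000L)
  frags <- random_fragments(400L, cs)
  cov <- fragments_to_end_coverage(frags, cs, library_strandness = "forward")
  wc <- count_promoter_windows(genes, cov)

  mfrags <- data.frame(chrom = frags$chrom, start = L - frags$end,
                       end = L - frags$start,
                       strand = ifelse(frags$strand == "+", "-", "+"))
  mcov <- fragments_to_end_coverage(mfrags, cs,
                                    library_strandness = "forward")
  mwc <- count_promoter_windows(mirror_genes(genes, L), mcov)
  m <- mwc[match(wc$gene_id, mwc$gene_id), ]
  expect_equal(m$sense, wc$sense)
  expect_equal(m$antisense, wc$antisense)
})

test_that("anchored interval counting emits two strands per anchor", {
  cs <- c(chr1 = 1000L)
  cov <- stranded_coverage(cs)
  cov$plus$chr1[451L] <- 1L  # 0-based 450
  anchors <- data.frame(chrom = "chr1", pos = 500L)
  out <- count_anchored_intervals(anchors, cov, flank = 100L)
  expect_equal(nrow(out), 2L)
  expect_equal(out$count[out$strand == "+"], 1)
  expect_equal(out$count[out$strand == "-"], 0)

  many <- data.frame(chrom = "chr1", pos = seq(200L, 800L, by = 5L))
  expect_equal(nrow(count_anchored_intervals(many, cov, 100L)),
               2L * nrow(many))

  expect_error(count_anchored_intervals(
    data.frame(chrom = "chr1", pos = 50L), cov, 100L), "outside")
  expect_error(count_anchored_intervals(
    data.frame(chrom = "chr1", pos = 500L), cov, 2000L), "outside")
})

test_that("window counts never exceed the conserved total signal", {
  set.seed(9)
  cs <- c(chr1 = 5000L)
  frags <- random_fragments(300L, cs)
  cov <- fragments_to_end_coverage(frags, cs, library_strandness = "forward")
  genes <- gene_table(sprintf("g%d", 1:4), "chr1", c("+", "-", "+", "-"),
                      c(600L, 1600L, 2600L, 3600L),
                      c(1500L, 2500L, 3500L, 4500L))
  wc <- count_promoter_windows(genes, cov)
  expect_lte(sum(wc$sense) + sum(wc$antisense), total_signal(cov))
})
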