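---
title: "Quantifying promoter directionality from stranded nascent transcription"
author: "promdir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying promoter directionality from stranded nascent transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promdir)
```

## The measurement model

Divergent transcription initiates within a gene's promoter on the strand
opposite to the coding gene and runs upstream, producing short noncoding
RNAs. With strand-specific nascent transcription data, both initiation
directions of one promoter can be quantified from the same library. The
package's unit of signal is the single terminal nucleotide of each
sequenced fragment on its transcript strand: reducing a fragment to one
base makes window counts insensitive to fragment length and gives every
fragment exactly one vote. By default the 3′ end is used; the 5′ end is
available through `end_convention`, since protocols differ in which end
is the better proxy for polymerase position, and `library_strandness`
("reverse" by default, as in dUTP-based protocols) states how a recorded
fragment orientation maps to the transcript strand.

For a promoter with TSS $t$ on the `+` strand, the sense window is
$[t, t+500)$ on the coding strand and the antisense (divergent) window is
$[t-500, t)$ on the opposite strand; minus-strand genes are exact
mirrors. With per-replicate window counts $s_r$ and $a_r$, the
directionality score is

$$
D = \log_{10}\frac{S}{A}, \qquad
S = \frac{1}{R}\sum_r (s_r + 1), \quad
A = \frac{1}{R}\sum_r (a_r + 1) .
$$

The pseudocount is added per replicate *before* averaging — the two
orders differ at low counts, and the per-replicate order is used
throughout. It guarantees $S, A \ge 1$, hence a finite score, at the
price of a bias toward zero that grows as the true rate approaches the
pseudocount; this bias matters for weakly divergent promoters and is
visible in the recovery analyses below.

Condition contrasts are plain ratios of the pseudocounted means:
divergent and sense `log2FC`, and the directionality change
$\Delta = (D_t - D_c)\log_2 10$, which then satisfies
$\Delta = \mathrm{log2FC}_{sense} - \mathrm{log2FC}_{divergent}$
identically. No shrinkage or dispersion modelling is applied — the
package deliberately stops at fold-change arithmetic, leaving
significance testing of per-gene differential expression to dedicated
tools.

## Which promoters are scored

The antisense window of a gene must not contain another gene's coding
transcription, or "divergent" signal would simply be the neighbour's
mRNA. Promoters are therefore classified before scoring:

* **overlapping** — the gene body intersects any other gene body on
  either strand;
* **divergent** — an opposite-strand gene body (or TSS) lies within the
  upstream window of the promoter, by default 500 bases, the same length
  as the antisense quantification window so the exclusion is exactly as
  wide as the signal it protects;
* **tandem** — everything else; only these are scored.

Published analyses of this kind do not state a numeric criterion for
"divergent gene pair"; tying the exclusion window to the quantification
window is this package's choice, and the window is a parameter. Curated
TSS positions (from TSS-sequencing data) take precedence over
annotation-derived ones, with the annotation as fallback; a curated entry
downstream of the gene end is ignored with a warning, since it would
invert the window geometry.

## Normalization choices

Internal (total-count) normalization hides genuine global shifts in
transcription. When spike-in material is present, size factors are
computed by median-of-ratios restricted to spike-in genes with nonzero
counts in every sample:
$sf_j = \mathrm{median}_i\, c_{ij}/(\prod_j c_{ij})^{1/m}$. The factors
are defined up to a common scale; only their ratios are meaningful. For
per-base tracks used in metagene analyses (nucleosome occupancy,
CUT&RUN-style binding), each track is divided by its total signal and
transformed as $\log_2(x + 10^{-6})$; the small pseudocount keeps empty
positions finite while compressing nothing else at typical scales.

## Quintiles, motifs, metagenes

Stratification is equal-count: genes are stably sorted by
`(score, gene_id)` and split into five contiguous groups whose sizes
differ by at most one (remainders at the low end). Printed score ranges
per quintile make the stratification auditable. Equal-count rather than
equal-width strata were chosen because observed score distributions are
heavy-tailed; published quintile boundaries are consistent with the
equal-count reading.

Motif analysis scans promoter sequences oriented in the coding direction
(minus-strand promoters are reverse-complemented first, so "sense" always
means the coding strand). Patterns are plain strings with one-position
alternatives (`AAAAAAA`; `CG[C/G]G`). All match starts are reported,
overlapping matches included — for homopolymer tracks this choice is
consequential (an A$_8$ run counts as two A$_7$ matches) and is stated
prominently rather than hidden. `N` never matches; promoters overhanging
chromosome ends are skipped and counted, not padded. Enrichment between
two promoter groups compares per-promoter match counts with a two-sided
Mann–Whitney test plus a pseudocounted fold
$(\bar c_A + 0.5)/(\bar c_B + 0.5)$; the test is specified here because
the upstream literature names only the tool it used, not the statistic.

Metagene matrices are TSS-anchored, strand-oriented (transcription always
runs left to right), one base per column over $[-500, 500)$ by default.
Missing data (off-chromosome positions) is `NA`, never 0 — tools differ
on this and the distinction changes column means near chromosome ends.
`skip_zeros` reproduces the common practice of dropping all-zero rows,
and logs how many it dropped.

## The simulator and what it does (not) show

`sim_params()` freezes an explicit generative model:

* gene bodies (log-normal length, floor 500 b) separated by uniform
  600–2000 b gaps, strands random — gaps exceed the 500 b windows, so
  every simulated promoter is tandem by construction;
* per-promoter sense rate $\lambda_s$ log-normal with mean exactly 50
  fragment ends per window per replicate (`sdlog` 0.5), three
  replicates;
* true directionality $\delta \sim N(0.8,\,0.5)$ on the log10 scale,
  with $\lambda_a = \lambda_s/10^{\delta}$ — moderately directional
  promoters whose divergent rate (≈8 at the centre) sits well above the
  +1 pseudocount, so recovery of $\delta$ by $D$ is informative at this
  depth. Real yeast promoters are often more directional (published
  quintile ranges reach scores of 1.5–3), where the divergent rate at
  this depth would be pseudocount-dominated; recovery statistics on real
  data are accordingly expected to be worse than on these simulations;
* divergent transcripts short: 3′ ends at $t - (1 + g)$ with $g$
  geometric (mean 150 b, capped at 500) — always inside the antisense
  window, mimicking the short unstable upstream transcripts seen in
  vivo;
* a depletion condition multiplying $\lambda_a$ by 4 in a random 25% of
  promoters (Poisson counts throughout; no overdispersion — the
  simulator makes no claim about real-data dispersion);
* spike-in genes with rates unaffected by condition, scaled by
  per-sample depth distortions;
* optional A-track planting at a fixed upstream offset with probability
  increasing in $\delta$ (logistic around the $\delta$ mean), so
  strongly directional promoters carry the motif more often, giving the
  enrichment machinery a signal of known direction.

Everything is a pure function of `(params, seed)`; sub-seeds per
condition and replicate keep stages independently reproducible, and run
directories carry md5 manifests.

Under these defaults the test suite demonstrates: Spearman correlation
≈ 0.96–0.97 between true $\delta$ and estimated $D$ over 2,000
promoters; top-quintile membership overlap ≈ 0.80–0.83 between
truth-ranked and estimate-ranked Q5 (the +1 pseudocount interacts with
the sense-rate spread to reorder promoters near the quintile boundary —
an intrinsic property of the estimator at this depth, not a code
artefact); affected-promoter mean divergent `log2FC` ≈ 1.78–1.85 against
the true $\log_2 4 = 2$ (same pseudocount compression), unaffected
promoters centred at 0; spike-in factor ratios recovered within ~2–3%
with 50 spike-in genes. These are statements about the simulator's
conditions; they bound what can be claimed about real libraries, which
add dispersion, mappability gaps and annotation error that the generator
deliberately omits.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open everywhere internally (GFF3 converted
on parse; BED native). Coverage is held in dense per-base integer
vectors, so window sums are bit-exact integer arithmetic at desk-scale
genomes. Windows truncated by chromosome edges are computed over the
truncated span and flagged, not dropped. bedGraph output is run-length
encoded with zero runs omitted; write→read round-trips are exact. Ties in
stratification are broken by gene id, making every output deterministic
under permutation of the input. Degenerate inputs follow explicit
contracts: empty annotations and empty simulations are valid; a
zero-replicate score, a zero-total track, an all-zero spike-in gene set,
and sub-5-gene stratification are errors; two all-zero groups in the
enrichment test return fold 1, p 1 (as does the all-tie case, where the
normal approximation of the rank-sum statistic degenerates).

## Problem sizes

The shipped tests and the acceptance script use 2,000 simulated
promoters (≈5 Mb genome, 6 coverage sets) for recovery analyses, 100
random fixtures for counting-oracle equivalence, 1,000 random sequences
for scanner-oracle equivalence and 100 seeded runs for enrichment power —
sizes at which every property is stable while the whole suite completes
in a couple of minutes on one core.

## Known limitations

One TSS per gene (no isoforms); no read-level simulation (no FASTQ,
alignment or duplicates); no nucleosome calling or peak calling; fold
changes are unshrunken; the Poisson generator understates real
biological dispersion; and the divergent/overlapping exclusion uses gene
bodies only, not UTR-extended transcription units.
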