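---
title: "Methods: palindromic NAC binding-site models and the senescence pipeline"
author: "nacbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: palindromic NAC binding-site models and the senescence pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

During monocarpic senescence of a cereal flag leaf, the photosynthetic
apparatus is dismantled and nitrogen is remobilized to the developing grain.
This process is transcriptionally coordinated, and NAC-family transcription
factors are among its central regulators. NAC proteins bind DNA motifs built
around a short `CGT` core; because the core alone is far too short to call
target genes from sequence, informative NAC binding-site (NACBS) models must
exploit two further regularities: the core tends to occur as an inverted
repeat (`CGT ... ACG`) separated by a 5–10 nucleotide spacer, and weakly
conserved `T` bases precede the core.

`nacbs` implements the complete analysis chain around this idea: build the
palindromic NACBS models, scan promoter sets for occurrences with exact
per-window p-values, test whether occurrence is over-represented among genes
up-regulated during senescence, and corroborate the candidate targets
through senescence expression profiles (microarray and qPCR) and
co-expression rankings. A synthetic-data module generates all inputs with
known ground truth so every stage is testable without any download.

## Motif models

Seven models are built from consensus strings: `NACBS-k` for spacer
`k = 5..10` is `ttn CGT (n×k) ACG nnn`, and `NACBS-1` is `nttnCGTgnnn`
(no inverted repeat, conserved `T` at the −2/−3 positions). Upper-case
positions are the fixed core, lower-case positions are weakly conserved,
`n` is free. A `weight_scheme()` expands each position into a probability
row:

* core base: probability `core_prob` (default **0.94**), remainder split
  equally over the other three bases;
* minor base: probability `minor_prob` (default **0.70**);
* `n`: uniform 0.25;
* every cell floored at 0.001 and the row renormalized, keeping log-odds
  scores finite.

The published supplementary weight matrices are not reproduced verbatim in
the main text of the study this design follows, so the default weights above
are this package's declared, configurable choice, not a claim of identity.
By construction the `ACG` block of each palindromic model is the positionwise
reverse complement of its `CGT` block; the test suite asserts this, along
with the information-content ordering core > minor > free.

Models are read and written in MEME minimal motif format (`read_meme()`,
`write_meme()`), the lingua franca of motif scanners; round-trips preserve
probabilities to 1e-6.

## Scanning and exact p-values

`scan_promoters()` scores every window of every promoter with the log2
odds `log2(p_model / p_background)` against a 0-order background (uniform by
default; a promoter-estimated background is available). Per-position scores
are rounded to a grid of step `granularity` (default **0.01** log2 units) and
the window score is the sum of the rounded values. The null distribution of
that sum under the background is computed *exactly* by dynamic programming —
one convolution per motif position with letter weights from the background —
so the upper tail gives an exact p-value for every achievable window score.
The test suite verifies the DP against full enumeration of all `4^L` words
for short random models to 1e-12; the granularity is therefore an exactness
knob only in the sense of score quantization, not of the tail computation.

A window is a hit when its p-value is at or below the threshold (default
**1e-4**, the conventional scanning threshold for these models). Both strands
are scanned by default via the reverse-complement model; windows containing
`N` are skipped; coordinates are 0-based half-open, promoter-relative.
P-values are per-window and deliberately not multiple-testing corrected
across windows, matching how such scans are thresholded in practice. At the
promoter level a sequence counts once no matter how many matches it
contains; this promoter-level counting is what makes a "total,
non-redundant" union row meaningful (the printed total of 532 per-motif hits
collapsing to 333 promoters in the reference study supports this reading).

## Enrichment

For a universe of `N` scanned promoters of which `K` contain a hit, and a
gene set of size `n` with `k` hits, `hypergeom_upper()` computes the exact
upper tail `P(X >= k)` of the hypergeometric distribution by log-space
summation. Reports annotate `**` for p ≤ 0.01, `*` for p ≤ 0.05, `NS`
otherwise, plus a half-up-rounded per-1000 rate. The test is one-tailed
(over-representation) because that is the directional claim of interest; a
two-sided option is exposed because recomputing the reference study's
down-regulated union with the one-tailed test gives p ≈ 0.043 where the
published table prints "not significant" — that cell (and the up-regulated
NACBS-10 cell, whose exact p is 0.0104, marginally above the 0.01 star
boundary) is treated as a flagged discrepancy rather than forced to agree.
No correction is applied across the seven motifs, mirroring the
per-motif-star layout of the reference table.

## Microarray stage

Single-channel intensities are background-corrected with the "half" rule
`max(signal − background, 0.5)` (named but not defined in the source study;
this is the convention of the method of that name), quantile-normalized
across arrays (delegated to `limma::normalizeQuantiles(ties = TRUE)`, which
matches the stated tie semantics), and filtered: a probe is kept when its
signal reaches `min_fold_over_bg` (default 1.1) times background in at least
`min_fraction_arrays` (default all) of the arrays of at least one condition
group — the group-wise rule keeps genes expressed in only one condition.

Probe redundancy is resolved by the 3'-biased rule: among probes targeting
one sequence, restrict to the two with the highest mean signal and take the
one closest to the target 3' end (labelling proceeds from the poly(A) tail,
so 3' probes are favoured); distance ties go to the higher signal, then to
the smaller probe id. The reading "restrict to top-2 by signal, then most
3'" is this package's resolution of an ambiguous verbal rule and is recorded
as such. Probe-to-gene assignment uses a plain Hamming search with up to 3
mismatches over the forward strand (ambiguous bases count as mismatches),
replacing a BLAST step that would need external databases.

Differential ranking uses a deliberately simple moderated two-sample t: the
pooled per-gene variance is shrunk toward the median gene variance with
prior weight `d0 = 4` and the statistic referred to `t` on `d0 + df` degrees
of freedom, with Benjamini–Hochberg adjustment. This is a documented
stand-in with the right qualitative behaviour (calibrated on null data,
stable under low replication), not a re-implementation of any published
empirical-Bayes pipeline. Ranking ties break by |log2 fold change|
descending, then gene id. The top fraction (default 20%, the reference
study's ~top-5000-of-24646 choice) is carried forward, split into up- and
down-regulated sets by fold-change sign. An outlier-array screen flags any
array whose median inter-array Spearman correlation falls more than 3 MADs
below the cohort median; exclusion is left as an explicit, reversible
choice.

## qPCR stage

Technical triplicates are averaged; when the replicate range exceeds 1
cycle, values more than 0.5 cycles from the median are dropped and the well
flagged `outlier_removed` — a formalization of "manual inspection" with
configurable thresholds. Two discordant replicates with nothing retained
yield `NA` with flag `discordant`. Reference-gene stability uses the
pairwise-ratio measure: for each candidate pair the SD (n−1) of per-sample
log2 ratios, averaged over partners, gives `M`; lower is more stable. The
single-pass variant is used rather than iterative exclusion — the source
study only cites the package implementing the measure, and the single-pass
average is the measure itself. Expression is normalized as
`2^(Ct_ref − Ct_gene)` against the most stable reference.

Samples are ordered by decreasing chlorophyll content (the senescence
proxy), ties broken by sample id. Profiles are clustered with k-means after
per-gene z-scoring — the clusters of interest are expression *patterns*, not
levels; raw-scale clustering remains available. Missing values are linearly
interpolated over the ordered samples first; constant genes map to all-zero
profiles. Lloyd's algorithm is run over `restarts` random initializations
(default 100) drawn from the distinct profiles in a canonical order, so the
result is deterministic given the seed and invariant to gene order; the best
inertia is kept. The cluster count follows the rule of thumb
`k = round(sqrt(n/2))` (half-up), which gives k = 7 for the 91-gene panel
(44 senescence-associated genes + 47 NAC genes).

## Co-expression rank bias

For each seed (NAC) gene, all other genes are ranked by Pearson correlation,
descending; rank 1 is the strongest co-expression partner. The question
"are NACBS-containing up-regulated genes biased toward the top of a NAC
gene's ranking?" is formalized — beyond the purely visual histograms of the
source study — as a one-sided Mann–Whitney test with `auc = U/(|A||B|)`
reported as the effect size; the histogram output (20 equal-width rank bins
by default) is preserved as the faithful counterpart of the published
figure. The p-value is exact by enumeration when `|A| + |B| <= 12` and a
tie-corrected normal approximation with continuity correction otherwise.
A `random_gene_sample()` helper provides the 500-gene random control set,
deterministic per seed.

## Synthetic data: what it emulates and what it does not

The generator reproduces the statistical *structure* the analysis assumes,
at about one sixth of genome scale so a full run stays under a few minutes:
2000 promoters of 1000 bp (scaling the 12643-promoter universe), up/down
set sizes 175/210 (scaling 1106/1329), planted NACBS-8 sites in 30% of the
up set versus 10% elsewhere, seven expression archetypes over 10 samples,
and Ct tables with eight candidate reference genes of graded stability.
Paper-scale universes are a config switch away.

Design choices worth knowing:

* **Site model vs search model.** Planted sites are words sampled from a
  near-deterministic NACBS-8 variant (`site_weights`, core 0.997). A real
  bound site is a concrete sequence close to consensus; the soft search
  weights (0.94/0.70) describe the degeneracy a scanner must tolerate, not
  the distribution of true sites. Sampling planted sites from the soft
  search model itself would make two thirds of them fall below the exact
  p = 1e-4 detection boundary, which models a scanner sensitivity question,
  not the enrichment question the pipeline is built to answer.
* **Expression archetypes** (log2 amplitudes): a single extreme late riser
  (11.6, the isocitrate-lyase-like pattern), a strong late riser (8), a late
  peak (5), a moderate linear riser (2) and an early riser levelling off (4)
  — the last two being the canonical mid-amplitude patterns whose 2- versus
  4-unit span distinguishes them — plus a marginally-affected flat group
  with a slight mid-course bump (0.8) and a late down-regulated group (−3).
  Shapes were designed to remain distinct after z-scoring, since the
  clustering operates on patterns. Noise is multiplicative lognormal,
  sd 0.2 log2 units.
* **Ct tables**: `Ct = 15 − log2(expression)` plus Gaussian cycle noise
  (sd 0.15) per replicate; 2% of wells get a 3–8 cycle aberration in one
  replicate. The eight reference candidates use noise sds 0.05 (an
  18S-rRNA-like, effectively invariant transcript) and 0.6–1.2 for the
  rest — typical of "housekeeping" genes that in fact drift across a
  senescence series, which is exactly why such screens are run. At 10
  samples the stability measure has an irreducible error floor: even with
  widely separated gradings the most stable candidate wins the ranking in
  about 96–97% of simulations, which is the context for the recovery rates
  the test suite asserts.
* **Microarrays**: genes carry 1–4 probes with distinct 3' distances and
  mild distance attenuation; 5% of probes are "dead" (signal at or below
  background), giving the low-signal filter a known truth; 50 genes are
  shifted by 4 log2 units between the two 3-array condition groups.

What the generator does **not** emulate: real promoter base composition and
repeat structure (sequences are i.i.d. 0-order), probe thermodynamics and
cross-hybridization, dissociation-curve artefacts, and the mutual-rank
structure of curated co-expression databases. Passing tests therefore
demonstrate the correctness and calibration of the *methods* under the
stated generative assumptions — not that any particular biological dataset
will show the same effect sizes.

## Numerical choices and degenerate inputs

* Score grid step 0.01 log2 units; the DP errors out above 1e7 grid cells
  and suggests a coarser granularity.
* Integer rates and percentages round half away from zero (so 91 genes give
  k = 7 and 5000/24646 prints as 20%).
* `summarize_replicates` with all-missing input returns `NA`/`no_data`;
  hypergeometric inputs are validated against every bound with the violated
  inequality named; zero-variance genes correlate at 0 with a warning;
  quantile normalization of a single column is a warned no-op.
* All generators and the clustering are deterministic given their seed;
  `run_pipeline()` writes a manifest (parameter hash + output checksums)
  sufficient to verify a reproduction.

## Known limitations

Only 0-order backgrounds are supported (no higher-order Markov models or
q-values); motif models are fixed-length (no variable spacers within one
model — each spacer width is its own model, as in the reference design); the
moderated statistic is a stand-in, so exact agreement with any specific
microarray pipeline is out of scope; and the co-expression stage builds
rankings from whatever expression matrix it is given rather than from any
external database.

## Problem sizes used by the test suite

The suite exercises the pipeline at the scaled-down defaults above: 2000 ×
1000 bp promoter universes for enrichment power and calibration (400
resampled null sets; 20 seeds for power), 91-gene panels over 20 seeds for
cluster recovery, 100 seeds for reference-gene recovery, and full `4^L`
enumeration for motif lengths up to 6 when validating the exact-p-value DP.
These sizes were chosen so that a complete run remains comfortable on a
single CPU while leaving the statistical assertions well-powered.
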