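---
title: "Methods and design of strainCGH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of strainCGH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainCGH)
```

## The measurement and the question

Comparative genomic hybridization (CGH) on a spotted microarray asks, for
every gene of a fully sequenced reference genome, whether a related strain
carries a sufficiently similar copy. Genomic DNA of the query strain and of
the reference are labelled with two dyes and co-hybridized to an array
carrying one probe per reference CDS. A probe whose gene is present in the
query lights up far above background in the test channel; a probe whose
gene is absent (or too diverged to hybridize) reads essentially background.

From per-strain presence/absence calls over a panel of strains one can
estimate the core genome (genes in every strain), quantify how much of each
plasmid, genomic island or gene cluster each strain carries, group strains
by gene content, and — because horizontally acquired islands are inherited
as contiguous blocks — locate candidate genomic islands as runs of
consecutive variably-present genes.

`strainCGH` implements that full pipeline, plus a synthetic-data generator
with complete ground truth so that every stage can be validated without
scanner output. The default generator layout emulates a four-replicon
metal-resistant β-proteobacterium: two chromosomes and two megaplasmids
carrying 6205 CDS probes, with 13 + 5 planted islands and a strain panel of
7 + 9 strains in two gene-content groups plus plasmid-cured validation
derivatives.

## Background correction: the normexp model with an offset

Net spot intensity (foreground minus local background median) is modelled
per channel and per array as

$$X = B + S, \qquad B \sim \mathcal{N}(\mu, \sigma^2), \qquad
S \sim \mathrm{Exp}(\text{mean } \alpha),$$

the classic normal + exponential convolution of two-colour preprocessing.
`normexp_fit()` obtains maximum-likelihood estimates of $(\mu, \sigma,
\alpha)$ (delegating to limma's estimator, started from method-of-moments
values), and `normexp_correct()` replaces each net intensity by the
posterior mean $E[S \mid X = x]$ plus an **offset of 50** intensity units.
The posterior mean is evaluated in the log domain with an asymptotic branch
for extreme arguments, so the corrected intensity is finite, strictly
increasing in $x$, and always strictly greater than the offset — log-ratios
downstream can never blow up. The test suite checks the analytic posterior
mean against direct numerical integration of $s\,p(s \mid x)$ to $10^{-6}$
relative accuracy, and parameter recovery to better than 10% median
relative error at $n = 10{,}000$.

Both channels are corrected identically; whether the original two-colour
protocols corrected the reference channel the same way is rarely stated,
and correcting both is the symmetric choice.

## Within-array normalization: print-tip loess

Spots deposited by one printing pin (a *print-tip group*, the `block` of
the spot table) share spatial and dye biases that vary smoothly with
intensity. After correction, each spot contributes
$M = \log_2(\text{test}) - \log_2(\text{ref})$ and
$A = \tfrac12(\log_2 \text{test} + \log_2 \text{ref})$;
`printtip_loess()` fits, within each tip group, a robust local linear
regression of $M$ on $A$ (tricube weights, span 0.3, four reweighting
iterations — the conventional defaults of this algorithm family) and
subtracts the fitted trend. $A$ is never altered, and tip groups with
fewer than 10 usable spots fall back to the whole-array fit. No
between-array normalization is performed: calling is within-array by
construction.

One design point deserves emphasis: **presence calling does not use the
loess-adjusted intensities.** Loess re-centres $M$ locally in $A$; in a
CGH experiment the absent genes *are* the low-$A$, low-$M$ population, so
a loess fit through them would absorb exactly the signal the caller needs.
Calling therefore uses the normexp-corrected test-channel intensity, while
the loess-normalized M/A values serve diagnostics and ratio-based outputs.

## Presence calling: fold over background, calibrated on known content

For each spot, `fold_change()` computes

$$\text{fold} = \frac{\text{corrected test intensity}}
{\text{background reference} + \text{offset}},$$

where the background reference is the spot's own measured background
(default, `per-spot`) or the array-wide fitted $\hat\mu$
(`array-background`). A gene is called **present when fold ≥ 20**
(inclusive), the cutoff used for the final strain comparisons; flagged
spots (any negative flag, the scanner-software convention) become "no
data" (`NA`), never absence. Multi-probe genes collapse by majority over
valid probes, ties giving `NA`.

The cutoff is not arbitrary: `calibrate_cutoff()` evaluates a grid
(default 1–100 by 0.5) against hybridizations of strains whose true
content is known — in the synthetic study, derivatives of the reference
cured of either megaplasmid — counting false positives (known-absent
called present) and false negatives (known-present called absent) at every
candidate cutoff and returning the smallest cutoff minimizing their sum
(deterministic, and conservative toward sensitivity). On default synthetic
data the calibrated trade-off and the 20-fold cutoff both achieve
fp + fn well below 1% of genes, and end-to-end per-gene accuracy against
generator truth exceeds 99%.

## Gene-content statistics and reporting conventions

* `core_set()`: the core is genes called present in **every** strain; a
  gene with "no data" anywhere is excluded from the core but kept in the
  denominator, so missingness can only shrink the reported core fraction,
  never inflate it.
* `pairwise_overlap()`: shared counts per strain pair; the diagonal is
  each strain's detectable-gene total. The reported percentage divides by
  the *smaller* of the two totals (bounded by 100; a strain whose content
  contains another's scores exactly 100), with the mean-of-totals variant
  available as an option.
* `region_occupancy()`: per gene set and strain, the percentage of
  *informative* members called present. "No data" members leave both the
  numerator and the denominator, so flagged spots cannot masquerade as
  absence. The present-member list per cell is retained for gene-level
  tables.
* Report rounding is one decimal, half-up (`round_half_up()`), matching
  how such occupancy tables are conventionally printed; values are stored
  unrounded and rounded only at report time.

## Clustering strains by gene content

Strains are clustered on profile vectors — by default each strain's row of
the pairwise shared-gene percentage matrix — using the distance
$d(i,j) = 1 - \text{cor}(p_i, p_j)$ and **complete linkage**
(`stats::hclust`), whose merge heights are non-decreasing by construction.
The two main content groups are obtained by removing the root merge
(`cut_two_groups()`), labelled I/II by decreasing mean island occupancy
when available, otherwise by size.

Two design choices are worth recording:

* **Profile convention.** The *reported* overlap percentages use the
  min-of-totals convention above. As clustering features, however, those
  percentages are uninformative precisely when one group's gene content
  nearly contains the other's (the situation this kind of strain panel
  presents: one group carries almost all mobile elements): containment
  forces cross-group percentages to saturate at 100, and the within-group
  signal vanishes. `overlap_profiles()` therefore uses the mean-of-totals
  percentage, which preserves content-size differences; with the default
  synthetic conditions it recovers the planted two-group partition with
  Rand index 1.0 (20-seed median) where the min-based profiles fail.
* **Support statistic.** `bootstrap_support()` resamples genes (the only
  exchangeable unit behind the profiles) with replacement, recomputes
  profiles → distances → trees, and reports for each internal node the
  percentage of replicates containing that node's exact strain set as a
  clade — the ordinary bootstrap probability (BP). This is deliberately
  *not* the multiscale approximately-unbiased (AU) p-value some clustering
  tools report: BP is fully specified, deterministic under a fixed seed,
  and checkable against a brute-force resample-recluster loop, which the
  test suite does. BP and AU values are not numerically interchangeable.

Trees serialize to newick with supports as internal node labels.

## Island scanning: a run-based formalization of pattern reading

Cartographic presence/absence maps make genomic islands visible as blocks
of genes absent from several strains. `scan_islands()` formalizes that
reading. First `gene_variability()` classifies each gene over the panel:
*conserved* (absent in no strain), *variable* (absent in ≥ `min_absent`
strains — default 4 — and present in ≥ `min_present` — default 1), else
*uninformative*; "no data" calls are ignored. A candidate island is then a
run of consecutive loci on one replicon that

1. starts and ends on a variable gene,
2. spans at least `min_genes` loci (default 5),
3. contains no more than `max_gap` consecutive non-variable loci
   (default 2), and
4. is at least `min_variable_frac` variable overall (default 0.8).

Maximal qualifying runs are reported; overlapping candidates resolve to
the longest. The implementation segments each replicon at gaps longer than
`max_gap` (no qualifying window can span one) and enumerates within
segments; the test suite proves it equal to exhaustive enumeration of all
windows on hundreds of random instances. All four knobs are configuration:
the defaults reproduce block-wise island structure on synthetic data
(recall ≥ 0.9 at default noise, exact boundaries noise-free) but any
run-based rule is an approximation to expert eyes on real maps.

Coordinates are 1-based inclusive; `island_size_kb()` is
$(\text{end} - \text{start} + 1)/1000$ rounded half-up to one decimal,
which reproduces published island-size tables from their printed
coordinates. `merge_split_island()` handles islands split in two by a
chromosomal inversion: the merged size is the **sum of the parts** — not
the spanning interval, which would silently include the unrelated sequence
between them — and the per-strain profile is the gene-count-weighted mean.
BED output is 0-based half-open; the report table stays 1-based inclusive.

## The synthetic-data generator

`build_genome_model()`, `assign_strain_content()`,
`make_validation_derivative()` and `simulate_scan()` generate the study.
Key modelling decisions, fixed once:

* **Layout.** Loci are laid out on a regular non-overlapping grid per
  replicon; islands are planted one per equal-width bin of the locus index
  (lengths 5–150 genes by default), so planted regions never touch.
  Plasmid replicons are additionally recorded as whole-replicon
  "plasmid-backbone" regions, the targets of cured derivatives.
* **Inheritance.** Backbone loci are present in every strain. Each planted
  region is inherited as a block with its group's probability (defaults:
  islands {I: 0.9, II: 0.2}; plasmid backbones {I: 1.0, II: 0.7}),
  followed by per-locus dropout (default 0.02) emulating diverged genes
  inside a carried element.
* **Intensities.** Backgrounds are Normal(100, 15²) on a 16-bit-like
  scale. A present spot's signal has mean `alpha_s` = 20,000, drawn as a
  detection floor (25% of `alpha_s`) plus an exponential spread above it.
  The floor reflects the physics of the assay — a truly present,
  hybridizing probe produces at least a markedly above-background signal;
  signals arbitrarily close to zero would belong to diverged genes, which
  the dropout mechanism models as absent instead — while the exponential
  tail keeps the intensity distribution compatible with the normexp
  correction model. A pure zero-anchored exponential would place ~15% of
  present genes below any 20-fold threshold, making the published cutoff
  unusable by construction rather than by measurement.
* **Controls.** Each simulated slide carries 600 blank buffer spots
  (`CTRL*` probes, background in both channels), interleaved over the
  print-tip grid as on real spotted arrays. Besides realism they matter
  statistically: for a strain carrying nearly every gene, the gene probes
  alone leave the background component of the normexp fit almost
  unidentified, and the estimator can anchor the "background" normal on
  the bright present-spot mode; the control cloud pins it down.
* **Biases.** Print-tip bias multiplies the test channel by
  $2^{0.3u}$ with $u$ spread over $[-1, 1]$ across the 4×4 blocks, and a
  dye trend multiplies it by $2^{0.15 (A - \bar A)}$ — both within the
  range print-tip loess is designed to remove. 2% of spots are flagged
  bad. Intensities are rounded to integers as a median-reporting scanner
  would.

What the generator does **not** emulate: cross-hybridization, probe GC or
length effects, saturation, spatial gradients within a block, and
inter-array batch structure. Passing tests therefore demonstrate that the
pipeline's logic is correct and well-calibrated under the stated noise
model, not that a 20-fold cutoff is optimal for any particular real
scanner and labelling chemistry — on real data the cutoff should be
re-calibrated against strains of known content exactly as the pipeline
does here.

Every stochastic operation takes an explicit integer seed, and a fixed
(configuration, seed) pair reproduces outputs byte-identically, including
the bootstrap supports.

## Numerical and degenerate-input choices

* `normexp_fit()` requires ≥ 50 finite values and non-zero variance.
* Corrected intensities are strictly > offset, so fold changes and
  log-ratios are always defined; no denominator can reach zero.
* Calibration requires ≥ 20 informative truth genes and warns when either
  truth class has fewer than 10 (one-sided calibration).
* Tip groups with < 10 spots fall back to the whole-array loess fit.
* Bootstrap replicates whose resampled profiles are degenerate (constant,
  or empty after resampling) contribute to no clade and still count in the
  denominator.
* Tied optimal cutoffs resolve to the smallest; overlapping island
  candidates resolve to the longest; `which.min` ties resolve first-index,
  making all tie-breaks deterministic.

## Problem sizes used by the test suite

The checks are sized to run comfortably on one CPU: the posterior-mean
oracle at 1,000 random parameter tuples; MLE recovery over 20 seeds at
n = 10,000; calling accuracy on one full default study (6,205 probes ×
16 strains + 2 derivatives); clustering recovery over 20 seeds at the
default genome with 200 bootstrap resamples; the island-scanner oracle on
100 random instances of ≤ 50 loci × 8 strains; and island recall over 20
seeds at 600-locus genomes with full scan simulation and calling. These
sizes are the package's choices for routine validation; all of them can be
scaled up through the same functions.

## Known limitations

* The island rule detects *variably present runs*; islands carried by
  every strain in the panel are invisible to it, as they are to the
  underlying experiment.
* Presence calls are per-gene and binary; partial-gene divergence and
  copy-number differences are out of scope.
* The overlap-percentage clustering treats strains as exchangeable
  profiles; it is a content comparison, not a phylogeny.
* Real GEO-deposited scan matrices can be adapted to the spot-table format
  by the user, but no GEO/SOFT ingestion is provided.
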