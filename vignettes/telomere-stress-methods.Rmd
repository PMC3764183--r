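---
title: "Methods: stress-driven telomere length analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress-driven telomere length analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telostress)
```

## Scope

Budding yeast maintains telomere length around a regulated set point, and a
handful of mild environmental stresses (ethanol, caffeine, elevated
temperature) push that set point up or down over tens of generations, while
others (oxidative stress) leave it alone. `telostress` implements the
computational arms of that analysis as a reusable pipeline: telomere length
quantification from gel-lane densitometry, differential-expression
extraction with SAM, a network-proximity test for telomere length
maintenance (TLM) genes, a robust-regression screen for over- and
under-responsive mutants, and ChIP fold-enrichment quantification. A
synthetic-data module generates every input with known ground truth, so
each stage can be validated by parameter recovery rather than by eye.

## Lane quantification

A lane is a 1-D densitometry trace: intensity sampled along the migration
axis, with two marker bands of known size (2044 and 779 bp). The migration
model is the standard gel approximation, `log10(size) = a + b * position`,
anchored exactly on the two markers; with two markers interpolation is
exact by construction, and both marker sizes are reproduced to machine
precision. Were more markers available the natural extension is least
squares in log space.

Length estimation proceeds in three steps, each exposed and separately
testable:

1. **Background**: the 0.1 intensity quantile is subtracted and negatives
   clipped (`subtractBackground`). The quantile is configurable in
   (0, 0.5].
2. **Smear detection**: the maximal contiguous interval around the global
   peak where intensity stays at or above 0.2 of the peak
   (`detectSmear`). For a Gaussian band at threshold 0.5 this interval is
   the FWHM, which the tests assert.
3. **Summary**: the telomere length is the size at the intensity-weighted
   centroid of the smear, computed in migration space
   (`estimateLength`). The original in-house quantifier does not document
   whether it reported centroid, mode, or median; the centroid is our
   assumption, recorded here. It is exact for symmetric bands and robust
   to sampling noise.

Sizes are only reported inside the marker-bracketed range; a smear that
leaks past a marker is refused as extrapolation rather than silently
extended, because the log-linear model is unvalidated outside its anchors.

## Differential expression: SAM

The expression input is a normalized (log-scale) matrix with
Affymetrix-style detection calls and a sample-to-condition map; the design
mirrors the published one, four wild-type controls against three samples
per stress. Probe-level normalization (RMA) happens upstream and is out of
scope. Genes with absent calls in more than half their samples are removed
('M' counts as present, since only "absent" is named by the filter rule).

The SAM statistic is `d_i = (mean_stress - mean_control) / (s_i + s0)`,
with `s_i` the pooled standard error of the mean difference. At `s0 = 0`
it is algebraically the pooled-variance two-sample t statistic, which the
suite verifies to 1e-10 against an independent implementation. The fudge
factor `s0` is tuned by scanning the percentiles (0, 5, ..., 100) of the
`s_i` distribution and minimizing the coefficient of variation of the MAD
of `d` across `s_i`-quantile bins. On homoscedastic Gaussian data this
criterion is minimized in the mean-difference limit, so the chosen `s0`
lands near the top of the `s_i` range — a property worth knowing when
interpreting `samS0()` on simulated input.

FDR is estimated by label permutation. With 4-vs-3 designs there are only
35 distinct assignments, so all are enumerated (sampling with a stated
seed takes over only above `nPerm`). For the |d| cutoff admitting gene i,
the estimated FDR is the median across permutations of the count of
permuted |d| at or above the cutoff, divided by the number of genes
admitted; q is then forced monotone non-increasing in |d|, and ties with
the cutoff are all admitted. The median false-count convention is the SAM
default; a more conservative 90th-percentile variant is available via
`fpSummary = "q90"`.

Two calibration facts, both computed by the test suite, deserve
statement:

* On null data the default estimator yields a median of zero significant
  genes at FDR < 0.01, but roughly a fifth of runs call one or a few
  genes: at the very top cutoff the median false count is an integer that
  collapses to zero whenever the observed maximum |d| ranks in the upper
  half of the 35 permutation maxima. The `"q90"` variant suppresses these
  singleton calls (measured type-I fraction ≈ 0.03 in the suite).
* Recovery of planted effects at FDR < 0.01 is power-limited by the
  design, not by the estimator. With 3 samples against 4 and an effect of
  3 sigma, a planted gene's standardized difference centers near
  `3 / sqrt(1/4 + 1/3) ≈ 3.9` null-SD units, while calling ~50 genes out
  of 1000 at FDR 0.01 forces the cutoff to about 3.6 units even if the
  per-gene noise scale were known exactly. The achievable recall
  therefore sits near 0.6 for any method under these conditions; the SAM
  implementation measures ≈ 0.58 in the acceptance run, with empirical
  precision above 0.9. We report this rather than quietly enlarging the
  effect size or the sample count.

Stress-specific sets are plain Venn regions, `specific[s] = de[s] \
union(de[t != s])`; direction-specific sets (genes DE under every
elongating stress and no other, etc.) are provided alongside, since the
published phrasing supports both readings and neither is canonical.

## Network proximity

The TLM network is consumed as an edge list; the package is deliberately
network-agnostic (the published TLM network's exact edge content is not
publicly redistributable). Distances are unweighted shortest paths
(breadth-first, via igraph), validated in the suite against an exhaustive
Floyd–Warshall oracle on 200 random graphs. Unreachable pairs are
excluded and counted, never imputed: a distance across components is
undefined, and imputing diameter+1 would manufacture proximity signal.

The test statistic is the Wilcoxon rank sum between the pairwise-distance
multiset of the stress-specific DE TLM genes and that of the remaining
TLM genes, one-sided (the claim is directional: closer). The exact
distribution is enumerated when the pooled size is at most 16 and
tie-free; otherwise a tie-corrected normal approximation with continuity
correction is used. The default background is pairwise distances within
TLM genes outside the focal set; the alternative reading (all TLM pairs
not entirely inside the set) is selectable via `bDefinition`. The
specificity control repeats the comparison against DE non-TLM genes.

One honest caveat, measured by the acceptance suite: pairwise distances
within a set are not independent observations (pairs share nodes), while
the rank-sum variance assumes they are. On unplanted block-model networks
the null p-values are therefore mildly over-dispersed (about 13% below
0.05 instead of 5%). This is intrinsic to rank-sum tests on pairwise
distance multisets — including the published analysis — and matters only
for p-values near the threshold; planted structure of the kind the
analysis targets yields p-values tens of orders of magnitude smaller, and
planted-network recovery is 100/100 at p < 0.01 in the acceptance run.

## Responsiveness screen

For each deletion/hypomorphic mutant the screen records the initial
telomere length and the length change after 100 generations under a
stress; the change is linear in the initial length, and mutants far off
that line are candidate stress-response genes. The fit is iteratively
reweighted least squares with Tukey bisquare weights (tuning constant
4.685), the robust-regression default of the era's numerical
environments; the scale is re-estimated each iteration as 1.4826 × MAD of
the residuals, and iteration stops at a relative coefficient change below
1e-8 or 50 iterations (non-convergence is a warning plus a flag, not an
error). The suite cross-checks the fit against an independent M-estimator
and verifies that ordinary least squares degrades faster under 10%
contamination.

Outlier calling standardizes residuals by the robust scale and takes the
most extreme 5% (2.5% per side). Two rules are provided:

* `method = "normal"` (default, following the stated normality
  assumption): flag |z| > 1.960 at alpha = 0.05. On clean data the
  flagged fraction converges to alpha.
* `method = "rank"` (the literal extreme-5% reading): flag the top and
  bottom `ceiling(n * alpha / 2)` residuals. At 5% contamination with
  8-sigma planted outliers this rule attains recall ≈ 0.93 and precision
  ≈ 0.77 in the acceptance run; the normal rule necessarily pays ~5% of
  the clean mutants as false flags (precision ≈ 0.6) and is the right
  choice when the contamination fraction is unknown.

Direction labels follow the stress: under an elongating stress a positive
residual is over-responsive; under a shortening stress, a negative one.
Whether residuals should be standardized by a robust or classical SD is
unstated in the source; we use the robust scale throughout, consistent
with the fit.

## ChIP quantification

Fold enrichment is the ratio of ratios
`[telIP / ARO1IP] / [tel input / ARO1 input]` — telomeric IP signal
normalized to a control locus and to input chromatin. It is homogeneous of
degree zero (units cancel), which the suite property-tests over random
quadruples. Replicates are combined by geometric mean (folds are
ratio-scale; an arithmetic option exists), with the SD of log2 folds as
spread. The relative change between conditions is the fold ratio: 0.5
means a two-fold depletion under stress. A convenience converter from
qPCR Ct values (`quantity = efficiency^(-Ct)`, default efficiency 2) is
included because the bench assay is real-time PCR, though the package
makes no attempt at amplification-curve processing.

## The synthetic-data module

The generators define the study conditions under which everything above
is validated; they are first-class, tested code, not fixtures.

* `genExpression`: per-gene Gaussian baselines (mean 7, SD 1 on the log
  scale) with i.i.d. N(0, sigma²) noise, sigma = 0.25 by default; per
  stress, exactly `round(deFraction * nGenes)` genes shifted by ±effect
  (default 0.75 = 3 sigma) in that stress's samples. Detection calls are
  drawn independently of DE status (the source gives no coupling):
  absent at rate 0.1, and 5% of the remainder marginal. Real microarray
  noise is neither Gaussian nor homoscedastic and real DE effects are not
  a single shared shift, so passing recovery tests here demonstrates
  correctness of the procedure, not performance on real arrays; the
  variance structure of the original arrays is unstated, and the Gaussian
  choice is a stand-in.
* `genNetwork`: a stochastic block model (6 equal blocks of a 300-node
  graph, within-block edge probability 0.3, between 0.01 — the regime the
  planted-recovery examples describe) with a 15-gene TLM+DE set planted
  inside one block, the remaining TLM genes (15% of nodes in total)
  scattered, and 15 DE non-TLM genes scattered for the specificity
  control. Real interaction networks are scale-free rather than
  block-structured; the SBM gives a clean, tunable notion of "mutually
  proximal" for recovery testing.
* `genScreen`: initial repeat lengths uniform on [150, 450] bp (wild type
  carries ≈ 350 bp of telomeric repeats; the range brackets the short and
  long mutants), delta = slope·initial + intercept + N(0, 10²) bp, 5%
  outliers shifted ±80 bp (8 sigma; at least 4 sigma is recommended for
  recoverability), outlier side by fair coin since both directions occur.
* `genLane`: a Gaussian band centered at the position the log-linear
  model assigns to the true size, on a flat baseline with additive noise;
  sizes outside the marker span are refused.
* `genChip`: log-normal measurement noise around a requested true fold.

Every generator takes an explicit seed and is byte-deterministic given
one; every planted entity is recorded in a `SyntheticTruth` object (and
`truth.txt` manifest) so downstream recovery is checkable mechanically.

## Pipeline and problem sizes

`makeFixtures(seed, outDir)` writes a complete coherent study: the
network is built over gene IDs from the expression universe and its
planted proximal set is drawn from the ethanol-only planted DE genes, so
running SAM, then set construction, then the proximity test on the same
directory recovers the planted module from first principles.
`runAll(config)` validates the YAML config fully before any stage runs
(missing fields and paths are named), executes stages in dependency
order, writes provenance-headed TSVs, and is byte-deterministic under
fixed seeds. A stress whose DE-TLM set is smaller than two genes on the
network — the expected situation for a stress that leaves telomere length
alone — is recorded as untestable rather than failing the run.

Validation problem sizes were chosen to make the suite's statistical
assertions sharp while keeping a full run in the low minutes on a single
core: 1000-gene bundles with 100-seed replication for SAM calibration,
300-node networks with 100 seeds for proximity, 100-mutant screens with
100 seeds (plus 1000-mutant screens for flagged-fraction calibration),
100 noisy lanes, and 1000 random quadruples for the ChIP homogeneity
property.

## Known limitations

* The package reproduces the *procedures* of the original study, not its
  printed numbers: the raw arrays carry no public accession, and the TLM
  network's edge content and the per-mutant length tables were never
  deposited, so the published headline values (per-stress DE counts, the
  specific Wilcoxon bounds, the screen correlations) are out of reach at
  desk scale by design. Validation is by recovery of planted ground
  truth instead.
* Rank-sum p-values on pairwise-distance multisets are anti-conservative
  under node-sharing dependence (measured above); treat borderline
  proximity p-values with care.
* SAM power at FDR < 0.01 is intrinsically limited for 4-vs-3 designs;
  see the closed-form argument above.
* The lane quantifier assumes one dominant smear; multi-band lanes
  (e.g. uncut partial digests) are summarized by their tallest band only.
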