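---
title: "Methods: measuring mosaic loss of chromosome Y"
author: "mosaicLOY"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring mosaic loss of chromosome Y}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicLOY)
```

# The measurement problem

In single cells, loss of chromosome Y (LOY) is binary; in bulk DNA from
whole blood it appears as a continuous mosaicism between 0 and 100% of
cells. Three technologies read this fraction out in different currencies:

* a SNP genotyping array reports, per probe, the Log R Ratio (LRR) — the
  log2 of observed over expected signal intensity, a proxy for local copy
  number;
* whole-genome sequencing reports read depth, proportional to copy number;
* droplet digital PCR (ddPCR) reports absolute target concentrations via
  Poisson statistics on ~15,000 droplet partitions.

The package implements the three readouts, the calibration that connects
them, and longitudinal analysis of serially sampled subjects.

# The array pathway: mLRRY

`computeMLRRY()` summarises a sample as the **median** LRR over probes in
the male-specific region of chromosome Y (MSY; default
chrY:2,781,480–56,887,902, 1-based and closed at both ends — the closed
interval is our reading of inclusive range notation, and `msyRegion()`
accepts build-specific coordinates). The median rather than the mean keeps
outlier probes (e.g. in ampliconic regions) from dominating; the test suite
checks this robustness property directly by contaminating 10% of probes.
Probes with missing LRR are excluded, never imputed.

QC (`qcSamples()`) requires at least 100 non-missing MSY probes (a robust
median needs support), an LRR standard deviation of at most 0.30 (a noisy
array criterion, computed over **autosomal** probes so that a genuinely
high-LOY sample is not mistaken for a noisy array — in our synthetic arrays
MSY probes are a large fraction of the chip, unlike real genome-wide
arrays), and at most 5% missing values. All three thresholds are arguments,
not constants. QC failure is a recorded state: no sample is dropped, and a
failed sample carries its reasons.

## Batch correction

Arrays processed in different batches or chip versions shift the mLRRY
scale. Because samples without Y loss (mLRRY near 0) dominate any
realistic cohort, the **mode** of a batch's mLRRY distribution sits at the
batch's technical offset. `estimateBatchMode()` estimates that mode by a
Gaussian kernel density (bandwidth by Silverman's rule of thumb,
configurable) evaluated on a 512-point grid spanning
\[min − 3h, max + 3h\]; `correctBatchEffects()` subtracts it per batch.
Ties in the density maximum are broken toward the grid point closest to
zero (no-loss samples are expected to dominate); a batch of identical
values returns that value; batches smaller than 25 samples keep raw values
with a flag, since a mode estimated from few points is worse than no
correction. Whether the original correction subtracted a mode or re-centred
through a local regression over experiment order cannot be pinned down; the
KDE-mode subtraction implemented here is a well-defined operationalisation
and is labelled as such. It is location-equivariant — shifting a batch by a
constant leaves corrected values unchanged to grid resolution — which the
property tests verify. The mode is accurate at realistic batch sizes
(hundreds of samples); at a few dozen samples per batch the multimodal
mixture of no-loss and mosaic samples can displace it, which is why the
minimum batch size exists.

# Calibration and the transformation

The depth and droplet readouts are linear in the Y fraction; the array
readout is logarithmic and compressed. `fitPowerCalibration()` fits

$$ y = a \, (2^{\mathrm{mLRRY}})^{b} $$

between the antiloged statistic and the orthogonally measured Y fraction by
ordinary least squares on the log-log scale (slope $b$, intercept $\ln a$),
with the log-scale $R^2$ as diagnostic. A nonlinear least-squares route
(`method = "nls"`, started at the log-log solution, with a scale offset in
the convergence test so that noiseless data converge) is provided as a
cross-check; both agree exactly on noiseless input. Pairs with non-positive
measured fraction have no logarithm and are excluded and counted. Constants
are rounded half-away-from-zero to the nearest integer; on well-calibrated
data the fit approaches $(a, b) = (1, 2)$, giving the closed forms

$$ \text{percent with Y} = 100 \cdot 2^{2\,\mathrm{mLRRY}},\qquad
   \mathrm{LOY}\,(\%) = 100 \,(1 - 2^{2\,\mathrm{mLRRY}}). $$

The factor 2 in the exponent is an intensity **compression**: the array
responds to a halving of Y dose with only half the expected log-intensity
change. The transformation is strictly monotone, approaches 100% only
asymptotically, and is inverted exactly by
`mlrryFromLoyPercent()` (round-trip verified to 1e−9 over
mLRRY ∈ \[−4, 0.2\]).

Negative LOY (apparent mosaic **gain** of Y) is reported, not clamped; the
`goyFlag` is raised when LOY falls below −2 percentage points (tolerance
configurable), and clamping to \[0, 100\] is opt-in. The comparison formula
`veitiaLoyFraction()` ($1.8(1 - 2^{\mathrm{mLRR}}) + 0.015$, fraction
scale) is evaluated on the same inputs as the main transformation; whether
its published applications used batch-corrected arguments is unknown, so
comparisons here always feed both formulas identical values.

# The sequencing pathway

`gcMappabilityCorrect()` discards windows with mappability below 0.8,
divides counts by mappability, and flattens GC bias by rescaling each
window by the ratio of the global autosomal median to its GC-decile-bin
median. Bin medians come from autosomal windows; bins with fewer than 20
such windows fall back to the global median. A decile-bin median was chosen
over a loess fit deliberately: it is deterministic, has no tuning
parameter beyond the bin count, and the property it must deliver — a flat
regression of corrected count on GC — is tested directly.

`chrYPloidy()` divides the median corrected count of Y windows inside the
MSY by half the median corrected autosomal count. The restriction to the
MSY (rather than all of chromosome Y) avoids pseudo-autosomal windows whose
dose is carried by both sex chromosomes; the choice of Y intervals used by
the original pipeline is not recoverable, so this restriction is our
documented decision. The estimator is scale-invariant, robust to a minority
of zeroed Y windows (median), and linear in the true fraction — the
property that lets depth anchor the array calibration. At least 50 MSY
windows are required; 0/`NA` ploidy states (all-zero Y counts = complete
loss) are legitimate outputs, not errors.

# The droplet pathway

Each droplet captures 0, 1 or more template copies, so the positive
fraction under-counts concentration; `poissonLambda()` recovers mean copies
per droplet from the zero class, $\lambda = -\ln(1 - p)$. A fully positive
channel is saturated (error). `wellRatio()` divides the FAM (AMELY) by the
VIC (AMELX) concentration — droplet-volume factors cancel — and
`aggregateDuplicates()` averages duplicate wells, flagging a sample for
re-analysis when the ratio standard deviation ($n-1$ denominator) is 1.2 or
higher, applied on the ratio scale exactly as published (the threshold is
permissive for ratios near 1 and is configurable). Channels are modelled
independently; double-positive droplets are not treated separately, a
simplification stated here once. A pass-through mode accepts pre-computed
instrument ratios.

# Longitudinal analysis

`buildSeries()` joins estimates to (subject, age) metadata; withheld
estimates drop the point, not the subject. The published account names
trajectory patterns without an algorithm, so `classifyTrajectory()` uses
explicit rules, all thresholds exposed: *progressor* requires OLS slope
≥ 0.75 %/year **and** net change ≥ 5 points; *decliner* the mirror;
*complex* requires ≥ 3 points and a pair of consecutive inter-visit changes
of opposite sign, each of magnitude ≥ 5 points (the literal reading of a
rise-then-fall / fall-then-rise pattern); *stable* otherwise, and fewer
than 2 points is *insufficient*. Complex takes precedence over
progressor/decliner. The defaults (0.75 %/yr, 5 points) were set once to
separate clearly progressing clones from measurement noise of the array
pathway (≈ 1 point per measurement at the default simulator settings) and
are not fitted to anything.

`highLoySubset()` keeps subjects whose maximum LOY reaches the threshold —
**inclusive**, "on or above" — default 30%. `ageAssociation()` pools all
samples in a simple OLS of the readout on age and reports the standardized
coefficient $\beta = b \,\mathrm{sd(age)}/\mathrm{sd(response)}$ (equal to
the Pearson correlation in simple regression, which the tests cross-check
against `pairwiseConcordance()`). Pooling ignores within-subject
correlation; a cluster-robust standard error (sandwich estimator, clusters
= subjects) is available via the `cluster` argument and off by default to
match the simple published model.

# The synthetic cohort

`simulateCohort()` generates ground-truth-labelled data for all three
pathways. Its defaults are the study conditions: 276 subjects contributing
exactly 798 samples, 2–5 draws each, ages 70–93, follow-up span at most
22.2 years; the random draw schedule is repaired deterministically to the
exact sample total. Trajectory archetypes are assigned with proportions
(progressor 0.34, stable 0.50, decliner 0.06, complex 0.10 — about one
third progressors, a few decliners); subjects with fewer than three draws
cannot be complex and draw from the remaining mix.

Generative models per pathway:

* **Array.** MSY probe LRR ~ Normal(0.5·log2(w) + batch offset, 0.15),
  autosomal probes ~ Normal(0, 0.15), where *w* is the true fraction of
  cells with Y. The mean embeds the factor-2 compression under which the
  closed-form transformation is exact — a modelling choice, stated
  prominently: it makes the calibration's target recoverable, and the
  per-probe noise level (0.15, not printed anywhere authoritative) is an
  assumption exposed as a parameter. Batches follow the sampling wave, so
  batch and draw occasion are confounded as they would be in a real serial
  study.
* **Depth.** Window counts ~ Poisson(copies · λ₁ · GC bias · mappability)
  with λ₁ = depth·windowSize/readLength/2 (≈ 1000 per haploid copy at 30×,
  10 kb windows, 150 bp reads); autosomes have 2 copies, MSY windows *w*.
  A linear GC bias and a low-mappability minority exercise the correction.
* **ddPCR.** VIC positives ~ Binomial(n, 1 − e^(−λₓ)), FAM positives ~
  Binomial(n, 1 − e^(−w·λₓ)), defaults 15,000 droplets and λₓ = 0.2.
* **Trajectories.** Progressors grow the LOY clone along a scaled logistic
  (non-linear, strictly monotone) with net change
  max(8 points, U(1.5, 3.5) %/yr × span); decliners mirror it; stable
  subjects jitter around a constant (sd 1 point), a small fraction (2%)
  with baseline fraction-with-Y up to 1.08 to exercise gain-of-Y flagging;
  complex subjects take per-visit steps of ≥ 8 points up then down (or the
  reverse). These effect sizes were fixed once as what a clearly
  progressing / clearly declining clone looks like against ≈ 1 point of
  array measurement noise.

A `truth` table accompanies every output; nothing unlabelled is generated.
Matched technology subsets mirror the pairwise study design: 121 samples
with duplicate ddPCR wells, 26 of those with sequencing windows.

**What the generator does not emulate:** probe cross-hybridisation, wave
artifacts, ampliconic-region intensity outliers beyond Gaussian noise,
double-positive droplet physics, alignment and duplicate-marking artifacts,
cell-type composition. Passing recovery tests therefore demonstrate
correctness of the estimators under the stated generative models, not
performance on any real cohort.

# Numerical choices and degenerate inputs

* Median of an even count: mean of the two central order statistics.
* KDE mode ties: toward zero; zero-variance batch: the common value.
* Rounding of calibration constants: half away from zero.
* `loy = 100` has no finite mLRRY (domain error on inversion); saturated
  droplet channels and zero-concentration reference channels are errors.
* Problem sizes in the test suite — 500-replicate recovery runs at 2,000
  MSY probes, single-seed depth simulations at 4,400 windows, the default
  276-subject cohort for classifier recovery — were chosen so each
  stochastic check resolves its stated tolerance comfortably while the
  whole suite stays fast to iterate.

# Known limitations

* The batch-mode correction assumes no-loss samples dominate each batch;
  cohorts enriched for extreme mosaicism would shift the mode.
* The ddPCR re-run threshold operates on the ratio scale as published; it
  barely constrains wells with ratios near 1.
* Trajectory categories are a concretisation of a verbal description;
  the classifier can be validated against simulated archetypes only, not
  against the original study's calls.
* The pooled age regression ignores repeated measures unless the
  cluster-robust option is used.
* The published calibration constants (e.g. a = 0.9242, b = 1.7703 against
  sequencing) derive from non-public cohort data; the fitting routine is
  validated on synthetic pairs where the truth is known.
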