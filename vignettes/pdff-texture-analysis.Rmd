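---
title: "Quantifying muscle fat infiltration patterns on PDFF maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying muscle fat infiltration patterns on PDFF maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdfftexture)
```

## The problem

Chemical shift encoding-based water–fat MRI yields proton density fat
fraction (PDFF) maps: per-voxel fat content in percent. The mean PDFF over a
segmented muscle is an established biomarker of muscle fat infiltration,
but it discards *how* the fat is arranged. Two muscles with identical mean
PDFF can differ structurally — diffuse, homogeneous infiltration versus
fat organized in streaks along the fibres — and that arrangement plausibly
matters for muscle function. Texture analysis quantifies the arrangement:
first-order statistics of the ROI intensity histogram, and second-order
statistics of the gray-level co-occurrence matrix (GLCM), which capture the
joint distribution of neighbouring voxel intensities.

This package implements that pipeline for thigh-muscle PDFF maps — knee
extensors (EXT, quadriceps) and flexors (FLEX, ischiocrural muscles), left
and right — together with the statistical layer that relates the features
to maximum voluntary isometric contraction (MVIC) strength, and a synthetic
phantom/cohort generator that makes every stage testable without subject
data.

## The feature set

Twelve parameters are computed per muscle:

* **mean PDFF** — the arithmetic mean of the in-ROI voxel values (percent);
* **3 global features** — variance, skewness and kurtosis of the ROI
  intensity histogram;
* **8 second-order features** — energy, entropy, contrast, homogeneity,
  correlation, variance, sum-average and dissimilarity of the 3D GLCM,
  averaged over the 13 neighbour directions.

### Preprocessing

GLCM displacements are single voxel steps, so voxel geometry must be
isotropic for the 13 directions to be metrically comparable. Volumes are
trilinearly resampled to 2 mm isotropic by default (the in-plane
acquisition resolution of a typical thigh protocol whose voxels are
3.2 × 2.0 × 4.0 mm); masks are resampled nearest-neighbour and re-binarized
at 0.5. The grid convention is fixed and documented: voxel *i* covers the
half-open interval [(i−1)·s, i·s) with its centre at (i−0.5)·s, and output
sample points beyond the input centre range are clamped (replicate
padding), which makes interpolation exact for constant volumes.

In-ROI intensities are then quantized onto `Ng = 200` equally sized bins.
The level of value *v* is `ceiling(Ng * (v - min) / (max - min))`, with the
minimum mapped to level 1 and the maximum to level Ng. Two window choices
are supported:

* `window = "roi"` (default): bin edges span the in-ROI min..max. This
  prevents GLCM sparseness when the ROI occupies a narrow intensity band
  (lean muscle typically spans only a few PDFF percent) and is how
  "the minimum and maximum gray levels present" is most naturally read.
* `window = "fixed"`: edges span a fixed physical range (0–100 % by
  default), making level units identical across ROIs.

The choice matters for *between-ROI* comparisons. Per-ROI windows express
texture in ROI-specific units: an ROI with a wider intensity range
compresses the same physical noise into fewer levels. When the analysis
question is "do two ROIs with the same mean differ in texture?", the fixed
window is the commensurable instrument, and the package's own
separability analysis (below) uses it. For screening within a cohort where
each muscle contributes its own feature values to a regression, the
default per-ROI window follows the texture-analysis convention. Both are
one config switch apart.

A constant ROI cannot be quantized meaningfully; it is flagged degenerate,
all voxels get level 1, and downstream features degrade gracefully
(correlation becomes `NA` rather than an error).

### Global features

There is no universal rule for the histogram bin count, so the package
takes the median of three classical rules: Sturges
(`k = ceiling(log2(n)) + 1`), Scott (`h = 3.49·s·n^(−1/3)`, `k =
ceiling(range/h)`) and Freedman–Diaconis (`h = 2·IQR·n^(−1/3)`), with the
IQR from the linear-interpolation (type-7) quantile definition. Degenerate
cases are explicit: zero SD gives Scott `k = 1` flagged; zero IQR falls
back to Sturges, flagged.

Moments are computed from the binned histogram — bin centres weighted by
counts, population (1/n) normalization — because the features are defined
as *histogram* statistics; a `method = "raw"` switch computes unbinned
moments for sensitivity analysis, and the test suite asserts that binned
moments converge to raw moments as the bin count grows. Kurtosis is
reported **non-excess** (a Normal sample gives ≈ 3). This differs by 3 from
the excess convention reported by some statistics packages; the choice
follows the texture-analysis literature and is worth checking before
comparing numbers across studies.

### Second-order features

The co-occurrence matrix for displacement *d* counts ordered in-ROI voxel
pairs (v, v+d), symmetrized by adding the transpose (equivalent to
accumulating *d* and −*d*) and normalized to probabilities. Symmetry makes
the two marginals equal (μ_x = μ_y), which simplifies correlation and
fixes the "variance" definition to `sum((i − μ_x)² p)`. Sum-average uses
the level-sum histogram, `sum_{k=2}^{2Ng} k·p_{x+y}(k)`. Entropy uses
log base 2 (switchable to natural log). Empty rows/columns of the matrix
are retained — no level compaction — so features are comparable across
muscles.

In 3D the 26 direct neighbours collapse to 13 unique directions (one per
±d pair). Features are computed per direction and averaged unweighted;
because the direction set maps onto itself under every axis-aligned
rotation of the grid, the average is rotation invariant, which the test
suite asserts bit-for-bit (to 1e−12) over all 24 proper cube rotations.
Two documented alternatives exist behind config switches, reflecting a
genuine ambiguity in how "taking into account discretization length
differences" can be implemented once resampling has made all offsets
single-voxel steps: `weighting = "inverse_length"` discounts diagonal
directions by 1/√2 and 1/√3, and `method = "pooled"` merges pair counts
into one GLCM before computing features (some toolboxes pool; averaging
per-direction features is this package's default because it is the
behaviour the rotation-invariance argument applies to directly).

## The statistical layer

The cohort table has two rows per subject (left and right side), treated
as independent observations with side as a fixed-effect covariate — the
design matches common practice for bilateral measurements but ignores
within-subject correlation; a cluster-robust (by subject) standard-error
mode is provided to gauge the impact. Coding is fixed and documented:
female = 0 / male = 1, left = 0 / right = 1.

* `sex_comparison_table()` — group means ± SD and unpaired t-tests
  (pooled-variance Student by default, Welch optional).
* `adjusted_single_feature_regression()` — OLS of an MVIC outcome on sex,
  side, age, BMI plus one feature (side-matched); reports the feature
  term's p (two-sided t, identical to the single-df F-test) and the model
  adjusted R², the two quantities of a screening table. Bonferroni flags
  use m = 12 by default — the twelve parameters screened per outcome.
* `stepwise_regression()` — forward entry (p < 0.05) with backward
  removal (p > 0.10) on F-test p-values, deterministic tie-break by
  candidate order, full audit log. No multiplicity correction is applied
  inside the stepwise procedure (matching the procedure it reproduces);
  the null simulations in the test suite quantify the consequence: with 26
  noise candidates the median number of spurious selections is ~1.

The pipeline's stepwise candidate set is sex, side, age, BMI, mean PDFF
and the 11 texture features of the relevant muscle group (16 candidates,
side-matched). `stepwise_regression()` itself takes any candidate vector,
so wider designs (e.g. per-side feature columns) are expressible directly.

## The synthetic generator

`generate_phantom()` builds a single-compartment muscle stand-in: an
ellipsoidal-cylinder ROI in a voxel grid (default 24 × 24 × 12 at
3.2 × 2.0 × 4.0 mm), a fat-infiltration pattern, white voxel noise, and an
exact mean constraint. Patterns:

* `homogeneous` — spatially uncorrelated noise only;
* `streaks` — thresholded anisotropic Gaussian-smoothed noise, elongated
  along the slice axis (σ = pattern_scale/2 in-plane, 3·pattern_scale
  through-plane), emulating fat streaks along muscle fibres; the top 30 %
  of the smoothed field is elevated by `pattern_amplitude_pct` (default
  3 pp);
* `blobs` — the isotropic variant.

After pattern and noise, the in-ROI mean is re-centred onto the target;
when clipping to the physical [0, 100] % range is active, the offset is
re-solved by bisection so the achieved mean still lands within numerical
precision of the target (asserted to 0.1 pp across seeds and noise levels
up to 5 pp SD). Everything is a pure function of (spec, seed); per-phantom
seeds derive from a master seed via a documented splitting rule
(`derive_seed()`), so cohorts are reproducible phantom-by-phantom.

`generate_cohort()` draws per-subject covariates — age ~ N(30.2, 6.0)
years, BMI ~ N(27.1, 2.6) kg/m², balanced sex — per-(side, group) mean
PDFF around 3.5 ± 1.5 % (FLEX offset +0.5 pp), and a latent uniform(0, 1)
*texture score* per muscle that scales the phantom streak amplitude.
Strength is generated per side for both outcomes from

MVIC = β₀ + β_sex·male + β_BMI·BMI + β_PDFF·meanPDFF + β_tex·score + ε,
ε ~ N(0, 15 Nm),

with defaults (β₀ = 40, β_sex = 85, β_BMI = 4.5, β_PDFF = −6, β_tex = 25)
chosen so female extension strength sits near 150 Nm and male near 240 Nm
— the scale reported for healthy young adults — with a negative fat
slope. One coefficient set drives both outcomes; real flexion strength is
roughly half of extension strength, a scale difference that is irrelevant
to the recovery properties the generator exists to test. The generating
coefficients are returned with the table, so parameter-recovery tests
(95 % CI coverage of the truth, asserted within 92–98 % over 500
replicates) close the loop.

What the generator does **not** emulate: MRI physics (echo fitting,
water–fat swaps, bias fields), multi-muscle anatomy, partial-volume
mixtures at muscle boundaries, subcutaneous fat contamination of masks, or
any calibrated relationship between the pattern knobs and real
infiltration texture — no quantitative description of the latter exists to
calibrate against. Passing tests therefore demonstrate the *machinery* —
exact co-occurrence counting, rotation invariance, correct regression
arithmetic, selection behaviour at known signal-to-noise — not fidelity of
the phantoms to patient images.

## Numerical choices and degenerate inputs

* Quantization: value exactly at the window maximum → level Ng; constant
  ROI → degenerate flag, level 1 everywhere.
* GLCM: directions with zero valid pairs raise an error naming the
  direction; the 13-direction average simply excludes them (and reports
  them) as long as at least one direction has pairs.
* Correlation with a zero marginal SD is `NA`, not an error; the
  direction average propagates `NA` only if every direction is `NA`.
* Entropy uses the 0·log 0 = 0 convention.
* Stepwise ties break by candidate-list order (`which.min` takes the
  first); identical tables and candidate orders give identical logs.
* The mean-constraint bisection runs 80 iterations on [−200, 200], far
  below the 0.1 pp tolerance the generator promises.

## Problem sizes used in the validation suite

The test and acceptance workloads are sized for a laptop-class single
core: oracle equivalence on 50 random volumes up to 8³ with Ng ≤ 8 (13
directions each, exhaustive triple-loop enumeration); rotation invariance
on 10 phantoms × 24 rotations; stepwise recovery and null behaviour on
200 replicates of 60-observation cohorts with 26 candidates; pattern
separability on 100 phantom pairs of 16 × 16 × 10 voxels; CI coverage on
500 table-only cohort replicates. The full run completes in a couple of
minutes.

## Known limitations

* Two rows per subject are modelled with a side fixed effect, not a mixed
  model; standard errors understate uncertainty when within-subject
  correlation is strong (the cluster-robust mode quantifies this).
* Histogram-moment features depend on the bin rule; the median-of-three
  choice is conventional, not optimal in any formal sense.
* The kurtosis convention (non-excess) and the per-ROI quantization
  window both differ across published toolboxes; numeric comparability
  with other software requires matching these switches.
* Features are computed on one ROI per muscle group; no sub-muscle
  anatomy, no exclusion of inter- vs intra-muscular fat.
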