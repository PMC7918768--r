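# pdfftexture

Texture analysis of proton density fat fraction (PDFF) maps of skeletal
muscle, and the statistics that relate texture to muscle strength.

## The problem

Water–fat MRI delivers quantitative PDFF maps: fat content in percent, per
voxel. The *mean* PDFF over a segmented muscle is the standard biomarker of
muscle fat infiltration, but it ignores the spatial arrangement of the fat.
Muscles with identical mean fat fraction can carry their fat homogeneously
or organized into streaks along the fibres, and that pattern is information
about muscle quality that the mean discards. This package computes, per
muscle ROI:

* **mean PDFF** (percent),
* **3 global features** from the ROI intensity histogram — variance,
  skewness, kurtosis — with the bin count chosen as the median of the
  Sturges, Scott and Freedman–Diaconis rules,
* **8 second-order features** from the 3D gray-level co-occurrence matrix
  (GLCM) — energy, entropy, contrast, homogeneity, correlation, variance,
  sum-average, dissimilarity:

  energy = Σ p², entropy = −Σ p log₂ p, contrast = Σ (i−j)² p(i,j),
  homogeneity = Σ p/(1+|i−j|), correlation = Σ (i−μ_x)(j−μ_y) p / (σ_x σ_y),
  variance = Σ (i−μ)² p, sum-average = Σ k·p_{x+y}(k),
  dissimilarity = Σ |i−j| p.

GLCMs are accumulated symmetrically for the 13 unique voxel-neighbour
directions (the 26 direct 3D neighbours collapse into ±d pairs) after
isotropic resampling and uniform 200-level quantization; features are
averaged over the 13 directions, which makes them invariant to axis-aligned
rotations of the volume.

The statistical layer reproduces a feature-screening design for maximum
voluntary isometric contraction (MVIC) strength of knee extensors (EXT)
and flexors (FLEX): covariate-adjusted regressions (sex, side, age, BMI +
one feature) reporting the feature's F-test p and the model adjusted R²
with Bonferroni marking, plus stepwise multivariate selection (entry
p < 0.05, removal p > 0.10) with a full audit log.

Because subject imaging data of this kind is rarely shareable, the package
includes a first-class synthetic module: single-compartment PDFF phantoms
with controllable fat patterns (homogeneous / streaks / blobs) and exact
mean control, and a cohort generator whose strength outcomes follow a known
linear model — so every pipeline stage is testable against ground truth.

## Worked example

A streak-patterned phantom with 5 % mean PDFF, and its twelve parameters:

```r
library(pdfftexture)

ph <- generate_phantom(phantom_spec(mean_pdff_pct = 5, pattern = "streaks",
                                    noise_sd_pct = 1, seed = 3))
ft <- texture_features(ph$volume, ph$mask)   # resamples to 2 mm, Ng = 200
t(round(ft[, -(1:2)], 3))
#> n_voxels        9888.000
#> mean_pdff          5.000
#> variance_global    2.028
#> skewness_global    0.605
#> kurtosis_global    2.388
#> energy             0.000
#> entropy           12.805
#> contrast        1181.774
#> homogeneity        0.104
#> correlation        0.534
#> sum_average      166.352
#> variance        1267.875
#> dissimilarity     25.378
```

The achieved ROI mean is exactly the 5 % target (the generator re-centres
after clipping). The positive skewness and high contrast are the streak
signature: a minority of high-fat voxels organized into bands, so many
neighbouring voxel pairs straddle a large intensity step. Correlation 0.53
reflects the spatial coherence of the bands (uncorrelated noise would give
≈ 0); entropy near 12.8 bits says the 200-level co-occurrence distribution
is spread over many cells.

An end-to-end synthetic study — 8 subjects, phantoms for both muscle
groups and sides, features, screening and stepwise selection:

```r
cfg <- list(seed = 11L, cohort = list(n_subjects = 8L),
            phantom = list(shape = c(14L, 14L, 10L)),
            quantizer = list(Ng = 64L))
ana <- run_pipeline(cfg, "runs/demo")
subset(ana$screen, outcome == "MVIC_EXT")
#>          parameter  outcome adj_r_squared      p bonferroni
#>          mean_pdff MVIC_EXT         0.798 0.4786      FALSE
#>    variance_global MVIC_EXT         0.851 0.0643      FALSE
#>    skewness_global MVIC_EXT         0.879 0.0198      FALSE
#>    ...
#>        correlation MVIC_EXT         0.884 0.0157      FALSE
ana$stepwise$MVIC_EXT$selected
#> [1] "sex"                 "skewness_global_EXT"
```

Each screening row is one adjusted regression; `p` is the feature term's
F-test p-value and `adj_r_squared` the model's adjusted R². With only 8
subjects nothing survives the Bonferroni threshold (0.05/12 ≈ 0.0042) —
as it should be at this size. The stepwise model picks sex (the dominant
strength determinant) plus a texture feature carrying the synthetic
pattern signal. The run directory contains the phantoms (NIfTI), all
tables (CSV), the resolved `config.yaml` and a log; re-running the same
config reproduces every CSV bit-identically.

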