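Package: pdfftexture
Title: Texture Analysis of Proton Density Fat Fraction Maps of Skeletal Muscle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying muscle fat infiltration patterns on
    quantitative water-fat MRI. Computes region-of-interest mean proton
    density fat fraction (PDFF), first-order histogram features with a
    median-of-three bin-count rule (Sturges, Scott, Freedman-Diaconis),
    and rotation-invariant three-dimensional gray-level co-occurrence
    matrix (GLCM) texture features over the 13 unique voxel-neighbour
    directions, after isotropic resampling and uniform gray-level
    quantization. Includes covariate-adjusted single-feature regression,
    F-test-driven stepwise predictor selection, and Bonferroni screening
    for relating features to muscle strength, plus a synthetic phantom
    and cohort generator with controllable fat-infiltration patterns so
    the whole pipeline is testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
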