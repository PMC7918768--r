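#' Full texture feature set for one muscle ROI
#'
#' Runs the standard extraction chain for one (volume, mask) pair:
#' isotropic resampling, in-ROI value extraction, mean PDFF, global
#' histogram features (median-of-three bin rule), uniform gray-level
#' quantization, and rotation-invariant 3D GLCM features — the twelve
#' parameters tabulated per muscle: mean PDFF, 3 global and 8 second-order
#' features.
#'
#' @param vol a [pdff_volume()].
#' @param mask a congruent [roi_mask()].
#' @param target_mm isotropic resampling target (mm); `NULL` skips
#'   resampling (e.g. when the input is already isotropic).
#' @param Ng gray levels for quantization (default 200).
#' @param window quantization window mode, see [quantize()].
#' @param glcm_method,glcm_weighting,log_base passed to
#'   [rotation_invariant_features()] / [glcm_features()].
#' @return one-row data.frame with columns `muscle_group`, `side`,
#'   `n_voxels`, `mean_pdff`, `variance_global`, `skewness_global`,
#'   `kurtosis_global`, `energy`, `entropy`, `contrast`, `homogeneity`,
#'   `correlation`, `sum_average`, `variance`, `dissimilarity`.
#' @export
texture_features <- function(vol, mask, target_mm = 2, Ng = 200L,
                             window = "roi",
                             glcm_method = "average",
                             glcm_weighting = "uniform",
                             log_base = 2) {
  if (!is.null(target_mm)) {
    rs <- resample_isotropic(vol, mask, target_mm)
    vol <- rs$volume
    mask <- rs$mask
  }
  vals <- extract_roi_values(vol, mask)
  gf <- global_features(vals)
  q <- quantize(vol, mask, Ng = Ng, window = window)
  so <- rotation_invariant_features(q, method = glcm_method,
                                    weighting = glcm_weighting,
                                    log_base = log_base)
  data.frame(
    muscle_group = mask$muscle_group,
    side = mask$side,
    n_voxels = length(vals),
    mean_pdff = mean_pdff(vals),
    variance_global = gf$variance_global,
    skewness_global = gf$skewness_global,
    kurtosis_global = gf$kurtosis_global,
    energy = so$energy,
    entropy = so$entropy,
    contrast = so$contrast,
    homogeneity = so$homogeneity,
    correlation = so$correlation,
    sum_average = so$sum_average,
    variance = so$variance,
    dissimilarity = so$dissimilarity,
    stringsAsFactors = FALSE
  )
}

#' Names of the twelve tabulated per-muscle parameters
#' @return character vector: mean PDFF plus the 11 texture features.
#' @export
feature_names <- function() {
  c("mean_pdff", "variance_global", "skewness_global", "kurtosis_global",
    "energy", "entropy", "contrast", "homogeneity", "correlation",
    "sum_average", "variance", "dissimilarity")
}
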