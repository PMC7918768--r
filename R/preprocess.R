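#' Resample a PDFF volume and its mask to isotropic spacing
#'
#' Trilinear interpolation for the map, nearest-neighbour for the mask
#' (re-binarized at 0.5). Because every GLCM displacement is a single voxel
#' step, isotropic resampling before texture analysis is what makes the 13
#' neighbour directions metrically comparable.
#'
#' Grid convention: voxel `i` has its centre at `(i - 0.5) * spacing` and
#' the physical extent per axis is the half-open `[0, n * spacing)`. The
#' output grid has `round(n * spacing / target_mm)` voxels per axis (at
#' least 1), so extents are preserved to within one voxel. Output sample
#' points outside the input centre range are clamped to the boundary voxel
#' (replicate padding), so interpolation preserves constant volumes exactly.
#'
#' @param vol a [pdff_volume()].
#' @param mask a [roi_mask()] congruent with `vol`.
#' @param target_mm positive scalar, the isotropic target spacing (default
#'   2 mm, the in-plane acquisition resolution).
#' @return list with resampled `volume` and `mask`.
#' @export
resample_isotropic <- function(vol, mask, target_mm = 2) {
  stopifnot(inherits(vol, "pdff_volume"), inherits(mask, "roi_mask"))
  check_congruent(vol, mask)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("`target_mm` must be a positive scalar")
  dims <- dim(vol$values)
  sp <- vol$spacing_mm
  out_dims <- pmax(1L, as.integer(round(dims * sp / target_mm)))

  ax <- lapply(1:3, function(a) {
    f <- ((seq_len(out_dims[a]) - 0.5) * target_mm) / sp[a] + 0.5
    f <- pmin(pmax(f, 1), dims[a])
    lo <- pmin(floor(f), max(dims[a] - 1L, 1L))
    w <- f - lo
    list(lo = as.integer(lo), hi = as.integer(pmin(lo + 1L, dims[a])),
         w = w, nn = as.integer(pmin(pmax(round(f), 1L), dims[a])))
  })

  V <- vol$values
  out <- array(0, dim = out_dims)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx) ax[[1]]$hi else ax[[1]]$lo
    iy <- if (cy) ax[[2]]$hi else ax[[2]]$lo
    iz <- if (cz) ax[[3]]$hi else ax[[3]]$lo
    wx <- if (cx) ax[[1]]$w else 1 - ax[[1]]$w
    wy <- if (cy) ax[[2]]$w else 1 - ax[[2]]$w
    wz <- if (cz) ax[[3]]$w else 1 - ax[[3]]$w
    w <- outer(outer(wx, wy), wz)
    out <- out + V[ix, iy, iz, drop = FALSE] * w
  }
  out <- clip01(out)  # guard tiny interpolation round-off at range edges

  m_out <- mask$values[ax[[1]]$nn, ax[[2]]$nn, ax[[3]]$nn, drop = FALSE] > 0.5
  list(volume = pdff_volume(out, spacing_mm = rep(target_mm, 3)),
       mask = roi_mask(m_out, muscle_group = mask$muscle_group,
                       side = mask$side))
}

#' Extract in-mask voxel values
#'
#' Returns exactly the in-ROI voxel values in lexicographic voxel-index
#' order (x fastest, then y, then z — R's column-major array order).
#'
#' @param vol a [pdff_volume()].
#' @param mask a congruent [roi_mask()].
#' @return numeric vector of fat fractions in percent.
#' @export
extract_roi_values <- function(vol, mask) {
  stopifnot(inherits(vol, "pdff_volume"), inherits(mask, "roi_mask"))
  check_congruent(vol, mask)
  v <- vol$values[mask$values]
  if (length(v) == 0L) stop("mask is empty")
  v
}

#' Mean PDFF of a value vector
#'
#' @param values non-empty numeric vector of fat fractions in percent.
#' @return arithmetic mean, percent.
#' @export
mean_pdff <- function(values) {
  if (length(values) == 0L) stop("empty value vector")
  mean(values)
}

#' Uniform gray-level quantization of an ROI
#'
#' Maps in-ROI intensities onto `Ng` equally sized bins so the GLCM is not
#' sparse. With window `"roi"` (default) the bin edges span the in-ROI
#' minimum..maximum; with `"fixed"` they span `fixed_range` (the full
#' physical 0..100 percent scale by default). The level of value `v` is
#' `ceiling(Ng * (v - min) / (max - min))` with the minimum mapped to level
#' 1 and the maximum to level `Ng`.
#'
#' A constant ROI (max = min) cannot be quantized meaningfully: all voxels
#' get level 1 and the result is flagged `degenerate`; downstream GLCM
#' features handle this case (e.g. correlation becomes missing).
#'
#' @param vol a [pdff_volume()].
#' @param mask a congruent, non-empty [roi_mask()].
#' @param Ng number of gray levels, >= 2 (default 200).
#' @param window `"roi"` or `"fixed"`.
#' @param fixed_range length-2 range used when `window = "fixed"`.
#' @return An object of class `quantized_roi`: list with `levels` (integer
#'   array, `NA` outside the mask), `Ng`, `level_edges` (the `Ng + 1` bin
#'   boundaries in percent), and `degenerate` flag.
#' @export
quantize <- function(vol, mask, Ng = 200L, window = c("roi", "fixed"),
                     fixed_range = c(0, 100)) {
  stopifnot(inherits(vol, "pdff_volume"), inherits(mask, "roi_mask"))
  check_congruent(vol, mask)
  window <- match.arg(window)
  Ng <- as.integer(Ng)
  if (Ng < 2L) stop("`Ng` must be >= 2")
  inroi <- vol$values[mask$values]
  if (length(inroi) == 0L) stop("mask is empty")
  rng <- if (window == "roi") range(inroi) else as.numeric(fixed_range)
  mn <- rng[1]; mx <- rng[2]
  degenerate <- mx <= mn
  lev <- array(NA_integer_, dim = dim(vol$values))
  if (degenerate) {
    lev[mask$values] <- 1L
    edges <- seq(mn, mn + 1, length.out = Ng + 1)  # placeholder edges
  } else {
    l <- ceiling(Ng * (inroi - mn) / (mx - mn))
    l[l < 1L] <- 1L          # the minimum itself maps to level 1
    l[l > Ng] <- Ng          # values at/above the window maximum
    lev[mask$values] <- as.integer(l)
    edges <- seq(mn, mx, length.out = Ng + 1)
  }
  structure(list(levels = lev, Ng = Ng, level_edges = edges,
                 degenerate = degenerate),
            class = "quantized_roi")
}
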