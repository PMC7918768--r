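#' PDFF volume container
#'
#' A 3D fat-fraction map in percent per voxel, with per-axis voxel spacing
#' in millimetres. Axis convention: x = left/right, y = anterior/posterior,
#' z = slice direction; R arrays are indexed `values[x, y, z]` with x the
#' fastest-varying index. Voxel indexing is 1-based in R; voxel `i` covers
#' the half-open physical interval `[(i-1)*spacing, i*spacing)` with its
#' centre at `(i-0.5)*spacing`.
#'
#' @param values numeric 3D array, fat fraction in percent; all values must
#'   be finite and within `[0, 100]`.
#' @param spacing_mm numeric length-3, voxel size per axis in mm.
#' @return An object of class `pdff_volume`: a list with elements `values`
#'   and `spacing_mm`.
#' @export
pdff_volume <- function(values, spacing_mm = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("PDFF values must all be finite")
  if (any(values < 0 | values > 100))
    stop("PDFF values must lie in [0, 100] percent")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive numbers")
  structure(list(values = values, spacing_mm = spacing_mm),
            class = "pdff_volume")
}

#' ROI mask container
#'
#' Binary region-of-interest mask congruent with a PDFF volume, labelled by
#' muscle group (EXT = knee extensors / quadriceps, FLEX = knee flexors /
#' ischiocrural muscles) and body side.
#'
#' @param values logical (or 0/1) 3D array; `TRUE` marks in-ROI voxels.
#' @param muscle_group `"EXT"` or `"FLEX"`.
#' @param side `"left"` or `"right"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(values, muscle_group = c("EXT", "FLEX"),
                     side = c("left", "right")) {
  muscle_group <- match.arg(muscle_group)
  side <- match.arg(side)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  storage <- array(as.logical(values), dim = dim(values))
  if (anyNA(storage)) stop("mask values must be 0/1 or logical")
  structure(list(values = storage, muscle_group = muscle_group, side = side),
            class = "roi_mask")
}

#' @export
print.pdff_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("PDFF volume %d x %d x %d, spacing %s mm, range [%.2f, %.2f]%%\n",
              d[1], d[2], d[3], paste(format(x$spacing_mm), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask %s/%s: %d voxels in mask (of %d)\n",
              x$muscle_group, x$side, sum(x$values), length(x$values)))
  invisible(x)
}

check_congruent <- function(vol, mask) {
  if (!identical(dim(vol$values), dim(mask$values)))
    stop("volume and mask have different grid dimensions")
  invisible(TRUE)
}

#' Read / write PDFF volumes and masks as NIfTI
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()].
#' Spacing is stored in / recovered from the NIfTI `pixdim` field. Masks are
#' written as 0/1 and re-binarized at 0.5 on read.
#'
#' @param x a `pdff_volume` or `roi_mask`.
#' @param path file path, conventionally ending in `.nii.gz`.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_volume_nifti <- function(x, path) {
  img <- RNifti::asNifti(x$values)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  pdff_volume(arr, spacing_mm = RNifti::pixdim(img)[1:3])
}

#' @rdname nifti_io
#' @param muscle_group,side labels attached to the mask on read.
#' @export
write_mask_nifti <- function(x, path) {
  img <- RNifti::asNifti(array(as.integer(x$values), dim = dim(x$values)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_mask_nifti <- function(path, muscle_group = "EXT", side = "left") {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img)) > 0.5
  roi_mask(arr, muscle_group = muscle_group, side = side)
}
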