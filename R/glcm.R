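#' The 13 unique 3D neighbour directions
#'
#' The 26 direct neighbours of a voxel come in 13 (+d, -d) pairs; since the
#' co-occurrence matrix is accumulated symmetrically, one representative per
#' pair suffices. Components are in \{-1, 0, 1\}.
#'
#' @return 13 x 3 integer matrix of (dx, dy, dz) offsets.
#' @export
glcm_directions <- function() {
  m <- matrix(c(
    1, 0, 0,
    0, 1, 0,
    0, 0, 1,
    1, 1, 0,
    1, -1, 0,
    1, 0, 1,
    1, 0, -1,
    0, 1, 1,
    0, 1, -1,
    1, 1, 1,
    1, 1, -1,
    1, -1, 1,
    -1, 1, 1), ncol = 3, byrow = TRUE)
  storage.mode(m) <- "integer"
  colnames(m) <- c("dx", "dy", "dz")
  m
}

#' Compute a 3D gray-level co-occurrence matrix for one direction
#'
#' Counts ordered voxel pairs `(v, v + d)` with both endpoints inside the
#' ROI, symmetrizes by adding the transpose (equivalent to accumulating `d`
#' and `-d`), and normalizes by the total pair count, giving the joint
#' probability `p(i, j)` that two neighbouring in-ROI voxels have quantized
#' levels `i` and `j`. Empty rows/columns are retained (no level
#' compaction), so features are comparable across ROIs.
#'
#' @param q a [quantize()]d ROI.
#' @param d integer length-3 displacement, typically a row of
#'   [glcm_directions()].
#' @return An object of class `glcm`: list with `p` (Ng x Ng probability
#'   matrix), `counts` (symmetrized integer pair counts), `Ng`,
#'   `direction`, `pair_count`.
#' @export
compute_glcm <- function(q, d) {
  stopifnot(inherits(q, "quantized_roi"))
  d <- as.integer(d)
  if (length(d) != 3L || any(abs(d) > 1L) || all(d == 0L))
    stop("`d` must be a nonzero displacement with components in {-1, 0, 1}")
  L <- q$levels
  dims <- dim(L)
  rng <- lapply(1:3, function(a) {
    seq.int(max(1L, 1L - d[a]), min(dims[a], dims[a] - d[a]))
  })
  if (any(lengths(rng) == 0L))
    stop(sprintf("no valid voxel pairs for direction (%d, %d, %d)", d[1], d[2], d[3]))
  a <- L[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  b <- L[rng[[1]] + d[1], rng[[2]] + d[2], rng[[3]] + d[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  i <- a[ok]; j <- b[ok]
  if (length(i) == 0L)
    stop(sprintf("empty GLCM: no in-mask voxel pairs for direction (%d, %d, %d)",
                 d[1], d[2], d[3]))
  Ng <- q$Ng
  counts <- matrix(tabulate((j - 1L) * Ng + i, nbins = Ng * Ng), Ng, Ng)
  counts <- counts + t(counts)
  total <- sum(counts)
  structure(list(p = counts / total, counts = counts, Ng = Ng,
                 direction = d, pair_count = total),
            class = "glcm")
}

#' Second-order (Haralick) features of one GLCM
#'
#' For a normalized symmetric co-occurrence matrix `p(i, j)` over levels
#' `1..Ng` with marginals `p_x = p_y` (means `mu_x = mu_y`, SDs
#' `sigma_x = sigma_y`):
#' \describe{
#'   \item{energy}{`sum p^2` (angular second moment), in (0, 1]}
#'   \item{entropy}{`-sum p * log(p)` with `0 log 0 = 0`; log base 2 by
#'     default}
#'   \item{contrast}{`sum (i - j)^2 p`}
#'   \item{homogeneity}{`sum p / (1 + |i - j|)`, in (0, 1]}
#'   \item{correlation}{`sum (i - mu_x)(j - mu_y) p / (sigma_x sigma_y)`;
#'     missing (NA) when a marginal SD is zero, i.e. a constant ROI}
#'   \item{variance}{`sum (i - mu)^2 p` with `mu` the mean level over the
#'     (symmetric) GLCM, i.e. `mu = mu_x`}
#'   \item{sum_average}{`sum_{k=2}^{2Ng} k * p_{x+y}(k)` where `p_{x+y}` is
#'     the level-sum histogram, equivalently `sum (i + j) p`}
#'   \item{dissimilarity}{`sum |i - j| p`}
#' }
#' All are dimensionless, in quantized-level units.
#'
#' @param g a [compute_glcm()] result (or compatible list with a normalized
#'   `p` matrix).
#' @param log_base base of the entropy logarithm (2, Haralick's convention).
#' @return named list of the eight feature values.
#' @export
glcm_features <- function(g, log_base = 2) {
  p <- g$p
  Ng <- nrow(p)
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
    stop("GLCM is not a normalized probability matrix")
  lev <- seq_len(Ng)
  i <- matrix(lev, Ng, Ng)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  sigma_x <- sqrt(sum((lev - mu_x)^2 * px))
  sigma_y <- sqrt(sum((lev - mu_y)^2 * py))
  nz <- p > 0
  list(
    energy = sum(p^2),
    entropy = -sum(p[nz] * log(p[nz])) / log(log_base),
    contrast = sum((i - j)^2 * p),
    homogeneity = sum(p / (1 + abs(i - j))),
    correlation = if (sigma_x > 0 && sigma_y > 0)
      sum((i - mu_x) * (j - mu_y) * p) / (sigma_x * sigma_y)
    else NA_real_,
    variance = sum((i - mu_x)^2 * p),
    sum_average = sum((i + j) * p),
    dissimilarity = sum(abs(i - j) * p)
  )
}

glcm_feature_names <- c("energy", "entropy", "contrast", "homogeneity",
                        "correlation", "variance", "sum_average",
                        "dissimilarity")

#' Rotation-invariant second-order features
#'
#' Computes the eight GLCM features for each of the 13 neighbour directions
#' and averages them; because the direction set maps onto itself under all
#' axis-aligned rotations and reflections of the grid (and each GLCM is
#' symmetric, so `d` and `-d` are equivalent), the average is invariant to
#' those rotations. Directions that yield no in-mask voxel pairs are
#' excluded from the mean (and reported); a missing correlation propagates
#' as missing only if it is missing for every direction.
#'
#' Two non-default modes are available: `method = "pooled"` merges the
#' per-direction pair counts into one pooled GLCM before computing the
#' features, and `weighting = "inverse_length"` weights each direction's
#' contribution by the inverse Euclidean length of its offset
#' (1, 1/sqrt(2), 1/sqrt(3)) to discount the longer diagonal steps.
#'
#' @param q a [quantize()]d ROI.
#' @param method `"average"` (per-direction features, then mean; default)
#'   or `"pooled"`.
#' @param weighting `"uniform"` (default) or `"inverse_length"`; only used
#'   by `method = "average"`.
#' @param log_base entropy log base.
#' @return named list of the eight averaged features, plus
#'   `n_directions_used` and `empty_directions` (character vector).
#' @export
rotation_invariant_features <- function(q, method = c("average", "pooled"),
                                        weighting = c("uniform", "inverse_length"),
                                        log_base = 2) {
  method <- match.arg(method)
  weighting <- match.arg(weighting)
  dirs <- glcm_directions()
  glcms <- vector("list", nrow(dirs))
  empty <- character(0)
  for (k in seq_len(nrow(dirs))) {
    glcms[k] <- list(tryCatch(compute_glcm(q, dirs[k, ]), error = function(e) NULL))
    if (is.null(glcms[[k]]))
      empty <- c(empty, paste(dirs[k, ], collapse = ","))
  }
  used <- which(!vapply(glcms, is.null, logical(1)))
  if (length(used) == 0L)
    stop("all 13 directions yield empty GLCMs; ROI too small or empty")

  if (method == "pooled") {
    counts <- Reduce(`+`, lapply(glcms[used], `[[`, "counts"))
    pooled <- list(p = counts / sum(counts), Ng = q$Ng)
    out <- glcm_features(pooled, log_base = log_base)
  } else {
    w <- if (weighting == "inverse_length")
      1 / sqrt(rowSums(dirs[used, , drop = FALSE]^2))
    else rep(1, length(used))
    w <- w / sum(w)
    fmat <- vapply(glcms[used], function(g)
      unlist(glcm_features(g, log_base = log_base)), numeric(8))
    out <- as.list(apply(fmat, 1, function(v) {
      keep <- !is.na(v)
      if (!any(keep)) return(NA_real_)
      sum(v[keep] * w[keep]) / sum(w[keep])
    }))
    names(out) <- rownames(fmat)
  }
  out$n_directions_used <- length(used)
  out$empty_directions <- empty
  out
}
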