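# Independent oracles and fixture builders shared across test files.
# Everything here is deliberately naive (triple loops, explicit formulas)
# so it cannot share a defect with the vectorized package code.

# exhaustive pair counting: for every in-mask voxel, look up the voxel at
# +d and -d and count both ordered pairs
brute_force_glcm_counts <- function(levels, Ng, d) {
  dims <- dim(levels)
  C <- matrix(0L, Ng, Ng)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    for (sgn in c(1L, -1L)) {
      xx <- x + sgn * d[1]; yy <- y + sgn * d[2]; zz <- z + sgn * d[3]
      if (xx < 1 || xx > dims[1] || yy < 1 || yy > dims[2] ||
          zz < 1 || zz > dims[3]) next
      b <- levels[xx, yy, zz]
      if (is.na(b)) next
      C[a, b] <- C[a, b] + 1L
    }
  }
  C
}

# direct double-loop evaluation of the eight second-order features
naive_glcm_features <- function(p, log_base = 2) {
  Ng <- nrow(p)
  mu_x <- 0; mu_y <- 0
  for (i in 1:Ng) for (j in 1:Ng) { mu_x <- mu_x + i * p[i, j]; mu_y <- mu_y + j * p[i, j] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    sx2 <- sx2 + (i - mu_x)^2 * p[i, j]
    sy2 <- sy2 + (j - mu_y)^2 * p[i, j]
  }
  energy <- 0; entropy <- 0; contrast <- 0; homog <- 0; corr_num <- 0
  varce <- 0; sumavg <- 0; dissim <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    pij <- p[i, j]
    energy <- energy + pij^2
    if (pij > 0) entropy <- entropy - pij * log(pij) / log(log_base)
    contrast <- contrast + (i - j)^2 * pij
    homog <- homog + pij / (1 + abs(i - j))
    corr_num <- corr_num + (i - mu_x) * (j - mu_y) * pij
    varce <- varce + (i - mu_x)^2 * pij
    sumavg <- sumavg + (i + j) * pij
    dissim <- dissim + abs(i - j) * pij
  }
  list(energy = energy, entropy = entropy, contrast = contrast,
       homogeneity = homog,
       correlation = if (sx2 > 0 && sy2 > 0) corr_num / sqrt(sx2 * sy2) else NA_real_,
       variance = varce, sum_average = sumavg, dissimilarity = dissim)
}

# quantized ROI built directly from a level array (NA outside the mask)
make_quantized <- function(levels, Ng) {
  structure(list(levels = levels, Ng = as.integer(Ng),
                 level_edges = seq(0, 100, length.out = Ng + 1),
                 degenerate = FALSE),
            class = "quantized_roi")
}

random_quantized <- function(dims, Ng, seed, mask_frac = 1) {
  withr::with_seed(seed, {
    lev <- array(sample.int(Ng, prod(dims), replace = TRUE), dim = dims)
    if (mask_frac < 1) {
      drop <- runif(prod(dims)) > mask_frac
      lev[drop] <- NA_integer_
    }
    make_quantized(lev, Ng)
  })
}

# the 24 proper axis-aligned rotations of a 3D array: axis permutation
# followed by axis reversals, keeping only orientation-preserving combos
cube_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  perm_sign <- c(1, -1, -1, 1, 1, -1)
  rots <- list()
  for (pi in seq_along(perms)) {
    for (fx in 0:1) for (fy in 0:1) for (fz in 0:1) {
      det <- perm_sign[pi] * (-1)^(fx + fy + fz)
      if (det != 1) next
      rots[[length(rots) + 1L]] <- list(perm = perms[[pi]], flip = c(fx, fy, fz))
    }
  }
  rots
}

apply_rotation <- function(arr, rot) {
  out <- aperm(arr, rot$perm)
  d <- dim(out)
  idx <- lapply(1:3, function(a) if (rot$flip[a]) rev(seq_len(d[a])) else seq_len(d[a]))
  out[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# compensated (Kahan) summation, the independent mean oracle
kahan_mean <- function(x) {
  s <- 0; c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s / length(x)
}

# small helper: wrap a plain array as pdff_volume + all-true mask
as_vol_mask <- function(arr, spacing = c(1, 1, 1), group = "EXT", side = "left") {
  list(volume = pdff_volume(arr, spacing_mm = spacing),
       mask = roi_mask(array(TRUE, dim = dim(arr)), muscle_group = group,
                       side = side))
}
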