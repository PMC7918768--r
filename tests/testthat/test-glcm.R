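test_that("there are exactly 13 canonical directions, one per +/- pair", {
  d <- glcm_directions()
  expect_equal(dim(d), c(13L, 3L))
  expect_true(all(d %in% -1:1))
  keys <- apply(d, 1, paste, collapse = ",")
  neg_keys <- apply(-d, 1, paste, collapse = ",")
  expect_equal(anyDuplicated(c(keys, neg_keys)), 0L)  # no d equals another's -d
  # together with their negations they are the 26 neighbours
  expect_equal(length(unique(c(keys, neg_keys))), 26L)
})

test_that("a constant ROI gives the degenerate single-cell GLCM and features", {
  q <- make_quantized(array(1L, dim = c(5, 5, 5)), Ng = 4)
  g <- compute_glcm(q, c(1, 0, 0))
  expect_equal(g$p[1, 1], 1)
  expect_equal(sum(g$p), 1)
  f <- glcm_features(g)
  expect_equal(f$energy, 1)
  expect_equal(f$entropy, 0)
  expect_equal(f$contrast, 0)
  expect_equal(f$homogeneity, 1)
  expect_equal(f$dissimilarity, 0)
  expect_equal(f$variance, 0)
  expect_true(is.na(f$correlation))
})

test_that("a single co-occurring pair is counted symmetrically", {
  lev <- array(NA_integer_, dim = c(8, 8, 8))
  lev[1, 1, 1] <- 1L; lev[2, 1, 1] <- 2L
  q <- make_quantized(lev, Ng = 2)
  g <- compute_glcm(q, c(1, 0, 0))
  expect_equal(g$p[1, 2], 0.5)
  expect_equal(g$p[2, 1], 0.5)
  expect_equal(g$pair_count, 2)  # ordered pairs after symmetrization
})

test_that("checkerboard GLCM features match hand evaluation", {
  # all mass on p(1,2) = p(2,1) = 0.5
  g <- list(p = matrix(c(0, 0.5, 0.5, 0), 2, 2), Ng = 2L)
  f <- glcm_features(g)
  expect_equal(f$contrast, 1)
  expect_equal(f$dissimilarity, 1)
  expect_equal(f$sum_average, 3)
  expect_equal(f$correlation, -1)
  expect_equal(f$energy, 0.5)
  expect_equal(f$entropy, 1)       # base-2 log of two equal cells
  expect_equal(f$homogeneity, 0.5)
  expect_equal(f$variance, 0.25)   # levels 1,2 with equal marginals
})

test_that("unnormalized matrices are rejected and empty directions error", {
  expect_error(glcm_features(list(p = matrix(1, 2, 2), Ng = 2L)), "normalized")
  lev <- array(NA_integer_, dim = c(8, 8, 8))
  lev[1, 1, 1] <- 1L  # an isolated voxel has no neighbours at all
  q <- make_quantized(lev, Ng = 2)
  expect_error(compute_glcm(q, c(0, 0, 1)), "0, 0, 1")
  expect_error(rotation_invariant_features(q), "empty")
})

test_that("GLCM counts match exhaustive enumeration on random masked volumes", {
  dirs <- glcm_directions()
  for (seed in 1:6) {
    q <- random_quantized(c(5, 5, 5), Ng = 6, seed = seed, mask_frac = 0.8)
    for (k in seq_len(nrow(dirs))) {
      got <- compute_glcm(q, dirs[k, ])
      want <- brute_force_glcm_counts(q$levels, q$Ng, dirs[k, ])
      expect_identical(unname(got$counts), unname(want))  # exact integer counts
      expect_equal(sum(got$p), 1, tolerance = 1e-12)
      expect_equal(got$p, t(got$p), tolerance = 1e-15)
      ff <- glcm_features(got)
      oracle <- naive_glcm_features(got$p)
      for (nm in names(oracle))
        expect_equal(ff[[nm]], oracle[[nm]], tolerance = 1e-12, label = nm)
    }
  }
})

test_that("direction-averaged features equal the mean of per-direction features", {
  q <- random_quantized(c(7, 7, 7), Ng = 5, seed = 17)
  avg <- rotation_invariant_features(q)
  dirs <- glcm_directions()
  per_dir <- sapply(seq_len(nrow(dirs)), function(k)
    unlist(glcm_features(compute_glcm(q, dirs[k, ]))))
  expect_equal(avg$n_directions_used, 13L)
  for (nm in rownames(per_dir))
    expect_equal(avg[[nm]], mean(per_dir[nm, ]), tolerance = 1e-12, label = nm)
})

test_that("13-direction averages are invariant under the 24 cube rotations", {
  q <- random_quantized(c(6, 8, 7), Ng = 4, seed = 23, mask_frac = 0.9)
  base <- rotation_invariant_features(q)
  fn <- c("energy", "entropy", "contrast", "homogeneity", "correlation",
          "variance", "sum_average", "dissimilarity")
  for (rot in cube_rotations()) {
    qr <- make_quantized(apply_rotation(q$levels, rot), q$Ng)
    fr <- rotation_invariant_features(qr)
    for (nm in fn)
      expect_equal(fr[[nm]], base[[nm]], tolerance = 1e-12, label = nm)
  }
})

test_that("texture features respond monotonically to checkerboard saltiness", {
  dims <- c(10, 10, 10)
  base <- array(1L, dim = dims)
  fracs <- c(0.1, 0.3, 0.5)
  feats <- lapply(seq_along(fracs), function(i) {
    withr::with_seed(100 + i, {
      lev <- base
      nswap <- round(fracs[i] * prod(dims))
      lev[sample.int(prod(dims), nswap)] <- 2L
      rotation_invariant_features(make_quantized(lev, 2))
    })
  })
  contrast <- sapply(feats, `[[`, "contrast")
  dissim <- sapply(feats, `[[`, "dissimilarity")
  energy <- sapply(feats, `[[`, "energy")
  homog <- sapply(feats, `[[`, "homogeneity")
  expect_true(all(diff(contrast) > 0))
  expect_true(all(diff(dissim) > 0))
  expect_true(all(diff(energy) < 0))
  expect_true(all(diff(homog) < 0))
})

test_that("pooled-GLCM mode and inverse-length weighting are consistent alternatives", {
  q <- random_quantized(c(7, 7, 7), Ng = 5, seed = 41)
  pooled <- rotation_invariant_features(q, method = "pooled")
  # pooled probabilities are the pair-count-weighted mix of the 13 GLCMs
  dirs <- glcm_directions()
  counts <- Reduce(`+`, lapply(seq_len(nrow(dirs)), function(k)
    compute_glcm(q, dirs[k, ])$counts))
  want <- naive_glcm_features(counts / sum(counts))
  for (nm in names(want))
    expect_equal(pooled[[nm]], want[[nm]], tolerance = 1e-12, label = nm)

  wtd <- rotation_invariant_features(q, weighting = "inverse_length")
  per_dir <- sapply(seq_len(nrow(dirs)), function(k)
    unlist(glcm_features(compute_glcm(q, dirs[k, ]))))
  w <- 1 / sqrt(rowSums(dirs^2))
  for (nm in rownames(per_dir))
    expect_equal(wtd[[nm]], sum(per_dir[nm, ] * w) / sum(w),
                 tolerance = 1e-12, label = nm)
})

test_that("feature ranges respect their theoretical bounds on random inputs", {
  for (seed in 1:10) {
    q <- random_quantized(c(6, 6, 6), Ng = 8, seed = 200 + seed, mask_frac = 0.85)
    f <- rotation_invariant_features(q)
    expect_gt(f$energy, 0); expect_lte(f$energy, 1)
    expect_gte(f$entropy, 0)
    expect_gte(f$contrast, 0)
    expect_gt(f$homogeneity, 0); expect_lte(f$homogeneity, 1)
    expect_gte(f$correlation, -1); expect_lte(f$correlation, 1)
    expect_gte(f$dissimilarity, 0)
  }
})
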