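test_that("unpaired t-test handles identical groups and matches the pooled formula", {
  r0 <- unpaired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  r <- unpaired_ttest(a, b)
  # hand-computed pooled-variance formula
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(abs(t_hand), 6, lower.tail = FALSE)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$p, p_hand, tolerance = 1e-12)
  expect_equal(r$df, 6)
  expect_equal(c(r$mean_a, r$sd_a), c(mean(a), sd(a)))
  expect_error(unpaired_ttest(1, c(1, 2)), "n >= 2")
})

test_that("a noiseless linear outcome is recovered exactly", {
  d <- fixed_table()
  d$MVIC <- 100 + 12 * d$feat
  # summary.lm warns about the (intended) numerically perfect fit
  r <- suppressWarnings(adjusted_single_feature_regression(d, "MVIC", "feat"))
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  est <- r$coefficients$estimate[r$coefficients$term == "feat"]
  expect_equal(est, 12, tolerance = 1e-9)
  expect_lt(r$feature_p, 1e-12)
})

test_that("regression output matches an explicit normal-equations oracle", {
  d <- fixed_table()
  # independent route: X'X solve, no lm
  X <- cbind(1, as.numeric(d$sex == "M"), as.numeric(d$side == "right"),
             d$age, d$bmi, d$feat)
  y <- d$MVIC
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- nrow(X); p <- ncol(X) - 1
  rss <- sum(res^2); tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  r2adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  sigma2 <- rss / (n - p - 1)
  se <- sqrt(diag(solve(t(X) %*% X)) * sigma2)
  tvals <- as.vector(beta) / se
  pvals <- 2 * pt(abs(tvals), n - p - 1, lower.tail = FALSE)

  r <- adjusted_single_feature_regression(d, "MVIC", "feat")
  expect_equal(r$r_squared, r2, tolerance = 1e-10)
  expect_equal(r$adj_r_squared, r2adj, tolerance = 1e-10)
  expect_equal(r$coefficients$estimate, as.vector(beta), tolerance = 1e-10)
  expect_equal(r$coefficients$p_value, pvals, tolerance = 1e-10)
  expect_equal(r$feature_p, pvals[6], tolerance = 1e-10)
})

test_that("the adjusted-R2 identity and F = t2 hold for fitted models", {
  set.seed(60)
  for (i in 1:20) {
    co <- generate_cohort(cohort_spec(n_subjects = 12, seed = 300 + i),
                          phantoms = FALSE)
    r <- adjusted_single_feature_regression(co$table, "MVIC_EXT", "pdff_EXT")
    expect_equal(r$adj_r_squared,
                 1 - (1 - r$r_squared) * (r$n - 1) / (r$n - r$n_predictors - 1),
                 tolerance = 1e-12)
    # single-df term: F-test p equals two-sided t-test p
    fit <- r$fit
    an <- anova(fit)
    expect_equal(an["pdff_EXT", "Pr(>F)"], r$feature_p, tolerance = 1e-12)
    expect_equal(an["pdff_EXT", "F value"],
                 r$coefficients$t_value[r$coefficients$term == "pdff_EXT"]^2,
                 tolerance = 1e-9)
  }
})

test_that("feature p-values are uniform under the null", {
  set.seed(70)
  n <- 40
  p_vals <- replicate(400, {
    d <- data.frame(sex = sample(c("M", "F"), n, TRUE),
                    side = sample(c("left", "right"), n, TRUE),
                    age = rnorm(n, 30, 6), bmi = rnorm(n, 27, 2.6),
                    feat = rnorm(n), MVIC = rnorm(n, 180, 30))
    adjusted_single_feature_regression(d, "MVIC", "feat")$feature_p
  })
  ks <- suppressWarnings(ks.test(p_vals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("a pure-noise predictor does not increase adjusted R2 in expectation", {
  set.seed(80)
  deltas <- replicate(500, {
    n <- 30
    d <- data.frame(x = rnorm(n), noise = rnorm(n))
    d$y <- 2 * d$x + rnorm(n)
    base <- summary(lm(y ~ x, d))$adj.r.squared
    full <- summary(lm(y ~ x + noise, d))$adj.r.squared
    full - base
  })
  expect_lte(mean(deltas), 0)
})

test_that("stepwise selection is deterministic, logged, and respects thresholds", {
  co <- generate_cohort(cohort_spec(n_subjects = 20, seed = 91), phantoms = FALSE)
  cands <- c("sex", "side", "age", "bmi", "pdff_EXT", "texture_score_EXT")
  a <- stepwise_regression(co$table, "MVIC_EXT", cands)
  b <- stepwise_regression(co$table, "MVIC_EXT", cands)
  expect_identical(a$log, b$log)
  expect_identical(a$selected, b$selected)
  expect_true(all(a$log$action %in% c("add", "remove")))
  # every retained predictor survives the removal threshold in the final model
  if (length(a$selected)) {
    cf <- a$final$coefficients
    expect_true(all(cf$p_value[cf$term != "(Intercept)"] < 0.10))
  }
  # nothing can enter at p_enter = 0
  e <- stepwise_regression(co$table, "MVIC_EXT", cands, p_enter = 0)
  expect_length(e$selected, 0)
  expect_null(e$final)
  expect_equal(nrow(e$log), 0L)
})

test_that("stepwise finds a strong true predictor among noise candidates", {
  set.seed(101)
  hits <- replicate(30, {
    n <- 60
    d <- as.data.frame(matrix(rnorm(n * 10), n))
    names(d) <- paste0("c", 1:10)
    d$y <- 2 * d$c3 + rnorm(n)
    sw <- stepwise_regression(d, "y", paste0("c", 1:10))
    "c3" %in% sw$selected
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Bonferroni flags reproduce the screening-table starring convention", {
  expect_true(bonferroni_flags(0.0001, m = 12))
  expect_false(bonferroni_flags(0.009, m = 12))
  expect_equal(bonferroni_flags(c(0.04, 0.06), m = 1), c(TRUE, FALSE))
  expect_error(bonferroni_flags(0.5, m = 0), "m")
})

test_that("cluster-robust standard errors differ from conventional ones", {
  co <- generate_cohort(cohort_spec(n_subjects = 15, seed = 55), phantoms = FALSE)
  plain <- adjusted_single_feature_regression(co$table, "MVIC_EXT", "pdff_EXT")
  robust <- adjusted_single_feature_regression(co$table, "MVIC_EXT", "pdff_EXT",
                                               cluster_se = TRUE)
  expect_equal(plain$coefficients$estimate, robust$coefficients$estimate)
  expect_false(isTRUE(all.equal(plain$coefficients$std_error,
                                robust$coefficients$std_error)))
})

test_that("KS utility and sex-comparison table run end to end", {
  set.seed(3)
  expect_gt(ks_normality(rnorm(100))$p, 0.01)
  co <- generate_cohort(cohort_spec(n_subjects = 10, seed = 8), phantoms = FALSE)
  tab <- sex_comparison_table(co$table[co$table$side == "left", ],
                              c("age", "bmi", "MVIC_EXT"))
  expect_equal(nrow(tab), 3)
  expect_true(all(c("mean_male", "sd_female", "p") %in% names(tab)))
})
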