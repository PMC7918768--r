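#' Unpaired two-sample t-test with group summaries
#'
#' Two-sided pooled-variance (Student) t-test by default — the common
#' statistical-software default for "unpaired t-test" — with Welch's
#' unequal-variance form available. Returns the group mean +/- SD
#' summaries alongside the test.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pooled variance (`TRUE`, default) or Welch (`FALSE`).
#' @return list: `t`, `df`, `p`, `mean_a`, `sd_a`, `mean_b`, `sd_b`.
#' @export
unpaired_ttest <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    # degenerate identical constant groups: no variance, no difference
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                mean_a = mean(a), sd_a = 0, mean_b = mean(b), sd_b = 0))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       mean_a = mean(a), sd_a = stats::sd(a),
       mean_b = mean(b), sd_b = stats::sd(b))
}

# shared covariate coding: female = 0 / male = 1, left = 0 / right = 1
code_covariates <- function(tbl) {
  out <- tbl
  if (!is.null(out$sex) && !is.numeric(out$sex))
    out$sex <- as.numeric(out$sex == "M")
  if (!is.null(out$side) && !is.numeric(out$side))
    out$side <- as.numeric(out$side == "right")
  out
}

# summarize an lm fit into the package's regression-result structure
lm_result <- function(fit) {
  sm <- summary(fit)
  ct <- sm$coefficients
  n <- length(stats::fitted(fit))
  p_pred <- nrow(ct) - 1L
  fstat <- sm$fstatistic
  p_model <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(
    coefficients = data.frame(term = rownames(ct),
                              estimate = ct[, 1], std_error = ct[, 2],
                              t_value = ct[, 3], p_value = ct[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    n = n, n_predictors = p_pred,
    p_model = unname(p_model),
    fit = fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Linear model (n = %d, %d predictors): R2 = %.4f, adj R2 = %.4f, model p = %.3g\n",
              x$n, x$n_predictors, x$r_squared, x$adj_r_squared, x$p_model))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Covariate-adjusted single-feature regression
#'
#' Ordinary least squares of a strength outcome on sex, side, age, BMI
#' (adjustment covariates) plus one imaging feature, using both sides' rows
#' (two observations per subject, side as a fixed effect; feature values
#' are side-matched to the outcome). The feature term's p-value is the
#' two-sided t-test, identical to the single-degree-of-freedom F-test, and
#' the model's adjusted R^2 is reported — the two quantities of a
#' feature-screening table. Cluster-robust (by subject) standard errors are
#' available to acknowledge the within-subject correlation the fixed-effect
#' design ignores.
#'
#' @param tbl data.frame with columns `sex` ("M"/"F" or 0/1), `side`
#'   ("left"/"right" or 0/1), `age`, `bmi`, the outcome and the feature.
#' @param outcome name of the outcome column (e.g. `"MVIC_EXT"`).
#' @param feature name of the feature column.
#' @param cluster_se if `TRUE`, replace conventional standard errors with
#'   cluster-robust (CR0, by `subject_id`) ones in the coefficient table.
#' @return a `regression_result` with extra fields `feature`, `outcome`,
#'   `feature_p` (the feature term's p-value).
#' @export
adjusted_single_feature_regression <- function(tbl, outcome, feature,
                                               cluster_se = FALSE) {
  stopifnot(outcome %in% names(tbl), feature %in% names(tbl))
  d <- code_covariates(tbl)
  fml <- stats::reformulate(c("sex", "side", "age", "bmi", feature),
                            response = outcome)
  fit <- stats::lm(fml, data = d)
  if (anyNA(stats::coef(fit))) stop("rank-deficient design matrix")
  res <- lm_result(fit)
  if (cluster_se) {
    res$coefficients[, c("std_error", "t_value", "p_value")] <-
      cluster_robust_se(fit, d$subject_id)
  }
  res$feature <- feature
  res$outcome <- outcome
  res$feature_p <- res$coefficients$p_value[res$coefficients$term == feature]
  res
}

# CR0 cluster-robust covariance; t-tests on n_clusters - 1 df
cluster_robust_se <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  u <- stats::residuals(fit)
  xu <- rowsum(X * u, group = cluster)
  bread <- solve(crossprod(X))
  vc <- bread %*% crossprod(xu) %*% bread
  se <- sqrt(diag(vc))
  tval <- stats::coef(fit) / se
  df <- length(unique(cluster)) - 1
  data.frame(std_error = se, t_value = tval,
             p_value = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

#' Stepwise regression by F-test p-value thresholds
#'
#' Classic forward-entry / backward-removal stepwise selection: at each
#' step the candidate with the smallest term p-value (single-df F-test,
#' equal to the squared-t test) enters if `p < p_enter`; after every entry,
#' included terms with `p > p_remove` are removed (worst first) until none
#' remain; the procedure stops when no candidate can enter. Ties break by
#' candidate-list order, making the procedure deterministic. An empty final
#' model is a valid result.
#'
#' @param tbl data.frame containing `outcome` and all `candidates` columns;
#'   `sex`/`side` character columns are coded female = 0 / male = 1,
#'   left = 0 / right = 1.
#' @param outcome outcome column name.
#' @param candidates character vector of candidate predictor names, in
#'   priority (tie-break) order.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @return An object of class `stepwise_result`: list with `selected`
#'   (final predictor set, in entry order), `log` (data.frame of every
#'   entry/removal with its p-value), and `final` (a `regression_result`,
#'   or `NULL` for the empty model).
#' @export
stepwise_regression <- function(tbl, outcome, candidates,
                                p_enter = 0.05, p_remove = 0.10) {
  stopifnot(outcome %in% names(tbl), all(candidates %in% names(tbl)))
  d <- code_covariates(tbl)
  selected <- character(0)
  log_rows <- list()
  step <- 0L

  term_p <- function(terms) {
    fml <- stats::reformulate(terms, response = outcome)
    fit <- stats::lm(fml, data = d)
    cf <- summary(fit)$coefficients
    list(fit = fit, p = cf[terms, 4])
  }

  repeat {
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0L) break
    entry_p <- rep(NA_real_, length(pool))
    for (k in seq_along(pool)) {
      fml <- stats::reformulate(c(selected, pool[k]), response = outcome)
      fit <- stats::lm(fml, data = d)
      cf <- summary(fit)$coefficients
      if (!(pool[k] %in% rownames(cf))) next  # collinear with current model
      entry_p[k] <- cf[pool[k], 4]
    }
    if (all(is.na(entry_p))) break
    best <- which.min(entry_p)  # first minimum: candidate-order tie-break
    if (!(entry_p[best] < p_enter)) break
    step <- step + 1L
    selected <- c(selected, pool[best])
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(step = step, action = "add", term = pool[best],
                 p_value = entry_p[best], stringsAsFactors = FALSE)
    # backward pass: drop worst offender until all retained terms survive
    repeat {
      if (length(selected) == 0L) break
      tp <- term_p(selected)$p
      worst <- which.max(tp)
      if (!(tp[worst] > p_remove)) break
      step <- step + 1L
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(step = step, action = "remove", term = selected[worst],
                   p_value = unname(tp[worst]), stringsAsFactors = FALSE)
      selected <- selected[-worst]
    }
  }

  final <- if (length(selected) > 0L) {
    lm_result(stats::lm(stats::reformulate(selected, response = outcome), data = d))
  } else NULL
  structure(list(selected = selected,
                 log = if (length(log_rows)) do.call(rbind, log_rows)
                       else data.frame(step = integer(0), action = character(0),
                                       term = character(0), p_value = numeric(0)),
                 final = final),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Stepwise selection (forward entry / backward removal)\n")
  if (nrow(x$log)) print(x$log, digits = 4) else cat("  no terms entered\n")
  cat("Final predictors:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)", "\n")
  if (!is.null(x$final)) print(x$final)
  invisible(x)
}

#' Bonferroni significance flags
#'
#' Flags p-values significant after Bonferroni correction for `m` tests:
#' `p < alpha / m`. The default `m = 12` corresponds to screening mean PDFF
#' plus 11 texture features against one strength outcome.
#'
#' @param p_values numeric vector of raw p-values.
#' @param m number of tests corrected for (default 12).
#' @param alpha family-wise level (default 0.05).
#' @return logical vector.
#' @export
bonferroni_flags <- function(p_values, m = 12, alpha = 0.05) {
  if (m < 1) stop("`m` must be >= 1")
  p_values < alpha / m
}

#' Kolmogorov-Smirnov normality check
#'
#' Convenience pass-through: one-sample KS test of `x` against a Normal
#' with `x`'s own mean and SD (note the estimated parameters make the
#' nominal p conservative; this mirrors routine software practice for a
#' screening check, not a calibrated test).
#'
#' @param x numeric vector.
#' @return list: `D`, `p`.
#' @export
ks_normality <- function(x) {
  ht <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(D = unname(ht$statistic), p = ht$p.value)
}

#' Sex-difference summary table
#'
#' Per variable: male and female mean +/- SD and the unpaired t-test
#' p-value, the group-comparison layer of a cohort analysis.
#'
#' @param tbl data.frame with a `sex` column ("M"/"F").
#' @param vars variable names to compare.
#' @param var_equal see [unpaired_ttest()].
#' @return data.frame with one row per variable.
#' @export
sex_comparison_table <- function(tbl, vars, var_equal = TRUE) {
  stopifnot("sex" %in% names(tbl), all(vars %in% names(tbl)))
  rows <- lapply(vars, function(v) {
    tt <- unpaired_ttest(tbl[[v]][tbl$sex == "M"], tbl[[v]][tbl$sex == "F"],
                         var_equal = var_equal)
    data.frame(variable = v, mean_male = tt$mean_a, sd_male = tt$sd_a,
               mean_female = tt$mean_b, sd_female = tt$sd_b,
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
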