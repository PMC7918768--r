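#' Histogram bin-count rules
#'
#' The three classical rules whose median decides the number of histogram
#' bins used for the global (first-order) features:
#' * Sturges: `k = ceiling(log2(n)) + 1`.
#' * Scott: bin width `h = 3.49 * s * n^(-1/3)` with `s` the sample SD
#'   (n - 1 denominator); `k = ceiling(range / h)`. Zero SD is degenerate:
#'   `k = 1`, flagged.
#' * Freedman-Diaconis: `h = 2 * IQR * n^(-1/3)` with the IQR from the
#'   linear-interpolation quantile definition ([stats::quantile()] type 7);
#'   `k = ceiling(range / h)`. Zero IQR falls back to Sturges, flagged.
#'
#' A degenerate result carries `attr(k, "degenerate") = TRUE`.
#'
#' @param n sample size (Sturges).
#' @param values numeric sample (Scott, Freedman-Diaconis, median rule).
#' @return integer bin count.
#' @name bin_rules
NULL

#' @rdname bin_rules
#' @export
bin_count_sturges <- function(n) {
  if (n < 1) stop("`n` must be >= 1")
  as.integer(ceiling(log2(n)) + 1)
}

#' @rdname bin_rules
#' @export
bin_count_scott <- function(values) {
  n <- length(values)
  if (n < 2) stop("need n >= 2")
  s <- stats::sd(values)
  r <- diff(range(values))
  if (s == 0 || r == 0) {
    k <- 1L
    attr(k, "degenerate") <- TRUE
    return(k)
  }
  h <- 3.49 * s * n^(-1 / 3)
  as.integer(ceiling(r / h))
}

#' @rdname bin_rules
#' @export
bin_count_freedman_diaconis <- function(values) {
  n <- length(values)
  if (n < 2) stop("need n >= 2")
  iqr <- stats::IQR(values, type = 7)
  r <- diff(range(values))
  if (iqr == 0 || r == 0) {
    k <- bin_count_sturges(n)
    attr(k, "degenerate") <- TRUE
    return(k)
  }
  h <- 2 * iqr * n^(-1 / 3)
  as.integer(ceiling(r / h))
}

#' Median-of-three bin count
#'
#' The histogram bin count used for the global features: the middle value
#' of the Sturges, Scott and Freedman-Diaconis counts. Degenerate flags on
#' any rule propagate to the result.
#'
#' @param values numeric sample, n >= 2.
#' @return integer bin count, possibly with `attr(, "degenerate")`.
#' @export
choose_bin_count <- function(values) {
  ks <- list(bin_count_sturges(length(values)),
             bin_count_scott(values),
             bin_count_freedman_diaconis(values))
  flagged <- any(vapply(ks, function(k) isTRUE(attr(k, "degenerate")), logical(1)))
  k <- as.integer(sort(vapply(ks, as.integer, integer(1)))[2])
  if (flagged) attr(k, "degenerate") <- TRUE
  k
}

#' Global (first-order) histogram features
#'
#' Variance, skewness and kurtosis of the ROI intensity distribution,
#' computed from a histogram with [choose_bin_count()] bins spanning the
#' data range: moments use bin centres weighted by counts with population
#' (1/n) normalization. Kurtosis is reported non-excess (a Normal
#' distribution gives ~3, not 0). A `raw` mode computes the same moments
#' from the unbinned voxel values for sensitivity analysis.
#'
#' A degenerate histogram (single bin or zero variance) yields variance 0
#' with skewness and kurtosis missing.
#'
#' @param values numeric vector of ROI intensities (percent), n >= 3.
#' @param nbins optional bin count override; default [choose_bin_count()].
#' @param method `"binned"` (default) or `"raw"`.
#' @param normalization `"population"` (1/n, default) or `"sample"`
#'   (n/(n-1) variance correction; skewness/kurtosis stay moment ratios).
#' @return list: `variance_global` (percent^2), `skewness_global`,
#'   `kurtosis_global` (dimensionless), `n_bins`, `degenerate`.
#' @export
global_features <- function(values, nbins = NULL,
                            method = c("binned", "raw"),
                            normalization = c("population", "sample")) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  n <- length(values)
  if (n < 3) stop("need at least 3 values")

  if (method == "raw") {
    x <- values
    k <- NA_integer_
  } else {
    k <- if (is.null(nbins)) choose_bin_count(values) else as.integer(nbins)
    mn <- min(values); mx <- max(values)
    if (as.integer(k) <= 1L || mx <= mn) {
      return(list(variance_global = 0, skewness_global = NA_real_,
                  kurtosis_global = NA_real_, n_bins = 1L, degenerate = TRUE))
    }
    l <- ceiling(k * (values - mn) / (mx - mn))
    l[l < 1L] <- 1L
    counts <- tabulate(l, nbins = k)
    edges <- seq(mn, mx, length.out = k + 1)
    centers <- (edges[-1] + edges[-(k + 1)]) / 2
    x <- rep(centers, counts)  # binned representation of the sample
  }

  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) {
    return(list(variance_global = 0, skewness_global = NA_real_,
                kurtosis_global = NA_real_,
                n_bins = if (is.na(k)) NA_integer_ else as.integer(k),
                degenerate = TRUE))
  }
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  variance <- if (normalization == "sample") m2 * n / (n - 1) else m2
  list(variance_global = variance,
       skewness_global = m3 / m2^1.5,
       kurtosis_global = m4 / m2^2,
       n_bins = if (is.na(k)) NA_integer_ else as.integer(k),
       degenerate = FALSE)
}
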