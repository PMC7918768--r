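`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-item RNG seed from a master seed
#'
#' Deterministic splitting rule used wherever the package generates several
#' independent random objects (phantoms, cohort replicates) from one master
#' seed: `seed_i = (master * 1000003 + index * 7919) mod (2^31 - 1)`, mapped
#' into `[1, 2^31 - 2]`. The multipliers are primes; the arithmetic stays
#' exact in double precision for any 32-bit master seed.
#'
#' @param master integer master seed.
#' @param index non-negative integer item index.
#' @return an integer seed usable with [set.seed()].
#' @export
derive_seed <- function(master, index) {
  x <- (abs(as.double(master)) * 1000003 + as.double(index) * 7919) %% 2147483646
  as.integer(x) + 1L
}

clip01 <- function(x, lo = 0, hi = 100) pmin(pmax(x, lo), hi)

# separable 1D Gaussian smoothing along one array axis, replicate padding
smooth_axis <- function(arr, sigma, axis) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k <- k / sum(k)
  n <- dim(arr)[axis]
  # replicate-padded index into the axis
  idx <- pmin(pmax(seq_len(n + 2 * r) - r, 1L), n)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])          # axis of interest down the rows
  mp <- m[idx, , drop = FALSE]
  sm <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
  sm <- sm[(r + 1):(r + n), , drop = FALSE]
  out <- array(sm, dim = d)
  aperm(out, order(perm))
}

gaussian_smooth3 <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3)
  for (ax in 1:3) arr <- smooth_axis(arr, sigma[ax], ax)
  arr
}
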