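#' Bootstrap configuration
#'
#' @param scheme `"block"` (resample non-overlapping blocks of consecutive
#'   time points, preserving autocorrelation within blocks) or
#'   `"independent"` (resample single time points; only valid for serially
#'   independent data).
#' @param block_length block length L in samples (default 10, roughly five
#'   autocorrelation time-scales of typical band-passed BOLD signals).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param ci_level confidence level (default 0.95).
#' @param ci_type `"normal"` (estimate +/- z * bootstrap SE; default) or
#'   `"percentile"`.
#' @return a `bootstrap_config` list.
#' @export
bootstrap_config <- function(scheme = c("block", "independent"),
                             block_length = 10L, n_boot = 1000L,
                             ci_level = 0.95,
                             ci_type = c("normal", "percentile")) {
  scheme <- match.arg(scheme)
  ci_type <- match.arg(ci_type)
  stopifnot(block_length >= 1, n_boot >= 1, ci_level > 0, ci_level < 1)
  structure(list(scheme = scheme, block_length = as.integer(block_length),
                 n_boot = as.integer(n_boot), ci_level = ci_level,
                 ci_type = ci_type),
            class = "bootstrap_config")
}

#' Block resampling of a multivariate time series
#'
#' Cuts the columns into `B = floor(T/L)` non-overlapping blocks of `L`
#' consecutive time points (a trailing remainder shorter than `L` is
#' dropped), draws `B` blocks with replacement and concatenates them.  All
#' regions are resampled jointly, so cross-region alignment is never broken.
#'
#' @param x a [region_ts()].
#' @param L block length; `L = 1` reduces to independent column resampling,
#'   `L = T` returns a copy of the (trimmed) input.
#' @return a resampled `region_ts` (standardized flag cleared).
#' @export
block_resample <- function(x, L) {
  stopifnot(inherits(x, "region_ts"))
  T <- ncol(x$data)
  L <- as.integer(L)
  if (L < 1L) stop("block length must be >= 1", call. = FALSE)
  if (L > T) stop("block length exceeds series length", call. = FALSE)
  if (T < 2L * L && L < T)  # L = T (single full block) is allowed
    stop("need T >= 2L for block resampling", call. = FALSE)
  B <- max(1L, T %/% L)
  pick <- sample.int(B, B, replace = TRUE)
  cols <- as.vector(outer(seq_len(L), (pick - 1L) * L, `+`))
  new_region_ts(x$data[, cols, drop = FALSE], standardized = FALSE)
}

#' @rdname block_resample
#' @export
independent_resample <- function(x) {
  stopifnot(inherits(x, "region_ts"))
  T <- ncol(x$data)
  new_region_ts(x$data[, sample.int(T, T, replace = TRUE), drop = FALSE],
                standardized = FALSE)
}

#' Bootstrap a connectivity statistic
#'
#' Approximates the sampling distribution of `statistic(x)` by resampling
#' time points (block-wise or independently per [bootstrap_config()]),
#' returning the bootstrap standard error, a confidence interval and a
#' two-sided z-test p-value for the null hypothesis that the population
#' value is zero (observed estimate divided by the bootstrap SE, normal
#' reference).
#'
#' @param x a [region_ts()].
#' @param statistic function mapping a `region_ts` to a numeric scalar (an
#'   estimator value; `cumulant_estimate` returns are unwrapped).
#' @param config a [bootstrap_config()].
#' @return a `bootstrap_result` with fields `estimate`, `replicates`, `se`,
#'   `ci`, `p_value`.
#' @export
bootstrap <- function(x, statistic, config = bootstrap_config()) {
  stopifnot(inherits(x, "region_ts"), is.function(statistic),
            inherits(config, "bootstrap_config"))
  stat1 <- function(z) {
    v <- statistic(z)
    if (inherits(v, "cumulant_estimate")) v <- v$value
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("statistic must return a finite numeric scalar", call. = FALSE)
    v
  }
  theta <- tryCatch(stat1(x), error = function(e)
    stop("statistic failed on the original data: ", conditionMessage(e),
         call. = FALSE))
  L <- if (config$scheme == "independent") 1L else config$block_length
  reps <- vapply(seq_len(config$n_boot), function(b) {
    xb <- block_resample(x, L)
    v <- tryCatch(suppressMessages(stat1(xb)), error = function(e)
      stop("statistic failed on bootstrap resample ", b, ": ",
           conditionMessage(e), call. = FALSE))
    v
  }, 1)
  finalize_bootstrap(theta, reps, config)
}

finalize_bootstrap <- function(theta, reps, config) {
  se <- stats::sd(reps)
  z <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  ci <- if (config$ci_type == "percentile")
    unname(stats::quantile(reps, c((1 - config$ci_level) / 2,
                                   1 - (1 - config$ci_level) / 2)))
  else theta + c(-1, 1) * z * se
  p <- if (se == 0) as.numeric(theta == 0) else
    2 * stats::pnorm(-abs(theta) / se)
  structure(list(estimate = theta, replicates = reps, se = se, ci = ci,
                 p_value = p, config = config),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap (%s, B = %d): estimate %.5g, se %.4g, %g%% CI [%.5g, %.5g], p = %.4g\n",
    x$config$scheme, x$config$n_boot, x$estimate, x$se,
    100 * x$config$ci_level, x$ci[1], x$ci[2], x$p_value))
  invisible(x)
}

#' Attach bootstrap uncertainty to a cumulant estimate
#'
#' Convenience wrapper: bootstraps the estimator that produced `est` on the
#' data and fills the `se`, `ci` and `p_value` slots.
#'
#' @param est a `cumulant_estimate`.
#' @param x the [region_ts()] the estimate came from.
#' @param config a [bootstrap_config()].
#' @return the `cumulant_estimate` with uncertainty fields set.
#' @export
add_uncertainty <- function(est, x, config = bootstrap_config()) {
  stopifnot(inherits(est, "cumulant_estimate"))
  stat <- estimate_statistic(est)
  b <- bootstrap(x, stat, config)
  est$se <- b$se; est$ci <- b$ci; est$p_value <- b$p_value
  est
}

# rebuild the estimator callable from an estimate's metadata
estimate_statistic <- function(est) {
  idx <- est$indices
  switch(est$measure,
    correlation = function(z) correlation2(z, idx[1], idx[2]),
    coskewness = function(z) coskewness(z, idx[1], idx[2], idx[3]),
    cokurtosis = function(z) cokurtosis(z, idx[1], idx[2], idx[3], idx[4]),
    edge_raw = function(z) edge_connectivity(z, idx[1:2], idx[3:4], "raw"),
    edge_redundant = function(z)
      edge_connectivity(z, idx[1:2], idx[3:4], "redundant"),
    edge_corrected = function(z)
      edge_connectivity(z, idx[1:2], idx[3:4], "corrected"),
    stop("no statistic for measure ", est$measure, call. = FALSE))
}

#' Coherent phase randomization
#'
#' Builds a Gaussianizing surrogate by rotating the discrete Fourier
#' transform of every row by the SAME uniformly random phase at each
#' frequency (Hermitian-symmetric; DC and Nyquist bins untouched).  Each
#' row's amplitude spectrum, and therefore its autocorrelation function, is
#' preserved exactly, and because the phases are shared the cross-spectra
#' (hence all pairwise cross-correlations) are preserved too.  What is
#' destroyed is any higher-order structure: the surrogate ensemble realizes
#' the null hypothesis of a linear Gaussian process with the observed
#' second-order structure.
#'
#' @param x a standardized [region_ts()].
#' @return a surrogate `region_ts` (still standardized: row means and
#'   variances are preserved exactly).
#' @export
phase_randomize <- function(x) {
  stopifnot(inherits(x, "region_ts"))
  x <- need_standardized(x)
  T <- ncol(x$data)
  m <- (T - 1L) %/% 2L
  rot <- rep(1 + 0i, T)
  if (m >= 1L) {
    th <- stats::runif(m, 0, 2 * pi)
    rot[2:(m + 1L)] <- exp(1i * th)
    rot[T:(T - m + 1L)] <- exp(-1i * th)
  }
  F <- stats::mvfft(t(x$data)) * rot
  surr <- t(Re(stats::mvfft(F, inverse = TRUE))) / T
  rownames(surr) <- x$region_ids
  new_region_ts(surr, standardized = TRUE)
}

#' Surrogate-data null test
#'
#' Two-sided empirical p-value of `statistic(x)` against an ensemble of
#' coherent phase-randomized surrogates:
#' `p = (1 + #{|T_surr| >= |T_obs|}) / (n_surrogates + 1)`.
#'
#' @param x a standardized [region_ts()].
#' @param statistic function mapping a `region_ts` to a scalar.
#' @param n_surrogates ensemble size (default 199).
#' @return a `surrogate_test` list with `p_value`, `observed`,
#'   `surrogates`.
#' @export
surrogate_null_test <- function(x, statistic, n_surrogates = 199L) {
  x <- need_standardized(x)
  stat1 <- function(z) {
    v <- statistic(z)
    if (inherits(v, "cumulant_estimate")) v$value else v
  }
  obs <- stat1(x)
  surr <- vapply(seq_len(n_surrogates), function(s)
    suppressMessages(stat1(phase_randomize(x))), 1)
  p <- (1 + sum(abs(surr) >= abs(obs))) / (n_surrogates + 1)
  structure(list(p_value = p, observed = obs, surrogates = surr),
            class = "surrogate_test")
}

#' @export
print.surrogate_test <- function(x, ...) {
  cat(sprintf("phase-randomization test: observed %.5g, %d surrogates, p = %.4g\n",
              x$observed, length(x$surrogates), x$p_value))
  invisible(x)
}

## ---- fast additive-block kernel for bootstrapping the coskewness --------
##
## The coskewness of any resample is a function of ten column-sum statistics
## (three first moments, three second moments, three pairwise products, one
## triple product), each additive over resampled blocks.  Precomputing the
## per-block sums turns one bootstrap replicate into a 10-number reduction,
## which is what makes the calibration experiments (10^6 replicates)
## tractable.  Algebraically identical to coskewness(block_resample(x, L))
## and drawn with the same RNG stream (sample.int of B blocks per
## replicate), which the test suite verifies by exact comparison.

coskew_from_sums <- function(S, T) {
  m1 <- S[, 1] / T; m2 <- S[, 2] / T; m3 <- S[, 3] / T
  s1 <- sqrt((S[, 4] - T * m1^2) / (T - 1))
  s2 <- sqrt((S[, 5] - T * m2^2) / (T - 1))
  s3 <- sqrt((S[, 6] - T * m3^2) / (T - 1))
  num <- S[, 10] - m1 * S[, 9] - m2 * S[, 8] - m3 * S[, 7] +
    2 * T * m1 * m2 * m3
  (num / T) / (s1 * s2 * s3)
}

coskew_block_sums <- function(xmat, L) {
  T <- ncol(xmat)
  B <- T %/% L
  Tu <- B * L
  x1 <- xmat[1, 1:Tu]; x2 <- xmat[2, 1:Tu]; x3 <- xmat[3, 1:Tu]
  g <- rep(seq_len(B), each = L)
  cbind(rowsum(x1, g), rowsum(x2, g), rowsum(x3, g),
        rowsum(x1^2, g), rowsum(x2^2, g), rowsum(x3^2, g),
        rowsum(x1 * x2, g), rowsum(x1 * x3, g), rowsum(x2 * x3, g),
        rowsum(x1 * x2 * x3, g))
}

# bootstrap replicates of the coskewness of a 3-region matrix; returns the
# replicate vector.  L = 1 is the independent scheme.
coskew_boot_replicates <- function(xmat, L, n_boot) {
  M <- coskew_block_sums(xmat, L)
  B <- nrow(M)
  T <- B * L
  idx <- matrix(sample.int(B, B * n_boot, replace = TRUE), nrow = B)
  S <- rowsum(M[as.vector(idx), , drop = FALSE],
              group = rep(seq_len(n_boot), each = B))
  coskew_from_sums(S, T)
}
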