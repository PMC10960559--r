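#' AR coefficient from an autocorrelation time-scale
#'
#' The model's lag-k autocorrelation is `phi^k`; requiring it to equal
#' `exp(-k/tau)` gives `phi = exp(-1/tau)`, so `tau` is the time-scale (in
#' samples) over which the autocorrelation decays by a factor e.
#'
#' @param tau positive time-scale in samples.
#' @return the AR(1) coefficient in (0, 1).
#' @export
phi_from_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a positive number of samples", call. = FALSE)
  exp(-1 / tau)
}

#' Innovation correlation from a target signal correlation
#'
#' The shared non-Gaussian input raises the pairwise signal correlation
#' above the Gaussian-innovation correlation `rho`; to reach a target signal
#' correlation `r` one must set `rho = r + (r - 1) * psi^2`.
#'
#' @param r target pairwise correlation of the simulated signals.
#' @param psi non-Gaussian innovation strength in [0, 1].
#' @return the Gaussian innovation correlation `rho`.
#' @export
rho_from_r <- function(r, psi) r + (r - 1) * psi^2

#' Non-Gaussian autoregressive generative model
#'
#' Defines the first-order vector-autoregressive model
#' `X_i(t+1) = phi X_i(t) + Z_i(t) + psi U(t)` in which `Z(t)` is an
#' equicorrelated (pairwise correlation `rho`) unit-variance Gaussian vector
#' and the SAME scalar non-Gaussian innovation `U(t)` drives every region.
#' The shared `U` is what creates genuine higher-order connectivity: a
#' skew-normal `U` yields nonzero coskewness, a heavy-tailed (t) `U` yields
#' nonzero cokurtosis and corrected edge connectivity.  All ground-truth
#' connectivities of the stationary process are available in closed form via
#' [ground_truth()].
#'
#' Either `tau` (autocorrelation time-scale, `phi = exp(-1/tau)`) or `phi`
#' may be given, and either `r` (target signal correlation, converted via
#' [rho_from_r()]) or `rho` directly.  Positive-definiteness of the Gaussian
#' innovation covariance requires `rho > -1/(n-1)`; with `psi` restricted to
#' [0, 1] a sufficient condition is `r > 1/2 - 1/(2(n-1))`, i.e. `r > 1/4`
#' for n = 3 and `r > 1/3` for n = 4.
#'
#' @param n number of regions (3 for third-order, 4 for fourth-order
#'   studies).
#' @param tau,phi autocorrelation time-scale in samples, or the AR
#'   coefficient directly (exactly one).
#' @param psi non-Gaussian innovation strength in [0, 1].
#' @param r,rho target signal correlation, or the Gaussian innovation
#'   correlation directly (exactly one).
#' @param innovation an [skew_normal_innovation()] or
#'   [student_t_innovation()] spec.
#' @return an object of class `hofc_model` with `print`, `coef`,
#'   [simulate][stats::simulate] and [ground_truth()] methods.
#' @examples
#' m <- hofc_model(n = 3, tau = 2, r = 0.4, psi = 1,
#'                 innovation = skew_normal_innovation(3))
#' ground_truth(m)$coskewness
#' x <- simulate(m, T = 500, seed = 1)
#' coskewness(x, "R1", "R2", "R3")
#' @export
hofc_model <- function(n, tau = NULL, phi = NULL, psi, r = NULL, rho = NULL,
                       innovation) {
  stopifnot(n >= 2, inherits(innovation, "innovation_spec"))
  n <- as.integer(n)
  if (is.null(phi) == is.null(tau))
    stop("give exactly one of tau or phi", call. = FALSE)
  if (is.null(phi)) phi <- phi_from_tau(tau) else tau <- -1 / log(phi)
  if (phi < 0 || phi >= 1)
    stop("phi must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(psi) || psi < 0 || psi > 1)
    stop("psi must lie in [0, 1]", call. = FALSE)
  if (is.null(rho) == is.null(r))
    stop("give exactly one of r or rho", call. = FALSE)
  if (is.null(rho)) rho <- rho_from_r(r, psi)
  m <- structure(list(n = n, tau = tau, phi = phi, psi = psi,
                      r = if (is.null(r)) (rho + psi^2) / (1 + psi^2) else r,
                      rho = rho, innovation = innovation),
                 class = "hofc_model")
  validate_model(m)
  m
}

#' Validate generative-model parameters
#'
#' Checks positive-definiteness of the equicorrelated Gaussian innovation
#' covariance (`rho > -1/(n-1)`) and reports the conservative sufficient
#' bound on the signal correlation (`r > 1/2 - 1/(2(n-1))`, valid for every
#' `psi` in [0, 1]).
#'
#' @param model an `hofc_model` (or a list with fields `n`, `rho`).
#' @return invisibly `TRUE`; errors with the violated bound otherwise.
#' @export
validate_model <- function(model) {
  lb <- -1 / (model$n - 1)
  if (!(model$rho > lb))
    stop(sprintf(
      "innovation covariance not positive-definite: rho = %.4f must exceed -1/(n-1) = %.4f (sufficient: r > %.4f for any psi in [0,1])",
      model$rho, lb, sufficient_r_bound(model$n)), call. = FALSE)
  invisible(TRUE)
}

#' @rdname validate_model
#' @param n number of regions.
#' @export
sufficient_r_bound <- function(n) 1 / 2 - 1 / (2 * (n - 1))

#' @export
print.hofc_model <- function(x, ...) {
  cat(sprintf(
    "non-Gaussian AR(1) model: n = %d regions\n  phi = %.4f (tau = %.3g samples), psi = %.3g, r = %.3g (rho = %.3g)\n",
    x$n, x$phi, x$tau, x$psi, x$r, x$rho))
  print(x$innovation)
  invisible(x)
}

#' @export
coef.hofc_model <- function(object, ...) {
  c(n = object$n, phi = object$phi, tau = object$tau, psi = object$psi,
    r = object$r, rho = object$rho)
}

#' Simulate from the generative model
#'
#' Draws a stationary realization of the model.  The process is started at
#' zero and a burn-in stretch (default `20 * tau` samples) is discarded so
#' that the returned series is effectively stationary.  Reproducible given
#' `seed`; the seed is recorded as an attribute of the result.
#'
#' @param object an [hofc_model()].
#' @param nsim number of independent series to draw (default 1).
#' @param seed optional integer seed.
#' @param T number of retained time points.
#' @param burn_in number of initial samples discarded.
#' @param ... unused.
#' @return a [region_ts()] (or a list of them when `nsim > 1`).
#' @export
simulate.hofc_model <- function(object, nsim = 1, seed = NULL, T = 1200,
                                burn_in = ceiling(20 * object$tau), ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(s) {
    x <- region_ts(simulate_kernel(object, T, burn_in))
    attr(x, "seed") <- seed
    attr(x, "model") <- coef(object)
    x
  })
  if (nsim == 1) out[[1]] else out
}

# one draw; returns a plain n x T matrix. innovations: E = C Z + psi U 1
simulate_kernel <- function(model, T, burn_in) {
  n <- model$n
  Ttot <- T + burn_in
  Z <- matrix(stats::rnorm(n * Ttot), nrow = n)
  E <- crossprod(equicorr_sqrt(n, model$rho), Z) +
    rep(model$psi * sample_innovation(model$innovation, Ttot), each = n)
  # X(t+1) = phi X(t) + E(t), X(0) = 0: recursive filter along time
  X <- stats::filter(t(E), filter = model$phi, method = "recursive")
  t(X)[, (burn_in + 1):Ttot, drop = FALSE]
}

# symmetric square root of the n x n equicorrelation matrix
equicorr_sqrt <- function(n, rho) {
  S <- matrix(rho, n, n)
  diag(S) <- 1
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("equicorrelation matrix not positive-definite", call. = FALSE)
  e$vectors %*% (sqrt(e$values) * t(e$vectors))
}

#' Closed-form ground-truth connectivities of the generative model
#'
#' Evaluates the population connectivities of the stationary process.
#' Writing `kappa4 = psi^4 c4U / (1 - phi^4)` for the common fourth
#' cumulant, `c = (rho + psi^2)/(1 - phi^2)` for the common covariance and
#' `v = (1 + psi^2)/(1 - phi^2)` for the variance:
#' \itemize{
#'   \item pairwise correlation `(rho + psi^2)/(1 + psi^2)`;
#'   \item coskewness
#'     `(1-phi^2)^{3/2} psi^3 c3U / ((1-phi^3)(1+psi^2)^{3/2})`;
#'   \item cokurtosis `(1-phi^2)^2 psi^4 c4U / ((1-phi^4)(1+psi^2)^2)`;
#'   \item raw edge connectivity `(kappa4 + 3c^2)/(kappa4 + v^2 + 2c^2)`,
#'     redundant part `3c^2/(v^2 + 2c^2)` (the same expression with the
#'     fourth cumulant set to zero), corrected part their difference.
#' }
#' Coskewness and cokurtosis do not depend on `rho`; the edge connectivity
#' does.
#'
#' @param model an [hofc_model()].
#' @return a list with elements `pair_correlation`, `coskewness`,
#'   `cokurtosis`, `edge_raw`, `edge_redundant`, `edge_corrected`.
#' @export
ground_truth <- function(model) {
  stopifnot(inherits(model, "hofc_model"))
  phi <- model$phi; psi <- model$psi; rho <- model$rho
  c3 <- innovation_c3(model$innovation)
  c4 <- innovation_c4(model$innovation)
  k4 <- psi^4 * c4 / (1 - phi^4)
  cc <- (rho + psi^2) / (1 - phi^2)
  v <- (1 + psi^2) / (1 - phi^2)
  raw <- (k4 + 3 * cc^2) / (k4 + v^2 + 2 * cc^2)
  red <- 3 * cc^2 / (v^2 + 2 * cc^2)
  list(
    pair_correlation = (rho + psi^2) / (1 + psi^2),
    coskewness = (1 - phi^2)^1.5 * psi^3 * c3 /
      ((1 - phi^3) * (1 + psi^2)^1.5),
    cokurtosis = (1 - phi^2)^2 * psi^4 * c4 /
      ((1 - phi^4) * (1 + psi^2)^2),
    edge_raw = raw, edge_redundant = red, edge_corrected = raw - red)
}

#' @rdname ground_truth
#' @export
true_correlation <- function(model) ground_truth(model)$pair_correlation

#' @rdname ground_truth
#' @export
true_coskewness <- function(model) ground_truth(model)$coskewness

#' @rdname ground_truth
#' @export
true_cokurtosis <- function(model) ground_truth(model)$cokurtosis

#' @rdname ground_truth
#' @export
true_edge_connectivity <- function(model) {
  gt <- ground_truth(model)
  c(raw = gt$edge_raw, redundant = gt$edge_redundant,
    corrected = gt$edge_corrected)
}
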