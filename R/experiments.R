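#' Ground-truth connectivity curves over a parameter grid
#'
#' Evaluates the closed-form coskewness (skew-normal innovations) or
#' cokurtosis and edge connectivity (t innovations) over a grid of the
#' non-Gaussian strength `psi` and the innovation shape parameter.
#'
#' @param psi_grid values of the non-Gaussian innovation strength in [0, 1].
#' @param shape_grid skew-normal `alpha` values (for
#'   `innovation = "skew_normal"`) or t degrees of freedom `nu` (for
#'   `innovation = "student_t"`).
#' @param innovation innovation family.
#' @param tau autocorrelation time-scale in samples (default 2, the
#'   least-squares fit to group-level BOLD autocorrelation reported for
#'   HCP-like acquisitions).
#' @param r common pairwise signal correlation (default 0.4).
#' @return a data.frame with one row per grid point; class
#'   `hofc_gt_curves` with a `plot` method.
#' @export
ground_truth_curves <- function(psi_grid = seq(0, 1, by = 0.1),
                                shape_grid = NULL,
                                innovation = c("skew_normal", "student_t"),
                                tau = 2, r = 0.4) {
  innovation <- match.arg(innovation)
  stopifnot(length(psi_grid) >= 1)
  if (is.null(shape_grid))
    shape_grid <- if (innovation == "skew_normal") seq(0, 6, by = 0.5)
                  else 5:20
  grid <- expand.grid(psi = psi_grid, shape = shape_grid,
                      KEEP.OUT.ATTRS = FALSE)
  n <- if (innovation == "skew_normal") 3L else 4L
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    spec <- if (innovation == "skew_normal")
      skew_normal_innovation(grid$shape[g]) else
      student_t_innovation(grid$shape[g])
    gt <- ground_truth(hofc_model(n = n, tau = tau, r = r,
                                  psi = grid$psi[g], innovation = spec))
    data.frame(psi = grid$psi[g], shape = grid$shape[g],
               coskewness = gt$coskewness, cokurtosis = gt$cokurtosis,
               edge_corrected = gt$edge_corrected)
  })
  out <- do.call(rbind, rows)
  names(out)[2] <- if (innovation == "skew_normal") "alpha" else "nu"
  attr(out, "innovation") <- innovation
  class(out) <- c("hofc_gt_curves", class(out))
  out
}

#' @export
plot.hofc_gt_curves <- function(x, measure = NULL, ...) {
  innovation <- attr(x, "innovation")
  if (is.null(measure))
    measure <- if (innovation == "skew_normal") "coskewness"
               else "cokurtosis"
  shp <- names(x)[2]
  shapes <- sort(unique(x[[shp]]))
  graphics::plot(range(x$psi), range(x[[measure]]), type = "n",
                 xlab = expression(psi), ylab = measure, ...)
  for (s in shapes) {
    sub <- x[x[[shp]] == s, ]
    graphics::lines(sub$psi[order(sub$psi)],
                    sub[[measure]][order(sub$psi)],
                    col = grDevices::grey(0.2 + 0.6 * match(s, shapes) /
                                            length(shapes)))
  }
  invisible(x)
}

# fast per-dataset estimates of one measure on nsim independent simulations
# of a model; vectorized across datasets (series stacked as columns of one
# recursive filter call).
simulate_estimates <- function(model, T, nsim, measure, burn_in = NULL,
                               chunk = 2000L) {
  if (is.null(burn_in)) burn_in <- ceiling(20 * model$tau)
  n <- model$n
  Ttot <- T + burn_in
  out <- numeric(0)
  left <- nsim
  while (left > 0L) {
    m <- min(chunk, left)
    Z <- matrix(stats::rnorm(n * m * Ttot), nrow = n * m)
    U <- matrix(model$psi * sample_innovation(model$innovation, m * Ttot),
                nrow = m)
    C <- equicorr_sqrt(n, model$rho)
    E <- matrix(0, n * m, Ttot)
    for (i in seq_len(n)) {
      rows_i <- seq.int(i, n * m, by = n)
      Ei <- matrix(0, m, Ttot)
      for (j in seq_len(n))
        Ei <- Ei + C[i, j] * Z[seq.int(j, n * m, by = n), , drop = FALSE]
      E[rows_i, ] <- Ei + U
    }
    X <- t(stats::filter(t(E), filter = model$phi, method = "recursive"))
    X <- X[, (burn_in + 1):Ttot, drop = FALSE]
    out <- c(out, estimate_stack(X, n, m, T, measure))
    left <- left - m
  }
  out
}

# X: (n*m) x T stacked series (dataset d occupies rows (d-1)*n + 1:n)
estimate_stack <- function(X, n, m, T, measure) {
  mu <- rowMeans(X)
  X <- (X - mu) / sqrt(rowSums((X - mu)^2) / (T - 1))
  r1 <- seq.int(1, n * m, by = n)
  vapply(seq_len(m), function(d) {
    xm <- X[r1[d] + 0:(n - 1), , drop = FALSE]
    switch(measure,
      correlation = moment_kernel(xm, c(1, 2)),
      coskewness = moment_kernel(xm, c(1, 2, 3)),
      cokurtosis = cum4_kernel(xm, 1, 2, 3, 4),
      edge_corrected = edge_raw_kernel(xm, c(1, 2), c(3, 4)) -
        edge_redundant_kernel(xm, c(1, 2), c(3, 4)),
      stop("unknown measure ", measure, call. = FALSE))
  }, 1)
}

#' Sampling study of a connectivity estimator
#'
#' For every grid point, simulates `n_datasets` independent series from the
#' generative model, estimates the measure on each, and tabulates the true
#' value, the Monte-Carlo mean and bias, the Monte-Carlo standard error
#' (ensemble SD) and the detection probability: the fraction of datasets in
#' which `|estimate| / sigma_MC` exceeds the two-sided normal critical value
#' at the given test size, with `sigma_MC` the ensemble SD at that grid
#' point (the sampling distribution itself, as available in a simulation
#' study; per-dataset bootstrap SEs are the practical alternative exposed
#' through [bootstrap()]).
#'
#' @param measure `"coskewness"` (n = 3, skew-normal innovations) or
#'   `"cokurtosis"`/`"edge_corrected"` (n = 4, t innovations).
#' @param psi_grid,shape_grid parameter grids (shape is `alpha` or `nu`).
#' @param tau,r,T model time-scale, pairwise correlation, series length.
#' @param n_datasets Monte-Carlo ensemble size per grid point.
#' @param alpha_level test size for the detection probability.
#' @param seed optional integer seed.
#' @return a data.frame (class `hofc_sampling_study`) with per-grid-point
#'   columns `true`, `mc_mean`, `bias`, `se`, `detection`; the pooled
#'   z-scored estimates are attached as attribute `"pooled_z"`.
#' @export
sampling_study <- function(measure = c("coskewness", "cokurtosis",
                                       "edge_corrected"),
                           psi_grid = seq(0, 1, by = 0.25),
                           shape_grid = NULL, tau = 2, r = 0.4, T = 1200,
                           n_datasets = 1000L, alpha_level = 0.05,
                           seed = NULL) {
  measure <- match.arg(measure)
  if (!is.null(seed)) set.seed(seed)
  skew <- measure == "coskewness"
  if (is.null(shape_grid)) shape_grid <- if (skew) c(0, 1.5, 3) else c(5, 8, 20)
  n <- if (skew) 3L else 4L
  zc <- stats::qnorm(1 - alpha_level / 2)
  grid <- expand.grid(psi = psi_grid, shape = shape_grid,
                      KEEP.OUT.ATTRS = FALSE)
  pooled <- list()
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    spec <- if (skew) skew_normal_innovation(grid$shape[g])
            else student_t_innovation(grid$shape[g])
    model <- hofc_model(n = n, tau = tau, r = r, psi = grid$psi[g],
                        innovation = spec)
    est <- simulate_estimates(model, T, n_datasets, measure)
    truth <- ground_truth(model)[[measure]]
    sig <- stats::sd(est)
    pooled[[g]] <<- (est - mean(est)) / sig
    data.frame(psi = grid$psi[g], shape = grid$shape[g], true = truth,
               mc_mean = mean(est), bias = mean(est) - truth, se = sig,
               detection = mean(abs(est) / sig > zc))
  })
  out <- do.call(rbind, rows)
  names(out)[2] <- if (skew) "alpha" else "nu"
  attr(out, "pooled_z") <- unlist(pooled)
  attr(out, "measure") <- measure
  class(out) <- c("hofc_sampling_study", class(out))
  out
}

#' Feasibility of fourth-order estimation at realistic scan lengths
#'
#' For each `(psi, nu)` grid point, simulates an ensemble and reports the
#' Monte-Carlo mean and the central 95% interval (2.5% and 97.5%
#' percentiles) of the cokurtosis and corrected edge-connectivity
#' estimators, flagging whether the interval excludes zero (i.e. whether
#' single-dataset detection is feasible at all).
#'
#' @inheritParams sampling_study
#' @param nu_grid t degrees-of-freedom grid.
#' @return a data.frame with one row per grid point and measure.
#' @export
fourth_order_feasibility <- function(psi_grid = c(0, 0.5, 1),
                                     nu_grid = c(5, 8, 20), tau = 2,
                                     r = 0.4, T = 1200, n_datasets = 1000L,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(psi = psi_grid, nu = nu_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    model <- hofc_model(n = 4, tau = tau, r = r, psi = grid$psi[g],
                        innovation = student_t_innovation(grid$nu[g]))
    out <- lapply(c("cokurtosis", "edge_corrected"), function(meas) {
      est <- simulate_estimates(model, T, n_datasets, meas)
      q <- unname(stats::quantile(est, c(0.025, 0.975)))
      data.frame(psi = grid$psi[g], nu = grid$nu[g], measure = meas,
                 true = ground_truth(model)[[meas]], mc_mean = mean(est),
                 q025 = q[1], q975 = q[2],
                 excludes_zero = q[1] > 0 || q[2] < 0)
    })
    do.call(rbind, out)
  })
  do.call(rbind, rows)
}

#' Null calibration of bootstrap z-tests for the coskewness
#'
#' Reproduces the calibration experiment: for each scanning time `T`,
#' simulate `n_experiments` null datasets (`psi = 0`, so no third-order
#' connectivity), estimate the coskewness of each, estimate its standard
#' error by bootstrap (block scheme with length `L`, or the independent
#' scheme via `scheme = "independent"`), and test H0: coskewness = 0 with a
#' two-sided z-test at level `alpha_level`.  Reports per `T` the Monte-Carlo
#' ("true") SE of the estimator, the mean bootstrap SE, and the null
#' rejection rate.  Block bootstrapping systematically *under*-estimates
#' the SE on autocorrelated data, which inflates the rejection rate above
#' the nominal level (strongly so for the independent scheme).
#'
#' @param scanning_times vector of series lengths T.
#' @param L block length (default 10).
#' @param B_rep bootstrap replicates per dataset (default 1000).
#' @param n_experiments datasets per scanning time (default 1000).
#' @param tau,r model parameters of the null process.
#' @param scheme `"block"` or `"independent"`.
#' @param alpha_level test size.
#' @param true_se_datasets ensemble size for the Monte-Carlo reference SE.
#' @param seed optional integer seed.
#' @return a data.frame with columns `T`, `true_se`, `boot_se`,
#'   `rejection_rate`.
#' @export
bootstrap_calibration <- function(scanning_times = c(300, 600, 1200, 2400),
                                  L = 10L, B_rep = 1000L,
                                  n_experiments = 1000L, tau = 2, r = 0.4,
                                  scheme = c("block", "independent"),
                                  alpha_level = 0.05,
                                  true_se_datasets = 5000L, seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  Lb <- if (scheme == "independent") 1L else as.integer(L)
  model <- hofc_model(n = 3, tau = tau, r = r, psi = 0,
                      innovation = skew_normal_innovation(0))
  zc <- stats::qnorm(1 - alpha_level / 2)
  rows <- lapply(scanning_times, function(T) {
    true_se <- stats::sd(simulate_estimates(model, T, true_se_datasets,
                                            "coskewness"))
    res <- vapply(seq_len(n_experiments), function(e) {
      x <- simulate_kernel(model, T, ceiling(20 * tau))
      xs <- x - rowMeans(x)
      xs <- xs / sqrt(rowSums(xs^2) / (T - 1))
      theta <- moment_kernel(xs, c(1, 2, 3))
      se <- stats::sd(coskew_boot_replicates(xs, Lb, B_rep))
      c(se = se, reject = abs(theta) / se > zc)
    }, c(1, 1))
    data.frame(T = T, true_se = true_se, boot_se = mean(res[1, ]),
               rejection_rate = mean(res[2, ]))
  })
  do.call(rbind, rows)
}

#' Fit an exponential autocorrelation time-scale
#'
#' Least-squares fit of `exp(-k/tau)` to an empirical autocorrelation
#' function over lags `k = 1..K`.  This is how the package's default
#' `tau = 2` was obtained from group-level BOLD autocorrelations.
#'
#' @param acf numeric vector of lag-1..K autocorrelations (lag 0 excluded).
#' @param lags integer lags matching `acf` (default `seq_along(acf)`).
#' @return the fitted `tau` (samples), with attribute `"sse"`; a warning
#'   flags an unstable fit (all mass at the boundary, e.g. white noise).
#' @export
fit_ar_timescale <- function(acf, lags = seq_along(acf)) {
  stopifnot(length(acf) == length(lags), length(acf) >= 2)
  if (all(acf <= 0))
    stop("cannot fit a positive decay time-scale: autocorrelations are all non-positive",
         call. = FALSE)
  sse <- function(tau) sum((acf - exp(-lags / tau))^2)
  opt <- stats::optimize(sse, interval = c(1e-3, 1e3))
  tau <- opt$minimum
  if (tau < 0.05)
    warning("fitted time-scale is at the lower boundary; autocorrelation is ",
            "indistinguishable from white noise", call. = FALSE)
  structure(tau, sse = opt$objective)
}
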