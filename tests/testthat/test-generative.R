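test_that("AR coefficient and innovation correlation follow the model algebra", {
  expect_equal(phi_from_tau(2), exp(-0.5), tolerance = 1e-12)
  expect_gt(phi_from_tau(1e8), 1 - 1e-7)  # tau -> Inf gives phi -> 1
  expect_error(phi_from_tau(0), "positive")
  expect_error(phi_from_tau(-3), "positive")
  expect_equal(rho_from_r(0.3, 0), 0.3)
  expect_equal(rho_from_r(1, 0.7), 1)
  expect_equal(rho_from_r(0.4, 1), -0.2)
})

test_that("positive-definiteness bounds match 1/4 (n=3) and 1/3 (n=4)", {
  expect_equal(sufficient_r_bound(3), 1 / 4)
  expect_equal(sufficient_r_bound(4), 1 / 3)
  # rho = -0.2 > -1/2: valid for n = 3
  expect_silent(hofc_model(n = 3, tau = 2, r = 0.4, psi = 1,
                           innovation = skew_normal_innovation(1)))
  # r below the bound at psi = 1 violates positive-definiteness
  expect_error(hofc_model(n = 3, tau = 2, r = 0.2, psi = 1,
                          innovation = skew_normal_innovation(1)),
               "positive-definite")
  expect_error(hofc_model(n = 4, tau = 2, r = 0.3, psi = 1,
                          innovation = student_t_innovation(6)),
               "positive-definite")
})

test_that("model constructor validates psi, phi and the innovation spec", {
  sn <- skew_normal_innovation(2)
  expect_error(hofc_model(n = 3, tau = 2, r = 0.4, psi = 1.2,
                          innovation = sn), "psi")
  expect_error(hofc_model(n = 3, r = 0.4, psi = 0.5, innovation = sn),
               "tau or phi")
  expect_error(hofc_model(n = 3, tau = 2, phi = 0.5, r = 0.4, psi = 0.5,
                          innovation = sn), "tau or phi")
  expect_error(hofc_model(n = 3, tau = 2, psi = 0.5, innovation = sn),
               "r or rho")
  expect_error(student_t_innovation(4), "nu >= 5")
})

test_that("skew-normal third cumulant: zero at delta 0, monotone, near 1 at the limit", {
  expect_equal(innovation_c3(skew_normal_innovation(0)), 0)
  a <- seq(0.5, 30, by = 0.5)
  c3 <- vapply(a, function(al) innovation_c3(skew_normal_innovation(al)), 1)
  expect_true(all(diff(c3) > 0))
  expect_equal(innovation_c3(skew_normal_innovation(1e8)), 0.995,
               tolerance = 0.005)
  expect_equal(innovation_c3(skew_normal_innovation(-3)),
               -innovation_c3(skew_normal_innovation(3)), tolerance = 1e-12)
})

test_that("t fourth cumulant is 6/(nu-4)", {
  expect_equal(innovation_c4(student_t_innovation(5)), 6)
  expect_equal(innovation_c4(student_t_innovation(10)), 1)
  expect_lt(innovation_c4(student_t_innovation(1e6)), 1e-5)
})

test_that("innovation samplers give mean 0, variance 1 and the stated cumulants", {
  set.seed(5)
  n <- 1e6
  u <- sample_innovation(skew_normal_innovation(3), n)
  expect_lt(abs(mean(u)), 4 / sqrt(n))
  expect_lt(abs(var(u) - 1), 4 * sqrt(2 / n))
  k3 <- mean((u - mean(u))^3)
  se3 <- sd((u - mean(u))^3) / sqrt(n)
  expect_lt(abs(k3 - innovation_c3(skew_normal_innovation(3))), 3 * se3)
  # delta = 0 reduces to the standard normal third cumulant
  u0 <- sample_innovation(skew_normal_innovation(0), n)
  expect_lt(abs(mean(u0^3)), 3 * sqrt(15 / n))
  ut <- sample_innovation(student_t_innovation(10), n)
  expect_lt(abs(var(ut) - 1), 0.01)
  k4 <- mean(ut^4) - 3 * var(ut)^2
  se4 <- sd(ut^4) / sqrt(n)
  expect_lt(abs(k4 - innovation_c4(student_t_innovation(10))), 3 * se4)
})

test_that("true correlation round-trips through rho_from_r and is recovered by simulation", {
  for (psi in c(0, 0.5, 1)) {
    m <- hofc_model(n = 3, tau = 2, r = 0.4, psi = psi,
                    innovation = skew_normal_innovation(2))
    expect_equal(true_correlation(m), 0.4, tolerance = 1e-12)
  }
  m0 <- hofc_model(n = 3, tau = 2, rho = 0.3, psi = 0,
                   innovation = skew_normal_innovation(0))
  expect_equal(true_correlation(m0), 0.3, tolerance = 1e-12)
  m <- hofc_model(n = 3, tau = 2, r = 0.4, psi = 0.5,
                  innovation = skew_normal_innovation(2))
  x <- standardize(simulate(m, T = 2e5, seed = 8))
  expect_lt(abs(correlation2(x, 1, 2)$value - 0.4), 0.02)
})

test_that("simulated series have the exp(-k/tau) autocorrelation", {
  m <- hofc_model(n = 3, tau = 2, r = 0.4, psi = 0.5,
                  innovation = skew_normal_innovation(2))
  x <- simulate(m, T = 1e5, seed = 9)
  a <- acf(x$data[1, ], lag.max = 5, plot = FALSE)$acf[-1]
  expect_equal(a, exp(-(1:5) / 2), tolerance = 0.03, ignore_attr = TRUE)
})

test_that("simulation is reproducible from the seed and respects burn-in", {
  m <- hofc_model(n = 3, tau = 2, r = 0.4, psi = 1,
                  innovation = skew_normal_innovation(3))
  x1 <- simulate(m, T = 500, seed = 42)
  x2 <- simulate(m, T = 500, seed = 42)
  expect_identical(x1$data, x2$data)
  expect_identical(dim(x1$data), c(3L, 500L))
  xs <- simulate(m, nsim = 3, T = 100, seed = 1)
  expect_length(xs, 3)
  expect_false(identical(xs[[1]]$data, xs[[2]]$data))
})

test_that("Gaussian-limit simulation has vanishing higher-order connectivity", {
  m <- hofc_model(n = 4, tau = 2, r = 0.4, psi = 0,
                  innovation = student_t_innovation(5))
  x <- standardize(simulate(m, T = 50000, seed = 10))
  # autocorrelated data: null scale a few times the iid sqrt(6/T)
  expect_lt(abs(coskewness(x, 1, 2, 3)$value), 6 * sqrt(6 / 50000))
  expect_lt(abs(cokurtosis(x, 1, 2, 3, 4)$value), 6 * sqrt(24 / 50000))
})

test_that("long simulations recover every closed form within Monte-Carlo error", {
  # ensemble of medium-length series; compare ensemble mean estimate with
  # the closed form at 3 standard errors of the ensemble mean
  recover <- function(model, measure, K = 32, T = 30000) {
    est <- vapply(seq_len(K), function(k) {
      x <- standardize(simulate(model, T = T))
      switch(measure,
        coskewness = coskewness(x, 1, 2, 3)$value,
        cokurtosis = cokurtosis(x, 1, 2, 3, 4)$value,
        edge_raw = edge_connectivity_raw(x, c(1, 2), c(3, 4))$value,
        edge_corrected =
          edge_connectivity_corrected(x, c(1, 2), c(3, 4))$value)
    }, 1)
    truth <- switch(measure,
      coskewness = true_coskewness(model),
      cokurtosis = true_cokurtosis(model),
      edge_raw = unname(true_edge_connectivity(model)["raw"]),
      edge_corrected = unname(true_edge_connectivity(model)["corrected"]))
    list(err = abs(mean(est) - truth), lim = 3 * sd(est) / sqrt(K))
  }
  set.seed(123)
  m3 <- hofc_model(n = 3, tau = 2, r = 0.4, psi = 1,
                   innovation = skew_normal_innovation(3))
  r <- recover(m3, "coskewness")
  expect_lt(r$err, r$lim)
  # nu = 12 keeps the fourth-moment estimator's own variance finite
  m4 <- hofc_model(n = 4, tau = 2, r = 0.4, psi = 1,
                   innovation = student_t_innovation(12))
  for (meas in c("cokurtosis", "edge_raw", "edge_corrected")) {
    r <- recover(m4, meas)
    expect_lt(r$err, r$lim)
  }
})

test_that("coskewness and cokurtosis are independent of the pairwise correlation", {
  # closed forms: rho does not enter
  gt <- lapply(c(0.35, 0.4, 0.5), function(r)
    ground_truth(hofc_model(n = 4, tau = 2, r = r, psi = 1,
                            innovation = student_t_innovation(8))))
  expect_equal(gt[[1]]$cokurtosis, gt[[2]]$cokurtosis, tolerance = 1e-12)
  expect_equal(gt[[2]]$cokurtosis, gt[[3]]$cokurtosis, tolerance = 1e-12)
  # the edge connectivity, in contrast, depends on rho
  expect_gt(abs(gt[[1]]$edge_corrected - gt[[3]]$edge_corrected), 1e-4)
  # and simulated sample coskewness at different r is statistically
  # indistinguishable
  set.seed(77)
  est <- lapply(c(0.35, 0.5), function(r) {
    m <- hofc_model(n = 3, tau = 2, r = r, psi = 1,
                    innovation = skew_normal_innovation(3))
    vapply(1:24, function(k)
      coskewness(standardize(simulate(m, T = 10000)), 1, 2, 3)$value, 1)
  })
  pooled_se <- sqrt(var(est[[1]]) / 24 + var(est[[2]]) / 24)
  expect_lt(abs(mean(est[[1]]) - mean(est[[2]])), 3 * pooled_se)
})

test_that("ground-truth monotonicity: coskewness rises with psi, cokurtosis falls with nu", {
  cs <- vapply(seq(0.1, 1, by = 0.1), function(psi)
    true_coskewness(hofc_model(n = 3, tau = 2, r = 0.4, psi = psi,
                               innovation = skew_normal_innovation(3))), 1)
  expect_true(all(diff(cs) > 0))
  ck <- vapply(5:15, function(nu)
    true_cokurtosis(hofc_model(n = 4, tau = 2, r = 0.4, psi = 1,
                               innovation = student_t_innovation(nu))), 1)
  expect_true(all(diff(ck) < 0))
})

test_that("edge connectivity closed form: corrected part vanishes without heavy tails", {
  m_inf <- hofc_model(n = 4, tau = 2, r = 0.4, psi = 1,
                      innovation = student_t_innovation(1e9))
  expect_lt(abs(ground_truth(m_inf)$edge_corrected), 1e-8)
  m_g <- hofc_model(n = 4, tau = 2, r = 0.4, psi = 0,
                    innovation = student_t_innovation(5))
  expect_equal(ground_truth(m_g)$edge_corrected, 0, tolerance = 1e-12)
  expect_equal(ground_truth(m_g)$cokurtosis, 0, tolerance = 1e-12)
  expect_equal(ground_truth(m_g)$coskewness, 0, tolerance = 1e-12)
})
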