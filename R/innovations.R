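#' Skew-normal innovation law
#'
#' Zero-mean, unit-variance skew-normal innovations for the generative
#' model.  The shape parameter `alpha` controls asymmetry through
#' `delta = alpha / sqrt(1 + alpha^2)`; `alpha = 0` is the standard normal.
#' Positive `alpha` makes simultaneous extreme activations more likely than
#' deactivations; negative values (left skew) are allowed and simply flip
#' the sign of the third cumulant.
#'
#' @param alpha real shape parameter.
#' @return an `innovation_spec` of subtype `skew_normal`, carrying the
#'   derived `delta` and the location/scale (`mu`, `kappa`) that make the
#'   law zero-mean and unit-variance.
#' @export
skew_normal_innovation <- function(alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  delta <- alpha / sqrt(1 + alpha^2)
  kappa <- sqrt(pi / (pi - 2 * delta^2))
  structure(list(family = "skew_normal", alpha = alpha, delta = delta,
                 kappa = kappa, mu = -kappa * delta * sqrt(2 / pi)),
            class = c("skew_normal_spec", "innovation_spec"))
}

#' Student-t innovation law
#'
#' Unit-variance scaled t innovations `U = sqrt((nu-2)/nu) * t_nu` for the
#' generative model.  The fourth cumulant `6/(nu-4)` exists only for
#' `nu >= 5`, which is therefore required.
#'
#' @param nu integer degrees of freedom, at least 5.
#' @return an `innovation_spec` of subtype `student_t`.
#' @export
student_t_innovation <- function(nu) {
  stopifnot(is.numeric(nu), length(nu) == 1L)
  if (nu < 5) stop("student_t innovation requires nu >= 5 (finite fourth cumulant)",
                   call. = FALSE)
  structure(list(family = "student_t", nu = nu),
            class = c("student_t_spec", "innovation_spec"))
}

#' @export
print.innovation_spec <- function(x, ...) {
  if (x$family == "skew_normal")
    cat(sprintf("skew-normal innovation: alpha = %g (delta = %.4f, c3 = %.4f)\n",
                x$alpha, x$delta, innovation_c3(x)))
  else
    cat(sprintf("student-t innovation: nu = %g (c4 = %.4f)\n",
                x$nu, innovation_c4(x)))
  invisible(x)
}

#' Third and fourth cumulants of an innovation law
#'
#' For the skew-normal law the third cumulant is
#' `((4-pi)/2) * (2 delta^2/pi)^{3/2} / (1 - 2 delta^2/pi)^{3/2}` (signed
#' like `delta`) and grows from 0 towards ~0.995 as `|delta| -> 1`; its
#' fourth cumulant is `2(pi-3) (2 delta^2/pi)^2 / (1 - 2 delta^2/pi)^2`.
#' The scaled t law is symmetric (third cumulant 0) with fourth cumulant
#' `6/(nu-4)`.
#'
#' @param spec an `innovation_spec`.
#' @return numeric scalar cumulant of the unit-variance law.
#' @export
innovation_c3 <- function(spec) UseMethod("innovation_c3")

#' @export
innovation_c3.skew_normal_spec <- function(spec) {
  b <- 2 * spec$delta^2 / pi
  sign(spec$delta) * (4 - pi) / 2 * b^1.5 / (1 - b)^1.5
}

#' @export
innovation_c3.student_t_spec <- function(spec) 0

#' @rdname innovation_c3
#' @export
innovation_c4 <- function(spec) UseMethod("innovation_c4")

#' @export
innovation_c4.skew_normal_spec <- function(spec) {
  b <- 2 * spec$delta^2 / pi
  2 * (pi - 3) * b^2 / (1 - b)^2
}

#' @export
innovation_c4.student_t_spec <- function(spec) 6 / (spec$nu - 4)

#' Draw innovations
#'
#' Samples the zero-mean unit-variance innovation law.  The skew-normal uses
#' the half-normal stochastic representation
#' `U = -sigma_U delta sqrt(2/pi) + sigma_U (delta |Z1| + sqrt(1-delta^2) Z2)`
#' with independent standard normals `Z1`, `Z2` and
#' `sigma_U = sqrt(pi/(pi - 2 delta^2))`; the t law scales `t_nu` draws by
#' `sqrt((nu-2)/nu)`.  Uses R's global RNG stream.
#'
#' @param spec an `innovation_spec`.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
sample_innovation <- function(spec, n) UseMethod("sample_innovation")

#' @export
sample_innovation.skew_normal_spec <- function(spec, n) {
  d <- spec$delta
  su <- sqrt(pi / (pi - 2 * d^2))
  -su * d * sqrt(2 / pi) +
    su * (d * abs(stats::rnorm(n)) + sqrt(1 - d^2) * stats::rnorm(n))
}

#' @export
sample_innovation.student_t_spec <- function(spec, n) {
  sqrt((spec$nu - 2) / spec$nu) * stats::rt(n, df = spec$nu)
}
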