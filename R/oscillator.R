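# Viscoelastic damped-oscillator model of wound-closure kinetics.
#
# Neurons are treated as beads bound to springs in a viscous medium; with
# mass normalised to 1 the displacement obeys x'' + nu x' + k x = 0, whose
# underdamped solution is
#
#   x(t) = a * exp(-nu t / 2) * cos(sqrt(k - nu^2/4) * t - phi).
#
# The same closed form, with a free baseline offset, is fitted directly to
# fluorescence closure curves: one half-period of the cosine is a smooth
# monotone S-shaped segment matching the observed monotonous displacement.

#' Displacement of the underdamped viscoelastic oscillator
#'
#' @param t Time(s) in minutes, `t >= 0`.
#' @param a Amplitude (curve units; sign free).
#' @param nu Damping rate (1/min), `nu >= 0`.
#' @param k Stiffness rate (1/min^2, mass normalised to 1); must satisfy
#'   `k > nu^2/4` (underdamped regime).
#' @param phi Phase (radians).
#' @return Displacement at `t`, same length as `t`.
#' @export
oscillator_displacement <- function(t, a, nu, k, phi) {
  if (any(t < 0)) stop("t must be non-negative")
  if (k <= nu^2 / 4)
    stop("overdamped parameters: need k > nu^2/4 (got k = ", k,
         ", nu^2/4 = ", nu^2 / 4, ")")
  omega <- sqrt(k - nu^2 / 4)
  a * exp(-nu * t / 2) * cos(omega * t - phi)
}

#' Angular frequency of the underdamped oscillator
#'
#' @inheritParams oscillator_displacement
#' @return `sqrt(k - nu^2/4)` in radians per minute.
#' @export
oscillator_omega <- function(nu, k) {
  if (k <= nu^2 / 4) stop("overdamped parameters: need k > nu^2/4")
  sqrt(k - nu^2 / 4)
}

# Fold the (a, phi) sign ambiguity: (a, phi) and (-a, phi + pi) generate
# the same trajectory. Canonical form keeps phi in (-pi/2, pi/2].
canonicalise_phase <- function(a, phi) {
  phi <- atan2(sin(phi), cos(phi))       # wrap to (-pi, pi]
  if (phi > pi / 2)  { phi <- phi - pi; a <- -a }
  if (phi <= -pi / 2) { phi <- phi + pi; a <- -a }
  list(a = a, phi = phi)
}

#' Fit the damped-oscillator model to a kinetic curve
#'
#' Nonlinear least squares of
#' `value(t) ~ offset + oscillator_displacement(t - t[1], a, nu, k, phi)`
#' using Levenberg-Marquardt with a multi-start over a phase grid (the
#' cosine phase creates local minima). Internally the model is
#' parameterised by the angular frequency `omega` so the underdamped
#' constraint `k > nu^2/4` holds by construction; `k = omega^2 + nu^2/4`
#' is reported.
#'
#' @param curve A [kinetic_curve()].
#' @param window Optional numeric length-2 time window (minutes) selecting
#'   the fitted points; default uses the whole curve.
#' @param n_phase_starts Number of equally spaced phase starting values.
#' @return An object of class `oscillator_fit` with elements `a`, `nu`,
#'   `k`, `phi`, `offset`, `omega`, `half_period`, `r2`, `fitted`,
#'   `window`, and `exceeds_half_period` (TRUE when the fitted window is
#'   longer than half a period, i.e. the monotone-segment assumption is
#'   violated, which triggers a warning).
#' @export
fit_oscillator <- function(curve, window = NULL, n_phase_starts = 12L) {
  stopifnot(inherits(curve, "kinetic_curve"))
  t <- curve$t; v <- curve$value
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; v <- v[keep]
  }
  if (length(t) < 6) stop("need at least 6 points in the fit window")
  if (diff(range(v)) == 0) stop("cannot fit a constant curve")
  ts <- t - t[1]

  span <- diff(range(ts))
  amp0 <- diff(range(v)) / 2
  off0 <- mean(range(v))
  # half period ~ observation span for a monotone segment
  omega0 <- pi / span
  phis <- seq(0, 2 * pi, length.out = n_phase_starts + 1L)[-(n_phase_starts + 1L)]

  resid_fn <- function(p) {
    om <- exp(p[["log_omega"]])
    nu <- exp(p[["log_nu"]])
    v - (p[["offset"]] + p[["a"]] * exp(-nu * ts / 2) *
           cos(om * ts - p[["phi"]]))
  }

  best <- NULL
  for (phi0 in phis) for (a0 in c(amp0, -amp0)) {
    start <- c(a = a0, log_nu = log(1 / span), log_omega = log(omega0),
               phi = phi0, offset = off0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cost <- sum(fit$fvec^2)
    if (is.null(best) || cost < best$cost) best <- list(fit = fit, cost = cost)
  }
  if (is.null(best))
    stop("oscillator fit failed to converge from any phase start; ",
         "residual range ", paste(signif(range(v), 4), collapse = " .. "))

  p <- best$fit$par
  nu <- exp(p[["log_nu"]]); omega <- exp(p[["log_omega"]])
  cf <- canonicalise_phase(p[["a"]], p[["phi"]])
  k <- omega^2 + nu^2 / 4
  fitted <- p[["offset"]] + oscillator_displacement(ts, cf$a, nu, k, cf$phi)
  ss_res <- sum((v - fitted)^2)
  ss_tot <- sum((v - mean(v))^2)
  half_period <- pi / omega
  exceeds <- span > half_period * (1 + 1e-9)
  if (exceeds)
    warning("fitted window (", signif(span, 4),
            " min) exceeds the model half-period (", signif(half_period, 4),
            " min); the monotone-segment assumption may be violated")
  structure(list(a = cf$a, nu = nu, k = k, phi = cf$phi,
                 offset = p[["offset"]], omega = omega,
                 half_period = half_period,
                 r2 = 1 - ss_res / ss_tot,
                 fitted = fitted, t = t, value = v,
                 window = range(t), exceeds_half_period = exceeds),
            class = "oscillator_fit")
}

#' @export
print.oscillator_fit <- function(x, ...) {
  cat("<oscillator_fit>\n")
  cat(sprintf("  a = %.6g, nu = %.6g /min, k = %.6g /min^2, phi = %.4f rad\n",
              x$a, x$nu, x$k, x$phi))
  cat(sprintf("  offset = %.6g, omega = %.6g rad/min, half period = %.4g min\n",
              x$offset, x$omega, x$half_period))
  cat(sprintf("  R^2 = %.6f over window [%g, %g] min\n",
              x$r2, x$window[1], x$window[2]))
  invisible(x)
}
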