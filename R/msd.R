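# Mean-squared displacement analysis of cell tracks.
#
# Per-track MSD is averaged over all overlapping lag pairs, then averaged
# across tracks without weighting (the convention of the DiPer tracking
# workflow). Anomalous-diffusion exponents come from an ordinary
# least-squares fit of log(MSD) against log(lag); with the 2D convention
# MSD = 4 D tau^alpha the prefactor D is exp(intercept)/4.

#' Mean-squared displacement of a track set
#'
#' Computes the 2D (x, y) MSD per track over all overlapping pairs of
#' frames separated by each lag, averages across tracks at each lag, and
#' fits a power law over the positive lags.
#'
#' @param ts A [track_set()] whose tracks are uniformly sampled (equal
#'   frame interval within each track, shared across tracks).
#' @param max_lag_fraction Largest lag used, as a fraction of each track's
#'   span in frames (default 0.5; long lags average few pairs and are
#'   noisy).
#' @param fit_range Optional numeric length-2 lag window (minutes) for the
#'   power-law fit; default all computed lags.
#' @return An object of class `msd_result` with `lags` (minutes; lag 0
#'   included with MSD 0), `msd` (um^2), `n_tracks`, and, when the fit is
#'   possible, `alpha`, `D_eff`, `r2`, `fit_range`. For all-stationary
#'   input the MSD is identically zero and the exponent fit is refused
#'   (`alpha = NA`).
#' @export
msd <- function(ts, max_lag_fraction = 0.5, fit_range = NULL) {
  stopifnot(inherits(ts, "track_set"))
  trs <- Filter(function(tr) n_samples(tr) >= 3, ts$tracks)
  if (!length(trs)) stop("need at least one track with >= 3 samples")
  if (max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop("max_lag_fraction must lie in (0, 1]")

  dts <- unlist(lapply(trs, function(tr) diff(tr$t)))
  dt0 <- dts[1]
  if (any(abs(dts - dt0) > 1e-9 * max(dt0, 1)))
    stop("non-uniform sampling interval; MSD requires a fixed frame interval")

  max_lag <- max(vapply(trs, function(tr)
    floor(max_lag_fraction * (n_samples(tr) - 1)), numeric(1)))
  if (max_lag < 1) stop("tracks too short for the requested lag fraction")

  acc <- matrix(NA_real_, nrow = length(trs), ncol = max_lag)
  for (i in seq_along(trs)) {
    tr <- trs[[i]]
    n <- n_samples(tr)
    top <- floor(max_lag_fraction * (n - 1))
    for (m in seq_len(min(top, max_lag))) {
      dx <- tr$x[(m + 1):n] - tr$x[1:(n - m)]
      dy <- tr$y[(m + 1):n] - tr$y[1:(n - m)]
      acc[i, m] <- mean(dx^2 + dy^2)
    }
  }
  msd_mean <- colMeans(acc, na.rm = TRUE)
  lags <- dt0 * seq_len(max_lag)

  res <- structure(list(lags = c(0, lags), msd = c(0, msd_mean),
                        n_tracks = length(trs),
                        alpha = NA_real_, D_eff = NA_real_, r2 = NA_real_,
                        fit_range = NULL),
                   class = "msd_result")
  if (all(msd_mean == 0)) return(res)  # all-stationary: refuse the fit
  fit <- fit_msd_powerlaw(res, fit_range)
  res$alpha <- fit$alpha; res$D_eff <- fit$D_eff; res$r2 <- fit$r2
  res$fit_range <- fit$fit_range
  res
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("<msd_result> %d lags from %d track(s)\n",
              length(x$lags), x$n_tracks))
  if (!is.na(x$alpha))
    cat(sprintf("  alpha = %.4f, D_eff = %.4g um^2/min^alpha, r2 = %.4f\n",
                x$alpha, x$D_eff, x$r2))
  invisible(x)
}

#' Power-law fit of an MSD curve
#'
#' Ordinary least squares of `log(msd)` on `log(lag)` over the requested
#' lag window; the anomalous exponent is the slope and the effective
#' diffusion prefactor uses the 2D convention `MSD = 4 D tau^alpha`.
#'
#' @param msd_result An `msd_result` (or any list with `lags`/`msd`).
#' @param fit_range Optional numeric length-2 lag window in minutes;
#'   default all positive lags.
#' @return List with `alpha`, `D_eff`, `r2`, `fit_range`.
#' @export
fit_msd_powerlaw <- function(msd_result, fit_range = NULL) {
  lags <- msd_result$lags
  vals <- msd_result$msd
  pos <- lags > 0
  lags <- lags[pos]; vals <- vals[pos]
  if (!is.null(fit_range)) {
    keep <- lags >= fit_range[1] & lags <= fit_range[2]
    lags <- lags[keep]; vals <- vals[keep]
  }
  if (length(lags) < 3) stop("need at least 3 positive lags in the fit range")
  if (any(vals <= 0))
    stop("MSD values must be positive in the fit range (log undefined)")
  lt <- log(lags); lm_ <- stats::lm.fit(cbind(1, lt), log(vals))
  coefs <- lm_$coefficients
  r2 <- 1 - sum(lm_$residuals^2) / sum((log(vals) - mean(log(vals)))^2)
  if (!is.finite(r2)) r2 <- 1  # zero-variance response: exact fit
  list(alpha = unname(coefs[2]), D_eff = unname(exp(coefs[1]) / 4),
       r2 = r2, fit_range = range(lags))
}
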