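# Discrete Frechet distance between trajectories and its randomised null.
#
# The discrete Frechet distance is the minimum over monotone couplings of
# the maximum pointwise Euclidean distance — the classic dynamic
# programming recurrence of Eiter & Mannila:
#   dp[i, j] = max(d(P_i, Q_j), min(dp[i-1, j], dp[i-1, j-1], dp[i, j-1]))

#' Discrete Frechet distance between two point sequences
#'
#' @param P,Q Two-column matrices of points (x, y), or [track()] objects
#'   (their 2D positions are used).
#' @return Non-negative distance in micrometres; 0 iff the two sequences
#'   are identical.
#' @export
discrete_frechet <- function(P, Q) {
  P <- frechet_coords(P); Q <- frechet_coords(Q)
  n <- nrow(P); m <- nrow(Q)
  if (!n || !m) stop("point sequences must be non-empty")
  # pairwise distances, n x m
  d <- sqrt(outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2)
  dp <- matrix(0, n, m)
  dp[1, 1] <- d[1, 1]
  if (m > 1) for (j in 2:m) dp[1, j] <- max(dp[1, j - 1], d[1, j])
  if (n > 1) for (i in 2:n) {
    dp[i, 1] <- max(dp[i - 1, 1], d[i, 1])
    if (m > 1) for (j in 2:m) {
      dp[i, j] <- max(min(dp[i - 1, j], dp[i - 1, j - 1], dp[i, j - 1]),
                      d[i, j])
    }
  }
  dp[n, m]
}

frechet_coords <- function(x) {
  if (inherits(x, "track")) return(track_xy(x))
  x <- as.matrix(x)
  if (ncol(x) != 2) stop("point sequence must have 2 columns (x, y)")
  storage.mode(x) <- "double"
  x
}

#' Frechet similarity test against direction-randomised trajectories
#'
#' Compares the observed discrete Frechet distance between a microglial
#' track and a neuronal track with a null distribution obtained by
#' randomising the neuronal track: starting from the same first point,
#' step magnitudes are resampled with replacement from the observed steps
#' and step directions are drawn uniformly. This preserves the scale of
#' motion while destroying directional correlation, the property under
#' test. The empirical p-value uses the add-one correction
#' `(1 + #{null <= observed}) / (n_perm + 1)`.
#'
#' @param microglia_track,neuron_track [track()] objects (>= 2 samples).
#' @param n_perm Number of randomised trajectories (>= 1).
#' @param seed Integer seed for the randomisation.
#' @return An object of class `frechet_result` with `distance`,
#'   `null_distances`, `empirical_p`.
#' @export
frechet_null <- function(microglia_track, neuron_track, n_perm = 200L,
                         seed = 1L) {
  stopifnot(inherits(microglia_track, "track"),
            inherits(neuron_track, "track"))
  if (n_samples(microglia_track) < 2 || n_samples(neuron_track) < 2)
    stop("both tracks need >= 2 samples")
  if (n_perm < 1) stop("n_perm must be at least 1")
  M <- track_xy(microglia_track)
  N <- track_xy(neuron_track)
  obs <- discrete_frechet(M, N)
  steps <- N[-1, , drop = FALSE] - N[-nrow(N), , drop = FALSE]
  mags <- sqrt(rowSums(steps^2))
  ns <- length(mags)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  null_d <- vapply(seq_len(n_perm), function(i) {
    m <- sample(mags, ns, replace = TRUE)
    th <- stats::runif(ns, 0, 2 * pi)
    rx <- cumsum(c(N[1, 1], m * cos(th)))
    ry <- cumsum(c(N[1, 2], m * sin(th)))
    discrete_frechet(M, cbind(rx, ry))
  }, numeric(1))
  structure(list(distance = obs, null_distances = null_d,
                 empirical_p = (1 + sum(null_d <= obs)) / (n_perm + 1)),
            class = "frechet_result")
}

#' @export
print.frechet_result <- function(x, ...) {
  cat(sprintf(paste0("<frechet_result> observed %.3f um; null median %.3f um ",
                     "(n = %d); empirical p = %.4f\n"),
              x$distance, stats::median(x$null_distances),
              length(x$null_distances), x$empirical_p))
  invisible(x)
}
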