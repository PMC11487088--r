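# Independent oracles and fixture builders used across the test files.

# Exhaustive discrete Frechet distance: recursion over all monotone
# couplings with memoisation. Independent of the package's DP routine.
brute_frechet <- function(P, Q) {
  n <- nrow(P); m <- nrow(Q)
  d <- sqrt(outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    r <- if (i == 1 && j == 1) d[1, 1]
    else if (i == 1) max(rec(1, j - 1), d[1, j])
    else if (j == 1) max(rec(i - 1, 1), d[i, 1])
    else max(min(rec(i - 1, j), rec(i - 1, j - 1), rec(i, j - 1)), d[i, j])
    memo[i, j] <<- r
    r
  }
  rec(n, m)
}

# Random seeded track set of plain Gaussian random walks.
random_walk_tracks <- function(n_tracks, n_steps, step_sd, dt = 1,
                               seed = 1) {
  set.seed(seed)
  track_set(lapply(seq_len(n_tracks), function(i) {
    track(sprintf("rw%04d", i), t = (0:n_steps) * dt,
          x = cumsum(c(0, rnorm(n_steps, 0, step_sd))),
          y = cumsum(c(0, rnorm(n_steps, 0, step_sd))))
  }), frame_interval = dt)
}

# Noisy radial tracks aimed at a planted convergence point inside the
# default geometry; used by the convergence-recovery checks.
radial_tracks_toward <- function(target, n_tracks = 20, noise = 1,
                                 seed = 1, geometry = make_geometry()) {
  set.seed(seed)
  starts <- NULL
  while (is.null(starts) || nrow(starts) < n_tracks) {
    th <- runif(n_tracks * 3, 0, pi)
    rr <- runif(n_tracks * 3, 0.85, 0.95)
    cand <- cbind(geometry$tectum_a * rr * cos(th),
                  geometry$tectum_b * rr * sin(th))
    keep <- sqrt((cand[, 1] - target[1])^2 + (cand[, 2] - target[2])^2) > 20
    starts <- cand[keep, , drop = FALSE]
  }
  starts <- starts[seq_len(n_tracks), , drop = FALSE]
  track_set(lapply(seq_len(n_tracks), function(i) {
    s <- starts[i, ]
    u <- (target - s) / sqrt(sum((target - s)^2))
    # advance 40% of the way with positional noise
    pos <- rbind(s, s + u * 0.4 * sqrt(sum((target - s)^2)))
    pos <- pos + matrix(rnorm(4, 0, noise), 2, 2)
    track(sprintf("rad%02d", i), t = c(0, 60), x = pos[, 1], y = pos[, 2])
  }), frame_interval = 60)
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
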