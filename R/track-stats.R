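# Per-track summary statistics, rostrocaudal linearisation, and
# displacement-field convergence analysis.

#' Summary statistics of a single track
#'
#' @param tr A [track()] with at least 2 samples.
#' @return List with `net_displacement` (um, 2D), `path_length` (um, 2D),
#'   `straightness` (net/path in `[0, 1]`, defined as 0 for a zero-length
#'   path), and `z_displacement` (um; signed net z change, only for 3D
#'   tracks — requesting it implicitly errors on 2D tracks via `NULL`).
#' @export
track_summary <- function(tr) {
  stopifnot(inherits(tr, "track"))
  if (n_samples(tr) < 2)
    stop("track '", tr$track_id, "' needs >= 2 samples for displacement statistics")
  xy <- track_xy(tr)
  steps <- sqrt(rowSums((xy[-1, , drop = FALSE] -
                           xy[-nrow(xy), , drop = FALSE])^2))
  path <- sum(steps)
  net <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  list(net_displacement = net,
       path_length = path,
       straightness = if (path > 0) net / path else 0,
       z_displacement = if (!is.null(tr$z))
         tr$z[length(tr$z)] - tr$z[1] else NULL)
}

#' Net z displacement of a 3D track
#'
#' @param tr A 3D [track()].
#' @return Signed z displacement in micrometres.
#' @export
z_displacement <- function(tr) {
  stopifnot(inherits(tr, "track"))
  if (is.null(tr$z))
    stop("track '", tr$track_id,
         "' is 2D; z displacement is undefined (not zero)")
  tr$z[length(tr$z)] - tr$z[1]
}

#' Linearise a track against the rostrocaudal curve
#'
#' Projects the track start perpendicularly onto the curved rostrocaudal
#' polyline and decomposes the net planar displacement onto the local
#' tangent/normal frame at the projection (normal = tangent rotated +90
#' degrees counter-clockwise).
#'
#' @param tr A [track()] with >= 2 samples.
#' @param curve Polyline matrix (x, y) with >= 2 vertices (um).
#' @return List with `s0` (arc length of the projected start, um),
#'   `lateral0` (signed normal offset of the start, um), `d_tangential`
#'   and `d_normal` (net displacement components, um).
#' @export
linearise <- function(tr, curve) {
  stopifnot(inherits(tr, "track"))
  if (n_samples(tr) < 2) stop("track needs >= 2 samples")
  start <- c(tr$x[1], tr$y[1])
  end <- c(tr$x[n_samples(tr)], tr$y[n_samples(tr)])
  pr <- project_on_polyline(start, curve)
  tangent <- pr$tangent
  normal <- c(-tangent[2], tangent[1])  # +90 deg CCW
  net <- end - start
  list(s0 = pr$s,
       lateral0 = sum((start - pr$point) * normal),
       d_tangential = sum(net * tangent),
       d_normal = sum(net * normal))
}

#' Displacement field of a track set
#'
#' One displacement vector per track, anchored at the track start.
#'
#' @param ts A [track_set()]; tracks with fewer than 2 samples are
#'   rejected.
#' @return Data frame with columns `track_id`, `x0`, `y0` (anchor, um),
#'   `dx`, `dy` (end minus start, um) and `zero` (flag for zero vectors,
#'   which are retained).
#' @export
displacement_field <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  rows <- lapply(ts$tracks, function(tr) {
    if (n_samples(tr) < 2)
      stop("track '", tr$track_id, "' has fewer than 2 samples")
    n <- n_samples(tr)
    data.frame(track_id = tr$track_id, x0 = tr$x[1], y0 = tr$y[1],
               dx = tr$x[n] - tr$x[1], dy = tr$y[n] - tr$y[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$zero <- out$dx == 0 & out$dy == 0
  out
}

#' Convergence point of a displacement field
#'
#' Extrapolates every displacement vector as a forward ray and intersects
#' all ray pairs. Intersections are kept when they lie forward along both
#' rays, inside the tectum outline, and come from a pair whose angular
#' separation is at least `min_angle_deg` (near-parallel pairs produce
#' unstable intersections). The centroid of the kept intersections
#' estimates the origin of the tissue contraction; it is also reported in
#' normalised polar coordinates via [normalise_polar()].
#'
#' @param field Data frame from [displacement_field()].
#' @param geometry A `tectum_geometry` supplying the outline, origin and
#'   rostral axis.
#' @param min_angle_deg Minimum angular separation between paired rays.
#' @return An object of class `convergence_result` with `intersections`
#'   (matrix), `centroid`, `r_norm`, `theta_deg`, `n_pairs_used`, and
#'   `defined` (FALSE when no valid intersection exists — not an error).
#' @export
convergence <- function(field, geometry, min_angle_deg = 10) {
  stopifnot(is.data.frame(field), inherits(geometry, "tectum_geometry"))
  f <- field[!field$zero, , drop = FALSE]
  if (nrow(f) < 2) stop("need at least 2 non-zero displacement vectors")
  P <- as.matrix(f[, c("x0", "y0")])
  D <- as.matrix(f[, c("dx", "dy")])
  Dn <- D / sqrt(rowSums(D^2))
  min_cos <- cos(min_angle_deg * pi / 180)
  pts <- list()
  n <- nrow(f)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cosang <- abs(sum(Dn[i, ] * Dn[j, ]))
    if (cosang > min_cos) next
    denom <- cross2(Dn[i, ], Dn[j, ])
    if (abs(denom) < 1e-14) next
    dp <- P[j, ] - P[i, ]
    ti <- cross2(dp, Dn[j, ]) / denom
    tj <- cross2(dp, Dn[i, ]) / denom
    if (ti <= 0 || tj <= 0) next  # behind one of the rays
    q <- P[i, ] + ti * Dn[i, ]
    if (!points_in_polygon(q[1], q[2], geometry$tectum_outline)) next
    pts[[length(pts) + 1L]] <- q
  }
  if (!length(pts)) {
    return(structure(list(intersections = matrix(numeric(0), 0, 2),
                          centroid = c(NA_real_, NA_real_),
                          r_norm = NA_real_, theta_deg = NA_real_,
                          n_pairs_used = 0L, defined = FALSE),
                     class = "convergence_result"))
  }
  ints <- do.call(rbind, pts)
  centroid <- colMeans(ints)
  pol <- normalise_polar(centroid, geometry)
  structure(list(intersections = ints, centroid = centroid,
                 r_norm = pol$r_norm, theta_deg = pol$theta_deg,
                 n_pairs_used = nrow(ints), defined = TRUE),
            class = "convergence_result")
}

#' @export
print.convergence_result <- function(x, ...) {
  if (!x$defined) {
    cat("<convergence_result> undefined (no valid ray intersections)\n")
  } else {
    cat(sprintf(paste0("<convergence_result> centroid (%.2f, %.2f) um from ",
                       "%d intersection(s)\n  polar: r_norm = %.3f, ",
                       "theta = %.1f deg\n"),
                x$centroid[1], x$centroid[2], x$n_pairs_used,
                x$r_norm, x$theta_deg))
  }
  invisible(x)
}
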