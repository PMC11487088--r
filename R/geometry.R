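# Planar geometry primitives shared by all modules.
#
# Conventions: coordinates are physical micrometres, origin at the image
# upper-left, y increasing downward (image convention). Polygons are
# two-column matrices (x, y) without a repeated closing vertex.

#' Signed polygon area (shoelace formula)
#'
#' @param poly Two-column numeric matrix of vertices (x, y), open ring.
#' @return Signed area in square micrometres; positive for counter-clockwise
#'   vertex order in a y-up frame.
#' @export
polygon_area_signed <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Absolute polygon area
#'
#' @inheritParams polygon_area_signed
#' @return Area in square micrometres (non-negative).
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' Polygon centroid
#'
#' Area-weighted centroid of a simple polygon.
#'
#' @inheritParams polygon_area_signed
#' @return Numeric length-2 vector (x, y).
#' @export
polygon_centroid <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || nrow(poly) < 3)
    stop("polygon must be a matrix with >= 3 rows and 2 columns (x, y)")
  if (!all(is.finite(poly))) stop("polygon vertices must be finite")
  storage.mode(poly) <- "double"
  # drop a repeated closing vertex if present
  n <- nrow(poly)
  if (n > 3 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  poly
}

# Proper intersection test for two closed segments, excluding shared
# endpoints of adjacent edges (handled by caller).
segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(q2 - q1, p1 - q1)
  d2 <- cross2(q2 - q1, p2 - q1)
  d3 <- cross2(p2 - p1, q1 - p1)
  d4 <- cross2(p2 - p1, q2 - p1)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    # c collinear with a-b; is it within the bounding box?
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(q1, q2, p1)) || (d2 == 0 && on_seg(q1, q2, p2)) ||
    (d3 == 0 && on_seg(p1, p2, q1)) || (d4 == 0 && on_seg(p1, p2, q2))
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' Pairwise edge intersection test; adjacent edges sharing exactly their
#' common vertex are permitted.
#'
#' @inheritParams polygon_area_signed
#' @return Logical scalar.
#' @export
polygon_is_simple <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  idx <- rbind(seq_len(n), c(seq_len(n)[-1], 1))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex by construction)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_intersect(poly[idx[1, i], ], poly[idx[2, i], ],
                             poly[idx[1, j], ], poly[idx[2, j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param x,y Numeric vectors of query coordinates (recycled together).
#' @param poly Polygon matrix.
#' @return Logical vector; boundary points count as inside.
#' @export
points_in_polygon <- function(x, y, poly) {
  poly <- as_polygon(poly)
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  jx <- c(px[n], px[-n]); jy <- c(py[n], py[-n])
  m <- length(x)
  inside <- logical(m)
  for (k in seq_len(m)) {
    crossings <- (py > y[k]) != (jy > y[k])
    if (!any(crossings)) { inside[k] <- FALSE; next }
    xin <- (jx - px) * (y[k] - py) / (jy - py) + px
    inside[k] <- (sum(crossings & (x[k] < xin)) %% 2) == 1
  }
  # boundary points: treat as inside (distance-to-edge zero)
  onb <- points_on_boundary(x, y, poly)
  inside | onb
}

points_on_boundary <- function(x, y, poly, tol = 1e-9) {
  n <- nrow(poly)
  res <- logical(length(x))
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (a[1] + t * ab[1] - x)^2 + (a[2] + t * ab[2] - y)^2
    res <- res | d2 <= tol^2
  }
  res
}

# Distance from `origin` to the outline along direction `dir` (unit not
# required). Returns the largest positive ray parameter among edge
# crossings, i.e. the outermost boundary crossing.
ray_outline_distance <- function(origin, dir, poly) {
  poly <- as_polygon(poly)
  dn <- sqrt(sum(dir^2))
  if (dn == 0) stop("direction vector must be non-zero")
  d <- dir / dn
  n <- nrow(poly)
  tmax <- -Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    e <- b - a
    denom <- cross2(d, e)
    if (abs(denom) < 1e-14) next
    diffap <- a - origin
    t <- cross2(diffap, e) / denom  # along ray
    u <- cross2(diffap, d) / denom  # along edge
    if (t > 0 && u >= -1e-12 && u <= 1 + 1e-12) tmax <- max(tmax, t)
  }
  if (!is.finite(tmax))
    stop("ray from origin does not cross the outline; origin may lie outside")
  tmax
}

# Closest point on a polyline; returns projection point, arc length s,
# unit tangent of the host segment, and the segment index.
project_on_polyline <- function(p, curve) {
  curve <- as.matrix(curve)
  if (ncol(curve) != 2 || nrow(curve) < 2)
    stop("curve must have >= 2 vertices with columns (x, y)")
  seg_len <- sqrt(rowSums((curve[-1, , drop = FALSE] -
                             curve[-nrow(curve), , drop = FALSE])^2))
  if (sum(seg_len) == 0) stop("curve has zero length")
  best <- list(d2 = Inf)
  s_acc <- 0
  for (i in seq_len(nrow(curve) - 1)) {
    a <- curve[i, ]; b <- curve[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- sum((p - a) * ab) / len2
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    d2 <- sum((p - q)^2)
    if (d2 < best$d2) {
      best <- list(d2 = d2, point = q, s = s_acc + t * sqrt(len2),
                   tangent = ab / sqrt(len2), segment = i)
    }
    s_acc <- s_acc + sqrt(len2)
  }
  best
}

half_ellipse_poly <- function(a, b, centre = c(0, 0), n = 64L) {
  # dome opening upward in a y-up frame: arc from (a,0) through (0,b) to (-a,0)
  th <- seq(0, pi, length.out = n)
  cbind(centre[1] + a * cos(th), centre[2] + b * sin(th))
}

#' Construct the analytic optic-tectum geometry
#'
#' Builds a schematic tectum used by the synthetic-data generators and the
#' multi-agent simulator: a half-ellipse outline; a concentric
#' periventricular-zone (PVZ) band of densely packed neuronal somata; an
#' inner neuropil region; and a rostrocaudal mid-band polyline. The frame
#' has its flat ventricular base on the x axis with the dome extending in
#' +y; the rostral axis points along +x.
#'
#' @param tectum_a,tectum_b Semi-axes of the half-ellipse outline (um).
#' @param pvz_inner_frac Fraction of the outline at which the inner PVZ
#'   boundary sits (the neuropil boundary); the PVZ band spans
#'   `[pvz_inner_frac, 1]` radially.
#' @param injury_angle_deg Angular position of the injury centre, degrees
#'   from the rostral (+x) axis.
#' @param injury_radius Injury radius (um); must fit inside the tectum.
#' @param n_vertices Vertices used to discretise each elliptical arc.
#' @param seed Integer seed; the default geometry is deterministic, the seed
#'   is kept for forward compatibility of jittered variants.
#' @return An object of class `tectum_geometry` with elements
#'   `tectum_outline`, `pvz_band`, `neuropil_region`, `rostrocaudal_curve`,
#'   `injury_center`, `injury_radius`, `origin`, `rostral_axis`.
#' @export
make_geometry <- function(tectum_a = 120, tectum_b = 80,
                          pvz_inner_frac = 0.55,
                          injury_angle_deg = 60,
                          injury_radius = 15,
                          n_vertices = 64L, seed = 1L) {
  if (tectum_a <= 0 || tectum_b <= 0) stop("tectum semi-axes must be positive")
  if (pvz_inner_frac <= 0 || pvz_inner_frac >= 1)
    stop("pvz_inner_frac must lie strictly between 0 and 1")
  if (injury_radius <= 0) stop("injury_radius must be positive")
  if (injury_radius >= min(tectum_a, tectum_b))
    stop("injury_radius must be smaller than the tectum semi-axes")

  outline <- half_ellipse_poly(tectum_a, tectum_b, n = n_vertices)
  f <- pvz_inner_frac
  # shrink slightly so band and neuropil are strictly inside the outline
  eps <- 1e-6
  outer_arc <- half_ellipse_poly(tectum_a * (1 - eps), tectum_b * (1 - eps),
                                 n = n_vertices)
  inner_arc <- half_ellipse_poly(tectum_a * f, tectum_b * f, n = n_vertices)
  # band: outer arc forward, inner arc reversed; closed along the base
  pvz_band <- rbind(outer_arc, inner_arc[rev(seq_len(nrow(inner_arc))), ])
  neuropil <- half_ellipse_poly(tectum_a * f * (1 - eps),
                                tectum_b * f * (1 - eps), n = n_vertices)

  mid <- (1 + f) / 2
  th <- seq(pi, 0, length.out = n_vertices)  # rostral end first (+x side last)
  rc_curve <- cbind(tectum_a * mid * cos(th), tectum_b * mid * sin(th))

  ang <- injury_angle_deg * pi / 180
  injury_center <- c(tectum_a * mid * cos(ang), tectum_b * mid * sin(ang))

  geom <- structure(list(
    tectum_outline = outline,
    pvz_band = pvz_band,
    neuropil_region = neuropil,
    rostrocaudal_curve = rc_curve,
    injury_center = injury_center,
    injury_radius = injury_radius,
    origin = polygon_centroid(outline),
    rostral_axis = c(1, 0),
    tectum_a = tectum_a, tectum_b = tectum_b,
    pvz_inner_frac = pvz_inner_frac,
    seed = as.integer(seed)
  ), class = "tectum_geometry")
  geom
}

#' @export
print.tectum_geometry <- function(x, ...) {
  cat("<tectum_geometry>\n")
  cat(sprintf("  outline: half-ellipse %g x %g um, %d vertices\n",
              x$tectum_a, x$tectum_b, nrow(x$tectum_outline)))
  cat(sprintf("  PVZ band: radial fraction [%g, 1]\n", x$pvz_inner_frac))
  cat(sprintf("  injury: centre (%.1f, %.1f), radius %g um\n",
              x$injury_center[1], x$injury_center[2], x$injury_radius))
  invisible(x)
}

#' Normalised polar coordinates of a point within the tectum
#'
#' Expresses a point relative to the tectum reference frame: `theta_deg` is
#' the signed angle (degrees, counter-clockwise) of the point from the
#' rostral axis as seen from the geometry origin, and `r_norm` is its radial
#' distance normalised by the distance from the origin to the tectum outline
#' along the same direction, so that points on the outline map to 1.
#'
#' @param p Numeric length-2 point (x, y) in um.
#' @param geometry A `tectum_geometry`.
#' @return A list with `r_norm` and `theta_deg`.
#' @export
normalise_polar <- function(p, geometry) {
  stopifnot(inherits(geometry, "tectum_geometry"))
  origin <- geometry$origin
  if (!all(points_in_polygon(origin[1], origin[2], geometry$tectum_outline)))
    stop("geometry origin lies outside the tectum outline")
  v <- c(p[1] - origin[1], p[2] - origin[2])
  r <- sqrt(sum(v^2))
  if (r == 0) return(list(r_norm = 0, theta_deg = 0))
  ax <- geometry$rostral_axis / sqrt(sum(geometry$rostral_axis^2))
  theta <- atan2(cross2(ax, v), sum(ax * v)) * 180 / pi
  denom <- ray_outline_distance(origin, v, geometry$tectum_outline)
  list(r_norm = r / denom, theta_deg = theta)
}
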