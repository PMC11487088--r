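# Track and TrackSet containers.
#
# A track holds one cell's time-stamped positions in physical units
# (minutes, micrometres). A track set bundles tracks with acquisition
# metadata (frame interval, pixel size) shared by downstream statistics.

#' Create a single cell track
#'
#' @param track_id Identifier (coerced to character).
#' @param t Numeric vector of time points in minutes, strictly increasing.
#' @param x,y Numeric coordinate vectors in micrometres.
#' @param z Optional numeric z coordinates in micrometres; `NULL` for 2D
#'   tracks. Z statistics refuse 2D tracks rather than returning zero.
#' @param cell_type One of `"neuron"`, `"microglia"`, `"other"`.
#' @param animal_id Identifier of the source animal.
#' @return An object of class `track`.
#' @export
track <- function(track_id, t, x, y, z = NULL,
                  cell_type = c("neuron", "microglia", "other"),
                  animal_id = "animal1") {
  cell_type <- match.arg(cell_type)
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(t)
  if (length(x) != n || length(y) != n)
    stop("t, x, y must have equal length in track '", track_id, "'")
  if (!is.null(z)) {
    z <- as.numeric(z)
    if (length(z) != n) stop("z length mismatch in track '", track_id, "'")
  }
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y)) ||
      (!is.null(z) && !all(is.finite(z))))
    stop("non-finite coordinates in track '", track_id, "'")
  if (n >= 2 && any(diff(t) <= 0))
    stop("time must be strictly increasing in track '", track_id, "'")
  structure(list(track_id = as.character(track_id),
                 cell_type = cell_type,
                 animal_id = as.character(animal_id),
                 t = t, x = x, y = y, z = z),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track '%s'> %s, %s, %d samples, t = [%g, %g] min%s\n",
              x$track_id, x$cell_type, x$animal_id, length(x$t),
              if (length(x$t)) min(x$t) else NA,
              if (length(x$t)) max(x$t) else NA,
              if (is.null(x$z)) " (2D)" else " (3D)"))
  invisible(x)
}

n_samples <- function(tr) length(tr$t)

#' Bundle tracks into a track set
#'
#' @param tracks List of [track()] objects.
#' @param frame_interval Nominal frame interval in minutes (metadata).
#' @param pixel_size Pixel size in micrometres per pixel (metadata).
#' @return An object of class `track_set`.
#' @export
track_set <- function(tracks, frame_interval = NA_real_,
                      pixel_size = NA_real_) {
  if (!length(tracks)) stop("a track set must contain at least one track")
  ok <- vapply(tracks, inherits, logical(1), what = "track")
  if (!all(ok)) stop("all elements must be track objects")
  ids <- vapply(tracks, `[[`, character(1), "track_id")
  names(tracks) <- ids
  structure(list(tracks = tracks,
                 frame_interval = as.numeric(frame_interval),
                 pixel_size = as.numeric(pixel_size)),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, frame interval %g min\n",
              length(x$tracks), x$frame_interval))
  invisible(x)
}

#' @export
length.track_set <- function(x) length(x$tracks)

#' Convert a track set to a long data frame
#'
#' One row per sample with columns `track_id`, `cell_type`, `animal_id`,
#' `t_min`, `x_um`, `y_um` and, when any track is 3D, `z_um` (`NA` for 2D
#' tracks). Rows are ordered by track id then time.
#'
#' @param x A `track_set`.
#' @param row.names,optional Ignored (base generic signature).
#' @param ... Ignored.
#' @export
as.data.frame.track_set <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  any3d <- any(vapply(x$tracks, function(tr) !is.null(tr$z), logical(1)))
  rows <- lapply(x$tracks, function(tr) {
    df <- data.frame(track_id = tr$track_id, cell_type = tr$cell_type,
                     animal_id = tr$animal_id, t_min = tr$t,
                     x_um = tr$x, y_um = tr$y,
                     stringsAsFactors = FALSE)
    if (any3d) df$z_um <- if (is.null(tr$z)) NA_real_ else tr$z
    df
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$t_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

track_xy <- function(tr) cbind(tr$x, tr$y)
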