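# Kinetic curves: scalar readouts over time (ROI fluorescence during wound
# closure, microglial accumulation in the neuropil) and their
# normalisation and threshold-crossing summaries.

#' Create a kinetic curve
#'
#' @param t Time in minutes, strictly increasing.
#' @param value Scalar readout (intensity or normalised units).
#' @param normalised Logical flag; `TRUE` when the curve has been passed
#'   through [normalise_curve()].
#' @param t0_hpi Time of the first sample in hours post-injury (metadata).
#' @return An object of class `kinetic_curve`.
#' @export
kinetic_curve <- function(t, value, normalised = FALSE, t0_hpi = NA_real_) {
  t <- as.numeric(t); value <- as.numeric(value)
  if (length(t) != length(value)) stop("t and value must match in length")
  if (length(t) >= 2 && any(diff(t) <= 0))
    stop("t must be strictly increasing")
  if (!all(is.finite(t)) || !all(is.finite(value)))
    stop("kinetic curve values must be finite")
  structure(list(t = t, value = value, normalised = isTRUE(normalised),
                 t0_hpi = as.numeric(t0_hpi)),
            class = "kinetic_curve")
}

#' @export
print.kinetic_curve <- function(x, ...) {
  cat(sprintf("<kinetic_curve> %d points, t = [%g, %g] min%s\n",
              length(x$t), min(x$t), max(x$t),
              if (x$normalised) ", normalised" else ""))
  invisible(x)
}

#' Normalise a kinetic curve between its first value and a reference time
#'
#' Maps the readout to 0 at the first sample and 1 at the reference time
#' (by default the last sample), without clamping:
#' `v'(t) = (v(t) - v(t1)) / (v(t_ref) - v(t1))`. The operation is
#' idempotent and invariant to affine rescaling of the input.
#'
#' @param curve A [kinetic_curve()].
#' @param t_ref Reference time (minutes); defaults to the last sample.
#'   Matched to the nearest sampled time point.
#' @return A normalised [kinetic_curve()].
#' @export
normalise_curve <- function(curve, t_ref = NULL) {
  stopifnot(inherits(curve, "kinetic_curve"))
  if (is.null(t_ref)) t_ref <- curve$t[length(curve$t)]
  i_ref <- which.min(abs(curve$t - t_ref))
  v0 <- curve$value[1]
  vr <- curve$value[i_ref]
  if (vr == v0)
    stop("cannot normalise: reference value equals the first value ",
         "(zero range)")
  kinetic_curve(curve$t, (curve$value - v0) / (vr - v0),
                normalised = TRUE, t0_hpi = curve$t0_hpi)
}

roi_mean_series <- function(stack, roi, z_index = NULL) {
  d <- dim(stack$data)
  ny <- d[1]; nx <- d[2]
  px <- stack$pixel_size
  # pixel centres in um, image convention (origin upper-left, y down)
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  gx <- rep(xc, each = ny)
  gy <- rep(yc, times = nx)
  inside <- points_in_polygon(gx, gy, roi)
  if (!any(inside)) stop("ROI contains no pixel centres (empty or outside image)")
  idx <- which(matrix(inside, ny, nx))
  nt <- n_frames(stack)
  vals <- vapply(seq_len(nt), function(i) {
    fr <- get_frame(stack, i, z_index)
    mean(fr[idx])
  }, numeric(1))
  kinetic_curve((seq_len(nt) - 1) * stack$frame_interval, vals,
                t0_hpi = stack$t0_hpi)
}

#' Wound-closure kinetic from an intensity stack
#'
#' Mean fluorescence intensity inside an ROI delimiting the initial wound
#' area, per frame, optionally normalised between 0 (first frame) and 1
#' (reference frame). For volumetric stacks a single optical plane is
#' used (default: the median plane).
#'
#' @param stack An [image_stack()].
#' @param wound_roi Polygon (um) delimiting the initial wound area.
#' @param z_index Optical plane for volumetric stacks; default median.
#' @param normalise Normalise the curve via [normalise_curve()]?
#' @param t_ref Reference time for normalisation (minutes; default last).
#' @return A [kinetic_curve()].
#' @export
closure_curve <- function(stack, wound_roi, z_index = NULL,
                          normalise = TRUE, t_ref = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  curve <- roi_mean_series(stack, wound_roi, z_index)
  if (normalise) curve <- normalise_curve(curve, t_ref)
  curve
}

#' Microglial accumulation kinetic from an intensity stack
#'
#' Mean fluorescence intensity in the neuropil ROI over time; same
#' machinery as [closure_curve()] with a different region of interest.
#'
#' @inheritParams closure_curve
#' @param neuropil_roi Polygon (um) delimiting the neuropil.
#' @return A [kinetic_curve()].
#' @export
accumulation_curve <- function(stack, neuropil_roi, z_index = NULL,
                               normalise = TRUE, t_ref = NULL) {
  closure_curve(stack, neuropil_roi, z_index = z_index,
                normalise = normalise, t_ref = t_ref)
}

#' Time at which a normalised curve first reaches a threshold
#'
#' Linear interpolation between the bracketing samples.
#'
#' @param curve A normalised [kinetic_curve()].
#' @param threshold Closure threshold on the normalised readout.
#' @return List with `t` (minutes; `NA` when the threshold is never
#'   reached) and `defined` (logical).
#' @export
closure_time <- function(curve, threshold = 0.95) {
  stopifnot(inherits(curve, "kinetic_curve"))
  if (!curve$normalised)
    stop("closure_time expects a normalised curve; see normalise_curve()")
  v <- curve$value; t <- curve$t
  hit <- which(v >= threshold)
  if (!length(hit)) return(list(t = NA_real_, defined = FALSE))
  i <- hit[1]
  if (i == 1) return(list(t = t[1], defined = TRUE))
  # interpolate between i-1 and i
  frac <- (threshold - v[i - 1]) / (v[i] - v[i - 1])
  list(t = t[i - 1] + frac * (t[i] - t[i - 1]), defined = TRUE)
}
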