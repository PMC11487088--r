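# Intensity stacks and binary mask series.
#
# In-memory layout follows the ImageJ hyperstack convention reduced to the
# axes used here: 2D+t stacks are arrays (y, x, t); 3D+t stacks are arrays
# (y, x, z, t). Pixel indices map to physical coordinates through
# pixel_size, with the pixel centre of [1,1] at (pixel_size/2,
# pixel_size/2) from the image upper-left origin, y increasing downward.

#' Create an intensity image stack
#'
#' @param data Numeric array: `(y, x, t)` for 2D time series or
#'   `(y, x, z, t)` for volumetric time series. Intensities must be
#'   non-negative.
#' @param pixel_size Micrometres per pixel (isotropic in x, y).
#' @param frame_interval Minutes between frames.
#' @param z_step Micrometres between optical planes (3D+t only).
#' @param t0_hpi Time of the first frame in hours post-injury (display
#'   metadata only; all internal time is minutes from the first frame).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size, frame_interval,
                        z_step = NA_real_, t0_hpi = NA_real_) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3, 4))
    stop("data must be a (y, x, t) or (y, x, z, t) array")
  if (any(data < 0)) stop("intensities must be non-negative")
  if (pixel_size <= 0 || frame_interval <= 0)
    stop("pixel_size and frame_interval must be positive")
  if (nd == 4 && (is.na(z_step) || z_step <= 0))
    stop("z_step must be positive for a volumetric stack")
  structure(list(data = data, pixel_size = as.numeric(pixel_size),
                 frame_interval = as.numeric(frame_interval),
                 z_step = as.numeric(z_step), t0_hpi = as.numeric(t0_hpi)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %s, %g um/px, %g min/frame\n",
              paste(d, collapse = " x "), x$pixel_size, x$frame_interval))
  invisible(x)
}

n_frames <- function(stack) {
  d <- dim(stack$data)
  d[length(d)]
}

get_frame <- function(stack, t_index, z_index = NULL) {
  d <- dim(stack$data)
  if (length(d) == 3) return(stack$data[, , t_index])
  if (is.null(z_index)) z_index <- ceiling(d[3] / 2)  # median plane
  stack$data[, , z_index, t_index]
}

#' Write a 2D time series as a multi-page TIFF
#'
#' Intensities are rescaled to the unit range expected by the TIFF writer
#' using a shared factor recorded nowhere in the file, so absolute scale is
#' not preserved; relative intensities within the stack are.
#'
#' @param stack An [image_stack()] with `(y, x, t)` data.
#' @param path Output path.
#' @param bits Bits per sample (8, 16 or 32).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, bits = 32L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (length(d) != 3) stop("TIFF export supports (y, x, t) stacks")
  mx <- max(stack$data)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(d[3]), function(i) stack$data[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Read a multi-page TIFF as a 2D time series
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval Physical metadata (not stored in TIFF).
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, pixel_size, frame_interval) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  image_stack(arr, pixel_size = pixel_size, frame_interval = frame_interval)
}

#' Create a binary mask series
#'
#' @param masks List of logical (or 0/1) matrices of identical dimensions.
#' @param times Acquisition times in seconds, strictly increasing.
#' @param pixel_size Micrometres per pixel.
#' @return An object of class `mask_series`.
#' @export
mask_series <- function(masks, times, pixel_size) {
  if (length(masks) != length(times)) stop("one time per mask required")
  if (length(masks) && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  masks <- lapply(masks, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "logical"
    m
  })
  if (length(masks) > 1) {
    d1 <- dim(masks[[1]])
    same <- vapply(masks, function(m) identical(dim(m), d1), logical(1))
    if (!all(same)) stop("all masks must share the same dimensions")
  }
  structure(list(masks = masks, times = as.numeric(times),
                 pixel_size = as.numeric(pixel_size)),
            class = "mask_series")
}

#' @export
print.mask_series <- function(x, ...) {
  cat(sprintf("<mask_series> %d frame(s), %g um/px\n",
              length(x$masks), x$pixel_size))
  invisible(x)
}

#' Write a mask series as a multi-page 0/255 TIFF
#'
#' @param ms A [mask_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_series <- function(ms, path) {
  stopifnot(inherits(ms, "mask_series"))
  pages <- lapply(ms$masks, function(m) {
    p <- matrix(0, nrow(m), ncol(m))
    p[m] <- 1
    p
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a multi-page 0/255 TIFF as a mask series
#'
#' Pixels above half range are foreground.
#'
#' @param path TIFF path.
#' @param times Frame times in seconds.
#' @param pixel_size Micrometres per pixel.
#' @return A [mask_series()].
#' @export
read_mask_series <- function(path, times, pixel_size) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  masks <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p > 0.5
  })
  mask_series(masks, times = times, pixel_size = pixel_size)
}
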