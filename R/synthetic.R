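# Seeded synthetic-data generators.
#
# These emulate the *structure* of the study's in vivo data — uninjured
# jitter versus injured directed superdiffusive tracks converging on a
# point, shrinking-wound outline stacks, recoiling ablation masks,
# blob-rendered intensity movies — so that every analysis stage is
# testable against known ground truth. They do not attempt photorealistic
# microscopy; noise is additive Gaussian on positions (per-localisation
# tracking error), not on steps.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  expr
}

#' Specification for synthetic track generation
#'
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @param n_tracks Number of tracks.
#' @param duration Total duration in minutes.
#' @param frame_interval Minutes between samples.
#' @param motion_model One of `"jitter"` (uninjured analogue: Gaussian-step
#'   random walk with small steps), `"directed_oscillator"` (injured
#'   analogue: displacement toward the convergence point following the
#'   damped-oscillator law, scaled to each start's distance),
#'   `"ballistic"` (straight constant-velocity), `"random_walk"`.
#' @param convergence_point Target point (um) for `directed_oscillator`;
#'   default the geometry's injury centre.
#' @param noise_sigma Per-localisation measurement noise (um, >= 0),
#'   added to positions.
#' @param step_sigma Per-axis step standard deviation (um) for the
#'   jitter/random-walk models. The study reports only "minimal movement"
#'   for uninjured animals, so this scale is a free parameter.
#' @param speed Speed (um/min) for the ballistic model.
#' @param amplitude Oscillator amplitude as a fraction of each start's
#'   distance to the convergence point.
#' @param nu,k,phi Oscillator parameters (1/min, 1/min^2, rad); defaults
#'   give a half-period close to `duration` so tracks traverse one
#'   monotone closure segment.
#' @param geometry A `tectum_geometry`; start points are drawn inside its
#'   PVZ band.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L, n_tracks = 30L, duration = 1080,
                       frame_interval = 15,
                       motion_model = c("jitter", "directed_oscillator",
                                        "ballistic", "random_walk"),
                       convergence_point = NULL,
                       noise_sigma = 0.05, step_sigma = 0.3,
                       speed = 0.5, amplitude = 0.8,
                       nu = 0.004, k = 1.25e-5, phi = 0,
                       geometry = make_geometry()) {
  motion_model <- match.arg(motion_model)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (step_sigma < 0) stop("step_sigma must be >= 0")
  if (duration <= 0 || frame_interval <= 0 || duration < frame_interval)
    stop("need duration >= frame_interval > 0")
  if (is.null(convergence_point)) convergence_point <- geometry$injury_center
  structure(list(seed = as.integer(seed), n_tracks = as.integer(n_tracks),
                 duration = duration, frame_interval = frame_interval,
                 motion_model = motion_model,
                 convergence_point = convergence_point,
                 noise_sigma = noise_sigma, step_sigma = step_sigma,
                 speed = speed, amplitude = amplitude,
                 nu = nu, k = k, phi = phi, geometry = geometry),
            class = "synth_spec")
}

sample_in_polygon <- function(n, poly) {
  bb <- apply(poly, 2, range)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    m <- (n - got) * 4L
    x <- stats::runif(m, bb[1, 1], bb[2, 1])
    y <- stats::runif(m, bb[1, 2], bb[2, 2])
    keep <- points_in_polygon(x, y, poly)
    take <- min(sum(keep), n - got)
    if (take > 0) {
      sel <- which(keep)[seq_len(take)]
      out[(got + 1):(got + take), ] <- cbind(x[sel], y[sel])
      got <- got + take
    }
  }
  out
}

#' Generate synthetic cell tracks
#'
#' @param spec A [synth_spec()].
#' @return A [track_set()] of 2D tracks starting inside the PVZ band.
#' @export
gen_tracks <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    tt <- seq(0, spec$duration, by = spec$frame_interval)
    nf <- length(tt)
    starts <- sample_in_polygon(spec$n_tracks, spec$geometry$pvz_band)
    tracks <- vector("list", spec$n_tracks)
    for (i in seq_len(spec$n_tracks)) {
      s <- starts[i, ]
      pos <- switch(spec$motion_model,
        jitter = ,
        random_walk = {
          dx <- c(0, stats::rnorm(nf - 1, 0, spec$step_sigma))
          dy <- c(0, stats::rnorm(nf - 1, 0, spec$step_sigma))
          cbind(s[1] + cumsum(dx), s[2] + cumsum(dy))
        },
        ballistic = {
          th <- stats::runif(1, 0, 2 * pi)
          cbind(s[1] + spec$speed * tt * cos(th),
                s[2] + spec$speed * tt * sin(th))
        },
        directed_oscillator = {
          v <- spec$convergence_point - s
          dist <- sqrt(sum(v^2))
          u <- if (dist > 0) v / dist else c(0, 0)
          # fractional progress toward the convergence point:
          # a * (1 - exp(-nu t / 2) cos(omega t - phi))
          frac <- spec$amplitude -
            oscillator_displacement(tt, spec$amplitude, spec$nu, spec$k,
                                    spec$phi)
          cbind(s[1] + u[1] * dist * frac, s[2] + u[2] * dist * frac)
        },
        stop("unknown motion model: ", spec$motion_model)
      )
      if (spec$noise_sigma > 0) {
        pos <- pos + matrix(stats::rnorm(2 * nf, 0, spec$noise_sigma),
                            nf, 2)
      }
      tracks[[i]] <- track(track_id = sprintf("synth%03d", i),
                           t = tt, x = pos[, 1], y = pos[, 2],
                           cell_type = "neuron", animal_id = "synthetic")
    }
    track_set(tracks, frame_interval = spec$frame_interval, pixel_size = 1)
  })
}

#' Render tracks as a Gaussian-blob intensity movie
#'
#' Every track position becomes an isotropic Gaussian blob of unit
#' integrated intensity; frames are sums of blobs. Enables testing ROI
#' intensity kinetics against ground-truth motion.
#'
#' @param ts A [track_set()] whose tracks share a common time base.
#' @param blob_sigma Blob standard deviation in micrometres (> 0).
#' @param shape Integer length-2 frame shape in pixels `(ny, nx)`.
#' @param pixel_size Micrometres per pixel.
#' @param origin Physical coordinates (um) of the image upper-left corner;
#'   positions are rendered relative to it.
#' @param frame_interval Minutes per frame; default taken from `ts`.
#' @return An [image_stack()] of shape `(ny, nx, n_frames)`.
#' @export
render_movie <- function(ts, blob_sigma, shape = c(128L, 128L),
                         pixel_size = 1, origin = c(0, 0),
                         frame_interval = NULL) {
  stopifnot(inherits(ts, "track_set"))
  if (blob_sigma <= 0) stop("blob_sigma must be positive")
  tt <- ts$tracks[[1]]$t
  same <- vapply(ts$tracks, function(tr) identical(tr$t, tt), logical(1))
  if (!all(same)) stop("all tracks must share one time base for rendering")
  ny <- shape[1]; nx <- shape[2]
  xc <- origin[1] + (seq_len(nx) - 0.5) * pixel_size
  yc <- origin[2] + (seq_len(ny) - 0.5) * pixel_size
  nf <- length(tt)
  arr <- array(0, dim = c(ny, nx, nf))
  norm <- pixel_size^2 / (2 * pi * blob_sigma^2)  # unit integral per blob
  for (f in seq_len(nf)) {
    frame <- matrix(0, ny, nx)
    for (tr in ts$tracks) {
      gx <- exp(-(xc - tr$x[f])^2 / (2 * blob_sigma^2))
      gy <- exp(-(yc - tr$y[f])^2 / (2 * blob_sigma^2))
      frame <- frame + norm * outer(gy, gx)
    }
    arr[, , f] <- frame
  }
  fi <- if (!is.null(frame_interval)) frame_interval
        else if (length(tt) > 1) tt[2] - tt[1] else 1
  image_stack(arr, pixel_size = pixel_size, frame_interval = fi)
}

#' Generate an empty movie (no tracks)
#'
#' @inheritParams render_movie
#' @param n_frames Number of frames.
#' @return All-zero [image_stack()].
#' @export
empty_movie <- function(n_frames, shape = c(128L, 128L), pixel_size = 1,
                        frame_interval = 15) {
  image_stack(array(0, dim = c(shape[1], shape[2], n_frames)),
              pixel_size = pixel_size, frame_interval = frame_interval)
}

regular_polygon_with_area <- function(area, centre, m = 32L, aspect = 1) {
  # radius giving an exact shoelace area for a regular m-gon
  r <- sqrt(2 * area / (m * sin(2 * pi / m)))
  th <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  cbind(centre[1] + r * aspect * cos(th), centre[2] + r / aspect * sin(th))
}

#' Generate paired start/end wound outline stacks
#'
#' Elliptical per-plane outlines with a parabolic axial profile whose
#' summed plane-area volume matches the requested volumes exactly (up to
#' floating point), so downstream repair indices are controlled.
#'
#' @param kind `"closing"` (`v_end <= v_start`) or `"enlarging"`.
#' @param v_start,v_end Requested volumes (um^3); `v_end = 0` produces an
#'   empty end stack (fully closed wound).
#' @param n_planes Number of outlined planes (>= 1).
#' @param z_step Plane spacing (um).
#' @param seed Integer seed (centre jitter between planes).
#' @return List with elements `start` and `end`, both [outline_stack()]s.
#' @export
gen_wound_series <- function(kind = c("closing", "enlarging"),
                             v_start = 2000, v_end = 500,
                             n_planes = 10L, z_step = 2, seed = 1L) {
  kind <- match.arg(kind)
  if (n_planes < 1) stop("n_planes must be >= 1")
  if (v_start <= 0) stop("v_start must be positive")
  if (v_end < 0) stop("v_end must be >= 0")
  if (kind == "closing" && v_end > v_start)
    stop("closing series requires v_end <= v_start")
  if (kind == "enlarging" && v_end < v_start)
    stop("enlarging series requires v_end >= v_start")

  make_stack <- function(v, jitter_seed) {
    if (v == 0) return(outline_stack(list(), z_step = z_step))
    j <- seq_len(n_planes)
    w <- 1 - ((j - (n_planes + 1) / 2) / ((n_planes + 1) / 2))^2
    w <- pmax(w, 0.05)
    areas <- (v / z_step) * w / sum(w)
    with_seed(jitter_seed, {
      centres <- cbind(50 + stats::rnorm(n_planes, 0, 0.5),
                       50 + stats::rnorm(n_planes, 0, 0.5))
      outline_stack(lapply(j, function(i)
        list(z_index = i,
             vertices = regular_polygon_with_area(areas[i], centres[i, ],
                                                  aspect = 1.15))),
        z_step = z_step)
    })
  }
  list(start = make_stack(v_start, seed),
       end = make_stack(v_end, seed + 1L))
}

#' Generate a synthetic laser-ablation mask series
#'
#' @param mode `"recoil"` (large first-interval shrinkage then
#'   near-static), `"static"` (constant mask), or `"drift"` (slow
#'   translation).
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame interval in seconds.
#' @param seed Integer seed.
#' @param shape Frame shape in pixels.
#' @param pixel_size Micrometres per pixel.
#' @return A [mask_series()].
#' @export
gen_ablation_masks <- function(mode = c("recoil", "static", "drift"),
                               n_frames = 10L, dt = 15, seed = 1L,
                               shape = c(64L, 64L), pixel_size = 0.5) {
  mode <- match.arg(mode)
  if (n_frames < 2) stop("n_frames must be >= 2")
  ny <- shape[1]; nx <- shape[2]
  cx0 <- nx / 2; cy0 <- ny / 2
  disc <- function(cx, cy, r) {
    outer(seq_len(ny) - cy, seq_len(nx) - cx,
          function(dy, dx) dx^2 + dy^2 <= r^2)
  }
  masks <- with_seed(seed, lapply(seq_len(n_frames), function(i) {
    switch(mode,
      static = disc(cx0, cy0, 20),
      recoil = {
        # big retraction over the first interval, then slow creep
        r <- if (i == 1) 20 else 12 - 0.05 * (i - 2)
        disc(cx0, cy0, r)
      },
      drift = disc(cx0 + (i - 1), cy0, 14)
    )
  }))
  mask_series(masks, times = (seq_len(n_frames) - 1) * dt,
              pixel_size = pixel_size)
}
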