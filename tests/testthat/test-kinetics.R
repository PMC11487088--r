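test_that("curve normalisation maps first to 0 and reference to 1", {
  c1 <- kinetic_curve(c(0, 15, 30), c(10, 15, 20))
  n1 <- normalise_curve(c1)
  expect_equal(n1$value, c(0, 0.5, 1))
  expect_true(n1$normalised)
  # idempotent and affine invariant
  expect_equal(normalise_curve(n1)$value, n1$value)
  c2 <- kinetic_curve(c1$t, 3 * c1$value - 7)
  expect_equal(normalise_curve(c2)$value, n1$value)
  expect_error(normalise_curve(kinetic_curve(c(0, 15), c(2, 2))),
               "zero range")
})

test_that("closure time interpolates linearly and flags unreachable", {
  ramp <- normalise_curve(kinetic_curve(seq(0, 100, 10), seq(0, 1, 0.1)))
  expect_equal(closure_time(ramp, 0.5)$t, 50)
  expect_equal(closure_time(ramp, 0.95)$t, 95)
  late <- normalise_curve(kinetic_curve(c(0, 50, 100), c(0, 0.2, 1)))
  expect_equal(closure_time(late, 1)$t, 100)
  flat <- kinetic_curve(c(0, 10, 20), c(0, 0, 0), normalised = TRUE)
  expect_false(closure_time(flat)$defined)
})

test_that("oscillator displacement follows the printed closed form", {
  # t = 0: even cosine
  expect_equal(oscillator_displacement(0, 2, 0.1, 1, 0.3),
               2 * cos(-0.3))
  # undamped pure cosine stays within the amplitude
  t <- seq(0, 50, 0.5)
  x <- oscillator_displacement(t, 1, 0, 1, 0)
  expect_equal(x, cos(t))
  expect_lte(max(abs(x)), 1)
  # direct evaluation at the half period
  om <- sqrt(1 - 0.2^2 / 4)
  expect_equal(oscillator_displacement(pi / om, 1, 0.2, 1, 0),
               -exp(-0.1 * pi / om), tolerance = 1e-12)
  expect_error(oscillator_displacement(1, 1, 2, 0.5, 0), "overdamped")
})

test_that("oscillator displacement solves the damped-oscillator ODE", {
  a <- 0.7; nu <- 0.02; k <- 0.002; phi <- 0.4
  h <- 1e-3
  t <- seq(1, 300, length.out = 50)
  x <- function(tt) oscillator_displacement(tt, a, nu, k, phi)
  xd <- (x(t + h) - x(t - h)) / (2 * h)
  xdd <- (x(t + h) - 2 * x(t) + x(t - h)) / h^2
  expect_lt(max(abs(xdd + nu * xd + k * x(t))), 1e-6 * abs(a))
})

test_that("oscillator fit recovers noiseless parameters to 1e-6", {
  t <- seq(0, 100, length.out = 60)
  v <- 0.5 + oscillator_displacement(t, -0.5, 0.01, 0.001, 0)
  f <- suppressWarnings(fit_oscillator(kinetic_curve(t, v)))
  expect_equal(f$a, -0.5, tolerance = 1e-6)
  expect_equal(f$nu, 0.01, tolerance = 1e-6)
  expect_equal(f$k, 0.001, tolerance = 1e-6)
  expect_equal(f$phi, 0, tolerance = 1e-6)
  expect_equal(f$offset, 0.5, tolerance = 1e-6)
  expect_gt(f$r2, 1 - 1e-10)
  # omega is recomputable from (k, nu)
  expect_equal(f$omega, sqrt(f$k - f$nu^2 / 4), tolerance = 1e-12)
  expect_error(fit_oscillator(kinetic_curve(t, rep(1, 60))), "constant")
})

test_that("ROI kinetics from rendered movies behave like the experiment", {
  # blobs converging into the wound ROI: monotone rising closure curve
  tt <- (0:8) * 15
  mk <- function(x0, y0) {
    frac <- seq(0, 1, length.out = length(tt))
    track(paste0("n", x0), t = tt, x = x0 + (40 - x0) * frac,
          y = y0 + (40 - y0) * frac)
  }
  ts <- track_set(list(mk(10, 10), mk(70, 15), mk(15, 70), mk(65, 65)),
                  frame_interval = 15)
  mv <- render_movie(ts, blob_sigma = 3, shape = c(80L, 80L), pixel_size = 1)
  roi <- cbind(c(30, 50, 50, 30), c(30, 30, 50, 50))
  cl <- closure_curve(mv, roi)
  expect_true(all(diff(cl$value) > 0))
  expect_equal(cl$value[1], 0)
  expect_equal(cl$value[length(cl$value)], 1)

  # constant movie: normalisation refused
  const <- empty_movie(4, shape = c(40L, 40L))
  expect_error(closure_curve(const, roi), "zero range")
  # ROI outside the image: error
  far_roi <- cbind(c(500, 600, 600, 500), c(500, 500, 600, 600))
  expect_error(closure_curve(mv, far_roi), "ROI")

  # whole-frame ROI on conserved blobs: constant accumulation readout
  still <- track_set(list(track("s", tt, rep(40, 9), rep(40, 9))),
                     frame_interval = 15)
  mv2 <- render_movie(still, blob_sigma = 2, shape = c(80L, 80L))
  whole <- cbind(c(0, 80, 80, 0), c(0, 0, 80, 80))
  acc <- accumulation_curve(mv2, whole, normalise = FALSE)
  expect_lt(diff(range(acc$value)), 1e-9 * mean(acc$value))
})
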