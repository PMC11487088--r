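test_that("generators are pure functions of spec and seed", {
  s <- synth_spec(seed = 5, n_tracks = 6, motion_model = "random_walk")
  expect_identical(gen_tracks(s), gen_tracks(s))
  w1 <- gen_wound_series(seed = 4)
  w2 <- gen_wound_series(seed = 4)
  expect_identical(w1, w2)
  expect_identical(gen_ablation_masks("recoil", seed = 3),
                   gen_ablation_masks("recoil", seed = 3))
})

test_that("noise-free jitter tracks are stationary", {
  s <- synth_spec(seed = 1, n_tracks = 5, motion_model = "jitter",
                  noise_sigma = 0, step_sigma = 0)
  ts <- gen_tracks(s)
  for (tr in ts$tracks) {
    expect_equal(diff(range(tr$x)), 0)
    expect_equal(diff(range(tr$y)), 0)
  }
})

test_that("noise-free directed tracks move along lines through the target", {
  s <- synth_spec(seed = 2, n_tracks = 10, motion_model = "directed_oscillator",
                  noise_sigma = 0)
  ts <- gen_tracks(s)
  cp <- s$convergence_point
  for (tr in ts$tracks) {
    # every sample collinear with start and convergence point
    sx <- tr$x[1]; sy <- tr$y[1]
    u <- c(cp[1] - sx, cp[2] - sy)
    u <- u / sqrt(sum(u^2))
    off_axis <- abs(-(tr$x - sx) * u[2] + (tr$y - sy) * u[1])
    expect_lt(max(off_axis), 1e-9)
    # displacement is toward the target, never past it at default amplitude
    d_start <- sqrt((cp[1] - sx)^2 + (cp[2] - sy)^2)
    d_end <- sqrt((cp[1] - tr$x[length(tr$x)])^2 +
                    (cp[2] - tr$y[length(tr$y)])^2)
    expect_lt(d_end, d_start)
  }
})

test_that("random-walk tracks are tortuous (low straightness)", {
  ts <- random_walk_tracks(1000, 100, step_sd = 1, seed = 7)
  s <- vapply(ts$tracks, function(tr) track_summary(tr)$straightness,
              numeric(1))
  expect_lt(mean(s), 0.5)
})

test_that("rendered movies conserve per-blob integrated intensity", {
  tr <- track("still", t = c(0, 15, 30), x = rep(40, 3), y = rep(40, 3))
  ts <- track_set(list(tr), frame_interval = 15)
  mv <- render_movie(ts, blob_sigma = 2, shape = c(80L, 80L), pixel_size = 1)
  sums <- apply(mv$data, 3, sum)
  expect_equal(sums, rep(1, 3), tolerance = 1e-6)
  # zero tracks give an all-zero stack
  expect_true(all(empty_movie(3, shape = c(16L, 16L))$data == 0))
  expect_error(render_movie(ts, blob_sigma = 0), "positive")
})

test_that("a blob leaving a fixed ROI strictly decreases ROI mean intensity", {
  tr <- track("mover", t = (0:5) * 15, x = 20 + (0:5) * 8, y = rep(30, 6))
  ts <- track_set(list(tr), frame_interval = 15)
  mv <- render_movie(ts, blob_sigma = 2, shape = c(60L, 80L), pixel_size = 1)
  roi <- cbind(c(12, 28, 28, 12), c(22, 22, 38, 38))  # around the start
  curve <- closure_curve(mv, roi, normalise = FALSE)
  expect_true(all(diff(curve$value) < 0))
})

test_that("wound series volumes match the request and drive the repair index", {
  w <- gen_wound_series("closing", v_start = 2000, v_end = 500,
                        n_planes = 10, z_step = 2, seed = 1)
  v_s <- injury_volume(w$start)
  v_e <- injury_volume(w$end)
  expect_close(v_s, 2000, 0.02 * 2000)
  expect_close(v_e, 500, 0.02 * 500)
  ri <- repair_index(v_s, v_e)
  expect_close(ri$ri, 0.75, 0.02)
  # equal volumes: no repair
  w0 <- gen_wound_series("closing", v_start = 1000, v_end = 1000, seed = 2)
  expect_close(repair_index(injury_volume(w0$start),
                            injury_volume(w0$end))$ri, 0, 1e-9)
  # full closure: empty end stack, index 1
  w1 <- gen_wound_series("closing", v_start = 1000, v_end = 0, seed = 3)
  expect_length(w1$end, 0)
  expect_equal(repair_index(injury_volume(w1$start), 0)$ri, 1)
  expect_error(gen_wound_series(n_planes = 0), "n_planes")
})

test_that("ablation mask modes have their designed signatures", {
  st <- gen_ablation_masks("static", n_frames = 5, seed = 1)
  ac <- area_change(st)
  expect_true(all(ac$intervals$total_remodelled == 0))

  rc <- gen_ablation_masks("recoil", n_frames = 8, seed = 1)
  acr <- area_change(rc)
  first <- acr$intervals$total_remodelled[1]
  later <- acr$intervals$total_remodelled[-1]
  expect_gt(first, 10 * max(later))

  dr <- gen_ablation_masks("drift", n_frames = 5, seed = 1)
  acd <- area_change(dr)
  expect_true(all(acd$intervals$total_remodelled > 0))
  expect_true(all(abs(acd$intervals$net) < acd$intervals$total_remodelled))
})
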