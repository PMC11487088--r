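test_that("straightness covers the closed-form cases", {
  expect_equal(track_summary(track("a", 0:2, c(0, 1, 2), c(0, 0, 0)))$straightness, 1)
  loop <- track("b", 0:4, c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(track_summary(loop)$straightness, 0)
  lshape <- track("c", 0:2, c(0, 1, 1), c(0, 0, 1))
  expect_equal(track_summary(lshape)$straightness, sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(track_summary(track("d", 0, 1, 1)), ">= 2 samples")
})

test_that("z statistics refuse 2D tracks instead of returning zero", {
  t2 <- track("p", 0:2, 1:3, 1:3)
  expect_error(z_displacement(t2), "2D")
  t3 <- track("q", 0:2, 1:3, 1:3, z = c(5, 6, 9))
  expect_equal(z_displacement(t3), 4)
})

test_that("linearisation decomposes displacement in the curve frame", {
  horiz <- cbind(c(0, 100), c(0, 0))
  par_tr <- track("par", c(0, 60), c(10, 30), c(5, 5))
  lp <- linearise(par_tr, horiz)
  expect_equal(lp$d_normal, 0)
  expect_equal(lp$d_tangential, 20)
  expect_equal(lp$s0, 10)
  expect_equal(lp$lateral0, 5)  # +y is +90 deg CCW from the +x tangent

  perp_tr <- track("perp", c(0, 60), c(10, 10), c(0, 8))
  lq <- linearise(perp_tr, horiz)
  expect_equal(lq$d_tangential, 0)
  expect_equal(lq$d_normal, 8)
})

test_that("arc-length projection is exact at polyline vertices", {
  th <- seq(0, pi / 2, length.out = 200)
  quarter <- cbind(10 * cos(th), 10 * sin(th))
  k <- 57
  seg <- sqrt(rowSums(diff(quarter)^2))
  s_true <- sum(seg[seq_len(k - 1)])
  tr <- track("arc", c(0, 10), x = c(quarter[k, 1], quarter[k, 1] + 1),
              y = c(quarter[k, 2], quarter[k, 2]))
  expect_equal(linearise(tr, quarter)$s0, s_true, tolerance = 1e-6)
})

test_that("tangential/normal components preserve the net displacement norm", {
  set.seed(8)
  curve <- cbind(cumsum(runif(6, 5, 15)), cumsum(rnorm(6, 0, 4)))
  for (i in 1:20) {
    tr <- track(paste0("r", i), c(0, 30), x = rnorm(2, 30, 15),
                y = rnorm(2, 10, 8))
    l <- linearise(tr, curve)
    net2 <- (tr$x[2] - tr$x[1])^2 + (tr$y[2] - tr$y[1])^2
    expect_equal(l$d_tangential^2 + l$d_normal^2, net2,
                 tolerance = 1e-6 * max(net2, 1))
  }
})

test_that("displacement fields keep one vector per track and flag zeros", {
  trs <- track_set(list(
    track("m", c(0, 10), c(0, 3), c(0, 4)),
    track("s", c(0, 10), c(5, 5), c(5, 5))))
  f <- displacement_field(trs)
  expect_equal(nrow(f), 2)
  expect_equal(f$dx[f$track_id == "m"], 3)
  expect_equal(f$dy[f$track_id == "m"], 4)
  expect_true(f$zero[f$track_id == "s"])
  expect_false(f$zero[f$track_id == "m"])
})

test_that("two rays aimed at one point intersect exactly there", {
  g <- make_geometry()
  target <- c(20, 45)
  stopifnot(points_in_polygon(target[1], target[2], g$tectum_outline))
  field <- data.frame(track_id = c("a", "b"),
                      x0 = c(-40, 80), y0 = c(10, 20),
                      dx = c(target[1] - -40, target[1] - 80) * 0.3,
                      dy = c(target[2] - 10, target[2] - 20) * 0.3,
                      zero = FALSE)
  cv <- convergence(field, g)
  expect_true(cv$defined)
  expect_equal(unname(cv$centroid), target, tolerance = 1e-9)
})

test_that("parallel displacement fields give an undefined convergence", {
  g <- make_geometry()
  field <- data.frame(track_id = c("a", "b"), x0 = c(0, 10), y0 = c(10, 10),
                      dx = c(1, 1), dy = c(0.2, 0.2), zero = FALSE)
  cv <- convergence(field, g)
  expect_false(cv$defined)
  expect_equal(cv$n_pairs_used, 0L)
})

test_that("noisy radial fields recover the planted convergence point", {
  g <- make_geometry()
  target <- c(10, 50)
  errs <- vapply(1:20, function(s) {
    ts <- radial_tracks_toward(target, n_tracks = 20, noise = 1, seed = s,
                               geometry = g)
    cv <- convergence(displacement_field(ts), g)
    sqrt(sum((cv$centroid - target)^2))
  }, numeric(1))
  expect_lt(max(errs), 5)
})

test_that("convergence is equivariant under translation", {
  g <- make_geometry()
  target <- c(10, 50)
  ts <- radial_tracks_toward(target, n_tracks = 12, noise = 0.5, seed = 3,
                             geometry = g)
  f <- displacement_field(ts)
  cv <- convergence(f, g)
  shift <- c(7, -4)
  f2 <- transform(f, x0 = x0 + shift[1], y0 = y0 + shift[2])
  g2 <- g
  for (nm in c("tectum_outline", "pvz_band", "neuropil_region",
               "rostrocaudal_curve"))
    g2[[nm]] <- sweep(g[[nm]], 2, -shift)
  g2$injury_center <- g$injury_center + shift
  g2$origin <- g$origin + shift
  cv2 <- convergence(f2, g2)
  expect_equal(cv2$centroid, cv$centroid + shift, tolerance = 1e-9)
})
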