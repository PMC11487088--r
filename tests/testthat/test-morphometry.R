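square_stack <- function(side = 10, n = 1, z_step = 2) {
  outline_stack(lapply(seq_len(n), function(z)
    list(z_index = z,
         vertices = cbind(c(0, side, side, 0), c(0, 0, side, side)))),
    z_step = z_step)
}

test_that("injury volume is exact for prisms and close for spheres", {
  expect_equal(injury_volume(square_stack(10, 1, 2)), 200)
  expect_equal(injury_volume(square_stack(10, 5, 2)), 1000)
  # discretised sphere, r = 20 um, 1 um plane spacing
  r <- 20
  zc <- seq(-r + 0.5, r - 0.5, by = 1)
  circ <- function(rad) {
    th <- seq(0, 2 * pi, length.out = 129)[-129]
    cbind(rad * cos(th), rad * sin(th))
  }
  sph <- outline_stack(lapply(seq_along(zc), function(i)
    list(z_index = i, vertices = circ(sqrt(r^2 - zc[i]^2)))), z_step = 1)
  v_true <- 4 / 3 * pi * r^3
  expect_close(injury_volume(sph), v_true, 0.03 * v_true)
  expect_error(injury_volume(outline_stack(list(), z_step = 1)), "empty")
})

test_that("volume is invariant to vertex order and additive over planes", {
  poly <- cbind(c(0, 8, 10, 3), c(0, 1, 9, 7))
  os <- outline_stack(list(list(z_index = 1, vertices = poly)), z_step = 3)
  rot <- poly[c(3, 4, 1, 2), ]
  rev_ <- poly[4:1, ]
  os_rot <- outline_stack(list(list(z_index = 1, vertices = rot)), z_step = 3)
  os_rev <- outline_stack(list(list(z_index = 1, vertices = rev_)), z_step = 3)
  expect_equal(injury_volume(os_rot), injury_volume(os))
  expect_equal(injury_volume(os_rev), injury_volume(os))
  both <- outline_stack(list(list(z_index = 1, vertices = poly),
                             list(z_index = 2, vertices = rot)), z_step = 3)
  expect_equal(injury_volume(both), 2 * injury_volume(os))
})

test_that("repair index follows its defining ratio", {
  expect_equal(repair_index(1000, 1000)$ri, 0)
  expect_equal(repair_index(1000, 0)$ri, 1)
  expect_equal(repair_index(2000, 500)$ri, 0.75)
  expect_true(repair_index(2000, 500)$closed)
  expect_false(repair_index(2000, 1500)$closed)
  expect_lt(repair_index(1000, 1500)$ri, 0)  # enlargement allowed
  expect_error(repair_index(0, 10), "positive")
  # strictly decreasing in the late volume
  ris <- vapply(seq(0, 2000, 100), function(v) repair_index(1000, v)$ri,
                numeric(1))
  expect_true(all(diff(ris) < 0))
})

test_that("enlarged fraction counts negative repair indices", {
  expect_equal(enlarged_fraction(c(-0.2, 0.3, -0.1, 0.8)), 50)
  expect_equal(enlarged_fraction(rep(0.4, 5)), 0)
})

test_that("packing density recovers designed foreground fractions", {
  skip_if_not_installed("EBImage")
  # ROI fully covered by foreground
  img <- matrix(0, 60, 60); img[11:50, 11:50] <- 1
  roi_in <- cbind(c(15, 45, 45, 15), c(15, 15, 45, 45))
  expect_equal(packing_density(img, roi_in, blur_sigma = 0), 1)
  # half-plane foreground
  img2 <- matrix(0, 60, 60); img2[, 31:60] <- 1
  whole <- cbind(c(0, 60, 60, 0), c(0, 0, 60, 60))
  expect_close(packing_density(img2, whole, blur_sigma = 0), 0.5, 1 / 60)
  # hexagonal disc packing with a known fill fraction
  r <- 4; sx <- 2 * r + 2; sy <- (2 * r + 2) * sqrt(3) / 2
  img3 <- matrix(0, 120, 120)
  yy <- row(img3); xx <- col(img3)
  centres <- expand.grid(i = 0:20, j = 0:20)
  for (k in seq_len(nrow(centres))) {
    cx <- centres$i[k] * sx + (centres$j[k] %% 2) * sx / 2
    cy <- centres$j[k] * sy
    if (cx > 130 || cy > 130) next
    img3[(xx - cx)^2 + (yy - cy)^2 <= r^2] <- 1
  }
  roi3 <- cbind(c(20, 100, 100, 20), c(20, 20, 100, 100))
  ny <- nrow(img3)
  truth <- {
    inroi <- xx >= 20 & xx <= 100 & yy >= 20 & yy <= 100
    mean(img3[inroi])
  }
  est <- packing_density(img3, roi3, blur_sigma = 0.8)
  expect_close(est, truth, 0.03)
  expect_error(packing_density(matrix(1, 5, 5), roi_in), "flat")
})

test_that("area change bookkeeping is exact", {
  px <- 0.5
  d <- function(cx, cy, r) {
    m <- matrix(FALSE, 40, 40)
    m[(col(m) - cx)^2 + (row(m) - cy)^2 <= r^2] <- TRUE
    m
  }
  same <- mask_series(list(d(20, 20, 10), d(20, 20, 10)), c(0, 15), px)
  ac0 <- area_change(same)
  expect_true(all(unlist(ac0$intervals[, 3:6]) == 0))
  expect_equal(ac0$cumulative$area, c(0, 0))

  disjoint <- mask_series(list(d(10, 10, 5), d(30, 30, 6)), c(0, 15), px)
  acd <- area_change(disjoint)
  expect_equal(acd$intervals$gained, sum(d(30, 30, 6)) * px^2)
  expect_equal(acd$intervals$lost, sum(d(10, 10, 5)) * px^2)

  # concentric shrinkage approximates the analytic annulus
  shrink <- mask_series(list(d(20, 20, 10), d(20, 20, 8)), c(0, 15), px)
  acs <- area_change(shrink)
  ann <- pi * (100 - 64) * px^2
  expect_close(acs$intervals$lost, ann, 0.1 * ann)
  expect_equal(acs$intervals$gained, 0)

  # conservation: gained - lost equals the raw area difference, exactly
  set.seed(5)
  masks <- lapply(1:5, function(i) matrix(runif(400) < 0.4, 20, 20))
  ms <- mask_series(masks, (0:4) * 10, px)
  ac <- area_change(ms)
  dareas <- diff(vapply(masks, sum, numeric(1))) * px^2
  expect_identical(ac$intervals$net, dareas)
  expect_true(all(ac$intervals$total_remodelled >= abs(ac$intervals$net)))
})

test_that("edge distance tracks mask boundaries and recoil speed", {
  px <- 0.5
  d <- function(cx, cy, r) {
    m <- matrix(FALSE, 80, 80)
    m[(col(m) - cx)^2 + (row(m) - cy)^2 <= r^2] <- TRUE
    m
  }
  centre_um <- c((40 - 0.5) * px, (40 - 0.5) * px)
  ms <- mask_series(list(d(40, 40, 20)), times = 0, pixel_size = px)
  ed <- edge_distance(ms, centre_um)
  expect_close(ed$distance, 20 * px, px)

  # mask translating away at constant speed: linear distance series
  v_px <- 2  # px / frame
  ms2 <- mask_series(lapply(0:4, function(i) d(56 + v_px * i, 40, 6)),
                     times = (0:4) * 10, pixel_size = px)
  ed2 <- edge_distance(ms2, centre_um)
  expect_true(all(diff(ed2$distance) > 0))
  sp <- recoil_speed(ed2, window = c(10, 40))
  expect_close(sp, v_px * px / 10, 0.2 * v_px * px / 10)
  expect_error(edge_distance(
    mask_series(list(matrix(FALSE, 4, 4)), 0, px), c(0, 0)), "empty mask")
})
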