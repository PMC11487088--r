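no_motility <- function(...) {
  mechanics_params(migration_speed = c(neuron = 0, microglia = 0, skin = 0),
                   ...)
}

pure_elastic <- function(k_e) {
  mechanics_params(k_e = k_e,
                   migration_speed = c(neuron = 0, microglia = 0, skin = 0),
                   c_rep = c(neuron = 0, microglia = 0, skin = 0),
                   c_adh = c(neuron = 0, microglia = 0, skin = 0))
}

test_that("default mechanics parameters carry the published per-kind values", {
  p <- mechanics_params()
  expect_equal(p$persistence_time, c(neuron = 10, microglia = 10, skin = 0))
  expect_equal(p$migration_speed, c(neuron = 0.01, microglia = 1, skin = 0))
  expect_equal(p$c_rep, c(neuron = 5, microglia = 5, skin = 5))
  expect_equal(p$c_adh, c(neuron = 0.1, microglia = 0, skin = 0))
  expect_equal(p$k_e, 5e-7)
  expect_equal(p$eta, 1)
})

test_that("the velocity law handles the canonical two-body cases", {
  p <- no_motility()
  # isolated agent: zero velocity
  st1 <- agent_state(0, 0, "neuron", p)
  expect_equal(compute_velocity(1, st1, p), c(0, 0))
  # overlapping neurons: equal and opposite, separating
  st2 <- agent_state(c(0, 4), c(0, 0), c("neuron", "neuron"),
                     mechanics_params(c_adh = c(neuron = 0, microglia = 0,
                                                skin = 0),
                                      migration_speed = c(neuron = 0,
                                                          microglia = 0,
                                                          skin = 0)))
  v1 <- compute_velocity(1, st2, p)
  v2 <- compute_velocity(2, st2, p)
  expect_equal(v1, -v2)
  expect_lt(v1[1], 0)  # agent 1 pushed towards -x
  # microglia-neuron pair, pure elastic: approach speed k_e * d each
  pe <- pure_elastic(0.01)
  st3 <- agent_state(c(0, 50), c(0, 0), c("neuron", "microglia"), pe)
  expect_equal(compute_velocity(1, st3, pe), c(0.01 * 50, 0))
  expect_equal(compute_velocity(2, st3, pe), c(-0.01 * 50, 0))
  # neuron-neuron pair beyond contact: no elastic force
  st4 <- agent_state(c(0, 50), c(0, 0), c("neuron", "neuron"), pe)
  expect_equal(compute_velocity(1, st4, pe), c(0, 0))
  # skin agents never move
  st5 <- agent_state(c(0, 2), c(0, 0), c("skin", "microglia"), pe)
  expect_equal(compute_velocity(1, st5, pe), c(0, 0))
})

test_that("pairwise forces exchange momentum (centroid pinned)", {
  p <- no_motility()
  set.seed(6)
  st <- agent_state(runif(12, 0, 30), runif(12, 0, 30),
                    sample(c("neuron", "microglia"), 12, replace = TRUE), p)
  vel <- t(vapply(1:12, compute_velocity, numeric(2), state = st, params = p))
  drift <- colMeans(vel) * 0.1  # one Euler step of the centroid
  expect_lt(max(abs(drift)), 1e-9)
})

test_that("two-body elastic separation decays at rate 2 k_e / eta", {
  ke <- 0.01
  pe <- pure_elastic(ke)
  st <- agent_state(c(0, 50), c(0, 0), c("neuron", "microglia"), pe)
  # compiled path, dt small enough for the Euler error to stay below 1e-4
  res <- tectrepair:::sim_run_cpp(st$x, st$y, c(1L, 2L), st$radius, c(0, 0), c(0, 0),
                     c(0, 0), c(0, 0), st$dirx, st$diry, st$timer,
                     ke, Inf, 1, 1.25, 0.002, 50000L, 50000L)
  sep <- abs(res$x[2, 2] - res$x[1, 2])
  expect_close(sep / (50 * exp(-2 * ke * 100)), 1, 1e-4)
})

test_that("reference R stepper and compiled core agree", {
  p <- no_motility()
  set.seed(9)
  st <- agent_state(runif(15, 0, 40), runif(15, 0, 40),
                    sample(c("neuron", "microglia", "skin"), 15,
                           replace = TRUE), p)
  kind_i <- match(st$kind, c("neuron", "microglia", "skin"))
  n_steps <- 20L
  res <- tectrepair:::sim_run_cpp(st$x, st$y, kind_i, st$radius,
                     unname(p$migration_speed[st$kind]),
                     unname(p$persistence_time[st$kind]),
                     unname(p$c_rep[st$kind]), unname(p$c_adh[st$kind]),
                     st$dirx, st$diry, st$timer,
                     p$k_e, p$elastic_cutoff, p$eta,
                     p$adhesion_reach_factor, 0.05, n_steps, n_steps)
  sr <- st
  for (i in seq_len(n_steps)) sr <- step_agents(sr, p, 0.05)
  expect_equal(res$x[, 2], sr$x, tolerance = 1e-10)
  expect_equal(res$y[, 2], sr$y, tolerance = 1e-10)
})

test_that("hexagonal packing produces a clipped triangular lattice", {
  sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  pts <- pack_positions(sq, 5)
  expect_true(all(points_in_polygon(pts[, 1], pts[, 2], sq)))
  xs <- sort(unique(pts[, 1])); ys <- sort(unique(pts[, 2]))
  expect_equal(min(diff(sort(unique(round(pts[, 2], 9))))), 5 * sqrt(3),
               tolerance = 1e-9)
  # same-row spacing is one diameter
  row1 <- sort(pts[pts[, 2] == ys[1], 1])
  expect_true(all(abs(diff(row1) - 10) < 1e-9))
  expect_identical(pack_positions(sq, 5, seed = 2, jitter = 1),
                   pack_positions(sq, 5, seed = 2, jitter = 1))
  expect_error(pack_positions(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)), 5),
               "area")
})

test_that("seeded simulations are byte-identical and conserve agents", {
  cfg <- sim_config(seed = 4, duration = 60, n_microglia = 8)
  r1 <- run_sim(cfg)
  r2 <- run_sim(cfg)
  expect_identical(r1, r2)
  expect_equal(unique(vapply(r1$snapshots, nrow, numeric(1))), r1$n_agents)
  # skin agents never move over the whole run
  skin0 <- subset(r1$snapshots[[1]], kind == "skin")
  skinN <- subset(r1$snapshots[[length(r1$snapshots)]], kind == "skin")
  expect_identical(skin0$x, skinN$x)
  expect_identical(skin0$y, skinN$y)
})
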