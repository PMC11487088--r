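# 2D multi-agent tissue model of the injured optic tectum.
#
# Three agent kinds: neurons (slow random motion, packed in the PVZ band),
# microglia (motile, exerting Hooke elastic traction on every agent they
# pair with), and skin (immobile anchors along the tectum boundary).
# Overdamped dynamics: V_i = (1/eta) * [sum_j(F_adh + F_rep + F_trac) +
# F_loc], integrated by forward Euler. Adhesion and repulsion use the
# polynomial potentials of PhysiCell-style centre-based models, with
# per-pair amplitudes combined as geometric means so pair forces are
# antisymmetric (momentum exchange).

KIND_LEVELS <- c("neuron", "microglia", "skin")

#' Mechanics parameters of the tissue model
#'
#' Defaults are the published per-kind parameter set for
#' neurons/microglia/skin: persistence time 10/10/0 min, migration speed
#' 0.01/1/0 um/min, relative repulsion 5/5/5, relative adhesion 0.1/0/0,
#' elastic coefficient 5e-7 1/min for all kinds. Effective viscosity
#' `eta` is fixed at 1 so the relative amplitudes act directly as
#' velocity scales. Agent radii and adhesion reach are not published;
#' defaults are configurable.
#'
#' @param persistence_time,migration_speed,c_rep,c_adh Named numeric
#'   vectors over kinds `neuron`, `microglia`, `skin`.
#' @param k_e Elastic traction coefficient (1/min).
#' @param eta Effective medium viscosity (dimensionless).
#' @param radius Agent radii (um) per kind.
#' @param adhesion_reach_factor Adhesion reach as a multiple of the summed
#'   radii (the repulsion reach).
#' @param elastic_cutoff Maximum range of the elastic term (um); `Inf`
#'   (default) applies it globally, since at the published amplitude a
#'   contact-range elastic term is numerically negligible.
#' @return An object of class `mechanics_params`.
#' @export
mechanics_params <- function(
    persistence_time = c(neuron = 10, microglia = 10, skin = 0),
    migration_speed = c(neuron = 0.01, microglia = 1, skin = 0),
    c_rep = c(neuron = 5, microglia = 5, skin = 5),
    c_adh = c(neuron = 0.1, microglia = 0, skin = 0),
    k_e = 5e-7,
    eta = 1,
    radius = c(neuron = 3, microglia = 5, skin = 5),
    adhesion_reach_factor = 1.25,
    elastic_cutoff = Inf) {
  for (v in list(persistence_time, migration_speed, c_rep, c_adh, radius))
    stopifnot(identical(sort(names(v)), sort(KIND_LEVELS)))
  if (any(radius <= 0)) stop("radii must be positive")
  if (eta <= 0) stop("eta must be positive")
  structure(list(persistence_time = persistence_time,
                 migration_speed = migration_speed,
                 c_rep = c_rep, c_adh = c_adh, k_e = k_e, eta = eta,
                 radius = radius,
                 adhesion_reach_factor = adhesion_reach_factor,
                 elastic_cutoff = elastic_cutoff),
            class = "mechanics_params")
}

#' Create a set of agents
#'
#' @param x,y Positions (um).
#' @param kind Character vector over `"neuron"`, `"microglia"`, `"skin"`.
#' @param params A [mechanics_params()] supplying radii.
#' @return An object of class `agent_state`: data frame with id, kind,
#'   position, radius, motility direction and timer.
#' @export
agent_state <- function(x, y, kind, params = mechanics_params()) {
  kind <- match.arg(kind, KIND_LEVELS, several.ok = TRUE)
  n <- length(x)
  stopifnot(length(y) == n, length(kind) == n)
  df <- data.frame(id = seq_len(n), kind = kind, x = as.numeric(x),
                   y = as.numeric(y),
                   radius = unname(params$radius[kind]),
                   dirx = 1, diry = 0,
                   timer = unname(params$persistence_time[kind]),
                   stringsAsFactors = FALSE)
  class(df) <- c("agent_state", "data.frame")
  df
}

#' Velocity of one agent under the force balance
#'
#' Reference implementation of the velocity law for a single agent
#' (the compiled simulation core applies the same physics to all agents
#' at once): repulsion of magnitude `sqrt(c_rep_i c_rep_j) (1 - d/R)^2`
#' inside the contact range `R = r_i + r_j`; adhesion of magnitude
#' `sqrt(c_adh_i c_adh_j) (1 - d/R_A)^2` inside the adhesion reach
#' `R_A = adhesion_reach_factor * R`; Hooke elastic traction
#' `k_e (r_j - r_i)` for every pair containing at least one microglia
#' (within `elastic_cutoff`); locomotion `speed * motility_direction`.
#' Skin agents always have zero velocity.
#'
#' @param i Index of the agent in `state`.
#' @param state An [agent_state()].
#' @param params A [mechanics_params()].
#' @return Numeric length-2 velocity (um/min).
#' @export
compute_velocity <- function(i, state, params = mechanics_params()) {
  stopifnot(inherits(state, "agent_state"))
  ki <- state$kind[i]
  if (ki == "skin") return(c(0, 0))
  pos_i <- c(state$x[i], state$y[i])
  f <- c(0, 0)
  for (j in seq_len(nrow(state))) {
    if (j == i) next
    dvec <- c(state$x[j], state$y[j]) - pos_i
    d <- sqrt(sum(dvec^2))
    R <- state$radius[i] + state$radius[j]
    RA <- params$adhesion_reach_factor * R
    u <- if (d > 1e-12) dvec / d else {
      th <- stats::runif(1, 0, 2 * pi)  # coincident: seeded random direction
      c(cos(th), sin(th))
    }
    kj <- state$kind[j]
    if (d < R) {
      cr <- sqrt(params$c_rep[[ki]] * params$c_rep[[kj]])
      f <- f - cr * (1 - d / R)^2 * u
    }
    ca <- sqrt(params$c_adh[[ki]] * params$c_adh[[kj]])
    if (ca > 0 && d < RA) f <- f + ca * (1 - d / RA)^2 * u
    if ((ki == "microglia" || kj == "microglia") &&
        d <= params$elastic_cutoff) {
      f <- f + params$k_e * dvec
    }
  }
  f_loc <- params$migration_speed[[ki]] * c(state$dirx[i], state$diry[i])
  (f + f_loc) / params$eta
}

#' Advance an agent state by one Euler step
#'
#' Reference single-step integrator built on [compute_velocity()];
#' motility directions are resampled uniformly when the persistence timer
#' expires. Long simulations should use [run_sim()], which runs the same
#' physics in compiled code.
#'
#' @param state An [agent_state()].
#' @param params A [mechanics_params()].
#' @param dt Time step (min).
#' @return Updated [agent_state()].
#' @export
step_agents <- function(state, params = mechanics_params(), dt = 0.1) {
  if (dt <= 0) stop("dt must be positive")
  vel <- t(vapply(seq_len(nrow(state)), compute_velocity, numeric(2),
                  state = state, params = params))
  mobile <- state$kind != "skin"
  out <- state
  # resample expired motility directions (ascending id order)
  for (i in which(mobile)) {
    sp <- params$migration_speed[[state$kind[i]]]
    tp <- params$persistence_time[[state$kind[i]]]
    if (sp > 0 && tp > 0) {
      out$timer[i] <- out$timer[i] - dt
      if (out$timer[i] <= 0) {
        th <- stats::runif(1, 0, 2 * pi)
        out$dirx[i] <- cos(th); out$diry[i] <- sin(th)
        out$timer[i] <- tp
      }
    }
  }
  out$x[mobile] <- state$x[mobile] + vel[mobile, 1] * dt
  out$y[mobile] <- state$y[mobile] + vel[mobile, 2] * dt
  if (any(!is.finite(out$x)) || any(!is.finite(out$y))) {
    bad <- which(!is.finite(out$x) | !is.finite(out$y))[1]
    stop("non-finite position for agent ", bad)
  }
  out
}

#' Hexagonal close packing of disc centres inside a polygon
#'
#' Rows spaced `radius * sqrt(3)` apart with alternate-row offset
#' `radius`, clipped to centres lying inside the region.
#'
#' @param region Polygon matrix (um).
#' @param radius Disc radius (um).
#' @param seed Integer seed for the optional jitter.
#' @param jitter Uniform positional jitter amplitude (um) applied to each
#'   centre.
#' @return Two-column matrix of centres.
#' @export
pack_positions <- function(region, radius, seed = 1L, jitter = 0) {
  region <- as_polygon(region)
  if (radius <= 0) stop("radius must be positive")
  if (polygon_area(region) <= pi * radius^2)
    stop("region area must exceed one disc area")
  bb <- apply(region, 2, range)
  xs <- seq(bb[1, 1], bb[2, 1], by = 2 * radius)
  ys <- seq(bb[1, 2], bb[2, 2], by = radius * sqrt(3))
  pts <- do.call(rbind, lapply(seq_along(ys), function(r) {
    off <- if (r %% 2 == 0) radius else 0
    cbind(xs + off, ys[r])
  }))
  if (jitter > 0) {
    pts <- with_seed(seed, pts + matrix(stats::runif(length(pts), -jitter,
                                                     jitter), ncol = 2))
  }
  keep <- points_in_polygon(pts[, 1], pts[, 2], region)
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts)) stop("no packed positions fall inside the region")
  pts
}

#' Simulation configuration
#'
#' @param geometry A `tectum_geometry`; its injury disc defines the wound.
#' @param params A [mechanics_params()].
#' @param dt Integration step (min).
#' @param duration Simulated time (min).
#' @param snapshot_interval Minutes between stored snapshots (must be a
#'   multiple of `dt`).
#' @param seed Integer seed (one RNG stream drives the whole run).
#' @param n_microglia Number of microglia agents placed in the neuropil.
#' @param elastic_gain Dimensionless multiplier applied to `k_e` for the
#'   wound-closure runs. The published elastic amplitude is a relative
#'   coefficient of the source framework; within this package's velocity
#'   scale a gain is required for traction to act on the closure
#'   timescale, and it is calibrated once against the closure/sweep
#'   behaviour (see the methods vignette).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(geometry = make_geometry(), params = mechanics_params(),
                       dt = 0.1, duration = 1440, snapshot_interval = 15,
                       seed = 1L, n_microglia = 60L, elastic_gain = 25) {
  if (dt <= 0) stop("dt must be positive")
  steps_per_snap <- snapshot_interval / dt
  if (abs(steps_per_snap - round(steps_per_snap)) > 1e-9)
    stop("snapshot_interval must be a multiple of dt")
  if (duration < snapshot_interval) stop("duration too short")
  structure(list(geometry = geometry, params = params, dt = dt,
                 duration = duration, snapshot_interval = snapshot_interval,
                 seed = as.integer(seed), n_microglia = as.integer(n_microglia),
                 elastic_gain = elastic_gain),
            class = "sim_config")
}

skin_ring_positions <- function(geometry, spacing) {
  outline <- geometry$tectum_outline * 1.06  # just outside the tissue
  seg <- rbind(outline, outline[1, , drop = FALSE])
  d <- sqrt(rowSums(diff(seg)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  targets <- seq(0, total - spacing / 2, by = spacing)
  t(vapply(targets, function(si) {
    k <- findInterval(si, s, rightmost.closed = TRUE)
    frac <- (si - s[k]) / d[k]
    seg[k, ] + frac * (seg[k + 1, ] - seg[k, ])
  }, numeric(2)))
}

init_agents <- function(config) {
  geom <- config$geometry
  par <- config$params
  neurons <- pack_positions(geom$pvz_band, par$radius[["neuron"]])
  wound_c <- geom$injury_center
  d2w <- (neurons[, 1] - wound_c[1])^2 + (neurons[, 2] - wound_c[2])^2
  neurons <- neurons[d2w > geom$injury_radius^2, , drop = FALSE]
  mg <- if (config$n_microglia > 0)
    sample_in_polygon(config$n_microglia, geom$neuropil_region)
  else matrix(numeric(0), 0, 2)
  skin <- skin_ring_positions(geom, 2 * par$radius[["skin"]])
  agent_state(
    x = c(neurons[, 1], mg[, 1], skin[, 1]),
    y = c(neurons[, 2], mg[, 2], skin[, 2]),
    kind = c(rep("neuron", nrow(neurons)), rep("microglia", nrow(mg)),
             rep("skin", nrow(skin))),
    params = par
  )
}

# Gaussian kernel density of neuron agents evaluated at query points.
neuron_density_at <- function(px, py, nx, ny, sigma) {
  dens <- numeric(length(px))
  for (i in seq_along(nx)) {
    dens <- dens + exp(-((px - nx[i])^2 + (py - ny[i])^2) / (2 * sigma^2))
  }
  dens / (2 * pi * sigma^2)
}

wound_grid <- function(geometry, spacing = 2) {
  wc <- geometry$injury_center; r <- geometry$injury_radius
  gx <- seq(wc[1] - r, wc[1] + r, by = spacing)
  gy <- seq(wc[2] - r, wc[2] + r, by = spacing)
  g <- expand.grid(x = gx, y = gy)
  keep <- (g$x - wc[1])^2 + (g$y - wc[2])^2 <= r^2
  g[keep, , drop = FALSE]
}

pvz_reference_grid <- function(geometry, spacing = 3) {
  bb <- apply(geometry$pvz_band, 2, range)
  g <- expand.grid(x = seq(bb[1, 1], bb[2, 1], by = spacing),
                   y = seq(bb[1, 2], bb[2, 2], by = spacing))
  keep <- points_in_polygon(g$x, g$y, geometry$pvz_band)
  g <- g[keep, , drop = FALSE]
  wc <- geometry$injury_center
  far <- (g$x - wc[1])^2 + (g$y - wc[2])^2 > (1.5 * geometry$injury_radius)^2
  g[far, , drop = FALSE]
}

#' Run the multi-agent wound-closure simulation
#'
#' Initialises a hexagonally packed neuron field in the PVZ band with the
#' injury disc cleared, microglia spread in the neuropil, and a ring of
#' immobile skin agents outside the outline; integrates the force balance
#' in compiled code; and derives the experimental-style readouts: a
#' wound-closure curve (normalised Gaussian-rendered neuron density
#' inside the wound disc over time, mirroring the ROI-intensity
#' measurement) and a repair analogue `1 - empty_end / empty_start`,
#' where a wound grid point is "empty" while its neuron density is below
#' half the median density of the surrounding PVZ at the same time point.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_result` with `snapshots` (list of
#'   `agent_state` data frames), `times` (min), `closure_curve`
#'   (normalised [kinetic_curve()], `NULL` if the wound density never
#'   changes), `repair_analogue`, `n_agents`, `config`.
#' @export
run_sim <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  par <- config$params
  set.seed(config$seed)
  state <- init_agents(config)
  kind_i <- match(state$kind, KIND_LEVELS)
  n_steps <- round(config$duration / config$dt)
  snap_every <- round(config$snapshot_interval / config$dt)
  n_steps <- (n_steps %/% snap_every) * snap_every

  res <- sim_run_cpp(
    state$x, state$y, kind_i, state$radius,
    unname(par$migration_speed[state$kind]),
    unname(par$persistence_time[state$kind]),
    unname(par$c_rep[state$kind]), unname(par$c_adh[state$kind]),
    state$dirx, state$diry, state$timer,
    par$k_e * config$elastic_gain, par$elastic_cutoff, par$eta,
    par$adhesion_reach_factor, config$dt, n_steps, snap_every)

  times <- res$t
  snapshots <- lapply(seq_along(times), function(s) {
    st <- state
    st$x <- res$x[, s]; st$y <- res$y[, s]
    st
  })

  wg <- wound_grid(config$geometry)
  ref <- pvz_reference_grid(config$geometry)
  sigma <- par$radius[["neuron"]]
  # emptiness is scored on the rim-eroded disc: points within one cell
  # radius of the wound boundary lie under the Gaussian shoulder of intact
  # rim cells and would flip with sub-cell-size rearrangements
  wc <- config$geometry$injury_center
  core <- (wg$x - wc[1])^2 + (wg$y - wc[2])^2 <=
    (config$geometry$injury_radius - sigma)^2
  closure_vals <- numeric(length(times))
  empty_frac <- numeric(length(times))
  for (s in seq_along(times)) {
    st <- snapshots[[s]]
    nx <- st$x[st$kind == "neuron"]; ny <- st$y[st$kind == "neuron"]
    dens_w <- neuron_density_at(wg$x, wg$y, nx, ny, sigma)
    dens_ref <- neuron_density_at(ref$x, ref$y, nx, ny, sigma)
    closure_vals[s] <- mean(dens_w)
    empty_frac[s] <- mean(dens_w[core] < 0.5 * stats::median(dens_ref))
  }
  repair <- if (empty_frac[1] > 0)
    1 - empty_frac[length(empty_frac)] / empty_frac[1] else NA_real_
  curve <- kinetic_curve(times, closure_vals)
  ncurve <- tryCatch(normalise_curve(curve), error = function(e) NULL)

  structure(list(snapshots = snapshots, times = times,
                 closure_curve = ncurve, raw_closure = curve,
                 repair_analogue = repair,
                 n_agents = nrow(state), config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(paste0("<sim_result> %d agents, %d snapshot(s) over %g min\n",
                     "  repair analogue = %.4f\n"),
              x$n_agents, length(x$times), max(x$times), x$repair_analogue))
  invisible(x)
}

#' Sweep the repair analogue over microglia counts
#'
#' Runs seeded replicate simulations for each microglia count and reports
#' the mean and standard deviation of the repair analogue, emulating the
#' in silico microglia-depletion experiment (linear rise then plateau).
#'
#' @param config Base [sim_config()].
#' @param counts Ascending integer vector of microglia counts.
#' @param replicates Replicate runs per count (distinct seeds).
#' @param seed Base seed; replicate seeds are derived deterministically.
#' @return Data frame with `n_microglia`, `mean_ri`, `sd_ri`, `n`.
#' @export
sweep_microglia <- function(config = sim_config(), counts = c(0, 4, 8, 16, 32),
                            replicates = 3L, seed = 1L) {
  if (is.unsorted(counts)) stop("counts must be sorted ascending")
  rows <- lapply(seq_along(counts), function(ci) {
    ris <- vapply(seq_len(replicates), function(r) {
      cfg <- config
      cfg$n_microglia <- as.integer(counts[ci])
      cfg$seed <- as.integer(seed + 1000L * ci + r)
      run_sim(cfg)$repair_analogue
    }, numeric(1))
    data.frame(n_microglia = counts[ci], mean_ri = mean(ris),
               sd_ri = stats::sd(ris), n = replicates)
  })
  do.call(rbind, rows)
}
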