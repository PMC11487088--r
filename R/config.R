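# Run configuration: a key/value tree with documented defaults, strict
# unknown-key rejection, and a persisted resolved form for reproducibility.

#' Default run configuration
#'
#' Every key consumed anywhere in the package has a documented default
#' here; configuration files may override any subset, and unknown keys are
#' rejected on load.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    synth = list(
      n_tracks = 30L,
      duration = 1080,          # min (4-22 hpi window)
      frame_interval = 15,      # min, long-term imaging interval
      motion_model = "jitter",
      noise_sigma = 0.2,        # um, per-localisation measurement noise
      step_sigma = 0.3,         # um, jitter/random-walk step scale
      speed = 0.5,              # um/min, ballistic model
      amplitude = 0.8,          # fraction of start-to-centre distance
      nu = 0.004,               # 1/min, synthetic oscillator damping
      k = 1.2e-5                # 1/min^2, synthetic oscillator stiffness
    ),
    tracks = list(
      max_lag_fraction = 0.5,
      min_angle_deg = 10,
      n_perm = 200L,
      closure_threshold = 0.95
    ),
    sim = list(
      dt = 0.1,                 # min
      duration = 1440,          # min
      snapshot_interval = 15,   # min (simulated frame interval)
      n_microglia = 60L,
      elastic_gain = 25         # multiplies the elastic coefficient (calibrated)
    )
  )
}

merge_config_tree <- function(base, override, path = character()) {
  for (key in names(override)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base))
      stop("unknown configuration key: '", full, "'")
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]]))
        stop("configuration key '", full, "' must be a mapping")
      base[[key]] <- merge_config_tree(base[[key]], override[[key]],
                                       c(path, key))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a run configuration file
#'
#' Reads a YAML or JSON file and merges it over [default_config()].
#' Unknown keys raise an error naming the offending key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for
#'   pure defaults.
#' @return Resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  override <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext)
  )
  if (is.null(override)) return(cfg)
  merge_config_tree(cfg, override)
}

#' Persist a resolved configuration next to run outputs
#'
#' @param cfg Configuration list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
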