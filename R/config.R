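#' Full run configuration
#'
#' Bundles everything one simulation batch needs: the scenario, the
#' algorithm, the gain table, the sensing parameters, the controller
#' geometry, and the protocol constants (timestep, time limit, success
#' radius, repetitions, seed). Every default is the published value where one
#' exists: the gain table rows, the 0.1 m success radius, the 180 s limit,
#' 20 repetitions, 10 ms timestep.
#'
#' @param scenario a [scenario_config()] or a preset name (`"a"`, `"b"`,
#'   `"c"`).
#' @param algorithm `"rmi"`, `"szl"` or `"sc"`.
#' @param gains a [gain_table()].
#' @param sensing a [sensing_params()] list.
#' @param control a [ctrl_params()] list.
#' @param dt timestep (s).
#' @param t_max time limit (s).
#' @param success_radius success radius (m).
#' @param warmup plume spin-up (s).
#' @param n_trials batch size.
#' @param seed base seed.
#' @param out_dir output directory for the command-line tools.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = "a", algorithm = "rmi",
                       gains = gain_table(), sensing = sensing_params(),
                       control = ctrl_params(), dt = 0.01, t_max = 180,
                       success_radius = 0.1, warmup = 6,
                       n_trials = 20, seed = 1L, out_dir = ".") {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  algorithm <- match.arg(algorithm, c("rmi", "szl", "sc"))
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(gains, "gain_table"))
  if (dt <= 0) stop("`dt` must be positive")
  if (t_max <= 0) stop("`t_max` must be positive")
  if (success_radius <= 0) stop("`success_radius` must be positive")
  structure(list(scenario = scenario, algorithm = algorithm, gains = gains,
                 sensing = sensing, control = control, dt = dt,
                 t_max = t_max, success_radius = success_radius,
                 warmup = warmup, n_trials = as.integer(n_trials),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s on scenario %s: %d trial(s), seed %d\n",
              toupper(x$algorithm), x$scenario$name, x$n_trials, x$seed))
  cat(sprintf("  dt %.3g s, limit %g s, success radius %g m\n",
              x$dt, x$t_max, x$success_radius))
  invisible(x)
}

# flatten a run_config into plain lists for YAML
config_to_list <- function(cfg) {
  sc <- cfg$scenario
  gt <- cfg$gains
  list(
    scenario = list(
      name = sc$name,
      odor_source = as.numeric(sc$odor_source),
      wind_source = as.numeric(sc$wind_source),
      wind_speed = sc$wind_speed,
      mean_wind_direction = sc$mean_wind_direction,
      turbulence = sc$turbulence,
      field_bounds = as.numeric(sc$field_bounds),
      start_pose = as.numeric(sc$start_pose),
      plume = sc$plume,
      transport_wind = sc$transport_wind),
    algorithm = cfg$algorithm,
    gains = list(corrected = gt$corrected, breakpoint = gt$breakpoint,
                 v_min = gt$v_min, v_max = gt$v_max,
                 w_min = gt$w_min, w_max = gt$w_max),
    sensing = unclass(cfg$sensing),
    control = unclass(cfg$control),
    dt = cfg$dt, t_max = cfg$t_max, success_radius = cfg$success_radius,
    warmup = cfg$warmup, n_trials = cfg$n_trials, seed = cfg$seed,
    out_dir = cfg$out_dir)
}

check_keys <- function(given, allowed, where) {
  bad <- setdiff(names(given), allowed)
  if (length(bad))
    stop("unknown configuration key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

#' Load a run configuration from YAML
#'
#' Reads a (possibly partial) YAML configuration; absent fields take the
#' published defaults, unknown keys are rejected by name. An empty file gives
#' the full default configuration. `save_config()` followed by
#' `load_config()` reproduces the configuration exactly.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_keys(raw, c("scenario", "algorithm", "gains", "sensing", "control",
                    "dt", "t_max", "success_radius", "warmup", "n_trials",
                    "seed", "out_dir"), "top level")

  scenario <- if (is.null(raw$scenario)) {
    scenario_preset("a")
  } else if (is.character(raw$scenario)) {
    scenario_preset(raw$scenario)
  } else {
    s <- raw$scenario
    check_keys(s, c("name", "preset", "odor_source", "wind_source",
                    "wind_speed", "mean_wind_direction", "turbulence",
                    "field_bounds", "start_pose", "plume",
                    "transport_wind"), "scenario")
    base <- if (!is.null(s$preset)) scenario_preset(s$preset)
            else if (!is.null(s$name) && s$name %in% c("a", "b", "c"))
              scenario_preset(s$name)
            else scenario_config()
    scenario_config(
      odor_source = s$odor_source %||% base$odor_source,
      wind_source = s$wind_source %||% base$wind_source,
      wind_speed = s$wind_speed %||% base$wind_speed,
      mean_wind_direction = s$mean_wind_direction %||% base$mean_wind_direction,
      turbulence = utils::modifyList(base$turbulence,
                                     as.list(s$turbulence %||% list())),
      field_bounds = s$field_bounds %||% base$field_bounds,
      start_pose = s$start_pose %||% base$start_pose,
      plume = utils::modifyList(base$plume, as.list(s$plume %||% list())),
      transport_wind = s$transport_wind %||% base$transport_wind,
      name = s$name %||% base$name)
  }

  g <- raw$gains %||% list()
  check_keys(g, c("corrected", "breakpoint", "v_min", "v_max", "w_min",
                  "w_max"), "gains")
  gains <- gain_table(corrected = g$corrected %||% TRUE,
                      breakpoint = g$breakpoint %||% 0.7,
                      v_min = g$v_min %||% 50, v_max = g$v_max %||% 250,
                      w_min = g$w_min %||% 0.5, w_max = g$w_max %||% 3.0)

  sn <- raw$sensing %||% list()
  check_keys(sn, names(formals(sensing_params)), "sensing")
  sensing <- do.call(sensing_params, sn)

  ct <- raw$control %||% list()
  check_keys(ct, names(formals(ctrl_params)), "control")
  control <- do.call(ctrl_params, ct)

  run_config(scenario = scenario,
             algorithm = raw$algorithm %||% "rmi",
             gains = gains, sensing = sensing, control = control,
             dt = raw$dt %||% 0.01, t_max = raw$t_max %||% 180,
             success_radius = raw$success_radius %||% 0.1,
             warmup = raw$warmup %||% 6,
             n_trials = raw$n_trials %||% 20, seed = raw$seed %||% 1L,
             out_dir = raw$out_dir %||% ".")
}

#' Save a run configuration to YAML
#'
#' @param cfg a [run_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(config_to_list(cfg), path, precision = 17L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable polynomial rolling hash of a configuration, for provenance headers
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(config_to_list(cfg))),
             collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a trial log as annotated CSV
#'
#' One CSV per trial with `#`-prefixed provenance header lines (package
#' version, algorithm, scenario, seed, outcome, localization time) followed
#' by the per-tick stimulus/command log.
#'
#' @param trial a `plume_trial`.
#' @param path output file.
#' @param every keep every `every`-th tick (downsampling for export).
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trial, path, every = 1L) {
  stopifnot(inherits(trial, "plume_trial"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# mothnav trial log (package %s)",
            as.character(utils::packageVersion("mothnav"))),
    sprintf("# algorithm: %s", trial$algorithm),
    sprintf("# scenario: %s", trial$scenario),
    sprintf("# seed: %d", trial$seed),
    sprintf("# outcome: %s", trial$outcome),
    sprintf("# localization_time: %s",
            if (is.na(trial$localization_time)) "NA"
            else format(trial$localization_time)),
    sprintf("# y_odor: %s", format(trial$y_odor))), con)
  df <- trial$log
  if (every > 1L) df <- df[seq(1L, nrow(df), by = every), , drop = FALSE]
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trial log written by [write_trial_log()]
#'
#' @param path CSV file.
#' @return The log data.frame, with the header fields attached as attributes
#'   `algorithm`, `scenario`, `seed`, `outcome`, `localization_time`,
#'   `y_odor`.
#' @export
read_trial_log <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(m)) return(NA_character_)
    sub(paste0("^# ", key, ": "), "", m[1])
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  attr(df, "algorithm") <- get("algorithm")
  attr(df, "scenario") <- get("scenario")
  attr(df, "seed") <- suppressWarnings(as.integer(get("seed")))
  attr(df, "outcome") <- get("outcome")
  attr(df, "localization_time") <- suppressWarnings(
    as.numeric(get("localization_time")))
  attr(df, "y_odor") <- suppressWarnings(as.numeric(get("y_odor")))
  df
}

#' Generate small deterministic test fixtures
#'
#' Writes tiny CSV fixtures used by the unit tests and by downstream
#' examples, all synthetic and reproducible from the seed:
#'
#' * `"events"` — a Poisson stream of detection-onset times (default rate
#'   1 Hz over 30 s; `rate = 0` gives an empty list).
#' * `"trajectory"` — a 3-point trajectory with crosswind offsets
#'   (0.3, -0.4, 0) m, whose crosswind RMSE is 0.2886751 m.
#' * `"rmi_log"` — a noiseless stimulus log generated exactly from the
#'   default active-mode gain law over a frequency grid, suitable for
#'   parameter recovery.
#'
#' @param kind one of `"events"`, `"trajectory"`, `"rmi_log"`.
#' @param seed RNG seed.
#' @param dir output directory.
#' @param rate Poisson onset rate for `"events"` (Hz).
#' @return The written file path, invisibly.
#' @export
make_fixture <- function(kind = c("events", "trajectory", "rmi_log"),
                         seed = 1L, dir = ".", rate = 1) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  path <- file.path(dir, paste0("fixture_", kind, ".csv"))
  if (kind == "events") {
    horizon <- 30
    n <- stats::rpois(1, rate * horizon)
    df <- data.frame(t = round(sort(stats::runif(n, 0, horizon)), 4))
  } else if (kind == "trajectory") {
    df <- data.frame(t = c(0, 1, 2), x = c(0.0, 0.5, 1.0),
                     y = c(0.3, -0.4, 0.0), heading = c(0, 0, 0))
  } else {
    f <- rep(seq(0.05, 1.45, by = 0.1), each = 20)
    g <- velocity_gain(f, "active", gain_table(), clamp = FALSE)
    df <- data.frame(t = seq_along(f) * 0.01, f = f, mode = "active",
                     v_cmd = g$K_v, w_cmd = g$K_w)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the batch described by a configuration
#'
#' @param cfg a [run_config()].
#' @return A `plume_batch` (see [run_batch()]).
#' @export
run_config_batch <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  run_batch(cfg$scenario, cfg$algorithm, n_trials = cfg$n_trials,
            base_seed = cfg$seed, gains = cfg$gains, sensing = cfg$sensing,
            params = cfg$control, dt = cfg$dt, t_max = cfg$t_max,
            success_radius = cfg$success_radius, warmup = cfg$warmup)
}
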