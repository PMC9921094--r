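#' Scenario configuration
#'
#' Builds the description of one experimental arena: where the odor source and
#' the wind source sit, the mean wind, its unsteadiness, the field bounds that
#' define search failure, and the agent's start pose. Defaults reproduce the
#' indoor co-aligned arena (scenario "a"): odor source at the origin, fan at
#' (-0.5, 0) blowing in +x at 1.0 m/s, start pose (1.5, 0) facing the source.
#'
#' The wind is spatially uniform at every instant; the wind-source position
#' only fixes the mean direction (the fan blows from `wind_source` into the
#' field). Unsteadiness is an Ornstein--Uhlenbeck perturbation of direction and
#' speed around the scenario mean, parameterised by its stationary standard
#' deviations and a correlation time.
#'
#' @param odor_source numeric length-2, odor source position (m).
#' @param wind_source numeric length-2, fan position (m); sets the mean wind
#'   direction unless `mean_wind_direction` is given.
#' @param wind_speed mean wind speed (m/s), must be positive.
#' @param mean_wind_direction mean wind direction (rad, direction of travel);
#'   default: from `wind_source` toward `odor_source` and on into the field.
#' @param turbulence list with `direction_sd` (rad), `speed_sd` (m/s) and
#'   `correlation_time` (s): stationary SDs and relaxation time of the
#'   Ornstein--Uhlenbeck wind perturbation. Zero SDs give constant wind.
#' @param field_bounds named numeric `c(xmin, xmax, ymin, ymax)` (m); leaving
#'   this rectangle ends a trial as failure.
#' @param start_pose named numeric `c(x, y, heading)`: start position (m) and
#'   heading (rad).
#' @param plume list of filament-plume parameters: `release_rate` (filaments/s),
#'   `sigma0` (initial Gaussian spread, m), `growth_rate` (m/s),
#'   `jitter_sd` (centerline jitter SD, m per sqrt(s)) and `q` (filament
#'   strength, arbitrary units).
#' @param transport_wind `NULL` (default) to advect the plume with the same
#'   wind the agent senses, or `list(direction =, speed =)` for a steady
#'   transport flow decoupled from the sensed wind — used when a local fan
#'   sets the wind cue at the agent while a slower ambient drift carries the
#'   odor (the crossed-cue arena "b").
#' @param name optional scenario label.
#'
#' @return An object of class `scenario_config`.
#' @seealso [scenario_preset()] for the three shipped arenas.
#' @export
#' @examples
#' sc <- scenario_config()
#' sc$mean_wind_direction  # 0: the fan at (-0.5, 0) blows in +x
scenario_config <- function(odor_source = c(0, 0),
                            wind_source = c(-0.5, 0),
                            wind_speed = 1.0,
                            mean_wind_direction = NULL,
                            turbulence = list(direction_sd = 0.1,
                                              speed_sd = 0.1,
                                              correlation_time = 2),
                            field_bounds = c(xmin = -0.5, xmax = 2,
                                             ymin = -1, ymax = 1),
                            start_pose = c(x = 1.5, y = 0, heading = pi),
                            plume = list(),
                            transport_wind = NULL,
                            name = "custom") {
  odor_source <- as.numeric(odor_source)
  wind_source <- as.numeric(wind_source)
  stopifnot(length(odor_source) == 2, length(wind_source) == 2,
            is.numeric(wind_speed), length(wind_speed) == 1)
  if (!is.finite(wind_speed) || wind_speed <= 0)
    stop("`wind_speed` must be a positive number")

  turb_default <- list(direction_sd = 0.1, speed_sd = 0.1, correlation_time = 2)
  turbulence <- utils::modifyList(turb_default, as.list(turbulence))
  if (!all(names(turbulence) %in% names(turb_default)))
    stop("unknown turbulence field(s): ",
         paste(setdiff(names(turbulence), names(turb_default)), collapse = ", "))
  if (turbulence$correlation_time <= 0)
    stop("`turbulence$correlation_time` must be positive")
  if (turbulence$direction_sd < 0 || turbulence$speed_sd < 0)
    stop("turbulence standard deviations must be non-negative")

  fb <- as.numeric(field_bounds)
  names(fb) <- c("xmin", "xmax", "ymin", "ymax")
  if (fb["xmin"] >= fb["xmax"] || fb["ymin"] >= fb["ymax"])
    stop("`field_bounds` must satisfy xmin < xmax and ymin < ymax")
  if (odor_source[1] < fb["xmin"] || odor_source[1] > fb["xmax"] ||
      odor_source[2] < fb["ymin"] || odor_source[2] > fb["ymax"])
    stop("`odor_source` must lie inside `field_bounds`")

  sp <- as.numeric(start_pose)
  names(sp) <- c("x", "y", "heading")

  if (is.null(mean_wind_direction)) {
    # fan blows from its own position into the field, i.e. toward the source
    # and beyond; for a fan at (-0.5, 0) and source (0, 0) this is 0 rad (+x)
    mean_wind_direction <- atan2(odor_source[2] - wind_source[2],
                                 odor_source[1] - wind_source[1])
    if (all(odor_source == wind_source)) mean_wind_direction <- 0
  }

  plume_default <- list(release_rate = 10, sigma0 = 0.02,
                        growth_rate = 0.005, jitter_sd = 0.02, q = 1)
  plume <- utils::modifyList(plume_default, as.list(plume))
  if (!all(names(plume) %in% names(plume_default)))
    stop("unknown plume field(s): ",
         paste(setdiff(names(plume), names(plume_default)), collapse = ", "))
  if (plume$release_rate <= 0) stop("`plume$release_rate` must be positive")
  if (plume$sigma0 <= 0) stop("`plume$sigma0` must be positive")
  if (plume$growth_rate < 0) stop("`plume$growth_rate` must be non-negative")

  if (!is.null(transport_wind)) {
    transport_wind <- as.list(transport_wind)
    if (!all(c("direction", "speed") %in% names(transport_wind)))
      stop("`transport_wind` needs `direction` and `speed`")
    if (transport_wind$speed < 0) stop("transport wind speed must be >= 0")
    transport_wind$direction <- wrap_angle(transport_wind$direction)
  }

  structure(list(name = name,
                 odor_source = odor_source,
                 wind_source = wind_source,
                 wind_speed = wind_speed,
                 mean_wind_direction = wrap_angle(mean_wind_direction),
                 turbulence = turbulence,
                 field_bounds = fb,
                 start_pose = sp,
                 plume = plume,
                 transport_wind = transport_wind),
            class = "scenario_config")
}

#' Shipped scenario presets
#'
#' Three arenas of increasing complexity, mirroring the standard robot
#' protocol:
#'
#' * `"a"` — indoor, wind source upwind of the odor source at (-0.5, 0), mean
#'   wind +x at 1.0 m/s with mild unsteadiness; start (1.5, 0) facing the
#'   source.
#' * `"b"` — indoor, fan at (0, -0.3) off-axis: the agent feels the fan's
#'   +y wind, while a steady ambient drift carries the odor toward the start
#'   region, displacing the plume centerline off the +x axis through the
#'   start pose (1.5, 0.3). Odor direction and wind direction are decoupled.
#' * `"c"` — outdoor, same geometry as "a" but gusty: large direction and
#'   speed fluctuations.
#'
#' @param name one of `"a"`, `"b"`, `"c"` (case-insensitive).
#' @return A `scenario_config`.
#' @export
#' @examples
#' scenario_preset("c")$turbulence$direction_sd
scenario_preset <- function(name = c("a", "b", "c")) {
  name <- match.arg(tolower(name), c("a", "b", "c"))
  switch(name,
    a = scenario_config(name = "a"),
    b = scenario_config(
      name = "b",
      wind_source = c(0, -0.3),
      # the fan at (0, -0.3) sets the wind cue the agent feels (+y), while a
      # steady ambient drift carries the odor toward the start region,
      # displacing the plume centerline off the +x axis: odor direction and
      # wind direction are decoupled, the defining feature of this arena
      turbulence = list(direction_sd = 0.3, speed_sd = 0.1,
                        correlation_time = 2),
      transport_wind = list(direction = atan2(0.3, 1.5), speed = 1.0),
      start_pose = c(x = 1.5, y = 0.3, heading = pi)),
    c = scenario_config(
      name = "c",
      turbulence = list(direction_sd = 0.5, speed_sd = 0.3,
                        correlation_time = 2),
      start_pose = c(x = 1.5, y = 0.3, heading = pi)))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config '", x$name, "'>\n", sep = "")
  cat(sprintf("  odor source   (%.2f, %.2f) m\n",
              x$odor_source[1], x$odor_source[2]))
  cat(sprintf("  wind source   (%.2f, %.2f) m, mean %.2f m/s toward %.3f rad\n",
              x$wind_source[1], x$wind_source[2], x$wind_speed,
              x$mean_wind_direction))
  cat(sprintf("  turbulence    dir SD %.2f rad, speed SD %.2f m/s, tau %.1f s\n",
              x$turbulence$direction_sd, x$turbulence$speed_sd,
              x$turbulence$correlation_time))
  if (!is.null(x$transport_wind))
    cat(sprintf("  plume drift   %.2f m/s toward %.3f rad (decoupled)\n",
                x$transport_wind$speed, x$transport_wind$direction))
  cat(sprintf("  field bounds  x [%.2f, %.2f], y [%.2f, %.2f] m\n",
              x$field_bounds["xmin"], x$field_bounds["xmax"],
              x$field_bounds["ymin"], x$field_bounds["ymax"]))
  cat(sprintf("  start pose    (%.2f, %.2f) m, heading %.2f rad\n",
              x$start_pose["x"], x$start_pose["y"], x$start_pose["heading"]))
  invisible(x)
}

#' Instantaneous wind state
#'
#' @param direction direction of travel (rad, world frame).
#' @param speed wind speed (m/s), non-negative.
#' @return An object of class `wind_state` with fields `direction`, `speed`.
#' @export
wind_state <- function(direction, speed) {
  if (speed < 0) stop("wind speed must be non-negative")
  structure(list(direction = wrap_angle(direction), speed = speed),
            class = "wind_state")
}

#' Advance the wind one timestep
#'
#' Direction and speed each follow an Ornstein--Uhlenbeck process around the
#' scenario mean, using the exact discretisation, so the stationary SDs equal
#' `turbulence$direction_sd` and `turbulence$speed_sd` for any `dt`. With both
#' SDs zero the wind is constant at the scenario mean. Speed is truncated at
#' zero. Draws from the current R RNG stream.
#'
#' @param wind a `wind_state`.
#' @param scenario a `scenario_config`.
#' @param dt timestep (s), positive.
#' @return The new `wind_state`.
#' @export
step_wind <- function(wind, scenario, dt) {
  if (dt <= 0) stop("`dt` must be positive")
  turb <- scenario$turbulence
  if (turb$correlation_time <= 0)
    stop("`turbulence$correlation_time` must be positive")
  a <- exp(-dt / turb$correlation_time)
  s <- sqrt(1 - a * a)
  dev <- wrap_angle(wind$direction - scenario$mean_wind_direction)
  dir <- scenario$mean_wind_direction +
    a * dev + turb$direction_sd * s * stats::rnorm(1)
  spd <- scenario$wind_speed + a * (wind$speed - scenario$wind_speed) +
    turb$speed_sd * s * stats::rnorm(1)
  wind_state(dir, max(spd, 0))
}

#' Create an empty filament plume
#'
#' The plume is a set of Gaussian filaments (puffs), each with a center, a
#' spread `sigma` and a strength `q`; it is stored in preallocated vectors so
#' stepping is cheap inside a simulation loop.
#'
#' @param capacity initial storage capacity (filaments).
#' @return An object of class `filament_plume`.
#' @export
new_plume <- function(capacity = 256L) {
  structure(list(x = numeric(capacity), y = numeric(capacity),
                 sigma = numeric(capacity), n = 0L,
                 release_accum = 0),
            class = "filament_plume")
}

#' @export
print.filament_plume <- function(x, ...) {
  cat("<filament_plume> ", x$n, " filament(s)\n", sep = "")
  invisible(x)
}

#' Advance the plume one timestep
#'
#' New filaments are released from the odor source at the configured rate
#' (deterministically: after `t` seconds exactly `floor(rate * t)` filaments
#' have been released). Every filament center is advected by the instantaneous
#' wind — or by the scenario's steady `transport_wind` when one is configured
#' — plus isotropic Brownian jitter of SD `jitter_sd * sqrt(dt)`; spreads
#' grow linearly at `growth_rate`. Filaments more than `3 * sigma` outside the
#' field bounds are pruned. Draws from the current R RNG stream.
#'
#' @param plume a `filament_plume`.
#' @param wind a `wind_state`.
#' @param scenario a `scenario_config`.
#' @param dt timestep (s), positive.
#' @param prune drop filaments far outside the field (default `TRUE`).
#' @return The advanced `filament_plume`.
#' @export
step_plume <- function(plume, wind, scenario, dt, prune = TRUE) {
  if (dt <= 0) stop("`dt` must be positive")
  pp <- scenario$plume
  n <- plume$n

  if (!is.null(scenario$transport_wind)) {
    tw <- scenario$transport_wind
    adv_dir <- tw$direction; adv_spd <- tw$speed
  } else {
    adv_dir <- wind$direction; adv_spd <- wind$speed
  }
  if (n > 0L) {
    idx <- seq_len(n)
    wx <- adv_spd * cos(adv_dir) * dt
    wy <- adv_spd * sin(adv_dir) * dt
    jit <- pp$jitter_sd * sqrt(dt)
    if (jit > 0) {
      plume$x[idx] <- plume$x[idx] + wx + stats::rnorm(n, sd = jit)
      plume$y[idx] <- plume$y[idx] + wy + stats::rnorm(n, sd = jit)
    } else {
      plume$x[idx] <- plume$x[idx] + wx
      plume$y[idx] <- plume$y[idx] + wy
    }
    plume$sigma[idx] <- plume$sigma[idx] + pp$growth_rate * dt
  }

  # deterministic release: floor(rate * t) filaments after t seconds
  plume$release_accum <- plume$release_accum + pp$release_rate * dt
  n_new <- floor(plume$release_accum + 1e-9)
  if (n_new > 0L) {
    plume$release_accum <- plume$release_accum - n_new
    if (n + n_new > length(plume$x)) {
      grow <- max(length(plume$x) * 2L, n + n_new)
      length(plume$x) <- grow; length(plume$y) <- grow
      length(plume$sigma) <- grow
    }
    j <- (n + 1L):(n + n_new)
    plume$x[j] <- scenario$odor_source[1]
    plume$y[j] <- scenario$odor_source[2]
    plume$sigma[j] <- pp$sigma0
    plume$n <- n <- n + as.integer(n_new)
  }

  if (prune && n > 0L) {
    idx <- seq_len(n)
    fb <- scenario$field_bounds
    m <- 3 * plume$sigma[idx]
    keep <- plume$x[idx] >= fb[["xmin"]] - m & plume$x[idx] <= fb[["xmax"]] + m &
            plume$y[idx] >= fb[["ymin"]] - m & plume$y[idx] <= fb[["ymax"]] + m
    if (!all(keep)) {
      k <- which(keep)
      nk <- length(k)
      plume$x[seq_len(nk)] <- plume$x[k]
      plume$y[seq_len(nk)] <- plume$y[k]
      plume$sigma[seq_len(nk)] <- plume$sigma[k]
      plume$n <- nk
    }
  }
  plume
}

#' Odor concentration at a point
#'
#' Sum of Gaussian kernels over the filaments:
#' `C(p) = sum_i q * exp(-|p - c_i|^2 / (2 sigma_i^2)) / sigma_i^2`.
#' Non-negative, additive over filaments and continuous in `p`; an empty plume
#' gives 0. Units are arbitrary; detection happens by thresholding.
#'
#' @param plume a `filament_plume`.
#' @param p numeric length-2 position (m), or an n x 2 matrix of positions.
#' @param q filament strength (default 1).
#' @return Concentration value(s), one per row of `p`.
#' @export
concentration_at <- function(plume, p, q = 1) {
  if (is.matrix(p)) return(apply(p, 1L, function(r) concentration_at(plume, r, q)))
  n <- plume$n
  if (n == 0L) return(0)
  idx <- seq_len(n)
  dx <- plume$x[idx] - p[1]
  dy <- plume$y[idx] - p[2]
  s2 <- plume$sigma[idx]^2
  sum(q * exp(-(dx * dx + dy * dy) / (2 * s2)) / s2)
}

# wrap an angle to (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi)
  a + ifelse(a <= 0, pi, -pi)
}
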