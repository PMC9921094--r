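#' Unicycle pose integration
#'
#' Advances a pose one timestep under a velocity command: the heading turns by
#' `w * dt`, then the position advances by `v * dt` along the new heading.
#' Commands are in robot units (mm/s); positions are in metres. The heading is
#' wrapped to (-pi, pi].
#'
#' @param pose named numeric `c(x, y, heading)` (m, m, rad), optionally with a
#'   `t` element (s) which is advanced by `dt`.
#' @param cmd list or named vector with `v` (mm/s) and `w` (rad/s).
#' @param dt timestep (s), positive.
#' @return The advanced pose, same layout as the input.
#' @export
#' @examples
#' integrate_pose(c(x = 0, y = 0, heading = 0), list(v = 100, w = 0), 1)
integrate_pose <- function(pose, cmd, dt) {
  if (dt <= 0) stop("`dt` must be positive")
  h <- wrap_angle(pose[["heading"]] + cmd$w * dt)
  pose[["heading"]] <- h
  step <- cmd$v / 1000 * dt
  pose[["x"]] <- pose[["x"]] + step * cos(h)
  pose[["y"]] <- pose[["y"]] + step * sin(h)
  if ("t" %in% names(pose)) pose[["t"]] <- pose[["t"]] + dt
  pose
}

#' Run one odor-source localization trial
#'
#' Closes the loop at a fixed timestep: advance the wind and the filament
#' plume, sample the bilateral odor sensors and the wind class at the agent,
#' update the sliding-window odor-detection frequency, query the navigation
#' policy, and integrate the unicycle pose. The trial ends at the first of:
#' the agent entering the success radius around the odor source
#' (`success`), leaving the field bounds (`exit_field`), or exhausting the
#' time limit (`timeout`). Identical seeds give bit-identical results.
#'
#' Before the agent starts, the plume is spun up for `warmup` seconds so the
#' arena holds an established plume at t = 0, as a physical arena would.
#'
#' @param scenario a [scenario_config()].
#' @param algorithm `"rmi"`, `"szl"` or `"sc"`.
#' @param seed integer seed for the trial's random stream.
#' @param gains a [gain_table()] (used by `"rmi"`).
#' @param sensing a [sensing_params()] list.
#' @param params a [ctrl_params()] list.
#' @param dt timestep (s), default 0.01 (the robot's 10 ms sensor sampling).
#' @param t_max time limit (s), default 180 (3 min).
#' @param success_radius success radius around the odor source (m),
#'   default 0.1.
#' @param warmup plume spin-up time before t = 0 (s).
#' @return An object of class `plume_trial`: a list with `outcome`
#'   (`"success"`, `"exit_field"` or `"timeout"`), `localization_time` (s;
#'   `NA` unless success), `trajectory` (matrix with columns t, x, y,
#'   heading), `log` (per-tick stimulus/command data.frame), `seed`,
#'   `algorithm` and `scenario`.
#' @export
#' @examples
#' tr <- run_trial(scenario_preset("a"), "rmi", seed = 1, t_max = 5)
#' tr$outcome
run_trial <- function(scenario, algorithm = c("rmi", "szl", "sc"), seed = 1L,
                      gains = gain_table(), sensing = sensing_params(),
                      params = ctrl_params(), dt = 0.01, t_max = 180,
                      success_radius = 0.1, warmup = 6) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(scenario, "scenario_config"), dt > 0, t_max > 0)
  set.seed(as.integer(seed))

  # --- unpack the scenario for the hot loop -------------------------------
  # The loop below inlines step_wind / step_plume / sample_sensors for
  # speed; it performs the identical arithmetic and consumes the RNG stream
  # in the same order (wind direction, wind speed, filament jitter x then y).
  turb <- scenario$turbulence
  ou_a <- exp(-dt / turb$correlation_time)
  ou_s <- sqrt(1 - ou_a * ou_a)
  dir_sd <- turb$direction_sd; spd_sd <- turb$speed_sd
  mu_dir <- scenario$mean_wind_direction; mu_spd <- scenario$wind_speed
  pp <- scenario$plume
  jit <- pp$jitter_sd * sqrt(dt)
  growth <- pp$growth_rate * dt
  rel_per_tick <- pp$release_rate * dt
  fb <- scenario$field_bounds
  bx0 <- fb[["xmin"]]; bx1 <- fb[["xmax"]]
  by0 <- fb[["ymin"]]; by1 <- fb[["ymax"]]
  ox <- scenario$odor_source[1]; oy <- scenario$odor_source[2]

  wd <- mu_dir; ws <- mu_spd                      # wind state
  decoupled <- !is.null(scenario$transport_wind)  # steady transport flow?
  if (decoupled) {
    twx <- scenario$transport_wind$speed *
      cos(scenario$transport_wind$direction) * dt
    twy <- scenario$transport_wind$speed *
      sin(scenario$transport_wind$direction) * dt
  }
  cap <- 256L                                     # filament storage
  px <- numeric(cap); py <- numeric(cap); psig <- numeric(cap)
  pn <- 0L; rel_accum <- 0

  env_step <- function() {
    # Ornstein-Uhlenbeck wind (exact discretisation)
    dev <- wd - mu_dir
    if (dev > pi) dev <- dev - 2 * pi else if (dev <= -pi) dev <- dev + 2 * pi
    wd <<- mu_dir + ou_a * dev + dir_sd * ou_s * stats::rnorm(1)
    ws <<- max(mu_spd + ou_a * (ws - mu_spd) + spd_sd * ou_s * stats::rnorm(1), 0)
    # advect + grow filaments
    if (pn > 0L) {
      idx <- seq_len(pn)
      if (decoupled) { adv_x <- twx } else { adv_x <- ws * cos(wd) * dt }
      if (decoupled) { adv_y <- twy } else { adv_y <- ws * sin(wd) * dt }
      wx <- adv_x; wy <- adv_y
      if (jit > 0) {
        px[idx] <<- px[idx] + wx + stats::rnorm(pn, sd = jit)
        py[idx] <<- py[idx] + wy + stats::rnorm(pn, sd = jit)
      } else {
        px[idx] <<- px[idx] + wx
        py[idx] <<- py[idx] + wy
      }
      psig[idx] <<- psig[idx] + growth
    }
    # deterministic release
    rel_accum <<- rel_accum + rel_per_tick
    n_new <- floor(rel_accum + 1e-9)
    if (n_new > 0L) {
      rel_accum <<- rel_accum - n_new
      if (pn + n_new > cap) {
        cap <<- max(cap * 2L, pn + as.integer(n_new))
        length(px) <<- cap; length(py) <<- cap; length(psig) <<- cap
      }
      j <- (pn + 1L):(pn + n_new)
      px[j] <<- ox; py[j] <<- oy; psig[j] <<- pp$sigma0
      pn <<- pn + as.integer(n_new)
    }
    # prune far outside the field
    if (pn > 0L) {
      idx <- seq_len(pn)
      m <- 3 * psig[idx]
      keep <- px[idx] >= bx0 - m & px[idx] <= bx1 + m &
              py[idx] >= by0 - m & py[idx] <= by1 + m
      if (!all(keep)) {
        k <- which(keep); nk <- length(k)
        px[seq_len(nk)] <<- px[k]; py[seq_len(nk)] <<- py[k]
        psig[seq_len(nk)] <<- psig[k]
        pn <<- nk
      }
    }
  }

  conc <- function(qx, qy) {
    if (pn == 0L) return(0)
    idx <- seq_len(pn)
    dx <- px[idx] - qx; dy <- py[idx] - qy
    s2 <- psig[idx] * psig[idx]
    sum(exp(-(dx * dx + dy * dy) / (2 * s2)) / s2)
  }

  if (warmup > 0) for (k in seq_len(ceiling(warmup / dt))) env_step()

  x <- scenario$start_pose[["x"]]
  y <- scenario$start_pose[["y"]]
  h <- wrap_angle(scenario$start_pose[["heading"]])
  r2 <- success_radius^2
  W <- sensing$window
  refractory <- sensing$refractory
  threshold <- sensing$threshold
  fo <- sensing$forward_offset; lo <- sensing$lateral_offset
  dead_band <- sensing$dead_band
  wind_levels <- c("front", "back", "left", "right")

  state <- controller_state(algorithm, params)
  prev_class <- NULL
  prev_left <- FALSE; prev_right <- FALSE
  last_edge_left <- -Inf; last_edge_right <- -Inf
  onsets <- numeric(1024L); n_onsets <- 0L; head <- 1L

  n_max <- as.integer(ceiling(t_max / dt))
  tv <- numeric(n_max + 1L); xv <- numeric(n_max + 1L)
  yv <- numeric(n_max + 1L); hv <- numeric(n_max + 1L)
  l_left <- logical(n_max); l_right <- logical(n_max)
  l_wc <- integer(n_max); l_f <- numeric(n_max)
  l_state <- character(n_max); l_mode <- character(n_max)
  l_v <- numeric(n_max); l_w <- numeric(n_max)

  tv[1L] <- 0; xv[1L] <- x; yv[1L] <- y; hv[1L] <- h
  outcome <- "timeout"; loc_time <- NA_real_; n_ticks <- 0L

  # degenerate starts: already at the source, or placed outside the field
  if ((x - ox)^2 + (y - oy)^2 <= r2) {
    outcome <- "success"; loc_time <- 0
  } else if (x < fb[["xmin"]] || x > fb[["xmax"]] ||
             y < fb[["ymin"]] || y > fb[["ymax"]]) {
    outcome <- "exit_field"
  } else {
    bp <- gains$breakpoint
    g_lo <- gains$coef[, "low", ]; g_hi <- gains$coef[, "high", ]
    v_min <- gains$v_min; v_max <- gains$v_max
    w_min <- gains$w_min; w_max <- gains$w_max
    qpi <- pi / 4

    for (i in seq_len(n_max)) {
      t_now <- i * dt
      env_step()

      # sensors (inline sample_sensors: same geometry and thresholding)
      ch <- cos(h); sh <- sin(h)
      left_hit <- conc(x + fo * ch - lo * sh, y + fo * sh + lo * ch) >= threshold
      right_hit <- conc(x + fo * ch + lo * sh, y + fo * sh - lo * ch) >= threshold
      wx <- ws * cos(wd); wy <- ws * sin(wd)
      wbx <- ch * wx + sh * wy; wby <- -sh * wx + ch * wy
      if (ws < dead_band) {
        wind_class <- if (is.null(prev_class)) "front" else prev_class
      } else {
        b <- atan2(-wby, -wbx); ab <- abs(b)
        wind_class <- if (ab <= qpi + 1e-12) "front"
          else if (ab >= 3 * qpi - 1e-12) "back"
          else if (b > 0) "left" else "right"
      }
      prev_class <- wind_class

      left_edge <- left_hit && !prev_left &&
        (t_now - last_edge_left >= refractory)
      right_edge <- right_hit && !prev_right &&
        (t_now - last_edge_right >= refractory)
      if (left_edge) last_edge_left <- t_now
      if (right_edge) last_edge_right <- t_now
      prev_left <- left_hit; prev_right <- right_hit
      onset <- left_edge || right_edge
      detected <- left_hit || right_hit
      side <- if (left_edge && right_edge) "front"
              else if (left_edge) "left"
              else if (right_edge) "right" else "none"

      if (onset) {
        n_onsets <- n_onsets + 1L
        if (n_onsets > length(onsets)) length(onsets) <- 2L * length(onsets)
        onsets[n_onsets] <- t_now
      }
      while (head <= n_onsets && onsets[head] <= t_now - W) head <- head + 1L
      f <- (n_onsets - head + 1L) / W

      if (algorithm == "rmi") {
        # inline select_mode + velocity_gain (scalar path)
        if (detected)
          state$mode <- if (wind_class == "front") "active" else "inactive"
        g <- if (f > bp) g_hi[state$mode, ] else g_lo[state$mode, ]
        K_v <- min(max(g[["a_v"]] * f + g[["b_v"]], v_min), v_max)
        K_w <- min(max(g[["a_w"]] * f + g[["b_w"]], w_min), w_max)
        state <- fsm_step(state, detected, side, K_w, dt, params)
        if (state$phase == "turn") {
          v <- min(max(K_v * params$straight_fraction, v_min), v_max)
          w <- state$turn_sign * K_w
        } else { v <- K_v; w <- 0 }
      } else if (algorithm == "szl") {
        state <- fsm_step(state, detected, side, params$szl_w, dt, params)
        v <- params$szl_v
        w <- if (state$phase == "turn") state$turn_sign * params$szl_w else 0
      } else {
        cmd <- sc_policy(state,
                         list(detected = detected, side = side,
                              wind_class = wind_class,
                              wind_vector_body = c(wbx, wby)),
                         params, dt)
        state <- cmd$state; v <- cmd$v; w <- cmd$w
      }

      h <- h + w * dt
      if (h > pi) h <- h - 2 * pi else if (h <= -pi) h <- h + 2 * pi
      step <- v / 1000 * dt
      x <- x + step * cos(h)
      y <- y + step * sin(h)
      if (!is.finite(x) || !is.finite(y) || !is.finite(h))
        stop("simulation fault: non-finite pose at t = ", t_now)

      n_ticks <- i
      tv[i + 1L] <- t_now; xv[i + 1L] <- x; yv[i + 1L] <- y; hv[i + 1L] <- h
      l_left[i] <- left_hit; l_right[i] <- right_hit
      l_wc[i] <- match(wind_class, wind_levels); l_f[i] <- f
      l_state[i] <- if (algorithm == "sc") state$sc_state else state$fsm
      l_mode[i] <- if (algorithm == "rmi") state$mode else ""
      l_v[i] <- v; l_w[i] <- w

      if ((x - ox)^2 + (y - oy)^2 <= r2) {
        outcome <- "success"; loc_time <- t_now; break
      }
      if (x < bx0 || x > bx1 || y < by0 || y > by1) {
        outcome <- "exit_field"; break
      }
    }
  }

  keep <- seq_len(n_ticks + 1L)
  trajectory <- cbind(t = tv[keep], x = xv[keep], y = yv[keep],
                      heading = hv[keep])
  ki <- seq_len(n_ticks)
  log <- data.frame(t = tv[ki + 1L], x = xv[ki + 1L], y = yv[ki + 1L],
                    heading = hv[ki + 1L],
                    left_hit = l_left[ki], right_hit = l_right[ki],
                    wind_class = wind_levels[l_wc[ki]], f = l_f[ki],
                    state = l_state[ki], mode = l_mode[ki],
                    v_cmd = l_v[ki], w_cmd = l_w[ki])

  structure(list(outcome = outcome, localization_time = loc_time,
                 trajectory = trajectory, log = log,
                 seed = as.integer(seed), algorithm = algorithm,
                 scenario = scenario$name,
                 y_odor = oy, t_max = t_max,
                 success_radius = success_radius),
            class = "plume_trial")
}

#' @export
print.plume_trial <- function(x, ...) {
  cat(sprintf("<plume_trial> %s, scenario %s, seed %d: %s",
              toupper(x$algorithm), x$scenario, x$seed, x$outcome))
  if (x$outcome == "success")
    cat(sprintf(" in %.2f s", x$localization_time))
  cat(sprintf(" (%d ticks, crosswind RMSE %.3f m)\n",
              nrow(x$trajectory) - 1L, crosswind_rmse(x)))
  invisible(x)
}

#' Plot a trial trajectory
#'
#' Draws the agent path in the arena, the odor source with its success
#' radius, and the start pose.
#'
#' @param x a `plume_trial`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.plume_trial <- function(x, ...) {
  tr <- x$trajectory
  graphics::plot(tr[, "x"], tr[, "y"], type = "l", asp = 1,
                 xlab = "x (m)", ylab = "y (m)",
                 main = sprintf("%s, scenario %s: %s", toupper(x$algorithm),
                                x$scenario, x$outcome), ...)
  th <- seq(0, 2 * pi, length.out = 90)
  graphics::lines(x$success_radius * cos(th), x$success_radius * sin(th) +
                    x$y_odor, col = "red")
  graphics::points(tr[1, "x"], tr[1, "y"], pch = 16, col = "blue")
  invisible(x)
}

#' Run a batch of independent trials
#'
#' Runs `n_trials` trials with seeds `base_seed, base_seed + 1, ...`; results
#' are order-stable and a repeated call with the same `base_seed` reproduces
#' the batch exactly.
#'
#' @inheritParams run_trial
#' @param n_trials number of repetitions (>= 1), default 20.
#' @param base_seed seed of the first trial.
#' @param ... passed on to [run_trial()].
#' @return An object of class `plume_batch`: a list of `plume_trial`s.
#' @export
run_batch <- function(scenario, algorithm = c("rmi", "szl", "sc"),
                      n_trials = 20, base_seed = 1L, ...) {
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  algorithm <- match.arg(algorithm)
  res <- lapply(seq_len(n_trials) - 1L,
                function(k) run_trial(scenario, algorithm,
                                      seed = as.integer(base_seed) + k, ...))
  structure(res, class = "plume_batch",
            algorithm = algorithm, scenario = scenario$name)
}

#' @export
print.plume_batch <- function(x, ...) {
  print(summarize_batch(x))
  invisible(x)
}

#' @export
summary.plume_batch <- function(object, ...) summarize_batch(object)
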