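#' Controller geometry and baseline parameters
#'
#' Tunables of the shared surge/zigzag/loop state machine and of the two
#' baseline policies. The surge duration (0.5 s) and the three-turns-then-loop
#' rule follow the stereotyped silk-moth program; the baselines run at a
#' constant 150 mm/s straight and 1.5 rad/s rotational speed. Turn amplitudes
#' and leg durations are geometric choices of this implementation.
#'
#' @param surge_duration surge length (s) before falling back to zigzag.
#' @param surge_turn_angle corrective turn toward the detecting sensor at
#'   surge onset (rad).
#' @param zigzag_turn_angle amplitude of each zigzag turn (rad).
#' @param zigzag_leg_duration straight run after each zigzag turn (s).
#' @param straight_fraction fraction of K_v commanded while turning (RMI).
#' @param szl_v,szl_w constant speeds of the surge-zigzag-loop baseline
#'   (mm/s, rad/s).
#' @param sc_v,sc_w constant speeds of the surge-cast baseline (mm/s, rad/s).
#' @param sc_lost_timeout time without a detection before surge gives way to
#'   casting (s).
#' @param sc_cast_initial first cast leg duration (s).
#' @param sc_cast_factor cast leg duration multiplier per reversal.
#' @param sc_cast_max cap on the cast leg duration (s), so casting sweeps a
#'   bounded corridor instead of growing without limit in a bounded arena.
#' @return A list of class `ctrl_params`.
#' @export
ctrl_params <- function(surge_duration = 0.5,
                        surge_turn_angle = pi / 6,
                        zigzag_turn_angle = pi / 3,
                        zigzag_leg_duration = 1.0,
                        straight_fraction = 1.0,
                        szl_v = 150, szl_w = 1.5,
                        sc_v = 150, sc_w = 1.5,
                        sc_lost_timeout = 1.0,
                        sc_cast_initial = 1.5,
                        sc_cast_factor = 2,
                        sc_cast_max = 8) {
  structure(list(surge_duration = surge_duration,
                 surge_turn_angle = surge_turn_angle,
                 zigzag_turn_angle = zigzag_turn_angle,
                 zigzag_leg_duration = zigzag_leg_duration,
                 straight_fraction = straight_fraction,
                 szl_v = szl_v, szl_w = szl_w,
                 sc_v = sc_v, sc_w = sc_w,
                 sc_lost_timeout = sc_lost_timeout,
                 sc_cast_initial = sc_cast_initial,
                 sc_cast_factor = sc_cast_factor,
                 sc_cast_max = sc_cast_max),
            class = "ctrl_params")
}

side_sign <- function(side) if (identical(side, "right")) -1 else 1

#' Initial controller state
#'
#' The moth-like controllers start in the zigzag state (crosswind scanning)
#' in inactive mode; the surge-cast controller starts casting. Surge is only
#' ever entered through an odor detection.
#'
#' @param algorithm `"rmi"`, `"szl"` or `"sc"`.
#' @param params a [ctrl_params()] list.
#' @return A list of class `controller_state`.
#' @export
controller_state <- function(algorithm = c("rmi", "szl", "sc"),
                             params = ctrl_params()) {
  algorithm <- match.arg(algorithm)
  st <- if (algorithm == "sc") {
    list(algorithm = algorithm,
         sc_state = "cast_turn",
         cast_sign = 1,
         uturn_sign = 1,
         leg_duration = params$sc_cast_initial,
         leg_timer = 0,
         t_since_detection = Inf)
  } else {
    list(algorithm = algorithm,
         fsm = "zigzag", mode = "inactive",
         phase = "turn", turn_sign = 1,
         turn_remaining = params$zigzag_turn_angle,
         leg_timer = 0,
         t_in_state = 0, zigzag_turns_done = 0L,
         last_hit_side = "front")
  }
  structure(st, class = "controller_state")
}

#' Advance the surge/zigzag/loop state machine one tick
#'
#' The shared behavioral program of the moth-like controllers. Any tick with
#' an odor detection (re)enters the surge state with its timer reset, so
#' surge persists while plume contact lasts; a fresh detection onset
#' additionally records the detecting side and starts a corrective turn
#' toward it. Surge then runs straight and, 0.5 s after the last detection
#' tick, falls back to zigzag. Zigzag performs up to three alternating
#' turn-plus-straight legs (first turn toward the last detection side); in
#' place of the fourth turn the agent enters loop, rotating continuously with
#' the sign of the third turn, until the next detection.
#'
#' Turn progress is integrated in angle, so the commanded angular speed of the
#' calling policy must be supplied as `omega_mag`.
#'
#' @param state a `controller_state` (rmi/szl layout).
#' @param detected logical: odor detected this tick (level flag: either
#'   sensor above threshold).
#' @param hit_side side of a fresh detection onset this tick — `"left"`,
#'   `"right"` or `"front"` (both sensors at once) — or `"none"` when the
#'   contact is continuing without a new onset.
#' @param omega_mag current angular speed magnitude (rad/s).
#' @param dt timestep (s), positive.
#' @param params a [ctrl_params()] list.
#' @return Updated `controller_state`; its `phase` field (`"turn"` or
#'   `"straight"`) together with `turn_sign` encodes the phase command.
#' @export
fsm_step <- function(state, detected, hit_side = "none", omega_mag,
                     dt, params = ctrl_params()) {
  if (dt <= 0) stop("`dt` must be positive")
  if (detected) {
    entering <- state$fsm != "surge"
    state$fsm <- "surge"
    state$t_in_state <- 0
    state$zigzag_turns_done <- 0L
    if (hit_side != "none") {
      # fresh onset: steer toward the detecting sensor
      state$last_hit_side <- hit_side
      state$turn_sign <- side_sign(hit_side)
      state$turn_remaining <-
        if (hit_side %in% c("left", "right")) params$surge_turn_angle else 0
    } else if (entering) {
      state$turn_remaining <- 0
    }
    if (state$turn_remaining > 0) {
      state$turn_remaining <- state$turn_remaining - omega_mag * dt
      state$phase <- if (state$turn_remaining > 0) "turn" else "straight"
    } else {
      state$phase <- "straight"
    }
    return(state)
  }
  state$t_in_state <- state$t_in_state + dt
  if (state$fsm == "surge") {
    if (state$t_in_state >= params$surge_duration) {
      state$fsm <- "zigzag"
      state$t_in_state <- 0
      state$zigzag_turns_done <- 0L
      state$turn_sign <- side_sign(state$last_hit_side)
      state$turn_remaining <- params$zigzag_turn_angle
      state$phase <- "turn"
    } else if (state$phase == "turn") {
      state$turn_remaining <- state$turn_remaining - omega_mag * dt
      if (state$turn_remaining <= 0) state$phase <- "straight"
    }
  } else if (state$fsm == "zigzag") {
    if (state$phase == "turn") {
      state$turn_remaining <- state$turn_remaining - omega_mag * dt
      if (state$turn_remaining <= 0) {
        state$phase <- "straight"
        state$leg_timer <- params$zigzag_leg_duration
      }
    } else {
      state$leg_timer <- state$leg_timer - dt
      if (state$leg_timer <= 0) {
        state$zigzag_turns_done <- state$zigzag_turns_done + 1L
        if (state$zigzag_turns_done >= 3L) {
          # the fourth turn never ends: loop, keeping the third turn's sign
          state$fsm <- "loop"
          state$t_in_state <- 0
          state$phase <- "turn"
        } else {
          # reversal: double amplitude so the heading alternates
          # symmetrically (+theta, -theta, ...) about the surge axis
          state$turn_sign <- -state$turn_sign
          state$phase <- "turn"
          state$turn_remaining <- 2 * params$zigzag_turn_angle
        }
      }
    }
  } else { # loop: constant rotation until a detection
    state$phase <- "turn"
  }
  state
}

#' Robust moth-inspired (RMI) policy
#'
#' One tick of the RMI controller: the search mode is re-selected at
#' detection ticks from the agreement of odor and wind direction (wind from
#' the front at a detection selects active search, any other direction
#' inactive; no detection retains the mode), the gain table is evaluated at
#' the current odor-detection frequency, and the surge/zigzag/loop machine is
#' advanced. Straight phases command `v = K_v`, turn phases
#' `v = K_v * straight_fraction` and `omega = +/- K_omega`. Deterministic in
#' its inputs.
#'
#' @param state a `controller_state` (from `controller_state("rmi")`).
#' @param percept list with `detected` (level flag: either sensor above
#'   threshold this tick), `side` (side of a fresh onset: `"left"`,
#'   `"right"`, `"front"`, or `"none"`) and `wind_class`.
#' @param f odor-detection frequency (Hz).
#' @param table a [gain_table()].
#' @param params a [ctrl_params()] list.
#' @param dt timestep (s).
#' @return List with `state` (updated) and the command `v` (mm/s),
#'   `w` (rad/s, signed).
#' @export
rmi_policy <- function(state, percept, f = 0, table = gain_table(),
                       params = ctrl_params(), dt = 0.01) {
  state$mode <- select_mode(percept$detected, percept$wind_class, state$mode)
  g <- velocity_gain(f, state$mode, table)
  state <- fsm_step(state, percept$detected, percept$side, g$K_w, dt, params)
  if (state$phase == "turn") {
    v <- min(max(g$K_v * params$straight_fraction, table$v_min), table$v_max)
    list(state = state, v = v, w = state$turn_sign * g$K_w)
  } else {
    list(state = state, v = g$K_v, w = 0)
  }
}

#' Surge-zigzag-loop (SZL) baseline policy
#'
#' The same behavioral program as RMI but with no modulation: constant
#' 150 mm/s straight speed and 1.5 rad/s turns, ignoring wind and
#' odor-detection frequency entirely.
#'
#' @inheritParams rmi_policy
#' @return List with `state`, `v` (mm/s), `w` (rad/s).
#' @export
szl_policy <- function(state, percept, params = ctrl_params(), dt = 0.01) {
  state <- fsm_step(state, percept$detected, percept$side, params$szl_w,
                    dt, params)
  if (state$phase == "turn")
    list(state = state, v = params$szl_v, w = state$turn_sign * params$szl_w)
  else
    list(state = state, v = params$szl_v, w = 0)
}

#' Surge-cast (SC) baseline policy
#'
#' The flying-insect strategy: an odor detection triggers an upwind surge
#' (turn until the wind arrives from the front, then advance); after
#' `sc_lost_timeout` seconds without a detection the agent casts — moves
#' crosswind, alternating sides, with leg durations growing by
#' `sc_cast_factor` at each reversal up to `sc_cast_max` — until the plume is
#' re-contacted.
#' Speeds are constant (150 mm/s, 1.5 rad/s). Without any detection the agent
#' casts indefinitely.
#'
#' @inheritParams rmi_policy
#' @param percept list with `detected`, `side`, `wind_class` and
#'   `wind_vector_body` (the body-frame wind, used to choose turn direction).
#' @return List with `state`, `v` (mm/s), `w` (rad/s).
#' @export
sc_policy <- function(state, percept, params = ctrl_params(), dt = 0.01) {
  if (percept$detected) {
    state$sc_state <- "surge"
    state$t_since_detection <- 0
    state$leg_duration <- params$sc_cast_initial
    state$cast_sign <- 1
  } else {
    state$t_since_detection <- state$t_since_detection + dt
  }

  wb <- percept$wind_vector_body
  # bearing the wind arrives from, in body frame (0 = dead ahead, >0 = left)
  b <- atan2(-wb[2], -wb[1])

  if (state$sc_state == "surge" &&
      state$t_since_detection >= params$sc_lost_timeout) {
    state$sc_state <- "cast_turn"
    state$cast_sign <- 1
    state$leg_duration <- params$sc_cast_initial
  }

  if (state$sc_state == "surge") {
    if (percept$wind_class == "front") {
      return(list(state = state, v = params$sc_v, w = 0))
    }
    return(list(state = state, v = params$sc_v,
                w = params$sc_w * (if (b >= 0) 1 else -1)))
  }

  if (state$sc_state == "cast_turn") {
    target <- if (state$cast_sign > 0) "left" else "right"
    err <- wrap_angle(state$cast_sign * pi / 2 - b)
    # latch once the leg is genuinely crosswind: the wind class alone is a
    # 90-degree-wide quadrant, too coarse to align a leg perpendicular to
    # the wind, so the latch also requires a small bearing error
    if (percept$wind_class == target && abs(err) < 0.15) {
      state$sc_state <- "cast_leg"
      state$leg_timer <- state$leg_duration
      return(list(state = state, v = params$sc_v, w = 0))
    }
    # near-reversals (~180 deg) alternate which side the U-turn arc bulges
    # toward (upwind vs downwind), so the arcs cancel across legs instead of
    # ratcheting the cast corridor sideways; smaller errors take the
    # shortest rotation
    w_sign <- if (abs(err) > 3 * pi / 4)
                state$uturn_sign * (if (b >= 0) 1 else -1)
              else if (err <= 0) 1 else -1
    return(list(state = state, v = params$sc_v, w = params$sc_w * w_sign))
  }

  # cast_leg: run straight; on expiry reverse with a longer leg
  state$leg_timer <- state$leg_timer - dt
  if (state$leg_timer <= 0) {
    state$cast_sign <- -state$cast_sign
    state$uturn_sign <- -state$uturn_sign
    state$leg_duration <- min(state$leg_duration * params$sc_cast_factor,
                              params$sc_cast_max)
    state$sc_state <- "cast_turn"
  }
  list(state = state, v = params$sc_v, w = 0)
}
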