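#' Sensing parameters
#'
#' Geometry and thresholds of the abstract sensor head: two odor sensors
#' mounted forward of the body center and offset laterally, a detection
#' threshold on the plume concentration, a sliding window for the
#' odor-detection frequency, a per-sensor refractory period so one filament
#' crossing counts as one detection, and a dead-band under which the wind
#' direction class is carried over.
#'
#' @param threshold concentration threshold for a detection (arbitrary units,
#'   positive). The default, together with the default refractory period,
#'   makes in-plume onset frequencies span roughly 0.5-1.4 Hz, falling toward
#'   zero with distance and crosswind offset — the frequency range over which
#'   the gain law is defined.
#' @param forward_offset sensor distance ahead of the body center (m).
#' @param lateral_offset half-spacing of the left/right sensors (m).
#' @param window sliding window W for the odor-detection frequency (s); the
#'   frequency resolution is 1/W.
#' @param refractory per-sensor refractory period (s): a sensor's
#'   false-to-true edge within this time of its previous edge is not a new
#'   onset. Plays the role of the odor sensor's recovery time; it bounds the
#'   onset frequency at 1/refractory and keeps it inside the domain of the
#'   gain law.
#' @param dead_band wind speed (m/s) below which the previous wind class is
#'   retained.
#' @return A list of class `sensing_params`.
#' @export
sensing_params <- function(threshold = 100,
                           forward_offset = 0.05,
                           lateral_offset = 0.03,
                           window = 5,
                           refractory = 0.5,
                           dead_band = 0.05) {
  if (threshold <= 0) stop("`threshold` must be positive")
  if (window <= 0) stop("`window` must be positive")
  if (refractory < 0) stop("`refractory` must be non-negative")
  structure(list(threshold = threshold,
                 forward_offset = forward_offset,
                 lateral_offset = lateral_offset,
                 window = window,
                 refractory = refractory,
                 dead_band = dead_band),
            class = "sensing_params")
}

#' Classify the body-frame wind direction
#'
#' Maps the wind vector, expressed in the agent's body frame, to one of four
#' classes by the quadrant of the wind's arrival bearing: `front` means wind
#' arriving from ahead (the agent faces upwind), `left`/`right` from the
#' sides, `back` from behind. Quadrants are centered on the body axes with
#' +/-45 degree half-width; a bearing exactly on a 45 degree boundary goes to
#' the axial class (`front` or `back`). Below the dead-band speed the previous
#' class is retained; with no history the class defaults to `front`.
#'
#' @param wind_vector_body numeric length-2 wind velocity in the body frame
#'   (m/s; +x is the agent's nose, +y its left).
#' @param prev_class previous class, or `NULL`.
#' @param dead_band minimum speed (m/s) for a fresh classification.
#' @return One of `"front"`, `"back"`, `"left"`, `"right"`.
#' @export
#' @examples
#' classify_wind_direction(c(-1, 0))  # blowing toward -x body = arriving ahead
classify_wind_direction <- function(wind_vector_body, prev_class = NULL,
                                    dead_band = 0.05) {
  spd <- sqrt(sum(wind_vector_body^2))
  if (spd < dead_band) {
    if (!is.null(prev_class)) return(prev_class)
    return("front")
  }
  # bearing the wind arrives FROM, in body frame
  b <- atan2(-wind_vector_body[2], -wind_vector_body[1])
  ab <- abs(b)
  qpi <- pi / 4
  if (ab <= qpi + 1e-12) "front"
  else if (ab >= 3 * qpi - 1e-12) "back"
  else if (b > 0) "left"
  else "right"
}

#' Sample the agent's sensors
#'
#' Evaluates the plume concentration at the left and right sensor positions
#' (thresholded into detection flags) and rotates the world wind into the body
#' frame, classifying its arrival direction.
#'
#' @param pose named numeric `c(x, y, heading)` (m, rad).
#' @param plume a `filament_plume`.
#' @param wind a `wind_state`.
#' @param params a [sensing_params()] list.
#' @param prev_class previous wind class (for the dead-band carry-over).
#' @return A list of class `stimulus_sample` with `left_hit`, `right_hit`,
#'   `wind_class`, `wind_vector_body`.
#' @export
sample_sensors <- function(pose, plume, wind, params = sensing_params(),
                           prev_class = NULL) {
  h <- pose[["heading"]]
  ch <- cos(h); sh <- sin(h)
  fo <- params$forward_offset; lo <- params$lateral_offset
  # body-frame sensor positions: (fo, +lo) left, (fo, -lo) right
  lx <- pose[["x"]] + fo * ch - lo * sh
  ly <- pose[["y"]] + fo * sh + lo * ch
  rx <- pose[["x"]] + fo * ch + lo * sh
  ry <- pose[["y"]] + fo * sh - lo * ch
  q <- 1
  left_hit <- concentration_at(plume, c(lx, ly), q) >= params$threshold
  right_hit <- concentration_at(plume, c(rx, ry), q) >= params$threshold

  wx <- wind$speed * cos(wind$direction)
  wy <- wind$speed * sin(wind$direction)
  wb <- c(ch * wx + sh * wy, -sh * wx + ch * wy)
  structure(list(left_hit = left_hit, right_hit = right_hit,
                 wind_class = classify_wind_direction(wb, prev_class,
                                                      params$dead_band),
                 wind_vector_body = wb),
            class = "stimulus_sample")
}

#' Odor-detection frequency
#'
#' The controller's measure of plume-contact quality: the number of discrete
#' detection onsets inside the sliding window `(t_now - W, t_now]`, divided by
#' `W` (Hz). An onset is a tick on which either odor sensor transitions from
#' no-detection to detection (edge counting, not level counting).
#'
#' @param event_times numeric vector of onset times (s).
#' @param t_now current time (s).
#' @param W window length (s), positive.
#' @return Frequency (Hz), non-negative.
#' @export
#' @examples
#' estimate_odor_frequency(c(1, 2, 3, 4, 5), t_now = 5, W = 5)  # 1 Hz
estimate_odor_frequency <- function(event_times, t_now, W = 5) {
  if (W <= 0) stop("`W` must be positive")
  sum(event_times > t_now - W & event_times <= t_now) / W
}

#' Extract detection onsets from logged sensor levels
#'
#' Replays the edge-and-refractory rule over recorded per-tick left/right
#' detection levels: a sensor contributes an onset when it transitions from
#' no-detection to detection and its previous onset is at least `refractory`
#' seconds old; a tick on which either sensor has such an edge is one
#' combined onset (both at once counts once, as a frontal detection). Useful
#' for re-analysing stimulus logs.
#'
#' @param left,right logical vectors of per-tick detection levels.
#' @param t numeric vector of tick times (s), same length.
#' @param refractory per-sensor refractory period (s).
#' @return A data.frame with `t` (onset times) and `side` (`"left"`,
#'   `"right"`, `"front"`).
#' @export
#' @examples
#' detect_onsets(c(FALSE, TRUE, TRUE, FALSE), c(FALSE, FALSE, FALSE, FALSE),
#'               t = (1:4) / 100)  # one onset: a 2-tick contact is one event
detect_onsets <- function(left, right, t, refractory = 0.5) {
  stopifnot(length(left) == length(right), length(left) == length(t))
  prev_l <- FALSE; prev_r <- FALSE
  last_l <- -Inf; last_r <- -Inf
  tt <- numeric(0); side <- character(0)
  for (i in seq_along(t)) {
    el <- left[i] && !prev_l && (t[i] - last_l >= refractory)
    er <- right[i] && !prev_r && (t[i] - last_r >= refractory)
    if (el) last_l <- t[i]
    if (er) last_r <- t[i]
    prev_l <- left[i]; prev_r <- right[i]
    if (el || er) {
      tt <- c(tt, t[i])
      side <- c(side, if (el && er) "front" else if (el) "left" else "right")
    }
  }
  data.frame(t = tt, side = side)
}
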