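#' Velocity-modulation gain table
#'
#' The RMI controller modulates its translational and angular speed as an
#' affine function of the odor-detection frequency f:
#' `K_{v,omega}(f) = a_{v,omega} * f + b_{v,omega}`,
#' with separate coefficient sets per search mode (active / inactive) and per
#' frequency branch (f <= 0.7 Hz vs f > 0.7 Hz). Defaults are the published
#' coefficient table, fitted to silk-moth behavior: in active mode speed rises
#' with f up to the 0.7 Hz breakpoint and falls beyond it; in inactive mode
#' translational speed is a constant 105 mm/s (a_v = 0).
#'
#' The published active-mode f > 0.7 row, read in the printed column order
#' (a_v = -114, a_omega = 246, b_v = -1.59, b_omega = 2.81), yields negative
#' speeds and an angular gain of 246 rad/s. The default `corrected = TRUE`
#' swaps the two middle entries (b_v = 246, a_omega = -1.59), which restores
#' positive speeds and near-continuity of K_v at the breakpoint
#' (166.52 vs 166.2 mm/s); `corrected = FALSE` keeps the raw printed
#' assignment.
#'
#' Evaluated gains are clamped to `[v_min, v_max]` and `[w_min, w_max]`,
#' reflecting the lowest and highest speeds a ground robot can run.
#'
#' @param corrected use the sign-consistent reading of the active f > 0.7 row
#'   (default) or the raw printed one.
#' @param breakpoint branch breakpoint f* (Hz), default 0.7.
#' @param v_min,v_max translational clamp (mm/s), `0 < v_min <= v_max`.
#' @param w_min,w_max angular clamp (rad/s), applied to the magnitude.
#' @return An object of class `gain_table`: a list with a `coef` array
#'   (mode x branch x parameter), the breakpoint and the clamps.
#' @export
#' @examples
#' gt <- gain_table()
#' velocity_gain(0, "active", gt, clamp = FALSE)    # K_v = 129 mm/s
#' velocity_gain(0.4, "inactive", gt, clamp = FALSE) # K_v = 105 mm/s
gain_table <- function(corrected = TRUE, breakpoint = 0.7,
                       v_min = 50, v_max = 250,
                       w_min = 0.5, w_max = 3.0) {
  if (!(v_min > 0 && v_min <= v_max)) stop("need 0 < v_min <= v_max")
  if (!(w_min > 0 && w_min <= w_max)) stop("need 0 < w_min <= w_max")
  co <- array(NA_real_, dim = c(2, 2, 4),
              dimnames = list(mode = c("active", "inactive"),
                              branch = c("low", "high"),
                              par = c("a_v", "a_w", "b_v", "b_w")))
  co["active", "low", ] <- c(53.6, 0.888, 129, 1.82)
  co["active", "high", ] <- if (corrected)
    c(-114, -1.59, 246, 2.81) else c(-114, 246, -1.59, 2.81)
  co["inactive", "low", ] <- c(0.0, 1.13, 105, 1.85)
  co["inactive", "high", ] <- c(0.0, -1.30, 105, 2.34)
  structure(list(coef = co, breakpoint = breakpoint, corrected = corrected,
                 v_min = v_min, v_max = v_max, w_min = w_min, w_max = w_max),
            class = "gain_table")
}

#' @export
print.gain_table <- function(x, ...) {
  cat("<gain_table> K(f) = a*f + b, breakpoint", x$breakpoint, "Hz",
      if (x$corrected) "(corrected high-f active row)" else
        "(raw printed high-f active row)", "\n")
  for (m in c("active", "inactive")) for (br in c("low", "high")) {
    p <- x$coef[m, br, ]
    cat(sprintf("  %-8s f %s %.1f: K_v = %6.1f*f + %6.2f mm/s   K_w = %6.3f*f + %5.2f rad/s\n",
                m, if (br == "low") "<=" else "> ", x$breakpoint,
                p["a_v"], p["b_v"], p["a_w"], p["b_w"]))
  }
  cat(sprintf("  clamps: v in [%g, %g] mm/s, |w| in [%g, %g] rad/s\n",
              x$v_min, x$v_max, x$w_min, x$w_max))
  invisible(x)
}

#' Evaluate the velocity gains
#'
#' Selects the frequency branch (`f <= breakpoint` vs `f > breakpoint`),
#' evaluates the affine laws for K_v and K_omega, and (by default) clamps K_v
#' to `[v_min, v_max]` and K_omega to `[w_min, w_max]`.
#'
#' @param f odor-detection frequency (Hz), non-negative; vectorised.
#' @param mode `"active"` or `"inactive"`.
#' @param table a [gain_table()].
#' @param clamp apply the speed clamps (default `TRUE`); `clamp = FALSE`
#'   returns the raw affine evaluation.
#' @return Named list with `K_v` (mm/s) and `K_w` (rad/s), each of length
#'   `length(f)`.
#' @export
velocity_gain <- function(f, mode = c("active", "inactive"),
                          table = gain_table(), clamp = TRUE) {
  mode <- match.arg(mode)
  if (any(f < 0)) stop("`f` must be non-negative")
  high <- f > table$breakpoint
  lo <- table$coef[mode, "low", ]
  hi <- table$coef[mode, "high", ]
  K_v <- ifelse(high, hi[["a_v"]] * f + hi[["b_v"]],
                lo[["a_v"]] * f + lo[["b_v"]])
  K_w <- ifelse(high, hi[["a_w"]] * f + hi[["b_w"]],
                lo[["a_w"]] * f + lo[["b_w"]])
  if (clamp) {
    K_v <- pmin(pmax(K_v, table$v_min), table$v_max)
    K_w <- pmin(pmax(K_w, table$w_min), table$w_max)
  }
  list(K_v = K_v, K_w = K_w)
}

#' Select the search mode from odor and wind agreement
#'
#' Active search is selected when an odor detection arrives with wind from the
#' front (odor and wind detected in the same direction: the agent faces
#' upwind); inactive search when a detection arrives with wind from any other
#' direction. Between detections the mode is retained.
#'
#' @param hit logical: did a detection occur this tick?
#' @param wind_class one of `"front"`, `"back"`, `"left"`, `"right"`.
#' @param prev_mode mode to retain when `hit` is `FALSE`.
#' @return `"active"` or `"inactive"`.
#' @export
select_mode <- function(hit, wind_class, prev_mode = "inactive") {
  if (!hit) return(prev_mode)
  if (wind_class == "front") "active" else "inactive"
}
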