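# shared fixtures for the test suite (everything built in code)

# a quiet arena: constant wind, no filament jitter
quiet_scenario <- function(...) {
  scenario_config(turbulence = list(direction_sd = 0, speed_sd = 0,
                                    correlation_time = 2),
                  plume = list(jitter_sd = 0),
                  ...)
}

# a plume holding exactly the given filaments
plume_with <- function(x, y, sigma) {
  p <- new_plume(capacity = max(8L, length(x)))
  p$x[seq_along(x)] <- x
  p$y[seq_along(y)] <- y
  p$sigma[seq_along(sigma)] <- sigma
  p$n <- length(x)
  p
}

# two-sided Fisher exact p-value by direct hypergeometric enumeration
# (independent oracle for compare_success_counts)
fisher_p_enum <- function(s1, n1, s2, n2) {
  k <- s1 + s2
  lo <- max(0L, k - n2); hi <- min(n1, k)
  probs <- stats::dhyper(lo:hi, n1, n2, k)
  p_obs <- stats::dhyper(s1, n1, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# noiseless per-tick log generated from a gain law, f at bin centers
law_log <- function(mode = "active", table = gain_table(),
                    f_grid = seq(0.05, 1.45, by = 0.1), per_bin = 20) {
  f <- rep(f_grid, each = per_bin)
  g <- velocity_gain(f, mode, table, clamp = FALSE)
  data.frame(t = seq_along(f) * 0.01, f = f, mode = mode,
             v_cmd = g$K_v, w_cmd = g$K_w)
}
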