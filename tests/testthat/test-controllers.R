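test_that("the gain table holds the published coefficients", {
  gt <- gain_table()
  expect_equal(unname(gt$coef["active", "low", ]), c(53.6, 0.888, 129, 1.82))
  expect_equal(unname(gt$coef["inactive", "low", ]), c(0.0, 1.13, 105, 1.85))
  expect_equal(unname(gt$coef["inactive", "high", ]), c(0.0, -1.30, 105, 2.34))
  # corrected high-frequency active row swaps the two middle printed entries
  expect_equal(unname(gt$coef["active", "high", ]), c(-114, -1.59, 246, 2.81))
  raw <- gain_table(corrected = FALSE)
  expect_equal(unname(raw$coef["active", "high", ]), c(-114, 246, -1.59, 2.81))
  expect_error(gain_table(v_min = 0), "v_min")
  expect_error(gain_table(v_min = 300, v_max = 250), "v_min")
})

test_that("velocity gains follow the piecewise affine law with clamping", {
  gt <- gain_table()
  expect_equal(velocity_gain(0, "active", gt, clamp = FALSE)$K_v, 129)
  expect_equal(velocity_gain(0, "active", gt, clamp = FALSE)$K_w, 1.82)
  expect_equal(velocity_gain(0.4, "inactive", gt, clamp = FALSE)$K_v, 105)
  expect_equal(velocity_gain(0.7, "active", gt, clamp = FALSE)$K_v,
               53.6 * 0.7 + 129)  # 166.52, low branch includes the breakpoint
  expect_equal(velocity_gain(0.8, "active", gt, clamp = FALSE)$K_v,
               -114 * 0.8 + 246)
  # near-continuity of K_v at the breakpoint under the corrected reading
  lo <- velocity_gain(0.7, "active", gt, clamp = FALSE)$K_v
  hi <- -114 * 0.7 + 246
  expect_lt(abs(lo - hi), 1)
  # the inactive K_w discontinuity at 0.7 Hz is as printed
  expect_equal(velocity_gain(0.7, "inactive", gt, clamp = FALSE)$K_w,
               1.13 * 0.7 + 1.85)
  expect_equal(velocity_gain(0.71, "inactive", gt, clamp = FALSE)$K_w,
               -1.30 * 0.71 + 2.34)
  # clamps
  expect_equal(velocity_gain(3, "active", gt)$K_v, 50)    # raw would be < 0
  expect_equal(velocity_gain(3, "active", gt)$K_w, 0.5)
  expect_error(velocity_gain(-0.1, "active", gt), "non-negative")
  # monotonicity: active K_v strictly increasing below the breakpoint,
  # inactive K_v constant
  f <- seq(0, 0.7, by = 0.05)
  expect_true(all(diff(velocity_gain(f, "active", gt, clamp = FALSE)$K_v) > 0))
  expect_true(all(velocity_gain(f, "inactive", gt, clamp = FALSE)$K_v == 105))
})

test_that("search mode follows odor-wind agreement and is retained", {
  expect_identical(select_mode(TRUE, "front"), "active")
  expect_identical(select_mode(TRUE, "left"), "inactive")
  expect_identical(select_mode(TRUE, "back"), "inactive")
  expect_identical(select_mode(FALSE, "front", prev_mode = "inactive"),
                   "inactive")
  expect_identical(select_mode(FALSE, "back", prev_mode = "active"), "active")
})

test_that("the state machine times surge, counts zigzag turns, ends in loop", {
  p <- ctrl_params()
  dt <- 0.01
  st <- controller_state("szl", p)
  st$fsm <- "loop"
  # a detection in any state re-enters surge with timers reset
  st2 <- fsm_step(st, TRUE, "left", 1.5, dt, p)
  expect_identical(st2$fsm, "surge")
  expect_identical(st2$t_in_state, 0)
  expect_identical(st2$zigzag_turns_done, 0L)
  expect_identical(st2$last_hit_side, "left")
  # continued contact keeps surge alive indefinitely
  for (i in 1:200) st2 <- fsm_step(st2, TRUE, "none", 1.5, dt, p)
  expect_identical(st2$fsm, "surge")
  # after 0.5 s without detection, surge falls back to zigzag
  st3 <- st2
  n_surge <- 0L
  while (st3$fsm == "surge") { st3 <- fsm_step(st3, FALSE, "none", 1.5, dt, p)
                               n_surge <- n_surge + 1L }
  expect_equal(n_surge * dt, p$surge_duration, tolerance = 2 * dt)
  expect_identical(st3$fsm, "zigzag")
  # first zigzag turn is toward the last hit side (left = +1)
  expect_identical(st3$turn_sign, 1)
  # run on without detections: three alternating turns, then loop
  signs <- integer(0)
  phase_prev <- st3$phase
  st4 <- st3
  for (i in 1:5000) {
    if (st4$fsm != "zigzag") break
    if (st4$phase == "turn" && phase_prev != "turn") NULL
    st4 <- fsm_step(st4, FALSE, "none", 1.5, dt, p)
    if (st4$phase == "straight" && phase_prev == "turn")
      signs <- c(signs, st4$turn_sign)
    phase_prev <- st4$phase
  }
  expect_identical(st4$fsm, "loop")
  expect_identical(signs, c(1, -1, 1))          # +, -, + across the turns
  expect_identical(st4$turn_sign, 1)           # loop keeps the third sign
  # loop persists and always commands a turn
  for (i in 1:100) st4 <- fsm_step(st4, FALSE, "none", 1.5, dt, p)
  expect_identical(st4$fsm, "loop")
  expect_identical(st4$phase, "turn")
})

test_that("RMI modulates speed by mode and frequency", {
  gt <- gain_table()
  p <- ctrl_params()
  st <- controller_state("rmi", p)
  # detection with wind from the front selects active search
  out <- rmi_policy(st, list(detected = TRUE, side = "front",
                             wind_class = "front"), f = 0.4, gt, p)
  expect_identical(out$state$mode, "active")
  expect_equal(out$v, 53.6 * 0.4 + 129)         # 150.44 mm/s, surge straight
  expect_identical(out$w, 0)
  # detection with crosswind selects inactive search: constant 105 mm/s
  out2 <- rmi_policy(st, list(detected = TRUE, side = "front",
                              wind_class = "left"), f = 0.3, gt, p)
  expect_identical(out2$state$mode, "inactive")
  expect_equal(out2$v, 105)
  # no detection retains the mode
  out3 <- rmi_policy(out2$state, list(detected = FALSE, side = "none",
                                      wind_class = "front"), f = 0, gt, p)
  expect_identical(out3$state$mode, "inactive")
  # purity: identical inputs give identical outputs
  expect_identical(out, rmi_policy(st, list(detected = TRUE, side = "front",
                                            wind_class = "front"),
                                   f = 0.4, gt, p))
})

test_that("SZL is the same program at constant speeds, ignoring wind", {
  p <- ctrl_params()
  st <- controller_state("szl", p)
  out <- szl_policy(st, list(detected = TRUE, side = "front",
                             wind_class = "front"), p)
  expect_identical(out$v, 150)
  # wind class is not an input: commands bitwise-equal for front vs back
  out_b <- szl_policy(st, list(detected = TRUE, side = "front",
                               wind_class = "back"), p)
  expect_identical(out, out_b)
  # loop turns at 1.5 rad/s
  st$fsm <- "loop"; st$phase <- "turn"; st$turn_sign <- -1
  out2 <- szl_policy(st, list(detected = FALSE, side = "none",
                              wind_class = "left"), p)
  expect_identical(abs(out2$w), 1.5)
  expect_identical(out2$v, 150)
})

test_that("RMI with a degenerate gain table reproduces SZL exactly", {
  # all slopes zero, intercepts at the baseline speeds, clamps wide open
  gt <- gain_table(v_min = 1e-9, v_max = 1e9, w_min = 1e-9, w_max = 1e9)
  gt$coef["active", , "a_v"] <- 0;  gt$coef["inactive", , "a_v"] <- 0
  gt$coef["active", , "a_w"] <- 0;  gt$coef["inactive", , "a_w"] <- 0
  gt$coef["active", , "b_v"] <- 150; gt$coef["inactive", , "b_v"] <- 150
  gt$coef["active", , "b_w"] <- 1.5; gt$coef["inactive", , "b_w"] <- 1.5
  p <- ctrl_params()
  st_r <- controller_state("rmi", p)
  st_s <- controller_state("szl", p)
  set.seed(5)
  for (i in 1:2000) {
    onset <- stats::runif(1) < 0.05
    level <- onset || stats::runif(1) < 0.2
    percept <- list(
      detected = level,
      side = if (onset) sample(c("left", "right", "front"), 1) else "none",
      wind_class = sample(c("front", "back", "left", "right"), 1))
    f <- stats::runif(1, 0, 2)
    o_r <- rmi_policy(st_r, percept, f, gt, p)
    o_s <- szl_policy(st_s, percept, p)
    expect_identical(o_r$v, o_s$v)
    expect_identical(o_r$w, o_s$w)
    st_r <- o_r$state; st_s <- o_s$state
  }
})

test_that("commanded speed is positive for every controller and stream", {
  gt <- gain_table()
  p <- ctrl_params()
  sts <- list(rmi = controller_state("rmi", p),
              szl = controller_state("szl", p),
              sc = controller_state("sc", p))
  set.seed(8)
  for (i in 1:1500) {
    onset <- stats::runif(1) < 0.05
    percept <- list(
      detected = onset || stats::runif(1) < 0.2,
      side = if (onset) sample(c("left", "right", "front"), 1) else "none",
      wind_class = sample(c("front", "back", "left", "right"), 1),
      wind_vector_body = stats::rnorm(2))
    f <- stats::runif(1, 0, 3)
    o1 <- rmi_policy(sts$rmi, percept, f, gt, p); sts$rmi <- o1$state
    o2 <- szl_policy(sts$szl, percept, p); sts$szl <- o2$state
    o3 <- sc_policy(sts$sc, percept, p); sts$sc <- o3$state
    expect_gte(o1$v, gt$v_min); expect_lte(o1$v, gt$v_max)
    expect_gt(o2$v, 0); expect_gt(o3$v, 0)
    expect_lte(abs(o1$w), gt$w_max)
  }
})

test_that("surge-cast surges upwind on contact and casts with doubling legs", {
  p <- ctrl_params()
  st <- controller_state("sc", p)
  expect_identical(st$sc_state, "cast_turn")  # without detection: cast only
  # detection while facing upwind: straight at 150, no turning
  upwind <- list(detected = TRUE, side = "front", wind_class = "front",
                 wind_vector_body = c(-1, 0))
  out <- sc_policy(st, upwind, p)
  expect_identical(out$state$sc_state, "surge")
  expect_identical(out$v, 150); expect_identical(out$w, 0)
  # detection with wind from the left: turn toward it at 1.5 rad/s
  crossw <- list(detected = TRUE, side = "front", wind_class = "left",
                 wind_vector_body = c(0, -1))
  out2 <- sc_policy(st, crossw, p)
  expect_identical(abs(out2$w), 1.5)

  # lost plume: cast legs alternate sides with durations d, 2d, 4d, ...
  # drive the policy with wind always arriving from the required side so the
  # cast turn completes instantly and leg durations are measurable
  st <- controller_state("sc", p)
  st$t_since_detection <- 100
  legs <- numeric(0); cur <- 0; last_state <- st$sc_state
  for (i in 1:6000) {
    wc <- if (st$cast_sign > 0) "left" else "right"
    percept <- list(detected = FALSE, side = "none", wind_class = wc,
                    wind_vector_body = c(0, -st$cast_sign))
    out <- sc_policy(st, percept, p, dt = 0.01)
    st <- out$state
    if (st$sc_state == "cast_leg") cur <- cur + 0.01
    if (st$sc_state == "cast_turn" && last_state == "cast_leg") {
      legs <- c(legs, cur); cur <- 0
    }
    last_state <- st$sc_state
    expect_false(st$sc_state == "surge")  # never surges without detection
  }
  expect_gte(length(legs), 3)
  expect_equal(legs[1], 1.5, tolerance = 0.05)
  expect_equal(legs[2], 3.0, tolerance = 0.05)
  expect_equal(legs[3], 6.0, tolerance = 0.05)
})
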