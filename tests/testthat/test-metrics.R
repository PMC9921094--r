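test_that("crosswind RMSE matches its closed forms", {
  expect_identical(crosswind_rmse(c(0.2, 0.2, 0.2), y_odor = 0.2), 0)
  # constant offset c gives |c|
  expect_equal(crosswind_rmse(rep(-0.35, 7), y_odor = 0), 0.35)
  # hand-computed three-point case
  expect_equal(crosswind_rmse(c(0.3, -0.4, 0), y_odor = 0),
               sqrt((0.09 + 0.16 + 0) / 3))
  expect_equal(crosswind_rmse(c(0.3, -0.4, 0), y_odor = 0), 0.2886751,
               tolerance = 1e-6)
  # matrix and trial interfaces agree with the vector one
  m <- cbind(t = 0:2, x = c(0, 0.5, 1), y = c(0.3, -0.4, 0), heading = 0)
  expect_equal(crosswind_rmse(m), crosswind_rmse(c(0.3, -0.4, 0)))
  expect_error(crosswind_rmse(numeric(0)), "empty")
})

test_that("batch summaries count outcomes and collect per-trial metrics", {
  fake <- function(outcome, t_loc, ys) {
    structure(list(outcome = outcome, localization_time = t_loc,
                   trajectory = cbind(t = seq_along(ys), x = 0, y = ys,
                                      heading = 0),
                   y_odor = 0, algorithm = "rmi", scenario = "a"),
              class = "plume_trial")
  }
  trials <- c(replicate(17, fake("success", 30, c(0.1, -0.1)),
                        simplify = FALSE),
              replicate(3, fake("timeout", NA_real_, c(0.5, 0.5)),
                        simplify = FALSE))
  s <- summarize_batch(trials)
  expect_equal(s$n_trials, 20)
  expect_equal(s$n_success, 17)
  expect_equal(s$success_rate, 0.85)
  expect_length(s$localization_times, 17)
  expect_equal(s$rmse_values,
               vapply(trials, crosswind_rmse, numeric(1)))
  # all failures: no localization times
  s0 <- summarize_batch(replicate(4, fake("exit_field", NA_real_, 0.2),
                                  simplify = FALSE))
  expect_length(s0$localization_times, 0)
  expect_equal(s0$success_rate, 0)
})

test_that("the Fisher comparison matches exact enumeration and is symmetric", {
  sm <- function(s, n) list(n_success = s, n_trials = n)
  expect_equal(compare_success_counts(sm(12, 20), sm(12, 20)), 1)
  # extreme 20/20 vs 0/20 table: hypergeometric tail value
  expect_equal(compare_success_counts(sm(20, 20), sm(0, 20)),
               fisher_p_enum(20, 20, 0, 20), tolerance = 1e-10)
  # symmetry under swapping groups
  expect_equal(compare_success_counts(sm(15, 20), sm(7, 20)),
               compare_success_counts(sm(7, 20), sm(15, 20)))
  expect_error(compare_success_counts(sm(0, 0), sm(1, 2)), "one trial")
  # monotone in imbalance for fixed margins
  p_small <- compare_success_counts(sm(11, 20), sm(9, 20))
  p_big <- compare_success_counts(sm(18, 20), sm(2, 20))
  expect_gt(p_small, p_big)
  expect_true(p_small <= 1 && p_big > 0)
  # rank-sum hook degrades to NA on empty groups
  expect_true(is.na(compare_rank_sum(numeric(0), 1:3)))
  expect_lt(compare_rank_sum(1:10, 101:110), 0.01)
})

test_that("modulation curves bin by mode and report medians or emptiness", {
  log <- law_log("active")
  cur <- modulation_curves(log, bin_width = 0.1)
  expect_s3_class(cur, "modulation_curve")
  pop <- cur[cur$n > 0, ]
  # noiseless log at bin centers: medians reproduce the generating law
  g <- velocity_gain(pop$f_mid, "active", gain_table(), clamp = FALSE)
  expect_equal(pop$v_med, g$K_v)
  expect_equal(pop$w_med, abs(g$K_w))
  expect_true(all(diff(cur$f_lo) > 0))
  expect_true(all(cur$f_hi > cur$f_lo))
  # empty log gives empty curves, not zeros
  cur0 <- modulation_curves(log[0, ])
  expect_equal(nrow(cur0), 0)
  # single-bin data populates exactly one bin
  one <- log[log$f == 0.05, ]
  cur1 <- modulation_curves(one, bin_width = 0.1)
  expect_equal(sum(cur1$n > 0), 1)
  expect_true(is.na(cur1$v_med[cur1$n == 0][1]) || all(cur1$n > 0))
})

test_that("piecewise gain recovery returns the generating coefficients", {
  cur <- modulation_curves(law_log("active"), bin_width = 0.1)
  fit <- fit_piecewise_gains(cur, breakpoint = 0.7)
  expect_lt(abs(fit$v$low$a - 53.6) / 53.6, 1e-6)
  expect_lt(abs(fit$v$low$b - 129) / 129, 1e-6)
  expect_lt(abs(fit$v$high$a - (-114)) / 114, 1e-6)
  expect_lt(abs(fit$v$high$b - 246) / 246, 1e-6)
  expect_lt(abs(fit$w$low$a - 0.888) / 0.888, 1e-6)
  cf <- coef(fit)
  expect_equal(dim(cf), c(4L, 2L))
  expect_equal(cf["v_low", "a"], fit$v$low$a)

  # constant-speed samples give a slope of ~0
  cur_c <- modulation_curves(law_log("inactive"), bin_width = 0.1)
  fit_c <- fit_piecewise_gains(cur_c, breakpoint = 0.7)
  expect_lt(abs(fit_c$v$low$a), 1e-9)
  expect_equal(fit_c$v$low$b, 105, tolerance = 1e-9)

  # an underdetermined branch is flagged and withheld
  few <- cur[cur$f_mid <= 0.15, ]
  fit_u <- fit_piecewise_gains(few, breakpoint = 0.7)
  expect_true(fit_u$v$high$underdetermined)
  expect_true(is.na(fit_u$v$high$a))
})

test_that("gain recovery tolerates measurement noise", {
  set.seed(31)
  f_grid <- seq(0.05, 1.45, by = 0.1)
  f <- rep(f_grid, each = 200)
  g <- velocity_gain(f, "active", gain_table(), clamp = FALSE)
  log <- data.frame(t = seq_along(f) * 0.01, f = f, mode = "active",
                    v_cmd = g$K_v + stats::rnorm(length(f), sd = 10),
                    w_cmd = g$K_w)
  # fit on the raw samples (one bin per sampled frequency keeps the median a
  # consistent estimator of the affine law at the bin center)
  cur <- modulation_curves(log, bin_width = 0.1)
  fit <- fit_piecewise_gains(cur, breakpoint = 0.7)
  expect_lt(abs(fit$v$low$a - 53.6), 3 * max(fit$v$low$se_a, 1))
  expect_lt(abs(fit$v$high$a - (-114)), 3 * max(fit$v$high$se_a, 1))
})
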