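#' Crosswind trajectory RMSE
#'
#' Root-mean-square deviation of the trajectory's crosswind coordinate from
#' the odor-source line:
#' `RMSE = sqrt( (1/n) * sum_i (y_i - y_odor)^2 )` over every logged step.
#' Small values mean the agent moved smoothly inside the plume instead of
#' meandering across it.
#'
#' @param trajectory a `plume_trial`, a matrix with a `y` column, or a numeric
#'   vector of y coordinates.
#' @param y_odor y coordinate of the odor source (m); taken from the trial if
#'   one is supplied.
#' @return RMSE (m), non-negative.
#' @export
#' @examples
#' crosswind_rmse(c(0.3, -0.4, 0), y_odor = 0)  # 0.2886751
crosswind_rmse <- function(trajectory, y_odor = 0) {
  if (inherits(trajectory, "plume_trial")) {
    y_odor <- trajectory$y_odor
    y <- trajectory$trajectory[, "y"]
  } else if (is.matrix(trajectory)) {
    y <- trajectory[, "y"]
  } else {
    y <- as.numeric(trajectory)
  }
  if (length(y) < 1) stop("empty trajectory")
  sqrt(mean((y - y_odor)^2))
}

#' Summarize a batch of trials
#'
#' Aggregates trial outcomes into the standard evaluation: success rate,
#' localization times of the successful trials, and per-trial crosswind RMSE.
#'
#' @param results a `plume_batch` or list of `plume_trial`s.
#' @return An object of class `batch_summary` with fields `algorithm`,
#'   `scenario`, `n_trials`, `n_success`, `success_rate`,
#'   `localization_times` (successful trials only) and `rmse_values` (all
#'   trials).
#' @export
summarize_batch <- function(results) {
  if (inherits(results, "plume_trial")) results <- list(results)
  if (length(results) < 1) stop("need at least one trial")
  outcomes <- vapply(results, function(r) r$outcome, character(1))
  times <- vapply(results, function(r) r$localization_time, numeric(1))
  rmse <- vapply(results, crosswind_rmse, numeric(1))
  structure(list(
    algorithm = if (!is.null(attr(results, "algorithm")))
      attr(results, "algorithm") else results[[1]]$algorithm,
    scenario = if (!is.null(attr(results, "scenario")))
      attr(results, "scenario") else results[[1]]$scenario,
    n_trials = length(results),
    n_success = sum(outcomes == "success"),
    success_rate = mean(outcomes == "success"),
    outcomes = outcomes,
    localization_times = times[outcomes == "success"],
    rmse_values = rmse), class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf("<batch_summary> %s, scenario %s: %d/%d successes (%.0f%%)\n",
              toupper(x$algorithm), x$scenario, x$n_success, x$n_trials,
              100 * x$success_rate))
  if (x$n_success > 0)
    cat(sprintf("  localization time  median %.1f s (range %.1f-%.1f)\n",
                stats::median(x$localization_times),
                min(x$localization_times), max(x$localization_times)))
  cat(sprintf("  crosswind RMSE     median %.3f m (mean %.3f)\n",
              stats::median(x$rmse_values), mean(x$rmse_values)))
  invisible(x)
}

#' Compare success counts of two batches
#'
#' Two-sided Fisher exact test on the 2 x 2 success/failure table of two
#' algorithms (or conditions).
#'
#' @param summary1,summary2 `batch_summary` objects (or lists with
#'   `n_success` and `n_trials`).
#' @return The two-sided p-value.
#' @export
compare_success_counts <- function(summary1, summary2) {
  if (summary1$n_trials < 1 || summary2$n_trials < 1)
    stop("both batches need at least one trial")
  tab <- matrix(c(summary1$n_success, summary1$n_trials - summary1$n_success,
                  summary2$n_success, summary2$n_trials - summary2$n_success),
                nrow = 2)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Rank-sum comparison of a continuous trial metric
#'
#' Convenience hook for comparing localization times or RMSE values between
#' two batches with a two-sided Wilcoxon rank-sum test.
#'
#' @param values1,values2 numeric vectors (e.g. `rmse_values`).
#' @return The two-sided p-value, or `NA` if either group is empty.
#' @export
compare_rank_sum <- function(values1, values2) {
  if (length(values1) < 1 || length(values2) < 1) return(NA_real_)
  stats::wilcox.test(values1, values2, exact = FALSE)$p.value
}

#' Frequency-binned behavioral modulation curves
#'
#' Reconstructs, from per-tick stimulus logs, how commanded speed varies with
#' odor-detection frequency: samples are partitioned by search mode and by
#' frequency bin, and the per-bin medians of the translational speed and of
#' the absolute angular speed are reported. Bins with no samples are reported
#' empty (`NA`), not zero.
#'
#' @param logs a `plume_trial`, a list of them, or a data.frame with columns
#'   `f`, `mode`, `v_cmd`, `w_cmd`.
#' @param bin_width frequency bin width (Hz), default 0.1.
#' @return A data.frame of class `modulation_curve` with columns `mode`,
#'   `f_lo`, `f_hi`, `f_mid`, `n`, `v_med` (mm/s), `w_med` (rad/s).
#' @export
modulation_curves <- function(logs, bin_width = 0.1) {
  df <- collect_logs(logs)
  if (nrow(df) == 0) {
    out <- data.frame(mode = character(), f_lo = numeric(),
                      f_hi = numeric(), f_mid = numeric(), n = integer(),
                      v_med = numeric(), w_med = numeric())
    class(out) <- c("modulation_curve", "data.frame")
    return(out)
  }
  modes <- unique(df$mode)
  n_bins <- max(1L, ceiling((max(df$f) + 1e-9) / bin_width))
  out <- do.call(rbind, lapply(modes, function(m) {
    sub <- df[df$mode == m, ]
    bin <- pmin(floor(sub$f / bin_width), n_bins - 1L)
    rows <- lapply(seq_len(n_bins) - 1L, function(b) {
      sel <- bin == b
      data.frame(mode = m, f_lo = b * bin_width, f_hi = (b + 1) * bin_width,
                 f_mid = (b + 0.5) * bin_width, n = sum(sel),
                 v_med = if (any(sel)) stats::median(sub$v_cmd[sel]) else NA_real_,
                 w_med = if (any(sel)) stats::median(abs(sub$w_cmd[sel])) else NA_real_)
    })
    do.call(rbind, rows)
  }))
  rownames(out) <- NULL
  class(out) <- c("modulation_curve", "data.frame")
  out
}

collect_logs <- function(logs) {
  if (inherits(logs, "plume_trial")) logs <- list(logs)
  if (is.data.frame(logs)) return(logs)
  do.call(rbind, lapply(logs, function(l)
    if (inherits(l, "plume_trial")) l$log else l))
}

#' Plot modulation curves
#'
#' @param x a `modulation_curve`.
#' @param what `"v"` (translational) or `"w"` (angular).
#' @param ... passed to [graphics::plot()].
#' @export
plot.modulation_curve <- function(x, what = c("v", "w"), ...) {
  what <- match.arg(what)
  col <- if (what == "v") "v_med" else "w_med"
  ylab <- if (what == "v") "median v (mm/s)" else "median |omega| (rad/s)"
  ok <- !is.na(x[[col]])
  graphics::plot(x$f_mid[ok], x[[col]][ok],
                 col = as.integer(factor(x$mode[ok])), pch = 16,
                 xlab = "odor-detection frequency (Hz)", ylab = ylab, ...)
  graphics::legend("topleft", legend = levels(factor(x$mode[ok])),
                   col = seq_along(levels(factor(x$mode[ok]))), pch = 16,
                   bty = "n")
  invisible(x)
}

#' Recover piecewise-affine gains from a modulation curve
#'
#' Least-squares affine fit `K = a * f + b` per frequency branch (below and
#' above a fixed breakpoint), for both the translational and the angular
#' channel, from the binned medians of a [modulation_curves()] result. This
#' closes the loop between the behavioral analysis and the controller: fed a
#' noiseless log generated by the gain law itself, it returns the generating
#' coefficients.
#'
#' @param curve a `modulation_curve` (one mode at a time: if several modes are
#'   present, pass `mode` to choose).
#' @param breakpoint branch breakpoint (Hz), default 0.7.
#' @param mode which mode label to fit when `curve` holds several.
#' @return An object of class `gain_fit`: per-branch coefficient estimates
#'   with standard errors. A branch with fewer than 2 populated bins is
#'   flagged underdetermined and its estimates are withheld (`NA`).
#' @export
fit_piecewise_gains <- function(curve, breakpoint = 0.7, mode = NULL) {
  stopifnot(is.data.frame(curve))
  if (!is.null(mode)) curve <- curve[curve$mode == mode, ]
  if (length(unique(curve$mode)) > 1)
    stop("curve holds several modes; pick one with `mode =`")
  curve <- curve[curve$n > 0, , drop = FALSE]

  fit_branch <- function(sub, col) {
    sub <- sub[!is.na(sub[[col]]), , drop = FALSE]
    if (nrow(sub) < 2)
      return(list(a = NA_real_, b = NA_real_, se_a = NA_real_,
                  se_b = NA_real_, underdetermined = TRUE))
    fm <- stats::lm(y ~ f, data = data.frame(f = sub$f_mid, y = sub[[col]]))
    cf <- stats::coef(fm)
    # a noiseless log fits exactly; the zero-residual SE warning is expected
    se <- suppressWarnings(sqrt(diag(stats::vcov(fm))))
    list(a = unname(cf["f"]), b = unname(cf["(Intercept)"]),
         se_a = unname(se["f"]), se_b = unname(se["(Intercept)"]),
         underdetermined = FALSE)
  }
  low <- curve[curve$f_mid <= breakpoint, , drop = FALSE]
  high <- curve[curve$f_mid > breakpoint, , drop = FALSE]
  structure(list(
    breakpoint = breakpoint,
    mode = if (nrow(curve) > 0) curve$mode[1] else NA_character_,
    v = list(low = fit_branch(low, "v_med"), high = fit_branch(high, "v_med")),
    w = list(low = fit_branch(low, "w_med"), high = fit_branch(high, "w_med"))),
    class = "gain_fit")
}

#' @export
print.gain_fit <- function(x, ...) {
  cat("<gain_fit> breakpoint", x$breakpoint, "Hz, mode:",
      x$mode, "\n")
  show <- function(ch, br, unit) {
    e <- x[[ch]][[br]]
    if (isTRUE(e$underdetermined))
      cat(sprintf("  K_%s %-4s: underdetermined (< 2 populated bins)\n",
                  ch, br))
    else
      cat(sprintf("  K_%s %-4s: a = %8.3f, b = %8.3f %s\n", ch, br,
                  e$a, e$b, unit))
  }
  show("v", "low", "mm/s"); show("v", "high", "mm/s")
  show("w", "low", "rad/s"); show("w", "high", "rad/s")
  invisible(x)
}

#' @export
coef.gain_fit <- function(object, ...) {
  m <- rbind(v_low = c(object$v$low$a, object$v$low$b),
             v_high = c(object$v$high$a, object$v$high$b),
             w_low = c(object$w$low$a, object$w$low$b),
             w_high = c(object$w$high$a, object$w$high$b))
  colnames(m) <- c("a", "b")
  m
}
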