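# Pyrene actin polymerization kinetics: plateau (Ymax) and half-time (t1/2)
# from bulk fluorescence traces.
#
# Model: baseline y0 during a nucleation lag, then pseudo-first-order
# elongation,
#   y(t) = y0,                                         t <  lag
#   y(t) = y0 + (ymax - y0) * (1 - exp(-k (t - lag))),  t >= lag
# so the half-time is t1/2 = lag + log(2) / k and the fitted curve passes
# through (t1/2, (y0 + ymax) / 2) by construction.

#' Polymerization trace
#'
#' @param time_s strictly increasing sample times (s), >= 10 samples.
#' @param fluorescence pyrene fluorescence (A.U.).
#' @param condition_label condition label.
#' @return an object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time_s, fluorescence, condition_label = "trace") {
  if (length(time_s) != length(fluorescence))
    stop("'time_s' and 'fluorescence' must have equal length")
  if (length(time_s) < 10) stop("a trace needs at least 10 samples")
  if (any(diff(time_s) <= 0)) stop("'time_s' must be strictly increasing")
  structure(list(time_s = as.numeric(time_s),
                 fluorescence = as.numeric(fluorescence),
                 condition_label = as.character(condition_label)),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> '%s': %d samples over %.0f s\n",
              x$condition_label, length(x$time_s), max(x$time_s)))
  invisible(x)
}

#' @export
plot.kinetic_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$fluorescence, xlab = "time (s)",
                 ylab = "pyrene fluorescence (A.U.)",
                 main = x$condition_label, pch = 16, cex = 0.5, ...)
  invisible(x)
}

# centered moving average with partial windows at the edges
moving_mean <- function(v, window) {
  h <- (window - 1) / 2
  n <- length(v)
  vapply(seq_len(n), function(i)
    mean(v[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Model-free plateau and half-time estimates
#'
#' Smooths the trace with a centered moving average; the plateau estimate is
#' the mean of the top decile of the smoothed trace, the baseline the mean
#' of the first few samples, and the half-time the first time the smoothed
#' trace crosses halfway between them (linearly interpolated).  Used to
#' initialize the model fit and as a model-agnostic fallback.
#'
#' @param trace a [kinetic_trace()].
#' @param smooth_window odd window length in samples, < n / 2.
#' @return list with `y0_est`, `ymax_est` and `t_half_est` (s).
#' @export
model_free_estimates <- function(trace, smooth_window = 5) {
  stopifnot(inherits(trace, "kinetic_trace"))
  n <- length(trace$time_s)
  if (smooth_window %% 2 == 0 || smooth_window >= n / 2)
    stop("'smooth_window' must be odd and smaller than half the trace")
  sm <- moving_mean(trace$fluorescence, smooth_window)
  ymax_est <- mean(sort(sm, decreasing = TRUE)[seq_len(max(1, n %/% 10))])
  # baseline: linear extrapolation of the smoothed start back to t <= 0
  # (corrects the upward bias of the first smoothed samples on traces that
  # rise without a lag), floored at the smoothed minimum
  y0_est <- max(min(trace$fluorescence), 2 * sm[1] - sm[2])
  if (ymax_est - y0_est <= 1e-9 * max(abs(ymax_est), 1))
    stop("no crossing: the trace never rises above its baseline")
  half <- (y0_est + ymax_est) / 2
  above <- which(sm >= half)
  if (!length(above))
    stop("no crossing: the trace never reaches half-maximum")
  i <- above[1]
  t_half_est <- if (i == 1) trace$time_s[1] else {
    f <- (half - sm[i - 1]) / (sm[i] - sm[i - 1])
    trace$time_s[i - 1] + f * (trace$time_s[i] - trace$time_s[i - 1])
  }
  list(y0_est = y0_est, ymax_est = ymax_est, t_half_est = t_half_est)
}

lag_exp_model <- function(t, y0, ymax, k, lag) {
  ifelse(t < lag, y0, y0 + (ymax - y0) * (1 - exp(-k * (t - lag))))
}

#' Fit a polymerization trace (lagged exponential saturation)
#'
#' Least-squares fit of the lag + pseudo-first-order saturation model via
#' Levenberg-Marquardt with multistart initialization from
#' [model_free_estimates()].  The observed (smoothed) maximum is reported
#' alongside the fitted plateau, since published plateau values may be
#' either.
#'
#' @param trace a [kinetic_trace()].
#' @param trim_baseline drop leading samples below 2% of the rise before
#'   fitting instead of letting the lag parameter absorb them.
#' @return an object of class `kinetic_fit` with fields `y0`, `ymax`,
#'   `t_half_s`, `k`, `lag_s`, `ymax_observed`, `rss`, `se` (approximate
#'   standard errors), `model`, `trace`.
#' @export
fit_kinetics <- function(trace, trim_baseline = FALSE) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$time_s; y <- trace$fluorescence
  noise <- stats::mad(diff(y)) / sqrt(2)
  if (max(y) - min(y) <= 5 * max(noise, 1e-12))
    stop("flat trace: no polymerization rise detected")
  if (trim_baseline) {
    rise <- min(y) + 0.02 * (max(y) - min(y))
    first <- which(y > rise)[1]
    if (!is.na(first) && first > 1) { t <- t[(first - 1):length(t)]
                                      y <- y[(first - 1):length(y)] }
  }
  mf <- model_free_estimates(trace)
  lag_starts <- unique(pmax(0, c(0, mf$t_half_est / 4, mf$t_half_est / 2)))
  best <- NULL; diag_msgs <- character(0)
  for (lag0 in lag_starts) {
    k0 <- log(2) / max(mf$t_half_est - lag0, diff(range(t)) / 100)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ lag_exp_model(t, y0, ymax, k, lag),
        start = list(y0 = mf$y0_est, ymax = mf$ymax_est, k = k0,
                     lag = lag0),
        lower = c(y0 = -Inf, ymax = mf$y0_est, k = 1e-8, lag = 0),
        upper = c(y0 = mf$ymax_est, ymax = Inf, k = Inf, lag = max(t)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) { diag_msgs <<- c(diag_msgs, conditionMessage(e))
                            NULL })
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("kinetic fit did not converge from any start; diagnostics: ",
         paste(unique(diag_msgs), collapse = "; "))
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, 2],
                 error = function(e) rep(NA_real_, 4))
  sm <- moving_mean(trace$fluorescence, 5)
  structure(list(y0 = unname(cf["y0"]), ymax = unname(cf["ymax"]),
                 k = unname(cf["k"]), lag_s = unname(cf["lag"]),
                 t_half_s = unname(cf["lag"] + log(2) / cf["k"]),
                 ymax_observed = max(sm), rss = best$rss,
                 se = se, model = "exp_sat_lag",
                 condition_label = trace$condition_label, trace = trace,
                 nls_fit = best$fit),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> '%s' (%s)\n", x$condition_label, x$model))
  cat(sprintf("  y0 = %.4g, Ymax = %.4g (observed max %.4g)\n",
              x$y0, x$ymax, x$ymax_observed))
  cat(sprintf("  t1/2 = %.1f s (lag %.1f s, k = %.4g /s), RSS = %.4g\n",
              x$t_half_s, x$lag_s, x$k, x$rss))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  c(y0 = object$y0, ymax = object$ymax, k = object$k, lag = object$lag_s,
    t_half_s = object$t_half_s)
}

#' @export
predict.kinetic_fit <- function(object, time_s = NULL, ...) {
  if (is.null(time_s)) time_s <- object$trace$time_s
  lag_exp_model(time_s, object$y0, object$ymax, object$k, object$lag_s)
}

#' @export
residuals.kinetic_fit <- function(object, ...) {
  object$trace$fluorescence - predict(object)
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  plot(x$trace, ...)
  tt <- seq(min(x$trace$time_s), max(x$trace$time_s), length.out = 300)
  graphics::lines(tt, predict(x, tt), col = "red3", lwd = 2)
  graphics::abline(v = x$t_half_s, h = (x$y0 + x$ymax) / 2, lty = 3)
  invisible(x)
}

#' Compare plateau values across conditions
#'
#' Collects Ymax from a set of per-replicate fits and delegates to
#' [compare_groups()], with the no-additive control (default
#' `"actin_alone"`) as the Dunnett reference.  Two conditions reduce to the
#' two-tailed t test.
#'
#' @param fits list of [fit_kinetics()] results (each carries its condition
#'   label).
#' @param control control condition label.
#' @param quantity `"ymax"` (fitted plateau) or `"ymax_observed"`.
#' @return a [compare_groups()] `group_comparison`.
#' @export
compare_ymax <- function(fits, control = "actin_alone", quantity = "ymax") {
  stopifnot(length(fits) >= 4)
  vals <- vapply(fits, function(f) f[[quantity]], numeric(1))
  grp <- vapply(fits, function(f) f$condition_label, character(1))
  if (length(unique(grp)) == 2)
    return(compare_groups(vals, grp, test = "t_test"))
  if (!control %in% grp)
    stop("control condition '", control, "' not present among the fits")
  compare_groups(vals, grp, test = "one_way_anova_dunnett",
                 control = control)
}
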