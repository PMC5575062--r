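# Standard-score normalization, correlation/regression with a linearity
# gate, and the group-comparison tests used for growth-cone measurements.

#' Standard-score (z-score) normalization of a paired sample
#'
#' Each variable is centered and scaled by its own sample standard deviation
#' (n - 1 denominator), giving unitless standard scores so measurements on
#' different scales (e.g. comet counts and marker intensity) can be related.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return an object of class `zscored_pair` with fields `x_z`, `y_z`, `n`
#'   and the source `means`/`sds`.
#' @export
zscore_pair <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  for (nm in c("x", "y")) {
    v <- get(nm)
    if (stats::sd(v) == 0)
      stop("variable '", nm, "' has zero variance; z-scores are undefined")
  }
  structure(list(x_z = (x - mean(x)) / stats::sd(x),
                 y_z = (y - mean(y)) / stats::sd(y), n = n,
                 means = c(x = mean(x), y = mean(y)),
                 sds = c(x = stats::sd(x), y = stats::sd(y))),
            class = "zscored_pair")
}

#' Pearson correlation with least-squares line
#'
#' Returns Pearson's r with its two-sided p-value (t distribution on n - 2
#' df), the least-squares regression line and 95% confidence-band
#' parameters.  On exactly z-scored input the slope equals r and the
#' intercept is 0 (to numerical precision) — the identity that lets the
#' printed slope of a standard-score scatter double as its correlation
#' coefficient.
#'
#' @param x a numeric vector or a [zscore_pair()] result.
#' @param y numeric vector (ignored when `x` is a `zscored_pair`).
#' @return an object of class `correlation_result` with fields `r`,
#'   `p_value`, `slope`, `intercept`, `slope_se`, `intercept_se`,
#'   `residual_sd`, `n`, `model = "linear"`.
#' @export
pearson_fit <- function(x, y = NULL) {
  if (inherits(x, "zscored_pair")) { y <- x$y_z; x <- x$x_z }
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate variance; correlation is undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = cf[2, 2], intercept_se = cf[1, 2],
                 residual_sd = summary(fit)$sigma, n = n,
                 model = "linear", lm_fit = fit),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> n = %d\n", x$n))
  cat(sprintf("  Pearson r = %.4f, p = %.3g\n", x$r, x$p_value))
  cat(sprintf("  line: y = %.4f x + %.4g\n", x$slope, x$intercept))
  invisible(x)
}

#' Second-order polynomial fit result
#'
#' @param coefficients named quadratic coefficients (intercept, x, x^2).
#' @param r_squared quadratic R-squared.
#' @param r_squared_linear linear-fit R-squared on the same data (never
#'   exceeds `r_squared`).
#' @param lack_of_linearity_p p-value of the quadratic-vs-linear F-test that
#'   triggered the quadratic fit.
#' @param deviation_from_model_p p-value of the cubic-vs-quadratic F-test
#'   (a non-significant value supports the quadratic model).
#' @param n sample size.
#' @return an object of class `polyfit_result`.
#' @export
polyfit_result <- function(coefficients, r_squared, r_squared_linear,
                           lack_of_linearity_p, deviation_from_model_p, n) {
  stopifnot(r_squared >= 0, r_squared <= 1,
            r_squared >= r_squared_linear - 1e-12)
  structure(list(coefficients = coefficients, r_squared = r_squared,
                 r_squared_linear = r_squared_linear,
                 lack_of_linearity_p = lack_of_linearity_p,
                 deviation_from_model_p = deviation_from_model_p, n = n,
                 model = "quadratic"),
            class = "polyfit_result")
}

#' @export
print.polyfit_result <- function(x, ...) {
  cat(sprintf("<polyfit_result> n = %d, R^2 = %.4f (linear %.4f)\n",
              x$n, x$r_squared, x$r_squared_linear))
  cat(sprintf("  y = %.4g + %.4g x + %.4g x^2\n", x$coefficients[1],
              x$coefficients[2], x$coefficients[3]))
  cat(sprintf("  linearity deviation p = %.3g; model deviation p = %.3g\n",
              x$lack_of_linearity_p, x$deviation_from_model_p))
  invisible(x)
}

#' Linear fit with escalation to a quadratic on significant non-linearity
#'
#' Fits the least-squares line and tests the deviation from linearity with a
#' nested-model F-test (quadratic vs linear) at `alpha`.  When the deviation
#' is not significant the linear [pearson_fit()] is returned; otherwise the
#' second-order polynomial fit is returned together with a
#' deviation-from-model check (cubic vs quadratic F-test, expected
#' non-significant).
#'
#' @param x,y numeric vectors, n >= 5.
#' @param alpha significance level of the linearity gate (default 0.05).
#' @return a `correlation_result` (linear branch) or `polyfit_result`
#'   (quadratic branch).
#' @export
fit_with_linearity_gate <- function(x, y, alpha = 0.05) {
  n <- length(x)
  if (n < 5) stop("need at least 5 observations for the linearity gate")
  lin <- stats::lm(y ~ x)
  quad <- stats::lm(y ~ x + I(x^2))
  p_lin <- stats::anova(lin, quad)[2, "Pr(>F)"]
  if (is.na(p_lin) || p_lin >= alpha) return(pearson_fit(x, y))
  cub <- stats::lm(y ~ x + I(x^2) + I(x^3))
  p_dev <- stats::anova(quad, cub)[2, "Pr(>F)"]
  polyfit_result(coefficients = stats::coef(quad),
                 r_squared = summary(quad)$r.squared,
                 r_squared_linear = summary(lin)$r.squared,
                 lack_of_linearity_p = p_lin,
                 deviation_from_model_p = p_dev, n = n)
}

#' Group comparison with the tests used for growth-cone measurements
#'
#' Two groups are compared by a two-tailed Student's t test (pooled
#' variance); more than two groups by one-way ANOVA followed by a
#' Dunnett-vs-control or Tukey all-pairs post hoc with single-step
#' multivariate-t adjustment.  A two-way layout (`factor2` supplied) uses a
#' two-way ANOVA with interaction and a Tukey post hoc over the cell means.
#' Means are reported with SEM = sd / sqrt(n).
#'
#' @param values numeric vector of measurements.
#' @param group factor/character of group labels (one per value).
#' @param test `"auto"` (t test for 2 groups, Dunnett otherwise),
#'   `"t_test"`, `"one_way_anova_dunnett"`, `"one_way_anova_tukey"` or
#'   `"two_way_anova_tukey"`.
#' @param control control-group label (required for Dunnett; defaults to the
#'   first level).
#' @param factor2 second factor for the two-way design.
#' @return an object of class `group_comparison` with fields `groups`
#'   (label, n, mean, sem), `test`, `anova_p` (omnibus, when applicable) and
#'   `comparisons` (comparison, estimate, p_raw, p_adj).
#' @export
compare_groups <- function(values, group,
                           test = c("auto", "t_test",
                                    "one_way_anova_dunnett",
                                    "one_way_anova_tukey",
                                    "two_way_anova_tukey"),
                           control = NULL, factor2 = NULL) {
  test <- match.arg(test)
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("every group needs at least 2 values")
  if (test == "auto")
    test <- if (nlevels(group) == 2) "t_test" else "one_way_anova_dunnett"
  if (test == "t_test" && nlevels(group) != 2)
    stop("t test requires exactly 2 groups")

  gs <- do.call(rbind, lapply(levels(group), function(g) {
    v <- values[group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))

  anova_p <- NA_real_
  if (test == "t_test") {
    tt <- stats::t.test(values ~ group, var.equal = TRUE,
                        alternative = "two.sided")
    cmp <- data.frame(
      comparison = paste(levels(group)[2], "-", levels(group)[1]),
      estimate = gs$mean[2] - gs$mean[1],
      p_raw = tt$p.value, p_adj = tt$p.value)
  } else if (test %in% c("one_way_anova_dunnett", "one_way_anova_tukey")) {
    if (test == "one_way_anova_dunnett") {
      if (is.null(control)) control <- levels(group)[1]
      if (!control %in% levels(group))
        stop("control label '", control, "' is not a group; Dunnett needs ",
             "a control group")
      group <- stats::relevel(group, ref = control)
    }
    d <- data.frame(y = values, g = group)
    fit <- stats::aov(y ~ g, data = d)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    type <- if (test == "one_way_anova_dunnett") "Dunnett" else "Tukey"
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = type))
    adj <- summary(gl)$test
    raw <- summary(gl, test = multcomp::adjusted("none"))$test
    cmp <- data.frame(comparison = names(adj$coefficients),
                      estimate = as.numeric(adj$coefficients),
                      p_raw = as.numeric(raw$pvalues),
                      p_adj = pmax(as.numeric(adj$pvalues),
                                   as.numeric(raw$pvalues)))
  } else { # two_way_anova_tukey
    if (is.null(factor2)) stop("two-way design requires 'factor2'")
    f2 <- factor(factor2)
    d <- data.frame(y = values, g = group, f2 = f2)
    fit <- stats::aov(y ~ g * f2, data = d)
    s <- summary(fit)[[1]]
    anova_p <- s[["Pr(>F)"]][1]
    cell <- interaction(group, f2, drop = TRUE, sep = ":")
    d2 <- data.frame(y = values, cell = cell)
    fit2 <- stats::aov(y ~ cell, data = d2)
    gl <- multcomp::glht(fit2, linfct = multcomp::mcp(cell = "Tukey"))
    adj <- summary(gl)$test
    raw <- summary(gl, test = multcomp::adjusted("none"))$test
    cmp <- data.frame(comparison = names(adj$coefficients),
                      estimate = as.numeric(adj$coefficients),
                      p_raw = as.numeric(raw$pvalues),
                      p_adj = pmax(as.numeric(adj$pvalues),
                                   as.numeric(raw$pvalues)))
    gs2 <- do.call(rbind, lapply(levels(cell), function(g) {
      v <- values[cell == g]
      data.frame(group = g, n = length(v), mean = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)))
    }))
    gs <- gs2
  }
  rownames(cmp) <- NULL
  structure(list(groups = gs, test = test, anova_p = anova_p,
                 comparisons = cmp),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s\n", x$test))
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %s: %.4f +/- %.4f (n = %d)\n", x$groups$group[i],
                x$groups$mean[i], x$groups$sem[i], x$groups$n[i]))
  if (!is.na(x$anova_p)) cat(sprintf("  ANOVA p = %.3g\n", x$anova_p))
  for (i in seq_len(nrow(x$comparisons)))
    cat(sprintf("  %s: diff %.4f, adj. p = %.3g\n",
                x$comparisons$comparison[i], x$comparisons$estimate[i],
                x$comparisons$p_adj[i]))
  invisible(x)
}
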