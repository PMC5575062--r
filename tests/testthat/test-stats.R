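test_that("z-scores center, scale and ignore affine shifts", {
  z <- zscore_pair(c(1, 2, 3), c(4, 6, 5))
  expect_equal(z$x_z, c(-1, 0, 1))
  set.seed(2)
  x <- rnorm(40, 10, 3); y <- rnorm(40, 5, 2)
  z2 <- zscore_pair(x, y)
  expect_lt(abs(mean(z2$x_z)), 1e-9); expect_lt(abs(sd(z2$x_z) - 1), 1e-9)
  expect_lt(abs(mean(z2$y_z)), 1e-9); expect_lt(abs(sd(z2$y_z) - 1), 1e-9)
  z3 <- zscore_pair(2.5 * x + 7, y)
  expect_equal(z2$x_z, z3$x_z, tolerance = 1e-12)
  expect_error(zscore_pair(rep(1, 5), 1:5), "'x' has zero variance")
  expect_error(zscore_pair(1:2, 1:2), "at least 3")
})

test_that("on z-scored data the regression slope is the Pearson r", {
  set.seed(3)
  x <- rnorm(60); y <- 0.4 * x + rnorm(60)
  z <- zscore_pair(x, y)
  fit <- pearson_fit(z)
  expect_equal(fit$slope, fit$r, tolerance = 1e-9)
  expect_lt(abs(fit$intercept), 1e-9)
  expect_equal(fit$r, cor(x, y), tolerance = 1e-12)
})

test_that("a standard-score slope of 0.6698 is its own correlation", {
  # the identity behind reading r off the printed line equation of a
  # standard-score scatter
  d <- paired_with_exact_r(0.6698, n = 200, seed = 4)
  fit <- pearson_fit(zscore_pair(d$x, d$y))
  expect_equal(fit$slope, 0.6698, tolerance = 1e-9)
  expect_equal(fit$r, 0.6698, tolerance = 1e-9)
})

test_that("perfect lines and simulated correlations behave", {
  x <- 1:20
  fit <- suppressWarnings(pearson_fit(x, 2 * x + 1))  # perfect-fit warning
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-12)
  tab <- simulate_paired_table(10000, 0.67, rng_seed = 5)
  r <- pearson_fit(tab$x, tab$y)$r
  band <- tanh(atanh(0.67) + c(-1, 1) * 2.576 / sqrt(10000 - 3))
  expect_gt(r, band[1]); expect_lt(r, band[2])
  expect_error(pearson_fit(rep(1, 10), 1:10), "degenerate")
})

test_that("r is affine-invariant and antisymmetric under sign flips", {
  set.seed(6)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  r0 <- pearson_fit(x, y)$r
  expect_equal(pearson_fit(3 * x + 2, 0.1 * y - 5)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_fit(-x, y)$r, -r0, tolerance = 1e-12)
})

test_that("the linearity gate keeps lines and escalates curvature", {
  set.seed(7)
  x <- seq(-3, 3, length.out = 50)
  lin <- fit_with_linearity_gate(x, 2 * x + rnorm(50, 0, 0.05))
  expect_s3_class(lin, "correlation_result")
  quad <- fit_with_linearity_gate(x, x^2 + rnorm(50, 0, 0.05))
  expect_s3_class(quad, "polyfit_result")
  expect_gt(quad$r_squared, quad$r_squared_linear)
  expect_lt(quad$lack_of_linearity_p, 0.05)
  expect_gt(quad$deviation_from_model_p, 0.05)   # cubic adds nothing
  expect_error(fit_with_linearity_gate(1:4, 1:4), "at least 5")
})

test_that("two identical samples give t = 0 and p = 1", {
  v <- c(1.2, 3.4, 2.2, 4.8, 3.1)
  cmp <- compare_groups(c(v, v), rep(c("a", "b"), each = 5))
  expect_equal(cmp$test, "t_test")
  expect_equal(cmp$comparisons$p_adj, 1)
  expect_equal(cmp$comparisons$estimate, 0)
  expect_equal(cmp$groups$sem, rep(sd(v) / sqrt(5), 2))
})

test_that("Dunnett and Tukey reduce to the t test for two groups", {
  set.seed(8)
  y <- c(rnorm(8, 0), rnorm(8, 1))
  g <- rep(c("ctrl", "trt"), each = 8)
  p_t <- compare_groups(y, g, test = "t_test")$comparisons$p_adj
  p_d <- compare_groups(y, g, test = "one_way_anova_dunnett",
                        control = "ctrl")$comparisons$p_adj
  p_k <- compare_groups(y, g, test = "one_way_anova_tukey")$comparisons$p_adj
  expect_equal(p_d, p_t, tolerance = 1e-6)
  expect_equal(p_k, p_t, tolerance = 1e-6)
})

test_that("adjusted p-values never undercut the raw ones", {
  set.seed(9)
  y <- rnorm(30); g <- rep(c("ctrl", "a", "b"), each = 10)
  for (tt in c("one_way_anova_dunnett", "one_way_anova_tukey")) {
    cmp <- compare_groups(y, g, test = tt, control = "ctrl")
    expect_true(all(cmp$comparisons$p_adj >= cmp$comparisons$p_raw - 1e-12))
  }
  expect_error(compare_groups(y, g, test = "one_way_anova_dunnett",
                              control = "nope"), "control")
})

test_that("group comparisons at published treadmilling presets separate", {
  # control 4.7258 +/- SEM 0.1918 vs nocodazole 1.6522 +/- 0.1183, n = 10:
  # sd = SEM * sqrt(n); the difference should be detected essentially always
  pre <- treadmill_presets()
  ctrl <- pre[pre$condition == "control", ]
  noc <- pre[pre$condition == "nocodazole", ]
  set.seed(10)
  hits <- mean(replicate(200, {
    y <- c(rnorm(10, ctrl$speed_um_min, ctrl$sem * sqrt(10)),
           rnorm(10, noc$speed_um_min, noc$sem * sqrt(10)))
    compare_groups(y, rep(c("c", "n"), each = 10))$comparisons$p_adj < 0.05
  }))
  expect_gt(hits, 0.95)
})

test_that("two-way layouts run a Tukey post hoc over cell means", {
  set.seed(11)
  y <- rnorm(40, rep(c(0, 0, 1, 1), each = 10))
  g <- rep(c("wt", "mut"), times = 20)
  f2 <- rep(c("veh", "drug"), each = 20)
  cmp <- compare_groups(y, g, test = "two_way_anova_tukey", factor2 = f2)
  expect_equal(nrow(cmp$groups), 4L)
  expect_equal(nrow(cmp$comparisons), 6L)   # all pairs of 4 cells
  expect_true(all(cmp$comparisons$p_adj >= cmp$comparisons$p_raw - 1e-12))
})

test_that("null calibration: type-I error near nominal for the main tests", {
  # reduced replication here; the >= 1000-replicate calibration including
  # Dunnett/Tukey family-wise rates runs in the acceptance suite
  set.seed(12)
  n_rep <- 400
  t_hits <- mean(replicate(n_rep, {
    compare_groups(rnorm(16), rep(c("a", "b"), each = 8))$comparisons$p_adj < 0.05
  }))
  expect_gt(t_hits, 0.02); expect_lt(t_hits, 0.08)
  r_hits <- mean(replicate(n_rep, {
    pearson_fit(rnorm(20), rnorm(20))$p_value < 0.05
  }))
  expect_gt(r_hits, 0.02); expect_lt(r_hits, 0.08)
})
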