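# Shared oracles and fixtures for the suite.

# One-to-one matching of detected vs true comet events within a tolerance;
# returns c(tp, fp, fn) for F1 computation.
match_events <- function(events, true_times_s, true_d_px, spacing_um,
                         tol_s = 6, tol_px = 4) {
  used <- rep(FALSE, length(true_times_s)); tp <- 0L
  for (i in seq_len(nrow(events))) {
    j <- which(!used & abs(true_times_s - events$time_s[i]) <= tol_s &
                 abs(true_d_px - events$distance_um[i] / spacing_um) <= tol_px)
    if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1L }
  }
  c(tp = tp, fp = nrow(events) - tp, fn = length(true_times_s) - tp)
}

f1_score <- function(m) as.numeric(2 * m["tp"] / (2 * m["tp"] + m["fp"] + m["fn"]))

# Paired sample whose z-scored least-squares slope is exactly `a`:
# y_z = a * x_z + sqrt(1 - a^2) * u_z with u orthogonal to x by construction.
paired_with_exact_r <- function(a, n = 200, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  u <- stats::residuals(stats::lm(stats::rnorm(n) ~ x))
  xs <- (x - mean(x)) / stats::sd(x)
  us <- (u - mean(u)) / stats::sd(u)
  list(x = x, y = a * xs + sqrt(1 - a^2) * us)
}

# Small single-neurite scene used by several image tests.
tiny_scene_config <- function(duration_s = 10, noise_gaussian_sd = 0,
                              seed = 1, ...) {
  scene_config(image_shape = c(96, 96), duration_s = duration_s,
               neurites = list(neurite_spec(c(20, 48), c(70, 48),
                                            marker_intensity = 200,
                                            label = "a")),
               noise_gaussian_sd = noise_gaussian_sd, rng_seed = seed, ...)
}
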