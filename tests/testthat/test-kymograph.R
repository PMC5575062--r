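test_that("a static scene gives identical kymograph columns", {
  set.seed(1)
  fr <- matrix(runif(64 * 64, 0, 100), 64, 64)
  st <- timelapse_stack(array(rep(fr, 5), c(64, 64, 5)), 0.16, 2)
  ky <- make_kymograph(st, line_roi(rbind(c(5, 30), c(50, 40))))
  expect_true(all(apply(ky$data, 1, function(r) diff(range(r))) == 0))
})

test_that("a horizontal integer-row ROI samples the image row exactly", {
  img <- matrix(as.numeric(1:400), 20, 20)
  st <- timelapse_stack(array(img, c(20, 20, 2)), 0.1, 1)
  ky <- make_kymograph(st, line_roi(rbind(c(2, 7), c(12, 7))))
  expect_equal(ky$data[, 1], img[8, 3:13])  # 0-based (x, y) -> [y+1, x+1]
  expect_equal(ky$sample_spacing_um, 0.1)
})

test_that("kymograph of a moving simulated track advances one row per frame", {
  sim <- simulate_kymograph(1, 1, c(50, 40), 100, 0, rng_seed = 2)
  arg <- apply(sim$kymo$data, 2, which.max)
  interior <- which(arg > 2 & arg < 49)
  expect_true(all(diff(arg[interior]) == 1))
})

test_that("ROIs leaving the image are reported with position", {
  st <- timelapse_stack(array(0, c(32, 32, 2)), 0.1, 1)
  expect_error(make_kymograph(st, line_roi(rbind(c(20, 16), c(40, 16)))),
               "exits the image")
})

test_that("manual endpoint slopes convert exactly to um/min", {
  ky <- kymograph(matrix(0, 20, 20), 0.1, 2)
  # 10 px over 10 frames = 1 px/frame = 0.1 um / 2 s * 60 = 3 um/min
  est <- estimate_speed_manual(ky, list(rbind(c(0, 0), c(10, 10))))
  expect_equal(est$mean_speed_um_min, 3)
  expect_equal(est$n_tracks, 1L)
  # slopes 1 and 3 px/frame average as speeds (3 + 9) / 2 = 6
  est2 <- estimate_speed_manual(ky, list(rbind(c(0, 0), c(10, 10)),
                                         rbind(c(0, 0), c(30, 10))))
  expect_equal(est2$mean_speed_um_min, 6)
  expect_error(estimate_speed_manual(ky, list(rbind(c(0, 5), c(10, 5)))),
               "identical time")
})

test_that("manual endpoints transcribed from simulation recover the truth", {
  sim <- simulate_kymograph(-1.5, 2, c(100, 60), 100, 0, rng_seed = 4,
                            sample_spacing_um = 0.1, frame_interval_s = 2)
  eps <- lapply(seq_len(nrow(sim$endpoints)), function(i)
    rbind(c(sim$endpoints$d0[i], sim$endpoints$t0[i]),
          c(sim$endpoints$d1[i], sim$endpoints$t1[i])))
  est <- estimate_speed_manual(sim$kymo, eps)
  expect_equal(est$mean_speed_um_min, 1.5 * 0.1 / 2 * 60, tolerance = 1e-9)
})

test_that("auto estimator converts a known slope at known calibration", {
  sim <- simulate_kymograph(1, 1, c(60, 60), 100, 0, rng_seed = 1,
                            sample_spacing_um = 0.1, frame_interval_s = 2)
  est <- estimate_speed_auto(sim$kymo, "anterograde")
  expect_equal(est$mean_speed_um_min, 3, tolerance = 0.05)
  man <- estimate_speed_manual(sim$kymo,
                               list(rbind(c(sim$endpoints$d0[1],
                                            sim$endpoints$t0[1]),
                                          c(sim$endpoints$d1[1],
                                            sim$endpoints$t1[1]))))
  # manual and auto agree within 5% on a noiseless single-track fixture
  expect_lt(abs(est$mean_speed_um_min - man$mean_speed_um_min) /
              man$mean_speed_um_min, 0.05)
})

test_that("static structure is flagged, never reported as zero speed", {
  band <- matrix(0, 50, 50); band[20:25, ] <- 100
  est <- estimate_speed_auto(kymograph(band, 0.1, 2))
  expect_equal(est$n_tracks, 0L)
  expect_true(is.na(est$mean_speed_um_min))
  expect_equal(est$flag, "no_track")
})

test_that("auto estimates are invariant to intensity scaling", {
  sim <- simulate_kymograph(-1, 3, c(100, 151), 100, 20, rng_seed = 11,
                            sample_spacing_um = 0.1, frame_interval_s = 2)
  e1 <- estimate_speed_auto(sim$kymo, "retrograde")
  scaled <- kymograph(sim$kymo$data * 17.3, 0.1, 2)
  e2 <- estimate_speed_auto(scaled, "retrograde")
  expect_equal(e1$per_track_slopes, e2$per_track_slopes, tolerance = 1e-12)
})

test_that("time reversal swaps direction but preserves |speed|", {
  sim <- simulate_kymograph(-1, 2, c(100, 151), 100, 10, rng_seed = 12,
                            sample_spacing_um = 0.1, frame_interval_s = 2)
  fwd <- estimate_speed_auto(sim$kymo, "retrograde")
  rev <- kymograph(sim$kymo$data[, ncol(sim$kymo$data):1], 0.1, 2)
  bwd <- estimate_speed_auto(rev, "anterograde")
  expect_equal(fwd$mean_speed_um_min, bwd$mean_speed_um_min,
               tolerance = 0.02)
})

test_that("doubling the pixel size doubles the reported speed", {
  sim <- simulate_kymograph(1, 1, c(60, 60), 100, 0, rng_seed = 3,
                            sample_spacing_um = 0.1, frame_interval_s = 2)
  e1 <- estimate_speed_auto(sim$kymo, "anterograde")
  e2 <- estimate_speed_auto(kymograph(sim$kymo$data, 0.2, 2), "anterograde")
  expect_equal(e2$mean_speed_um_min, 2 * e1$mean_speed_um_min,
               tolerance = 1e-12)
})

test_that("speed recovery stays within 10% across the physiological range", {
  # reduced sweep (2 speeds x 5 seeds); the full 1-6 um/min x 20-seed sweep
  # runs in the acceptance suite
  for (v in c(2, 5)) {
    slope <- -v * 2 / (60 * 0.1)
    ests <- vapply(1:5, function(s) {
      sim <- simulate_kymograph(slope, 3, c(100, 151), 100, 20,
                                rng_seed = 900 + 10 * v + s,
                                sample_spacing_um = 0.1,
                                frame_interval_s = 2)
      estimate_speed_auto(sim$kymo, "retrograde")$mean_speed_um_min
    }, numeric(1))
    expect_lt(abs(mean(ests) - v) / v, 0.1)
  }
})
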