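test_that("default acquisition yields 151 frames over 5 min at 2 s", {
  sc <- simulate_timelapse(tiny_scene_config(duration_s = 300))
  expect_equal(n_frames(sc$channels$actin), 151L)
  expect_equal(n_frames(sc$channels$ebc), 151L)
  expect_equal(n_frames(sc$channels$marker), 151L)
})

test_that("an empty noiseless scene is exactly the background level", {
  cfg <- scene_config(image_shape = c(48, 48), duration_s = 6,
                      neurites = list(neurite_spec(c(14, 24), c(30, 24),
                        flow_speed_um_min = 0, speckle_density = 0,
                        comet_rate_per_min = 0, marker_intensity = 0)),
                      noise_gaussian_sd = 0, background_level = 7,
                      rng_seed = 1)
  sc <- simulate_timelapse(cfg)
  expect_true(all(sc$channels$actin$data == 7))
  expect_true(all(sc$channels$ebc$data == 7))
  expect_true(all(abs(sc$channels$marker$data - 7) < 1e-9))
})

test_that("identical config and seed give bit-identical stacks", {
  a <- simulate_timelapse(tiny_scene_config(noise_gaussian_sd = 2, seed = 9))
  b <- simulate_timelapse(tiny_scene_config(noise_gaussian_sd = 2, seed = 9))
  expect_identical(a$channels$actin$data, b$channels$actin$data)
  expect_identical(a$channels$ebc$data, b$channels$ebc$data)
  expect_identical(a$truth$a$comet_times_s, b$truth$a$comet_times_s)
  c_ <- simulate_timelapse(tiny_scene_config(noise_gaussian_sd = 2, seed = 10))
  expect_false(identical(a$channels$actin$data, c_$channels$actin$data))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_timelapse(tiny_scene_config()))
  expect_identical(.Random.seed, before)
})

test_that("doubling speckle intensity doubles the foreground signal", {
  mk <- function(amp) {
    cfg <- tiny_scene_config(noise_gaussian_sd = 0, background_level = 0,
                             speckle_intensity = amp)
    cfg$neurites[[1]]$marker_intensity <- 0
    cfg$neurites[[1]]$comet_rate_per_min <- 0
    sum(simulate_timelapse(cfg)$channels$actin$data)
  }
  expect_equal(mk(200) / mk(100), 2, tolerance = 1e-9)
})

test_that("a footprint leaving the image names the offending neurite", {
  cfg <- scene_config(image_shape = c(48, 48), duration_s = 6,
                      neurites = list(neurite_spec(c(10, 24), c(46, 24),
                                                   label = "edge_case")))
  expect_error(simulate_timelapse(cfg), "edge_case")
})

test_that("realized comet counts follow the Poisson law", {
  # 200 replicates of rate 4/min over 300 s: mean ~ Poisson(20)
  set.seed(77)
  counts <- replicate(200, length(sample_comet_times(4, 300)))
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 200))
  dispersion <- var(counts) / mean(counts)
  expect_gt(dispersion, 0.8)
  expect_lt(dispersion, 1.2)
  # and the rendered scene realizes exactly the truth's event times
  sc <- simulate_timelapse(tiny_scene_config(duration_s = 60))
  expect_true(all(sc$truth$a$comet_times_s >= 0))
  expect_true(all(sc$truth$a$comet_times_s <= 60))
})

test_that("simulated kymograph tracks trace their configured slope", {
  # slope 1 px/frame, one track from (0, 0): argmax of column t is row t
  sim <- simulate_kymograph(1, 0, c(40, 30), rng_seed = 1)
  expect_true(all(sim$kymo$data == 0))               # n_tracks = 0, no noise
  sim1 <- simulate_kymograph(1, 1, c(40, 30), 100, 0, rng_seed = 5)
  arg <- apply(sim1$kymo$data, 2, which.max) - 1
  ep <- sim1$endpoints
  frames <- (ep$t0[1] + 1):(ep$t1[1] - 1)            # strictly inside
  expect_true(all(abs(arg[frames + 1] -
                        (ep$d0[1] + (frames - ep$t0[1]))) <= 1))
  # a slope too steep to stay in the image is rejected
  expect_error(simulate_kymograph(50, 1, c(40, 30)), "outside")
})

test_that("paired tables hit the requested correlation", {
  t1 <- simulate_paired_table(100, 1, rng_seed = 3)
  expect_equal(cor(t1$x, t1$y), 1, tolerance = 1e-12)
  t2 <- simulate_paired_table(10000, 0.67, rng_seed = 3)
  # Fisher-z 99% interval around 0.67 at n = 10000
  band <- tanh(atanh(0.67) + c(-1, 1) * 2.576 / sqrt(10000 - 3))
  expect_gt(cor(t2$x, t2$y), band[1])
  expect_lt(cor(t2$x, t2$y), band[2])
  expect_identical(simulate_paired_table(50, 0.3, rng_seed = 8),
                   simulate_paired_table(50, 0.3, rng_seed = 8))
  expect_error(simulate_paired_table(50, 1.2), "\\[-1, 1\\]")
  expect_error(simulate_paired_table(2, 0.5), "at least 3")
})

test_that("kinetic traces honor half-time and plateau by construction", {
  cfg <- kinetic_sim_config(y0 = 0.1, ymax = 1.3, t_half_s = 300,
                            lag_s = 50, noise_sd = 0,
                            sampling_interval_s = 10, duration_s = 6000)
  tr <- simulate_kinetic_trace(cfg)
  # value at t_half is exactly (y0 + ymax) / 2 on the noiseless curve
  expect_equal(gcflow:::kinetic_curve(cfg, 300), (0.1 + 1.3) / 2,
               tolerance = 1e-12)
  # far beyond t_half the curve is within 1% of the plateau
  expect_lt(abs(tr$fluorescence[length(tr$fluorescence)] - 1.3) / 1.3, 0.01)
  # baseline holds during the lag
  expect_true(all(tr$fluorescence[tr$time_s < 50] == 0.1))
  expect_error(kinetic_sim_config(y0 = 1, ymax = 0.5), "ymax > y0")
  expect_error(kinetic_sim_config(t_half_s = 10, lag_s = 20), "t_half")
  expect_error(kinetic_sim_config(sampling_interval_s = 100,
                                  duration_s = 50), "smaller")
})

test_that("coverage scenes are built at the requested overlap fraction", {
  for (f in c(0.5, 0.75)) {
    sc <- simulate_coverage_scene(f, rng_seed = 2)
    expect_lt(abs(sc$true_fraction - f), 0.02)
  }
})

test_that("scenes serialize to TIFF + JSON and read back", {
  sc <- simulate_timelapse(tiny_scene_config(duration_s = 6))
  dir <- file.path(tempdir(), "scene_out")
  write_scene(sc, dir)
  expect_true(all(file.exists(file.path(dir,
    c("actin.tif", "ebc.tif", "marker.tif", "ground_truth.json",
      "rois.json")))))
  back <- read_stack(file.path(dir, "actin.tif"))
  expect_equal(dim(back$data), dim(sc$channels$actin$data))
  expect_equal(back$pixel_size_um, 0.16)
  rois <- read_roi(file.path(dir, "rois.json"))
  expect_equal(length(rois), 3L)            # axis + neck + outline
  unlink(dir, recursive = TRUE)
})
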