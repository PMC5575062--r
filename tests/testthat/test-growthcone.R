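test_that("mean-threshold keeps pixels strictly above the crop mean", {
  crop <- matrix(c(1, 1, 1, 3), 2, 2)       # mean 1.5; only the 3 survives
  m <- mean_threshold_mask(crop)
  expect_false(m$degenerate)
  expect_equal(nrow(m$coords), 1L)
  expect_equal(unname(m$coords[1, ]), c(1, 1))   # 0-based (x, y)
  # constant crops flag as degenerate with an empty mask
  m0 <- mean_threshold_mask(matrix(7, 4, 4))
  expect_true(m0$degenerate)
  expect_equal(nrow(m0$coords), 0L)
  expect_error(mean_threshold_mask(matrix(numeric(0), 0, 0)), "nonempty")
})

test_that("mean-threshold mask is invariant under positive affine maps", {
  set.seed(5)
  crop <- matrix(runif(100, 0, 50), 10, 10)
  m1 <- mean_threshold_mask(crop)
  m2 <- mean_threshold_mask(3.7 * crop + 12)
  expect_identical(m1$coords, m2$coords)
})

test_that("largest 8-connected component filter keeps one object", {
  crop <- matrix(0, 8, 8)
  crop[2:4, 2:4] <- 10                       # 9-px object
  crop[7, 7] <- 10                           # lone bright pixel
  full <- mean_threshold_mask(crop, keep_largest = FALSE)
  one <- mean_threshold_mask(crop, keep_largest = TRUE)
  expect_equal(nrow(full$coords), 10L)
  expect_equal(nrow(one$coords), 9L)
  # diagonal contact counts as connected (8-connectivity)
  diag2 <- matrix(0, 4, 4); diag2[1, 1] <- 10; diag2[2, 2] <- 10
  md <- mean_threshold_mask(diag2, keep_largest = TRUE)
  expect_equal(nrow(md$coords), 2L)
})

test_that("segmentation of a simulated growth cone overlaps the truth", {
  sc <- simulate_timelapse(tiny_scene_config())
  fr <- get_frame(sc$channels$marker, 1)
  pts <- sc$rois$a$outline$points
  x0 <- floor(min(pts[, 1])); x1 <- ceiling(max(pts[, 1]))
  y0 <- floor(min(pts[, 2])); y1 <- ceiling(max(pts[, 2]))
  m <- mean_threshold_mask(fr[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)])
  det <- matrix(FALSE, nrow(fr), ncol(fr))
  det[cbind(m$coords[, 2] + 1 + y0, m$coords[, 1] + 1 + x0)] <- TRUE
  gt <- sc$truth$a$gc_footprint
  jaccard <- sum(det & gt) / sum(det | gt)
  expect_gte(jaccard, 0.8)
})

test_that("tracing measures original intensities, not the thresholded mask", {
  # segmentation channel has structure; measurement channel is constant c:
  # every per-frame mean must equal c exactly
  sc <- simulate_timelapse(tiny_scene_config(duration_s = 8))
  const <- timelapse_stack(array(42, dim(sc$channels$marker$data)), 0.16, 2)
  tr <- trace_growthcone(sc$channels$marker, c(50, 28, 40, 40),
                         measure_channel = const)
  expect_true(all(tr$per_frame$mean_intensity[!tr$per_frame$degenerate] == 42))
  expect_equal(tr$summary_intensity, 42)
})

test_that("a 151-frame video yields a 151-point trace", {
  sc <- simulate_timelapse(tiny_scene_config(duration_s = 300))
  tr <- trace_growthcone(sc$channels$marker, c(50, 28, 40, 40))
  expect_equal(nrow(tr$per_frame), 151L)
  expect_equal(length(tr$mask_coords), 151L)
  expect_equal(tr$per_frame$time_s[151], 300)
})

test_that("marker intensities are recovered in order and ratio", {
  cfg <- scene_config(image_shape = c(128, 128), duration_s = 60,
                      neurites = list(
                        neurite_spec(c(30, 64), c(100, 64),
                                     marker_intensity = 100, label = "dim"),
                        neurite_spec(c(64, 25), c(64, 100),
                                     marker_intensity = 300,
                                     label = "bright")),
                      rng_seed = 5)
  sc <- simulate_timelapse(cfg)
  summ <- vapply(c("dim", "bright"), function(lab) {
    pts <- sc$rois[[lab]]$outline$points
    x0 <- floor(min(pts[, 1])); y0 <- floor(min(pts[, 2]))
    trace_growthcone(sc$channels$marker,
                     c(x0, y0, ceiling(max(pts[, 1])) - x0 + 1,
                       ceiling(max(pts[, 2])) - y0 + 1),
                     label = lab)$summary_intensity
  }, numeric(1))
  expect_gt(summ["bright"], summ["dim"])
  expect_lt(abs(summ["bright"] / summ["dim"] - 3) / 3, 0.15)
})

test_that("mostly-degenerate segmentations abort with a clear error", {
  flat <- timelapse_stack(array(3, c(16, 16, 4)), 0.16, 2)
  expect_error(trace_growthcone(flat, c(0, 0, 16, 16)),
               "segmentation failed")
})

test_that("manual polygon means follow the even-odd rule exactly", {
  img <- matrix(0, 6, 6); img[3, 3] <- 7    # pixel center (2, 2), 0-based
  sq <- rbind(c(1.5, 1.5), c(2.5, 1.5), c(2.5, 2.5), c(1.5, 2.5))
  expect_equal(manual_region_mean(img, sq), 7)
  # constant image -> the constant, whatever the outline
  expect_equal(manual_region_mean(matrix(3.3, 10, 10),
                                  rbind(c(1, 1), c(8, 2), c(5, 7))), 3.3)
  # axis-aligned rectangle on a ramp: closed-form mean of enclosed values
  ramp <- outer(0:9, 0:9, function(y, x) x + 10 * y)
  rect <- rbind(c(1.5, 2.5), c(6.5, 2.5), c(6.5, 5.5), c(1.5, 5.5))
  enclosed <- ramp[4:6, 3:7]                # centers x in 2..6, y in 3..5
  expect_equal(manual_region_mean(ramp, rect), mean(enclosed))
  expect_error(manual_region_mean(img, rbind(c(0, 0), c(1, 1))), "3 vertices")
  expect_error(manual_region_mean(img,
                                  rbind(c(0.1, 0.1), c(0.2, 0.1),
                                        c(0.2, 0.2))), "no pixel")
})
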