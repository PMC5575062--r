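# Synthetic growth-cone scenes with known ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: speckled F-actin flowing retrogradely (tip -> base) inside a
# neurite footprint, EB3-like puncta born at the growth-cone neck at a
# Poisson rate and moving tipward, and a diffuse marker filling the growth
# cone; acquisition defaults match a 5-min video at one frame per 2 s
# (151 frames).

# Evaluate expr under a temporary RNG state; the caller's stream is restored.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of one synthetic neurite
#'
#' Geometry (shaft from `base_xy` to `tip_xy`, a disk-shaped growth cone at
#' the tip) and dynamics: retrograde F-actin speckle flow, tipward EB3-like
#' comets entering at the neck at a Poisson rate, and the diffuse marker
#' intensity of this growth cone.  Speeds are ground truth that the analysis
#' modules are benchmarked against.
#'
#' @param base_xy,tip_xy 0-based `(x, y)` pixel coordinates of the shaft base
#'   and the growth-cone center; must differ.
#' @param shaft_width_px,growthcone_radius_px footprint geometry in pixels.
#' @param flow_speed_um_min retrograde F-actin flow speed (um/min, >= 0).
#' @param speckle_density F-actin speckles per um^2 of footprint.
#' @param speckle_lifetime_s mean exponential speckle lifetime (s).
#' @param comet_rate_per_min Poisson intensity of comets entering the neck
#'   (comets/min, >= 0).
#' @param comet_speed_um_min anterograde comet speed (um/min).
#' @param marker_intensity diffuse marker level of this growth cone (A.U.).
#' @param label neurite label.
#' @return an object of class `neurite_spec`.
#' @export
neurite_spec <- function(base_xy, tip_xy, shaft_width_px = 5,
                         growthcone_radius_px = 10,
                         flow_speed_um_min = 4.7, speckle_density = 1.5,
                         speckle_lifetime_s = 40, comet_rate_per_min = 4,
                         comet_speed_um_min = 6, marker_intensity = 100,
                         label = "n1") {
  base_xy <- as.numeric(base_xy); tip_xy <- as.numeric(tip_xy)
  if (all(base_xy == tip_xy)) stop("'tip_xy' must differ from 'base_xy'")
  if (flow_speed_um_min < 0) stop("'flow_speed_um_min' must be >= 0")
  if (comet_rate_per_min < 0) stop("'comet_rate_per_min' must be >= 0")
  structure(list(base_xy = base_xy, tip_xy = tip_xy,
                 shaft_width_px = shaft_width_px,
                 growthcone_radius_px = growthcone_radius_px,
                 flow_speed_um_min = flow_speed_um_min,
                 speckle_density = speckle_density,
                 speckle_lifetime_s = speckle_lifetime_s,
                 comet_rate_per_min = comet_rate_per_min,
                 comet_speed_um_min = comet_speed_um_min,
                 marker_intensity = marker_intensity,
                 label = as.character(label)),
            class = "neurite_spec")
}

#' Configuration of a synthetic time-lapse scene
#'
#' Defaults reproduce the acquisition regime the analysis is built for:
#' 5 min at one frame per 2 s (151 frames), 0.16 um/px.  The pixel size is a
#' free parameter — every speed computation downstream reads it from the
#' stack metadata, never from this default.
#'
#' @param image_shape `c(H, W)` image size in pixels.
#' @param pixel_size_um pixel size (um/px, > 0).
#' @param frame_interval_s frame interval (s, > 0).
#' @param duration_s acquisition duration (s, > 0); the stack has
#'   `floor(duration_s / frame_interval_s) + 1` frames.
#' @param neurites list of [neurite_spec()] objects.
#' @param psf_sigma_px Gaussian PSF sigma in pixels; puncta are rendered by
#'   Gaussian splatting at sub-pixel positions with this sigma.
#' @param noise_gaussian_sd additive Gaussian read-noise sd (0 disables).
#' @param noise_poisson_scale photons per intensity unit for shot noise
#'   (0 disables).
#' @param background_level constant background intensity.
#' @param speckle_intensity,comet_intensity peak amplitude of one speckle /
#'   comet before noise (A.U.).
#' @param rng_seed integer seed making the scene reproducible.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(128, 128), pixel_size_um = 0.16,
                         frame_interval_s = 2, duration_s = 300,
                         neurites = list(), psf_sigma_px = 1.2,
                         noise_gaussian_sd = 2, noise_poisson_scale = 0,
                         background_level = 10, speckle_intensity = 120,
                         comet_intensity = 200, rng_seed = 1L) {
  if (!(pixel_size_um > 0)) stop("'pixel_size_um' must be > 0")
  if (!(frame_interval_s > 0)) stop("'frame_interval_s' must be > 0")
  if (!(duration_s > 0)) stop("'duration_s' must be > 0")
  if (inherits(neurites, "neurite_spec")) neurites <- list(neurites)
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 duration_s = duration_s, neurites = neurites,
                 psf_sigma_px = psf_sigma_px,
                 noise_gaussian_sd = noise_gaussian_sd,
                 noise_poisson_scale = noise_poisson_scale,
                 background_level = background_level,
                 speckle_intensity = speckle_intensity,
                 comet_intensity = comet_intensity,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

# Footprint mask of one neurite: pixels within shaft_width/2 of the base-tip
# segment, plus a disk of growthcone_radius at the tip.  Returns an H x W
# logical matrix; pixel (x, y) maps to [y + 1, x + 1].
neurite_footprint <- function(spec, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  a <- spec$base_xy; b <- spec$tip_xy
  ab <- b - a; len2 <- sum(ab^2)
  tt <- pmin(1, pmax(0, ((xs - a[1]) * ab[1] + (ys - a[2]) * ab[2]) / len2))
  d2 <- (xs - (a[1] + tt * ab[1]))^2 + (ys - (a[2] + tt * ab[2]))^2
  shaft <- d2 <= (spec$shaft_width_px / 2)^2
  gc <- (xs - b[1])^2 + (ys - b[2])^2 <= spec$growthcone_radius_px^2
  shaft | gc
}

check_footprint_inside <- function(spec, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  r <- max(spec$shaft_width_px / 2, spec$growthcone_radius_px)
  pts <- rbind(spec$base_xy, spec$tip_xy)
  if (any(pts[, 1] - r < 0) || any(pts[, 1] + r > W - 1) ||
      any(pts[, 2] - r < 0) || any(pts[, 2] + r > H - 1))
    stop(sprintf("footprint of neurite '%s' extends outside the %d x %d image",
                 spec$label, H, W))
  invisible(TRUE)
}

# Add a Gaussian spot of amplitude amp at sub-pixel (x, y) to matrix img.
splat_gaussian <- function(img, x, y, sigma, amp) {
  H <- nrow(img); W <- ncol(img)
  r <- ceiling(3 * sigma)
  cx <- round(x); cy <- round(y)
  xi <- max(0, cx - r):min(W - 1, cx + r)
  yi <- max(0, cy - r):min(H - 1, cy + r)
  if (!length(xi) || !length(yi)) return(img)
  gx <- exp(-(xi - x)^2 / (2 * sigma^2))
  gy <- exp(-(yi - y)^2 / (2 * sigma^2))
  img[yi + 1, xi + 1] <- img[yi + 1, xi + 1] + amp * outer(gy, gx)
  img
}

#' Sample comet entry times for one neurite
#'
#' Comet entries at the growth-cone neck form a homogeneous Poisson process;
#' this draws the event times for one observation window.  Used internally by
#' [simulate_timelapse()] and exposed so the Poisson law of realized counts
#' can be checked directly.
#'
#' @param rate_per_min Poisson intensity (comets/min, >= 0).
#' @param duration_s window length (s).
#' @return sorted numeric vector of event times in `[0, duration_s]`.
#' @export
sample_comet_times <- function(rate_per_min, duration_s) {
  stopifnot(rate_per_min >= 0, duration_s > 0)
  n <- stats::rpois(1, rate_per_min / 60 * duration_s)
  sort(stats::runif(n, 0, duration_s))
}

apply_noise <- function(a, gaussian_sd, poisson_scale) {
  if (poisson_scale > 0)
    a[] <- stats::rpois(length(a), poisson_scale * pmax(a, 0)) / poisson_scale
  if (gaussian_sd > 0)
    a[] <- a + stats::rnorm(length(a), 0, gaussian_sd)
  a
}

#' Simulate a multi-channel growth-cone time-lapse
#'
#' Renders three co-registered channels on the same frame grid:
#' \describe{
#'   \item{actin}{F-actin speckles advected tip-to-base (retrograde) at each
#'     neurite's `flow_speed_um_min`, with Poisson birth/exponential death
#'     keeping the speckle density stationary.}
#'   \item{ebc}{EB3-like Gaussian puncta born at the shaft side of the neck
#'     at `comet_rate_per_min` (Poisson), moving tipward at
#'     `comet_speed_um_min` and dying at the growth-cone tip.}
#'   \item{marker}{the growth-cone/neurite footprint filled at
#'     `marker_intensity`, PSF-blurred.}
#' }
#' Identical configuration (including `rng_seed`) gives bit-identical output.
#'
#' @param config a [scene_config()].
#' @return a list with elements `channels` (named list of
#'   [timelapse_stack()]), `truth` (per-neurite ground truth: flow speeds,
#'   comet event times and paths, marker intensities, footprint masks) and
#'   `rois` (per-neurite axis, neck and outline [line_roi()]s).
#' @export
simulate_timelapse <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  H <- config$image_shape[1]; W <- config$image_shape[2]
  nf <- frames_for_duration(config$duration_s, config$frame_interval_s)
  if (nf < 1) stop("configuration yields zero frames")
  times <- (seq_len(nf) - 1) * config$frame_interval_s
  px <- config$pixel_size_um; sig <- config$psf_sigma_px

  for (sp in config$neurites) check_footprint_inside(sp, config$image_shape)

  with_seed(config$rng_seed, {
    actin <- array(config$background_level, c(H, W, nf))
    ebc   <- array(config$background_level, c(H, W, nf))
    marker_frame <- matrix(0, H, W)
    truth <- list(); rois <- list()

    for (sp in config$neurites) {
      fp <- neurite_footprint(sp, config$image_shape)
      fp_idx <- which(fp)
      axis <- sp$tip_xy - sp$base_xy
      axis_len <- sqrt(sum(axis^2)); u <- axis / axis_len
      v_flow_px_s <- sp$flow_speed_um_min / 60 / px     # retrograde, tip->base
      v_comet_px_s <- sp$comet_speed_um_min / 60 / px   # anterograde

      # --- actin speckles: stationary birth-death population ---------------
      area_um2 <- length(fp_idx) * px^2
      n_ss <- sp$speckle_density * area_um2
      birth_rate <- n_ss / sp$speckle_lifetime_s        # per second
      t0 <- -5 * sp$speckle_lifetime_s
      n_births <- stats::rpois(1, birth_rate * (config$duration_s - t0))
      if (n_births > 0) {
        tb <- stats::runif(n_births, t0, config$duration_s)
        life <- stats::rexp(n_births, 1 / sp$speckle_lifetime_s)
        pick <- sample(fp_idx, n_births, replace = TRUE)
        px0 <- (pick - 1) %/% H   # 0-based x (column)
        py0 <- (pick - 1) %% H    # 0-based y (row)
        for (t in seq_len(nf)) {
          alive <- which(tb <= times[t] & times[t] <= tb + life)
          if (!length(alive)) next
          fr <- actin[, , t]
          for (k in alive) {
            dt <- times[t] - tb[k]
            xx <- px0[k] - u[1] * v_flow_px_s * dt
            yy <- py0[k] - u[2] * v_flow_px_s * dt
            ix <- round(xx); iy <- round(yy)
            if (ix < 0 || ix > W - 1 || iy < 0 || iy > H - 1) next
            if (!fp[iy + 1, ix + 1]) next
            fr <- splat_gaussian(fr, xx, yy, sig, config$speckle_intensity)
          }
          actin[, , t] <- fr
        }
      }

      # --- EB3-like comets -------------------------------------------------
      neck_arc <- axis_len - sp$growthcone_radius_px
      neck_xy <- sp$base_xy + u * neck_arc
      comet_t <- sample_comet_times(sp$comet_rate_per_min, config$duration_s)
      travel_s <- sp$growthcone_radius_px / max(v_comet_px_s, 1e-9)
      for (tk in comet_t) {
        vis <- which(times >= tk & times <= tk + travel_s)
        for (t in vis) {
          dt <- times[t] - tk
          xx <- neck_xy[1] + u[1] * v_comet_px_s * dt
          yy <- neck_xy[2] + u[2] * v_comet_px_s * dt
          ebc[, , t] <- splat_gaussian(ebc[, , t], xx, yy, sig,
                                       config$comet_intensity)
        }
      }

      # --- marker footprint ------------------------------------------------
      gc_only <- neurite_footprint(
        neurite_spec(sp$base_xy, sp$tip_xy, shaft_width_px = 1,
                     growthcone_radius_px = sp$growthcone_radius_px,
                     label = sp$label),
        config$image_shape)
      marker_frame[gc_only] <- marker_frame[gc_only] + sp$marker_intensity

      # --- ROIs and truth --------------------------------------------------
      perp <- c(-u[2], u[1]) * (sp$shaft_width_px / 2 + 2)
      rois[[sp$label]] <- list(
        axis = line_roi(rbind(sp$base_xy, sp$tip_xy), label = sp$label,
                        kind = "neurite_axis"),
        neck = line_roi(rbind(neck_xy - perp, neck_xy + perp),
                        label = paste0(sp$label, "_neck"), kind = "neck"),
        outline = local({
          th <- seq(0, 2 * pi, length.out = 25)[-25]
          r <- sp$growthcone_radius_px + 2
          line_roi(cbind(sp$tip_xy[1] + r * cos(th),
                         sp$tip_xy[2] + r * sin(th)),
                   label = paste0(sp$label, "_gc"),
                   kind = "growthcone_outline")
        }))
      truth[[sp$label]] <- list(
        flow_speed_um_min = sp$flow_speed_um_min,
        comet_times_s = comet_t,
        comet_rate_per_min = sp$comet_rate_per_min,
        marker_intensity = sp$marker_intensity,
        footprint = fp, gc_footprint = gc_only,
        neck_xy = neck_xy, axis_len_px = axis_len)
    }

    marker_blur <- EBImage::gblur(marker_frame + config$background_level,
                                  sigma = max(sig, 0.3))
    marker <- array(rep(marker_blur, nf), c(H, W, nf))

    actin  <- apply_noise(actin, config$noise_gaussian_sd,
                          config$noise_poisson_scale)
    ebc    <- apply_noise(ebc, config$noise_gaussian_sd,
                          config$noise_poisson_scale)
    marker <- apply_noise(marker, config$noise_gaussian_sd,
                          config$noise_poisson_scale)

    mk <- function(a, ch) timelapse_stack(pmax(a, 0), px,
                                          config$frame_interval_s, ch)
    list(channels = list(actin = mk(actin, "actin"), ebc = mk(ebc, "ebc"),
                         marker = mk(marker, "marker")),
         truth = truth, rois = rois)
  })
}

#' Write a simulated scene to disk
#'
#' One multi-page TIFF per channel (with calibration sidecars), a ground-truth
#' JSON with the per-neurite parameters and realized comet events, and one ROI
#' JSON holding every neurite's axis, neck and outline ROI.
#'
#' @param scene result of [simulate_timelapse()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(scene$channels))
    write_stack(scene$channels[[ch]], file.path(dir, paste0(ch, ".tif")))
  tr <- lapply(scene$truth, function(t)
    t[c("flow_speed_um_min", "comet_times_s", "comet_rate_per_min",
        "marker_intensity", "neck_xy", "axis_len_px")])
  jsonlite::write_json(tr, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_roi(unlist(lapply(scene$rois, function(r) r), recursive = FALSE),
            file.path(dir, "rois.json"))
  invisible(dir)
}

#' Simulate a kymograph with straight tracks of known slope
#'
#' Paints `n_tracks` anti-aliased straight tracks of the given slope
#' (px/frame, positive = moving away from the line start) at random offsets
#' on a distance x time image, plus Gaussian noise.  The true endpoints are
#' returned so downstream slope estimates can be scored against ground truth.
#'
#' @param slope_px_per_frame signed track slope in pixels per frame.
#' @param n_tracks number of tracks (>= 0).
#' @param kymo_shape `c(D, T)` in pixels x frames.
#' @param line_intensity peak track amplitude (A.U.).
#' @param noise_sd Gaussian noise sd (0 disables).
#' @param rng_seed integer seed.
#' @param sample_spacing_um,frame_interval_s calibration attached to the
#'   kymograph.
#' @param track_sigma_px transverse Gaussian half-width of a track.
#' @return list with `kymo` (a [kymograph()]) and `endpoints` (data.frame of
#'   true track endpoints `d0, t0, d1, t1` in px/frames).
#' @export
simulate_kymograph <- function(slope_px_per_frame, n_tracks,
                               kymo_shape = c(100, 151), line_intensity = 100,
                               noise_sd = 0, rng_seed = 1L,
                               sample_spacing_um = 0.16, frame_interval_s = 2,
                               track_sigma_px = 1) {
  D <- kymo_shape[1]; Tn <- kymo_shape[2]
  stopifnot(D >= 2, Tn >= 2, n_tracks >= 0)
  if (abs(slope_px_per_frame) >= D)
    stop("slope ", slope_px_per_frame,
         " px/frame crosses the whole distance axis within one frame; ",
         "tracks would lie entirely outside the image")
  with_seed(rng_seed, {
    img <- matrix(0, D, Tn)
    s <- slope_px_per_frame
    # offsets such that the track intersects the image for a decent span
    lo <- min(0, -s * (Tn - 1)); hi <- (D - 1) + max(0, -s * (Tn - 1))
    ep <- matrix(NA_real_, n_tracks, 4)
    for (k in seq_len(n_tracks)) {
      d0 <- stats::runif(1, lo, hi)
      tt <- 0:(Tn - 1)
      dd <- d0 + s * tt
      inside <- dd >= 0 & dd <= D - 1
      if (!any(inside)) { ep[k, ] <- NA; next }
      for (i in which(inside))
        img <- splat_gaussian(img, tt[i], dd[i], track_sigma_px,
                              line_intensity)
      t_in <- range(tt[inside])
      ep[k, ] <- c(d0 + s * t_in[1], t_in[1], d0 + s * t_in[2], t_in[2])
    }
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
    ep <- as.data.frame(ep); names(ep) <- c("d0", "t0", "d1", "t1")
    list(kymo = kymograph(img, sample_spacing_um, frame_interval_s,
                          source_roi = "simulated"),
         endpoints = ep[stats::complete.cases(ep), , drop = FALSE])
  })
}

#' Simulate a growth-cone neck kymograph with comet crossings
#'
#' A neck kymograph is taken along a short line across the neurite; each
#' comet entering the growth cone appears as a compact bright spot.  Events
#' are Poisson in time; the true event times are returned for
#' detection-performance scoring.
#'
#' @param rate_per_min Poisson comet rate (comets/min).
#' @param window_s observation window (s).
#' @param kymo_shape `c(D, T)`; `T` defaults to the frame count of the
#'   window at `frame_interval_s`.
#' @param spot_sigma `c(distance_px, frames)` Gaussian spot extent.
#' @param intensity spot peak amplitude.
#' @param noise_sd Gaussian noise sd.
#' @param rng_seed integer seed.
#' @param sample_spacing_um,frame_interval_s calibration.
#' @return list with `kymo`, `event_times_s` (truth) and `event_d_px`.
#' @export
simulate_neck_kymograph <- function(rate_per_min, window_s = 300,
                                    kymo_shape = NULL,
                                    spot_sigma = c(1.0, 0.8), intensity = 100,
                                    noise_sd = 0, rng_seed = 1L,
                                    sample_spacing_um = 0.16,
                                    frame_interval_s = 2) {
  Tn <- frames_for_duration(window_s, frame_interval_s)
  if (is.null(kymo_shape)) kymo_shape <- c(51, Tn)
  D <- kymo_shape[1]; Tn <- kymo_shape[2]
  with_seed(rng_seed, {
    ev <- sample_comet_times(rate_per_min, window_s)
    dd <- stats::runif(length(ev), 0.05 * (D - 1), 0.95 * (D - 1))
    img <- matrix(0, D, Tn)
    for (k in seq_along(ev)) {
      tk <- ev[k] / frame_interval_s          # frame coordinate
      tw <- max(0, floor(tk - 4 * spot_sigma[2])):
            min(Tn - 1, ceiling(tk + 4 * spot_sigma[2]))
      for (t in tw) {
        amp <- intensity * exp(-(t - tk)^2 / (2 * spot_sigma[2]^2))
        img <- splat_gaussian(img, t, dd[k], spot_sigma[1], amp)
      }
    }
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
    list(kymo = kymograph(img, sample_spacing_um, frame_interval_s,
                          source_roi = "simulated_neck"),
         event_times_s = ev, event_d_px = dd)
  })
}

#' Simulate a two-channel coverage scene with known overlap fraction
#'
#' Builds a reporter channel whose max projection is a bright disk (the
#' growth cone) and an EB3-like channel bright on a concentric sub-region
#' whose area is `target_fraction` of the disk, so the true coverage percent
#' is `100 * target_fraction` up to pixelation.
#'
#' @param target_fraction fraction of the reference area covered by the EB3
#'   channel, in (0, 1].
#' @param image_shape `c(H, W)`.
#' @param n_frames number of frames in each stack.
#' @param radius_px reference disk radius.
#' @param noise_sd Gaussian noise sd added to both channels.
#' @param rng_seed integer seed.
#' @param pixel_size_um,frame_interval_s calibration.
#' @return list with `ref`, `ebc` ([timelapse_stack()]s), `region` (outline
#'   [line_roi()]) and `true_fraction` (pixel-exact ground truth).
#' @export
simulate_coverage_scene <- function(target_fraction, image_shape = c(64, 64),
                                    n_frames = 5, radius_px = 20,
                                    noise_sd = 2, rng_seed = 1L,
                                    pixel_size_um = 0.16,
                                    frame_interval_s = 2) {
  stopifnot(target_fraction > 0, target_fraction <= 1)
  H <- image_shape[1]; W <- image_shape[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  d2 <- (xs - cx)^2 + (ys - cy)^2
  ref_mask <- d2 <= radius_px^2
  # concentric disk with matching pixel-count fraction
  r_in <- radius_px * sqrt(target_fraction)
  ebc_mask <- d2 <= r_in^2
  # adjust radius to hit the pixel-count target as closely as possible
  target_n <- round(target_fraction * sum(ref_mask))
  rr <- sort(d2[ref_mask])
  if (target_n >= 1 && target_n <= length(rr)) {
    ebc_mask <- ref_mask & (d2 <= rr[target_n])
  }
  true_fraction <- sum(ebc_mask & ref_mask) / sum(ref_mask)
  with_seed(rng_seed, {
    mk <- function(mask, amp, ch) {
      a <- array(10, c(H, W, n_frames))
      for (t in seq_len(n_frames)) {
        fr <- matrix(10, H, W); fr[mask] <- amp
        if (noise_sd > 0) fr <- fr + stats::rnorm(length(fr), 0, noise_sd)
        a[, , t] <- fr
      }
      timelapse_stack(pmax(a, 0), pixel_size_um, frame_interval_s, ch)
    }
    ref <- mk(ref_mask, 150, "marker"); ebc <- mk(ebc_mask, 150, "ebc")
    th <- seq(0, 2 * pi, length.out = 33)[-33]
    region <- line_roi(cbind(cx + (radius_px + 4) * cos(th),
                             cy + (radius_px + 4) * sin(th)),
                       label = "gc", kind = "growthcone_outline")
    list(ref = ref, ebc = ebc, region = region,
         true_fraction = true_fraction)
  })
}

#' Sample a paired table with a chosen Pearson correlation
#'
#' Draws `n` observations from a standard bivariate normal with correlation
#' `true_r` — the fixture for the z-score / Pearson correlation statistics.
#'
#' @param n sample size (>= 3).
#' @param true_r population correlation in `[-1, 1]`.
#' @param rng_seed integer seed.
#' @return data.frame with columns `x` and `y`.
#' @export
simulate_paired_table <- function(n, true_r, rng_seed = 1L) {
  if (n < 3) stop("'n' must be at least 3")
  if (abs(true_r) > 1) stop("'true_r' must lie in [-1, 1]")
  with_seed(rng_seed, {
    x <- stats::rnorm(n)
    e <- stats::rnorm(n)
    y <- true_r * x + sqrt(1 - true_r^2) * e
    data.frame(x = x, y = y)
  })
}

#' Configuration of a synthetic polymerization trace
#'
#' Ground-truth parameterization of a saturating pyrene-actin polymerization
#' curve: baseline `y0` up to a nucleation lag, then a pseudo-first-order
#' rise to plateau `ymax`; the noiseless curve passes through
#' `(y0 + ymax) / 2` exactly at `t_half_s`.
#'
#' @param y0 baseline fluorescence (A.U., >= 0).
#' @param ymax plateau fluorescence (A.U., > y0).
#' @param t_half_s half-time (s, > lag_s).
#' @param lag_s nucleation lag (s, >= 0).
#' @param shape rise-shape exponent (1 = single exponential).
#' @param noise_sd additive Gaussian noise sd (A.U.).
#' @param sampling_interval_s sampling interval (s).
#' @param duration_s trace duration (s, > sampling_interval_s).
#' @param rng_seed integer seed.
#' @return an object of class `kinetic_sim_config`.
#' @export
kinetic_sim_config <- function(y0 = 0, ymax = 1, t_half_s = 300, lag_s = 0,
                               shape = 1, noise_sd = 0,
                               sampling_interval_s = 10, duration_s = 1800,
                               rng_seed = 1L) {
  if (!(ymax > y0) || y0 < 0) stop("need ymax > y0 >= 0")
  if (!(t_half_s > lag_s) || lag_s < 0) stop("need t_half_s > lag_s >= 0")
  if (sampling_interval_s >= duration_s)
    stop("'sampling_interval_s' must be smaller than 'duration_s'")
  structure(list(y0 = y0, ymax = ymax, t_half_s = t_half_s, lag_s = lag_s,
                 shape = shape, noise_sd = noise_sd,
                 sampling_interval_s = sampling_interval_s,
                 duration_s = duration_s, rng_seed = as.integer(rng_seed)),
            class = "kinetic_sim_config")
}

# Noiseless saturating-curve value at times t for a kinetic_sim_config.
kinetic_curve <- function(config, t) {
  k <- log(2)^(1 / config$shape) / (config$t_half_s - config$lag_s)
  y <- ifelse(t < config$lag_s, config$y0,
              config$y0 + (config$ymax - config$y0) *
                (1 - exp(-(k * (t - config$lag_s))^config$shape)))
  y
}

#' Simulate a pyrene polymerization trace
#'
#' @param config a [kinetic_sim_config()].
#' @param condition_label condition label attached to the trace.
#' @return a [kinetic_trace()].
#' @export
simulate_kinetic_trace <- function(config, condition_label = "simulated") {
  stopifnot(inherits(config, "kinetic_sim_config"))
  t <- seq(0, config$duration_s, by = config$sampling_interval_s)
  y <- kinetic_curve(config, t)
  with_seed(config$rng_seed, {
    if (config$noise_sd > 0) y <- y + stats::rnorm(length(y), 0, config$noise_sd)
    kinetic_trace(t, y, condition_label)
  })
}

#' Published per-condition presets for pyrene polymerization assays
#'
#' Plateau (Ymax, A.U.) and half-time (t1/2, s) means with SEMs for actin
#' polymerization alone and with drebrin / drebrin-S142D, microtubules and
#' EB3, as reported for bulk pyrene assays of these conditions.  Used to
#' parameterize realistic simulated traces.
#'
#' @return data.frame with columns `condition`, `ymax`, `ymax_sem`,
#'   `t_half_s`, `t_half_sem`, `n_min`, `n_max`.
#' @export
pyrene_presets <- function() {
  data.frame(
    condition = c("actin_alone", "actin_dbn", "actin_dbnS142D",
                  "actin_mt_eb3_dbn", "actin_mt_eb3_dbnS142D"),
    ymax = c(1.035, 0.7504, 0.8003, 0.6915, 0.5267),
    ymax_sem = c(0.04785, 0.03016, 0.0116, 0.06875, 0.06545),
    t_half_s = c(302.2, 233.2, 266.7, 167.2, 236.3),
    t_half_sem = c(106.9, 57.24, 48.95, 61.07, 101.2),
    n_min = 2L, n_max = 5L)
}

#' Published growth-cone treadmilling-speed presets
#'
#' Mean retrograde F-actin treadmilling speeds (um/min) with SEMs and group
#' sizes for control growth cones and after microtubule drug treatment, used
#' as ground-truth presets for simulated group comparisons.
#'
#' @return data.frame with columns `condition`, `speed_um_min`, `sem`, `n`.
#' @export
treadmill_presets <- function() {
  data.frame(condition = c("control", "nocodazole", "taxol"),
             speed_um_min = c(4.7258, 1.6522, 5.7273),
             sem = c(0.1918, 0.1183, 0.2150),
             n = 10L)
}
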