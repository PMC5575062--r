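# Kymograph construction and F-actin treadmilling speed estimation.
#
# A kymograph resamples a time-lapse along a line ROI: row d, column t holds
# the intensity at arc-length position d in frame t.  Linear motion along the
# line appears as a straight track whose slope (px/frame), scaled by the
# spatial and temporal calibration, is the speed in um/min:
#   speed = |slope| * (sample_spacing_um / frame_interval_s) * 60.

#' Kymograph (distance x time image)
#'
#' @param data D x T numeric matrix: D distance samples along the source
#'   line, T frames.
#' @param sample_spacing_um micrometres per distance sample (> 0).
#' @param frame_interval_s seconds per column (> 0).
#' @param source_roi label of the ROI the kymograph was sampled from.
#' @return an object of class `kymograph`.
#' @export
kymograph <- function(data, sample_spacing_um, frame_interval_s,
                      source_roi = "roi") {
  data <- as.matrix(data)
  if (nrow(data) < 2 || ncol(data) < 2)
    stop("a kymograph needs at least 2 distance samples and 2 frames")
  if (!(sample_spacing_um > 0) || !(frame_interval_s > 0))
    stop("kymograph calibration must be strictly positive")
  structure(list(data = data, sample_spacing_um = sample_spacing_um,
                 frame_interval_s = frame_interval_s,
                 source_roi = as.character(source_roi)),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> from '%s': %d distance samples x %d frames\n",
              x$source_roi, nrow(x$data), ncol(x$data)))
  cat(sprintf("  %.4g um/sample, %.4g s/frame\n",
              x$sample_spacing_um, x$frame_interval_s))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  d <- dim(x$data)
  graphics::image(x = (0:(d[2] - 1)) * x$frame_interval_s,
                  y = (0:(d[1] - 1)) * x$sample_spacing_um,
                  z = t(x$data), xlab = "time (s)", ylab = "distance (um)",
                  col = grDevices::gray.colors(256, 0, 1), useRaster = TRUE,
                  main = x$source_roi, ...)
  invisible(x)
}

# Bilinear interpolation of matrix img (H x W) at 0-based pixel-center
# coordinates (x, y); vectorized over x, y.  Caller guarantees in-bounds.
bilinear_at <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x0 <- pmin(floor(x), W - 2); y0 <- pmin(floor(y), H - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + x0 * H
  img[i00]       * (1 - fx) * (1 - fy) +
  img[i00 + H]   * fx       * (1 - fy) +
  img[i00 + 1]   * (1 - fx) * fy       +
  img[i00 + H + 1] * fx     * fy
}

# Resample a polyline at unit arc-length steps; returns n x 2 (x, y) matrix
# and the unit tangent at every sample.
resample_polyline <- function(points) {
  seg <- diff(points)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- seq(0, floor(total))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(points) - 1)
  frac <- (s - cum[idx]) / seglen[idx]
  xy <- points[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  tang <- seg[idx, , drop = FALSE] / seglen[idx]
  list(xy = xy, tangent = tang)
}

#' Build a kymograph along a line ROI
#'
#' Samples the stack at unit arc-length steps along the (poly)line; row d,
#' column t is the bilinearly interpolated intensity at arc position d in
#' frame t.  For `width_px > 1` the mean across the perpendicular width is
#' taken, matching the averaging of wide-line kymographs.  The sample spacing
#' equals the stack's pixel size.
#'
#' @param stack a [timelapse_stack()].
#' @param roi a [line_roi()]; point order defines the distance axis
#'   (d = 0 at the first point).
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return a [kymograph()].
#' @export
make_kymograph <- function(stack, roi,
                           interpolation = c("bilinear", "nearest")) {
  stopifnot(inherits(stack, "timelapse_stack"), inherits(roi, "line_roi"))
  interpolation <- match.arg(interpolation)
  rs <- resample_polyline(roi$points)
  H <- dim(stack$data)[1]; W <- dim(stack$data)[2]
  offsets <- seq(-(roi$width_px - 1) / 2, (roi$width_px - 1) / 2)
  normal <- cbind(-rs$tangent[, 2], rs$tangent[, 1])
  xs <- outer(rs$xy[, 1], rep(1, length(offsets))) +
        outer(normal[, 1], offsets)
  ys <- outer(rs$xy[, 2], rep(1, length(offsets))) +
        outer(normal[, 2], offsets)
  bad <- which(xs < 0 | xs > W - 1 | ys < 0 | ys > H - 1)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(xs))[1]
    stop(sprintf(
      "ROI '%s' exits the image bounds at arc-length sample %d (x=%.1f, y=%.1f)",
      roi$label, i - 1, xs[bad[1]], ys[bad[1]]))
  }
  if (interpolation == "nearest") { xs <- round(xs); ys <- round(ys) }
  nf <- dim(stack$data)[3]
  out <- matrix(0, nrow(rs$xy), nf)
  for (t in seq_len(nf)) {
    vals <- bilinear_at(stack$data[, , t], as.vector(xs), as.vector(ys))
    out[, t] <- rowMeans(matrix(vals, nrow(rs$xy)))
  }
  kymograph(out, stack$pixel_size_um, stack$frame_interval_s,
            source_roi = roi$label)
}

#' Treadmilling-speed estimate from kymograph trajectories
#'
#' @param per_track_slopes signed slopes in px/frame (positive = motion away
#'   from the line start, i.e. anterograde for a base-to-tip ROI).
#' @param sample_spacing_um,frame_interval_s calibration used for the
#'   conversion to um/min.
#' @param method one of `"auto_radon"`, `"ridge_trace"`,
#'   `"manual_endpoints"`.
#' @param flag optional quality flag (e.g. `"no_track"`).
#' @return an object of class `treadmill_estimate` with fields
#'   `per_track_slopes`, `mean_speed_um_min` (mean of |slope| converted to
#'   um/min; `NA` when no track was found), `n_tracks`, `method`, `flag`.
#' @export
treadmill_estimate <- function(per_track_slopes, sample_spacing_um,
                               frame_interval_s,
                               method = c("auto_radon", "ridge_trace",
                                          "manual_endpoints"),
                               flag = NULL) {
  method <- match.arg(method)
  n <- length(per_track_slopes)
  speed <- if (n == 0) NA_real_ else
    mean(abs(per_track_slopes)) * sample_spacing_um / frame_interval_s * 60
  structure(list(per_track_slopes = as.numeric(per_track_slopes),
                 mean_speed_um_min = speed, n_tracks = n, method = method,
                 sample_spacing_um = sample_spacing_um,
                 frame_interval_s = frame_interval_s, flag = flag),
            class = "treadmill_estimate")
}

#' @export
print.treadmill_estimate <- function(x, ...) {
  cat(sprintf("<treadmill_estimate> (%s): %d track(s)\n", x$method,
              x$n_tracks))
  if (x$n_tracks > 0)
    cat(sprintf("  mean speed %.3f um/min (slopes %s px/frame)\n",
                x$mean_speed_um_min,
                paste(sprintf("%.3f", x$per_track_slopes), collapse = ", ")))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Treadmilling speed from manually traced trajectory endpoints
#'
#' The faithful re-implementation of slope measurement by hand: each
#' trajectory is a pair of (distance, time) endpoints read off the
#' kymograph; its slope is `delta_d / delta_t` (px/frame) and the reported
#' speed is the mean of |slope| converted to um/min.  Exact arithmetic, no
#' detection.
#'
#' @param kymo a [kymograph()] (used for its calibration).
#' @param endpoints list of endpoint pairs; each element is a 2 x 2 matrix or
#'   list of two `c(d_px, t_frame)` points.  Time coordinates of a pair must
#'   differ.
#' @return a [treadmill_estimate()] with `method = "manual_endpoints"`.
#' @export
estimate_speed_manual <- function(kymo, endpoints) {
  stopifnot(inherits(kymo, "kymograph"))
  if (!length(endpoints)) stop("'endpoints' must contain at least one pair")
  slopes <- vapply(endpoints, function(p) {
    if (is.list(p)) p <- rbind(p[[1]], p[[2]])
    p <- matrix(as.numeric(p), 2, 2, byrow = is.null(dim(p)))
    dt <- p[2, 2] - p[1, 2]
    if (dt == 0) stop("endpoint pair with identical time coordinates ",
                      "(vertical trajectory) has undefined slope")
    (p[2, 1] - p[1, 1]) / dt
  }, numeric(1))
  treadmill_estimate(slopes, kymo$sample_spacing_um, kymo$frame_interval_s,
                     method = "manual_endpoints")
}

# Shear-projection score: for slope s (px/frame), average the image along
# lines d = o + s * t.  The offset o is the intercept at t = 0 and ranges
# wide enough that every line intersecting the image is represented,
# including tracks confined to a corner.
shear_projection <- function(z, s) {
  D <- nrow(z); Tn <- ncol(z)
  o_min <- floor(min(0, -s * (Tn - 1)))
  o_max <- ceiling((D - 1) + max(0, -s * (Tn - 1)))
  offs <- o_min:o_max
  p <- numeric(length(offs)); cnt <- numeric(length(offs))
  for (t in seq_len(Tn)) {
    d <- offs + s * (t - 1)           # source row (0-based) per offset
    ok <- d >= 0 & d <= D - 1
    if (!any(ok)) next
    dlo <- floor(d[ok]); frac <- d[ok] - dlo
    col <- z[, t]
    v <- col[dlo + 1] * (1 - frac) + col[pmin(dlo + 2, D)] * frac
    p[ok] <- p[ok] + v
    cnt[ok] <- cnt[ok] + 1
  }
  keep <- cnt >= max(3, Tn / 4)
  list(offsets = offs,
       profile = ifelse(cnt > 0, p / pmax(cnt, 1), NA_real_), valid = keep)
}

#' Automatic treadmilling-speed estimation from a kymograph
#'
#' Detects straight trajectories and averages their slopes.  The dominant
#' orientation is found on an orientation histogram (1 degree resolution,
#' parabolic peak interpolation; a shear-projection variance score restricted
#' to the requested direction sign), tracks are localized as peaks of the
#' sheared projection, and each track's slope is refined by ridge tracing
#' (per-column intensity maxima around the predicted line, least-squares line
#' fit).  Tracks shorter than 5 frames or spanning fewer than 3 distance
#' samples are discarded.
#'
#' Directions assume the source ROI runs base-to-tip, so retrograde motion
#' (tip to base) has negative slope on the distance axis.
#'
#' @param kymo a [kymograph()].
#' @param direction `"retrograde"` (negative slopes; default) or
#'   `"anterograde"` (positive slopes).
#' @param max_tracks maximum number of tracks returned.
#' @param min_track_frames,min_track_span_px minimum trajectory extent.
#' @return a [treadmill_estimate()]; when no track is found it carries
#'   `n_tracks = 0`, `mean_speed_um_min = NA` and `flag = "no_track"` —
#'   never a silent zero.
#' @export
estimate_speed_auto <- function(kymo,
                                direction = c("retrograde", "anterograde"),
                                max_tracks = 12, min_track_frames = 5,
                                min_track_span_px = 3) {
  stopifnot(inherits(kymo, "kymograph"))
  direction <- match.arg(direction)
  z <- kymo$data
  D <- nrow(z); Tn <- ncol(z)
  # remove static structure (horizontal bands) and per-column offsets
  z <- z - rowMeans(z)
  z <- pmax(z - stats::median(z), 0)
  if (stats::sd(z) < 1e-12)
    return(treadmill_estimate(numeric(0), kymo$sample_spacing_um,
                              kymo$frame_interval_s, "auto_radon",
                              flag = "no_track"))

  # Orientation histogram from the gradient structure tensor: every pixel on
  # a track votes for the track's local orientation (the direction
  # perpendicular to its intensity gradient), weighted by squared gradient
  # magnitude.  Local votes cannot alias across parallel tracks the way a
  # global projection score can.
  sign_ <- if (direction == "retrograde") -1 else 1
  zs <- gauss_smooth2d(z, 1)
  gdd <- (zs[c(2:D, D), ] - zs[c(1, 1:(D - 1)), ]) / 2    # d/d(distance)
  gdt <- (zs[, c(2:Tn, Tn)] - zs[, c(1, 1:(Tn - 1))]) / 2 # d/d(time)
  mag <- gdd^2 + gdt^2
  strong <- mag > stats::quantile(mag, 0.90) & mag > 0
  if (!any(strong))
    return(treadmill_estimate(numeric(0), kymo$sample_spacing_um,
                              kymo$frame_interval_s, "auto_radon",
                              flag = "no_track"))
  # ridge direction (dt, dd) = (gdd, -gdt); slope = dd/dt
  ang <- atan2(-gdt[strong], gdd[strong]) * 180 / pi
  ang <- ifelse(ang > 90, ang - 180, ifelse(ang <= -90, ang + 180, ang))
  w <- mag[strong]
  bins <- seq(-89.5, 89.5, by = 1)           # 1 degree resolution
  hist_w <- vapply(bins, function(b)
    sum(w[ang >= b - 0.5 & ang < b + 0.5]), numeric(1))
  # restrict to the requested sign; drop near-static and near-vertical bins
  usable <- if (sign_ < 0) bins < -2 & bins > -88 else bins > 2 & bins < 88
  if (!any(hist_w[usable] > 0))
    return(treadmill_estimate(numeric(0), kymo$sample_spacing_um,
                              kymo$frame_interval_s, "auto_radon",
                              flag = "no_track"))
  hu <- hist_w; hu[!usable] <- 0
  best <- which(hu == max(hu))
  i <- best[which.max(abs(bins[best]))]      # ties toward the steeper angle
  if (length(best) > 1)
    gc_log("orientation tie at %s deg; keeping steeper %.1f deg",
           paste(bins[best], collapse = ","), bins[i])
  th <- bins[i]
  if (i > 1 && i < length(bins)) {           # parabolic peak interpolation
    y1 <- hu[i - 1]; y2 <- hu[i]; y3 <- hu[i + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 0) th <- bins[i] + 0.5 * (y1 - y3) / den
  }
  s_hat <- tan(th * pi / 180)

  # track offsets: peaks of the projection at the peak orientation; the bar
  # is deliberately low (median + 1 MAD, global maximum as fallback) because
  # ridge refinement rejects or merges spurious offsets downstream
  pr <- shear_projection(z, s_hat)
  prof <- pr$profile; prof[!pr$valid] <- NA
  n_off <- length(prof)
  med <- stats::median(prof, na.rm = TRUE)
  madv <- stats::mad(prof, na.rm = TRUE)
  thr <- med + max(madv, 1e-12)
  is_peak <- function(j) {
    !is.na(prof[j]) && prof[j] > thr &&
      prof[j] >= max(prof[max(1, j - 2):min(n_off, j + 2)], na.rm = TRUE)
  }
  cand <- which(vapply(seq_len(n_off), is_peak, logical(1)))
  if (!length(cand)) cand <- which.max(prof)
  if (length(cand) > max_tracks)
    cand <- cand[order(prof[cand], decreasing = TRUE)[seq_len(max_tracks)]]
  cand <- sort(pr$offsets[cand])            # intercepts at t = 0

  # per-track ridge refinement, iterated so the traced line can drift away
  # from the initial orientation-histogram slope
  win <- 3
  slopes_ref <- c(); ics_ref <- c(); wt_ref <- c()
  for (d0 in cand) {
    sl <- s_hat; ic <- d0                   # line d = ic + sl * t
    ok <- FALSE
    for (iter in 1:3) {
      ts <- c(); ds <- c(); ws <- c()
      for (t in seq_len(Tn)) {
        ctr <- ic + sl * (t - 1)
        if (ctr < -win || ctr > D - 1 + win) next
        rows <- max(0, floor(ctr - win)):min(D - 1, ceiling(ctr + win))
        if (!length(rows)) next
        v <- z[rows + 1, t]
        j <- which.max(v)
        if (v[j] <= 0) next
        ts <- c(ts, t - 1); ds <- c(ds, rows[j]); ws <- c(ws, v[j])
      }
      if (length(ts) < min_track_frames) break
      if (diff(range(ds)) < min_track_span_px) break
      fit <- stats::lm.wfit(cbind(1, ts), ds, w = ws)
      if (anyNA(fit$coefficients)) break
      ic <- fit$coefficients[1]; sl <- fit$coefficients[2]
      ok <- TRUE
    }
    if (!ok || is.na(sl) || sign(sl) != sign_) next
    # different offsets can converge onto the same ridge: keep one copy
    dup <- length(slopes_ref) &&
      any(abs(ics_ref - ic) < 2 & abs(slopes_ref - sl) < 0.05)
    if (!dup) {
      slopes_ref <- c(slopes_ref, sl); ics_ref <- c(ics_ref, ic)
      wt_ref <- c(wt_ref, sum(ws))
    }
  }
  # drop faint ridges (tails, partial overlaps) relative to the strongest
  if (length(slopes_ref)) {
    good <- wt_ref >= 0.3 * max(wt_ref)
    slopes_ref <- slopes_ref[good]
  }
  if (!length(slopes_ref))
    return(treadmill_estimate(numeric(0), kymo$sample_spacing_um,
                              kymo$frame_interval_s, "auto_radon",
                              flag = "no_track"))
  treadmill_estimate(slopes_ref, kymo$sample_spacing_um,
                     kymo$frame_interval_s, "auto_radon")
}
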