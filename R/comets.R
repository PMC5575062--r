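# EB3 comet counting at the growth-cone neck and comet-coverage measurement.

#' Record of comets crossing a neurite neck
#'
#' @param neurite_label source neurite/ROI label.
#' @param events data.frame with columns `time_s`, `distance_um` (one row per
#'   detected crossing).
#' @param window_s observation window length in seconds.
#' @return an object of class `comet_record`; `count` equals `nrow(events)`.
#' @export
comet_record <- function(neurite_label, events, window_s) {
  stopifnot(is.data.frame(events),
            all(c("time_s", "distance_um") %in% names(events)))
  if (nrow(events) && (any(events$time_s < 0) ||
                       any(events$time_s > window_s)))
    stop("event times must lie inside [0, window_s]")
  structure(list(neurite_label = as.character(neurite_label),
                 count = nrow(events), window_s = window_s, events = events),
            class = "comet_record")
}

#' @export
print.comet_record <- function(x, ...) {
  cat(sprintf("<comet_record> '%s': %d comet(s) in %.0f s (%.2f /min)\n",
              x$neurite_label, x$count, x$window_s,
              x$count / x$window_s * 60))
  invisible(x)
}

# Separable Gaussian smoothing of a matrix with reflective borders.
gauss_smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_apply <- function(mat) {
    n <- nrow(mat)
    idx <- c(rev(seq_len(min(r, n))), seq_len(n),
             n + 1 - rev(seq_len(min(r, n))))
    if (r > n) { # degenerate tiny input: fall back to full reflection cycle
      idx <- pmax(pmin(((-r):(n - 1 + r)) %% (2 * n), 2 * n - 1), 0)
      idx <- ifelse(idx >= n, 2 * n - 1 - idx, idx) + 1
    }
    padded <- mat[idx, , drop = FALSE]
    out <- apply(padded, 2, function(col) stats::filter(col, k, sides = 2))
    out[(r + 1):(r + n), , drop = FALSE]
  }
  sm <- pad_apply(m)
  t(pad_apply(t(sm)))
}

#' Count EB3 comets in a neck kymograph
#'
#' Comets crossing the neck line appear as distinct compact spots in the
#' (distance across neurite) x time kymograph.  Spots are enhanced by a
#' difference-of-Gaussians band-pass, local maxima with prominence at least
#' `min_prominence_mads` robust MADs of the filtered background are kept,
#' and maxima closer than `min_separation` (non-maximum suppression, one
#' count per maximal connected detection) are merged.  Thresholds are
#' data-relative, so counts are invariant to global intensity scaling.
#'
#' @param kymo a [kymograph()] sampled along a neck ROI of the EB3 channel.
#' @param min_prominence_mads detection prominence in MAD units (default 5).
#' @param min_separation `c(px, frames)` minimum spot separation; both
#'   must be positive.
#' @param sigma_small,sigma_large DoG scales in pixels.
#' @param maxima_sigma smoothing of the surface on which maxima are
#'   localized; lighter than `sigma_small` so that nearly touching spots
#'   that pass the DoG gate keep separate maxima.
#' @return a [comet_record()]; an all-zero kymograph gives count 0.
#' @export
count_comets <- function(kymo, min_prominence_mads = 5,
                         min_separation = c(2, 2),
                         sigma_small = 1, sigma_large = 3,
                         maxima_sigma = 0.5) {
  stopifnot(inherits(kymo, "kymograph"))
  if (any(min_separation <= 0))
    stop("'min_separation' must be positive in both axes")
  z <- kymo$data
  D <- nrow(z); Tn <- ncol(z)
  dog <- gauss_smooth2d(z, sigma_small) - gauss_smooth2d(z, sigma_large)
  # Robust background spread from the left half of the DoG distribution:
  # spots only add positive response, so reflecting the sub-median values
  # around the median estimates the noise MAD even when comets are dense
  # enough to cover much of the kymograph.
  med <- stats::median(dog)
  neg <- dog[dog <= med]
  bg <- stats::mad(c(neg, 2 * med - neg), center = med)
  thr <- med + min_prominence_mads * bg
  if (bg == 0) thr <- med + 1e-9

  # local maxima over the 8-neighborhood of the lightly smoothed surface,
  # gated by the DoG threshold: the band-pass decides what is signal, the
  # sharper surface keeps nearly touching comets as separate maxima
  fine <- gauss_smooth2d(z, maxima_sigma)
  cand <- which(dog > thr)
  if (length(cand)) {
    keep <- vapply(cand, function(i) {
      r <- (i - 1) %% D + 1; c <- (i - 1) %/% D + 1
      rr <- max(1, r - 1):min(D, r + 1)
      cc <- max(1, c - 1):min(Tn, c + 1)
      fine[r, c] >= max(fine[rr, cc])  # ties are resolved by the NMS pass
    }, logical(1))
    cand <- cand[keep]
  }
  # non-maximum suppression: strongest first, suppress within the window
  if (length(cand)) {
    rs <- (cand - 1) %% D; cs <- (cand - 1) %/% D  # 0-based (d, t)
    ord <- order(dog[cand], decreasing = TRUE)
    sel <- logical(length(cand))
    for (j in ord) {
      if (any(sel & abs(rs - rs[j]) < min_separation[1] &
                    abs(cs - cs[j]) < min_separation[2])) next
      sel[j] <- TRUE
    }
    rs <- rs[sel]; cs <- cs[sel]
  } else rs <- cs <- numeric(0)

  window_s <- (Tn - 1) * kymo$frame_interval_s
  ord <- order(cs)
  events <- data.frame(time_s = cs[ord] * kymo$frame_interval_s,
                       distance_um = rs[ord] * kymo$sample_spacing_um)
  comet_record(kymo$source_roi, events, window_s)
}

#' Coverage of the reporter-covered area by EB3 signal
#'
#' @param reference_channel name of the reference reporter.
#' @param reference_area_px,ebc_overlap_area_px pixel areas of the reference
#'   mask and of its intersection with the EB3 mask.
#' @return an object of class `coverage_result`; `percent` =
#'   `100 * overlap / reference_area`.
#' @export
coverage_result <- function(reference_channel, reference_area_px,
                            ebc_overlap_area_px) {
  if (reference_area_px <= 0) stop("reference area must be positive")
  if (ebc_overlap_area_px > reference_area_px)
    stop("overlap cannot exceed the reference area")
  structure(list(reference_channel = as.character(reference_channel),
                 reference_area_px = as.integer(reference_area_px),
                 ebc_overlap_area_px = as.integer(ebc_overlap_area_px),
                 percent = 100 * ebc_overlap_area_px / reference_area_px),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf(
    "<coverage_result> %.2f%% of the %s-covered area (%d px) carries EB3 signal\n",
    x$percent, x$reference_channel, x$reference_area_px))
  invisible(x)
}

# Otsu threshold of a numeric vector (256-bin histogram); scale-invariant.
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (v - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1)),
                      range = c(0, 1))
  rng[1] + th * diff(rng)
}

#' Percentage of reporter-covered growth-cone area occupied by EB3 signal
#'
#' Max-projects both co-registered stacks over time, thresholds each
#' projection inside the region (Otsu by default; `"mean"` applies the
#' mean-threshold rule of the growth-cone tracer) and reports
#' `100 * |EB3 mask intersect reference mask| / |reference mask|`.
#'
#' @param ref_stack reference reporter [timelapse_stack()] (e.g. Lifeact or
#'   the marker channel).
#' @param ebc_stack EB3 [timelapse_stack()] of the same shape.
#' @param region optional `growthcone_outline` [line_roi()] polygon
#'   restricting the measurement; `NULL` uses the whole image.
#' @param method thresholding method, `"otsu"` (default) or `"mean"`.
#' @return a [coverage_result()].
#' @export
coverage_percent <- function(ref_stack, ebc_stack, region = NULL,
                             method = c("otsu", "mean")) {
  stopifnot(inherits(ref_stack, "timelapse_stack"),
            inherits(ebc_stack, "timelapse_stack"))
  method <- match.arg(method)
  if (!identical(dim(ref_stack$data)[1:2], dim(ebc_stack$data)[1:2]))
    stop("reference and EB3 stacks must share the same frame shape")
  proj <- function(s) apply(s$data, c(1, 2), max)
  rp <- proj(ref_stack); ep <- proj(ebc_stack)
  H <- nrow(rp); W <- ncol(rp)
  inreg <- if (is.null(region)) matrix(TRUE, H, W) else
    polygon_mask(region$points, c(H, W))
  if (!any(inreg)) stop("region encloses no pixels")
  th_of <- function(p) {
    v <- p[inreg]
    if (method == "otsu") otsu_threshold(v) else mean(v)
  }
  rmask <- inreg & (rp > th_of(rp))
  emask <- inreg & (ep > th_of(ep))
  if (!any(rmask)) stop("no reference signal in region")
  coverage_result(ref_stack$channel, sum(rmask), sum(emask & rmask))
}
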