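# Automatic growth-cone delineation by mean thresholding, with per-frame
# intensity retrieval from the original (unthresholded) channel, and the
# manual polygon-outline measurement it replaces.

#' Mean-threshold segmentation of one cropped frame
#'
#' Keeps the pixels whose intensity is strictly greater than the crop's
#' arithmetic mean (the "Mean" auto-threshold rule; the exact mean is used,
#' not a histogram approximation).  With `keep_largest = TRUE` only the
#' largest 8-connected component survives, so a single dynamic growth cone
#' is delineated even when dim debris crosses the threshold.
#'
#' @param crop numeric matrix (one cropped frame).
#' @param keep_largest keep only the largest 8-connected component.
#' @return a list with `coords` (n x 2 matrix of 0-based `(x, y)` pixel
#'   coordinates, possibly empty) and `degenerate` (`TRUE` when no pixel
#'   exceeds the mean, e.g. for a constant crop).
#' @export
mean_threshold_mask <- function(crop, keep_largest = TRUE) {
  crop <- as.matrix(crop)
  if (!length(crop)) stop("'crop' must be nonempty")
  mask <- crop > mean(crop)
  if (!any(mask))
    return(list(coords = matrix(numeric(0), 0, 2), degenerate = TRUE))
  if (keep_largest) {
    lab <- label_components8(mask)
    tab <- tabulate(lab[lab > 0])
    mask <- lab == which.max(tab)
  }
  idx <- which(mask)
  H <- nrow(crop)
  coords <- cbind(x = (idx - 1) %/% H, y = (idx - 1) %% H)
  list(coords = coords, degenerate = FALSE)
}

# 8-connected component labelling of a logical matrix (iterative flood fill).
label_components8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  todo <- which(mask & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (i - 1) %% H + 1; c <- (i - 1) %/% H + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > H || cc < 1 || cc > W) next
        j <- (cc - 1) * H + rr
        if (mask[j] && lab[j] == 0L) { lab[j] <- cur; stack <- c(stack, j) }
      }
    }
  }
  lab
}

#' Per-frame growth-cone trace
#'
#' @param label trace label.
#' @param per_frame data.frame with columns `frame`, `time_s`, `n_pixels`,
#'   `mean_intensity`, `degenerate`.
#' @param mask_coords list (one element per frame) of 0-based `(x, y)`
#'   coordinate matrices.
#' @return an object of class `growthcone_trace`; `summary_intensity` is the
#'   mean of `mean_intensity` over non-degenerate frames.
#' @export
growthcone_trace <- function(label, per_frame, mask_coords) {
  stopifnot(nrow(per_frame) == length(mask_coords))
  ok <- !per_frame$degenerate
  structure(list(label = as.character(label), per_frame = per_frame,
                 mask_coords = mask_coords,
                 summary_intensity = mean(per_frame$mean_intensity[ok]),
                 n_degenerate = sum(!ok)),
            class = "growthcone_trace")
}

#' @export
print.growthcone_trace <- function(x, ...) {
  cat(sprintf(
    "<growthcone_trace> '%s': %d frames (%d degenerate), mean intensity %.2f\n",
    x$label, nrow(x$per_frame), x$n_degenerate, x$summary_intensity))
  invisible(x)
}

#' @export
plot.growthcone_trace <- function(x, ...) {
  ok <- !x$per_frame$degenerate
  graphics::plot(x$per_frame$time_s[ok], x$per_frame$mean_intensity[ok],
                 type = "l", xlab = "time (s)",
                 ylab = "mean intensity (A.U.)", main = x$label, ...)
  graphics::abline(h = x$summary_intensity, lty = 2)
  invisible(x)
}

#' Trace a growth cone through a time-lapse by mean auto-thresholding
#'
#' For every frame, the segmentation channel is cropped to `crop_rect`, the
#' mean-threshold mask is computed, and the mean of the *original*
#' measurement-channel intensities at the mask coordinates is retrieved —
#' the thresholded image itself is never measured.  Degenerate frames
#' (empty mask) are flagged, excluded from the time-averaged summary, and
#' reported; more than 50% degenerate frames is an error.
#'
#' @param stack segmentation-channel [timelapse_stack()].
#' @param crop_rect `c(x, y, w, h)` crop rectangle, 0-based corner.
#' @param measure_channel co-registered [timelapse_stack()] to measure
#'   (defaults to `stack` itself).
#' @param keep_largest see [mean_threshold_mask()].
#' @param label trace label.
#' @return a [growthcone_trace()].
#' @export
trace_growthcone <- function(stack, crop_rect, measure_channel = stack,
                             keep_largest = TRUE, label = "gc") {
  stopifnot(inherits(stack, "timelapse_stack"),
            inherits(measure_channel, "timelapse_stack"))
  d <- dim(stack$data)
  if (!identical(d, dim(measure_channel$data)))
    stop("segmentation and measurement stacks must share dimensions")
  x0 <- crop_rect[1]; y0 <- crop_rect[2]
  w <- crop_rect[3]; h <- crop_rect[4]
  if (x0 < 0 || y0 < 0 || x0 + w > d[2] || y0 + h > d[1])
    stop("crop rectangle extends outside the image")
  rows <- (y0 + 1):(y0 + h); cols <- (x0 + 1):(x0 + w)
  nf <- d[3]
  per <- data.frame(frame = seq_len(nf) - 1L,
                    time_s = (seq_len(nf) - 1) * stack$frame_interval_s,
                    n_pixels = 0L, mean_intensity = NA_real_,
                    degenerate = FALSE)
  masks <- vector("list", nf)
  for (t in seq_len(nf)) {
    m <- mean_threshold_mask(stack$data[rows, cols, t],
                             keep_largest = keep_largest)
    masks[[t]] <- m$coords
    if (m$degenerate || nrow(m$coords) == 0) {
      per$degenerate[t] <- TRUE
      next
    }
    mc <- measure_channel$data[rows, cols, t]
    per$n_pixels[t] <- nrow(m$coords)
    per$mean_intensity[t] <- mean(mc[m$coords[, 2] + 1 +
                                       m$coords[, 1] * h])
  }
  if (mean(per$degenerate) > 0.5)
    stop("segmentation failed: more than 50% of frames are degenerate")
  growthcone_trace(label, per, masks)
}

# Even-odd rule point-in-polygon test for pixel centers; vectorized over
# points.  Vertices are 0-based (x, y); edges wrap around.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Logical mask of pixels whose centers fall inside the polygon.
polygon_mask <- function(poly, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  xs <- rep(0:(W - 1), each = H)
  ys <- rep(0:(H - 1), W)
  matrix(points_in_polygon(xs, ys, poly), H, W)
}

#' Mean intensity inside a manually drawn outline
#'
#' The counterpart of delineating a growth cone by hand: the mean of the
#' original intensities over all pixels whose centers fall inside the
#' polygon (even-odd rule).
#'
#' @param img numeric matrix (a frame or a projection).
#' @param outline a `growthcone_outline` [line_roi()] or an n x 2 vertex
#'   matrix (0-based `(x, y)`, n >= 3); the polygon is closed implicitly.
#' @return mean intensity (scalar).
#' @export
manual_region_mean <- function(img, outline) {
  poly <- if (inherits(outline, "line_roi")) outline$points else
    matrix(as.numeric(outline), ncol = 2)
  if (nrow(poly) < 3) stop("a polygon outline needs at least 3 vertices")
  m <- polygon_mask(poly, dim(img))
  if (!any(m)) stop("polygon encloses no pixel centers")
  mean(img[m])
}
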