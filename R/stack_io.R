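#' Calibrated time-lapse image stack
#'
#' Container for a single-channel time-lapse: an H x W x T array of
#' nonnegative intensities plus the spatial and temporal calibration every
#' downstream measurement needs.  Frames are stored on the third dimension;
#' pixel coordinates are 0-based `(x, y) = (column, row)` at pixel centers
#' throughout the package.
#'
#' @param data numeric H x W x T array (a matrix is promoted to T = 1).
#' @param pixel_size_um pixel size in micrometres, strictly positive.
#' @param frame_interval_s frame interval in seconds, strictly positive.
#' @param channel channel name, e.g. `"actin"`, `"ebc"`, `"marker"`.
#' @return an object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(data, pixel_size_um, frame_interval_s,
                            channel = "unknown") {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be an H x W x T array")
  if (dim(data)[3] < 1L) stop("stack must contain at least one frame")
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
            is.numeric(frame_interval_s), length(frame_interval_s) == 1L)
  if (!(pixel_size_um > 0)) stop("'pixel_size_um' must be > 0")
  if (!(frame_interval_s > 0)) stop("'frame_interval_s' must be > 0")
  structure(list(data = data,
                 pixel_size_um = as.numeric(pixel_size_um),
                 frame_interval_s = as.numeric(frame_interval_s),
                 channel = as.character(channel)),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<timelapse_stack> channel '%s': %d x %d px, %d frames\n",
              x$channel, d[1], d[2], d[3]))
  cat(sprintf("  calibration: %.4g um/px, %.4g s/frame (%.4g s total)\n",
              x$pixel_size_um, x$frame_interval_s,
              (d[3] - 1) * x$frame_interval_s))
  invisible(x)
}

#' @export
dim.timelapse_stack <- function(x) dim(x$data)

#' Number of frames in a stack
#' @param stack a [timelapse_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$data)[3]

#' Extract one frame as a matrix
#' @param stack a [timelapse_stack()].
#' @param t 1-based frame index.
#' @return H x W numeric matrix.
#' @export
get_frame <- function(stack, t) {
  stopifnot(t >= 1, t <= n_frames(stack))
  stack$data[, , t]
}

#' Number of frames acquired over a duration
#'
#' A time-lapse acquired for `duration_s` seconds with one frame every
#' `interval_s` seconds contains `floor(duration_s / interval_s) + 1` frames,
#' since the frame at t = 0 is counted.  A 5-min acquisition at 2-s intervals
#' therefore yields 151 frames.
#'
#' @param duration_s acquisition duration in seconds (> 0).
#' @param interval_s frame interval in seconds (> 0).
#' @return integer frame count.
#' @export
frames_for_duration <- function(duration_s, interval_s) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("'duration_s' must be positive")
  if (!is.numeric(interval_s) || interval_s <= 0)
    stop("'interval_s' must be positive")
  as.integer(floor(duration_s / interval_s) + 1)
}

# --- TIFF IO -----------------------------------------------------------------

# Calibration sidecar: plain-R tiff cannot write custom tags, so write_stack
# stores calibration (and the intensity scale used for 16-bit quantisation)
# in '<path>.json' next to the TIFF.  read_stack resolves calibration as
# explicit argument > sidecar JSON > TIFF resolution tags > error.
sidecar_path <- function(path) paste0(path, ".json")

#' Write a time-lapse stack as a multi-page grayscale TIFF
#'
#' Integer-valued stacks with maximum below 2^16 are stored losslessly as
#' 16-bit; other stacks are scaled to the 16-bit range (the scale factor is
#' recorded in the calibration sidecar and undone on reading).
#'
#' @param stack a [timelapse_stack()].
#' @param path output TIFF path; a JSON sidecar `path.json` carries the
#'   calibration.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "timelapse_stack"))
  a <- stack$data
  if (any(a < 0)) stop("stack intensities must be nonnegative")
  is_int <- all(a == floor(a)) && max(a) <= 65535
  scale <- if (is_int) 65535 else max(a, 1e-12)
  pages <- lapply(seq_len(dim(a)[3]), function(t) a[, , t] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  meta <- list(pixel_size_um = stack$pixel_size_um,
               frame_interval_s = stack$frame_interval_s,
               channel = stack$channel,
               intensity_scale = if (is_int) 65535 else scale,
               integer_data = is_int)
  jsonlite::write_json(meta, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a calibrated stack
#'
#' @param path TIFF file path.
#' @param pixel_size_um,frame_interval_s calibration; when `NULL`, taken from
#'   the sidecar JSON written by [write_stack()], then from TIFF resolution
#'   tags (pixel size only).  Reading fails if the calibration cannot be
#'   resolved: there is no silent default.
#' @param channel channel name override.
#' @return a [timelapse_stack()].  Integer data written by [write_stack()]
#'   round-trips exactly.
#' @export
read_stack <- function(path, pixel_size_um = NULL, frame_interval_s = NULL,
                       channel = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, function(p) length(dim(p)) == 2L, logical(1))))
    stop("only grayscale (single-sample) TIFF pages are supported; ",
         "got an RGB or multi-sample page")
  shp <- dim(pages[[1]])
  if (any(!vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("TIFF pages have mixed shapes")

  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)

  px <- pixel_size_um
  if (is.null(px) && !is.null(meta)) px <- meta$pixel_size_um
  if (is.null(px)) {
    xres <- attr(pages[[1]], "x.resolution")
    unit <- attr(pages[[1]], "resolution.unit")
    if (!is.null(xres) && xres > 0) {
      # resolution = pixels per unit; express as um/px
      px <- switch(if (is.null(unit)) "inch" else unit,
                   cm = 1e4 / xres, inch = 25400 / xres, NULL)
    }
  }
  if (is.null(px))
    stop("pixel size not supplied and not present in metadata for ", path)
  fi <- frame_interval_s
  if (is.null(fi) && !is.null(meta)) fi <- meta$frame_interval_s
  if (is.null(fi))
    stop("frame interval not supplied and not present in metadata for ", path)

  a <- array(0, dim = c(shp, length(pages)))
  for (t in seq_along(pages)) a[, , t] <- pages[[t]]
  if (!is.null(meta)) {
    if (isTRUE(meta$integer_data)) a <- round(a) else
      a <- a / 65535 * meta$intensity_scale
  }
  ch <- if (!is.null(channel)) channel else
    if (!is.null(meta)) meta$channel else "unknown"
  timelapse_stack(a, px, fi, ch)
}

# --- Line / polygon ROIs -----------------------------------------------------

#' Line, polyline or outline ROI
#'
#' Coordinates are 0-based `(x, y)` pixel centers, matching the convention of
#' the whole package.  For `neurite_axis` ROIs the point order is meaningful:
#' it runs base-to-tip, which fixes the sign convention of kymograph slopes
#' (retrograde F-actin motion moves toward the line start, i.e. has negative
#' slope).
#'
#' @param points n x 2 numeric matrix (or list of `c(x, y)`) with n >= 2;
#'   consecutive points must be distinct.
#' @param width_px odd integer line width in pixels (default 1, the width
#'   used for all kymographs here).
#' @param label ROI label.
#' @param kind one of `"neurite_axis"`, `"neck"`, `"growthcone_outline"`.
#' @return an object of class `line_roi`.
#' @export
line_roi <- function(points, width_px = 1L, label = "roi",
                     kind = c("neurite_axis", "neck", "growthcone_outline")) {
  kind <- match.arg(kind)
  if (is.list(points)) points <- do.call(rbind, points)
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) < 2L) stop("a line ROI needs at least 2 points")
  d <- diff(points)
  if (any(rowSums(d^2) == 0)) stop("consecutive ROI points must be distinct")
  width_px <- as.integer(width_px)
  if (width_px < 1L || width_px %% 2L == 0L)
    stop("'width_px' must be an odd integer >= 1")
  structure(list(points = points, width_px = width_px,
                 label = as.character(label), kind = kind),
            class = "line_roi")
}

#' @export
print.line_roi <- function(x, ...) {
  cat(sprintf("<line_roi> '%s' (%s): %d points, width %d px, length %.2f px\n",
              x$label, x$kind, nrow(x$points), x$width_px, roi_length_px(x)))
  invisible(x)
}

#' Arc length of a polyline ROI in pixels
#' @param roi a [line_roi()].
#' @return total arc length in pixel units.
#' @export
roi_length_px <- function(roi) {
  sum(sqrt(rowSums(diff(roi$points)^2)))
}

#' Read / write ROIs as JSON
#'
#' The interchange format is a JSON array of objects with fields `points`
#' (array of `[x, y]`, 0-based pixel centers), `width_px` (defaults to 1 when
#' omitted), `label` and `kind`.  Write-then-read is the identity.
#'
#' @param path JSON file path.
#' @return `read_roi`: a list of [line_roi()] objects.
#' @export
read_roi <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    pts <- do.call(rbind, lapply(r$points, function(p) as.numeric(unlist(p))))
    line_roi(pts,
             width_px = if (is.null(r$width_px)) 1L else r$width_px,
             label = if (is.null(r$label)) "roi" else r$label,
             kind = if (is.null(r$kind)) "neurite_axis" else r$kind)
  })
}

#' @rdname read_roi
#' @param rois a list of [line_roi()] objects (a single ROI is accepted).
#' @export
write_roi <- function(rois, path) {
  if (inherits(rois, "line_roi")) rois <- list(rois)
  out <- lapply(rois, function(r) {
    list(points = lapply(seq_len(nrow(r$points)),
                         function(i) as.numeric(r$points[i, ])),
         width_px = r$width_px, label = r$label, kind = r$kind)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- Result tables -----------------------------------------------------------

#' Validated long-format result table
#'
#' All numeric results leave the package as rows of
#' `(cell, neurite, quantity, value, units)`; a row with empty units is
#' rejected so no measurement can be exported unit-less.
#'
#' @param df data.frame with columns `cell`, `neurite`, `quantity`, `value`,
#'   `units`.
#' @return the validated data.frame with class `result_table` prepended.
#' @export
result_table <- function(df) {
  need <- c("cell", "neurite", "quantity", "value", "units")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("result table missing columns: ",
                         paste(miss, collapse = ", "))
  u <- as.character(df$units)
  if (any(is.na(u) | !nzchar(u)))
    stop("every result row must carry nonempty units")
  if (!is.numeric(df$value)) stop("'value' must be numeric")
  class(df) <- c("result_table", class(df))
  df
}

#' @export
print.result_table <- function(x, ...) {
  cat(sprintf("<result_table> %d measurements\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

# Shared logging: terse messages to stderr, gated by option gcflow.verbose.
gc_log <- function(fmt, ...) {
  if (isTRUE(getOption("gcflow.verbose", FALSE)))
    message(sprintf(fmt, ...))
  invisible(NULL)
}
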