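# End-to-end orchestration: simulate (or load) a cell, build kymographs,
# measure treadmilling speed, comet counts, coverage and marker intensity
# per neurite, and correlate the paired per-growth-cone measurements.

#' Run the full growth-cone analysis pipeline for one cell
#'
#' Stages run in dependency order on a simulated scene (when
#' `config$simulate` is present) or on stacks/ROIs named in the config:
#' F-actin kymograph + speed per neurite axis, comet count per neck,
#' EB3 coverage and marker intensity per growth cone, then cross-neurite
#' Pearson correlations of the paired measurements (computed only when at
#' least 3 neurites yield pairs).  Fully deterministic given the seed; with
#' `out_dir` set, per-stage CSVs, kymograph TIFFs, a combined JSON and the
#' echoed parameters are written.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{simulate}{arguments for [scene_config()]; `neurites` is a list
#'       of [neurite_spec()] argument lists.}
#'     \item{stacks}{alternatively, named TIFF paths (`actin`, `ebc`,
#'       `marker`) plus `rois` (ROI JSON path).}
#'     \item{analyses}{character subset of
#'       `c("speed", "comets", "coverage", "intensity", "correlation")`;
#'       empty runs nothing (a warning is logged).}
#'   }
#' @param out_dir optional output directory.
#' @param seed integer seed overriding `config$simulate$rng_seed`.
#' @param cell_id cell identifier used in output tables.
#' @return an object of class `cell_analysis`: per-neurite
#'   `treadmill_estimate`, `comet_record`, `coverage_result`,
#'   `growthcone_trace` summaries, the derived `correlation_result`s and the
#'   combined [result_table()].
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         cell_id = "cell1") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  analyses <- config$analyses
  if (is.null(analyses))
    analyses <- c("speed", "comets", "coverage", "intensity", "correlation")
  known <- c("speed", "comets", "coverage", "intensity", "correlation")
  if (length(setdiff(analyses, known)))
    stop("unknown analyses: ", paste(setdiff(analyses, known), collapse = ", "))
  if (!length(analyses)) {
    warning("empty analyses list: nothing to do")
    return(invisible(structure(list(cell_id = cell_id, neurites = list(),
                                    correlations = list(), table = NULL),
                               class = "cell_analysis")))
  }

  # --- acquire scene ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    sa <- config$simulate
    if (!is.null(seed)) sa$rng_seed <- seed
    sa$neurites <- lapply(sa$neurites, function(n)
      if (inherits(n, "neurite_spec")) n else do.call(neurite_spec, n))
    scene <- simulate_timelapse(do.call(scene_config, sa))
    channels <- scene$channels; rois <- scene$rois; truth <- scene$truth
  } else if (!is.null(config$stacks)) {
    channels <- lapply(config$stacks, read_stack)
    roi_list <- read_roi(config$rois)
    rois <- list(); truth <- NULL
    for (r in roi_list) {
      base <- sub("_(neck|gc)$", "", r$label)
      slot <- switch(r$kind, neurite_axis = "axis", neck = "neck",
                     growthcone_outline = "outline")
      rois[[base]][[slot]] <- r
    }
  } else stop("config must name either 'simulate' or 'stacks'")

  neurites <- list()
  for (label in names(rois)) {
    res <- list()
    r <- rois[[label]]
    if ("speed" %in% analyses && !is.null(r$axis) &&
        !is.null(channels$actin)) {
      ky <- make_kymograph(channels$actin, r$axis)
      res$kymo_actin <- ky
      res$speed <- estimate_speed_auto(ky, direction = "retrograde")
      gc_log("[%s] speed: %.3f um/min (%d tracks)", label,
             res$speed$mean_speed_um_min, res$speed$n_tracks)
    }
    if ("comets" %in% analyses && !is.null(r$neck) &&
        !is.null(channels$ebc)) {
      kn <- make_kymograph(channels$ebc, r$neck)
      res$comets <- count_comets(kn)
      gc_log("[%s] comets: %d", label, res$comets$count)
    }
    if ("coverage" %in% analyses && !is.null(r$outline) &&
        !is.null(channels$ebc) && !is.null(channels$marker)) {
      res$coverage <- tryCatch(
        coverage_percent(channels$marker, channels$ebc, r$outline),
        error = function(e) NULL)
    }
    if ("intensity" %in% analyses && !is.null(r$outline) &&
        !is.null(channels$marker)) {
      pts <- r$outline$points
      d <- dim(channels$marker$data)
      x0 <- max(0, floor(min(pts[, 1]))); x1 <- min(d[2] - 1, ceiling(max(pts[, 1])))
      y0 <- max(0, floor(min(pts[, 2]))); y1 <- min(d[1] - 1, ceiling(max(pts[, 2])))
      res$intensity <- tryCatch(
        trace_growthcone(channels$marker,
                         c(x0, y0, x1 - x0 + 1, y1 - y0 + 1), label = label),
        error = function(e) NULL)
    }
    neurites[[label]] <- res
  }

  # --- cross-neurite correlations -------------------------------------------
  correlations <- list()
  if ("correlation" %in% analyses) {
    g <- function(f) vapply(neurites, function(n) {
      v <- f(n); if (is.null(v) || !is.finite(v)) NA_real_ else v
    }, numeric(1))
    speed <- g(function(n) n$speed$mean_speed_um_min)
    count <- g(function(n) as.numeric(n$comets$count))
    inten <- g(function(n) n$intensity$summary_intensity)
    pair_if <- function(a, b) {
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) >= 3 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0)
        pearson_fit(zscore_pair(a[ok], b[ok])) else NULL
    }
    correlations$comets_vs_speed <- pair_if(count, speed)
    correlations$marker_vs_speed <- pair_if(inten, speed)
    correlations$comets_vs_marker <- pair_if(count, inten)
  }

  # --- combined table --------------------------------------------------------
  rows <- list()
  add <- function(neurite, quantity, value, units)
    rows[[length(rows) + 1]] <<- data.frame(cell = cell_id,
                                            neurite = neurite,
                                            quantity = quantity,
                                            value = value, units = units)
  for (label in names(neurites)) {
    n <- neurites[[label]]
    if (!is.null(n$speed) && n$speed$n_tracks > 0)
      add(label, "treadmilling_speed", n$speed$mean_speed_um_min, "um/min")
    if (!is.null(n$comets))
      add(label, "comet_count", n$comets$count, "comets/window")
    if (!is.null(n$coverage))
      add(label, "ebc_coverage", n$coverage$percent, "percent")
    if (!is.null(n$intensity))
      add(label, "marker_intensity", n$intensity$summary_intensity, "A.U.")
  }
  for (nm in names(correlations)) if (!is.null(correlations[[nm]]))
    add("all", paste0("pearson_r_", nm), correlations[[nm]]$r, "unitless")
  tab <- if (length(rows)) result_table(do.call(rbind, rows)) else NULL

  out <- structure(list(cell_id = cell_id, neurites = neurites,
                        correlations = correlations, table = tab,
                        analyses = analyses),
                   class = "cell_analysis")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(tab))
      utils::write.csv(as.data.frame(tab),
                       file.path(out_dir, "cell_analysis.csv"),
                       row.names = FALSE)
    for (label in names(neurites)) {
      ky <- neurites[[label]]$kymo_actin
      if (!is.null(ky)) {
        st <- timelapse_stack(array(ky$data, c(dim(ky$data), 1)),
                              ky$sample_spacing_um, ky$frame_interval_s,
                              paste0("kymo_", label))
        write_stack(st, file.path(out_dir, paste0("kymo_", label, ".tif")))
      }
    }
    json <- list(cell_id = cell_id, analyses = analyses,
                 table = if (!is.null(tab)) as.data.frame(tab) else NULL)
    jsonlite::write_json(json, file.path(out_dir, "cell_analysis.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    yaml::write_yaml(list(analyses = analyses, seed = seed,
                          cell_id = cell_id),
                     file.path(out_dir, "params_used.yaml"))
  }
  out
}

#' @export
print.cell_analysis <- function(x, ...) {
  cat(sprintf("<cell_analysis> '%s': %d neurite(s), analyses: %s\n",
              x$cell_id, length(x$neurites),
              paste(x$analyses, collapse = ", ")))
  if (!is.null(x$table)) print(x$table)
  for (nm in names(x$correlations)) if (!is.null(x$correlations[[nm]]))
    cat(sprintf("  %s: r = %.3f (p = %.3g)\n", nm, x$correlations[[nm]]$r,
                x$correlations[[nm]]$p_value))
  invisible(x)
}

#' Build the scene configuration of a stage-2-like synthetic cell
#'
#' Arranges `n_neurites` radially around the cell center with the supplied
#' flow speeds and comet rates — the standard fixture for end-to-end
#' benchmarking where the comet rate is proportional to the flow speed.
#'
#' @param n_neurites number of neurites.
#' @param flow_speeds_um_min per-neurite retrograde flow speeds.
#' @param comet_rates_per_min per-neurite comet rates.
#' @param marker_intensities per-neurite marker levels.
#' @param image_shape,duration_s,rng_seed passed to [scene_config()].
#' @param ... further [scene_config()] arguments.
#' @return a [scene_config()].
#' @export
stage2_cell_config <- function(n_neurites = 5,
                               flow_speeds_um_min = seq(1.5, 6,
                                 length.out = n_neurites),
                               comet_rates_per_min = flow_speeds_um_min,
                               marker_intensities = 60 +
                                 40 * seq_len(n_neurites),
                               image_shape = c(192, 192), duration_s = 300,
                               rng_seed = 1L, ...) {
  ctr <- (image_shape[c(2, 1)] - 1) / 2
  R_base <- 18; R_tip <- min(image_shape) / 2 - 16
  specs <- lapply(seq_len(n_neurites), function(i) {
    th <- 2 * pi * (i - 1) / n_neurites + 0.3
    u <- c(cos(th), sin(th))
    neurite_spec(base_xy = ctr + R_base * u, tip_xy = ctr + R_tip * u,
                 flow_speed_um_min = flow_speeds_um_min[i],
                 comet_rate_per_min = comet_rates_per_min[i],
                 marker_intensity = marker_intensities[i],
                 label = paste0("n", i))
  })
  scene_config(image_shape = image_shape, duration_s = duration_s,
               neurites = specs, rng_seed = rng_seed, ...)
}
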