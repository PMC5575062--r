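# gcflow

Quantification of cytoskeletal dynamics in neuronal growth cones from
fluorescence time-lapse microscopy, with a synthetic-scene generator that
makes every measurement verifiable by parameter recovery.

## What it measures

Developing neurons decide which neurite becomes the axon in part through the
interplay of microtubules and F-actin in growth cones. The quantities this
package extracts are the standard readouts of that interplay:

- **F-actin treadmilling speed** — a kymograph is sampled along a line ROI
  through a growth cone; linear retrograde flow of the actin reporter
  (e.g. Lifeact) appears as straight tracks whose slope, in px/frame, is
  converted to µm/min via `speed = |slope| · (pixel size / frame interval) · 60`.
  Both the classical manual-endpoint measurement and an automatic estimator
  (gradient-orientation histogram at 1° resolution + iterative ridge
  tracing) are provided.
- **EB3 comet counts** — microtubule plus-ends labelled with EB3 cross the
  growth-cone neck as distinct spots in a neck kymograph; spots are detected
  by difference-of-Gaussians band-pass filtering with a robust
  (MAD-denominated) prominence threshold.
- **EB3 coverage** — the percentage of the reporter-covered growth-cone area
  (max projection over time) occupied by EB3 signal.
- **Growth-cone intensity tracing** — per-frame delineation of the growth
  cone by the mean auto-threshold rule (pixels strictly above the crop
  mean, largest 8-connected component), retrieving mean intensities of the
  *original* channel at the mask coordinates across all frames.
- **Correlation statistics** — standard-score (z-score) normalization,
  Pearson correlation with the slope-equals-r identity on z-scored data,
  linear fits with escalation to a second-order polynomial when a
  nested-model F-test finds significant deviation from linearity, t tests,
  and one-/two-way ANOVA with Dunnett or Tukey post hocs.
- **Pyrene actin polymerization kinetics** — plateau (Ymax) and half-time
  (t1/2) of bulk polymerization traces, fitted with a lagged
  single-exponential saturation model
  `y(t) = y0 + (ymax − y0)(1 − e^{−k(t−lag)})` for `t ≥ lag`, so that
  `t1/2 = lag + ln 2 / k`; model-free estimates serve as initialization and
  fallback.

Because the microscopy videos behind such studies are rarely deposited, the
package ships a first-class simulator (`simulate_timelapse()`,
`simulate_kymograph()`, `simulate_neck_kymograph()`,
`simulate_coverage_scene()`, `simulate_kinetic_trace()`,
`simulate_paired_table()`) that generates calibrated TIFF-compatible scenes
with known ground truth: retrograde speckle flow at 0.3–6 µm/min, Poisson
comet entries, a diffuse marker channel, and saturating kinetics — under the
default acquisition regime of 5-min videos at one frame per 2 s (151
frames).

## Worked example

```r
library(gcflow)

# a synthetic stage-2 cell: 5 neurites, comet rate proportional to flow speed
cfg <- list(simulate = stage2_cell_config(n_neurites = 5, rng_seed = 11),
            analyses = c("speed", "comets", "intensity", "correlation"))
res <- run_pipeline(cfg)
res
#> <cell_analysis> 'cell1': 5 neurite(s), analyses: speed, comets, intensity, correlation
#> <result_table> 18 measurements
#>     cell neurite           quantity      value         units
#> 1  cell1      n1 treadmilling_speed   1.643378        um/min
#> 2  cell1      n1        comet_count   7.000000 comets/window
#> 3  cell1      n1   marker_intensity 100.447895          A.U.
#> 4  cell1      n2 treadmilling_speed   2.638734        um/min
#> ...
#>   comets_vs_speed: r = 0.735 (p = 0.157)
#>   marker_vs_speed: r = 0.999 (p = 1.73e-05)
```

The configured ground-truth speeds of this cell are 1.5, 2.6, 3.8, 4.9 and
6.0 µm/min; the table shows the pipeline recovering them from the rendered
pixels (1.64, 2.64, … µm/min), counting the comets each neck received in 5
minutes, and correlating the per-neurite measurements the way paired
growth-cone data are analyzed (z-scored, Pearson).

Single stages work standalone:

```r
sim <- simulate_kymograph(-1, n_tracks = 3, kymo_shape = c(100, 151),
                          line_intensity = 100, noise_sd = 20, rng_seed = 1,
                          sample_spacing_um = 0.1, frame_interval_s = 2)
estimate_speed_auto(sim$kymo, "retrograde")
#> <treadmill_estimate> (auto_radon): 3 track(s)
#>   mean speed 2.995 um/min (slopes -0.999, -0.998, -0.997 px/frame)
```

A thin command-line front-end is installed at `inst/cli/gcflow`
(`gcflow simulate|kymo|speed|comets|coverage|intensity|run`).

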