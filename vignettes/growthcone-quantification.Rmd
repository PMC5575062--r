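---
title: "Quantifying growth-cone cytoskeletal dynamics with gcflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying growth-cone cytoskeletal dynamics with gcflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcflow)
```

## The measurement problem

Before a neuron polarizes, its growth cones compete: the one with the most
dynamic F-actin and the most incoming microtubule plus-ends tends to become
the axon. Live imaging of such cells produces two-channel time-lapse videos
(an F-actin reporter such as Lifeact, and the plus-end marker EB3), from
which four quantities are classically extracted: the retrograde F-actin
treadmilling speed in each growth cone, the number of EB3 comets entering
each neurite, the fraction of the growth-cone area that EB3 signal reaches,
and the level of a diffuse marker (e.g. the actin-binding protein drebrin)
per growth cone. Paired per-growth-cone measurements are then related by
correlation after standard-score normalization, and drug or knockdown
conditions are compared by t tests or ANOVA with post hoc corrections. A
complementary cell-free readout is bulk pyrene-actin polymerization,
summarized by its plateau (Ymax) and half-time (t1/2).

gcflow implements this entire chain as tested, scriptable R functions, plus
a synthetic-scene generator with known ground truth, so that every stage can
be validated by parameter recovery rather than by eye.

## Conventions

* Pixel coordinates are 0-based `(x, y) = (column, row)` at pixel centers,
  fixed once for the whole package because ROI conventions differ between
  imaging tools.
* Stacks carry their calibration (`pixel_size_um`, `frame_interval_s`)
  explicitly; every speed in µm/min is computed from that metadata, never
  from a hard-coded default. Reading a TIFF without resolvable calibration
  is an error. Since plain TIFF written by the `tiff` package cannot hold
  custom tags, `write_stack()` places the calibration in a JSON sidecar;
  the read priority is explicit argument > sidecar > TIFF resolution tags.
* A duration of `d` seconds at interval `i` contains `floor(d/i) + 1`
  frames — the frame at `t = 0` counts, so 5 min at 2 s is 151 frames.
* Axis ROIs are ordered base→tip; retrograde motion therefore has negative
  slope in kymograph space.

## Kymographs and treadmilling speed

`make_kymograph()` samples the stack at unit arc-length steps along a line
ROI with bilinear interpolation (nearest-neighbour is available for
bit-exact toy fixtures); width > 1 averages across the perpendicular. The
sample spacing equals the pixel size, so a trajectory of slope `s` px/frame
corresponds to `|s| · pixel_size / interval · 60` µm/min.

Two estimators are provided:

* `estimate_speed_manual()` is the faithful re-implementation of measuring
  trajectory endpoints by hand: exact arithmetic on user-supplied
  (distance, time) pairs.
* `estimate_speed_auto()` is this package's addition. The dominant
  orientation is found on a gradient structure-tensor orientation histogram
  (1° bins, votes weighted by squared gradient magnitude, restricted to the
  requested direction sign, parabolic peak interpolation, ties broken toward
  the steeper angle). We chose local gradient voting over a global
  projection score after observing that projections can alias across
  parallel tracks and lock onto "ghost" orientations. Track offsets are then
  peaks of the shear projection at the peak orientation (the offset range
  covers corner-clipped tracks), and each track's slope is refined by
  iterated ridge tracing — per-column intensity maxima within ±3 px of the
  predicted line, weighted least-squares refit, three iterations — so the
  final slope is free of the 1° grid. Tracks shorter than 5 frames or
  spanning under 3 distance samples are discarded; ridges collecting less
  than 30% of the strongest ridge's traced weight are treated as tails and
  dropped; duplicate convergences are merged. When nothing survives, the
  estimate is flagged `no_track` — never silently zero.

On simulated kymographs at 0.1 µm/px and 2 s/frame with signal-to-noise 5,
speeds of 1–6 µm/min are recovered with mean error below 5% (the acceptance
suite enforces < 10%). Manual and automatic estimates agree within 5% on
noiseless single-track fixtures.

## Comet counting

Comets crossing a neck line appear as compact spots in the neck kymograph.
`count_comets()` band-passes the image with a difference of Gaussians
(σ = 1 and 3 px), thresholds at `median + 5 · MAD` — the MAD is estimated
from the symmetric left tail of the DoG distribution, because dense comet
traffic would otherwise inflate the noise estimate with its own signal —
and extracts local maxima. Maxima are localized on a lightly smoothed
surface (σ = 0.5 px) gated by the DoG threshold: the band-pass decides what
is signal, the sharper surface keeps nearly touching comets apart. Maxima
closer than `min_separation` (default 2 px, 2 frames) merge into one
detection, so an oscillating comet that crosses twice within the kernel is
counted once.

Two comets that genuinely land within one PSF of each other in both time
and position fuse into a single spot and are irreducibly counted once; at 8
comets/min over 5 minutes this costs a few percent of the count. This is a
physical resolution limit, not a detector threshold, and it is why the
neck-kymograph generator spreads crossings across a realistic line length —
on a very short line the dense-rate benchmark would be unattainable for any
detector.

`coverage_percent()` max-projects both channels, thresholds each inside the
region of interest (Otsu by default, parameter-free and scale-invariant;
the mean-threshold rule is available by flag since the thresholding method
behind published coverage percentages is typically unstated), and reports
`100 · |EB3 ∩ reference| / |reference|`.

## Growth-cone delineation and intensity retrieval

`mean_threshold_mask()` implements the "Mean" auto-threshold: pixels
strictly greater than the crop's arithmetic mean. Strict inequality makes a
constant crop yield an empty mask (flagged degenerate) rather than a full
one — a constant crop contains no growth cone. The exact mean is canonical
here; histogram-binned approximations used by some imaging tools differ in
the low bits. By default only the largest 8-connected component is kept so
the delineation follows the single dynamic growth cone; the unfiltered
behaviour is exposed (`keep_largest = FALSE`) because either policy is
defensible and published descriptions rarely say which was used.

`trace_growthcone()` applies the mask per frame to the segmentation channel
and retrieves the mean of the *original* measurement-channel intensities at
the mask coordinates — measuring the thresholded image itself would be a
bug, and the class invariant forbids it. Degenerate frames are excluded
from the time average and reported; more than 50% degenerate frames aborts.
`manual_region_mean()` reproduces the manual alternative: mean of pixels
whose centers fall inside a polygon under the even-odd rule.

## Statistics

`zscore_pair()` normalizes each variable by its own sample mean and
standard deviation (n−1 denominator throughout, consistent with
SEM = sd/√n). On z-scored data the least-squares slope equals Pearson's r
exactly, which is why the slope printed on a standard-score scatter can be
read as its correlation coefficient; `pearson_fit()` asserts this identity
to 1e-9.

`fit_with_linearity_gate()` formalizes "test for linearity, escalate if it
fails": a nested-model F-test (quadratic vs linear) at α = 0.05 decides the
branch; the quadratic branch additionally reports the cubic-vs-quadratic
F-test as a deviation-from-model check. The F-test was chosen because it is
objective and reproducible; published analyses that escalate from linear to
second-order fits rarely name their criterion.

`compare_groups()` routes two groups to the two-tailed pooled t test and
more groups to one-way ANOVA with Dunnett (vs control) or Tukey (all pairs)
post hocs via single-step multivariate-t adjustment (multcomp); a two-way
layout runs ANOVA with interaction and Tukey over the cell means. Both post
hocs reduce to the t test when only two groups are supplied, and adjusted
p-values never undercut raw ones. The acceptance suite calibrates the
empirical type-I error of every test to [0.03, 0.07] at nominal 0.05 over
1000 null replicates.

Slope/r pairs that disagree in the third decimal can arise in published
standard-score scatters from undocumented pooled scalings; no attempt is
made to reproduce such pairings, only the exact identity on per-variable
z-scores.

## Polymerization kinetics

Pyrene traces show a nucleation lag followed by pseudo-first-order
elongation, so `fit_kinetics()` fits
`y(t) = y0 + (ymax − y0)(1 − e^{−k(t−lag)})` for `t ≥ lag` (baseline `y0`
before), by Levenberg–Marquardt with multistart initialization from
`model_free_estimates()` (smoothed top-decile plateau; baseline from linear
back-extrapolation of the smoothed start; first half-crossing, linearly
interpolated). `t1/2 = lag + ln 2 / k`, so the fitted curve passes through
`(t1/2, (y0+ymax)/2)` by construction. Pre-polymerization baseline cycles
are absorbed by the lag parameter rather than trimmed (trimming available
by flag). Because a published "Ymax" may be either a fitted plateau or an
observed maximum, both are reported (`ymax`, `ymax_observed`).
`pyrene_presets()` carries per-condition plateau/half-time means and SEMs
for actin alone and with drebrin/microtubule/EB3 additions, for generating
realistic fixtures; at 2% noise, 50 simulated traces recover both
parameters with median error well under 5%.

## The synthetic generator: what it emulates, and what not

`simulate_timelapse()` renders three co-registered channels on the frame
grid `floor(duration/interval) + 1`: F-actin speckles (a stationary
birth–death population, density per µm², exponential lifetimes) advected
tip→base at the configured speed and rendered by Gaussian splatting at
sub-pixel positions (σ = PSF), EB3-like puncta born at the neck at a
Poisson rate and moving tipward, and a PSF-blurred marker filling the
growth-cone footprint. Noise is `Poisson(scale·signal)/scale` plus additive
Gaussian; either term can be disabled. Identical configurations and seeds
give bit-identical stacks, and the caller's RNG stream is untouched.

Defaults encode the study conditions the analysis assumes: 5 min at 2 s
(151 frames), 0.16 µm/px (a plausible value for a 60×/1.4 NA camera setup;
time-lapse pixel sizes are rarely published, so calibration is a free
parameter that all downstream math reads from metadata), flow speeds in the
0.3–6 µm/min range, comet rates of a few per minute.

Deliberately not emulated: spectral bleed-through, photobleaching, 3D
stacks, curved or accelerating trajectories, comet lifetime statistics.
Passing recovery tests on these scenes therefore demonstrates correctness
of the measurement chain under the stated noise model — not robustness to
every artifact of real microscopy.

## Problem sizes and numerical choices

The test and acceptance suites run simulations at the scales the
measurements are specified for: 151-frame kymographs, 20 seeds per speed,
50 seeds per comet rate, 1000 null replicates per statistical test, 50
kinetic traces, and 20 five-neurite cells for the end-to-end correlation —
about four minutes of compute in total. Tolerances are part of each
contract: 10% mean error for speeds, 10% count error and F1 ≥ 0.95 for
comets, ±3 points for coverage, 15% for intensity ratios, [0.03, 0.07]
type-I bands, 5% median kinetic errors. Degenerate inputs fail loudly by
design: zero-variance variables, constant crops, flat kinetic traces,
vertical manual trajectories and out-of-bounds ROIs all raise descriptive
errors instead of returning numbers.
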