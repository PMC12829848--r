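# biofilmlapse

Quantitative analysis of multi-mode time-lapse imaging of bacterial
macro-colonies ("biofilms") growing on agar. The package is aimed at labs
running low-cost automated imagers that cycle each dish through bright-field
transillumination, white epi-illumination and dual-colour epi-fluorescence
every 20 minutes for days, and that need the resulting frame stacks turned
into defensible numbers: growth curves, reporter-expression dynamics, and
instrument quality-control metrics.

## What it computes

Per well and imaging cycle, from the 8-bit frame stacks:

* **Biomass proxy** — inverted transillumination intensity
  (255 − *I*), reference-subtracted against the *t*₀ frame, Otsu-binarized,
  and integrated over the colony ROI as
  (*Ī*<sub>in</sub> − *Ī*<sub>out</sub>) × area. A relative attenuation
  measure, invariant to constant illumination offsets.
* **Integrated and normalized fluorescence** — the transillumination ROI
  transferred to each *t*₀-subtracted fluorescence frame; normalized
  fluorescence divides by the biomass proxy at the same cycle.
* **Growth onset and alignment** — onset is the earliest cycle at/after the
  area minimum followed by *k* = 3 strict increases; series are re-timed so
  onset is *t* = 0 for treated-vs-control comparison, with trapezoidal AUC
  and per-bin fold-change matrices.
* **Kymographs and drift** — line profiles (bilinear) stacked over cycles,
  baseline-subtracted; dish-edge position per cycle from the maximum
  absolute first difference of the raw profile, giving positional drift in
  px and mm.
* **QC metrics** — cycle-timing deviations from timestamp logs; noise
  (population SD outside the ROI), signal (mean of samples ≥ 3× noise) and
  S/N; temporal and spatial CVs (100 × SD/mean); limit of detection
  5 × SD(blank)/slope from a calibration series; Laplacian focus variance;
  USAF-1951 resolution (element frequency 2^(group + (element−1)/6) lp/mm,
  finest element with Michelson contrast ≥ 0.10); flat-field uniformity CV
  over a window between an alignment disk's hole and edge.

A synthetic scene generator (`generate_stack()`, `generate_usaf_target()`,
`generate_alignment_disk()`, `generate_timestamps()`,
`generate_calibration_series()`) renders all of these inputs with known
ground truth — growing discs with two-reporter dynamics, sensor noise,
vignetting, positional jitter, green→red crosstalk, timing drift — so every
stage has a parameter-recovery test. See the vignette
(`vignettes/biofilm-quantification.Rmd`) for the model and its assumptions.

## Worked example

Simulate one well under the default study conditions (512 × 384 px frames,
60 cycles of 1200 s, noise SD 2, 5% vignette, 1 px jitter) and quantify it:

```r
library(biofilmlapse)

sim <- generate_stack(
  scene_config(wells = 1, channels = c("trans", "green", "red"),
               n_cycles = 60, seed = 1),
  growth_model(), reporter_model())

series <- quantify_stacks(
  scene_stack(sim, 1, "trans"),
  list(green = scene_stack(sim, 1, "green"),
       red   = scene_stack(sim, 1, "red")))

dplyr::slice(series, c(10, 25, 40, 60))
#> # A tibble: 4 × 9
#>   cycle time_s area_px  biomass fluor_green norm_green fluor_red
#> 1     9  10800    2074  230460.      23372.      0.101     7816.
#> 2    24  28800   26315 3043400.    1170375.      0.385   559190.
#> 3    39  46800   38974 4502998.    1799203.      0.400  1168312.
#> 4    59  70800   43901 5080019.    1725387.      0.340  1554902.
```

The colony is detected from cycle 7 (`attr(series, "onset_cycle")`), its
area grows to ~44 000 px and the biomass proxy to ~5.1 × 10⁶ intensity·px.
Integrated green fluorescence peaks at cycle 35 and then falls as the
central region shuts down, while red keeps rising — the expected
two-reporter signature; the normalized green AUC over the run is
`auc(series$norm_green, series$time_s)` ≈ 2.12 × 10⁴.

Drift analysis over the dish edge of the same well:

```r
mid <- (384 + 1) / 2
km <- build_kymograph(scene_stack(sim, 1, "trans"),
                      p0 = c(mid, 5), p1 = c(mid, 160),
                      mode = "inverted_transillumination")
positional_deviation(km, pixel_size = sim$scene$pixel_size)
```

reports a maximum edge displacement of 4 px (0.43 mm at this pixel size)
under the default 1-px-SD jitter. `autoplot(km)` draws the kymograph;
`plot_biofilm_series(series)` the growth and fluorescence curves;
`run_pipeline(pipeline_config(...))` runs everything end-to-end and writes
`series.csv`, `summary.csv`, kymograph matrices/heatmaps and
`qc_report.json`. A command-line wrapper with `simulate`, `quantify`,
`kymo`, `qc` and `report` subcommands lives at
`inst/scripts/lapse_pipeline.R`.

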