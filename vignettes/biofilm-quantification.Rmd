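---
title: "Quantifying biofilm development from multi-mode time-lapse stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biofilm development from multi-mode time-lapse stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmlapse)
```

## The measurement problem

A macro-colony ("biofilm") growing on agar in a small Petri dish is imaged
repeatedly — every 20 minutes for several days — in four modes:
white-light transillumination (the colony absorbs transmitted light, so
attenuation proxies biomass), white epi-illumination (surface morphology),
and two epi-fluorescence channels carrying transcriptional-reporter signals
(a green protein such as GFPmut2 and a red one such as mCherry). The
package turns those frame stacks into per-well time series of four derived
quantities, and provides the instrument-validation metrics needed to trust
them.

The core measurement chain, applied per well and cycle, is:

1. **Inversion.** Transillumination intensities are inverted, $I' = 255 - I$,
   so absorbing structures become positive signal (frames are 8-bit).
2. **Reference subtraction.** The cycle-0 frame is subtracted and the
   difference clipped at zero. This cancels every static feature — uneven
   illumination, the dish rim, sensor fixed pattern — and leaves only
   signal gained since $t_0$. The clip at zero (rather than an absolute
   value) encodes the physical assumption that a colony can only *darken*
   transillumination relative to the empty dish.
3. **Otsu segmentation.** The inverted difference frame is binarized at
   the threshold maximizing between-class variance over the 256-bin
   histogram. The ROI is the largest 8-connected component with interior
   holes filled: one central colony per dish is assumed, and interior
   intensity dips (rings, wrinkles) must not punch holes in the mask.
4. **Biomass proxy.** $(\bar I_\mathrm{in} - \bar I_\mathrm{out}) \times
   \mathrm{area}$ on the inverted difference frame, clipped at zero. The
   inner-minus-outer difference makes the proxy invariant to any constant
   frame offset. It is a *relative* attenuation measure — extracellular
   matrix contributes, so it is not an optical density.
5. **Fluorescence transfer.** The transillumination ROI is re-applied to
   the $t_0$-subtracted fluorescence frames; integrated fluorescence is
   again $(\bar I_\mathrm{in} - \bar I_\mathrm{out}) \times \mathrm{area}$,
   and **normalized fluorescence** divides it by the biomass proxy at the
   same cycle, removing the trivial dependence of total signal on colony
   size. A zero biomass proxy leaves the ratio undefined (`NA`), never 0.

Kymographs stack a line profile (bilinear interpolation, one sample per
pixel by default) over cycles, baseline-subtracted against the cycle-0
profile; transillumination is inverted before profiling, fluorescence is
profiled raw. Dish-edge drift is the per-cycle displacement of the maximum
absolute first difference of the *raw* profile — quantification never uses
the min–max display normalization.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_area` | 20 | px | ROIs smaller than this are "not detected": near-background signal produces speckle masks whose statistics are meaningless. Area is reported as 0 and fluorescence as missing. |
| `k` (onset) | 3 | cycles | Growth onset = earliest point at/after the area minimum followed by `k` strict increases. Three consecutive rises at 20-min sampling suppress single-frame noise without delaying onset detection by more than an hour. |
| `k` (S/N) | 3 | — | Signal = mean of profile samples ≥ 3× noise, the conventional detection multiplier; noise is the population SD outside the ROI on subtracted frames. `min_run` (default 1) optionally requires qualifying samples to be contiguous, because an isolated ≥3σ Gaussian excursion occurs about once per 800 samples and is not a signal region. |
| LOD factor | 5 | — | Limit of detection = 5 × SD(blank) / calibration slope, after subtracting the blank mean from all points. |
| Contrast cutoff | 0.10 | — | Resolution = finest bar element whose Michelson contrast $(I_{max}-I_{min})/(I_{max}+I_{min})$ stays ≥ 10%, the usual stripe-discriminability criterion. |
| Uniformity window | 250 px at 2312-px width | px | Flat-field CV window between the alignment-disk hole and edge; scales proportionally with frame width so test-scale frames probe the same fraction of the field. |

Population (divide-by-$n$) standard deviations are used throughout, the
common image-analysis convention; users wanting sample SDs can apply the
$\sqrt{n/(n-1)}$ factor.

## What the synthetic generator emulates — and what it does not

Every stage is tested by parameter recovery against scenes with known
ground truth, generated by `generate_stack()`:

* a disc of radius $r(t) = r_0 + (r_{max}-r_0)(1-e^{-\rho\,\max(0,t-\ell)})$
  (non-decreasing, lagged, saturating) attenuating the transillumination
  background by `inner_density` grey levels, with an error-function edge
  over `edge_softness` px — real colony edges are gradual, and a soft edge
  keeps Otsu thresholds stable;
* green reporter rising with a saturating time course, then decaying in
  the central 60% of the disc radius from `green_decline_onset` onward
  while the expanding rim keeps expressing, so integrated green peaks and
  falls; red rising monotonically and uniformly — the qualitative
  two-reporter signature of mature-colony expression dynamics;
* `crosstalk_green_to_red` × the green field added to the red channel
  (spectral bleed-through of GFP emission past a long-pass filter);
* additive Gaussian sensor noise (default SD 2 grey levels), a radial
  vignette (default 5% at the corner), an integer rigid per-cycle
  translation shared by all channels of a well (tray repositioning error,
  default SD 1 px), and a dark field beyond the dish edge providing the
  brightness step used for drift detection;
* timestamp logs with per-stamp jitter and cumulative per-cycle drift, a
  three-bar USAF-1951 chart, a fluorescent alignment disk, and a linear
  fluorescein-style calibration series.

The generator is phenomenological. It does not model optics (no PSF or
photon shot noise), agar or condensation, colony morphology (wrinkles,
rings), the spatial form of real reporter fields, or JPEG compression.
Passing recovery tests therefore demonstrates that the *measurement chain*
is correct and unbiased under controlled conditions — not that it is
robust to every artefact of real acquisitions. Defaults are the study
conditions: 512 × 384 px test frames (the full 2312 × 1736, 9-well
geometry is behind `scale = "full"`), 3 wells, 60 cycles of 1200 s, dish
diameter 36.7 mm spanning 90% of the frame height.

## Numerical choices and degenerate inputs

* **Otsu ties** resolve to the lowest maximizing threshold and the mask is
  a strictly-greater comparison, so a perfectly bimodal frame splits
  exactly at the lower mode; a constant frame is a "degenerate histogram"
  error. Inside `quantify_stacks()` a constant difference frame (no growth
  yet) is treated as "not detected" rather than an error.
* **Edge ties** in `detect_edge()` resolve to the smallest index, and the
  returned index is the sample after the step (rising-index convention).
* **Empty masks** yield area 0, `NA` means, `detected = FALSE`; an
  all-zero or all-missing normalized-fluorescence series has AUC 0; the
  AUC integrates (trapezoid) from the *first non-missing, nonzero* value
  to the endpoint.
* **Fold-change bins** with a zero control mean are `NA`, and binning is
  done on onset-aligned times (default 1-cycle bins), since treated series
  are systematically delayed and raw-time ratios would compare different
  developmental stages.
* **8-bit clipping** interacts with near-zero fluorescence: negative noise
  excursions clip at 0, biasing small means upward. `crosstalk_estimate()`
  therefore regresses interior (eroded-ROI) red on green means *with an
  intercept* and discards cycles below 20 grey levels; a through-origin
  regression on integrated intensities would fold the constant clip offset
  into the slope.
* **16-bit inputs** are rescaled to 8-bit with a logged divisor, since all
  arithmetic (inversion, histograms) assumes the 8-bit range.

## Design decisions that were genuinely open

* The Fiji-style workflow behind the measurement chain does not specify
  connected-component or hole-filling rules; largest-component plus
  hole-filling is this package's convention (one colony per dish).
* The timestamp carrier is a `timestamps.csv` sidecar (cycle, well,
  channel, epoch seconds); image-file metadata is deliberately not parsed.
* Profile interpolation is bilinear; the line-selection tools of common
  image software do not document their scheme, and bilinear is exact for
  the piecewise-linear intensity fields the tests construct.
* "First time point at which normalized fluorescence was detected" (the
  AUC start) is operationalized as the first cycle with a detected ROI
  (≥ 20 px) and positive integrated fluorescence.
* Monte-Carlo LOD checks use 12 blank replicates: with triplicate blanks
  the small-sample bias of the SD estimate (≈ 28% low for $n=3$) would
  dominate the comparison against the closed form $5\sigma/m$, which is a
  property of tiny blank panels, not of the estimator.

## Problem sizes

The test suite and the acceptance script run the generator at the 512 × 384
test scale (60-cycle single-well stacks for recovery checks; 30 cycles for
the crosstalk scene; 100 random 16 × 16 frames for the threshold oracle;
100 seeds for the LOD Monte Carlo), sizes chosen so the whole suite
completes in a couple of minutes while every recovery check still operates
on discs hundreds of pixels across.

## Known limitations

* Drift is quantified along the analysis line only; there is no 2-D
  registration, so a purely perpendicular shift is invisible to
  `positional_deviation()`.
* The biomass proxy saturates when the colony becomes opaque and is
  contaminated by strongly absorbing chromoproteins (red fluorescent
  protein absorbs visible light), so cross-strain comparisons need equal
  pigmentation.
* With per-cycle jitter enabled, early cycles can transiently segment the
  jitter residual of the dish rim instead of a tiny colony; the `min_area`
  rule suppresses most but not all of these frames, which matters only
  before growth onset.
* The soft colony edge biases the recovered mean amplitude low by roughly
  the ratio of the edge band to the disc area (≈ 2σ · 2πr / πr²); recovery
  checks are therefore most meaningful for mature discs.

## A worked example

```{r example, eval = FALSE}
sim <- generate_stack(
  scene_config(wells = 1, channels = c("trans", "green", "red"),
               n_cycles = 60, seed = 1),
  growth_model(), reporter_model())

series <- quantify_stacks(
  scene_stack(sim, 1, "trans"),
  list(green = scene_stack(sim, 1, "green"),
       red = scene_stack(sim, 1, "red")))
plot_biofilm_series(series)

km <- build_kymograph(scene_stack(sim, 1, "trans"),
                      p0 = c(192.5, 1), p1 = c(192.5, 512),
                      mode = "inverted_transillumination")
autoplot(km)
```
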