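#' Biomass proxy from a transillumination ROI
#'
#' The biomass proxy is the inverted transmitted-light intensity (255 - I)
#' integrated over the colony after t0-reference subtraction, computed as
#' `(mean_inner - mean_outer) * area` on the inverted difference frame. It
#' is a relative attenuation measure, not an absolute optical density.
#' Negative values (inner darker than background) are clipped to 0, and an
#' undetected ROI yields 0.
#'
#' @param roi A [roi_result()] measured on the inverted, t0-subtracted
#'   transillumination frame.
#' @return Biomass proxy in intensity x px.
#' @export
biomass_proxy <- function(roi) {
  stopifnot(inherits(roi, "roi_result"))
  if (!roi$detected || roi$area == 0) return(0)
  max(0, (roi$mean_inner - roi$mean_outer) * roi$area)
}

#' Integrated fluorescence intensity of a ROI
#'
#' `(mean_inner - mean_outer) * area` on the t0-subtracted fluorescence
#' frame. Unlike the biomass proxy the value may be negative (inner dimmer
#' than the surround); that case is preserved and flagged with a warning.
#'
#' @param roi A [roi_result()] transferred onto the fluorescence frame.
#' @return Integrated intensity in intensity x px (`NA` if undetected).
#' @export
fluorescence_intensity <- function(roi) {
  stopifnot(inherits(roi, "roi_result"))
  if (!roi$detected || roi$area == 0) return(NA_real_)
  val <- (roi$mean_inner - roi$mean_outer) * roi$area
  if (!is.na(val) && val < 0)
    warning("inner fluorescence below outer background; negative integrated ",
            "intensity retained", call. = FALSE)
  val
}

#' Biomass-normalized fluorescence
#'
#' Integrated fluorescence divided by the biomass proxy at the same time
#' point, removing the trivial dependence of total signal on colony size.
#' A zero biomass proxy leaves the ratio undefined (`NA`).
#'
#' @param fluor Integrated fluorescence, intensity x px.
#' @param biomass Biomass proxy, intensity x px.
#' @return Dimensionless ratio (vectorized).
#' @export
normalized_fluorescence <- function(fluor, biomass) {
  out <- ifelse(!is.na(biomass) & biomass > 0, fluor / biomass, NA_real_)
  as.numeric(out)
}

#' Growth onset from a binarized-area series
#'
#' The onset is the earliest position at or after the series minimum from
#' which the area increases strictly for `k` consecutive steps — the start
#' of stable regrowth used to align treated and control series. Ties in the
#' minimum resolve to the earliest.
#'
#' @param area Numeric vector of per-cycle ROI areas.
#' @param k Number of consecutive strict increases required (default 3,
#'   which suppresses single-frame noise at 20-min sampling).
#' @return 1-based position of the onset within `area`, or `NA` with a
#'   warning if no position qualifies ("no growth").
#' @export
growth_onset <- function(area, k = 3) {
  stopifnot(k >= 1)
  n <- length(area)
  start <- which.min(area)            # earliest tie
  for (t in start:n) {
    if (t + k > n) break
    if (all(area[(t + 1):(t + k)] > area[t:(t + k - 1)])) return(t)
  }
  warning("no growth: no stable area increase found after the minimum",
          call. = FALSE)
  NA_integer_
}

#' Align a series so its growth onset is time zero
#'
#' Subtracts the onset time from the time column; pre-onset points are kept
#' with negative times so series with different lags become comparable.
#'
#' @param series Tibble with a `time_s` column (e.g. from
#'   [quantify_scene()]).
#' @param onset 1-based row position of the onset (see [growth_onset()]).
#' @return The series with `time_s` shifted and an `aligned` attribute.
#' @export
align_series <- function(series, onset) {
  stopifnot(is.data.frame(series), "time_s" %in% names(series))
  if (is.na(onset)) return(series)
  out <- dplyr::mutate(series, time_s = .data$time_s - .data$time_s[!!onset])
  attr(out, "aligned") <- TRUE
  out
}

#' Area under the normalized-fluorescence curve
#'
#' Trapezoidal integral from the first detected point (first non-missing,
#' nonzero value) to the series endpoint. An all-zero or all-missing series
#' integrates to 0.
#'
#' @param y Normalized fluorescence values.
#' @param times Times in seconds, same length as `y`.
#' @return The integral (dimensionless x s).
#' @export
auc <- function(y, times) {
  stopifnot(length(y) == length(times))
  first <- which(!is.na(y) & y != 0)[1]
  if (is.na(first) || first == length(y)) return(0)
  idx <- first:length(y)
  yy <- y[idx]; tt <- times[idx]
  ok <- !is.na(yy)
  yy <- yy[ok]; tt <- tt[ok]
  if (length(yy) < 2) return(0)
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' Fold-change matrix of treated vs control normalized fluorescence
#'
#' Bins both series on their (onset-aligned) time axis and returns the
#' ratio of per-bin means, one row per strain and one column per bin.
#' Bins whose control mean is zero (or that lack data) give `NA`.
#'
#' @param treated,control Tibbles with columns `strain`, `time_s`, `value`.
#' @param bin_width Bin width in seconds (default one 20-min cycle).
#' @return A matrix strains x bins (dimnames give strain and bin start, s),
#'   with the long-form tibble in attribute `"tidy"`.
#' @export
fold_change_matrix <- function(treated, control, bin_width = 1200) {
  bin_means <- function(df) {
    df |>
      dplyr::mutate(bin = floor(.data$time_s / bin_width) * bin_width) |>
      dplyr::summarise(m = mean(.data$value, na.rm = TRUE),
                       .by = c("strain", "bin"))
  }
  tr <- bin_means(treated); ct <- bin_means(control)
  long <- dplyr::inner_join(tr, ct, by = c("strain", "bin"),
                            suffix = c("_treated", "_control")) |>
    dplyr::mutate(fold_change = ifelse(
      !is.na(.data$m_control) & .data$m_control != 0,
      .data$m_treated / .data$m_control, NA_real_)) |>
    dplyr::arrange(.data$strain, .data$bin)
  wide <- tidyr::pivot_wider(
    dplyr::select(long, "strain", "bin", "fold_change"),
    names_from = "bin", values_from = "fold_change")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$strain
  attr(m, "tidy") <- dplyr::select(long, "strain", "bin", "fold_change")
  m
}

#' Estimate green-to-red spectral crosstalk from a dual-reporter stack
#'
#' Regresses the per-cycle mean red intensity inside the colony on the mean
#' green intensity (both on t0-subtracted frames), using the
#' transillumination ROI eroded by `erode_px` so partially covered edge
#' pixels are excluded, and only cycles whose interior green signal exceeds
#' `min_level` grey levels (near-background cycles are nonlinear because of
#' 8-bit zero clipping). The regression keeps an intercept, which absorbs
#' constant sensor offsets; the slope estimates the bleed-through fraction.
#'
#' @param trans_stack Transillumination [lapse_stack()] (ROI source).
#' @param green_stack,red_stack Fluorescence stacks on the same cycle grid.
#' @param min_area Detection threshold on ROI area, px.
#' @param erode_px Erosion radius applied to the ROI mask, px.
#' @param min_level Minimum interior green signal for a cycle to be used.
#' @return List with `fraction` (slope), `n_cycles` used, and `fit`.
#' @export
crosstalk_estimate <- function(trans_stack, green_stack, red_stack,
                               min_area = 20, erode_px = 6, min_level = 20) {
  seg <- segment_stack(trans_stack, min_area = min_area)
  gd <- subtract_reference(green_stack)$frames
  rd <- subtract_reference(red_stack)$frames
  brush <- EBImage::makeBrush(2 * erode_px + 1, "disc")
  pts <- purrr::map(seq_along(seg$rois), function(i) {
    roi <- seg$rois[[i]]
    if (!roi$detected) return(NULL)
    interior <- EBImage::erode(roi$mask * 1, brush) > 0
    if (sum(interior) < 100) return(NULL)
    c(green = mean(gd[[i]][interior]), red = mean(rd[[i]][interior]))
  })
  m <- do.call(rbind, purrr::compact(pts))
  use <- !is.null(m) && nrow(m) > 2
  if (use) m <- m[m[, "green"] >= min_level, , drop = FALSE]
  if (!use || nrow(m) < 3)
    stop("too few usable cycles to estimate crosstalk", call. = FALSE)
  fit <- stats::lm(red ~ green, data = as.data.frame(m))
  list(fraction = unname(stats::coef(fit)[["green"]]),
       n_cycles = nrow(m), fit = fit)
}

#' Quantify one well of a multi-channel scene into a biofilm series
#'
#' The full measurement chain for one well: segment the transillumination
#' stack (invert, subtract t0, Otsu, largest component), compute the
#' biomass proxy per cycle, transfer each ROI onto the t0-subtracted
#' fluorescence frames, and derive integrated and biomass-normalized
#' fluorescence. Cycles where no ROI is detected report area 0, biomass 0
#' and missing fluorescence.
#'
#' @param trans_stack Transillumination [lapse_stack()].
#' @param fluor_stacks Named list of fluorescence `lapse_stack`s sharing the
#'   cycle grid (may be empty).
#' @param min_area Detection threshold on ROI area, px.
#' @param k Consecutive-increase count for [growth_onset()].
#' @return A tibble (one row per cycle): `cycle`, `time_s`, `area_px`,
#'   `biomass`, then `fluor_<ch>` and `norm_<ch>` per fluorescence channel;
#'   attributes `onset` (row position or `NA`) and `onset_cycle`.
#' @export
quantify_stacks <- function(trans_stack, fluor_stacks = list(),
                            min_area = 20, k = 3) {
  seg <- segment_stack(trans_stack, min_area = min_area)
  biomass <- purrr::map_dbl(seg$rois, biomass_proxy)
  out <- tibble::tibble(
    cycle = seg$cycles,
    time_s = seg$times %||% (seg$cycles * NA_real_),
    area_px = purrr::map_dbl(seg$rois, "area"),
    biomass = biomass
  )
  for (ch in names(fluor_stacks)) {
    fs <- fluor_stacks[[ch]]
    stopifnot(identical(fs$cycles, trans_stack$cycles))
    diff_f <- subtract_reference(fs)
    fl <- purrr::map2_dbl(seg$rois, diff_f$frames, function(roi, fr) {
      if (!roi$detected) return(NA_real_)
      suppressWarnings(fluorescence_intensity(transfer_roi(roi, fr)))
    })
    out[[paste0("fluor_", ch)]] <- fl
    out[[paste0("norm_", ch)]] <- normalized_fluorescence(fl, biomass)
  }
  onset <- suppressWarnings(growth_onset(out$area_px, k = k))
  attr(out, "onset") <- onset
  attr(out, "onset_cycle") <- if (is.na(onset)) NA_integer_
                              else out$cycle[onset]
  out
}
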