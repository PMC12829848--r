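#' Cycle-timing deviations from a timestamp log
#'
#' For a marker frame per cycle (one fixed well x channel), the deviation
#' of each measured inter-cycle interval from the nominal one:
#' `deviation_i = (stamp_{i+1} - stamp_i) - expected_interval`.
#'
#' @param stamps Numeric epoch seconds (one per cycle, ordered), or a
#'   tibble with an `epoch_s` column for a single well x channel.
#' @param expected_interval Nominal cycle interval, s (default 1200).
#' @return Tibble with `cycle` (index of the completed interval) and
#'   `deviation_s`.
#' @export
timing_deviations <- function(stamps, expected_interval = 1200) {
  if (is.data.frame(stamps)) {
    if (!is.null(stamps$well) &&
        nrow(dplyr::distinct(stamps[c("well", "channel")])) > 1)
      stop("pass the stamps of a single well x channel marker frame",
           call. = FALSE)
    stamps <- stamps$epoch_s[order(stamps$cycle %||% seq_along(stamps$epoch_s))]
  }
  if (length(stamps) < 2)
    return(tibble::tibble(cycle = integer(), deviation_s = numeric()))
  tibble::tibble(cycle = seq_len(length(stamps) - 1L),
                 deviation_s = diff(stamps) - expected_interval)
}

#' Noise level outside the biofilm ROI
#'
#' The population standard deviation of the intensities outside the ROI on
#' a t0-subtracted frame (or profile): everything beyond the colony is,
#' by definition, background noise.
#'
#' @param x Numeric matrix or vector (subtracted frame or profile).
#' @param roi_mask Logical mask of the ROI (`NULL` = everything is outside).
#' @return Noise level in grey levels.
#' @export
noise_level <- function(x, roi_mask = NULL) {
  outside <- if (is.null(roi_mask)) as.numeric(x) else as.numeric(x[!roi_mask])
  if (length(outside) == 0)
    stop("empty outside region: cannot estimate noise", call. = FALSE)
  pop_sd(outside)
}

#' Signal level and signal-to-noise ratio of a profile
#'
#' The signal is the mean of the profile samples at or above `k` times the
#' noise level (default k = 3); S/N is signal over noise. `min_run`
#' restricts qualifying samples to contiguous runs of at least that length,
#' so isolated noise excursions do not count as signal regions (the default
#' 1 applies the plain threshold rule).
#'
#' @param profile Numeric vector (t0-subtracted intensities).
#' @param noise Noise level, grey levels (> 0).
#' @param k Threshold multiplier.
#' @param min_run Minimum contiguous run length of qualifying samples.
#' @return List with `signal` and `snr` (both `NA` when nothing qualifies).
#' @export
signal_and_snr <- function(profile, noise, k = 3, min_run = 1) {
  if (is.na(noise) || noise <= 0)
    stop("undefined S/N: noise level must be > 0", call. = FALSE)
  q <- profile >= k * noise
  if (min_run > 1) {
    r <- rle(q)
    r$values <- r$values & r$lengths >= min_run
    q <- inverse.rle(r)
  }
  if (!any(q)) return(list(signal = NA_real_, snr = NA_real_))
  signal <- mean(profile[q])
  list(signal = signal, snr = signal / noise)
}

# coefficient of variation in percent (population SD); NA with a warning
# when the mean is zero
cv_pct <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  if (length(x) == 0 || m == 0) {
    warning("CV undefined: mean is zero", call. = FALSE)
    return(NA_real_)
  }
  100 * pop_sd(x) / m
}

#' Temporal and spatial coefficients of variation
#'
#' CV = 100 x SD/mean (population SD). For a matrix of profiles
#' (rows = time, columns = positions), the temporal CV is computed per
#' position over time and the spatial CV per time point across positions.
#' A plain vector is treated as a time series (temporal CV only).
#'
#' @param x Numeric vector or rows-by-time matrix of profiles.
#' @return List with `temporal` and `spatial` CV vectors, %.
#' @export
cv_stats <- function(x) {
  if (is.matrix(x)) {
    list(temporal = apply(x, 2, cv_pct), spatial = apply(x, 1, cv_pct))
  } else {
    list(temporal = cv_pct(x), spatial = NA_real_)
  }
}

#' Limit of detection from a calibration series
#'
#' Blank-subtracted mean intensities are fitted with a straight line
#' `intensity = a + m * concentration`; the LOD is
#' `factor x SD(blank) / m` (default factor 5), in mol/L.
#'
#' @param calibration Tibble with columns `concentration` and `intensity`
#'   (replicates as rows), blanks at concentration 0.
#' @param factor Multiple of the blank SD defining detection.
#' @return List with `lod`, `slope`, `blank_sd`, `fit` (the `lm`).
#' @export
lod_estimate <- function(calibration, factor = 5) {
  stopifnot(all(c("concentration", "intensity") %in% names(calibration)))
  blanks <- calibration$intensity[calibration$concentration == 0]
  if (length(blanks) == 0)
    stop("calibration table must include blank (0 M) replicates",
         call. = FALSE)
  if (length(unique(calibration$concentration[
        calibration$concentration > 0])) < 2)
    stop("need at least 2 nonzero concentrations", call. = FALSE)
  blank_sd <- pop_sd(blanks)
  means <- calibration |>
    dplyr::summarise(m = mean(.data$intensity), .by = "concentration") |>
    dplyr::mutate(m = .data$m - mean(blanks))
  fit <- stats::lm(m ~ concentration, data = means)
  slope <- stats::coef(fit)[["concentration"]]
  list(lod = factor * blank_sd / slope, slope = slope, blank_sd = blank_sd,
       fit = fit)
}

# 3x3 Laplacian (4-connected weights), valid interior only
laplacian_filter <- function(frame) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr < 3 || nc < 3) stop("frame too small for a 3x3 filter", call. = FALSE)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  4 * frame[i, j] - frame[i - 1, j] - frame[i + 1, j] -
    frame[i, j - 1] - frame[i, j + 1]
}

#' Laplacian focus metric
#'
#' Applies a 3x3 Laplacian filter (4-connected weights, border excluded),
#' extracts a line profile from the filtered image and returns the
#' population variance of the profile — large for sharp edges, near zero
#' when defocused.
#'
#' @param frame Numeric matrix.
#' @param p0,p1 Profile endpoints in the coordinates of `frame`
#'   (default: full central row). Must stay 1 px inside the border.
#' @return Variance of the Laplacian-filtered profile, intensity^2.
#' @export
focus_metric <- function(frame, p0 = NULL, p1 = NULL) {
  lap <- laplacian_filter(frame)
  if (is.null(p0)) {
    mid <- (nrow(lap) + 1) / 2
    p0 <- c(mid, 1); p1 <- c(mid, ncol(lap))
  } else {
    p0 <- p0 - 1; p1 <- p1 - 1   # interior offset of the valid region
  }
  prof <- line_profile(lap, p0, p1)
  mean((prof - mean(prof))^2)
}

#' Michelson contrast of a bar-pattern profile
#'
#' `(Imax - Imin) / (Imax + Imin)` where Imax is the mean of the profile's
#' interior local maxima (bar peaks for a bright-bar pattern, gaps for a
#' dark-bar one) and Imin the mean of its interior local minima; plateaus
#' are collapsed before extrema detection. A profile without interior
#' extrema falls back to its global max/min.
#'
#' @param profile Numeric vector across at least one full bar period.
#' @return Contrast fraction in `[0, 1]`.
#' @export
michelson_contrast <- function(profile) {
  v <- rle(as.numeric(profile))$values   # collapse plateaus
  imax <- max(profile); imin <- min(profile)
  if (length(v) >= 3) {
    d <- sign(diff(v))
    up_down <- which(d[-length(d)] > 0 & d[-1] < 0) + 1
    down_up <- which(d[-length(d)] < 0 & d[-1] > 0) + 1
    if (length(up_down) > 0) imax <- mean(v[up_down])
    if (length(down_up) > 0) imin <- mean(v[down_up])
  }
  if (imax + imin == 0) return(0)
  (imax - imin) / (imax + imin)
}

#' USAF-1951 element spatial frequency
#'
#' `2^(group + (element - 1)/6)` line pairs per mm.
#'
#' @param group Group number (the chart's large number).
#' @param element Element number within the group (1-6).
#' @return Frequency in line pairs/mm (vectorized).
#' @export
usaf_frequency <- function(group, element) {
  2^(group + (element - 1) / 6)
}

#' Resolution estimate from a rendered bar-target frame
#'
#' Scans the chart elements from coarse to fine, computing the Michelson
#' contrast of each element from its band profile (band rows averaged,
#' sampled at the known bar and gap centres so the bright field outside the
#' band cannot leak in), and returns the finest element before the first
#' one whose contrast drops below `cutoff` (default 0.10, the usual
#' stripe-discriminability criterion). The resolved line-pair spacing is
#' `1000 / frequency` in micrometres.
#'
#' @param frame Target frame matrix.
#' @param elements Element metadata tibble from [generate_usaf_target()].
#' @param cutoff Michelson-contrast cutoff.
#' @return List with `group`, `element`, `freq_lp_mm`, `spacing_um` and a
#'   `contrasts` tibble (per-element contrast and pass flag).
#' @export
resolution_estimate <- function(frame, elements, cutoff = 0.10) {
  els <- dplyr::arrange(elements, .data$freq_lp_mm)
  els$contrast <- purrr::map_dbl(seq_len(nrow(els)), function(i) {
    prof <- colMeans(frame[els$row0[i]:els$row1[i], , drop = FALSE])
    x0 <- els$col0[i] - 1          # bar pattern phase origin (x = index - 0.5)
    per <- els$period_px[i]; bar <- els$bar_px[i]
    bar_idx <- x0 + (0:2) * per + bar / 2 + 0.5
    gap_idx <- x0 + (0:1) * per + bar + (per - bar) / 2 + 0.5
    at <- function(ix) stats::approx(seq_along(prof), prof, ix)$y
    imin <- mean(at(bar_idx)); imax <- mean(at(gap_idx))
    if (imax + imin == 0) 0 else (imax - imin) / (imax + imin)
  })
  els$pass <- els$contrast >= cutoff
  fail <- which(!els$pass)
  last <- if (length(fail) == 0) nrow(els) else fail[1] - 1L
  if (last == 0) {
    warning("no element reaches the contrast cutoff; resolution unresolved",
            call. = FALSE)
    return(list(group = NA, element = NA, freq_lp_mm = NA_real_,
                spacing_um = NA_real_,
                contrasts = dplyr::select(els, "group", "element",
                                          "freq_lp_mm", "contrast", "pass")))
  }
  list(group = els$group[last], element = els$element[last],
       freq_lp_mm = els$freq_lp_mm[last],
       spacing_um = 1000 / els$freq_lp_mm[last],
       contrasts = dplyr::select(els, "group", "element", "freq_lp_mm",
                                 "contrast", "pass"))
}

#' Flat-field uniformity CV of an alignment-disk frame
#'
#' Samples radial intensity profiles in four directions (+x, -x, +y, -y)
#' from the disk centre and reports the CV over a window placed between
#' the central hole and the disk edge. The default window length scales
#' the reference 250 px (at 2312 px frame width) with the actual frame
#' width. The window must clear both the hole rim and the disk-edge rim.
#'
#' @param frame Disk frame matrix.
#' @param center `c(row, col)` disk centre.
#' @param hole_radius,disk_radius Hole and disk radii, px.
#' @param window Window length in px (`NULL` = scaled default).
#' @param margin Clearance from hole and edge rims, px.
#' @return Tibble: `direction`, `cv_pct`, `window_px`.
#' @export
uniformity_cv <- function(frame, center, hole_radius, disk_radius,
                          window = NULL, margin = 5) {
  if (is.null(window)) window <- max(10L, round(250 * ncol(frame) / 2312))
  start <- hole_radius + margin
  end <- start + window - 1
  if (end > disk_radius - margin)
    stop("window not clear of hole/edge: reduce `window` or `margin`",
         call. = FALSE)
  dirs <- list(`+x` = c(0, 1), `-x` = c(0, -1),
               `+y` = c(1, 0), `-y` = c(-1, 0))
  cvs <- purrr::imap(dirs, function(d, nm) {
    p0 <- center + d * start
    p1 <- center + d * end
    prof <- line_profile(frame, p0, p1, n_samples = window)
    suppressWarnings(cv_pct(prof))
  })
  tibble::tibble(direction = names(dirs), cv_pct = unlist(cvs, use.names = FALSE),
                 window_px = window)
}
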