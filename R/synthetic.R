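#' Scene configuration for the synthetic image-stack generator
#'
#' Describes the acquisition geometry the generator emulates: frame size,
#' number of wells, the ordered channel labels, cycle count and interval,
#' and the physical pixel size derived from the Petri-dish diameter.
#'
#' Defaults describe the down-scaled test scene (512 x 384 px, 3 wells,
#' 60 cycles at 20-min intervals); `scale = "full"` switches to the
#' instrument's native 2312 x 1736 px geometry with 9 wells.
#'
#' @param frame_width,frame_height Frame size in pixels.
#' @param wells Number of wells (each gets its own stack per channel).
#' @param channels Ordered unique channel labels. Recognized roles:
#'   `"trans"` (transillumination), `"epi"` (epi-white), `"green"`, `"red"`.
#' @param n_cycles Number of imaging cycles.
#' @param cycle_interval Seconds between cycles (default 1200 s = 20 min).
#' @param pixel_size mm per pixel; default places the dish across 90% of the
#'   frame height.
#' @param dish_diameter Petri-dish diameter in mm (default 36.7 mm).
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @param scale `"test"` or `"full"`; presets overridden by explicit args.
#'
#' @return A `scene_config` list.
#' @export
scene_config <- function(frame_width = NULL, frame_height = NULL, wells = NULL,
                         channels = c("trans", "epi", "green", "red"),
                         n_cycles = NULL, cycle_interval = 1200,
                         pixel_size = NULL, dish_diameter = 36.7, seed = 1L,
                         scale = c("test", "full")) {
  scale <- match.arg(scale)
  preset <- if (scale == "full") {
    list(frame_width = 2312L, frame_height = 1736L, wells = 9L, n_cycles = 360L)
  } else {
    list(frame_width = 512L, frame_height = 384L, wells = 3L, n_cycles = 60L)
  }
  frame_width <- as.integer(frame_width %||% preset$frame_width)
  frame_height <- as.integer(frame_height %||% preset$frame_height)
  wells <- as.integer(wells %||% preset$wells)
  n_cycles <- as.integer(n_cycles %||% preset$n_cycles)
  if (frame_width < 1L || frame_height < 1L || wells < 1L || n_cycles < 1L)
    stop("frame size, wells and n_cycles must all be >= 1", call. = FALSE)
  if (cycle_interval <= 0) stop("cycle_interval must be > 0", call. = FALSE)
  channels <- as.character(channels)
  if (anyDuplicated(channels)) stop("channel labels must be unique", call. = FALSE)
  if (is.null(pixel_size)) pixel_size <- dish_diameter / (0.9 * frame_height)
  structure(
    list(frame_width = frame_width, frame_height = frame_height, wells = wells,
         channels = channels, n_cycles = n_cycles,
         cycle_interval = cycle_interval, pixel_size = pixel_size,
         dish_diameter = dish_diameter, seed = as.integer(seed)),
    class = "scene_config"
  )
}

#' Radial growth model for the synthetic biofilm disc
#'
#' The disc radius follows a lagged saturating curve,
#' `r(t) = r0 + (r_max - r0) * (1 - exp(-growth_rate * max(0, t - lag)))`,
#' which is non-decreasing by construction. The disc attenuates the
#' transillumination background by `inner_density` grey levels and its edge
#' is rendered as a smooth error-function transition over `edge_softness`
#' pixels (real biofilm edges are not binary, and a soft edge keeps Otsu
#' thresholds stable).
#'
#' @param r0 Initial radius, px (0 = empty dish at t0).
#' @param r_max Plateau radius, px.
#' @param growth_rate Rate constant, 1/cycle.
#' @param lag_cycles Cycles before growth starts.
#' @param inner_density Transillumination attenuation amplitude, grey levels.
#' @param edge_softness Edge transition scale, px (0 = hard edge).
#'
#' @return A `growth_model` list.
#' @export
growth_model <- function(r0 = 0, r_max = 120, growth_rate = 0.08,
                         lag_cycles = 6, inner_density = 120,
                         edge_softness = 2) {
  if (r0 < 0 || r_max < r0) stop("need 0 <= r0 <= r_max", call. = FALSE)
  if (inner_density < 0 || inner_density > 255)
    stop("inner_density must lie in [0, 255]", call. = FALSE)
  structure(
    list(r0 = r0, r_max = r_max, growth_rate = growth_rate,
         lag_cycles = lag_cycles, inner_density = inner_density,
         edge_softness = edge_softness),
    class = "growth_model"
  )
}

#' Disc radius at given cycles
#'
#' @param growth A [growth_model()].
#' @param cycles Integer vector of cycle indices (0-based).
#' @return Numeric radii in pixels, non-decreasing in `cycles`.
#' @export
radius_at <- function(growth, cycles) {
  growth$r0 + (growth$r_max - growth$r0) *
    (1 - exp(-growth$growth_rate * pmax(0, cycles - growth$lag_cycles)))
}

#' Two-reporter expression model for the synthetic scene
#'
#' Green fluorescence rises with a saturating time course and, from
#' `green_decline_onset` onward, decays in the central region of the disc
#' while the expanding rim keeps expressing — so the integrated green signal
#' peaks and then falls. Red fluorescence rises monotonically and uniformly
#' across the disc. The rendered red channel additionally receives
#' `crosstalk_green_to_red` times the green field (spectral bleed-through),
#' and all channels get additive Gaussian sensor noise, a radial vignette
#' and a per-cycle rigid positional jitter shared by all channels of a well.
#'
#' @param green_amplitude,red_amplitude Peak reporter amplitudes, grey levels.
#' @param green_decline_onset Cycle index at which the central green decline
#'   starts.
#' @param crosstalk_green_to_red Fraction in `[0, 1]` of the green field
#'   added to the red channel.
#' @param noise_sd Additive Gaussian noise SD, grey levels.
#' @param vignette_strength Fractional intensity falloff at the frame corner.
#' @param jitter_sd SD of the per-cycle integer translation, px.
#' @param green_rise_cycles,red_rise_cycles Rise time constants, cycles.
#' @param green_decline_rate Central decay rate constant, 1/cycle.
#' @param decline_radius_frac Fraction of the disc radius forming the
#'   declining central region.
#' @param decline_depth Maximum fractional loss of central green signal.
#' @param fluor_background Uniform fluorescence background, grey levels.
#'
#' @return A `reporter_model` list.
#' @export
reporter_model <- function(green_amplitude = 60, red_amplitude = 40,
                           green_decline_onset = 35,
                           crosstalk_green_to_red = 0.05, noise_sd = 2,
                           vignette_strength = 0.05, jitter_sd = 1,
                           green_rise_cycles = 12, red_rise_cycles = 25,
                           green_decline_rate = 0.15,
                           decline_radius_frac = 0.6, decline_depth = 0.85,
                           fluor_background = 6) {
  if (green_amplitude < 0 || green_amplitude > 255 ||
      red_amplitude < 0 || red_amplitude > 255)
    stop("reporter amplitudes must lie in [0, 255]", call. = FALSE)
  if (crosstalk_green_to_red < 0 || crosstalk_green_to_red > 1)
    stop("crosstalk fraction must lie in [0, 1]", call. = FALSE)
  structure(
    list(green_amplitude = green_amplitude, red_amplitude = red_amplitude,
         green_decline_onset = green_decline_onset,
         crosstalk_green_to_red = crosstalk_green_to_red, noise_sd = noise_sd,
         vignette_strength = vignette_strength, jitter_sd = jitter_sd,
         green_rise_cycles = green_rise_cycles,
         red_rise_cycles = red_rise_cycles,
         green_decline_rate = green_decline_rate,
         decline_radius_frac = decline_radius_frac,
         decline_depth = decline_depth, fluor_background = fluor_background),
    class = "reporter_model"
  )
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# distance-from-point matrix for an h x w frame (1-based pixel centres)
dist_matrix <- function(h, w, center) {
  dr <- (seq_len(h) - center[1])^2
  dc <- (seq_len(w) - center[2])^2
  sqrt(outer(dr, dc, `+`))
}

# smooth disc indicator: 1 inside radius r, erf-style transition over `soft` px
soft_disc <- function(d, r, soft) {
  if (r <= 0) return(array(0, dim(d)))
  if (soft <= 0) return((d <= r) * 1)
  stats::pnorm((r - d) / soft)
}

#' Render synthetic multi-channel time-lapse stacks
#'
#' Renders one [lapse_stack()] per well x channel together with the ground
#' truth used to generate it (per-cycle disc radius, jitter offsets and
#' reporter levels), for parameter-recovery testing of the downstream
#' pipeline. Transillumination frames show a dark disc of radius `r(t)` on a
#' bright background with a dark dish rim; epi frames show a bright colony;
#' fluorescence frames show the reporter fields restricted to the disc, with
#' green-to-red crosstalk added to the red channel. All frames are rounded
#' and clipped to the 8-bit range.
#'
#' @param scene A [scene_config()].
#' @param growth A [growth_model()].
#' @param reporters A [reporter_model()].
#' @param jitter_offsets Optional `n_cycles` x 2 matrix of (row, col)
#'   translations in px applied to every well, overriding random jitter —
#'   used to inject known drift.
#'
#' @return A `lapse_scene` list with elements `stacks` (named
#'   `well<w>.<channel>`), `ground_truth` (tibble), and the three configs.
#' @export
generate_stack <- function(scene, growth, reporters,
                           jitter_offsets = NULL) {
  stopifnot(inherits(scene, "scene_config"), inherits(growth, "growth_model"),
            inherits(reporters, "reporter_model"))
  h <- scene$frame_height; w <- scene$frame_width
  cycles <- seq_len(scene$n_cycles) - 1L
  radii <- radius_at(growth, cycles)
  half_extent <- min(h, w) / 2
  if (any(radii > half_extent)) {
    bad <- cycles[which(radii > half_extent)[1]]
    stop(sprintf("disc radius %.1f px exceeds the frame half-extent at cycle %d",
                 radii[which(cycles == bad)], bad), call. = FALSE)
  }
  if (!is.null(jitter_offsets)) {
    jitter_offsets <- as.matrix(jitter_offsets)
    stopifnot(nrow(jitter_offsets) == scene$n_cycles,
              ncol(jitter_offsets) == 2)
  }

  dish_r <- scene$dish_diameter / 2 / scene$pixel_size
  centre0 <- c((h + 1) / 2, (w + 1) / 2)
  vign <- if (reporters$vignette_strength > 0) {
    dmax <- sqrt(sum((c(h, w) / 2)^2))
    1 - reporters$vignette_strength * (dist_matrix(h, w, centre0) / dmax)^2
  } else 1

  # per-cycle reporter levels (ground truth)
  g_level <- reporters$green_amplitude *
    (1 - exp(-pmax(0, cycles - growth$lag_cycles) / reporters$green_rise_cycles))
  r_level <- reporters$red_amplitude *
    (1 - exp(-pmax(0, cycles - growth$lag_cycles) / reporters$red_rise_cycles))
  decline_amt <- reporters$decline_depth *
    (1 - exp(-reporters$green_decline_rate *
               pmax(0, cycles - reporters$green_decline_onset)))

  with_seed(scene$seed, {
    stacks <- list()
    gt <- vector("list", scene$wells)
    for (well in seq_len(scene$wells)) {
      jit <- if (!is.null(jitter_offsets)) jitter_offsets
             else if (reporters$jitter_sd > 0)
               matrix(round(stats::rnorm(2 * scene$n_cycles,
                                         sd = reporters$jitter_sd)),
                      ncol = 2)
             else matrix(0, scene$n_cycles, 2)
      frames <- stats::setNames(
        rep(list(vector("list", scene$n_cycles)), length(scene$channels)),
        scene$channels)
      for (t in seq_len(scene$n_cycles)) {
        centre <- centre0 + jit[t, ]
        d <- dist_matrix(h, w, centre)
        S <- soft_disc(d, radii[t], growth$edge_softness)
        C <- soft_disc(d, reporters$decline_radius_frac * radii[t],
                       growth$edge_softness)
        # beyond the dish edge the bright field drops to the dark tray,
        # giving the sharp brightness step used for drift detection
        dish_f <- 1 - 0.75 * (d > dish_r)
        g_field <- g_level[t] * S * (1 - decline_amt[t] * C)
        r_field <- r_level[t] * S
        for (ch in scene$channels) {
          base <- switch(ch,
            trans = (200 - growth$inner_density * S) * dish_f * vign,
            epi   = (90 + 80 * S) * dish_f * vign,
            green = (reporters$fluor_background + g_field) * vign,
            red   = (reporters$fluor_background + r_field +
                       reporters$crosstalk_green_to_red * g_field) * vign,
            # unknown channel label: flat mid-grey field
            (128 + 0 * d) * vign)
          if (reporters$noise_sd > 0)
            base <- base + stats::rnorm(length(base), sd = reporters$noise_sd)
          frames[[ch]][[t]] <- matrix(clip8(round(base)), h, w)
        }
      }
      for (ch in scene$channels) {
        stacks[[sprintf("well%d.%s", well, ch)]] <-
          lapse_stack(frames[[ch]], well = well, channel = ch,
                      cycles = cycles, times = cycles * scene$cycle_interval)
      }
      gt[[well]] <- tibble::tibble(
        well = well, cycle = cycles, radius_px = radii,
        disc_px = pi * radii^2,
        jitter_row = jit[, 1], jitter_col = jit[, 2],
        green_level = g_level, red_level = r_level,
        green_central_decline = decline_amt, red_level_effective = r_level)
    }
    structure(
      list(stacks = stacks, ground_truth = dplyr::bind_rows(gt),
           scene = scene, growth = growth, reporters = reporters),
      class = "lapse_scene")
  })
}

#' @export
print.lapse_scene <- function(x, ...) {
  cat(sprintf("<lapse_scene> %d wells x %d channels x %d cycles (%d x %d px)\n",
              x$scene$wells, length(x$scene$channels), x$scene$n_cycles,
              x$scene$frame_height, x$scene$frame_width))
  invisible(x)
}

#' Pull one stack out of a generated scene
#'
#' @param scene_out A `lapse_scene` from [generate_stack()].
#' @param well Well number.
#' @param channel Channel label.
#' @return The requested [lapse_stack()].
#' @export
scene_stack <- function(scene_out, well, channel) {
  key <- sprintf("well%d.%s", well, channel)
  out <- scene_out$stacks[[key]]
  if (is.null(out))
    stop(sprintf("no stack '%s' in this scene", key), call. = FALSE)
  out
}

#' Render a USAF-1951 style three-bar resolution target
#'
#' Each requested element is drawn as three dark vertical bars on a bright
#' background at spatial frequency `2^(group + (element - 1)/6)` line pairs
#' per mm, in its own horizontal band. An optional Gaussian blur emulates
#' optical defocus.
#'
#' @param groups Integer vector of USAF groups to render (all 6 elements each).
#' @param pixel_size mm per pixel.
#' @param blur_sd Gaussian blur SD in px (0 = none).
#' @param bar_intensity,background Grey levels of bars and field.
#'
#' @return A list with `frame` (matrix) and `elements` (tibble: group,
#'   element, freq_lp_mm, period_px, band and bar extents in 1-based
#'   inclusive pixel coordinates).
#' @export
generate_usaf_target <- function(groups = 0:2, pixel_size = 0.05, blur_sd = 0,
                                 bar_intensity = 0, background = 200) {
  els <- tidyr::expand_grid(group = sort(groups), element = 1:6) |>
    dplyr::mutate(freq_lp_mm = usaf_frequency(.data$group, .data$element),
                  period_px = 1 / (.data$freq_lp_mm * pixel_size),
                  bar_px = .data$period_px / 2)
  if (any(els$bar_px < 2))
    stop("finest requested element is not resolvable at >= 2 px per line; ",
         "reduce the group range or the pixel size", call. = FALSE)
  margin <- 8
  els <- els |>
    dplyr::mutate(band_h = pmax(8L, ceiling(5 * .data$bar_px)),
                  band_w = ceiling(2 * .data$period_px + .data$bar_px))
  heights <- els$band_h + margin
  row0 <- margin + cumsum(c(0, utils::head(heights, -1)))
  els$row0 <- row0 + 1L
  els$row1 <- row0 + els$band_h
  els$col0 <- margin + 1L
  els$col1 <- margin + els$band_w
  h <- sum(heights) + 2 * margin
  w <- max(els$col1) + margin
  frame <- matrix(background, h, w)
  cols <- seq_len(w) - 0.5   # pixel-centre x coordinates
  for (i in seq_len(nrow(els))) {
    phase <- (cols - (els$col0[i] - 1)) %% els$period_px[i]
    bar_col <- phase >= 0 & phase < els$bar_px[i] &
      cols >= (els$col0[i] - 1) & cols < (els$col0[i] - 1 + els$band_w[i])
    frame[els$row0[i]:els$row1[i], bar_col] <- bar_intensity
  }
  if (blur_sd > 0)
    frame <- EBImage::imageData(EBImage::gblur(frame, sigma = blur_sd))
  list(frame = matrix(clip8(round(frame)), h, w),
       elements = dplyr::select(els, "group", "element", "freq_lp_mm",
                                "period_px", "bar_px", "row0", "row1",
                                "col0", "col1", "band_w"))
}

#' Render a fluorescent alignment-disk calibration frame
#'
#' A uniform annulus between a central hole and the disk edge, optionally
#' modulated by a linear radial vignette, with bright rims at the hole and
#' edge boundaries (alignment disks fluoresce strongly at machined edges,
#' producing the characteristic profile peaks).
#'
#' @param frame_width,frame_height Frame size, px.
#' @param disk_radius,hole_radius Disk and central-hole radii, px.
#' @param intensity Annulus grey level before vignetting.
#' @param vignette_strength Fractional falloff at the disk edge (linear in
#'   radius; 0 = flat field).
#' @param edge_peak Rim brightness as a multiple of `intensity`.
#' @param background Grey level outside the disk and inside the hole.
#'
#' @return A list with `frame`, `center` (row, col), `hole_radius`,
#'   `disk_radius`.
#' @export
generate_alignment_disk <- function(frame_width = 512, frame_height = 384,
                                    disk_radius = 150, hole_radius = 15,
                                    intensity = 180, vignette_strength = 0,
                                    edge_peak = 1.25, background = 5) {
  stopifnot(hole_radius < disk_radius)
  h <- frame_height; w <- frame_width
  centre <- c((h + 1) / 2, (w + 1) / 2)
  d <- dist_matrix(h, w, centre)
  vign <- 1 - vignette_strength * d / disk_radius
  frame <- matrix(background, h, w)
  annulus <- d > hole_radius & d <= disk_radius
  frame[annulus] <- (intensity * vign)[annulus]
  rim <- abs(d - hole_radius) <= 1 | abs(d - disk_radius) <= 1
  frame[rim] <- clip8(edge_peak * intensity)
  list(frame = matrix(clip8(round(frame)), h, w), center = centre,
       hole_radius = hole_radius, disk_radius = disk_radius)
}

#' Generate a synthetic acquisition timestamp log
#'
#' Emulates the per-frame capture times of a cycle-based imager: within a
#' cycle the wells and channels are staggered in acquisition order, cycles
#' are `interval` seconds apart, and the log can carry per-cycle Gaussian
#' timing jitter plus a cumulative drift (each cycle runs
#' `cumulative_drift_per_cycle` seconds long, so the offset from the ideal
#' schedule grows linearly).
#'
#' @param n_cycles Number of cycles (0 gives an empty log).
#' @param interval Nominal cycle interval, s.
#' @param per_cycle_jitter_sd SD of independent per-stamp jitter, s.
#' @param cumulative_drift_per_cycle Extra seconds accrued per cycle.
#' @param wells,channels Wells and channel labels imaged each cycle.
#' @param seed Optional RNG seed for the jitter.
#' @param t0 Epoch seconds of the first stamp.
#'
#' @return Tibble with columns cycle, well, channel, epoch_s, iso_time.
#' @export
generate_timestamps <- function(n_cycles, interval = 1200,
                                per_cycle_jitter_sd = 0,
                                cumulative_drift_per_cycle = 0,
                                wells = 1, channels = "trans", seed = NULL,
                                t0 = 0) {
  chs <- as.character(channels)
  if (n_cycles == 0) {
    return(tibble::tibble(cycle = integer(), well = integer(),
                          channel = character(), epoch_s = numeric(),
                          iso_time = character()))
  }
  grid <- tidyr::expand_grid(cycle = seq_len(n_cycles) - 1L,
                             well = seq_len(wells), channel = chs)
  slot <- (match(grid$well, seq_len(wells)) - 1L) * length(chs) +
    (match(grid$channel, chs) - 1L)
  stagger <- slot * 0.6 * interval / (wells * length(chs))
  with_seed(seed, {
    jitter <- if (per_cycle_jitter_sd > 0)
      stats::rnorm(nrow(grid), sd = per_cycle_jitter_sd) else 0
    grid |>
      dplyr::mutate(
        epoch_s = t0 + .data$cycle * (interval + cumulative_drift_per_cycle) +
          stagger + jitter,
        iso_time = format(as.POSIXct(.data$epoch_s, origin = "1970-01-01",
                                     tz = "UTC"), "%Y-%m-%dT%H:%M:%OS2Z"))
  })
}

#' Generate a synthetic fluorescein-style calibration series
#'
#' Intensities follow `blank_mean + slope * concentration` with Gaussian
#' measurement noise of SD `blank_sd`, emulating a serial-dilution
#' sensitivity experiment with blank replicates.
#'
#' @param concentrations Concentrations in mol/L; include 0 for blanks
#'   (added automatically if absent).
#' @param slope Response slope, intensity per mol/L.
#' @param blank_mean,blank_sd Blank intensity mean and SD.
#' @param replicates Replicates per concentration.
#' @param seed Optional RNG seed.
#'
#' @return Tibble with columns concentration, replicate, intensity.
#' @export
generate_calibration_series <- function(concentrations = c(0, 10^seq(-9, -3)),
                                        slope = 8.3e8, blank_mean = 10,
                                        blank_sd = 2, replicates = 3,
                                        seed = NULL) {
  if (!any(concentrations == 0)) concentrations <- c(0, concentrations)
  grid <- tidyr::expand_grid(concentration = sort(concentrations),
                             replicate = seq_len(replicates))
  with_seed(seed, {
    noise <- if (blank_sd > 0) stats::rnorm(nrow(grid), sd = blank_sd) else 0
    dplyr::mutate(grid,
                  intensity = blank_mean + slope * .data$concentration + noise)
  })
}
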