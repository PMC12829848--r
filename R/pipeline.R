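#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: where frames come from (a
#' directory, or the synthetic generator when `input` is `NULL`), which
#' channel plays which role, the analysis-line definition, and the numeric
#' constants of the measurement chain (detection area, onset run length,
#' S/N multiplier, LOD factor, contrast cutoff).
#'
#' @param input Frame directory, or `NULL` to simulate a scene.
#' @param out Output directory.
#' @param scale `"test"` (512 x 384, 3 wells) or `"full"` (2312 x 1736,
#'   9 wells) for simulated scenes.
#' @param wells Wells to process (`NULL` = all in the scene/directory).
#' @param channels Channel labels; roles are taken from the names
#'   `trans`, `epi`, `green`, `red`.
#' @param seed Integer seed for the simulation.
#' @param min_area Detection threshold on ROI area, px.
#' @param onset_k Consecutive strict increases defining growth onset.
#' @param snr_k S/N threshold multiplier.
#' @param lod_factor LOD multiple of the blank SD.
#' @param contrast_cutoff Michelson-contrast resolution cutoff.
#' @param pixel_size mm per pixel (`NULL` = scene default).
#' @param line Analysis line as `list(p0 = c(row, col), p1 = c(row, col))`
#'   (`NULL` = horizontal through the frame centre).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, out = "lapse-out",
                            scale = c("test", "full"), wells = NULL,
                            channels = c("trans", "epi", "green", "red"),
                            seed = 1L, min_area = 20, onset_k = 3,
                            snr_k = 3, lod_factor = 5,
                            contrast_cutoff = 0.10, pixel_size = NULL,
                            line = NULL) {
  scale <- match.arg(scale)
  knobs <- c(min_area = min_area, onset_k = onset_k, snr_k = snr_k,
             lod_factor = lod_factor, contrast_cutoff = contrast_cutoff)
  if (any(knobs <= 0)) stop("all numeric knobs must be positive", call. = FALSE)
  structure(
    list(input = input, out = out, scale = scale, wells = wells,
         channels = channels, seed = as.integer(seed), min_area = min_area,
         onset_k = onset_k, snr_k = snr_k, lod_factor = lod_factor,
         contrast_cutoff = contrast_cutoff, pixel_size = pixel_size,
         line = line),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] args.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

# hash of the analysis-relevant configuration (output location excluded,
# so reruns into different directories compare equal)
config_hash <- function(config) {
  x <- unclass(config)
  rlang::hash(x[setdiff(names(x), "out")])
}

write_csv_commented <- function(df, path, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comments), con)
  writeLines(readr::format_csv(df), con, sep = "")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the multi-channel stacks, quantifies every well
#' into a biofilm series, builds kymographs, computes the QC metrics, and
#' writes `series.csv`, `summary.csv`, per-well kymograph CSV matrices and
#' PNG heatmaps, `qc_report.json` and a run log to the output directory.
#' Every CSV carries a commented header with the units and the
#' configuration hash, and a rerun with the same inputs and seed is
#' byte-identical. Stages whose input channels are missing are skipped and
#' listed in the log (fluorescence quantification requires the
#' transillumination ROI source).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `series`, `summary`, `kymographs`, `qc`,
#'   `skipped` and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  skipped <- character()

  if (is.null(config$input)) {
    scene <- scene_config(scale = config$scale, seed = config$seed,
                          channels = config$channels,
                          pixel_size = config$pixel_size)
    sim <- generate_stack(scene, growth_model(), reporter_model())
    wells <- config$wells %||% seq_len(scene$wells)
    get_stack <- function(w, ch) {
      s <- sim$stacks[[sprintf("well%d.%s", w, ch)]]
      if (is.null(s)) NULL else s
    }
    pixel_size <- scene$pixel_size
  } else {
    wells <- config$wells %||%
      stop("`wells` must be given when loading from a directory",
           call. = FALSE)
    get_stack <- function(w, ch) {
      tryCatch(suppressWarnings(load_stack(config$input, w, ch)),
               error = function(e) NULL)
    }
    pixel_size <- config$pixel_size
  }

  fluor_chs <- intersect(c("green", "red"), config$channels)
  series <- list(); kymos <- list(); qc_drift <- list(); qc_noise <- list()
  timing <- NULL
  for (w in wells) {
    trans <- get_stack(w, "trans")
    bf <- trans %||% get_stack(w, "epi")
    if (is.null(trans)) {
      skipped <- c(skipped, sprintf(
        "well %d: fluorescence quantification skipped (ROI source 'trans' absent)", w))
    } else {
      fls <- purrr::compact(stats::setNames(
        purrr::map(fluor_chs, ~ get_stack(w, .x)), fluor_chs))
      s <- quantify_stacks(trans, fls, min_area = config$min_area,
                           k = config$onset_k)
      series[[length(series) + 1L]] <- dplyr::mutate(
        s, well = w, onset_cycle = attr(s, "onset_cycle"), .before = 1)
    }
    if (!is.null(bf)) {
      d <- frame_dim(bf)
      line <- config$line %||%
        list(p0 = c((d[1] + 1) / 2, 1), p1 = c((d[1] + 1) / 2, d[2]))
      km <- build_kymograph(bf, line$p0, line$p1,
                            mode = "inverted_transillumination")
      kymos[[sprintf("well%d", w)]] <- km
      qc_drift[[length(qc_drift) + 1L]] <- dplyr::mutate(
        positional_deviation(km, pixel_size), well = w, .before = 1)
      if (is.null(timing) && !is.null(bf$times))
        timing <- timing_deviations(bf$times)
    } else {
      skipped <- c(skipped, sprintf(
        "well %d: kymograph/drift skipped (no bright-field channel)", w))
    }
    for (ch in fluor_chs) {
      fs <- get_stack(w, ch)
      if (is.null(fs) || is.null(trans)) next
      sub <- subtract_reference(fs)
      last_roi <- segment_stack(trans, min_area = config$min_area)$rois[[
        n_frames(trans)]]
      qc_noise[[length(qc_noise) + 1L]] <- tibble::tibble(
        well = w, channel = ch,
        noise = noise_level(sub$frames[[n_frames(fs)]], last_roi$mask))
    }
  }

  series <- dplyr::bind_rows(series)
  summary <- if (nrow(series) > 0) {
    series |>
      dplyr::summarise(
        onset_cycle = .data$onset_cycle[1],
        endpoint_area_px = dplyr::last(.data$area_px),
        endpoint_biomass = dplyr::last(.data$biomass),
        dplyr::across(dplyr::starts_with("norm_"),
                      ~ auc(.x, .data$time_s), .names = "auc_{.col}"),
        .by = "well")
  } else tibble::tibble()

  qc <- list(
    config_hash = hash,
    timing = if (!is.null(timing)) list(
      mean_deviation_s = mean(timing$deviation_s),
      sd_deviation_s = pop_sd(timing$deviation_s),
      max_abs_deviation_s = max(abs(timing$deviation_s))) else NULL,
    drift = if (length(qc_drift) > 0) {
      dplyr::bind_rows(qc_drift) |>
        dplyr::summarise(max_abs_deviation_px = max(abs(.data$deviation_px)),
                         max_abs_deviation_mm = max(abs(.data$deviation_mm)),
                         .by = "well")
    } else NULL,
    noise = if (length(qc_noise) > 0) dplyr::bind_rows(qc_noise) else NULL,
    skipped = skipped)

  paths <- list(series = file.path(config$out, "series.csv"),
                summary = file.path(config$out, "summary.csv"),
                qc = file.path(config$out, "qc_report.json"),
                log = file.path(config$out, "run_log.txt"))
  hdr <- sprintf("config=%s units: time_s=s area_px=px biomass,fluor=intensity.px norm=dimensionless", hash)
  if (nrow(series) > 0) write_csv_commented(series, paths$series, hdr)
  if (nrow(summary) > 0) write_csv_commented(summary, paths$summary, hdr)
  for (nm in names(kymos)) {
    write_kymograph_csv(kymos[[nm]],
                        file.path(config$out, sprintf("kymo_%s.csv", nm)))
    png::writePNG(normalize_kymograph(kymos[[nm]]),
                  file.path(config$out, sprintf("kymo_%s.png", nm)))
  }
  jsonlite::write_json(qc, paths$qc, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  writeLines(c(sprintf("biofilmlapse %s",
                       as.character(utils::packageVersion("biofilmlapse"))),
               sprintf("config hash: %s", hash),
               sprintf("seed: %d", config$seed),
               sprintf("wells: %s", paste(wells, collapse = ",")),
               if (length(skipped)) paste("skipped:", skipped) else
                 "skipped: none"),
             paths$log)
  invisible(list(series = series, summary = summary, kymographs = kymos,
                 qc = qc, skipped = skipped, paths = paths))
}
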