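#' Plot a kymograph as a heatmap
#'
#' Positions run along x, cycles along y (top = t0, as in the usual
#' temporal-heatmap layout); fill is the display-normalized intensity.
#'
#' @param object A `lapse_kymograph`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lapse_kymograph <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(norm = as.vector(t(normalize_kymograph(object))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$cycle,
                                   fill = .data$norm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "normalized\nintensity") +
    ggplot2::labs(x = "position along line (px)", y = "cycle",
                  title = sprintf("Kymograph (%s)", object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot biofilm series measurements over time
#'
#' Long-formats the per-cycle measurements of one or more wells and facets
#' by measurement (area, biomass proxy, integrated and normalized
#' fluorescence).
#'
#' @param series Series tibble from [quantify_stacks()] or [run_pipeline()].
#' @param measures Column names to show (default: all measurement columns).
#' @return A ggplot.
#' @export
plot_biofilm_series <- function(series, measures = NULL) {
  if (!"well" %in% names(series)) series$well <- 1L
  measures <- measures %||%
    intersect(c("area_px", "biomass",
                grep("^(fluor|norm)_", names(series), value = TRUE)),
              names(series))
  x <- if (all(is.na(series$time_s))) "cycle" else "time_s"
  df <- tidyr::pivot_longer(series, dplyr::all_of(measures),
                            names_to = "measure")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data$value,
                                   colour = factor(.data$well))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = if (x == "time_s") "time (s)" else "cycle",
                  colour = "well") +
    ggplot2::theme_minimal()
}

#' Plot a fold-change matrix as a heatmap
#'
#' @param fc Matrix from [fold_change_matrix()].
#' @return A ggplot.
#' @export
plot_fold_change <- function(fc) {
  df <- attr(fc, "tidy")
  if (is.null(df)) {
    df <- tidyr::expand_grid(strain = rownames(fc),
                             bin = as.numeric(colnames(fc))) |>
      dplyr::mutate(fold_change = as.vector(t(fc)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin / 60, y = .data$strain,
                                   fill = .data$fold_change)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 1, name = "fold change") +
    ggplot2::labs(x = "onset-aligned time (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot positional deviation of the dish edge per cycle
#'
#' @param deviation Tibble from [positional_deviation()] (optionally with a
#'   `well` column).
#' @return A ggplot.
#' @export
plot_positional_deviation <- function(deviation) {
  if (!"well" %in% names(deviation)) deviation$well <- 1L
  ggplot2::ggplot(deviation,
                  ggplot2::aes(x = .data$cycle, y = .data$deviation_px,
                               colour = factor(.data$well))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "cycle", y = "edge deviation (px)", colour = "well") +
    ggplot2::theme_minimal()
}

#' One-line summaries of result objects
#'
#' @param x A `lapse_kymograph` or `lapse_scene`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.lapse_kymograph <- function(x, ...) {
  tibble::tibble(cycles = nrow(x$values), positions = ncol(x$values),
                 mode = x$mode, baseline_subtracted = x$baseline_subtracted)
}

#' @rdname glance.lapse_kymograph
#' @export
glance.lapse_scene <- function(x, ...) {
  tibble::tibble(wells = x$scene$wells, channels = length(x$scene$channels),
                 cycles = x$scene$n_cycles,
                 frame_height = x$scene$frame_height,
                 frame_width = x$scene$frame_width, seed = x$scene$seed)
}

#' @rdname glance.lapse_kymograph
#' @export
tidy.lapse_scene <- function(x, ...) x$ground_truth
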