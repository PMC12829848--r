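#' Intensity profile along a line, with bilinear interpolation
#'
#' Samples `n_samples` evenly spaced points from `p0` to `p1` inclusive,
#' interpolating bilinearly between pixel centres (1-based row/col
#' coordinates). By default the sample count is the rounded line length in
#' pixels plus one, i.e. roughly one sample per pixel.
#'
#' @param frame Numeric matrix.
#' @param p0,p1 Numeric `c(row, col)` endpoints.
#' @param n_samples Number of samples (>= 2).
#' @return Numeric vector of interpolated intensities.
#' @export
line_profile <- function(frame, p0, p1, n_samples = NULL) {
  stopifnot(length(p0) == 2, length(p1) == 2)
  if (is.null(n_samples))
    n_samples <- max(2L, round(sqrt(sum((p1 - p0)^2))) + 1L)
  s <- seq(0, 1, length.out = n_samples)
  r <- p0[1] + s * (p1[1] - p0[1])
  c <- p0[2] + s * (p1[2] - p0[2])
  nr <- nrow(frame); nc <- ncol(frame)
  if (any(r < 1 | r > nr | c < 1 | c > nc))
    stop("line endpoints fall outside the frame", call. = FALSE)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  f00 <- frame[cbind(r0, c0)]
  f10 <- frame[cbind(r0 + 1, c0)]
  f01 <- frame[cbind(r0, c0 + 1)]
  f11 <- frame[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * f00 + fr * (1 - fc) * f10 +
    (1 - fr) * fc * f01 + fr * fc * f11
}

#' Build a kymograph (position x time matrix) from a stack
#'
#' Extracts the line profile of every frame and stacks them as rows
#' (row = cycle, column = position along the line). In
#' `inverted_transillumination` mode intensities are inverted (255 - I)
#' before profiling so the colony appears as positive signal; in
#' `raw_fluorescence` mode raw intensities are used. Each row is
#' baseline-corrected by subtracting the t0 profile; the raw (unsubtracted)
#' profiles and the baseline are retained for drift analysis.
#'
#' @param stack A [lapse_stack()].
#' @param p0,p1 Line endpoints, `c(row, col)`.
#' @param mode `"inverted_transillumination"` or `"raw_fluorescence"`.
#' @param n_samples Samples per profile (default: line length in px).
#' @return A `lapse_kymograph`: `values` (baseline-subtracted matrix),
#'   `raw` (unsubtracted), `baseline`, `line`, `mode`, `cycles`,
#'   `baseline_subtracted = TRUE`.
#' @export
build_kymograph <- function(stack, p0, p1,
                            mode = c("inverted_transillumination",
                                     "raw_fluorescence"),
                            n_samples = NULL) {
  mode <- match.arg(mode)
  profs <- purrr::map(stack$frames, function(f) {
    if (mode == "inverted_transillumination") f <- 255 - f
    line_profile(f, p0, p1, n_samples)
  })
  raw <- do.call(rbind, profs)
  rownames(raw) <- stack$cycles
  structure(
    list(values = sweep(raw, 2, raw[1, ]), raw = raw, baseline = raw[1, ],
         line = list(p0 = p0, p1 = p1), mode = mode, cycles = stack$cycles,
         baseline_subtracted = TRUE),
    class = "lapse_kymograph")
}

#' @export
print.lapse_kymograph <- function(x, ...) {
  cat(sprintf("<lapse_kymograph> %d cycles x %d positions (%s)\n",
              nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' @rdname build_kymograph
#' @param x A `lapse_kymograph`.
#' @param ... Unused.
#' @export
tidy.lapse_kymograph <- function(x, ...) {
  tidyr::expand_grid(cycle = x$cycles,
                     position = seq_len(ncol(x$values))) |>
    dplyr::mutate(value = as.vector(t(x$values)),
                  raw = as.vector(t(x$raw)))
}

#' Display-normalize a kymograph matrix to [0, 1]
#'
#' Per-matrix min-max scaling for rendering; quantification always uses the
#' raw values, so this is kept separate from the stored matrices.
#'
#' @param kymo A `lapse_kymograph` or matrix.
#' @return A matrix scaled to `[0, 1]`.
#' @export
normalize_kymograph <- function(kymo) {
  m <- if (inherits(kymo, "lapse_kymograph")) kymo$values else kymo
  rng <- range(m)
  if (diff(rng) == 0) return(m * 0)
  (m - rng[1]) / diff(rng)
}

#' Detect the strongest edge along a profile
#'
#' The edge is the position of the maximum absolute first difference —
#' the steepest brightness step, used to localize the dish edge. Ties
#' resolve to the smallest index, and the returned index is the sample
#' just after the step (rising-index convention).
#'
#' @param profile Numeric vector.
#' @return 1-based index of the edge sample.
#' @export
detect_edge <- function(profile) {
  if (length(profile) < 2 || diff(range(profile)) == 0)
    stop("no edge: profile is constant", call. = FALSE)
  d <- abs(diff(profile))
  which.max(d) + 1L
}

#' Per-cycle positional deviation of the dish edge
#'
#' Detects the dish edge on the raw bright-field profile of every cycle and
#' reports its displacement from the t0 position, in pixels and (when a
#' pixel size is supplied) in mm. This quantifies rigid sample-positioning
#' drift along the analysis line.
#'
#' @param kymo A `lapse_kymograph` built over the dish edge (raw profiles
#'   are taken from its `raw` matrix), or a plain matrix of raw profiles.
#' @param pixel_size mm per pixel (optional).
#' @return Tibble: `cycle`, `edge_px`, `deviation_px`, `deviation_mm`.
#' @export
positional_deviation <- function(kymo, pixel_size = NULL) {
  raw <- if (inherits(kymo, "lapse_kymograph")) kymo$raw else kymo
  cycles <- if (inherits(kymo, "lapse_kymograph")) kymo$cycles
            else seq_len(nrow(raw)) - 1L
  edges <- apply(raw, 1, detect_edge)
  tibble::tibble(
    cycle = cycles,
    edge_px = as.integer(edges),
    deviation_px = as.numeric(edges - edges[1]),
    deviation_mm = if (is.null(pixel_size)) NA_real_
                   else as.numeric(edges - edges[1]) * pixel_size)
}

#' Write / read a kymograph matrix as CSV
#'
#' Value-preserving export: the numeric matrix round-trips exactly through
#' the CSV (full precision, one row per cycle).
#'
#' @param kymo A `lapse_kymograph` or matrix.
#' @param path CSV path.
#' @return `write_kymograph_csv()` the path; `read_kymograph_csv()` a matrix.
#' @export
write_kymograph_csv <- function(kymo, path) {
  m <- if (inherits(kymo, "lapse_kymograph")) kymo$values else kymo
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_kymograph_csv
#' @export
read_kymograph_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ","))
}
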