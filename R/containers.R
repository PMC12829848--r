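#' Time-lapse stack container
#'
#' A `lapse_stack` holds the cycle-ordered frames of one well x channel
#' combination: a list of numeric matrices on the 8-bit scale `[0, 255]`
#' (rows = image rows, top-left origin), the integer cycle indices, and the
#' acquisition times in epoch seconds when a timestamp log was available.
#'
#' @param frames List of numeric matrices with identical dimensions, values
#'   in `[0, 255]`.
#' @param well Well identifier (integer or string).
#' @param channel Channel label, e.g. `"trans"`, `"green"`.
#' @param cycles Integer vector of cycle indices (0-based, as in the
#'   on-disk filename schema), strictly increasing, same length as `frames`.
#' @param times Optional numeric vector of epoch seconds per cycle.
#'
#' @return An object of class `lapse_stack`.
#' @export
lapse_stack <- function(frames, well, channel, cycles = seq_along(frames) - 1L,
                        times = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  dims <- vapply(frames, dim, integer(2))
  if (ncol(dims) > 1L && any(dims[, -1, drop = FALSE] != dims[, 1]))
    stop("all frames in a stack must share the same dimensions", call. = FALSE)
  cycles <- as.integer(cycles)
  if (length(cycles) != length(frames))
    stop("`cycles` must have one entry per frame", call. = FALSE)
  if (is.unsorted(cycles, strictly = TRUE))
    stop("cycle indices must be strictly increasing", call. = FALSE)
  if (!is.null(times) && length(times) != length(frames))
    stop("`times` must have one entry per frame", call. = FALSE)
  structure(
    list(frames = frames, well = well, channel = as.character(channel),
         cycles = cycles, times = times),
    class = "lapse_stack"
  )
}

#' @export
print.lapse_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<lapse_stack> well %s, channel '%s': %d frames of %d x %d px\n",
              x$well, x$channel, length(x$frames), d[1], d[2]))
  cat(sprintf("  cycles %d..%d%s\n", min(x$cycles), max(x$cycles),
              if (is.null(x$times)) "" else ", timestamps attached"))
  invisible(x)
}

#' @export
length.lapse_stack <- function(x) length(x$frames)

n_frames <- function(stack) length(stack$frames)

frame_dim <- function(stack) dim(stack$frames[[1]])

#' Region-of-interest measurement for a single frame
#'
#' Bundles the binary mask with the summary statistics measured on the frame
#' the mask was applied to: pixel area, mean intensity inside the ROI and
#' mean intensity of the complement (the background/noise region).
#'
#' @param mask Logical matrix (`TRUE` = inside the ROI).
#' @param area ROI area in pixels; must equal `sum(mask)`.
#' @param mean_inner,mean_outer Mean intensities inside/outside the ROI
#'   (`NA` when the respective region is empty).
#' @param detected Logical; `FALSE` when the frame yielded no usable ROI.
#'
#' @return An object of class `roi_result`.
#' @export
roi_result <- function(mask, area, mean_inner, mean_outer, detected = area > 0) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (area != sum(mask))
    stop("`area` must equal the number of TRUE mask pixels", call. = FALSE)
  structure(
    list(mask = mask, area = as.numeric(area),
         mean_inner = as.numeric(mean_inner),
         mean_outer = as.numeric(mean_outer),
         detected = isTRUE(detected)),
    class = "roi_result"
  )
}

#' @export
print.roi_result <- function(x, ...) {
  cat(sprintf("<roi_result> area %s px, mean inner %s, mean outer %s%s\n",
              format(x$area), format(round(x$mean_inner, 2)),
              format(round(x$mean_outer, 2)),
              if (x$detected) "" else " (not detected)"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname roi_result
#' @param x A `roi_result`.
#' @param ... Unused.
#' @export
tidy.roi_result <- function(x, ...) {
  tibble::tibble(area_px = x$area, mean_inner = x$mean_inner,
                 mean_outer = x$mean_outer, detected = x$detected)
}

# internal: clip to the 8-bit range
clip8 <- function(x) pmin(pmax(x, 0), 255)

# internal: population standard deviation (divides by n, not n - 1)
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
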