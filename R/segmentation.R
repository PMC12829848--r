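#' Subtract the reference (t0) frame from a stack
#'
#' Corrects for static background and uneven illumination by subtracting the
#' first frame of the stack from every frame, clipping at zero: transformed
#' frames hold only signal gained since t0. For transillumination the stack
#' should be intensity-inverted first (see [invert_intensity()]), since a
#' growing colony only darkens the transmitted light relative to t0.
#'
#' @param stack A [lapse_stack()].
#' @return A `lapse_stack` of difference frames; the first is all zero.
#' @export
subtract_reference <- function(stack) {
  stopifnot(inherits(stack, "lapse_stack"), n_frames(stack) >= 1L)
  ref <- stack$frames[[1]]
  out <- stack
  out$frames <- purrr::map(stack$frames, ~ clip8(.x - ref))
  out
}

#' Invert 8-bit intensities
#'
#' `255 - x`, elementwise: dark (absorbing) structures become bright signal.
#'
#' @param x A frame matrix or a [lapse_stack()].
#' @return Same shape as the input.
#' @export
invert_intensity <- function(x) {
  if (inherits(x, "lapse_stack")) {
    x$frames <- purrr::map(x$frames, ~ 255 - .x)
    return(x)
  }
  255 - x
}

#' Otsu threshold of an 8-bit frame
#'
#' Maximizes the between-class variance over the 256-bin intensity
#' histogram. Ties are resolved to the lowest maximizing threshold, and the
#' mask uses a strictly-greater comparison, so a perfectly bimodal frame
#' splits exactly at the lower mode.
#'
#' @param frame Numeric matrix with values in `[0, 255]`.
#' @return List with `threshold` (integer cut point) and `mask` (logical
#'   matrix, `frame > threshold`).
#' @export
otsu_threshold <- function(frame) {
  v <- floor(as.numeric(frame))
  if (length(unique(v)) < 2L)
    stop("degenerate histogram: frame has fewer than 2 distinct values",
         call. = FALSE)
  counts <- tabulate(v + 1L, nbins = 256L)
  n <- length(v)
  levels <- 0:255
  w0 <- cumsum(counts)                      # class sizes for cut at t
  s0 <- cumsum(counts * levels)             # class intensity sums
  total <- s0[256]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (total - s0) / w1, 0)
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2  # between-class variance
  bcv <- bcv[1:255]                           # cuts at t = 0..254
  thr <- levels[which.max(bcv)]               # which.max -> lowest tie
  list(threshold = thr, mask = frame > thr)
}

#' Extract the biofilm ROI from a binary mask
#'
#' The ROI is the largest 8-connected component of the mask with interior
#' holes filled (one central colony per dish is assumed). `mean_inner` and
#' `mean_outer` are measured on `frame`.
#'
#' @param mask Logical matrix.
#' @param frame Numeric matrix the means are computed on.
#' @return A [roi_result()]; an empty mask yields area 0, `NA` means and
#'   `detected = FALSE`.
#' @export
extract_roi <- function(mask, frame) {
  stopifnot(identical(dim(mask), dim(frame)))
  if (!any(mask)) {
    return(roi_result(mask & FALSE, 0, NA_real_, mean(frame),
                      detected = FALSE))
  }
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  roi <- EBImage::fillHull((lab == keep) * 1) > 0
  roi <- matrix(as.logical(roi), nrow(mask), ncol(mask))
  roi_result(roi, sum(roi), mean(frame[roi]), mean(frame[!roi]))
}

#' Transfer a transillumination ROI onto a fluorescence frame
#'
#' Keeps the mask (and hence the area) fixed and recomputes the inner/outer
#' mean intensities on the fluorescence frame, mirroring the reuse of the
#' transmitted-light ROI for reporter quantification.
#'
#' @param roi A [roi_result()].
#' @param fluor_frame Numeric matrix with the same dimensions as the mask.
#' @return A [roi_result()] measured on `fluor_frame`.
#' @export
transfer_roi <- function(roi, fluor_frame) {
  stopifnot(inherits(roi, "roi_result"),
            identical(dim(roi$mask), dim(fluor_frame)))
  if (!any(roi$mask)) {
    return(roi_result(roi$mask, 0, NA_real_, mean(fluor_frame),
                      detected = FALSE))
  }
  roi_result(roi$mask, roi$area, mean(fluor_frame[roi$mask]),
             mean(fluor_frame[!roi$mask]), detected = roi$detected)
}

#' Segment a transillumination stack into per-cycle ROIs
#'
#' Runs the full per-frame chain — invert, subtract the t0 reference, Otsu
#' binarize, extract the largest hole-filled component — and applies the
#' detection rule: frames whose ROI is smaller than `min_area` px (or whose
#' difference frame is constant, as before any growth) are reported as not
#' detected with area 0.
#'
#' @param stack Transillumination [lapse_stack()].
#' @param min_area Minimum ROI area in px to count as detected.
#' @return List with `rois` (list of [roi_result()]) and `frames` (the
#'   inverted difference frames the ROIs were measured on).
#' @export
segment_stack <- function(stack, min_area = 20) {
  diff_stack <- subtract_reference(invert_intensity(stack))
  rois <- purrr::map(diff_stack$frames, function(f) {
    ot <- tryCatch(otsu_threshold(f), error = function(e) NULL)
    if (is.null(ot))
      return(roi_result(matrix(FALSE, nrow(f), ncol(f)), 0, NA_real_,
                        mean(f), detected = FALSE))
    roi <- extract_roi(ot$mask, f)
    if (roi$area < min_area) {
      roi <- roi_result(matrix(FALSE, nrow(f), ncol(f)), 0, NA_real_,
                        mean(f), detected = FALSE)
    }
    roi
  })
  list(rois = rois, frames = diff_stack$frames, cycles = stack$cycles,
       times = stack$times)
}
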