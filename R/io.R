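#' Read a single image frame
#'
#' Reads PNG or TIFF via the png/tiff packages and other formats (JPEG)
#' via EBImage. Intensities are returned on the 8-bit scale `[0, 255]`;
#' 16-bit inputs are rescaled to 8-bit (divisor 257) with a message.
#'
#' @param path Image file path.
#' @return A numeric matrix (grayscale) or `h x w x ch` array (colour).
#' @export
read_frame <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read image '%s': file not found", path),
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, info = TRUE),
    EBImage::imageData(EBImage::readImage(path))
  )
  bits <- attr(img, "bits.per.sample")
  if (!is.null(bits) && bits > 8)
    message(sprintf("'%s': %d-bit input rescaled to 8-bit (divisor %d)",
                    basename(path), bits, (2^bits - 1) %/% 255))
  attributes(img) <- attributes(img)["dim"]
  if (ext %in% c("png", "tif", "tiff")) {
    # png/tiff return [0,1]; EBImage is transposed (x, y) -> fix below
    img <- img * 255
  } else {
    img <- aperm(if (length(dim(img)) == 2) img else img,
                 if (length(dim(img)) == 2) c(2, 1) else c(2, 1, 3))
    if (max(img) <= 1) img <- img * 255
  }
  if (length(dim(img)) == 2) round(img) else img
}

#' Reduce a colour frame to a single grey channel
#'
#' Mirrors the channel-splitting step of the analysis: red-fluorescence
#' frames keep only the red component (removing green bleed recorded in the
#' other components), green-fluorescence frames the green component, and
#' bright-field frames are converted with the standard Rec.601 luma weights.
#'
#' @param frame Matrix (returned unchanged) or `h x w x 3(+)` array on the
#'   `[0, 255]` scale.
#' @param policy One of `"red_channel"`, `"green_channel"`, `"luma"`.
#' @return A numeric matrix on `[0, 255]`.
#' @export
extract_channel_gray <- function(frame,
                                 policy = c("luma", "red_channel",
                                            "green_channel")) {
  policy <- match.arg(policy)
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) != 3 || dim(frame)[3] < 3)
    stop("expected a matrix or an array with >= 3 colour channels",
         call. = FALSE)
  out <- switch(policy,
    red_channel = frame[, , 1],
    green_channel = frame[, , 2],
    luma = 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3])
  matrix(out, dim(frame)[1], dim(frame)[2])
}

frame_file_name <- function(well, channel, cycle, format = "png") {
  sprintf("well%s_ch-%s_t%04d.%s", well, channel, cycle, format)
}

#' Write a stack (or a whole scene) to a frame directory
#'
#' Frames are written losslessly as `well{W}_ch-{channel}_t{cycle}.png`
#' (or `.tiff`). [write_scene()] additionally writes `timestamps.csv`
#' (cycle, well, channel, iso_time, epoch_s) and `ground_truth.json`.
#'
#' @param stack A [lapse_stack()].
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @return The directory, invisibly.
#' @export
write_stack <- function(stack, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$frames)) {
    path <- file.path(dir, frame_file_name(stack$well, stack$channel,
                                           stack$cycles[i], format))
    m <- stack$frames[[i]] / 255
    if (format == "png") png::writePNG(m, path) else tiff::writeTIFF(m, path)
  }
  invisible(dir)
}

#' @rdname write_stack
#' @param scene_out A `lapse_scene` from [generate_stack()].
#' @export
write_scene <- function(scene_out, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ts <- purrr::map(scene_out$stacks, function(s) {
    write_stack(s, dir, format)
    tibble::tibble(cycle = s$cycles, well = s$well, channel = s$channel,
                   epoch_s = s$times %||% (s$cycles * NA_real_))
  }) |> dplyr::bind_rows() |>
    dplyr::arrange(.data$cycle, .data$well, .data$channel) |>
    dplyr::mutate(iso_time = format(as.POSIXct(.data$epoch_s,
                                               origin = "1970-01-01",
                                               tz = "UTC"),
                                    "%Y-%m-%dT%H:%M:%OS2Z"),
                  .before = "epoch_s")
  readr::write_csv(ts, file.path(dir, "timestamps.csv"))
  jsonlite::write_json(
    list(scene = unclass(scene_out$scene),
         growth = unclass(scene_out$growth),
         reporters = unclass(scene_out$reporters),
         ground_truth = scene_out$ground_truth),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

default_schema <- "^well(\\d+)_ch-(.+?)_t(\\d+)\\.(png|tiff?|jpe?g)$"

#' Load a time-lapse stack from a frame directory
#'
#' Collects the frames of one well x channel combination, sorted by cycle
#' index, and joins acquisition timestamps from a `timestamps.csv` sidecar
#' (columns cycle, well, channel, epoch_s) when present. A gap in an
#' otherwise contiguous cycle range raises a warning listing the missing
#' cycles; duplicated (well, channel, cycle) files or an empty match are
#' errors. Colour frames are reduced to grey per `policy` (default chosen
#' from the channel label: red/green components for the fluorescence
#' channels, luma otherwise).
#'
#' @param directory Directory of frames.
#' @param well,channel Well id and channel label to load.
#' @param schema Regex with capture groups (well, channel, cycle, ext).
#' @param policy Channel-reduction policy for colour frames; `NULL` = by
#'   channel label.
#' @return A [lapse_stack()].
#' @export
load_stack <- function(directory, well, channel, schema = default_schema,
                       policy = NULL) {
  if (!dir.exists(directory))
    stop(sprintf("directory '%s' does not exist", directory), call. = FALSE)
  files <- list.files(directory)
  m <- regmatches(files, regexec(schema, files))
  hit <- lengths(m) >= 4
  info <- tibble::tibble(
    file = files[hit],
    well = purrr::map_chr(m[hit], 2),
    channel = purrr::map_chr(m[hit], 3),
    cycle = as.integer(purrr::map_chr(m[hit], 4))
  ) |>
    dplyr::filter(.data$well == as.character(!!well),
                  .data$channel == !!channel)
  if (nrow(info) == 0)
    stop(sprintf("no frames matched well %s / channel '%s' in '%s'",
                 well, channel, directory), call. = FALSE)
  dup <- info$cycle[duplicated(info$cycle)]
  if (length(dup) > 0)
    stop(sprintf("duplicate frames for well %s / channel '%s' at cycle(s) %s",
                 well, channel, paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  info <- dplyr::arrange(info, .data$cycle)
  gaps <- setdiff(seq(min(info$cycle), max(info$cycle)), info$cycle)
  if (length(gaps) > 0)
    warning(sprintf("missing cycle(s) %s for well %s / channel '%s'",
                    paste(gaps, collapse = ", "), well, channel),
            call. = FALSE)
  if (is.null(policy))
    policy <- switch(channel, red = "red_channel", green = "green_channel",
                     "luma")
  frames <- purrr::map(file.path(directory, info$file), function(p) {
    f <- read_frame(p)
    tryCatch(extract_channel_gray(f, policy),
             error = function(e) stop(sprintf("unreadable image '%s': %s",
                                              p, conditionMessage(e)),
                                      call. = FALSE))
  })
  times <- NULL
  ts_path <- file.path(directory, "timestamps.csv")
  if (file.exists(ts_path)) {
    ts <- readr::read_csv(ts_path, show_col_types = FALSE, comment = "#") |>
      dplyr::filter(as.character(.data$well) == as.character(!!well),
                    .data$channel == !!channel)
    times <- ts$epoch_s[match(info$cycle, ts$cycle)]
    if (all(is.na(times))) times <- NULL
  }
  lapse_stack(frames, well = well, channel = channel, cycles = info$cycle,
              times = times)
}
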