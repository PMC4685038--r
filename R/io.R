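#' Calibrated multi-channel image sequence
#'
#' Lightweight container for a T-frame, C-channel intensity stack with its
#' physical calibration. Frames are stored as a list of `H x W x C` arrays.
#'
#' @param frames List of `H x W x C` numeric arrays (nonnegative, finite).
#' @param pixel_size Pixel size (um/px).
#' @param frame_interval Frame interval (min).
#' @param channel_names Character vector of channel labels (length C).
#' @return An object of class `ImageSequence`.
#' @export
image_sequence <- function(frames, pixel_size, frame_interval, channel_names) {
  stopifnot(length(frames) >= 1, pixel_size > 0, frame_interval > 0)
  d <- dim(frames[[1]])
  if (length(d) != 3 || d[3] != length(channel_names))
    stop("each frame must be an H x W x C array matching channel_names")
  for (f in frames) {
    if (!identical(dim(f), d)) stop("all frames must share dimensions")
    if (any(!is.finite(f)) || any(f < 0))
      stop("intensities must be finite and nonnegative")
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channel_names = channel_names),
            class = "ImageSequence")
}

#' @export
print.ImageSequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("ImageSequence: %d frames, %d x %d px, channels [%s], %g um/px, %g min/frame\n",
              length(x$frames), d[1], d[2],
              paste(x$channel_names, collapse = ", "),
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
length.ImageSequence <- function(x) length(x$frames)

#' Write / read an image sequence as multi-page TIFF
#'
#' One 32-bit float multi-page TIFF per channel
#' (`<prefix>_<channel>.tif`), pages in frame order, plus a JSON sidecar
#' (`<prefix>_meta.json`) holding the calibration. Intensities are stored
#' normalised by the stack maximum (recorded as `intensity_scale` in the
#' sidecar) and restored on reading.
#'
#' @param x An [image_sequence()].
#' @param prefix Output path prefix.
#' @return `write_image_sequence` returns the written file paths
#'   (invisibly); `read_image_sequence` returns the restored
#'   `ImageSequence`.
#' @export
write_image_sequence <- function(x, prefix) {
  stopifnot(inherits(x, "ImageSequence"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  scale <- max(1, vapply(x$frames, max, numeric(1)))
  paths <- character(0)
  for (ci in seq_along(x$channel_names)) {
    pages <- lapply(x$frames, function(f) f[, , ci] / scale)
    p <- sprintf("%s_%s.tif", prefix, x$channel_names[ci])
    tiff::writeTIFF(pages, p, bits.per.sample = 32L)
    paths <- c(paths, p)
  }
  meta <- list(pixel_size = x$pixel_size, frame_interval = x$frame_interval,
               channel_names = x$channel_names, intensity_scale = scale)
  mp <- sprintf("%s_meta.json", prefix)
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' @rdname write_image_sequence
#' @export
read_image_sequence <- function(prefix) {
  meta <- jsonlite::read_json(sprintf("%s_meta.json", prefix),
                              simplifyVector = TRUE)
  per_channel <- lapply(meta$channel_names, function(ch)
    tiff::readTIFF(sprintf("%s_%s.tif", prefix, ch), all = TRUE))
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  n_frames <- length(per_channel[[1]])
  frames <- lapply(seq_len(n_frames), function(f) {
    mats <- lapply(per_channel, function(pc) pc[[f]] * scale)
    array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  })
  image_sequence(frames, meta$pixel_size, meta$frame_interval,
                 meta$channel_names)
}

#' Read a simulation config from YAML or JSON
#'
#' The file holds the fields of [simulation_config()]; `phenotypes` is a
#' list of named field sets passed to [phenotype_spec()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A [simulation_config()].
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$phenotypes)) {
    raw$phenotypes <- lapply(raw$phenotypes, function(p) {
      p$lamellipodia_count_range <- as.integer(unlist(p$lamellipodia_count_range))
      do.call(phenotype_spec, p)
    })
  }
  if (!is.null(raw$wound_center)) raw$wound_center <- as.numeric(unlist(raw$wound_center))
  do.call(simulation_config, raw)
}

#' Write the ground-truth table as CSV
#'
#' @param truth Ground-truth data frame from [run_simulation()].
#' @param path Output CSV path.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
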