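#' Write a multi-channel frame as a multi-page TIFF
#'
#' One 16-bit page per channel, in channel order; channel names are stored
#' in a sidecar `<path>.channels.txt` so round-tripping preserves them.
#'
#' @param frame a `myo_frame` or named list of matrices in `[0, 65535]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame_tiff <- function(frame, path) {
  channels <- if (inherits(frame, "myo_frame")) frame$channels else frame
  pages <- lapply(channels, function(ch) pmin(pmax(ch / 65535, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  writeLines(names(channels), paste0(path, ".channels.txt"))
  invisible(path)
}

#' Read a multi-page TIFF written by [write_frame_tiff()]
#'
#' @param path TIFF file path.
#' @param channel_names optional channel names; defaults to the sidecar
#'   file when present, else `channel_1`, `channel_2`, ...
#' @param metadata optional one-row tibble of frame metadata.
#' @return A `myo_frame` with intensities back on the `[0, 65535]` scale.
#' @export
read_frame_tiff <- function(path, channel_names = NULL, metadata = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".channels.txt")
  channel_names <- channel_names %||%
    (if (file.exists(sidecar)) readLines(sidecar) else
      paste0("channel_", seq_along(pages)))
  channels <- lapply(pages, function(p) p * 65535)
  names(channels) <- channel_names
  structure(list(channels = channels, pixel_size = NA_real_,
                 metadata = metadata %||%
                   tibble::tibble(frame_id = basename(path))),
            class = "myo_frame")
}

#' Write a scene's truth table as CSV
#'
#' @param scene a `myo_scene`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(scene, path) {
  readr::write_csv(scene$cells, path)
  invisible(path)
}
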