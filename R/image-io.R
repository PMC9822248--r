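#' Read / write multi-channel images as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per channel; pixel size (nm) and channel order are recorded
#' in `<path>.json`. Intensities are stored as 32-bit floats rescaled to
#' [0, 1]; the arbitrary units of the analysis are restored on read from the
#' recorded `intensity_offset` and `intensity_scale`.
#'
#' @param channels named list of numeric matrices (same dimensions).
#' @param path TIFF output path.
#' @param pixel_size nm per pixel, stored in the sidecar.
#' @return `write_channels_tiff()` returns `path` invisibly;
#'   `read_channels_tiff()` returns a list with `channels` and `pixel_size`.
#' @export
write_channels_tiff <- function(channels, path, pixel_size) {
  stopifnot(is.list(channels), length(channels) >= 1)
  mn <- min(vapply(channels, min, numeric(1)))
  mx <- max(vapply(channels, max, numeric(1)))
  rg <- max(mx - mn, 1e-12)
  pages <- lapply(channels, function(ch) (ch - mn) / rg)  # writeTIFF wants [0, 1]
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size = pixel_size, channel_order = names(channels),
         intensity_offset = mn, intensity_scale = rg),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_channels_tiff
#' @export
read_channels_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  channels <- lapply(pages, function(p) p * meta$intensity_scale + meta$intensity_offset)
  names(channels) <- meta$channel_order
  list(channels = channels, pixel_size = meta$pixel_size)
}
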