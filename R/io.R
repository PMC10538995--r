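#' Write a simulated section to disk
#'
#' Writes each channel as a single-channel 16-bit TIFF, the ground truth as
#' two CSVs (`fibers.csv`, `capillaries.csv`) and the simulation
#' parameters as a JSON sidecar (`params.json`). Intensities are stored as
#' raw counts over a 16-bit range.
#'
#' @param section A `muscle_section` from [generate_section()].
#' @param dir Output directory (created if needed).
#' @param max_intensity Intensity mapped to the top of the 16-bit range.
#' @return `dir`, invisibly.
#' @export
write_section <- function(section, dir, max_intensity = 65535) {
  stopifnot(inherits(section, "muscle_section"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(section$channels)) {
    ch <- section$channels[[nm]]
    img <- pmin(pmax(ch$pixels / max_intensity, 0), 1)
    tiff::writeTIFF(img, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 16, compression = "none")
  }
  fib <- section$truth$fibers
  write.csv(fib[setdiff(names(fib), "polygon")],
            file.path(dir, "fibers.csv"), row.names = FALSE)
  write.csv(section$truth$capillaries, file.path(dir, "capillaries.csv"),
            row.names = FALSE)
  p <- section$params
  p$channel_means <- as.data.frame(p$channel_means)
  jsonlite::write_json(unclass(p), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a single-channel TIFF as a channel image
#'
#' @param path TIFF path (as written by [write_section()], or any
#'   single-channel TIFF).
#' @param channel Channel label (see [channel_image()]).
#' @param pixel_size Pixel size, um/px.
#' @param max_intensity Scale factor mapping the stored \[0, 1\] range back
#'   to intensities.
#' @param ... Passed to [channel_image()] (exposure, gain, saturation).
#' @return A [channel_image].
#' @export
read_channel_tiff <- function(path, channel, pixel_size,
                              max_intensity = 65535, ...) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  channel_image(px * max_intensity, channel, pixel_size, ...)
}
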