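#' Single-channel section image
#'
#' Container for one 2-D intensity grid of a muscle cross-section together
#' with its channel identity and acquisition metadata. Intensities are in
#' arbitrary units (a.u.) and must be nonnegative; pixel size converts pixel
#' counts to physical distances.
#'
#' @param pixels Numeric matrix of nonnegative intensities, rows = image
#'   rows, columns = image columns.
#' @param channel Channel label, one of `"NADH"`, `"Fp"`, `"MHC1"`,
#'   `"MHC2a"`, `"DAPI"`, `"CAP"`, `"COLLAGEN"`, `"SDHA"`, `"CS"`.
#' @param pixel_size Pixel edge length in micrometres per pixel.
#' @param exposure Exposure time in milliseconds (metadata; acquisitions
#'   pooled into one analysis must match).
#' @param gain Instrument gain (a.u., metadata).
#' @param saturation Optional intensity at which the detector clips; fibers
#'   containing pixels at or above this level are flagged as saturated.
#'
#' @return An object of class `channel_image`.
#' @export
#' @examples
#' img <- channel_image(matrix(100, 8, 8), "NADH", pixel_size = 1.5)
#' dim(img)
channel_image <- function(pixels, channel, pixel_size,
                          exposure = 1, gain = 1, saturation = NULL) {
  channel <- match.arg(channel, .channels_all)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (any(pixels < 0, na.rm = TRUE)) {
    abort("Channel intensities must be nonnegative.")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number (µm/px).")
  }
  structure(
    list(pixels = pixels, channel = channel, pixel_size = pixel_size,
         exposure = exposure, gain = gain, saturation = saturation),
    class = "channel_image"
  )
}

.channels_all <- c("NADH", "Fp", "MHC1", "MHC2a", "DAPI", "CAP",
                   "COLLAGEN", "SDHA", "CS")

#' @export
dim.channel_image <- function(x) dim(x$pixels)

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf(
    "<channel_image> %s  %d x %d px @ %.3g µm/px  [%.4g, %.4g] a.u.\n",
    x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
    min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
as_tibble.channel_image <- function(x, ...) {
  px <- x$pixels
  tibble(
    row = rep(seq_len(nrow(px)), times = ncol(px)),
    col = rep(seq_len(ncol(px)), each = nrow(px)),
    intensity = as.vector(px)
  )
}

# stop unless two channels share shape and pixel size
check_coregistered <- function(a, b) {
  if (!identical(dim(a$pixels), dim(b$pixels))) {
    abort(sprintf("Channels %s and %s are not co-registered: shapes %s vs %s.",
                  a$channel, b$channel,
                  paste(dim(a$pixels), collapse = "x"),
                  paste(dim(b$pixels), collapse = "x")))
  }
  if (!isTRUE(all.equal(a$pixel_size, b$pixel_size))) {
    abort("Channels disagree on pixel size.")
  }
  invisible(TRUE)
}

# acquisition-metadata equality gate; pooling across exposures/gains is
# refused unless an explicit rescale factor is configured by the caller
check_acquisition <- function(channel, reference, rescale = NULL) {
  if (is.null(reference)) return(1)
  same <- isTRUE(all.equal(channel$exposure, reference$exposure)) &&
    isTRUE(all.equal(channel$gain, reference$gain))
  if (same) return(1)
  if (is.null(rescale)) {
    abort(paste0(
      "Channel '", channel$channel, "' was acquired at exposure/gain (",
      channel$exposure, ", ", channel$gain, ") but the reference acquisition",
      " used (", reference$exposure, ", ", reference$gain, "). Intensities",
      " from different acquisitions cannot be pooled; supply an explicit",
      " `rescale` factor to override."))
  }
  rescale
}

#' Plot a channel image
#'
#' Renders a channel as a ggplot2 raster, optionally overlaying fiber
#' boundaries from a segmentation table.
#'
#' @param object A [channel_image].
#' @param fibers Optional fiber table from [segment_fibers()]; boundaries of
#'   its label image are drawn on top.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.channel_image <- function(object, fibers = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "a.u.") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(object$channel, " channel"),
                  x = "column (px)", y = "row (px)")
  if (!is.null(fibers)) {
    lab <- fiber_labels(fibers)
    edge <- which(label_boundary(lab), arr.ind = TRUE)
    p <- p + ggplot2::geom_point(
      data = tibble(row = edge[, 1], col = edge[, 2]),
      ggplot2::aes(x = .data$col, y = .data$row),
      inherit.aes = FALSE, size = 0.1, colour = "white")
  }
  p
}
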