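#' Segment individual myofibers from MHC immunofluorescence channels
#'
#' Automates the tracing of fibers in a cross-section. The max-projection
#' of the supplied channels is thresholded (Otsu), holes are filled, and
#' touching fibers are split by watershed on the distance transform —
#' fibers tile the section and are separated by dark extracellular
#' boundaries, which is exactly the geometry watershed handles. Because
#' type IIx fibers are negative on both MHC channels, pass an
#' autofluorescence channel (NADH or Fp, in which all fibers are bright)
#' as `hint`, mirroring how sections are traced on the accompanying
#' autofluorescence image.
#'
#' @param mhc1,mhc2a [channel_image]s of the MHC I and MHC IIa stains,
#'   co-registered.
#' @param hint Optional co-registered [channel_image] in which every fiber
#'   is bright (typically NADH or Fp autofluorescence).
#' @param min_area_um2 Minimum fiber area; smaller components are discarded
#'   as debris. Default 500 um^2.
#' @param watershed_tolerance Minimum depth (px, on the distance transform)
#'   between basins before they are split; raises robustness against
#'   over-segmentation of convex fibers.
#' @param threshold Optional explicit foreground intensity cutoff; Otsu on
#'   the pooled pixel intensities when `NULL`.
#'
#' @return A tibble with one row per fiber ROI: `fiber_id`, `area_um2`,
#'   `centroid_row`, `centroid_col`, `border` (touches the field-of-view
#'   edge), `included` (border fibers are excluded from quantification:
#'   their area is censored by the field of view). The integer label image
#'   is attached as attribute `"label"`, the pixel size as `"pixel_size"`;
#'   retrieve them with [fiber_labels()].
#' @export
#' @examples
#' sec <- generate_section(section_params(n_fibers = 25,
#'                                        image_size = c(224, 224), seed = 3))
#' fib <- segment_fibers(sec$channels$mhc1, sec$channels$mhc2a,
#'                       hint = sec$channels$fp)
#' nrow(fib)
segment_fibers <- function(mhc1, mhc2a, hint = NULL,
                           min_area_um2 = 500,
                           watershed_tolerance = 2,
                           threshold = NULL) {
  stopifnot(inherits(mhc1, "channel_image"), inherits(mhc2a, "channel_image"))
  check_coregistered(mhc1, mhc2a)
  if (length(mhc1$pixels) == 0) abort("Empty image.")
  ps <- mhc1$pixel_size
  layers <- list(mhc1$pixels, mhc2a$pixels)
  if (!is.null(hint)) {
    stopifnot(inherits(hint, "channel_image"))
    check_coregistered(mhc1, hint)
    layers <- c(layers, list(hint$pixels))
  }

  if (!is.null(threshold)) {
    binary <- Reduce(`|`, lapply(layers, function(px) px > threshold))
  } else {
    # each channel is bimodal on its own (a fiber class vs background);
    # thresholding per channel and taking the union captures classes of
    # different brightness (e.g. IIx fibers visible only on the
    # autofluorescence hint) that a pooled threshold would miss
    masks <- lapply(layers, .foreground_mask)
    masks <- masks[!vapply(masks, is.null, TRUE)]
    if (length(masks) == 0) {
      return(.empty_fiber_table(matrix(0L, nrow(mhc1$pixels),
                                       ncol(mhc1$pixels)), ps))
    }
    binary <- Reduce(`|`, masks)
  }
  if (!any(binary)) {
    return(.empty_fiber_table(matrix(0L, nrow(mhc1$pixels),
                                     ncol(mhc1$pixels)), ps))
  }

  mask <- EBImage::fillHull(EBImage::Image(binary * 1)) > 0.5
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(binary),
                ncol(binary))

  min_px <- ceiling(min_area_um2 / ps^2)
  lab <- .filter_relabel(lab, min_px)
  .fiber_table(lab, ps)
}

# Otsu foreground mask with a contrast guard: NULL when the split does not
# separate two populations by clearly more than their within-class spread
# (a blank, noise-only channel would otherwise be split down the middle)
.foreground_mask <- function(px) {
  v <- as.vector(px)
  if (stats::var(v) == 0) return(NULL)
  cut <- otsu_cutoff(v)
  lo <- v[v <= cut]; hi <- v[v > cut]
  if (!length(lo) || !length(hi)) return(NULL)
  within_sd <- sqrt((sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
                      length(v))
  if (mean(hi) - mean(lo) < 4 * within_sd) return(NULL)
  px > cut
}

# drop labels below min_px pixels and relabel 1..n compactly
.filter_relabel <- function(lab, min_px) {
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_px)
  map <- integer(max(lab))
  map[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

.fiber_table <- function(lab, ps) {
  n <- max(lab)
  if (n == 0L) return(.empty_fiber_table(lab, ps))
  H <- nrow(lab); W <- ncol(lab)
  idx <- which(lab > 0L)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  f <- lab[idx]
  area_px <- tabulate(f, nbins = n)
  border_ids <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  border_ids <- border_ids[border_ids > 0L]
  out <- tibble(
    fiber_id = seq_len(n),
    area_um2 = area_px * ps^2,
    centroid_row = as.numeric(tapply(r, f, mean)),
    centroid_col = as.numeric(tapply(cc, f, mean)),
    border = seq_len(n) %in% border_ids
  )
  out$included <- !out$border
  attr(out, "label") <- lab
  attr(out, "pixel_size") <- ps
  class(out) <- c("fiber_rois", class(out))
  out
}

.empty_fiber_table <- function(lab, ps) {
  out <- tibble(fiber_id = integer(), area_um2 = numeric(),
                centroid_row = numeric(), centroid_col = numeric(),
                border = logical(), included = logical())
  attr(out, "label") <- lab
  attr(out, "pixel_size") <- ps
  class(out) <- c("fiber_rois", class(out))
  out
}

#' Accessors for a fiber segmentation table
#'
#' `fiber_labels()` returns the integer label image backing a fiber table
#' (0 = background, k = fiber `fiber_id == k`); `fiber_pixel_size()` its
#' pixel size in um/px.
#'
#' @param fibers A fiber table from [segment_fibers()] or
#'   [fibers_from_truth()].
#' @return An integer matrix / a scalar.
#' @export
fiber_labels <- function(fibers) {
  lab <- attr(fibers, "label")
  if (is.null(lab)) abort("`fibers` carries no label image.")
  lab
}

#' @rdname fiber_labels
#' @export
fiber_pixel_size <- function(fibers) {
  ps <- attr(fibers, "pixel_size")
  if (is.null(ps)) abort("`fibers` carries no pixel size.")
  ps
}

#' Build a fiber table from an integer label image
#'
#' Adopts externally provided fiber regions (e.g. manually traced ROIs
#' rasterised to a label image) as segmentation output: pixels labelled
#' `k > 0` belong to fiber `k`, 0 is background.
#'
#' @param label Integer matrix of fiber labels.
#' @param pixel_size Pixel size, um/px.
#' @return A fiber table as from [segment_fibers()].
#' @export
fibers_from_label <- function(label, pixel_size) {
  if (!is.matrix(label)) abort("`label` must be a matrix.")
  storage.mode(label) <- "integer"
  .fiber_table(label, pixel_size)
}

#' Build a fiber table directly from simulator ground truth
#'
#' Bypasses segmentation by adopting the planted fiber regions of a
#' [generate_section()] truth object as ROIs. Useful for isolating
#' quantification from segmentation in validation work, and the analogue of
#' importing externally traced ROIs.
#'
#' @param truth A `section_truth` object.
#' @return A fiber table as from [segment_fibers()].
#' @export
fibers_from_truth <- function(truth) {
  stopifnot(inherits(truth, "section_truth"))
  out <- .fiber_table(truth$label, truth$pixel_size)
  out
}

# TRUE at pixels adjacent to a differing label (for plotting overlays)
label_boundary <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  b <- matrix(FALSE, H, W)
  b[-H, ] <- b[-H, ] | (lab[-H, ] != lab[-1, ])
  b[, -W] <- b[, -W] | (lab[, -W] != lab[, -1])
  b & lab > 0L
}
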