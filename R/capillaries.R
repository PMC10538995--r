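#' Detect capillaries in a PAS-type capillary stain channel
#'
#' Thresholds the channel (Otsu), labels connected bright blobs and keeps
#' one detection (the centroid) per blob whose equivalent diameter falls in
#' the capillary size range. Blobs larger than the upper bound are likely
#' two or more merged capillaries closer than the resolvable separation:
#' they yield a single detection with a warning. Blobs below the lower
#' bound are discarded as debris.
#'
#' @param cap_channel A [channel_image] of the capillary stain.
#' @param diameter_range Acceptable equivalent-diameter range, um
#'   (default 2-8 um).
#' @param threshold Optional explicit intensity cutoff; Otsu when `NULL`.
#' @return Tibble: `capillary_id`, `row`, `col` (px, centroid),
#'   `diameter_um`, `merged` (flagged oversize blob). Empty when nothing is
#'   detected.
#' @export
detect_capillaries <- function(cap_channel, diameter_range = c(2, 8),
                               threshold = NULL) {
  blobs <- .detect_blobs(cap_channel, threshold)
  if (nrow(blobs) == 0) {
    return(tibble(capillary_id = integer(), row = numeric(),
                  col = numeric(), diameter_um = numeric(),
                  merged = logical()))
  }
  merged <- blobs$diameter_um > diameter_range[2]
  if (any(merged)) {
    warn(sprintf(
      "%d blob(s) exceed %.3g µm equivalent diameter: possibly merged capillaries, each kept as one detection.",
      sum(merged), diameter_range[2]))
  }
  keep <- blobs$diameter_um >= diameter_range[1]
  out <- blobs[keep, , drop = FALSE]
  tibble(capillary_id = seq_len(nrow(out)), row = out$row, col = out$col,
         diameter_um = out$diameter_um, merged = merged[keep])
}

#' Count DAPI-stained nuclei
#'
#' Blob detection on the DAPI channel within the nuclear size range.
#'
#' @param dapi A [channel_image].
#' @param diameter_range Acceptable equivalent-diameter range, um
#'   (default 3-10 um).
#' @param threshold Optional explicit cutoff; Otsu when `NULL`.
#' @return Tibble: `nucleus_id`, `row`, `col`, `diameter_um`.
#' @export
nuclei_count <- function(dapi, diameter_range = c(3, 10), threshold = NULL) {
  blobs <- .detect_blobs(dapi, threshold)
  keep <- blobs$diameter_um >= diameter_range[1] &
    blobs$diameter_um <= diameter_range[2]
  out <- blobs[keep, , drop = FALSE]
  tibble(nucleus_id = seq_len(nrow(out)), row = out$row, col = out$col,
         diameter_um = out$diameter_um)
}

# shared blob detector: threshold -> connected components -> centroids
.detect_blobs <- function(channel, threshold = NULL) {
  stopifnot(inherits(channel, "channel_image"))
  px <- channel$pixels
  if (length(px) == 0) abort("Empty image.")
  cutoff <- threshold %||% otsu_cutoff(as.vector(px))
  binary <- px > cutoff
  empty <- tibble(row = numeric(), col = numeric(), diameter_um = numeric())
  if (!any(binary)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(binary * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(px), ncol(px))
  n <- max(lab)
  if (n == 0) return(empty)
  idx <- which(lab > 0L)
  H <- nrow(px)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  f <- lab[idx]
  area <- tabulate(f, nbins = n)
  tibble(
    row = as.numeric(tapply(r, f, mean)),
    col = as.numeric(tapply(cc, f, mean)),
    diameter_um = 2 * sqrt(area / pi) * channel$pixel_size)
}

#' Build the capillary-fiber contact graph
#'
#' An edge (capillary, fiber) exists iff the capillary centre lies within
#' `contact_tolerance` (um) of the fiber's nearest pixel. Symmetric and
#' deterministic; fiber relabelings permute but never change the graph.
#'
#' @param fibers Fiber table (shared coordinate frame with the
#'   capillaries).
#' @param capillaries Tibble with `capillary_id`, `row`, `col` (px), e.g.
#'   from [detect_capillaries()] or simulator truth.
#' @param contact_tolerance Contact distance, um. The default 8 um (about
#'   one capillary diameter) covers the extracellular gap between abutting
#'   fibers, so a capillary in the gap or at a junction contacts every
#'   adjacent fiber without bridging to non-adjacent ones.
#' @param area_mm2 Optional explicit analyzed area (mm^2); by default the
#'   convex hull of the fiber pixels (the "defined area" excludes empty
#'   margins of the field of view).
#' @return An object of class `capillary_map`: list with `edges` (tibble
#'   capillary_id, fiber_id), `capillaries`, `n_fibers`, and the analyzed
#'   `area_mm2`.
#' @export
build_contact_graph <- function(fibers, capillaries, contact_tolerance = 8,
                                area_mm2 = NULL) {
  if (contact_tolerance < 0) abort("`contact_tolerance` must be >= 0.")
  lab <- fiber_labels(fibers)
  ps <- fiber_pixel_size(fibers)
  tol_px <- contact_tolerance / ps
  r <- ceiling(tol_px)
  H <- nrow(lab); W <- ncol(lab)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= tol_px^2, , drop = FALSE]
  edges <- purrr::map_dfr(seq_len(nrow(capillaries)), function(k) {
    ri <- round(capillaries$row[k]) + off$di
    ci <- round(capillaries$col[k]) + off$dj
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    hit <- unique(lab[cbind(ri[ok], ci[ok])])
    hit <- hit[hit > 0L]
    if (!length(hit)) return(NULL)
    tibble(capillary_id = capillaries$capillary_id[k], fiber_id = hit)
  })
  if (nrow(edges) == 0) {
    edges <- tibble(capillary_id = integer(), fiber_id = integer())
  }
  structure(
    list(edges = edges, capillaries = capillaries,
         n_fibers = nrow(fibers), fiber_ids = fibers$fiber_id,
         area_mm2 = area_mm2 %||% analyzed_area_mm2(fibers)),
    class = "capillary_map")
}

#' @export
print.capillary_map <- function(x, ...) {
  cat(sprintf(
    "<capillary_map> %d capillaries, %d fibers, %d contacts over %.4g mm^2\n",
    nrow(x$capillaries), x$n_fibers, nrow(x$edges), x$area_mm2))
  invisible(x)
}

#' Analyzed section area
#'
#' Area of the convex hull of all fiber pixels, in mm^2 — the "defined
#' area" over which densities are reported, excluding empty image margins.
#'
#' @param fibers Fiber table.
#' @return Scalar area (mm^2).
#' @export
analyzed_area_mm2 <- function(fibers) {
  lab <- fiber_labels(fibers)
  ps <- fiber_pixel_size(fibers)
  idx <- which(lab > 0L)
  if (!length(idx)) return(0)
  H <- nrow(lab)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  # convex hull over pixel corner points so single-pixel extents count
  pts <- cbind(c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
               c(cc - 0.5, cc + 0.5, cc - 0.5, cc + 0.5))
  h <- grDevices::chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  n <- length(h)
  area_px <- abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2
  area_px * ps^2 / 1e6
}
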