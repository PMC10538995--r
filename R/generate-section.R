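#' Simulate a multi-channel muscle cross-section with planted ground truth
#'
#' Generates one synthetic vastus lateralis-like section: a Lloyd-relaxed
#' Voronoi tessellation of near-convex fibers separated by a thin
#' extracellular gap, per-fiber MHC types drawn from the configured
#' proportions (plus a small hybrid rate), fiber-type-specific NADH/Fp
#' autofluorescence, MHC immunofluorescence channels, capillaries rendered
#' as small discs at retained fiber junctions, peripheral nuclei on the
#' DAPI channel, sparse extracellular collagen staining, additive Gaussian
#' noise over a uniform background, and optional saturation clipping.
#' Everything planted is returned as ground truth so downstream stages can
#' be validated without real data.
#'
#' @param params A [section_params] object.
#' @return An object of class `muscle_section`: a list with
#'   * `channels`: named list of [channel_image]s (`nadh`, `fp`, `mhc1`,
#'     `mhc2a`, `dapi`, `cap`, `collagen`);
#'   * `truth`: a `section_truth` list with `fibers` (tibble: fiber_id,
#'     type, centroid, area, planted means, boundary polygon), `capillaries`
#'     and `nuclei` coordinate tibbles, the planted `background_level`, the
#'     eroded fiber `label` matrix and the full tessellation `label_full`;
#'   * `params`: the input parameters.
#' @details The simulation is fully deterministic for a fixed
#'   `params$seed`; no global RNG state is consumed or left behind.
#' @export
#' @examples
#' sec <- generate_section(section_params(n_fibers = 25,
#'                                        image_size = c(224, 224),
#'                                        seed = 42))
#' table(sec$truth$fibers$type)
generate_section <- function(params) {
  stopifnot(inherits(params, "section_params"))
  withr::with_seed(params$seed, .generate_section_impl(params))
}

.generate_section_impl <- function(p) {
  H <- p$image_size[1]; W <- p$image_size[2]
  rowm <- matrix(seq_len(H), H, W)
  colm <- matrix(seq_len(W), H, W, byrow = TRUE)

  ## --- geometry: Lloyd-relaxed Voronoi tessellation -----------------------
  ys <- runif(p$n_fibers, 1, H)
  xs <- runif(p$n_fibers, 1, W)
  # Lloyd relaxation on a stride-2 grid (centroids are insensitive to the
  # subsampling); one full-resolution assignment at the end
  ri <- seq(1L, H, by = 2L); ci <- seq(1L, W, by = 2L)
  rowc <- matrix(ri, length(ri), length(ci))
  colc <- matrix(ci, length(ri), length(ci), byrow = TRUE)
  for (it in seq_len(p$lloyd_iters)) {
    lab_c <- .nearest_seed_labels(rowc, colc, ys, xs)
    ys2 <- tapply(as.vector(rowc), as.vector(lab_c), mean)
    xs2 <- tapply(as.vector(colc), as.vector(lab_c), mean)
    idx <- as.integer(names(ys2))
    ys[idx] <- ys2; xs[idx] <- xs2
  }
  lab_full <- .nearest_seed_labels(rowm, colm, ys, xs)

  ## --- erode each cell to carve the inter-fiber gap -----------------------
  interior <- .uniform_neighborhood(lab_full, p$erosion_px)
  lab <- lab_full
  lab[!interior] <- 0L

  ## --- fiber types --------------------------------------------------------
  is_hybrid <- runif(p$n_fibers) < p$hybrid_rate
  base_type <- sample(names(p$type_proportions), p$n_fibers, replace = TRUE,
                      prob = p$type_proportions)
  type <- ifelse(is_hybrid, "hybrid", base_type)

  means <- p$channel_means
  mrow <- match(type, means$type)

  ## --- capillaries at fiber junctions -------------------------------------
  junc <- .junction_points(lab_full)
  min_sep <- 2 * ceiling(p$capillary_radius_um / p$pixel_size) + 1
  junc <- .greedy_separate(junc, min_sep)
  keep <- runif(nrow(junc)) < p$capillary_retention
  caps <- junc[keep, , drop = FALSE]
  faces <- .face_midpoints(lab_full)
  if (nrow(faces)) {
    faces <- faces[runif(nrow(faces)) < p$capillary_face_rate, , drop = FALSE]
    caps <- .greedy_separate(rbind(caps, faces), min_sep)
  }
  capillaries <- tibble(capillary_id = seq_len(nrow(caps)),
                        row = caps[, 1], col = caps[, 2])

  ## --- nuclei at fiber peripheries ----------------------------------------
  deep <- EBImage::erode(EBImage::Image(interior * 1),
                         EBImage::makeBrush(7, "box")) > 0.5
  rim <- which(interior & !deep)       # interior band next to the boundary
  n_nuc <- rpois(p$n_fibers, p$nuclei_per_fiber)
  rim_lab <- lab_full[rim]
  nuc_idx <- integer(0)
  for (f in seq_len(p$n_fibers)) {
    pool <- rim[rim_lab == f]
    if (length(pool) && n_nuc[f] > 0) {
      nuc_idx <- c(nuc_idx, sample(pool, min(n_nuc[f], length(pool))))
    }
  }
  nuc <- cbind(((nuc_idx - 1L) %% H) + 1L, ((nuc_idx - 1L) %/% H) + 1L)
  nuc_sep <- 2 * ceiling(p$nucleus_radius_um / p$pixel_size) + 2
  nuc <- .greedy_separate(nuc, nuc_sep)
  nuclei <- tibble(nucleus_id = seq_len(nrow(nuc)),
                   row = nuc[, 1], col = nuc[, 2])

  ## --- collagen: planted fraction of tissue pixels, extracellular ---------
  gap_idx <- which(lab == 0L)
  n_stained <- round(p$collagen_fraction * H * W)
  stained_idx <- if (n_stained > 0) sample(gap_idx, min(n_stained, length(gap_idx)))
                 else integer(0)

  ## --- render channels ----------------------------------------------------
  bg <- p$background_level
  fiber_px <- lab > 0L
  add_by_type <- function(col) {
    img <- matrix(0, H, W)
    lvl <- means[[col]][mrow]           # per-fiber level
    img[fiber_px] <- lvl[lab[fiber_px]]
    img
  }
  nadh_img <- add_by_type("nadh")
  fp_img   <- add_by_type("fp")
  mhc1_img <- add_by_type("mhc1")
  mhc2_img <- add_by_type("mhc2a")

  dapi_img <- .render_discs(matrix(0, H, W), nuclei$row, nuclei$col,
                            p$nucleus_radius_um / p$pixel_size, p$disc_level)
  cap_img <- .render_discs(matrix(0, H, W), capillaries$row, capillaries$col,
                           p$capillary_radius_um / p$pixel_size, p$disc_level)
  col_img <- matrix(0, H, W)
  col_img[stained_idx] <- p$collagen_level

  finish <- function(img, channel) {
    img <- img + bg
    if (p$noise_sd > 0) img <- img + rnorm(length(img), 0, p$noise_sd)
    img[img < 0] <- 0
    if (!is.null(p$saturation_cap)) img[img > p$saturation_cap] <- p$saturation_cap
    channel_image(matrix(img, H, W), channel, p$pixel_size,
                  saturation = p$saturation_cap)
  }
  channels <- list(
    nadh     = finish(nadh_img, "NADH"),
    fp       = finish(fp_img, "Fp"),
    mhc1     = finish(mhc1_img, "MHC1"),
    mhc2a    = finish(mhc2_img, "MHC2a"),
    dapi     = finish(dapi_img, "DAPI"),
    cap      = finish(cap_img, "CAP"),
    collagen = finish(col_img, "COLLAGEN")
  )

  ## --- ground truth -------------------------------------------------------
  area_px <- tabulate(lab[fiber_px], nbins = p$n_fibers)
  cen_r <- tapply(as.vector(rowm)[fiber_px], lab[fiber_px], mean)
  cen_c <- tapply(as.vector(colm)[fiber_px], lab[fiber_px], mean)
  polys <- .label_polygons(lab, p$n_fibers)
  fibers <- tibble(
    fiber_id = seq_len(p$n_fibers),
    type = type,
    centroid_row = as.numeric(cen_r[as.character(seq_len(p$n_fibers))]),
    centroid_col = as.numeric(cen_c[as.character(seq_len(p$n_fibers))]),
    area_um2 = area_px * p$pixel_size^2,
    true_nadh = means$nadh[mrow],
    true_fp = means$fp[mrow],
    polygon = polys
  )
  fibers$true_redox <- with(fibers, ifelse(true_fp + true_nadh > 0,
                                           true_fp / (true_fp + true_nadh),
                                           NA_real_))
  truth <- structure(
    list(fibers = fibers, capillaries = capillaries, nuclei = nuclei,
         collagen_idx = stained_idx, background_level = bg,
         label = lab, label_full = lab_full, pixel_size = p$pixel_size),
    class = "section_truth")

  structure(list(channels = channels, truth = truth, params = p),
            class = "muscle_section")
}

#' @export
print.muscle_section <- function(x, ...) {
  cat(sprintf(
    "<muscle_section> %d x %d px, %d fibers (%s), %d capillaries, %d nuclei\n",
    x$params$image_size[1], x$params$image_size[2],
    nrow(x$truth$fibers),
    paste(names(table(x$truth$fibers$type)),
          table(x$truth$fibers$type), sep = ":", collapse = " "),
    nrow(x$truth$capillaries), nrow(x$truth$nuclei)))
  invisible(x)
}

## ---- internal geometry helpers -------------------------------------------

# label each pixel with the index of its nearest seed (squared Euclidean)
.nearest_seed_labels <- function(rowm, colm, ys, xs) {
  best <- matrix(Inf, nrow(rowm), ncol(rowm))
  lab <- matrix(0L, nrow(rowm), ncol(rowm))
  for (s in seq_along(ys)) {
    d <- (rowm - ys[s])^2 + (colm - xs[s])^2
    upd <- d < best
    best[upd] <- d[upd]
    lab[upd] <- s
  }
  lab
}

# TRUE where the whole Chebyshev-radius-k neighborhood shares one label;
# out-of-image neighbours are treated as matching so border fibers are not
# eroded against the field-of-view edge
.uniform_neighborhood <- function(lab, k) {
  H <- nrow(lab); W <- ncol(lab)
  ok <- matrix(TRUE, H, W)
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  for (di in -k:k) for (dj in -k:k) {
    if (di == 0 && dj == 0) next
    shifted <- lab[clamp(seq_len(H) + di, H), clamp(seq_len(W) + dj, W)]
    ok <- ok & (shifted == lab)
  }
  ok
}

# junction candidates: centers of 2x2 blocks containing >= 3 distinct labels
# (interior Voronoi vertices), plus edge crossings where two cells meet the
# image border (capillaries occur there anatomically too)
.junction_points <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  a <- lab[-H, -W]; b <- lab[-1, -W]; ca <- lab[-H, -1]; d <- lab[-1, -1]
  ndist <- 1L + (b != a) + (ca != a & ca != b) +
    (d != a & d != b & d != ca)
  ij <- which(ndist >= 3L, arr.ind = TRUE)
  pts <- cbind(ij[, 1] + 0.5, ij[, 2] + 0.5)
  edge <- rbind(
    cbind(1, which(lab[1, -W] != lab[1, -1]) + 0.5),
    cbind(H, which(lab[H, -W] != lab[H, -1]) + 0.5),
    cbind(which(lab[-H, 1] != lab[-1, 1]) + 0.5, 1),
    cbind(which(lab[-H, W] != lab[-1, W]) + 0.5, W)
  )
  out <- rbind(pts, edge)
  cbind(round(out[, 1]), round(out[, 2]))
}

# midpoint of each shared boundary face between two adjacent cells
.face_midpoints <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  # horizontally and vertically adjacent pixel pairs with differing labels
  h1 <- lab[, -W]; h2 <- lab[, -1]
  v1 <- lab[-H, ]; v2 <- lab[-1, ]
  hi <- which(h1 != h2, arr.ind = TRUE)
  vi <- which(v1 != v2, arr.ind = TRUE)
  pr <- c(hi[, 1], vi[, 1] + 0.5)
  pc <- c(hi[, 2] + 0.5, vi[, 2])
  key <- c(
    paste(pmin(h1[hi], h2[hi]), pmax(h1[hi], h2[hi])),
    paste(pmin(v1[vi], v2[vi]), pmax(v1[vi], v2[vi]))
  )
  if (!length(key)) return(matrix(numeric(0), ncol = 2))
  mr <- tapply(pr, key, mean)
  mc <- tapply(pc, key, mean)
  cbind(round(as.numeric(mr)), round(as.numeric(mc)))
}

# greedy minimum-separation thinning: keep a point iff it is at least
# min_sep px from every previously kept point
.greedy_separate <- function(pts, min_sep) {
  if (nrow(pts) == 0) return(pts)
  keep <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(pts))) {
    if (nrow(keep) == 0 ||
        min((keep[, 1] - pts[i, 1])^2 + (keep[, 2] - pts[i, 2])^2) >=
          min_sep^2) {
      keep <- rbind(keep, pts[i, , drop = FALSE])
    }
  }
  keep
}

# paint filled discs of a given radius (px) at the given centres
.render_discs <- function(img, rows, cols, radius_px, level) {
  if (length(rows) == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  r <- ceiling(radius_px)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= radius_px^2, ]
  for (k in seq_along(rows)) {
    ri <- rows[k] + off$di; ci <- cols[k] + off$dj
    okpix <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    img[cbind(ri[okpix], ci[okpix])] <- level
  }
  img
}

# per-label boundary polygons (oriented contours, 1-based pixel coords)
.label_polygons <- function(lab, n) {
  oc <- EBImage::ocontour(EBImage::Image(lab))
  polys <- vector("list", n)
  for (f in seq_len(n)) {
    if (f <= length(oc) && !is.null(oc[[f]])) {
      m <- oc[[f]] + 1  # ocontour is 0-based
      colnames(m) <- c("row", "col")
      polys[[f]] <- m
    } else {
      polys[[f]] <- matrix(numeric(0), ncol = 2,
                           dimnames = list(NULL, c("row", "col")))
    }
  }
  polys
}
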