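#' Parameters for the synthetic muscle cross-section simulator
#'
#' Bundles and validates every knob of the section simulator. Defaults
#' emulate a vastus lateralis cross-section imaged at x20: ~70 fibers of
#' 4-6 x 10^3 um^2, MHC type proportions 45.9/44.5/9.6 % (I/IIa/IIx) with a
#' small hybrid rate, capillaries at fiber junctions at a retention giving a
#' capillary-to-fiber ratio near 2.3, nuclei at fiber peripheries near
#' 780/mm^2, and channel mean intensities ordered as observed in human
#' muscle (Fp: I > IIa > IIx; NADH: I ~ IIa > IIx). Absolute intensity
#' scales are free parameters in arbitrary units.
#'
#' @param n_fibers Number of fibers to tessellate.
#' @param image_size Integer vector `c(rows, cols)` in pixels.
#' @param pixel_size Pixel edge length, um/px.
#' @param type_proportions Named fractions for types I, IIa, IIx; must be
#'   nonnegative and sum to 1 (within 1e-9). Applied to non-hybrid fibers.
#' @param hybrid_rate Probability that a fiber co-expresses both MHC
#'   isoforms (classified hybrid and excluded downstream).
#' @param channel_means Data frame with columns `type` (`"I"`, `"IIa"`,
#'   `"IIx"`, `"hybrid"`) and per-channel mean intensities above background
#'   (`nadh`, `fp`, `mhc1`, `mhc2a`), a.u.
#' @param noise_sd SD of additive Gaussian intensity noise, a.u.
#' @param background_level Additive background intensity, a.u.
#' @param capillary_retention Probability a fiber-junction capillary is
#'   kept; together with `capillary_face_rate` this controls the
#'   capillary-to-fiber ratio.
#' @param capillary_face_rate Probability that the midpoint of a shared
#'   boundary face between two fibers additionally hosts a capillary.
#'   Junction vertices alone yield at most ~1.7 capillaries per fiber in a
#'   planar tessellation; capillaries running along fiber faces bring the
#'   simulated capillary-to-fiber ratio up to the ~2.3 observed in human
#'   vastus lateralis.
#' @param nuclei_per_fiber Mean (Poisson) nuclei per fiber.
#' @param collagen_fraction Fraction of tissue pixels planted as
#'   collagen-stained (extracellular, in the inter-fiber space).
#' @param saturation_cap Optional intensity ceiling; when set, all channels
#'   are clipped there and clipped fibers can be flagged downstream.
#' @param erosion_px Half-width (px) of the inter-fiber boundary gap carved
#'   out of the full tessellation; the default 3 px (4.5 um at the default
#'   pixel size) leaves an extracellular band wide enough to measure
#'   background in even after ROI dilation.
#' @param lloyd_iters Lloyd relaxation iterations applied to the seed
#'   points before tessellating (regularises fiber shapes).
#' @param capillary_radius_um,nucleus_radius_um Rendered disc radii, um.
#' @param disc_level,collagen_level Intensity of rendered discs / stained
#'   pixels above background, a.u.
#' @param seed Integer seed; the simulator is fully deterministic given it.
#'
#' @return A validated `section_params` object (a list).
#' @seealso [generate_section()]
#' @export
#' @examples
#' p <- section_params(n_fibers = 30, image_size = c(256, 256), seed = 1)
#' p$type_proportions
section_params <- function(n_fibers = 70,
                           image_size = c(384, 384),
                           pixel_size = 1.5,
                           type_proportions = c(I = 0.459, IIa = 0.445,
                                                IIx = 0.096),
                           hybrid_rate = 0.02,
                           channel_means = default_channel_means(),
                           noise_sd = 8,
                           background_level = 50,
                           capillary_retention = 0.95,
                           capillary_face_rate = 0.25,
                           nuclei_per_fiber = 3.7,
                           collagen_fraction = 0.0075,
                           saturation_cap = NULL,
                           erosion_px = 3,
                           lloyd_iters = 4,
                           capillary_radius_um = 2.25,
                           nucleus_radius_um = 2.25,
                           disc_level = 500,
                           collagen_level = 400,
                           seed = 1) {
  if (length(image_size) == 1) image_size <- rep(image_size, 2)
  image_size <- as.integer(image_size)
  if (any(image_size <= 0)) abort("`image_size` must be positive.")
  if (n_fibers < 1) abort("`n_fibers` must be >= 1.")
  if (any(type_proportions < 0)) {
    abort("`type_proportions` must be nonnegative.")
  }
  if (abs(sum(type_proportions) - 1) > 1e-9) {
    abort("`type_proportions` must sum to 1 (within 1e-9).")
  }
  if (is.null(names(type_proportions))) {
    names(type_proportions) <- c("I", "IIa", "IIx")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (capillary_retention < 0 || capillary_retention > 1) {
    abort("`capillary_retention` must lie in [0, 1].")
  }
  if (capillary_face_rate < 0 || capillary_face_rate > 1) {
    abort("`capillary_face_rate` must lie in [0, 1].")
  }
  if (hybrid_rate < 0 || hybrid_rate > 1) {
    abort("`hybrid_rate` must lie in [0, 1].")
  }
  if (pixel_size <= 0) abort("`pixel_size` must be positive.")
  # each fiber needs room for an interior after erosion; reject rather than
  # let fibers overlap or degenerate
  if (prod(image_size) < 64 * n_fibers) {
    abort(sprintf(
      "Image of %d x %d px is too small to host %d non-overlapping fibers.",
      image_size[1], image_size[2], n_fibers))
  }
  stopifnot(is.data.frame(channel_means),
            all(c("type", "nadh", "fp", "mhc1", "mhc2a") %in%
                  names(channel_means)))
  structure(
    list(n_fibers = as.integer(n_fibers), image_size = image_size,
         pixel_size = pixel_size, type_proportions = type_proportions,
         hybrid_rate = hybrid_rate, channel_means = channel_means,
         noise_sd = noise_sd, background_level = background_level,
         capillary_retention = capillary_retention,
         capillary_face_rate = capillary_face_rate,
         nuclei_per_fiber = nuclei_per_fiber,
         collagen_fraction = collagen_fraction,
         saturation_cap = saturation_cap,
         erosion_px = as.integer(erosion_px),
         lloyd_iters = as.integer(lloyd_iters),
         capillary_radius_um = capillary_radius_um,
         nucleus_radius_um = nucleus_radius_um,
         disc_level = disc_level, collagen_level = collagen_level,
         seed = as.integer(seed)),
    class = "section_params"
  )
}

#' Default per-type channel means for the simulator
#'
#' Mean intensities above background, chosen to reproduce the fiber-type
#' orderings seen in human vastus lateralis (Fp highest in type I, lowest in
#' IIx; NADH similar in I and IIa, lowest in IIx) with redox-ratio spacing
#' of roughly 7-8 % between adjacent types. Hybrid fibers express both MHC
#' isoforms. Units are arbitrary.
#'
#' @return A tibble with one row per fiber type.
#' @export
default_channel_means <- function() {
  tibble(
    type  = c("I", "IIa", "IIx", "hybrid"),
    nadh  = c(520, 510, 418, 515),
    fp    = c(500, 420, 300, 460),
    mhc1  = c(600,   0,   0, 600),
    mhc2a = c(  0, 600,   0, 600)
  )
}

#' @export
print.section_params <- function(x, ...) {
  cat(sprintf(
    "<section_params> %d fibers on %d x %d px @ %.3g µm/px, seed %d\n",
    x$n_fibers, x$image_size[1], x$image_size[2], x$pixel_size, x$seed))
  cat("  type proportions:",
      paste(sprintf("%s=%.3f", names(x$type_proportions),
                    x$type_proportions), collapse = ", "),
      sprintf(" hybrid rate %.3f\n", x$hybrid_rate))
  cat(sprintf("  background %.4g a.u., noise SD %.4g, capillary retention %.2f\n",
              x$background_level, x$noise_sd, x$capillary_retention))
  invisible(x)
}
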