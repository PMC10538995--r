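#' Estimate the background intensity of a channel
#'
#' Background is the median intensity of pixels outside every fiber ROI,
#' after dilating the ROIs (default 2 px) to keep partial-volume pixels at
#' fiber edges out of the estimate. Deterministic. If the ROIs (after
#' dilation) tile the whole image there is no background to measure and the
#' function errors, demanding an explicit background value.
#'
#' @param channel A [channel_image].
#' @param fibers Fiber table whose label image defines the ROIs.
#' @param dilate_px Dilation radius applied to the ROIs before masking
#'   (px); 0 disables.
#' @return Scalar background level (a.u.).
#' @export
#' @examples
#' sec <- generate_section(section_params(n_fibers = 25,
#'                                        image_size = c(224, 224),
#'                                        noise_sd = 0, seed = 5))
#' fib <- fibers_from_truth(sec$truth)
#' estimate_background(sec$channels$nadh, fib)  # exactly the planted level
estimate_background <- function(channel, fibers, dilate_px = 2) {
  stopifnot(inherits(channel, "channel_image"))
  lab <- fiber_labels(fibers)
  if (!identical(dim(lab), dim(channel$pixels))) {
    abort("Fiber label image and channel have different shapes.")
  }
  mask <- lab > 0L
  if (dilate_px > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(dilate_px) + 1L, "box")
    mask <- EBImage::dilate(EBImage::Image(mask * 1), brush) > 0.5
  }
  outside <- !mask
  if (!any(outside)) {
    abort(paste0(
      "Fiber ROIs (after dilation) tile the whole image; no background ",
      "pixels remain. Supply an explicit background value instead."))
  }
  median(channel$pixels[outside])
}

#' Background-subtracted per-fiber intensities
#'
#' The per-fiber "relative intensity": mean of the fiber's interior pixels
#' minus the background, floored at 0 (arbitrary-unit intensities cannot be
#' negative; floored fibers are flagged). Fibers containing any pixel at or
#' above the channel's saturation level are flagged as saturated, so they
#' can be excluded the way saturated acquisitions are. Intensities from a
#' different exposure/gain than the section's reference acquisition are
#' refused unless an explicit `rescale` factor is configured.
#'
#' @param channel A [channel_image].
#' @param fibers Fiber table.
#' @param background Scalar background (a.u.), e.g. from
#'   [estimate_background()].
#' @param statistic `"mean"` (default, standard densitometry) or
#'   `"median"`.
#' @param reference Optional [channel_image] giving the reference
#'   exposure/gain; a mismatch errors unless `rescale` is supplied.
#' @param rescale Optional multiplicative factor applied to intensities
#'   acquired under a non-reference exposure/gain.
#' @return A tibble: `fiber_id`, `intensity` (a.u., >= 0), `floored`
#'   (subtraction hit the 0 floor), `saturated`.
#' @export
quantify_fibers <- function(channel, fibers, background,
                            statistic = c("mean", "median"),
                            reference = NULL, rescale = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(channel, "channel_image"))
  factor <- check_acquisition(channel, reference, rescale)
  lab <- fiber_labels(fibers)
  if (!identical(dim(lab), dim(channel$pixels))) {
    abort("Fiber label image and channel have different shapes.")
  }
  idx <- lab > 0L
  fun <- if (statistic == "mean") mean else median
  raw <- tapply(channel$pixels[idx] * factor, lab[idx], fun)
  raw <- as.numeric(raw[as.character(fibers$fiber_id)])
  val <- raw - background
  floored <- !is.na(val) & val < 0
  val[floored] <- 0
  sat_level <- channel$saturation
  saturated <- if (is.null(sat_level)) {
    rep(FALSE, nrow(fibers))
  } else {
    satmax <- tapply(channel$pixels[idx], lab[idx], max)
    as.numeric(satmax[as.character(fibers$fiber_id)]) >= sat_level
  }
  tibble(fiber_id = fibers$fiber_id, intensity = val,
         floored = floored, saturated = saturated)
}

#' Optical redox ratio
#'
#' The oxidation-to-reduction ratio Fp / (Fp + NADH), dimensionless in
#' \[0, 1\]; higher values indicate a more oxidized state. Scale-invariant:
#' multiplying both intensities by the same positive factor leaves the
#' ratio unchanged. Undefined when both intensities are zero (`NA` with a
#' warning — such fibers are dropped from summaries).
#'
#' @param fp,nadh Nonnegative intensities (vectorised).
#' @return Numeric vector of ratios in \[0, 1\].
#' @export
#' @examples
#' redox_ratio(fp = 3, nadh = 1)   # 0.75
#' redox_ratio(fp = 2, nadh = 2)   # 0.5
redox_ratio <- function(fp, nadh) {
  if (any(fp < 0, na.rm = TRUE) || any(nadh < 0, na.rm = TRUE)) {
    abort("`fp` and `nadh` must be nonnegative.")
  }
  tot <- fp + nadh
  und <- !is.na(tot) & tot == 0
  if (any(und)) {
    warn(sprintf(
      "%d fiber(s) with Fp + NADH = 0: redox ratio undefined, set to NA.",
      sum(und)))
  }
  out <- fp / tot
  out[und] <- NA_real_
  out
}

#' Per-fiber redox quantification
#'
#' Convenience wrapper for the standard per-section pipeline: estimates (or
#' takes) the background of the NADH and Fp channels, computes
#' background-subtracted per-fiber intensities, and the per-fiber redox
#' ratio. The ratio is computed per fiber first; summaries over types
#' average these per-fiber ratios (mean-of-ratios, matching per-fiber dot
#' plots — not the ratio of type-mean intensities).
#'
#' @param fibers Fiber table (classified or not).
#' @param nadh,fp Co-registered [channel_image]s.
#' @param background Either `"auto"` (default; [estimate_background()] per
#'   channel) or a named numeric `c(nadh = , fp = )`.
#' @param statistic Per-fiber statistic, `"mean"` or `"median"`.
#' @return The fiber table with `nadh`, `fp`, `redox_ratio`, `floored`,
#'   `saturated` columns added.
#' @export
#' @examples
#' sec <- generate_section(section_params(n_fibers = 25,
#'                                        image_size = c(224, 224), seed = 7))
#' fib <- fibers_from_truth(sec$truth) |>
#'   classify_fibers(sec$channels$mhc1, sec$channels$mhc2a) |>
#'   quantify_redox(sec$channels$nadh, sec$channels$fp)
#' head(fib[, c("fiber_id", "type", "nadh", "fp", "redox_ratio")])
quantify_redox <- function(fibers, nadh, fp, background = "auto",
                           statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  check_coregistered(nadh, fp)
  if (identical(background, "auto")) {
    bg <- c(nadh = estimate_background(nadh, fibers),
            fp = estimate_background(fp, fibers))
  } else {
    bg <- background
    if (is.null(bg[["nadh"]]) || is.null(bg[["fp"]])) {
      abort("`background` must be \"auto\" or name both `nadh` and `fp`.")
    }
  }
  qn <- quantify_fibers(nadh, fibers, bg[["nadh"]], statistic = statistic)
  qf <- quantify_fibers(fp, fibers, bg[["fp"]], statistic = statistic)
  out <- dplyr::mutate(
    fibers,
    nadh = qn$intensity,
    fp = qf$intensity,
    redox_ratio = redox_ratio(qf$intensity, qn$intensity),
    floored = qn$floored | qf$floored,
    saturated = qn$saturated | qf$saturated)
  attr(out, "background") <- bg
  attr(out, "label") <- fiber_labels(fibers)
  attr(out, "pixel_size") <- fiber_pixel_size(fibers)
  class(out) <- unique(c("fiber_rois", class(out)))
  out
}

#' Summarise redox indices by fiber type
#'
#' Averages per-fiber values within each included fiber type
#' (mean-of-ratios for the redox ratio; hybrids and border fibers never
#' enter).
#'
#' @param fibers A quantified, classified fiber table.
#' @return A tibble with one row per fiber type: n_fibers, mean NADH, Fp,
#'   redox ratio, and mean fiber area.
#' @export
summarise_by_type <- function(fibers) {
  stopifnot(all(c("type", "redox_ratio") %in% names(fibers)))
  fibers |>
    dplyr::filter(.data$included, !is.na(.data$redox_ratio)) |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      n_fibers = dplyr::n(),
      nadh = mean(.data$nadh),
      fp = mean(.data$fp),
      redox_ratio = mean(.data$redox_ratio),
      area_um2 = mean(.data$area_um2),
      .groups = "drop")
}
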