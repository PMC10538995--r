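#' Fit an NADH calibration series
#'
#' Validates the autofluorescence readout against serial dilutions of
#' beta-NADH spanning the physiological range (e.g. 1 mM down to 0.01 mM,
#' run in triplicate): a least-squares line of mean intensity on
#' concentration, its coefficient of determination, and the interassay
#' variability defined as the mean over concentration levels of the
#' per-level coefficient of variation (SD/mean x 100 %).
#'
#' @param series Data frame with columns `concentration` (mM, > 0, at
#'   least 3 distinct levels) and `intensity` (a.u., >= 1 replicate per
#'   level).
#' @return An object of class `calibration_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `interassay_cv` (%), `levels` (per-level
#'   summary tibble) and the underlying `lm` fit. Has [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @export
#' @examples
#' ser <- data.frame(concentration = rep(c(0.01, 0.1, 0.5, 1), each = 3))
#' ser$intensity <- 5 + 2 * ser$concentration
#' fit <- fit_calibration(ser)
#' glance(fit)  # r_squared = 1, interassay_cv = 0
fit_calibration <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("concentration", "intensity") %in% names(series)))
  if (any(series$concentration <= 0)) {
    abort("Concentrations must be strictly positive.")
  }
  levels <- series |>
    dplyr::group_by(concentration = .data$concentration) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_intensity = mean(.data$intensity),
                     sd_intensity = sd(.data$intensity),
                     .groups = "drop")
  if (nrow(levels) < 3) {
    abort("Need at least 3 distinct concentration levels.")
  }
  # single-replicate levels have no SD; their CV is 0 by convention
  levels$cv <- ifelse(levels$n > 1 & levels$mean_intensity != 0,
                      100 * levels$sd_intensity / levels$mean_intensity, 0)
  fit <- lm(mean_intensity ~ concentration, data = levels)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((levels$mean_intensity - mean(levels$mean_intensity))^2)
  structure(
    list(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         interassay_cv = mean(levels$cv),
         levels = levels,
         fit = fit),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> intensity = %.6g + %.6g x conc (R^2 = %.4f), interassay CV %.2f%%\n",
    x$intercept, x$slope, x$r_squared, x$interassay_cv))
  invisible(x)
}

#' @export
tidy.calibration_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(term = rownames(co),
         estimate = co[, "Estimate"],
         std.error = co[, "Std. Error"])
}

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         interassay_cv = x$interassay_cv, n_levels = nrow(x$levels))
}

#' @export
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$levels,
                  ggplot2::aes(x = .data$concentration,
                               y = .data$mean_intensity)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "NADH concentration (mM)",
                  y = "mean intensity (a.u.)",
                  title = sprintf("Calibration: R² = %.4f, interassay CV %.1f%%",
                                  object$r_squared, object$interassay_cv))
}

#' Collagen staining fraction
#'
#' Ratio of stained area to tissue area for a collagen-stain channel
#' (Picro-Sirius-type): the fraction of tissue pixels whose intensity
#' exceeds the positivity cutoff, together with the mean stained intensity.
#'
#' @param collagen A [channel_image].
#' @param tissue_mask Logical matrix marking tissue pixels (nonempty).
#' @param cutoff Positivity cutoff (a.u.); pixels strictly above it count
#'   as stained.
#' @return A tibble with `stained_fraction` in \[0, 1\], `stained_area_um2`,
#'   `tissue_area_um2` and `relative_intensity` (mean stained intensity
#'   above cutoff, 0 when nothing is stained).
#' @export
collagen_fraction <- function(collagen, tissue_mask, cutoff) {
  stopifnot(inherits(collagen, "channel_image"))
  if (!is.logical(tissue_mask) ||
      !identical(dim(tissue_mask), dim(collagen$pixels))) {
    abort("`tissue_mask` must be a logical matrix matching the channel.")
  }
  if (!any(tissue_mask)) abort("Empty tissue mask.")
  px <- collagen$pixels[tissue_mask]
  stained <- px > cutoff
  ps2 <- collagen$pixel_size^2
  tibble(
    stained_fraction = mean(stained),
    stained_area_um2 = sum(stained) * ps2,
    tissue_area_um2 = length(px) * ps2,
    relative_intensity = if (any(stained)) mean(px[stained]) else 0)
}
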