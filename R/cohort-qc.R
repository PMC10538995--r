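#' Goldberg cutoffs with Black adjustment
#'
#' Plausibility bounds for the ratio of reported energy intake to basal
#' metabolic rate (EI:BMR). Under accurate reporting, EI:BMR should equal
#' the physical activity level (PAL); the Black-adjusted Goldberg bounds
#' allow for within-subject variation in intake reporting, BMR estimation
#' and PAL:
#'
#' \deqn{bounds = PAL \times \exp\!\left(\mp s \cdot \frac{S/100}{\sqrt{n}}\right),
#'   \quad S = \sqrt{CV_{EI}^2/d + CV_{BMR}^2 + CV_{PAL}^2}}
#'
#' with `n` subjects, `d` days of recording and `s` the SD limit
#' (commonly 2). The bounds are reciprocal-symmetric about PAL on the log
#' scale (`lower * upper = PAL^2`) and collapse to PAL when every CV is 0.
#'
#' @param n Number of subjects (cohort cutoff) or 1 (individual cutoff).
#' @param d Days of dietary recording.
#' @param cv_ei Within-subject CV of daily energy intake, %.
#' @param cv_bmr CV of (estimated) BMR, %.
#' @param cv_pal CV of PAL, %.
#' @param pal Physical activity level (> 0).
#' @param sd_limit Half-width of the plausibility band in SD units.
#' @return Named numeric `c(lower, upper)`.
#' @export
#' @examples
#' goldberg_cutoffs(n = 19, d = 3, cv_ei = 23, cv_bmr = 8.5, cv_pal = 15,
#'                  pal = 1.55)
goldberg_cutoffs <- function(n, d, cv_ei, cv_bmr, cv_pal, pal,
                             sd_limit = 2) {
  if (n < 1 || d < 1) abort("`n` and `d` must be >= 1.")
  if (any(c(cv_ei, cv_bmr, cv_pal) < 0)) abort("CVs must be >= 0.")
  if (pal <= 0) abort("`pal` must be positive.")
  s <- sqrt(cv_ei^2 / d + cv_bmr^2 + cv_pal^2)
  half <- sd_limit * (s / 100) / sqrt(n)
  c(lower = pal * exp(-half), upper = pal * exp(half))
}

#' Classify dietary-reporting plausibility by EI:BMR
#'
#' Labels each record `under`, `plausible` or `over` by comparing its
#' EI:BMR ratio against a plausibility interval (bounds inclusive — a
#' ratio exactly at a cutoff counts as plausible). Defaults are the
#' individual-level Goldberg/Black cutoffs 0.76-2.41; cohort-level
#' screening commonly uses 1.18-1.55.
#'
#' @param diet Data frame with either an `ei_bmr` column or both
#'   `energy_intake` (kcal/day) and `bmr` (kcal/day, > 0); BMR comes from
#'   an external regression model (its coefficients are study-specific and
#'   are never hard-coded here), so it is an input column.
#' @param lower,upper Plausibility bounds; `lower < upper`.
#' @return The input as a tibble with `ei_bmr` and `plausibility`
#'   (`"under"`, `"plausible"`, `"over"`) columns added.
#' @export
#' @examples
#' classify_plausibility(data.frame(energy_intake = 2200, bmr = 1600))
classify_plausibility <- function(diet, lower = 0.76, upper = 2.41) {
  if (lower >= upper) abort("`lower` must be < `upper`.")
  diet <- as_tibble(diet)
  if (!"ei_bmr" %in% names(diet)) {
    if (!all(c("energy_intake", "bmr") %in% names(diet))) {
      abort("Need `ei_bmr` or both `energy_intake` and `bmr` columns.")
    }
    if (any(diet$bmr <= 0)) abort("`bmr` must be positive.")
    diet$ei_bmr <- diet$energy_intake / diet$bmr
  }
  diet$plausibility <- dplyr::case_when(
    diet$ei_bmr < lower ~ "under",
    diet$ei_bmr > upper ~ "over",
    TRUE ~ "plausible")
  diet
}

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' `glucose [mg/dL] x insulin [mU/L] / 405` (the mass-unit convention;
#' numerically equivalent to the molar form glucose [mmol/L] x insulin /
#' 22.5 within 0.5 %).
#'
#' @param glucose Fasting plasma glucose, mg/dL (> 0).
#' @param insulin Fasting plasma insulin, mU/L (> 0).
#' @return HOMA-IR (dimensionless, vectorised).
#' @export
#' @examples
#' homa_ir(glucose = 90, insulin = 4.5)  # 1.0
homa_ir <- function(glucose, insulin) {
  if (any(glucose <= 0, na.rm = TRUE) || any(insulin <= 0, na.rm = TRUE)) {
    abort("`glucose` and `insulin` must be positive.")
  }
  glucose * insulin / 405
}
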