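#' Exercise-induced change scores
#'
#' Per-subject, per-fiber-type delta between two timepoints
#' (`value(to) - value(from)`, e.g. post minus baseline). A subject/type
#' cell missing either timepoint yields a missing delta — never an implied
#' zero.
#'
#' @param data Long tibble with `subject_id`, `timepoint`, `fiber_type`,
#'   `value` (and optionally `outcome`, kept in the grouping).
#' @param from,to Timepoint labels; must differ.
#' @return Tibble: grouping columns plus `delta`.
#' @export
#' @examples
#' sim <- generate_cohort(n_subjects = 4, subject_sd = 0, resid_sd = 0,
#'                        time_effects = c(baseline = 0, post = 0.02,
#'                                         post3h = 0), seed = 1)
#' exercise_delta(sim$data)  # delta = 0.02 everywhere
exercise_delta <- function(data, from = "baseline", to = "post") {
  if (identical(from, to)) abort("`from` and `to` must differ.")
  stopifnot(all(c("subject_id", "timepoint", "fiber_type", "value") %in%
                  names(data)))
  keys <- intersect(c("subject_id", "sex", "fiber_type", "outcome"),
                    names(data))
  wide <- data |>
    dplyr::filter(.data$timepoint %in% c(from, to)) |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(keys),
                       names_from = "timepoint",
                       values_from = "value")
  for (tp in c(from, to)) if (!tp %in% names(wide)) wide[[tp]] <- NA_real_
  wide$delta <- wide[[to]] - wide[[from]]
  dplyr::select(wide, dplyr::all_of(keys), delta = "delta")
}

#' Spearman rank correlation with tie-averaged ranks
#'
#' Rank correlation between two paired vectors: pairs with any missing
#' value are dropped, ties receive average ranks, and the two-sided p-value
#' comes from the t approximation (appropriate in the presence of ties).
#' A constant vector has no rank ordering: rho is undefined and reported
#' missing.
#'
#' @param x,y Numeric vectors of equal length; >= 3 complete pairs
#'   required.
#' @return One-row tibble: `rho`, `p_value`, `n` (complete pairs used).
#' @export
#' @examples
#' spearman_correlation(1:8, c(2, 3, 5, 4, 7, 8, 9, 12))
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant vector: Spearman's rho is undefined.")
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Percent difference relative to a reference mean
#'
#' `100 * (a - b) / b`: how much higher (positive) or lower (negative) `a`
#' is than the reference `b`. Note the asymmetry: `percent_difference(a, b)`
#' is generally not `-percent_difference(b, a)` — always state the
#' reference.
#'
#' @param a Level mean.
#' @param b Reference mean; must be > 0.
#' @return Percent difference (vectorised).
#' @export
#' @examples
#' percent_difference(1.072, 1)  # 7.2 % higher
percent_difference <- function(a, b) {
  if (any(b <= 0, na.rm = TRUE)) {
    abort("Reference mean `b` must be strictly positive.")
  }
  100 * (a - b) / b
}
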