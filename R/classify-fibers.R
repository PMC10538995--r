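#' Assign MHC fiber types by positivity rules
#'
#' Scores each fiber ROI on the MHC I and MHC IIa channels (median interior
#' intensity — robust to nucleus hotspots) and applies the standard
#' double-staining rules: positive for MHC I and negative for MHC IIa is
#' type I; negative/positive is type IIa; negative for both is type IIx
#' (no IIx antibody is needed — IIx is defined by double-negativity);
#' positive for both is a hybrid fiber, which is excluded from all
#' downstream analyses. A score exactly at the cutoff counts as negative
#' (conservative positivity).
#'
#' @param fibers Fiber table from [segment_fibers()] or
#'   [fibers_from_truth()].
#' @param mhc1,mhc2a Co-registered MHC [channel_image]s.
#' @param thresholds Optional named numeric `c(mhc1 = , mhc2a = )` of
#'   positivity cutoffs (a.u.). When `NULL`, each cutoff is derived by
#'   [auto_threshold()] on the per-ROI medians of that channel.
#' @param fallback Optional named numeric of fallback cutoffs used (with a
#'   warning) when a channel's score distribution is not bimodal.
#'
#' @return The fiber table with columns `mhc1_score`, `mhc2a_score`,
#'   `type` (`"I"`, `"IIa"`, `"IIx"`, `"hybrid"`) added, and `included`
#'   updated so hybrid fibers (and border fibers) are excluded.
#' @export
#' @examples
#' sec <- generate_section(section_params(n_fibers = 25,
#'                                        image_size = c(224, 224), seed = 3))
#' fib <- fibers_from_truth(sec$truth)
#' fib <- classify_fibers(fib, sec$channels$mhc1, sec$channels$mhc2a)
#' table(fib$type)
classify_fibers <- function(fibers, mhc1, mhc2a, thresholds = NULL,
                            fallback = NULL) {
  stopifnot(inherits(mhc1, "channel_image"), inherits(mhc2a, "channel_image"))
  check_coregistered(mhc1, mhc2a)
  lab <- fiber_labels(fibers)
  if (!identical(dim(lab), dim(mhc1$pixels))) {
    abort("Fiber label image and channels have different shapes.")
  }
  s1 <- roi_scores(mhc1, fibers)
  s2 <- roi_scores(mhc2a, fibers)

  if (is.null(thresholds)) {
    t1 <- auto_threshold(s1, fallback = fallback[["mhc1"]])
    t2 <- auto_threshold(s2, fallback = fallback[["mhc2a"]])
  } else {
    t1 <- thresholds[["mhc1"]]; t2 <- thresholds[["mhc2a"]]
    if (is.null(t1) || is.null(t2)) {
      abort("`thresholds` must name both `mhc1` and `mhc2a`.")
    }
  }

  pos1 <- s1 > t1   # tie at the cutoff counts as negative
  pos2 <- s2 > t2
  type <- dplyr::case_when(
    pos1 & !pos2 ~ "I",
    !pos1 & pos2 ~ "IIa",
    !pos1 & !pos2 ~ "IIx",
    TRUE ~ "hybrid"
  )
  out <- dplyr::mutate(fibers,
                       mhc1_score = s1, mhc2a_score = s2, type = type,
                       included = .data$included & type != "hybrid")
  attr(out, "thresholds") <- c(mhc1 = t1, mhc2a = t2)
  attr(out, "label") <- lab
  attr(out, "pixel_size") <- fiber_pixel_size(fibers)
  class(out) <- unique(c("fiber_rois", class(out)))
  out
}

#' Per-ROI channel scores
#'
#' Summarises a channel over each fiber's interior pixels (default:
#' median).
#'
#' @param channel A [channel_image].
#' @param fibers A fiber table.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return Numeric vector aligned with `fibers$fiber_id`.
#' @export
roi_scores <- function(channel, fibers, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  lab <- fiber_labels(fibers)
  idx <- lab > 0L
  fun <- if (statistic == "median") median else mean
  sc <- tapply(channel$pixels[idx], lab[idx], fun)
  as.numeric(sc[as.character(fibers$fiber_id)])
}

#' Data-driven positivity cutoff for per-ROI scores
#'
#' Otsu's method on the per-ROI score distribution: the cutoff maximising
#' between-class variance over candidate midpoints between consecutive
#' sorted unique values. Deterministic, and equivariant under affine
#' rescaling of the scores. When the distribution shows no usable
#' bimodality (between-class variance below `bimodality_min` of the total),
#' the function warns and returns `fallback`, or errors if none is given.
#'
#' @param scores Numeric vector of per-ROI scores (>= 2 values).
#' @param fallback Cutoff returned when the distribution is unimodal.
#' @param bimodality_min Minimum fraction of total variance the best split
#'   must explain to be trusted.
#' @return A scalar cutoff; scores strictly above it are "positive".
#' @export
#' @examples
#' auto_threshold(c(rnorm(20, 10), rnorm(20, 100)))
auto_threshold <- function(scores, fallback = NULL, bimodality_min = 0.5) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2) abort("Need at least 2 ROI scores.")
  tot <- stats::var(scores)
  if (tot == 0) {
    return(.threshold_fallback(fallback, "all ROI scores are identical"))
  }
  cut <- otsu_cutoff(scores)
  lo <- scores[scores <= cut]; hi <- scores[scores > cut]
  between <- (length(lo) * (mean(lo) - mean(scores))^2 +
                length(hi) * (mean(hi) - mean(scores))^2) /
    (length(scores) - 1)
  if (length(lo) == 0 || length(hi) == 0 || between / tot < bimodality_min) {
    return(.threshold_fallback(
      fallback, "ROI score distribution does not look bimodal"))
  }
  cut
}

.threshold_fallback <- function(fallback, why) {
  if (is.null(fallback)) {
    abort(paste0(why, " and no fallback cutoff was supplied."))
  }
  warn(paste0(why, "; falling back to the supplied cutoff."))
  fallback
}

# 1-D Otsu: candidate cutoffs are midpoints between consecutive sorted
# unique values; the between-class variance is maximised; ties resolve to
# the lowest candidate. Affine-equivariant by construction.
otsu_cutoff <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2) return(u[1])
  cand <- (u[-1] + u[-length(u)]) / 2
  n <- length(x)
  xs <- sort(x)
  cs <- cumsum(xs)
  # class split index for each candidate: all xs <= cand in class 1
  k <- as.numeric(findInterval(cand, xs))
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  between <- k * (n - k) * (m1 - m2)^2
  cand[which.max(between)]
}

#' Plot per-fiber type calls
#'
#' @param object A classified fiber table (from [classify_fibers()]).
#' @param ... Unused.
#' @return A ggplot of MHC scores coloured by assigned type.
#' @export
autoplot.fiber_rois <- function(object, ...) {
  if (!all(c("mhc1_score", "mhc2a_score", "type") %in% names(object))) {
    abort("Run classify_fibers() before plotting type calls.")
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mhc1_score, y = .data$mhc2a_score,
                               colour = .data$type,
                               shape = .data$included)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "MHC I score (a.u.)", y = "MHC IIa score (a.u.)",
                  colour = "fiber type", shape = "included")
}
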