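#' Fit the fiber-type/time linear mixed model
#'
#' REML linear mixed model for a long-format outcome table: fixed effects
#' for timepoint and fiber type (optionally their interaction and/or sex)
#' and a random intercept per participant. This is the standard model for
#' repeated biopsy designs with cells missing at random: unbalanced and
#' missing cells are handled by the likelihood, without listwise deletion
#' of subjects. The unit of analysis is the per-subject, per-type
#' (per-timepoint) mean — fibers are aggregated before modeling, matching
#' a random structure with participant intercepts only.
#'
#' @param data Long tibble with columns `subject_id`, `timepoint`,
#'   `fiber_type`, `value` (and `sex` if used), at most one row per cell.
#' @param fixed Character vector of fixed-effect terms among
#'   `"time"`, `"fiber_type"`, `"sex"`.
#' @param interaction Add the time x fiber-type interaction.
#' @param level_order Optional named list giving factor level orders,
#'   e.g. `list(timepoint = c("baseline", "post", "post3h"))`.
#' @return An object of class `redox_lmm` wrapping the `lmerMod` fit (with
#'   Satterthwaite-degree-of-freedom machinery), the model formula and the
#'   data. Methods: [tidy()], [glance()], [pairwise_contrasts()].
#' @details A fixed factor with fewer than 2 observed levels makes the
#'   design singular and errors explicitly. Non-convergence errors with the
#'   optimizer diagnostics rather than returning silently.
#' @export
#' @examples
#' sim <- generate_cohort(n_subjects = 8, seed = 2)
#' fit <- fit_redox_lmm(sim$data)
#' tidy(fit)
fit_redox_lmm <- function(data, fixed = c("time", "fiber_type"),
                          interaction = FALSE, level_order = NULL) {
  stopifnot(is.data.frame(data))
  term_map <- c(time = "timepoint", fiber_type = "fiber_type", sex = "sex")
  bad <- setdiff(fixed, names(term_map))
  if (length(bad)) abort(paste0("Unknown fixed term(s): ",
                                paste(bad, collapse = ", ")))
  cols <- unname(term_map[fixed])
  need <- c("subject_id", "value", cols)
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("Missing column(s): ",
                                 paste(miss, collapse = ", ")))

  df <- as.data.frame(data)
  for (cl in cols) {
    lv <- level_order[[cl]] %||% unique(df[[cl]])
    df[[cl]] <- factor(df[[cl]], levels = lv)
    if (nlevels(droplevels(df[[cl]])) < 2) {
      abort(sprintf(
        "Fixed factor `%s` has fewer than 2 observed levels: singular design.",
        cl))
    }
  }
  df$subject_id <- factor(df$subject_id)

  rhs <- paste(cols, collapse = " + ")
  if (interaction && all(c("timepoint", "fiber_type") %in% cols)) {
    rhs <- paste(rhs, "+ timepoint:fiber_type")
  }
  form <- as.formula(paste("value ~", rhs, "+ (1 | subject_id)"))

  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = df, REML = TRUE),
    message = function(m) invokeRestart("muffleMessage"))
  # a non-zero optimizer return code is genuine non-convergence and is
  # fatal — except for exactly-degenerate (zero residual variance) data,
  # where the profiled deviance surface is flat and the estimates are the
  # exact least-squares solution; lme4's post-hoc gradient checks are
  # heuristics that fire spuriously near degeneracy and stay warnings
  code <- fit@optinfo$conv$opt
  if (!is.null(code) && code != 0) {
    degenerate <- stats::sigma(fit) <=
      1e-5 * max(sd(df$value), .Machine$double.eps)
    if (degenerate) {
      warn("Zero residual variance: degenerate noiseless fit.")
    } else {
      fit <- withCallingHandlers(
        lmerTest::lmer(form, data = df, REML = TRUE,
                       control = lme4::lmerControl(optimizer = "bobyqa")),
        message = function(m) invokeRestart("muffleMessage"))
      code <- fit@optinfo$conv$opt
      if (!is.null(code) && code != 0) {
        abort(paste0(
          "Mixed model optimizer failed (code ", code, "): ",
          paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; ")))
      }
    }
  }
  structure(list(model = fit, formula = form, data = as_tibble(df)),
            class = "redox_lmm")
}

#' @export
print.redox_lmm <- function(x, ...) {
  cat("<redox_lmm> ", deparse(x$formula), "\n")
  print(summary(x$model)$coefficients)
  invisible(x)
}

#' @export
tidy.redox_lmm <- function(x, ...) {
  co <- summary(x$model)$coefficients
  tibble(term = rownames(co),
         estimate = co[, "Estimate"],
         std.error = co[, "Std. Error"],
         df = co[, "df"],
         statistic = co[, "t value"],
         p.value = co[, "Pr(>|t|)"])
}

#' @export
glance.redox_lmm <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$model))
  tibble(
    n_obs = stats::nobs(x$model),
    n_subjects = nlevels(x$model@flist$subject_id),
    subject_sd = vc$sdcor[vc$grp == "subject_id"],
    resid_sd = vc$sdcor[vc$grp == "Residual"],
    REMLcrit = lme4::REMLcrit(x$model),
    singular = lme4::isSingular(x$model))
}

#' Variance components of a fitted mixed model
#'
#' @param x A `redox_lmm`.
#' @return Tibble with `component` (`"subject"`, `"residual"`) and `sd`.
#' @export
variance_components <- function(x) {
  stopifnot(inherits(x, "redox_lmm"))
  vc <- as.data.frame(lme4::VarCorr(x$model))
  tibble(component = c("subject", "residual"),
         sd = c(vc$sdcor[vc$grp == "subject_id"],
                vc$sdcor[vc$grp == "Residual"]))
}

#' Omnibus tests for the fixed factors
#'
#' Type III F tests with Satterthwaite denominator degrees of freedom.
#'
#' @param x A `redox_lmm`.
#' @return Tibble: `term`, `statistic`, `num_df`, `den_df`, `p.value`.
#' @export
omnibus_tests <- function(x) {
  stopifnot(inherits(x, "redox_lmm"))
  a <- anova(x$model, type = 3, ddf = "Satterthwaite")
  tibble(term = rownames(a),
         statistic = a[["F value"]],
         num_df = a[["NumDF"]],
         den_df = a[["DenDF"]],
         p.value = a[["Pr(>F)"]])
}

#' Tukey-adjusted pairwise contrasts on estimated marginal means
#'
#' All pairwise comparisons of one factor's estimated marginal means
#' (least-squares means), with family-wise Tukey adjustment over that
#' factor's pairs (cross-factor contrasts are never pooled into the
#' family), Satterthwaite degrees of freedom, and two-sided 95 % CIs.
#' Each contrast is also expressed as a percent difference relative to the
#' later-listed (reference) level — "A is x % higher than B" — with the CI
#' endpoints transformed to the percent scale by dividing by the reference
#' marginal mean.
#'
#' @param x A `redox_lmm`.
#' @param factor Which factor to compare: `"fiber_type"`, `"timepoint"` or
#'   `"sex"`.
#' @param level Confidence level (default 0.95).
#' @return Tibble of `contrast_result` rows: `contrast`, `level_a`,
#'   `level_b` (reference), `estimate`, `se`, `df`, `ci_low`, `ci_high`
#'   (outcome scale), `percent_difference`, `pd_ci_low`, `pd_ci_high`
#'   (percent scale), `p_adjusted`.
#' @export
#' @examples
#' sim <- generate_cohort(n_subjects = 10, seed = 3)
#' fit <- fit_redox_lmm(sim$data)
#' pairwise_contrasts(fit, "fiber_type")
pairwise_contrasts <- function(x, factor = "fiber_type", level = 0.95) {
  stopifnot(inherits(x, "redox_lmm"))
  if (!factor %in% all.vars(x$formula)) {
    abort(sprintf("Factor `%s` is not in the fitted model.", factor))
  }
  emm <- emmeans::emmeans(x$model, specs = factor,
                          lmer.df = "satterthwaite")
  emm_tab <- as.data.frame(emm)
  prs <- summary(emmeans::contrast(emm, method = "pairwise",
                                   adjust = "tukey"),
                 infer = c(TRUE, TRUE), level = level)
  sides <- strsplit(as.character(prs$contrast), " - ", fixed = TRUE)
  level_a <- vapply(sides, `[`, "", 1)
  level_b <- vapply(sides, `[`, "", 2)
  ref_mean <- emm_tab$emmean[match(level_b, emm_tab[[1]])]

  out <- tibble(
    contrast = as.character(prs$contrast),
    level_a = level_a,
    level_b = level_b,
    estimate = prs$estimate,
    se = prs$SE,
    df = prs$df,
    ci_low = prs$lower.CL,
    ci_high = prs$upper.CL,
    percent_difference = 100 * prs$estimate / ref_mean,
    pd_ci_low = 100 * prs$lower.CL / ref_mean,
    pd_ci_high = 100 * prs$upper.CL / ref_mean,
    p_adjusted = prs$p.value)
  # a (numerically) zero difference estimated with (numerically) zero
  # uncertainty — degenerate noiseless designs — is certainly null, not 0/0
  scale <- max(abs(emm_tab$emmean), 1)
  degen <- !is.na(out$estimate) & abs(out$estimate) <= 1e-8 * scale &
    (out$se <= 1e-8 * scale | is.nan(out$p_adjusted))
  out$estimate[degen] <- 0
  out$percent_difference[degen] <- 0
  out$p_adjusted[degen] <- 1
  class(out) <- c("contrast_results", class(out))
  out
}

#' Plot pairwise contrasts
#'
#' @param object A tibble from [pairwise_contrasts()].
#' @param ... Unused.
#' @return A ggplot of percent differences with their CIs.
#' @export
autoplot.contrast_results <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$contrast,
                               y = .data$percent_difference)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$pd_ci_low,
                                          ymax = .data$pd_ci_high)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "percent difference vs reference level (%)")
}
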