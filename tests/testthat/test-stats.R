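test_that("a noiseless cohort is recovered exactly by the mixed model", {
  sim <- generate_cohort(n_subjects = 8, subject_sd = 0, resid_sd = 0,
                         time_effects = c(baseline = 0, post = 0.012,
                                          post3h = 0.004),
                         seed = 61)
  fit <- suppressWarnings(fit_redox_lmm(sim$data))
  td <- tidy(fit)
  planted <- c(`(Intercept)` = 0.452 + 0.0325,
               timepointpost = 0.012, timepointpost3h = 0.004,
               fiber_typeIIa = -0.0325, fiber_typeIIx = -0.066)
  expect_lt(max(abs(td$estimate - unname(planted[td$term]))), 1e-8)
})

test_that("variance components are recovered within 10% at 200 subjects", {
  sim <- generate_cohort(n_subjects = 200, subject_sd = 1.0,
                         resid_sd = 0.5, grand_mean = 10,
                         type_effects = c(I = 1, IIa = 0, IIx = -1),
                         seed = 62)
  fit <- fit_redox_lmm(sim$data)
  vc <- variance_components(fit)
  expect_lt(abs(vc$sd[vc$component == "subject"] - 1.0), 0.1)
  expect_lt(abs(vc$sd[vc$component == "residual"] - 0.5), 0.05)
})

test_that("degenerate subject variance reduces to ordinary least squares", {
  sim <- generate_cohort(n_subjects = 12, subject_sd = 0, resid_sd = 0.02,
                         seed = 63)
  fit <- suppressWarnings(fit_redox_lmm(sim$data))
  ols <- lm(value ~ timepoint + fiber_type,
            data = transform(as.data.frame(sim$data),
                             timepoint = factor(timepoint,
                                                c("baseline", "post",
                                                  "post3h")),
                             fiber_type = factor(fiber_type,
                                                 c("I", "IIa", "IIx"))))
  expect_lt(max(abs(tidy(fit)$estimate - unname(coef(ols)))), 1e-6)
})

test_that("singular designs and unknown terms error explicitly", {
  sim <- generate_cohort(n_subjects = 6, seed = 64)
  one_tp <- dplyr::filter(sim$data, timepoint == "baseline")
  expect_error(fit_redox_lmm(one_tp), "fewer than 2")
  expect_error(fit_redox_lmm(sim$data, fixed = c("time", "banana")),
               "Unknown fixed term")
})

test_that("pairwise contrasts cover all level pairs with Tukey adjustment", {
  sim <- generate_cohort(n_subjects = 12, seed = 65)
  fit <- fit_redox_lmm(sim$data)
  pc <- pairwise_contrasts(fit, "fiber_type")
  expect_equal(nrow(pc), 3)           # 3-level factor -> 3 pairs
  expect_true(all(pc$p_adjusted >= 0 & pc$p_adjusted <= 1))
  expect_true(all(pc$ci_low <= pc$estimate & pc$estimate <= pc$ci_high))
  expect_true(all(pc$pd_ci_low <= pc$percent_difference &
                    pc$percent_difference <= pc$pd_ci_high))
  # Tukey-adjusted p is never smaller than the unadjusted p
  emm <- emmeans::emmeans(fit$model, "fiber_type")
  raw <- summary(emmeans::contrast(emm, "pairwise", adjust = "none"))
  expect_true(all(pc$p_adjusted >= raw$p.value - 1e-12))
  expect_error(pairwise_contrasts(fit, "sex"), "not in the fitted model")
})

test_that("identical level means in a noiseless fit give a certain null", {
  sim <- generate_cohort(n_subjects = 6, subject_sd = 0.05, resid_sd = 0,
                         type_effects = c(I = 0, IIa = 0, IIx = 0),
                         seed = 66)
  fit <- suppressWarnings(fit_redox_lmm(sim$data))
  pc <- suppressWarnings(pairwise_contrasts(fit, "fiber_type"))
  expect_equal(pc$estimate, rep(0, 3))
  expect_equal(pc$percent_difference, rep(0, 3))
  expect_equal(pc$p_adjusted, rep(1, 3))
})

test_that("percent differences mirror the reporting convention", {
  expect_equal(percent_difference(1, 1), 0)
  expect_equal(percent_difference(1.072, 1), 7.2, tolerance = 1e-12)
  # not antisymmetric: state the reference
  expect_false(isTRUE(all.equal(percent_difference(3, 2),
                                -percent_difference(2, 3))))
  expect_error(percent_difference(1, 0), "positive")
})

test_that("exercise deltas subtract timepoints per subject and type", {
  sim <- generate_cohort(n_subjects = 5, subject_sd = 0, resid_sd = 0,
                         time_effects = c(baseline = 0, post = 0.02,
                                          post3h = 0.005),
                         seed = 67)
  d <- exercise_delta(sim$data, from = "baseline", to = "post")
  expect_equal(unique(d$delta), 0.02, tolerance = 1e-12)
  # removing a baseline row yields a missing delta, not zero
  drop1 <- dplyr::filter(sim$data,
                         !(subject_id == "S01" & timepoint == "baseline" &
                             fiber_type == "I"))
  d2 <- exercise_delta(drop1)
  expect_true(is.na(d2$delta[d2$subject_id == "S01" & d2$fiber_type == "I"]))
  expect_error(exercise_delta(sim$data, from = "post", to = "post"),
               "must differ")
})

test_that("Spearman correlation matches the rank-enumeration oracle", {
  expect_equal(spearman_correlation(1:9, (1:9)^3)$rho, 1)
  expect_equal(spearman_correlation(1:9, -(1:9))$rho, -1)
  withr::with_seed(68, {
    for (i in 1:50) {
      x <- sample(1:4, 7, replace = TRUE)   # heavy ties
      y <- sample(1:4, 7, replace = TRUE)
      if (sd(x) == 0 || sd(y) == 0) next
      expect_equal(spearman_correlation(x, y)$rho,
                   brute_force_spearman(x, y), tolerance = 1e-12)
    }
  })
  expect_warning(out <- spearman_correlation(rep(1, 5), 1:5), "undefined")
  expect_true(is.na(out$rho))
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
  # incomplete pairs are dropped
  expect_equal(spearman_correlation(c(1, 2, 3, NA, 5),
                                    c(2, 4, 6, 8, 10))$n, 4)
})

test_that("MAR deletion moves planted estimates by less than their SE", {
  shifts <- vapply(1:12, function(i) {
    full <- generate_cohort(n_subjects = 19, seed = i)
    fit_f <- fit_redox_lmm(full$data)
    miss <- generate_cohort(n_subjects = 19, missing_rate = 0.2, seed = i)
    fit_m <- fit_redox_lmm(miss$data)
    tf <- tidy(fit_f); tm <- tidy(fit_m)
    idx <- tf$term == "fiber_typeIIa"
    abs(tf$estimate[idx] - tm$estimate[idx]) / tm$std.error[idx]
  }, numeric(1))
  expect_lt(median(shifts), 1)
})

test_that("result objects expose tidy, glance and autoplot surfaces", {
  sim <- generate_cohort(n_subjects = 8, seed = 70)
  fit <- fit_redox_lmm(sim$data)
  expect_s3_class(tidy(fit), "tbl_df")
  g <- glance(fit)
  expect_equal(g$n_subjects, 8)
  pc <- pairwise_contrasts(fit, "fiber_type")
  expect_s3_class(autoplot(pc), "ggplot")
  om <- omnibus_tests(fit)
  expect_true(all(c("timepoint", "fiber_type") %in% om$term))
})
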