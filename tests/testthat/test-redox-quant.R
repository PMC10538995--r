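test_that("background estimation is exact without noise and unbiased with", {
  sec <- generate_section(small_params(seed = 41, noise_sd = 0))
  fib <- fibers_from_truth(sec$truth)
  expect_equal(estimate_background(sec$channels$nadh, fib),
               sec$truth$background_level)

  noisy <- generate_section(small_params(seed = 42, noise_sd = 8))
  fibn <- fibers_from_truth(noisy$truth)
  lab <- fiber_labels(fibn)
  n_bg <- sum(lab == 0)
  expect_gte(n_bg, 1e4)
  b <- estimate_background(noisy$channels$nadh, fibn)
  se_median <- 1.2533 * 8 / sqrt(n_bg)
  expect_lt(abs(b - noisy$truth$background_level), 3 * se_median + 0.5)
})

test_that("ROIs tiling the whole image force an explicit background", {
  lab <- matrix(1L, 30, 30)
  fib <- fibers_from_label(lab, 1)
  ch <- channel_image(matrix(100, 30, 30), "NADH", 1)
  expect_error(estimate_background(ch, fib), "explicit background")
})

test_that("per-fiber intensity is mean minus background, floored at zero", {
  fx <- two_fiber_fixture(level1 = 500, level2 = 50, background = 100)
  q <- quantify_fibers(fx$channel, fx$fibers, background = 100)
  expect_equal(q$intensity[1], 400)
  expect_equal(q$intensity[2], 0)           # dimmer than background
  expect_false(q$floored[1])
  expect_true(q$floored[2])                 # flagged, never negative
})

test_that("saturated fibers are flagged", {
  fx <- two_fiber_fixture(level1 = 4095, level2 = 900, background = 100)
  ch <- channel_image(fx$channel$pixels, "Fp", 1, saturation = 4095)
  q <- quantify_fibers(ch, fx$fibers, background = 100)
  expect_true(q$saturated[1])
  expect_false(q$saturated[2])
})

test_that("pooling across acquisitions requires an explicit rescale", {
  fx <- two_fiber_fixture()
  ref <- channel_image(fx$channel$pixels, "Fp", 1, exposure = 10)
  other <- channel_image(fx$channel$pixels, "Fp", 1, exposure = 20)
  expect_error(
    quantify_fibers(other, fx$fibers, background = 0, reference = ref),
    "cannot be pooled")
  q <- quantify_fibers(other, fx$fibers, background = 0, reference = ref,
                       rescale = 0.5)
  expect_equal(q$intensity[1], 250)
})

test_that("redox ratio obeys its closed forms and algebra", {
  expect_equal(redox_ratio(2, 2), 0.5)
  expect_equal(redox_ratio(0, 5), 0)
  expect_equal(redox_ratio(3, 1), 0.75)
  expect_warning(r <- redox_ratio(0, 0), "undefined")
  expect_true(is.na(r))
  expect_error(redox_ratio(-1, 2), "nonnegative")
  withr::with_seed(8, {
    fp <- runif(500, 0, 100); nadh <- runif(500, 1e-6, 100)
    k <- runif(500, 0.01, 50)
  })
  r <- redox_ratio(fp, nadh)
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(redox_ratio(k * fp, k * nadh), r, tolerance = 1e-12)
  # strictly monotone in each argument
  expect_true(all(redox_ratio(fp + 1, nadh) > r))
  expect_true(all(redox_ratio(fp, nadh + 1) < r))
})

test_that("mean-of-ratios differs from ratio-of-means and we use the former", {
  # constructed counterexample: two fibers
  fp <- c(1, 30); nadh <- c(9, 10)
  mean_of_ratios <- mean(redox_ratio(fp, nadh))     # (0.1 + 0.75) / 2
  ratio_of_means <- redox_ratio(mean(fp), mean(nadh))
  expect_false(isTRUE(all.equal(mean_of_ratios, ratio_of_means)))

  lab <- matrix(0L, 20, 40)
  lab[5:15, 3:18] <- 1L; lab[5:15, 23:38] <- 2L
  fib <- fibers_from_label(lab, 1)
  mkch <- function(levels, channel) {
    px <- matrix(0, 20, 40)
    for (k in 1:2) px[lab == k] <- levels[k]
    channel_image(px, channel, 1)
  }
  fib$type <- c("I", "I")
  out <- quantify_redox(fib, mkch(nadh, "NADH"), mkch(fp, "Fp"),
                        background = c(nadh = 0, fp = 0))
  expect_equal(mean(out$redox_ratio), mean_of_ratios, tolerance = 1e-12)
})

test_that("type-wise Fp ordering I > IIa > IIx survives noise", {
  kept <- vapply(1:8, function(s) {
    sec <- generate_section(small_params(seed = 300 + s, n_fibers = 40,
                                         image_size = c(288, 288)))
    fib <- fibers_from_truth(sec$truth)
    fib$type <- sec$truth$fibers$type
    fib <- quantify_redox(fib, sec$channels$nadh, sec$channels$fp)
    fp_ordering_holds(summarise_by_type(fib))
  }, logical(1))
  expect_true(all(kept))
})

test_that("calibration fitting recovers planted lines exactly", {
  conc <- rep(c(0.01, 0.05, 0.1, 0.5, 1), each = 3)
  ser <- data.frame(concentration = conc, intensity = 5 + 2 * conc)
  fit <- fit_calibration(ser)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$interassay_cv, 0)
  g <- glance(fit)
  expect_equal(g$n_levels, 5)
  expect_error(fit_calibration(
    data.frame(concentration = rep(1, 6), intensity = rnorm(6))),
    "distinct")
  expect_error(fit_calibration(
    data.frame(concentration = c(-1, 1, 2), intensity = 1:3)),
    "positive")
})

test_that("interassay CV is the mean per-level CV", {
  ser <- data.frame(
    concentration = rep(c(0.1, 0.5, 1), each = 3),
    intensity = c(10, 10, 10, 20, 22, 18, 30, 30, 30))
  fit <- fit_calibration(ser)
  cv_expected <- mean(c(0, sd(c(20, 22, 18)) / 20 * 100, 0))
  expect_equal(fit$interassay_cv, cv_expected, tolerance = 1e-12)
})

test_that("collagen fraction counts planted stained pixels exactly", {
  px <- matrix(10, 200, 200)
  withr::with_seed(9, idx <- sample(length(px), 300))  # 0.75 % of 40,000
  px[idx] <- 500
  ch <- channel_image(px, "COLLAGEN", 1)
  tissue <- matrix(TRUE, 200, 200)
  out <- collagen_fraction(ch, tissue, cutoff = 100)
  expect_equal(out$stained_fraction, 0.0075, tolerance = 1e-15)
  expect_equal(collagen_fraction(
    channel_image(matrix(10, 20, 20), "COLLAGEN", 1),
    matrix(TRUE, 20, 20), cutoff = 100)$stained_fraction, 0)
  expect_equal(collagen_fraction(
    channel_image(matrix(500, 20, 20), "COLLAGEN", 1),
    matrix(TRUE, 20, 20), cutoff = 100)$stained_fraction, 1)
  expect_error(collagen_fraction(ch, matrix(FALSE, 200, 200), 100),
               "Empty tissue mask")
})
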