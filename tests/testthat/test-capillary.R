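test_that("capillary detection exactly recovers the planted set", {
  for (noise in c(0, 8)) {
    sec <- generate_section(small_params(seed = 51, noise_sd = noise))
    det <- detect_capillaries(sec$channels$cap)
    truth <- sec$truth$capillaries
    expect_equal(nrow(det), nrow(truth))
    # match each detection to its nearest planted capillary within 1 px
    d <- vapply(seq_len(nrow(det)), function(k) {
      sqrt(min((truth$row - det$row[k])^2 + (truth$col - det$col[k])^2))
    }, numeric(1))
    expect_lt(max(d), 1.01)
  }
})

test_that("blank channels yield no detections", {
  blank <- channel_image(matrix(50, 64, 64), "CAP", 1.5)
  expect_equal(nrow(detect_capillaries(blank)), 0)
  expect_equal(nrow(nuclei_count(channel_image(matrix(50, 64, 64),
                                               "DAPI", 1.5))), 0)
})

test_that("two merged blobs give one flagged detection with a warning", {
  px <- matrix(10, 40, 40)
  # two discs 3 px apart merge into one blob wider than the capillary range
  for (ctr in list(c(20, 18), c(20, 23))) {
    for (di in -2:2) for (dj in -2:2) {
      if (di^2 + dj^2 <= 4) px[ctr[1] + di, ctr[2] + dj] <- 500
    }
  }
  ch <- channel_image(px, "CAP", 1.5)
  expect_warning(det <- detect_capillaries(ch), "merged")
  expect_equal(nrow(det), 1)
  expect_true(det$merged)
})

test_that("nuclei are counted exactly on noiseless sections", {
  sec <- generate_section(small_params(seed = 52, noise_sd = 0))
  det <- nuclei_count(sec$channels$dapi)
  expect_equal(nrow(det), nrow(sec$truth$nuclei))
  fib <- fibers_from_truth(sec$truth)
  cm <- build_contact_graph(fib, sec$truth$capillaries)
  panel <- capillary_panel(fib, cm, nuclei = det)
  expect_equal(panel$nuclei_density, nrow(sec$truth$nuclei) / cm$area_mm2)
})

test_that("contact degrees follow the constructed geometry", {
  # three fibers meeting at a junction; capillary at the shared vertex
  lab <- matrix(0L, 60, 60)
  lab[5:28, 5:28] <- 1L
  lab[5:28, 34:55] <- 2L
  lab[34:55, 5:55] <- 3L
  fib <- fibers_from_label(lab, 1)
  caps <- tibble::tibble(capillary_id = 1:2,
                         row = c(31, 15), col = c(31, 15))
  cm <- build_contact_graph(fib, caps, contact_tolerance = 8)
  deg <- table(factor(cm$edges$capillary_id, levels = 1:2))
  expect_equal(unname(deg[["1"]]), 3)   # junction capillary touches all 3
  expect_equal(unname(deg[["2"]]), 1)   # interior capillary touches 1
  expect_error(build_contact_graph(fib, caps, contact_tolerance = -1))
})

test_that("the contact graph is invariant under fiber relabeling", {
  sec <- generate_section(small_params(seed = 53))
  fib <- fibers_from_truth(sec$truth)
  cm <- build_contact_graph(fib, sec$truth$capillaries)
  # permute labels
  n <- nrow(fib)
  withr::with_seed(3, perm <- sample(n))
  lab2 <- fiber_labels(fib)
  lab2[lab2 > 0] <- perm[lab2[lab2 > 0]]
  fib2 <- fibers_from_label(lab2, fiber_pixel_size(fib))
  cm2 <- build_contact_graph(fib2, sec$truth$capillaries)
  e1 <- dplyr::arrange(dplyr::mutate(cm$edges,
                                     fiber_id = perm[fiber_id]),
                       capillary_id, fiber_id)
  e2 <- dplyr::arrange(cm2$edges, capillary_id, fiber_id)
  expect_equal(as.data.frame(e1), as.data.frame(e2))
})

test_that("the hand-countable two-fiber panel matches enumeration", {
  # 2 fibers, 4 capillaries with fiber contact degrees (3, 2) over
  # 0.01 mm^2: two gap capillaries touch both fibers, one touches only
  # fiber 1, one sits beyond tolerance of either (still counted in CD)
  lab <- matrix(0L, 80, 80)
  lab[10:38, 10:70] <- 1L
  lab[46:70, 10:70] <- 2L
  fib <- fibers_from_label(lab, 1)
  caps <- tibble::tibble(capillary_id = 1:4,
                         row = c(42, 42, 5, 79),
                         col = c(20, 60, 30, 30))
  cm <- build_contact_graph(fib, caps, contact_tolerance = 5,
                            area_mm2 = 0.01)
  panel <- capillary_panel(fib, cm, dd = FALSE)
  expect_equal(panel$capillary_density, 400)
  expect_equal(panel$cf_ratio, 2)
  expect_equal(panel$cc, 2.5)
  expect_equal(panel$sharing_factor, 1.25)
  oracle <- brute_force_panel(cm$edges, 4, 2, 0.01, fib$fiber_id,
                              fib$area_um2)
  expect_equal(panel$capillary_density, oracle$capillary_density)
  expect_equal(panel$cc, oracle$cc)
  expect_equal(panel$cc_per_fa, oracle$cc_per_fa)
  # handshake identity
  expect_equal(sum(table(cm$edges$capillary_id)), nrow(cm$edges))
  expect_equal(sum(table(cm$edges$fiber_id)), nrow(cm$edges))
})

test_that("an empty capillary set gives zero densities and missing SF", {
  lab <- matrix(0L, 40, 40); lab[5:35, 5:35] <- 1L
  fib <- fibers_from_label(lab, 1)
  cm <- build_contact_graph(fib, tibble::tibble(
    capillary_id = integer(), row = numeric(), col = numeric()))
  panel <- capillary_panel(fib, cm, dd = FALSE)
  expect_equal(panel$capillary_density, 0)
  expect_equal(panel$cf_ratio, 0)
  expect_equal(panel$cc, 0)
  expect_true(is.na(panel$sharing_factor))
})

test_that("duplicating capillaries doubles CD, C:F, CC but not SF", {
  sec <- generate_section(small_params(seed = 54))
  fib <- fibers_from_truth(sec$truth)
  caps <- sec$truth$capillaries
  cm1 <- build_contact_graph(fib, caps)
  p1 <- capillary_panel(fib, cm1, dd = FALSE)
  caps2 <- dplyr::bind_rows(caps,
                            dplyr::mutate(caps,
                                          capillary_id = capillary_id +
                                            nrow(caps)))
  cm2 <- build_contact_graph(fib, caps2)
  p2 <- capillary_panel(fib, cm2, dd = FALSE)
  expect_equal(p2$capillary_density, 2 * p1$capillary_density)
  expect_equal(p2$cf_ratio, 2 * p1$cf_ratio)
  expect_equal(p2$cc, 2 * p1$cc)
  expect_equal(p2$sharing_factor, p1$sharing_factor)
})

test_that("diffusion distances match the brute-force oracle", {
  # square fiber with a central capillary
  lab <- matrix(0L, 41, 41); lab[6:36, 6:36] <- 1L
  fib <- fibers_from_label(lab, 2)     # 2 µm/px
  caps <- tibble::tibble(capillary_id = 1L, row = 21, col = 21)
  dd <- diffusion_distances(fib, caps)
  oracle <- brute_force_distance(c(41, 41), caps)
  d_in <- oracle[lab == 1L]
  expect_lt(abs(dd$avg_dd_um - unname(quantile(d_in, 0.5)) * 2), 2)
  expect_lt(abs(dd$max_dd_um - unname(quantile(d_in, 0.95)) * 2), 2)
  expect_gte(dd$max_dd_um, dd$avg_dd_um)

  # capillaries at every boundary pixel: avg DD at most half the inradius
  is_bnd <- lab == 1L
  inner <- matrix(FALSE, 41, 41)
  inner[2:40, 2:40] <- lab[1:39, 2:40] == 1L & lab[3:41, 2:40] == 1L &
    lab[2:40, 1:39] == 1L & lab[2:40, 3:41] == 1L
  bnd <- which(is_bnd & !inner, arr.ind = TRUE)
  caps_b <- tibble::tibble(capillary_id = seq_len(nrow(bnd)),
                           row = bnd[, 1], col = bnd[, 2])
  dd_b <- diffusion_distances(fib, caps_b)
  inradius_um <- 15 * 2
  expect_lte(dd_b$avg_dd_um, inradius_um / 2)
})

test_that("diffusion distances are translation invariant", {
  lab <- matrix(0L, 60, 60); lab[5:25, 5:25] <- 1L
  caps <- tibble::tibble(capillary_id = 1:2, row = c(10, 26),
                         col = c(10, 26))
  lab2 <- matrix(0L, 60, 60); lab2[25:45, 25:45] <- 1L
  caps2 <- dplyr::mutate(caps, row = row + 20, col = col + 20)
  d1 <- diffusion_distances(fibers_from_label(lab, 1.5), caps)
  d2 <- diffusion_distances(fibers_from_label(lab2, 1.5), caps2)
  expect_equal(d1$avg_dd_um, d2$avg_dd_um, tolerance = 1e-9)
  expect_equal(d1$max_dd_um, d2$max_dd_um, tolerance = 1e-9)
})

test_that("regression-form distances are config-gated and monotone", {
  expect_error(diffusion_distances_regression(2.3, 5500), "disabled")
  const <- list(max_dd = function(cf, fa) 35, avg_dd = function(cf, fa) 18)
  out <- diffusion_distances_regression(1.7, 1234, const)
  expect_equal(out$max_dd_um, 35)
  expect_equal(out$avg_dd_um, 18)
  expect_equal(out$method, "regression")
  pow <- list(max_dd = function(cf, fa) 0.415 * (cf * fa)^0.477,
              avg_dd = function(cf, fa) 0.207 * (cf * fa)^0.232)
  fa <- seq(2000, 8000, by = 500)
  vals <- diffusion_distances_regression(2.3, fa, pow)
  expect_true(all(diff(vals$max_dd_um) > 0))
  expect_true(all(diff(vals$avg_dd_um) > 0))
})
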