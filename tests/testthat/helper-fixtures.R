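# Shared fixtures and independent oracles, all built in code.

# small, quick section parameters for unit tests
small_params <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_fibers = 25, image_size = c(224, 224), seed = seed),
    list(...))
  do.call(section_params, args)
}

# hand-built two-fiber section: two rectangular fibers separated by a gap,
# on a uniform background, with explicit channel intensities
two_fiber_fixture <- function(gap = 4, background = 100,
                              level1 = 500, level2 = 700,
                              pixel_size = 1, size = 60) {
  lab <- matrix(0L, size, size)
  half <- floor((size - gap) / 2)
  lab[6:(size - 5), 6:(half - 1)] <- 1L
  lab[6:(size - 5), (half + gap):(size - 5)] <- 2L
  px <- matrix(background, size, size)
  px[lab == 1L] <- level1
  px[lab == 2L] <- level2
  list(label = lab,
       fibers = fibers_from_label(lab, pixel_size),
       channel = channel_image(px, "Fp", pixel_size))
}

# brute-force per-pixel nearest-capillary distances (oracle for the
# distance-transform path)
brute_force_distance <- function(dims, capillaries) {
  out <- matrix(NA_real_, dims[1], dims[2])
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      out[i, j] <- sqrt(min((capillaries$row - i)^2 +
                              (capillaries$col - j)^2))
    }
  }
  out
}

# brute-force Spearman's rho: explicit average ranks (counting smaller
# values and averaging tie positions), then the Pearson product-moment
# formula on the ranks
brute_force_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) {
      smaller <- sum(v < vi)
      ties <- sum(v == vi)
      smaller + (ties + 1) / 2
    }, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# brute-force capillarization panel by direct enumeration over the edges
brute_force_panel <- function(edges, n_cap, n_fib, area_mm2, fiber_ids,
                              areas_um2) {
  degree <- vapply(fiber_ids,
                   function(f) sum(edges$fiber_id == f), numeric(1))
  cc <- sum(degree) / n_fib
  cf <- n_cap / n_fib
  list(capillary_density = n_cap / area_mm2,
       cf_ratio = cf,
       cc = cc,
       sharing_factor = if (n_cap > 0) cc / cf else NA_real_,
       cc_per_fa = sum(degree / areas_um2) / n_fib * 1000)
}

# match recovered ROIs to truth fibers by maximal pixel overlap; returns a
# tibble of (truth_id, recovered_id, jaccard)
match_to_truth <- function(truth_label, recovered_label) {
  both <- truth_label > 0 & recovered_label > 0
  tab <- table(truth = truth_label[both], rec = recovered_label[both])
  truth_ids <- as.integer(rownames(tab))
  rec_ids <- as.integer(colnames(tab)[apply(tab, 1, which.max)])
  jac <- vapply(seq_along(truth_ids), function(i) {
    t <- truth_ids[i]; r <- rec_ids[i]
    sum(truth_label == t & recovered_label == r) /
      sum(truth_label == t | recovered_label == r)
  }, numeric(1))
  tibble::tibble(truth_id = truth_ids, recovered_id = rec_ids,
                 jaccard = jac)
}

# Fp ordering I > IIa > IIx among the fiber types present in a summary
# (adjacent comparisons are vacuously true when a type is absent)
fp_ordering_holds <- function(byt) {
  g <- function(ty) if (ty %in% byt$type) byt$fp[byt$type == ty] else NULL
  ok <- TRUE
  if (!is.null(g("I")) && !is.null(g("IIa"))) ok <- ok && g("I") > g("IIa")
  if (!is.null(g("IIa")) && !is.null(g("IIx"))) ok <- ok && g("IIa") > g("IIx")
  if (!is.null(g("I")) && !is.null(g("IIx"))) ok <- ok && g("I") > g("IIx")
  ok
}

# full segment -> classify run against a simulated section
segment_and_classify <- function(sec) {
  fib <- segment_fibers(sec$channels$mhc1, sec$channels$mhc2a,
                        hint = sec$channels$fp)
  classify_fibers(fib, sec$channels$mhc1, sec$channels$mhc2a)
}
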