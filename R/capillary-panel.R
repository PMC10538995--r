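#' Section-level capillarization panel
#'
#' Computes the standard capillarization morphometrics from a contact
#' graph:
#' * capillary density CD = capillaries / analyzed area (per mm^2);
#' * capillary-to-fiber ratio C:F = capillaries / fibers;
#' * capillary contacts CC = mean contact degree over fibers;
#' * sharing factor SF = CC / C:F (exact per-section identity);
#' * CC/FA = mean over fibers of (degree / fiber area in um^2) x 1,000;
#' * maximal and average O2 diffusion distances (95th / 50th percentile of
#'   the per-pixel distance to the nearest capillary, averaged over
#'   fibers), from [diffusion_distances()];
#' * nuclei density when nuclei are supplied.
#'
#' With no capillaries CD, C:F and CC are 0 and SF is undefined (`NA`).
#' Capillaries contacting no fiber still count in CD and C:F; they simply
#' contribute no contacts.
#'
#' @param fibers Fiber table (areas in um^2).
#' @param cap_map A `capillary_map` from [build_contact_graph()].
#' @param nuclei Optional nuclei tibble (e.g. [nuclei_count()]).
#' @param dd Logical; compute geometric diffusion distances (default TRUE).
#' @return One-row tibble: `n_fibers`, `n_capillaries`, `area_mm2`,
#'   `capillary_density`, `cf_ratio`, `cc`, `sharing_factor`, `cc_per_fa`,
#'   `max_dd_um`, `avg_dd_um`, `nuclei_density`.
#' @export
#' @examples
#' sec <- generate_section(section_params(n_fibers = 25,
#'                                        image_size = c(224, 224), seed = 2))
#' fib <- fibers_from_truth(sec$truth)
#' cm <- build_contact_graph(fib, sec$truth$capillaries)
#' capillary_panel(fib, cm, nuclei = sec$truth$nuclei)
capillary_panel <- function(fibers, cap_map, nuclei = NULL, dd = TRUE) {
  stopifnot(inherits(cap_map, "capillary_map"))
  n_fib <- nrow(fibers)
  if (n_fib == 0) abort("Zero fibers: panel undefined.")
  area <- cap_map$area_mm2
  if (area <= 0) abort("Analyzed area must be positive.")
  n_cap <- nrow(cap_map$capillaries)

  degree <- tabulate(match(cap_map$edges$fiber_id, fibers$fiber_id),
                     nbins = n_fib)
  cd <- n_cap / area
  cf <- n_cap / n_fib
  cc <- mean(degree)
  sf <- if (n_cap > 0) cc / cf else NA_real_
  cc_fa <- mean(degree / fibers$area_um2) * 1000

  if (dd && n_cap > 0) {
    dd_tab <- diffusion_distances(fibers, cap_map$capillaries)
    max_dd <- mean(dd_tab$max_dd_um)
    avg_dd <- mean(dd_tab$avg_dd_um)
  } else {
    max_dd <- NA_real_
    avg_dd <- NA_real_
  }

  tibble(
    n_fibers = n_fib, n_capillaries = n_cap, area_mm2 = area,
    capillary_density = cd, cf_ratio = cf, cc = cc,
    sharing_factor = sf, cc_per_fa = cc_fa,
    max_dd_um = max_dd, avg_dd_um = avg_dd,
    nuclei_density = if (is.null(nuclei)) NA_real_ else nrow(nuclei) / area)
}

#' Geometric O2 diffusion distances per fiber
#'
#' For every interior pixel of each fiber, the Euclidean distance to the
#' nearest capillary centre (via the distance transform of the capillary
#' point image). The maximal diffusion distance is the distance within
#' which 95 % of the fiber's area is served by a capillary (95th
#' percentile); the average diffusion distance is where 50 % of the area
#' is served (50th percentile). Distances are reported in um.
#'
#' @param fibers Fiber table.
#' @param capillaries Tibble with `row`, `col` capillary centres (px);
#'   at least one — with none the distances are undefined.
#' @param probs Served-area fractions for (average, maximal); fixed
#'   defaults `c(0.5, 0.95)`.
#' @return Tibble: `fiber_id`, `avg_dd_um`, `max_dd_um`.
#' @export
diffusion_distances <- function(fibers, capillaries,
                                probs = c(0.5, 0.95)) {
  if (nrow(capillaries) == 0) {
    abort("No capillaries in section: diffusion distances undefined.")
  }
  lab <- fiber_labels(fibers)
  ps <- fiber_pixel_size(fibers)
  dist_px <- nearest_capillary_distance(dim(lab), capillaries)
  idx <- lab > 0L
  d <- dist_px[idx]
  f <- lab[idx]
  q <- tapply(d, f, quantile, probs = probs, names = FALSE)
  q <- do.call(rbind, q[as.character(fibers$fiber_id)])
  tibble(fiber_id = fibers$fiber_id,
         avg_dd_um = q[, 1] * ps,
         max_dd_um = q[, 2] * ps)
}

#' Per-pixel distance to the nearest capillary
#'
#' Distance transform of the capillary point image: each pixel's Euclidean
#' distance (in px) to the nearest capillary centre.
#'
#' @param dims `c(rows, cols)` of the section.
#' @param capillaries Tibble with `row`, `col` (px).
#' @return Numeric matrix of distances (px).
#' @export
nearest_capillary_distance <- function(dims, capillaries) {
  m <- matrix(1, dims[1], dims[2])
  m[cbind(pmin(pmax(round(capillaries$row), 1), dims[1]),
          pmin(pmax(round(capillaries$col), 1), dims[2]))] <- 0
  dm <- EBImage::distmap(EBImage::Image(m))
  matrix(as.numeric(EBImage::imageData(dm)), dims[1], dims[2])
}

#' Regression-form diffusion distances
#'
#' Evaluates a user-configured regression for the maximal and average
#' diffusion distances as a function of the capillary-to-fiber ratio and
#' mean fiber area. The algebraic form printed in the morphometry
#' literature is typographically ambiguous (exponents/operators may have
#' been lost in typesetting), so no coefficients are hard-coded: the
#' functional form must be supplied explicitly, and the result is reported
#' alongside — never in place of — the geometric estimate from
#' [diffusion_distances()].
#'
#' @param cf_ratio Capillary-to-fiber ratio.
#' @param mean_fa Mean fiber area, um^2.
#' @param coefficients A list with functions `max_dd` and `avg_dd`, each
#'   taking `(cf_ratio, mean_fa)` and returning um. `NULL` (default)
#'   disables the operation with an explanatory error.
#' @return Tibble: `max_dd_um`, `avg_dd_um`, `method = "regression"`.
#' @export
#' @examples
#' co <- list(max_dd = function(cf, fa) 0.415 * (cf * fa)^0.477,
#'            avg_dd = function(cf, fa) 0.207 * (cf * fa)^0.232)
#' diffusion_distances_regression(2.3, 5500, co)
diffusion_distances_regression <- function(cf_ratio, mean_fa,
                                           coefficients = NULL) {
  if (is.null(coefficients)) {
    abort(paste0(
      "Regression-based diffusion distances are disabled: the published ",
      "functional form is typographically ambiguous, so its coefficients ",
      "must be supplied explicitly (a list with functions `max_dd` and ",
      "`avg_dd` of (cf_ratio, mean_fa)). The geometric estimate from ",
      "diffusion_distances() is the primary method."))
  }
  stopifnot(is.function(coefficients$max_dd), is.function(coefficients$avg_dd))
  tibble(max_dd_um = coefficients$max_dd(cf_ratio, mean_fa),
         avg_dd_um = coefficients$avg_dd(cf_ratio, mean_fa),
         method = "regression")
}
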