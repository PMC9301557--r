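#' One-way sensitivity-analysis specifications
#'
#' The deterministic sensitivity levers and their ranges: direct screening
#' cost, maintenance cost and heavy-smoker incidence varied by +/-30%
#' relative to base; the discount rate over 0-8%; LDCT sensitivity over
#' 0.63-0.95 and specificity over 0.65-0.97; and the CPI (cost inflation)
#' rate varied +/-30% around a 2%/year reference (the base-case run itself
#' uses constant-CNY accounting, i.e. CPI 0).
#'
#' @param params A `lcs_parameters` object.
#' @param cpi_reference Reference CPI rate around which the +/-30% range is
#'   taken (default 0.02).
#' @return A tibble of `lcs_dsa` specs: `parameter`, `base`, `low`, `high`,
#'   `rule`.
#' @export
build_dsa_specs <- function(params, cpi_reference = 0.02) {
  stopifnot(inherits(params, "lcs_parameters"))
  rel <- function(x) c(0.7, 1.3) * x
  tibble::tribble(
    ~parameter, ~base, ~low, ~high, ~rule,
    "direct_screening_cost", params$costs$direct_screening,
    rel(params$costs$direct_screening)[1], rel(params$costs$direct_screening)[2],
    "+/-30% relative",
    "maintenance_cost", params$costs$maintenance_fraction,
    rel(params$costs$maintenance_fraction)[1], rel(params$costs$maintenance_fraction)[2],
    "+/-30% relative",
    "discount_rate", params$economics$discount_rate, 0, 0.08, "explicit bounds",
    "cpi_rate", cpi_reference, rel(cpi_reference)[1], rel(cpi_reference)[2],
    "+/-30% around reference",
    "heavy_smoker_incidence", params$options$incidence_multiplier,
    rel(params$options$incidence_multiplier)[1], rel(params$options$incidence_multiplier)[2],
    "+/-30% relative",
    "ldct_sensitivity", params$ldct$sensitivity, 0.63, 0.95, "explicit bounds",
    "ldct_specificity", params$ldct$specificity, 0.65, 0.97, "explicit bounds"
  )
}

# set one DSA lever on a parameter set
apply_dsa_value <- function(params, parameter, value) {
  switch(parameter,
         direct_screening_cost = {
           params$costs$direct_screening <- value
         },
         maintenance_cost = {
           params$costs$maintenance_fraction <- value
         },
         discount_rate = {
           params$economics$discount_rate <- value
         },
         cpi_rate = {
           params$costs$cpi_rate <- value
         },
         heavy_smoker_incidence = {
           params$options$incidence_multiplier <- value
         },
         ldct_sensitivity = {
           params$ldct$sensitivity <- value
         },
         ldct_specificity = {
           params$ldct$specificity <- value
         },
         abort(paste0("unknown DSA parameter: ", parameter),
               class = "lcs_parameter_error"))
  params
}

#' One-way (tornado) deterministic sensitivity analysis
#'
#' For each lever, reruns the comparison at the low and high value with all
#' other inputs at base, records the resulting ICERs, and sorts by swing
#' (absolute difference between the high and low ICER). Fully
#' deterministic. Detection probabilities are calibrated once on the base
#' inputs and held fixed.
#'
#' @param params A `lcs_parameters` object.
#' @param comparison A list with elements `a` and `b` (strategies compared,
#'   A versus B); defaults to annual screening versus nonscreening at start
#'   age 65.
#' @param specs DSA specs from [build_dsa_specs()] (or a compatible tibble).
#' @return A `lcs_tornado` tibble: `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `icer_base`, `swing`, sorted by decreasing swing.
#' @export
run_tornado <- function(params, comparison = list(a = strategy("annual", 65),
                                                  b = strategy("none", 65)),
                        specs = build_dsa_specs(params)) {
  stopifnot(inherits(params, "lcs_parameters"))
  if (is.null(params$detection)) {
    params <- set_detection(params, calibrate_detection(params)$probabilities)
  }
  icer_for <- function(p) {
    a <- run_cohort(p, comparison$a)$summary
    b <- run_cohort(p, comparison$b)$summary
    icer(a$total_cost, a$total_qalys, b$total_cost, b$total_qalys)$icer
  }
  base_icer <- icer_for(params)
  out <- purrr::pmap_dfr(specs, function(parameter, base, low, high, rule) {
    il <- icer_for(apply_dsa_value(params, parameter, low))
    ih <- icer_for(apply_dsa_value(params, parameter, high))
    tibble::tibble(parameter = parameter, low = low, high = high,
                   icer_low = il, icer_high = ih,
                   icer_base = base_icer, swing = abs(ih - il))
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$swing))
  class(out) <- c("lcs_tornado", class(out))
  out
}

# draw one moment-matched parameter set; probabilities/proportions/utilities
# are beta, costs and ratio-scale parameters gamma; degenerate means (0, 1)
# stay fixed
draw_psa_parameters <- function(params, cv = params$psa$cv) {
  b1 <- function(m) if (m <= 0 || m >= 1) m else psa_sample(1, m, cv, "beta")
  g1 <- function(m) if (m <= 0) m else psa_sample(1, m, cv, "gamma")
  bvec <- function(x) vapply(x, b1, numeric(1))
  gvec <- function(x) vapply(x, g1, numeric(1))
  simplex <- function(x) {
    y <- bvec(x)
    y / sum(y)
  }
  # rates per 100k are drawn as beta on the per-person proportion scale
  rvec <- function(x) vapply(x, function(m) {
    if (m <= 0) m else 1e5 * psa_sample(1, m / 1e5, cv, "beta")
  }, numeric(1))
  q <- params
  q$incidence$male <- rvec(params$incidence$male)
  q$incidence$female <- rvec(params$incidence$female)
  q$smoking$male <- bvec(params$smoking$male)
  q$smoking$female <- bvec(params$smoking$female)
  q$risk$odds_ratio_smoker <- g1(params$risk$odds_ratio_smoker)
  q$risk$rr_heavy <- g1(params$risk$rr_heavy)
  q$stage_dist$nonscreened <- simplex(params$stage_dist$nonscreened)
  q$stage_dist$screened <- simplex(params$stage_dist$screened)
  q$ldct$sensitivity <- b1(params$ldct$sensitivity)
  q$ldct$specificity <- b1(params$ldct$specificity)
  q$mortality$all_cause$value <- bvec(params$mortality$all_cause$value)
  q$transitions$progression <- bvec(params$transitions$progression)
  q$transitions$lc_death <- bvec(params$transitions$lc_death)
  q$utilities <- bvec(params$utilities)
  for (nm in c("direct_screening", "indirect_screening", "prediagnosis", "biopsy")) {
    q$costs[[nm]] <- g1(params$costs[[nm]])
  }
  q$costs$treatment <- gvec(params$costs$treatment)
  q$costs$maintenance_fraction <- b1(params$costs$maintenance_fraction)
  q
}

#' Probabilistic sensitivity analysis
#'
#' Draws every distribution-tagged parameter from its moment-matched beta
#' or gamma distribution (coefficient of variation `cv`), reruns both arms
#' of the comparison per draw, and records the incremental cost and QALY
#' pair. Draws that fail validation (e.g. a stage's sampled outgoing
#' probabilities exceeding one) are resampled and counted. Detection
#' probabilities are calibrated once on the base inputs and held fixed
#' across draws.
#'
#' @param params A `lcs_parameters` object.
#' @param n_draws Number of Monte Carlo draws (default 10,000).
#' @param seed Integer seed; the same seed reproduces the run exactly.
#' @param comparison List with strategies `a` and `b` (default annual vs
#'   nonscreening at start age 65).
#' @param cv Coefficient of variation for all parameters (default
#'   `params$psa$cv`, 0.1).
#' @param threshold_grid Thresholds (CNY/QALY) for the acceptability curve.
#' @return A `lcs_psa` object: `$draws` (tibble with `draw`, `delta_cost`,
#'   `delta_qaly`, `icer`), `$summary` (mean ICER as ratio-of-means and as
#'   mean-of-ratios, probability cost-effective at the base threshold,
#'   resample count), and `$ceac` (acceptability curve).
#' @export
run_psa <- function(params, n_draws = 10000, seed = 1,
                    comparison = list(a = strategy("annual", 65),
                                      b = strategy("none", 65)),
                    cv = params$psa$cv,
                    threshold_grid = seq(0, 5e5, length.out = 51)) {
  stopifnot(inherits(params, "lcs_parameters"), n_draws >= 1)
  if (is.null(params$detection)) {
    params <- set_detection(params, calibrate_detection(params)$probabilities)
  }
  set.seed(seed)
  resampled <- 0L
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    repeat {
      q <- draw_psa_parameters(params, cv)
      v <- validate_parameters(q)
      if (!any(v$severity == "error")) break
      resampled <- resampled + 1L
      if (resampled > 50L * n_draws) {
        abort("PSA resampling limit exceeded; check parameter dispersion",
              class = "lcs_parameter_error")
      }
    }
    a <- run_cohort(q, comparison$a)$summary
    b <- run_cohort(q, comparison$b)$summary
    rows[[i]] <- tibble::tibble(draw = i,
                                delta_cost = a$total_cost - b$total_cost,
                                delta_qaly = a$total_qalys - b$total_qalys)
  }
  draws <- dplyr::mutate(dplyr::bind_rows(rows),
                         icer = ifelse(.data$delta_qaly == 0, NA_real_,
                                       .data$delta_cost / .data$delta_qaly))
  thr <- params$economics$threshold
  nmb_ce <- function(lambda) mean(draws$delta_qaly * lambda - draws$delta_cost >= 0)
  ceac <- tibble::tibble(threshold = threshold_grid,
                         probability_cost_effective = vapply(threshold_grid, nmb_ce, numeric(1)))
  summary <- list(
    icer_ratio_of_means = mean(draws$delta_cost) / mean(draws$delta_qaly),
    icer_mean_of_ratios = mean(draws$icer[is.finite(draws$icer)]),
    probability_cost_effective = nmb_ce(thr),
    threshold = thr,
    n_draws = n_draws,
    n_resampled = resampled,
    seed = seed,
    cv = cv
  )
  structure(list(draws = draws, summary = summary, ceac = ceac,
                 comparison = comparison),
            class = "lcs_psa")
}

#' @export
print.lcs_psa <- function(x, ...) {
  s <- x$summary
  cat("<lcs_psa>", s$n_draws, "draws (cv =", s$cv, ", seed =", s$seed, ")\n")
  cat(sprintf("  mean ICER (ratio of means):  %.2f CNY/QALY\n", s$icer_ratio_of_means))
  cat(sprintf("  mean ICER (mean of ratios):  %.2f CNY/QALY\n", s$icer_mean_of_ratios))
  cat(sprintf("  P(cost-effective at %s): %.3f\n",
              format(s$threshold, big.mark = ","), s$probability_cost_effective))
  invisible(x)
}
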