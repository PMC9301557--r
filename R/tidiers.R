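#' Tidy the cycle trace of a cohort run
#'
#' @param x A `lcs_run` from [run_cohort()].
#' @param ... Unused.
#' @return The per-cycle trace tibble (one row per model year: occupancy,
#'   event counters, nominal and discounted cost and QALY accruals).
#' @method tidy lcs_run
#' @export
tidy.lcs_run <- function(x, ...) {
  x$trace
}

#' One-row outcome summary of a cohort run
#'
#' @param x A `lcs_run` from [run_cohort()].
#' @param ... Unused.
#' @return A one-row tibble: strategy, discounted totals, cumulative
#'   lung-cancer deaths, per-person figures.
#' @method glance lcs_run
#' @export
glance.lcs_run <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    interval = x$strategy$interval,
    start_age = x$strategy$start_age,
    total_cost = s$total_cost,
    total_qalys = s$total_qalys,
    lc_deaths = s$lc_deaths,
    per_person_cost = s$per_person_cost,
    per_person_qalys = s$per_person_qalys,
    screens = s$screens,
    false_positives = s$false_positives
  )
}

#' @rdname tidy.lcs_run
#' @method tidy lcs_psa
#' @export
tidy.lcs_psa <- function(x, ...) {
  x$draws
}

#' @rdname glance.lcs_run
#' @method glance lcs_psa
#' @export
glance.lcs_psa <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    icer_ratio_of_means = s$icer_ratio_of_means,
    icer_mean_of_ratios = s$icer_mean_of_ratios,
    probability_cost_effective = s$probability_cost_effective,
    threshold = s$threshold,
    n_draws = s$n_draws,
    n_resampled = s$n_resampled
  )
}

#' @rdname tidy.lcs_run
#' @method tidy lcs_calibration
#' @export
tidy.lcs_calibration <- function(x, ...) {
  tibble::tibble(stage = lcs_stages(),
                 detection_probability = unname(x$probabilities),
                 achieved = unname(x$achieved),
                 target = unname(x$target))
}

#' @rdname tidy.lcs_run
#' @method tidy lcs_microsim
#' @export
tidy.lcs_microsim <- function(x, ...) {
  x$totals
}
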