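#' Incremental cost-effectiveness ratio of strategy A versus strategy B
#'
#' Computes the incremental comparison on unrounded inputs:
#' `(cost_a - cost_b) / (qaly_a - qaly_b)`, with standard dominance
#' handling — `dominant` if A is cheaper and more effective, `dominated` if
#' A is costlier and less effective, `undefined` when the QALY difference
#' is exactly zero (no division is attempted).
#'
#' @param cost_a,qaly_a Discounted totals of the comparator strategy.
#' @param cost_b,qaly_b Discounted totals of the reference strategy.
#' @return A one-row tibble: `delta_cost`, `delta_qaly`, `icer`,
#'   `dominance` (`"none"`, `"dominant"`, `"dominated"`, `"undefined"`).
#' @export
#' @examples
#' icer(2552.16e6, 135.93e4, 2489.69e6, 135.92e4) # from rounded table cells
icer <- function(cost_a, qaly_a, cost_b, qaly_b) {
  stopifnot(is.finite(cost_a), is.finite(qaly_a), is.finite(cost_b), is.finite(qaly_b))
  dc <- cost_a - cost_b
  dq <- qaly_a - qaly_b
  dominance <- if (dq == 0) {
    "undefined"
  } else if (dc < 0 && dq > 0) {
    "dominant"
  } else if (dc > 0 && dq < 0) {
    "dominated"
  } else {
    "none"
  }
  tibble::tibble(delta_cost = dc, delta_qaly = dq,
                 icer = if (dq == 0) NA_real_ else dc / dq,
                 dominance = dominance)
}

#' Percent reduction in lung-cancer deaths versus nonscreening
#'
#' @param scr,non `lcs_run` objects (or their `$summary` lists) for the
#'   screening and nonscreening arms at the same start age.
#' @return Percent reduction, `100 * (non - scr) / non`; `NA` when the
#'   nonscreening arm has no lung-cancer deaths.
#' @export
mortality_reduction <- function(scr, non) {
  g <- function(x) if (inherits(x, "lcs_run")) x$summary$lc_deaths else x$lc_deaths
  s <- g(scr)
  n <- g(non)
  if (n == 0) return(NA_real_)
  100 * (n - s) / n
}

#' Classify an ICER against the willingness-to-pay threshold
#'
#' Cost-effective iff the ICER does not exceed the threshold (ties count as
#' cost-effective). Dominant comparisons are cost-effective; dominated or
#' undefined ones are not.
#'
#' @param icer_value ICER in CNY/QALY (may be `NA` when flagged).
#' @param threshold Willingness-to-pay threshold in CNY/QALY.
#' @param dominance Optional dominance flag from [icer()].
#' @return Logical.
#' @export
classify_cost_effective <- function(icer_value, threshold, dominance = "none") {
  stopifnot(threshold > 0)
  dplyr::case_when(
    dominance == "dominant" ~ TRUE,
    dominance %in% c("dominated", "undefined") ~ FALSE,
    TRUE ~ icer_value <= threshold
  )
}

#' Evaluate the full screening-strategy grid
#'
#' Runs all 15 strategy cells (nonscreening, one-time, annual at start ages
#' 50-74), computes each screening arm's ICER versus nonscreening and the
#' annual-versus-one-time ICER, the lung-cancer mortality reduction, and
#' the threshold classification. Costs are also reported in millions of CNY
#' per cohort and QALYs in units of 10,000 years, mirroring the
#' conventional reporting scale. If detection probabilities are missing
#' they are calibrated once first.
#'
#' @param params A `lcs_parameters` object.
#' @param start_ages Start ages to evaluate (default all five).
#' @return A `lcs_grid` tibble, one row per strategy cell, with a
#'   `comparisons` attribute holding the pairwise incremental results
#'   (including a check ICER recomputed from the rounded report cells, so
#'   table-rounding discrepancies stay visible).
#' @export
evaluate_grid <- function(params, start_ages = c(50, 55, 60, 65, 70)) {
  stopifnot(inherits(params, "lcs_parameters"))
  if (is.null(params$detection)) {
    params <- set_detection(params, calibrate_detection(params)$probabilities)
  }
  thr <- params$economics$threshold

  runs <- tidyr::expand_grid(start_age = start_ages,
                             interval = c("none", "one_time", "annual"))
  runs$run <- purrr::pmap(runs, function(start_age, interval) {
    run_cohort(params, strategy(interval, start_age))
  })

  cells <- dplyr::mutate(
    runs,
    cost = purrr::map_dbl(.data$run, ~ .x$summary$total_cost),
    qalys = purrr::map_dbl(.data$run, ~ .x$summary$total_qalys),
    lc_deaths = purrr::map_dbl(.data$run, ~ .x$summary$lc_deaths),
    per_person_cost = purrr::map_dbl(.data$run, ~ .x$summary$per_person_cost),
    cost_million = .data$cost / 1e6,
    qalys_10k = .data$qalys / 1e4
  )

  out <- cells |>
    dplyr::group_by(.data$start_age) |>
    dplyr::group_modify(function(g, key) {
      non <- g[g$interval == "none", ]
      one <- g[g$interval == "one_time", ]
      ann <- g[g$interval == "annual", ]
      res <- function(row) {
        if (row$interval == "none") {
          return(tibble::tibble(mortality_reduction_pct = NA_real_,
                                icer_vs_nonscreening = NA_real_,
                                dominance = NA_character_,
                                cost_effective = NA,
                                icer_annual_vs_onetime = NA_real_))
        }
        ce <- icer(row$cost, row$qalys, non$cost, non$qalys)
        tibble::tibble(
          mortality_reduction_pct = mortality_reduction(
            list(lc_deaths = row$lc_deaths), list(lc_deaths = non$lc_deaths)),
          icer_vs_nonscreening = ce$icer,
          dominance = ce$dominance,
          cost_effective = classify_cost_effective(ce$icer, thr, ce$dominance),
          icer_annual_vs_onetime = if (row$interval == "annual") {
            icer(ann$cost, ann$qalys, one$cost, one$qalys)$icer
          } else NA_real_
        )
      }
      dplyr::bind_cols(g, dplyr::bind_rows(lapply(seq_len(nrow(g)),
                                                  function(i) res(g[i, ]))))
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-"run")

  comparisons <- cells |>
    dplyr::group_by(.data$start_age) |>
    dplyr::group_modify(function(g, key) {
      non <- g[g$interval == "none", ]
      one <- g[g$interval == "one_time", ]
      ann <- g[g$interval == "annual", ]
      pair <- function(a, b, label) {
        ce <- icer(a$cost, a$qalys, b$cost, b$qalys)
        rounded <- icer(round(a$cost / 1e6, 2) * 1e6, round(a$qalys / 1e4, 2) * 1e4,
                        round(b$cost / 1e6, 2) * 1e6, round(b$qalys / 1e4, 2) * 1e4)
        dplyr::mutate(ce, comparison = label,
                      icer_from_rounded_cells = rounded$icer,
                      cost_effective = classify_cost_effective(ce$icer, thr, ce$dominance))
      }
      dplyr::bind_rows(pair(one, non, "one_time_vs_none"),
                       pair(ann, non, "annual_vs_none"),
                       pair(ann, one, "annual_vs_one_time"))
    }) |>
    dplyr::ungroup()

  attr(out, "comparisons") <- comparisons
  attr(out, "threshold") <- thr
  class(out) <- c("lcs_grid", class(out))
  out
}

#' Pairwise incremental comparisons of a strategy grid
#'
#' @param grid A `lcs_grid` from [evaluate_grid()].
#' @return Tibble of the 15 pairwise incremental results.
#' @export
grid_comparisons <- function(grid) {
  attr(grid, "comparisons")
}

#' Cost-effectiveness efficiency frontier (supplementary output)
#'
#' Standard CEA frontier over all strategy cells: strategies are sorted by
#' cost, strictly dominated and extendedly dominated ones removed. This is
#' an auxiliary output beyond the pairwise-versus-nonscreening analysis.
#'
#' @param grid A `lcs_grid` from [evaluate_grid()].
#' @return Tibble of frontier strategies with frontier ICERs.
#' @export
efficiency_frontier <- function(grid) {
  df <- dplyr::arrange(tibble::as_tibble(grid), .data$cost, dplyr::desc(.data$qalys))
  keep <- list()
  best_q <- -Inf
  for (i in seq_len(nrow(df))) {
    if (df$qalys[i] > best_q) {
      keep[[length(keep) + 1]] <- df[i, ]
      best_q <- df$qalys[i]
    }
  }
  fr <- dplyr::bind_rows(keep)
  # extended dominance: drop points whose incremental ICER exceeds the next one
  repeat {
    if (nrow(fr) < 3) break
    ic <- c(NA, diff(fr$cost) / diff(fr$qalys))
    drop <- which(diff(ic[-1]) < 0)[1]
    if (is.na(drop)) break
    fr <- fr[-(drop + 1), ]
  }
  fr$frontier_icer <- c(NA, diff(fr$cost) / diff(fr$qalys))
  fr
}
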