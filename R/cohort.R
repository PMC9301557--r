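#' Discount factor for a given year
#'
#' Year-0 flows are undiscounted; a flow in year `t` is weighted by
#' `(1 + rate)^(-t)`.
#'
#' @param years_elapsed Whole years since cohort entry (>= 0).
#' @param rate Annual discount rate (>= 0).
#' @return Dimensionless discount weight.
#' @export
#' @examples
#' discount_factor(2, 0.05) # 0.9070295
discount_factor <- function(years_elapsed, rate) {
  if (any(years_elapsed < 0) || any(rate < 0)) {
    abort("years_elapsed and rate must be nonnegative", class = "lcs_parameter_error")
  }
  (1 + rate)^(-years_elapsed)
}

#' Screening strategy specification
#'
#' @param interval One of `"none"`, `"one_time"`, `"annual"`.
#' @param start_age Start age: 50, 55, 60, 65 or 70.
#' @return A `lcs_strategy` object.
#' @export
#' @examples
#' strategy("annual", 55)
strategy <- function(interval = c("none", "one_time", "annual"), start_age = 50) {
  interval <- match.arg(interval)
  if (!start_age %in% c(50, 55, 60, 65, 70)) {
    abort("start_age must be one of 50, 55, 60, 65, 70", class = "lcs_parameter_error")
  }
  structure(list(interval = interval, start_age = as.integer(start_age)),
            class = "lcs_strategy")
}

as_strategy <- function(x) {
  if (inherits(x, "lcs_strategy")) return(x)
  if (is.character(x) && length(x) == 1 && grepl(":", x)) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    return(strategy(parts[1], as.integer(parts[2])))
  }
  abort("expected a strategy() object or a string like 'annual:55'",
        class = "lcs_parameter_error")
}

#' @export
print.lcs_strategy <- function(x, ...) {
  cat("<lcs_strategy>", x$interval, "screening, start age", x$start_age, "\n")
  invisible(x)
}

#' The full 15-cell strategy grid
#'
#' @return A tibble of all interval-by-start-age combinations.
#' @export
strategy_grid <- function() {
  tidyr::expand_grid(interval = c("none", "one_time", "annual"),
                     start_age = c(50L, 55L, 60L, 65L, 70L))
}

#' Annual transition matrix at a given age
#'
#' Builds the row-stochastic one-cycle transition matrix over the thirteen
#' health states. Competing risks within a row are composed by applying
#' other-cause death first; the surviving mass is then split among stage
#' progression, lung-cancer death, and staying. The healthy row routes the
#' incidence probability to undiagnosed carcinoma in situ. Diagnosed
#' (maintenance) stages by default retain only their stage-specific
#' lung-cancer death risk; option `diagnosed_progression = "table"` applies
#' the same progression probabilities as the undiagnosed pool.
#'
#' @param params A `lcs_parameters` object.
#' @param age Current age (years).
#' @param incidence_prob Annual probability that a healthy heavy smoker
#'   develops lung cancer.
#' @return A 13 x 13 row-stochastic matrix with state dimnames.
#' @export
build_cycle_transition <- function(params, age, incidence_prob) {
  states <- health_states()
  m <- matrix(0, length(states), length(states), dimnames = list(states, states))
  if (!is.finite(incidence_prob) || incidence_prob < 0 || incidence_prob > 1) {
    abort("incidence_prob must lie in [0, 1]", class = "lcs_parameter_error")
  }
  p_oc <- annual_all_cause(params, age)
  pr <- params$transitions$progression
  dth <- params$transitions$lc_death
  surv <- 1 - p_oc

  m["Healthy", "Death_OtherCause"] <- p_oc
  m["Healthy", "Undiagnosed_CIS"] <- surv * incidence_prob
  m["Healthy", "Healthy"] <- surv * (1 - incidence_prob)

  # outgoing (to-state, probability) pairs per preclinical stage
  prog_map <- list(
    CIS = c(I = unname(pr["cis_to_I"])),
    I = c(II = unname(pr["I_to_II"]), III = unname(pr["I_to_III"]),
          IV = unname(pr["I_to_IV"])),
    II = c(III = unname(pr["II_to_III"]), IV = unname(pr["II_to_IV"])),
    III = c(IV = unname(pr["III_to_IV"])),
    IV = numeric()
  )
  fill_cancer_row <- function(from, prefix, progress) {
    m[from, "Death_OtherCause"] <<- p_oc
    m[from, "Death_LungCancer"] <<- surv * dth[[sub(paste0(prefix, "_"), "", from)]]
    moved <- dth[[sub(paste0(prefix, "_"), "", from)]]
    if (progress) {
      stg <- sub(paste0(prefix, "_"), "", from)
      for (to in names(prog_map[[stg]])) {
        m[from, paste0(prefix, "_", to)] <<- surv * prog_map[[stg]][[to]]
        moved <- moved + prog_map[[stg]][[to]]
      }
    }
    m[from, from] <<- surv * (1 - moved)
  }
  for (s in lcs_stages()) {
    fill_cancer_row(paste0("Undiagnosed_", s), "Undiagnosed", progress = TRUE)
    fill_cancer_row(paste0("Diagnosed_", s), "Diagnosed",
                    progress = identical(params$options$diagnosed_progression, "table"))
  }
  m["Death_LungCancer", "Death_LungCancer"] <- 1
  m["Death_OtherCause", "Death_OtherCause"] <- 1

  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-9)) {
    abort(paste0("internal error: transition rows not stochastic at age ", age),
          class = "lcs_internal_error")
  }
  m
}

#' Apply a screening round to a cohort state vector
#'
#' Every alive, undiagnosed person is screened (adherence 100%) and incurs
#' the direct plus indirect screening cost. Undiagnosed cancer mass is
#' detected with probability equal to LDCT sensitivity and moves to the
#' diagnosed (maintenance) states, paying prediagnosis, biopsy and stage
#' treatment costs. Cancer-free mass incurs a false-positive workup
#' (prediagnosis + biopsy) with probability one minus specificity. Detected
#' mass is either placed at its current (undiagnosed) stage or distributed
#' across stages per the screened-cohort stage split, following option
#' `screen_stage_split`: `"never"` (default: detection does not alter the
#' underlying stage), `"entry"` (the program's first screen distributes its
#' detections per the prevalence-round split), or `"always"`. The default is
#' stage-preserving because the cohort enters disease-free: the preclinical
#' pool a screen faces is dominated by carcinoma in situ, and forcing it
#' onto the screened-cohort split would fabricate advanced-stage cases.
#'
#' @param state Named occupancy vector over [health_states()].
#' @param params A `lcs_parameters` object.
#' @param entry Is this the first screen of the program?
#' @return A list: `state` (updated vector), `cost` (total, undiscounted),
#'   and `counters` (screens, false positives, detections by stage, and the
#'   cost split).
#' @export
apply_screening_event <- function(state, params, entry = FALSE) {
  u <- undiagnosed_states()
  d <- diagnosed_states()
  sens <- params$ldct$sensitivity
  spec <- params$ldct$specificity
  cs <- params$costs

  screened <- state[["Healthy"]] + sum(state[u])
  cost_screen <- screened * (cs$direct_screening + cs$indirect_screening)

  detected <- state[u] * sens
  state[u] <- state[u] - detected
  mode <- params$options$screen_stage_split %||% "never"
  placed <- if (identical(mode, "always") || (identical(mode, "entry") && entry)) {
    sum(detected) * params$stage_dist$screened
  } else {
    setNames(unname(detected), lcs_stages())
  }
  state[d] <- state[d] + placed

  fp <- state[["Healthy"]] * (1 - spec)
  cost_dx <- sum(detected) * (cs$prediagnosis + cs$biopsy) +
    sum(placed * cs$treatment)
  cost_fp <- fp * (cs$prediagnosis + cs$biopsy)

  list(state = state,
       cost = cost_screen + cost_dx + cost_fp,
       counters = list(screens = screened, false_positives = fp,
                       detections = placed, detected_total = sum(detected),
                       cost_screen = cost_screen, cost_dx = cost_dx,
                       cost_fp = cost_fp))
}

#' Apply symptomatic (clinical) detection to a cohort state vector
#'
#' Undiagnosed cancer mass presents clinically with a per-stage annual
#' detection probability (calibrated so the nonscreened stage distribution
#' at diagnosis matches its target; see [calibrate_detection()]) and moves
#' to the diagnosed states, paying prediagnosis, biopsy and stage treatment
#' costs.
#'
#' @inheritParams apply_screening_event
#' @return A list: `state`, `cost`, `counters` (detections by stage).
#' @export
apply_symptomatic_detection <- function(state, params) {
  if (is.null(params$detection)) {
    abort("clinical-detection probabilities are not set; run calibrate_detection() first",
          class = "lcs_calibration_error")
  }
  u <- undiagnosed_states()
  d <- diagnosed_states()
  cs <- params$costs
  detected <- state[u] * params$detection
  state[u] <- state[u] - detected
  state[d] <- state[d] + detected
  detected <- setNames(unname(detected), lcs_stages())
  cost <- sum(detected) * (cs$prediagnosis + cs$biopsy) + sum(detected * cs$treatment)
  list(state = state, cost = cost, counters = list(detections = detected))
}

#' Run the cohort model for one screening strategy
#'
#' Evolves a closed cohort of heavy smokers from the strategy's start age to
#' the horizon age through annual cycles. Each cycle charges maintenance
#' costs on the diagnosed pool, applies the age-specific transition matrix
#' (incidence, progression, lung-cancer and other-cause death), applies the
#' scheduled screen (one-time: first program year only; annual: every year)
#' followed by symptomatic detection, and accrues discounted costs and
#' QALYs. The run is fully deterministic.
#'
#' @param params A `lcs_parameters` object with detection probabilities set.
#' @param strategy A [strategy()] object or a string like `"annual:55"`.
#' @return A `lcs_run` object: `$trace` (tibble, one row per cycle with
#'   occupancy, event counters and cost/QALY accruals) and `$summary`
#'   (total discounted cost and QALYs, cumulative lung-cancer deaths,
#'   per-person cost).
#' @export
#' @examples
#' \donttest{
#' p <- default_parameters()
#' p <- set_detection(p, calibrate_detection(p)$probabilities)
#' run <- run_cohort(p, strategy("annual", 70))
#' glance(run)
#' }
run_cohort <- function(params, strategy) {
  stopifnot(inherits(params, "lcs_parameters"))
  st <- as_strategy(strategy)
  if (is.null(params$detection)) {
    abort("clinical-detection probabilities are not set; run calibrate_detection() first",
          class = "lcs_calibration_error")
  }
  eco <- params$economics
  states <- health_states()
  u <- undiagnosed_states()
  d <- diagnosed_states()
  ages <- seq(st$start_age, eco$horizon_end_age)
  sched <- cohort_incidence_schedule(params, st$start_age)
  screen_cycle <- switch(st$interval,
                         none = rep(FALSE, length(ages)),
                         one_time = seq_along(ages) == 1,
                         annual = rep(TRUE, length(ages)))
  first_screen <- if (any(screen_cycle)) which(screen_cycle)[1] else NA_integer_

  util <- c(Healthy = unname(params$utilities[["Healthy"]]),
            setNames(unname(params$utilities[lcs_stages()]), u),
            setNames(unname(params$utilities[lcs_stages()]), d),
            Death_LungCancer = 0, Death_OtherCause = 0)
  if (identical(params$options$undiagnosed_utility, "healthy")) {
    util[u] <- params$utilities[["Healthy"]]
  }

  v <- setNames(numeric(length(states)), states)
  v[["Healthy"]] <- eco$cohort_size
  r <- eco$discount_rate
  cpi <- params$costs$cpi_rate
  maint_unit <- params$costs$maintenance_fraction * params$costs$treatment
  half_cycle <- isTRUE(params$options$half_cycle_correction)

  trace_cols <- c("cycle", "age", "new_cancers", "screens", "false_positives",
                  paste0("dx_screen_", lcs_stages()),
                  paste0("dx_symptomatic_", lcs_stages()),
                  "lc_deaths", "cost_maintenance", "cost_screening",
                  "cost_diagnosis", "cost", "cost_discounted",
                  "qalys", "qalys_discounted", paste0("n_", states))
  tr <- matrix(0, nrow = length(ages), ncol = length(trace_cols),
               dimnames = list(NULL, trace_cols))
  for (t in seq_along(ages)) {
    age <- ages[t]
    yrs <- t - 1
    disc <- discount_factor(yrs, r)
    infl <- (1 + cpi)^yrs
    v_start <- v
    lc_dead_before <- v[["Death_LungCancer"]]

    cost_maintenance <- sum(v[d] * maint_unit)

    m <- build_cycle_transition(params, age, sched$annual_probability[t])
    v <- setNames(as.numeric(v %*% m), states)

    scr <- NULL
    if (screen_cycle[t]) {
      scr <- apply_screening_event(v, params, entry = identical(t, first_screen))
      v <- scr$state
    }
    sym <- apply_symptomatic_detection(v, params)
    v <- sym$state

    qaly <- if (half_cycle) {
      sum((v_start + v) / 2 * util) * eco$cycle_length
    } else {
      sum(v * util) * eco$cycle_length
    }
    cost_screening <- if (is.null(scr)) 0 else scr$counters$cost_screen + scr$counters$cost_fp
    cost_dx_screen <- if (is.null(scr)) 0 else scr$counters$cost_dx
    cost_nominal <- (cost_maintenance + cost_screening + cost_dx_screen + sym$cost) * infl

    dx_scr <- if (is.null(scr)) numeric(5) else as.numeric(scr$counters$detections)
    new_cancers <- v_start[["Healthy"]] * (1 - annual_all_cause(params, age)) *
      sched$annual_probability[t]
    tr[t, ] <- c(yrs, age, new_cancers,
                 if (is.null(scr)) 0 else scr$counters$screens,
                 if (is.null(scr)) 0 else scr$counters$false_positives,
                 dx_scr,
                 as.numeric(sym$counters$detections),
                 v[["Death_LungCancer"]] - lc_dead_before,
                 cost_maintenance * infl,
                 cost_screening * infl,
                 (cost_dx_screen + sym$cost) * infl,
                 cost_nominal,
                 cost_nominal * disc,
                 qaly,
                 qaly * disc,
                 as.numeric(v))
    if (abs(sum(v) - eco$cohort_size) > 1e-6) {
      abort("internal error: cohort mass not conserved", class = "lcs_internal_error")
    }
  }
  trace <- tibble::as_tibble(tr)
  summary <- list(
    total_cost = sum(trace$cost_discounted),
    total_qalys = sum(trace$qalys_discounted),
    total_cost_undiscounted = sum(trace$cost),
    total_qalys_undiscounted = sum(trace$qalys),
    lc_deaths = unname(v[["Death_LungCancer"]]),
    other_deaths = unname(v[["Death_OtherCause"]]),
    per_person_cost = sum(trace$cost_discounted) / eco$cohort_size,
    per_person_qalys = sum(trace$qalys_discounted) / eco$cohort_size,
    screens = sum(trace$screens),
    false_positives = sum(trace$false_positives)
  )
  structure(list(trace = trace, summary = summary, strategy = st,
                 cohort_size = eco$cohort_size),
            class = "lcs_run")
}

#' @export
print.lcs_run <- function(x, ...) {
  s <- x$summary
  cat("<lcs_run>", x$strategy$interval, "screening, start age",
      x$strategy$start_age, "\n")
  cat(sprintf("  discounted cost : %.2f M CNY (%.2f CNY/person)\n",
              s$total_cost / 1e6, s$per_person_cost))
  cat(sprintf("  discounted QALYs: %.2f x 10^4 (%.4f/person)\n",
              s$total_qalys / 1e4, s$per_person_qalys))
  cat(sprintf("  lung-cancer deaths: %.1f\n", s$lc_deaths))
  invisible(x)
}
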