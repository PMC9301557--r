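#' Generate a synthetic LDCT screening registry
#'
#' Emulates a single-round screening registry: each participant's confirmed
#' lung-cancer status is Bernoulli with the given detection (yield)
#' fraction, and stages among detected cancers are multinomial with the
#' screened-cohort stage distribution. Only the confirmed-cancer yield is
#' modelled (the registry's raw LDCT positivity rate is not an input), so a
#' positive test result is recorded exactly for confirmed cancers.
#'
#' @param n Number of screened participants (default 10,175).
#' @param detection_rate Confirmed-cancer yield per screen (default
#'   65/10,175, about 0.64%).
#' @param stage_dist Stage distribution among detected cancers (default the
#'   screened-cohort split).
#' @param seed Integer seed.
#' @return Tibble with `participant_id`, `age`, `sex`, `ldct_result`,
#'   `confirmed_cancer`, `stage` (`NA` unless confirmed).
#' @export
generate_screening_registry <- function(n = 10175,
                                        detection_rate = 65 / 10175,
                                        stage_dist = default_parameters()$stage_dist$screened,
                                        seed = 1) {
  if (n < 1) abort("n must be >= 1", class = "lcs_parameter_error")
  if (detection_rate < 0 || detection_rate > 1) {
    abort("detection_rate must lie in [0, 1]", class = "lcs_parameter_error")
  }
  stage_dist <- as.numeric(stage_dist)
  if (any(stage_dist < 0) || abs(sum(stage_dist) - 1) > 1e-9) {
    abort("stage_dist must be a distribution over the five stages",
          class = "lcs_parameter_error")
  }
  set.seed(seed)
  cancer <- runif(n) < detection_rate
  stage <- rep(NA_character_, n)
  if (any(cancer)) {
    stage[cancer] <- sample(lcs_stages(), sum(cancer), replace = TRUE,
                            prob = stage_dist)
  }
  tibble::tibble(
    participant_id = seq_len(n),
    age = sample(50:74, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.6, 0.4)),
    ldct_result = ifelse(cancer, "positive", "negative"),
    confirmed_cancer = cancer,
    stage = stage
  )
}

#' Estimate the cancer-detection fraction of a screening registry
#'
#' @param records Registry tibble from [generate_screening_registry()] (any
#'   data frame with a logical `confirmed_cancer` column).
#' @return One-row tibble: `cancers`, `screened`, `rate`, exact
#'   Clopper-Pearson 95% interval (`conf_low`, `conf_high`).
#' @export
estimate_detection_rate <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    abort("empty registry", class = "lcs_parameter_error")
  }
  x <- sum(records$confirmed_cancer)
  n <- nrow(records)
  ci <- binom.test(x, n)$conf.int
  tibble::tibble(cancers = x, screened = n, rate = x / n,
                 conf_low = ci[1], conf_high = ci[2])
}

#' Generate synthetic stage-labelled treatment-cost claims
#'
#' Emulates a per-patient insurance-claims extract: each patient draws a
#' stage at diagnosis from `stage_mix` and a total treatment cost from a
#' gamma distribution with the stage's mean cost and the given coefficient
#' of variation (medical costs are right-skewed, hence gamma).
#'
#' @param n_patients Number of patients (default 4,947).
#' @param stage_means Named mean treatment cost per stage (CNY).
#' @param cv Coefficient of variation of cost within stage (> 0,
#'   default 0.5).
#' @param stage_mix Stage mix of the claims population (default the
#'   nonscreened stage-at-diagnosis split).
#' @param seed Integer seed.
#' @return Tibble with `patient_id`, `stage`, `cost`.
#' @export
generate_claims <- function(n_patients = 4947,
                            stage_means = default_parameters()$costs$treatment,
                            cv = 0.5,
                            stage_mix = default_parameters()$stage_dist$nonscreened,
                            seed = 1) {
  if (cv <= 0) abort("cv must be > 0", class = "lcs_parameter_error")
  if (any(stage_means[as.numeric(stage_mix) > 0] <= 0)) {
    abort("stage means must be positive for stages with mass",
          class = "lcs_parameter_error")
  }
  set.seed(seed)
  stage <- sample(lcs_stages(), n_patients, replace = TRUE,
                  prob = as.numeric(stage_mix))
  cost <- rgamma(n_patients, shape = 1 / cv^2,
                 scale = as.numeric(stage_means[stage]) * cv^2)
  tibble::tibble(patient_id = seq_len(n_patients), stage = stage, cost = cost)
}

#' Per-stage mean treatment costs from claims
#'
#' @param claims Claims tibble from [generate_claims()] (any data frame
#'   with `stage` and `cost` columns).
#' @return Tibble with one row per stage: `n`, `mean_cost`, `se` (`NA` when
#'   fewer than two records), stages absent from the data reported with
#'   `n = 0` rather than imputed.
#' @export
estimate_stage_costs <- function(claims) {
  if (is.null(claims) || nrow(claims) == 0) {
    abort("empty claims data", class = "lcs_parameter_error")
  }
  obs <- claims |>
    dplyr::group_by(stage = factor(.data$stage, levels = lcs_stages())) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_cost = mean(.data$cost),
                     se = if (dplyr::n() > 1) sd(.data$cost) / sqrt(dplyr::n()) else NA_real_,
                     .groups = "drop")
  tidyr::complete(obs, stage, fill = list(n = 0L)) |>
    dplyr::mutate(stage = as.character(.data$stage))
}

#' Individual-level microsimulation of the cohort model
#'
#' Independent oracle for [run_cohort()]: simulates each person through the
#' same annual event sequence (other-cause death, incidence, stage
#' progression, lung-cancer death, screening and symptomatic detection,
#' cost/utility accrual with discounting) by explicit per-person Bernoulli
#' and categorical draws. The state-evolution logic is written separately
#' from the matrix engine so a shared defect cannot validate itself;
#' results are scaled to the cohort size with Monte Carlo standard errors.
#'
#' @param params A `lcs_parameters` object with detection probabilities set.
#' @param strategy A [strategy()] object or `"annual:55"`-style string.
#' @param n_individuals Number of simulated persons.
#' @param seed Integer seed; identical inputs and seed reproduce the result
#'   exactly.
#' @return A `lcs_microsim` object: `$totals` tibble with `metric`
#'   (`cost`, `qalys`, `lc_deaths`), `estimate` (scaled to cohort size),
#'   `se`, and `$n_individuals`.
#' @export
microsimulate_cohort <- function(params, strategy, n_individuals = 10000, seed = 1) {
  stopifnot(inherits(params, "lcs_parameters"), n_individuals >= 1)
  st <- as_strategy(strategy)
  if (is.null(params$detection)) {
    abort("clinical-detection probabilities are not set; run calibrate_detection() first",
          class = "lcs_calibration_error")
  }
  set.seed(seed)
  n <- as.integer(n_individuals)
  eco <- params$economics
  ages <- seq(st$start_age, eco$horizon_end_age)
  sched <- cohort_incidence_schedule(params, st$start_age)
  screen_cycle <- switch(st$interval,
                         none = rep(FALSE, length(ages)),
                         one_time = seq_along(ages) == 1,
                         annual = rep(TRUE, length(ages)))
  first_screen <- if (any(screen_cycle)) which(screen_cycle)[1] else NA_integer_

  # state codes: 1 healthy, 2-6 undiagnosed CIS-IV, 7-11 diagnosed CIS-IV,
  # 12 lung-cancer death, 13 other-cause death
  HEALTHY <- 1L
  U0 <- 1L   # offset: undiagnosed stage s -> 1 + s
  D0 <- 6L   # offset: diagnosed stage s -> 6 + s
  DEATH_LC <- 12L
  DEATH_OC <- 13L

  pr <- params$transitions$progression
  dth <- params$transitions$lc_death
  diag_progresses <- identical(params$options$diagnosed_progression, "table")
  # per-stage outcome tables for one survivor-year: list of (target stage
  # offsets within the undiagnosed/diagnosed block, probabilities)
  prog_targets <- list(c(2L), c(3L, 4L, 5L), c(4L, 5L), c(5L), integer())
  prog_probs <- list(unname(pr["cis_to_I"]),
                     unname(pr[c("I_to_II", "I_to_III", "I_to_IV")]),
                     unname(pr[c("II_to_III", "II_to_IV")]),
                     unname(pr["III_to_IV"]),
                     numeric())

  sens <- params$ldct$sensitivity
  spec <- params$ldct$specificity
  cs <- params$costs
  screen_fee <- cs$direct_screening + cs$indirect_screening
  workup <- cs$prediagnosis + cs$biopsy
  treat <- as.numeric(cs$treatment)
  maint <- cs$maintenance_fraction * treat
  det <- as.numeric(params$detection)
  screened_split <- as.numeric(params$stage_dist$screened)
  split_mode <- params$options$screen_stage_split %||% "never"

  u_util <- if (identical(params$options$undiagnosed_utility, "healthy")) {
    rep(params$utilities[["Healthy"]], 5)
  } else {
    as.numeric(params$utilities[lcs_stages()])
  }
  util <- c(params$utilities[["Healthy"]], u_util,
            as.numeric(params$utilities[lcs_stages()]), 0, 0)

  state <- rep(HEALTHY, n)
  cost <- numeric(n)
  qaly <- numeric(n)
  r <- eco$discount_rate
  cpi <- cs$cpi_rate

  for (t in seq_along(ages)) {
    yrs <- t - 1
    disc <- (1 + r)^(-yrs)
    infl <- (1 + cpi)^yrs
    p_oc <- annual_all_cause(params, ages[t])
    p_inc <- sched$annual_probability[t]

    # maintenance on the diagnosed pool at the start of the year
    in_d <- state >= (D0 + 1L) & state <= (D0 + 5L)
    cost[in_d] <- cost[in_d] + maint[state[in_d] - D0] * infl * disc

    alive <- state < DEATH_LC
    u_oc <- runif(n)
    u_ev <- runif(n)
    new_state <- state
    die_oc <- alive & u_oc < p_oc
    new_state[die_oc] <- DEATH_OC
    surv <- alive & !die_oc

    idx <- which(surv & state == HEALTHY)
    new_state[idx[u_ev[idx] < p_inc]] <- U0 + 1L

    for (s in 1:5) {
      idx <- which(surv & state == U0 + s)
      if (length(idx)) {
        pp <- c(prog_probs[[s]], dth[[s]])
        tg <- c(U0 + prog_targets[[s]], DEATH_LC)
        cum <- cumsum(pp)
        pick <- findInterval(u_ev[idx], c(0, cum), rightmost.closed = FALSE)
        moved <- pick <= length(pp) & pick >= 1
        new_state[idx[moved]] <- tg[pick[moved]]
      }
      idx <- which(surv & state == D0 + s)
      if (length(idx)) {
        pp <- c(if (diag_progresses) prog_probs[[s]] else numeric(), dth[[s]])
        tg <- c(if (diag_progresses) D0 + prog_targets[[s]] else integer(), DEATH_LC)
        cum <- cumsum(pp)
        pick <- findInterval(u_ev[idx], c(0, cum), rightmost.closed = FALSE)
        moved <- pick <= length(pp) & pick >= 1
        new_state[idx[moved]] <- tg[pick[moved]]
      }
    }
    state <- new_state

    if (screen_cycle[t]) {
      undiag <- state >= HEALTHY & state <= (U0 + 5L)
      cost[undiag] <- cost[undiag] + screen_fee * infl * disc
      u_scr <- runif(n)
      hit <- undiag & state > HEALTHY & u_scr < sens
      if (any(hit)) {
        ih <- which(hit)
        if (identical(split_mode, "always") ||
            (identical(split_mode, "entry") && identical(t, first_screen))) {
          new_stage <- sample(1:5, length(ih), replace = TRUE, prob = screened_split)
        } else {
          new_stage <- state[ih] - U0
        }
        state[ih] <- D0 + new_stage
        cost[ih] <- cost[ih] + (workup + treat[new_stage]) * infl * disc
      }
      fp <- undiag & state == HEALTHY & runif(n) < (1 - spec)
      cost[fp] <- cost[fp] + workup * infl * disc
    }

    u_sym <- runif(n)
    is_u <- state >= (U0 + 1L) & state <= (U0 + 5L)
    sym <- is_u & u_sym < det[pmax(state - U0, 1L)]
    if (any(sym)) {
      is_ <- which(sym)
      stg <- state[is_] - U0
      state[is_] <- D0 + stg
      cost[is_] <- cost[is_] + (workup + treat[stg]) * infl * disc
    }

    qaly <- qaly + util[state] * disc * eco$cycle_length
  }

  died_lc <- as.numeric(state == DEATH_LC)
  scale <- eco$cohort_size
  mc_se <- function(x) if (n > 1) sd(x) / sqrt(n) * scale else NA_real_
  totals <- tibble::tibble(
    metric = c("cost", "qalys", "lc_deaths"),
    estimate = c(mean(cost), mean(qaly), mean(died_lc)) * scale,
    se = c(mc_se(cost), mc_se(qaly), mc_se(died_lc))
  )
  structure(list(totals = totals, n_individuals = n, strategy = st, seed = seed),
            class = "lcs_microsim")
}

#' @export
print.lcs_microsim <- function(x, ...) {
  cat("<lcs_microsim>", x$n_individuals, "individuals,", x$strategy$interval,
      "screening, start age", x$strategy$start_age, "\n")
  print(x$totals)
  invisible(x)
}
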