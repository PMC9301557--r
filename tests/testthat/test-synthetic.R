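test_that("the screening registry reproduces the yield and stage split", {
  reg <- generate_screening_registry(seed = 1)
  expect_identical(nrow(reg), 10175L)
  # confirmed implies positive; stage present iff confirmed
  expect_true(all(reg$ldct_result[reg$confirmed_cancer] == "positive"))
  expect_true(all(is.na(reg$stage) == !reg$confirmed_cancer))
  # binomial(10175, 65/10175): observed count within 4 sd of 65
  expect_lt(abs(sum(reg$confirmed_cancer) - 65), 4 * sqrt(65))

  none <- generate_screening_registry(n = 500, detection_rate = 0, seed = 2)
  expect_identical(sum(none$confirmed_cancer), 0L)

  # law of large numbers on the stage split
  big <- generate_screening_registry(n = 1e6, seed = 3)
  props <- table(factor(big$stage, levels = c("CIS", "I", "II", "III", "IV")))
  props <- as.numeric(props) / sum(props)
  expect_true(all(abs(props - c(0.0370, 0.6852, 0.0370, 0.1852, 0.0556)) < 0.005))

  expect_error(generate_screening_registry(detection_rate = 2),
               class = "lcs_parameter_error")
})

test_that("the detection-rate estimator returns the exact binomial interval", {
  reg <- tibble::tibble(confirmed_cancer = c(rep(TRUE, 65), rep(FALSE, 10110)))
  est <- estimate_detection_rate(reg)
  expect_equal(est$rate, 65 / 10175)
  expect_equal(round(100 * est$rate, 2), 0.64)
  expect_lt(est$conf_low, est$rate)
  expect_gt(est$conf_high, est$rate)

  zero <- estimate_detection_rate(tibble::tibble(confirmed_cancer = rep(FALSE, 100)))
  expect_equal(zero$rate, 0)
  expect_gt(zero$conf_high, 0)

  all_pos <- estimate_detection_rate(tibble::tibble(confirmed_cancer = rep(TRUE, 7)))
  expect_equal(all_pos$rate, 1)

  expect_error(estimate_detection_rate(tibble::tibble(confirmed_cancer = logical())),
               class = "lcs_parameter_error")
})

test_that("synthetic claims recover the stage mean costs", {
  cl <- generate_claims(seed = 4)
  expect_identical(nrow(cl), 4947L)
  expect_true(all(cl$cost > 0))
  # nonscreened stage mix has no carcinoma in situ
  expect_false(any(cl$stage == "CIS"))

  est <- estimate_stage_costs(cl)
  truth <- default_parameters()$costs$treatment
  for (s in c("I", "II", "III", "IV")) {
    row <- est[est$stage == s, ]
    expect_gt(row$n, 1)
    expect_lt(abs(row$mean_cost - truth[[s]]), 3 * row$se)
  }
  expect_identical(est$n[est$stage == "CIS"], 0L)

  # cv -> 0 degenerates to the exact stage means
  tight <- generate_claims(n_patients = 50, cv = 1e-6, seed = 5)
  expect_equal(tight$cost, unname(truth[tight$stage]), tolerance = 1e-4)

  one <- estimate_stage_costs(tibble::tibble(stage = "I", cost = 1234))
  expect_equal(one$mean_cost[one$stage == "I"], 1234)
  expect_true(is.na(one$se[one$stage == "I"]))
  two <- estimate_stage_costs(tibble::tibble(stage = c("II", "II"),
                                             cost = c(100, 200)))
  expect_equal(two$mean_cost[two$stage == "II"], 150)

  expect_error(generate_claims(cv = 0), class = "lcs_parameter_error")
})

test_that("a deathless microsimulated person accrues exactly one QALY a year", {
  p <- inert_params
  p$options$incidence_multiplier <- 0
  ms <- microsimulate_cohort(p, strategy("none", 70), n_individuals = 200, seed = 1)
  q <- ms$totals[ms$totals$metric == "qalys", ]
  expect_equal(q$estimate, 10 * 1e5)
  expect_equal(q$se, 0)
  expect_equal(ms$totals$estimate[ms$totals$metric == "lc_deaths"], 0)
})

test_that("microsimulation is byte-identical under a fixed seed", {
  a <- microsimulate_cohort(cal_params, strategy("annual", 70),
                            n_individuals = 2000, seed = 9)
  b <- microsimulate_cohort(cal_params, strategy("annual", 70),
                            n_individuals = 2000, seed = 9)
  expect_identical(a$totals, b$totals)
  c_ <- microsimulate_cohort(cal_params, strategy("annual", 70),
                             n_individuals = 2000, seed = 10)
  expect_false(identical(a$totals$estimate, c_$totals$estimate))
})

test_that("the microsimulation agrees with the cohort engine", {
  for (arm in c("none", "annual")) {
    eng <- run_cohort(cal_params, strategy(arm, 70))$summary
    ms <- microsimulate_cohort(cal_params, strategy(arm, 70),
                               n_individuals = 30000, seed = 21)
    expected <- c(cost = eng$total_cost, qalys = eng$total_qalys,
                  lc_deaths = eng$lc_deaths)
    z <- (ms$totals$estimate - expected[ms$totals$metric]) / ms$totals$se
    expect_true(all(abs(z) < 3), label = paste("z-scores", arm))
  }
})

test_that("screening averts simulated lung-cancer deaths at matched seeds", {
  deaths <- function(arm) {
    ms <- microsimulate_cohort(cal_params, strategy(arm, 70),
                               n_individuals = 50000, seed = 33)
    ms$totals$estimate[ms$totals$metric == "lc_deaths"]
  }
  expect_lt(deaths("annual"), deaths("none"))
})
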