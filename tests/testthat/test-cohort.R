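test_that("discount factors follow the closed form with year 0 undiscounted", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(1, 0.05), 1 / 1.05)
  expect_equal(discount_factor(2, 0.05), 0.907029478458, tolerance = 1e-10)
  expect_error(discount_factor(-1, 0.05), class = "lcs_parameter_error")
})

test_that("cycle transition matrices are row-stochastic at every age", {
  sched <- cohort_incidence_schedule(base_params, 50)
  for (t in seq_len(nrow(sched))) {
    m <- build_cycle_transition(base_params, sched$age[t],
                                sched$annual_probability[t])
    expect_equal(unname(rowSums(m)), rep(1, 13), tolerance = 1e-9)
    expect_true(all(m >= 0))
    # death states absorb
    expect_equal(m["Death_LungCancer", "Death_LungCancer"], 1)
    expect_equal(m["Death_OtherCause", "Death_OtherCause"], 1)
  }
})

test_that("transition rows implement the published probabilities", {
  m <- build_cycle_transition(base_params, 60, 0.002)
  p_oc <- 1 - (1 - 0.0819)^(1 / 5)
  surv <- 1 - p_oc
  # healthy row routes incidence into undiagnosed CIS after other-cause death
  expect_equal(m["Healthy", "Undiagnosed_CIS"], surv * 0.002)
  # stage I splits to II/III/IV in proportion 0.3682/0.0328/0.0745
  expect_equal(m["Undiagnosed_I", "Undiagnosed_II"], surv * 0.3682)
  expect_equal(m["Undiagnosed_I", "Undiagnosed_III"], surv * 0.0328)
  expect_equal(m["Undiagnosed_I", "Undiagnosed_IV"], surv * 0.0745)
  expect_equal(m["Undiagnosed_I", "Death_LungCancer"], surv * 0.04)
  # the stage IV death entry derives from the 0.18 annual probability
  expect_equal(m["Undiagnosed_IV", "Death_LungCancer"], surv * 0.18)
  expect_equal(m["Diagnosed_IV", "Death_LungCancer"], surv * 0.18)
  # maintenance stages do not progress by default
  expect_equal(m["Diagnosed_I", "Diagnosed_II"], 0)

  p <- base_params
  p$options$diagnosed_progression <- "table"
  m2 <- build_cycle_transition(p, 60, 0.002)
  expect_equal(m2["Diagnosed_I", "Diagnosed_II"], surv * 0.3682)

  # no mortality and no incidence leaves the healthy row an identity
  p0 <- base_params
  p0$mortality$all_cause$value <- rep(0, 5)
  m0 <- build_cycle_transition(p0, 60, 0)
  expect_equal(m0["Healthy", "Healthy"], 1)

  expect_error(build_cycle_transition(base_params, 60, 1.5),
               class = "lcs_parameter_error")
})

test_that("a deathless, undiscounted cohort accrues exactly one QALY per year", {
  run <- run_cohort(inert_params, strategy("none", 70))
  expect_equal(run$summary$total_qalys, 10 * 1e5)
  expect_equal(run$summary$total_qalys_undiscounted, 10 * 1e5)
  expect_equal(run$summary$lc_deaths, 0)
})

test_that("cohort mass is conserved at every cycle", {
  for (st in list(strategy("none", 50), strategy("annual", 50),
                  strategy("one_time", 70))) {
    tr <- tidy(run_cohort(cal_params, st))
    occ <- rowSums(tr[paste0("n_", health_states())])
    expect_true(all(abs(occ - 1e5) < 1e-6))
  }
})

test_that("zero discounting makes discounted and undiscounted totals equal", {
  p <- cal_params
  p$economics$discount_rate <- 0
  run <- run_cohort(p, strategy("annual", 50))
  expect_identical(run$summary$total_cost, run$summary$total_cost_undiscounted)
  expect_identical(run$summary$total_qalys, run$summary$total_qalys_undiscounted)
})

test_that("totals decrease weakly as the discount rate rises", {
  costs <- qalys <- numeric()
  for (r in c(0, 0.03, 0.05, 0.08)) {
    p <- cal_params
    p$economics$discount_rate <- r
    s <- run_cohort(p, strategy("annual", 50))$summary
    costs <- c(costs, s$total_cost)
    qalys <- c(qalys, s$total_qalys)
  }
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
})

test_that("an inert screen changes cost by exactly the screening fee", {
  p <- cal_params
  p$ldct$sensitivity <- 0
  p$ldct$specificity <- 1
  non <- run_cohort(p, strategy("none", 70))
  ann <- run_cohort(p, strategy("annual", 70))
  expect_equal(ann$summary$total_qalys, non$summary$total_qalys)
  expect_equal(ann$summary$lc_deaths, non$summary$lc_deaths)
  tr <- tidy(ann)
  fee <- 245.86 + 23.07
  expected_extra <- sum(tr$screens * fee * discount_factor(tr$cycle, 0.05))
  expect_equal(ann$summary$total_cost - non$summary$total_cost, expected_extra)
  expect_equal(ann$summary$false_positives, 0)
})

test_that("screening detects, charges and flags false positives as specified", {
  state <- setNames(numeric(13), health_states())
  state["Healthy"] <- 10175
  out <- apply_screening_event(state, base_params)
  # (1 - 0.81) * 10,175 false-positive workups
  expect_equal(out$counters$false_positives, 1933.25)
  expect_equal(out$counters$cost_fp, 1933.25 * (628.36 + 1232.44))
  expect_equal(out$counters$detected_total, 0)
  expect_equal(out$counters$cost_screen, 10175 * (245.86 + 23.07))

  # an inert test (sens 0, spec 1) only charges the screening fee
  p <- base_params
  p$ldct$sensitivity <- 0
  p$ldct$specificity <- 1
  state["Undiagnosed_I"] <- 500
  out2 <- apply_screening_event(state, p)
  expect_equal(out2$state, state)
  expect_equal(out2$cost, (10175 + 500) * (245.86 + 23.07))

  # detected mass moves stage-preserving by default, split when asked
  out3 <- apply_screening_event(state, base_params)
  expect_equal(unname(out3$state["Diagnosed_I"]), 500 * 0.79)
  p_split <- base_params
  p_split$options$screen_stage_split <- "always"
  out4 <- apply_screening_event(state, p_split)
  expect_equal(unname(out4$state["Diagnosed_IV"]), 500 * 0.79 * 0.0556)
})

test_that("symptomatic detection uses calibrated hazards and bills diagnosis", {
  state <- setNames(numeric(13), health_states())
  state["Undiagnosed_IV"] <- 100
  p <- set_detection(base_params, c(0, 0, 0, 0, 0.5))
  out <- apply_symptomatic_detection(state, p)
  expect_equal(unname(out$state["Diagnosed_IV"]), 50)
  expect_equal(out$cost, 50 * (628.36 + 1232.44 + 116471.34))

  p0 <- set_detection(base_params, rep(0, 5))
  out0 <- apply_symptomatic_detection(state, p0)
  expect_equal(out0$state, state)
  expect_equal(out0$cost, 0)

  expect_error(apply_symptomatic_detection(state, base_params),
               class = "lcs_calibration_error")
  expect_error(run_cohort(base_params, strategy("none", 50)),
               class = "lcs_calibration_error")
})

test_that("maintenance charges 10% of stage treatment per diagnosed year", {
  tr <- tidy(run_cohort(cal_params, strategy("annual", 65)))
  treat <- cal_params$costs$treatment
  d_cols <- paste0("n_Diagnosed_", names(treat))
  # maintenance in cycle t is billed on the diagnosed pool entering it
  for (t in c(3, 7)) {
    expected <- 0.10 * sum(unlist(tr[t - 1, d_cols]) * treat)
    expect_equal(tr$cost_maintenance[t], expected)
  }
  # one person-year in diagnosed stage IV costs 11,647.134 undiscounted
  expect_equal(0.10 * unname(treat["IV"]), 11647.134)
})

test_that("run summaries are internally consistent", {
  run <- run_cohort(cal_params, strategy("one_time", 60))
  s <- run$summary
  expect_equal(s$per_person_cost * 1e5, s$total_cost)
  tr <- tidy(run)
  expect_equal(sum(tr$cost_discounted), s$total_cost)
  expect_equal(sum(tr$lc_deaths), s$lc_deaths, tolerance = 1e-9)
  expect_true(all(tr$cost_discounted <= tr$cost + 1e-9))
  # one-time screening screens only in the first program year
  expect_true(tr$screens[1] > 0)
  expect_true(all(tr$screens[-1] == 0))

  g <- glance(run)
  expect_identical(g$interval, "one_time")
  expect_equal(g$total_cost, s$total_cost)
})
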