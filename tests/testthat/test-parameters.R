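test_that("packaged defaults load, self-validate and carry canonical units", {
  p <- base_params
  expect_s3_class(p, "lcs_parameters")
  v <- validate_parameters(p)
  expect_identical(sum(v$severity == "error"), 0L)

  # percent-style entries are stored as proportions
  expect_equal(p$ldct$sensitivity, 0.79)
  expect_equal(p$ldct$specificity, 0.81)
  expect_equal(p$mortality$all_cause$value[1], 0.0359)
  expect_equal(unname(p$costs$treatment["IV"]), 116471.34)
  expect_equal(p$economics$threshold, 212676)
  expect_equal(sum(p$stage_dist$screened), 1, tolerance = 1e-9)
  # per-stage outgoing mass for stage I is 0.5155 <= 1, hence no violation
  expect_equal(unname(p$transitions$progression["I_to_II"] +
                        p$transitions$progression["I_to_III"] +
                        p$transitions$progression["I_to_IV"] +
                        p$transitions$lc_death["I"]), 0.5155)
})

test_that("config overrides merge onto defaults and are tracked", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("ldct:", "  sensitivity: 0.79", "economics:", "  discount_rate: 0.03"), cfg)
  p <- load_parameters(cfg)
  expect_equal(p$ldct$sensitivity, 0.79)
  expect_equal(p$economics$discount_rate, 0.03)
  # untouched fields keep the packaged values
  expect_equal(p$ldct$specificity, base_params$ldct$specificity)
  expect_equal(p$costs$biopsy, base_params$costs$biopsy)
  expect_setequal(p$meta$overridden, c("ldct$sensitivity", "economics$discount_rate"))

  # empty config is exactly the packaged default set
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  p0 <- load_parameters(empty)
  p0$meta <- base_params$meta
  expect_equal(p0, base_params)
})

test_that("percent units keys convert and ambiguous magnitudes are refused", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("ldct:", "  sensitivity: {value: 63, units: percent}"), cfg)
  expect_equal(load_parameters(cfg)$ldct$sensitivity, 0.63)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("ldct:", "  specificity: 1.2"), bad)
  expect_error(load_parameters(bad), "specificity", class = "lcs_config_error")

  garbled <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("ldct: [unclosed", "  nonsense::"), garbled)
  expect_error(load_parameters(garbled), class = "lcs_config_error")

  expect_error(load_parameters("no/such/file.yaml"), class = "lcs_config_error")
})

test_that("validate_parameters reports violations without stopping", {
  p <- base_params
  p$stage_dist$nonscreened <- c(CIS = 0.5, I = 0.5, II = 0.5, III = 0, IV = 0)
  v <- validate_parameters(p)
  expect_true(any(grepl("sum to 1", v$rule) & grepl("nonscreened", v$parameter)))

  p2 <- base_params
  p2$economics$discount_rate <- 0.2
  expect_true(any(grepl("discount_rate", validate_parameters(p2)$parameter)))

  p3 <- base_params
  p3$transitions$lc_death["I"] <- 0.8 # 0.4755 progression + 0.8 death > 1
  expect_true(any(grepl("stage I", validate_parameters(p3)$parameter)))

  # an odds ratio below 1 is only a warning, not an error
  p4 <- base_params
  p4$risk$odds_ratio_smoker <- 0.8
  v4 <- validate_parameters(p4)
  expect_identical(sum(v4$severity == "error"), 0L)
  expect_true(any(v4$severity == "warning"))
})

test_that("a written parameter set reloads identically", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(cal_params, f)
  p2 <- load_parameters(f)
  p2$meta <- cal_params$meta
  expect_equal(p2, cal_params, tolerance = 1e-12)
})

test_that("the five-year reading of all-cause mortality converts to annual", {
  m5 <- build_cycle_transition(base_params, 52, 0)
  expect_equal(m5["Healthy", "Death_OtherCause"], 1 - (1 - 0.0359)^(1 / 5))

  p <- base_params
  p$options$all_cause_interpretation <- "annual"
  m1 <- build_cycle_transition(p, 52, 0)
  expect_equal(m1["Healthy", "Death_OtherCause"], 0.0359)
})

test_that("psa_distribution_params moment-matches beta and gamma", {
  g <- psa_distribution_params(245.86, 0.1, "gamma")
  expect_equal(g$shape, 100)
  expect_equal(g$scale, 2.4586)

  b <- psa_distribution_params(0.79, 0.1, "beta")
  ab_expected <- 0.21 / (0.79 * 0.01) - 1
  expect_equal(b$shape1 + b$shape2, ab_expected)
  expect_equal(b$shape1, 0.79 * ab_expected)
  expect_false(b$clamped)

  # sampled moments agree with the request to within 1%
  set.seed(1)
  gs <- psa_sample(1e6, 245.86, 0.1, "gamma")
  expect_equal(mean(gs), 245.86, tolerance = 0.01)
  expect_equal(sd(gs), 24.586, tolerance = 0.01)
  bs <- psa_sample(1e6, 0.79, 0.1, "beta")
  expect_equal(mean(bs), 0.79, tolerance = 0.01)
  expect_equal(sd(bs), 0.079, tolerance = 0.01)

  # infeasible beta variance clamps the cv and flags it
  cl <- psa_distribution_params(0.9, 0.5, "beta")
  expect_true(cl$clamped)
  expect_true(cl$shape1 > 0 && cl$shape2 > 0)

  expect_error(psa_distribution_params(1.2, 0.1, "beta"), class = "lcs_parameter_error")
  expect_error(psa_distribution_params(-1, 0.1, "gamma"), class = "lcs_parameter_error")
  expect_error(psa_distribution_params(0.5, 0, "beta"), class = "lcs_parameter_error")
})

test_that("PSA draws re-validate and keep their support", {
  set.seed(7)
  for (i in 1:25) {
    q <- lungscreen:::draw_psa_parameters(cal_params, cv = 0.1)
    v <- validate_parameters(q)
    # occasional transition-mass violations are allowed (the PSA loop
    # resamples them); everything else must stay in range
    other <- v[!grepl("transitions", v$parameter), ]
    expect_identical(sum(other$severity == "error"), 0L)
    expect_true(all(q$utilities >= 0 & q$utilities <= 1))
    expect_true(all(unlist(q$costs[c("direct_screening", "biopsy")]) >= 0))
  }
})
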