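#' Packaged base-case parameter set
#'
#' Returns the full model input bundle shipped with the package: age-banded
#' lung-cancer incidence and all-cause mortality, smoking prevalence by sex,
#' the heavy-smoker relative risk, stage distributions at diagnosis for the
#' screened and nonscreened pathways, LDCT sensitivity/specificity, annual
#' stage transition and lung-cancer death probabilities, stage utilities,
#' screening/diagnosis/treatment costs, and economic settings (5% discount
#' rate, 212,676 CNY/QALY threshold, horizon age 79, cohort of 100,000).
#'
#' The smoker odds ratio is not part of the published input table; the
#' packaged value (2.5) is an assumption and is flagged as such in
#' `$risk$odds_ratio_assumed`.
#'
#' @return A `lcs_parameters` object (named list).
#' @export
#' @examples
#' p <- default_parameters()
#' p$ldct$sensitivity
default_parameters <- function() {
  path <- system.file("extdata", "table1_defaults.yaml", package = "lungscreen")
  load_parameters(path)
}

#' Load model parameters from a YAML or JSON configuration file
#'
#' Reads a (possibly partial) configuration and fills every omitted field
#' from the packaged base-case defaults. Percent-style entries must be given
#' as `{value: 79, units: percent}`; bare numbers are taken as proportions,
#' which prevents silent 100-fold unit errors.
#'
#' @param config_path Path to a YAML (or JSON) configuration file, or `NULL`
#'   for pure defaults.
#' @return A validated `lcs_parameters` object. Fields overridden by the
#'   config are recorded in `$meta$overridden`.
#' @export
load_parameters <- function(config_path = NULL) {
  defaults_path <- system.file("extdata", "table1_defaults.yaml", package = "lungscreen")
  raw <- yaml::read_yaml(defaults_path)
  overridden <- character()
  if (!is.null(config_path) &&
      !identical(normalizePath(config_path, mustWork = FALSE),
                 normalizePath(defaults_path, mustWork = FALSE))) {
    if (!file.exists(config_path)) {
      abort(paste0("configuration file not found: ", config_path),
            class = "lcs_config_error")
    }
    user <- tryCatch(
      {
        if (grepl("\\.json$", config_path, ignore.case = TRUE)) {
          jsonlite::read_json(config_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
        } else {
          yaml::read_yaml(config_path)
        }
      },
      error = function(e) {
        abort(paste0("failed to parse configuration '", config_path, "': ",
                     conditionMessage(e)),
              class = "lcs_config_error")
      }
    )
    if (!is.null(user)) {
      overridden <- leaf_paths(user)
      raw <- deep_merge(raw, user)
    }
  }
  p <- canonicalise_parameters(raw)
  p$meta$overridden <- overridden
  p$meta$source <- config_path %||% "packaged defaults"
  v <- validate_parameters(p)
  bad <- v[v$severity == "error", , drop = FALSE]
  if (nrow(bad) > 0) {
    abort(paste0("invalid parameter configuration:\n",
                 paste0("  - ", bad$parameter, " = ", signif(bad$value, 6),
                        ": ", bad$rule, collapse = "\n")),
          class = "lcs_validation_error")
  }
  for (w in which(v$severity == "warning")) {
    warn(paste0(v$parameter[w], " = ", signif(v$value[w], 6), ": ", v$rule[w]))
  }
  p
}

#' Write a parameter set back to YAML
#'
#' Serialises the canonical (proportion-scale) parameter set so that
#' `load_parameters()` on the written file reproduces it exactly.
#'
#' @param params A `lcs_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "lcs_parameters"))
  out <- list(
    incidence_per_100k = df_to_rows(params$incidence),
    smoking_rate = df_to_rows(params$smoking),
    risk = params$risk,
    stage_distribution = lapply(params$stage_dist, as.list),
    ldct = params$ldct,
    mortality = list(
      all_cause = df_to_rows(params$mortality$all_cause),
      lung_cancer_per_100k = df_to_rows(params$mortality$lc_rate)
    ),
    transitions = list(progression = as.list(params$transitions$progression),
                       lc_death = as.list(params$transitions$lc_death)),
    utilities = as.list(params$utilities),
    costs = c(params$costs[setdiff(names(params$costs), "treatment")],
              list(treatment = as.list(params$costs$treatment))),
    economics = params$economics,
    psa = params$psa,
    options = params$options
  )
  if (!is.null(params$detection)) out$detection <- as.list(params$detection)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs (ranges, stage
#' distributions summing to one, per-stage outgoing transition mass not
#' exceeding one, economic settings) and reports violations instead of
#' stopping.
#'
#' @param params A `lcs_parameters` object.
#' @return A tibble with columns `parameter`, `value`, `rule`, `severity`
#'   (`"error"` or `"warning"`); zero error rows means the set is valid.
#' @export
validate_parameters <- function(params) {
  rows <- list()
  add <- function(parameter, value, rule, severity = "error") {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      parameter = parameter, value = as.numeric(value)[1],
      rule = rule, severity = severity)
  }
  chk_range <- function(x, nm, lo = 0, hi = Inf, lo_ok = TRUE, hi_ok = TRUE) {
    for (i in seq_along(x)) {
      v <- x[i]
      bad <- !is.finite(v) || (if (lo_ok) v < lo else v <= lo) ||
        (if (hi_ok) v > hi else v >= hi)
      if (bad) add(paste0(nm, if (length(x) > 1) paste0("[", names(x)[i] %||% i, "]") else ""),
                   v, paste0("must be in [", lo, ", ", hi, "]"))
    }
  }

  chk_bands <- function(tbl, nm) {
    if (any(tbl$age_lower >= tbl$age_upper)) add(nm, NA, "age bands need lower < upper")
    if (is.unsorted(tbl$age_lower)) add(nm, NA, "age bands must be ordered")
  }
  chk_bands(params$incidence, "incidence_per_100k")
  chk_range(params$incidence$male, "incidence_per_100k$male", 0)
  chk_range(params$incidence$female, "incidence_per_100k$female", 0)
  chk_range(params$smoking$male, "smoking_rate$male", 0, 1)
  chk_range(params$smoking$female, "smoking_rate$female", 0, 1)

  if (!is.finite(params$risk$odds_ratio_smoker) || params$risk$odds_ratio_smoker <= 0) {
    add("risk$odds_ratio_smoker", params$risk$odds_ratio_smoker, "must be > 0")
  } else if (params$risk$odds_ratio_smoker < 1) {
    add("risk$odds_ratio_smoker", params$risk$odds_ratio_smoker,
        "odds ratio < 1 implies protective smoking", "warning")
  }
  if (!is.finite(params$risk$rr_heavy) || params$risk$rr_heavy <= 0) {
    add("risk$rr_heavy", params$risk$rr_heavy, "must be > 0")
  }

  for (nm in names(params$stage_dist)) {
    d <- params$stage_dist[[nm]]
    chk_range(d, paste0("stage_distribution$", nm), 0, 1)
    if (abs(sum(d) - 1) > 1e-9) {
      add(paste0("stage_distribution$", nm), sum(d), "stage proportions must sum to 1 (within 1e-9)")
    }
  }

  chk_range(params$ldct$sensitivity, "ldct$sensitivity", 0, 1)
  chk_range(params$ldct$specificity, "ldct$specificity", 0, 1)

  chk_range(params$mortality$all_cause$value, "mortality$all_cause", 0, 1)
  chk_range(params$mortality$lc_rate$value, "mortality$lung_cancer_per_100k", 0)

  pr <- params$transitions$progression
  dth <- params$transitions$lc_death
  chk_range(pr, "transitions$progression", 0, 1)
  chk_range(dth, "transitions$lc_death", 0, 1)
  out_mass <- c(
    CIS = unname(pr["cis_to_I"] + dth["CIS"]),
    I = unname(pr["I_to_II"] + pr["I_to_III"] + pr["I_to_IV"] + dth["I"]),
    II = unname(pr["II_to_III"] + pr["II_to_IV"] + dth["II"]),
    III = unname(pr["III_to_IV"] + dth["III"]),
    IV = unname(dth["IV"])
  )
  for (s in names(out_mass)) {
    if (is.finite(out_mass[[s]]) && out_mass[[s]] > 1) {
      add(paste0("transitions[stage ", s, "]"), out_mass[[s]],
          "outgoing progression + death probability must be <= 1")
    }
  }

  chk_range(params$utilities, "utilities", 0, 1)

  for (nm in c("direct_screening", "indirect_screening", "prediagnosis", "biopsy")) {
    chk_range(params$costs[[nm]], paste0("costs$", nm), 0)
  }
  chk_range(params$costs$treatment, "costs$treatment", 0)
  chk_range(params$costs$maintenance_fraction, "costs$maintenance_fraction", 0, 1)
  chk_range(params$costs$cpi_rate, "costs$cpi_rate", 0)

  eco <- params$economics
  chk_range(eco$discount_rate, "economics$discount_rate", 0, 0.08)
  if (!is.finite(eco$threshold) || eco$threshold <= 0) {
    add("economics$threshold", eco$threshold, "must be > 0")
  }
  if (!is.finite(eco$horizon_end_age) || eco$horizon_end_age <= 70 || eco$horizon_end_age > 120) {
    add("economics$horizon_end_age", eco$horizon_end_age,
        "must exceed the oldest start age (70) and be plausible (<= 120)")
  }
  if (!is.finite(eco$cohort_size) || eco$cohort_size <= 0) {
    add("economics$cohort_size", eco$cohort_size, "must be > 0")
  }
  if (!identical(as.numeric(eco$cycle_length), 1)) {
    add("economics$cycle_length", eco$cycle_length, "cycle length is fixed at 1 year")
  }

  if (!is.finite(params$psa$cv) || params$psa$cv <= 0) {
    add("psa$cv", params$psa$cv, "must be > 0")
  }
  if (!is.null(params$detection)) {
    chk_range(params$detection, "detection", 0, 1)
    if (length(params$detection) != 5) add("detection", length(params$detection),
                                           "needs one annual probability per stage")
  }
  opt <- params$options
  chk_opt <- function(nm, allowed) {
    if (!isTRUE(opt[[nm]] %in% allowed)) {
      add(paste0("options$", nm), NA,
          paste0("must be one of: ", paste(allowed, collapse = ", ")))
    }
  }
  chk_opt("all_cause_interpretation", c("annual", "five_year"))
  chk_opt("rate_conversion", c("linear", "exponential"))
  chk_opt("heavy_incidence_mode", c("as_printed", "smoker_based"))
  chk_opt("diagnosed_progression", c("none", "table"))
  chk_opt("undiagnosed_utility", c("stage", "healthy"))
  chk_opt("band_extrapolation", c("carry_forward", "linear"))
  chk_opt("screen_stage_split", c("never", "entry", "always"))
  if (!is.null(opt$sex_mix)) chk_range(opt$sex_mix, "options$sex_mix", 0, 1)
  chk_range(opt$incidence_multiplier, "options$incidence_multiplier", 0)

  if (length(rows) == 0) {
    tibble::tibble(parameter = character(), value = numeric(),
                   rule = character(), severity = character())
  } else {
    dplyr::bind_rows(rows)
  }
}

#' Moment-matched hyperparameters for PSA distributions
#'
#' Solves for beta or gamma hyperparameters whose mean equals `mean` and
#' whose standard deviation equals `cv * mean`. For the beta family, when
#' the requested variance is infeasible (`var >= mean * (1 - mean)`), the
#' coefficient of variation is clamped downward and flagged.
#'
#' @param mean Target mean: in (0, 1) for beta, > 0 for gamma.
#' @param cv Coefficient of variation (> 0).
#' @param family `"beta"` or `"gamma"`.
#' @return A list: `family`, hyperparameters (`shape1`/`shape2` or
#'   `shape`/`scale`), the achieved `mean` and `sd`, and `clamped`.
#' @export
#' @examples
#' psa_distribution_params(245.86, 0.1, "gamma") # shape 100, scale 2.4586
psa_distribution_params <- function(mean, cv, family = c("beta", "gamma")) {
  family <- match.arg(family)
  if (!is.finite(mean)) abort("mean must be finite", class = "lcs_parameter_error")
  if (!is.finite(cv) || cv <= 0) {
    abort("cv must be a positive number (degenerate cv = 0 is not a distribution)",
          class = "lcs_parameter_error")
  }
  if (family == "gamma") {
    if (mean <= 0) abort("gamma requires mean > 0", class = "lcs_parameter_error")
    shape <- 1 / cv^2
    scale <- mean * cv^2
    return(list(family = "gamma", shape = shape, scale = scale,
                mean = mean, sd = cv * mean, clamped = FALSE))
  }
  if (mean <= 0 || mean >= 1) {
    abort("beta requires mean in (0, 1)", class = "lcs_parameter_error")
  }
  clamped <- FALSE
  cv_max <- sqrt((1 - mean) / mean)
  if (cv >= cv_max) {
    cv <- 0.99 * cv_max
    clamped <- TRUE
  }
  v <- (cv * mean)^2
  ab <- mean * (1 - mean) / v - 1
  list(family = "beta", shape1 = mean * ab, shape2 = (1 - mean) * ab,
       mean = mean, sd = cv * mean, clamped = clamped)
}

#' Draw moment-matched PSA samples
#'
#' @param n Number of draws.
#' @inheritParams psa_distribution_params
#' @return Numeric vector of length `n`.
#' @export
psa_sample <- function(n, mean, cv, family = c("beta", "gamma")) {
  h <- psa_distribution_params(mean, cv, family)
  if (h$family == "gamma") {
    rgamma(n, shape = h$shape, scale = h$scale)
  } else {
    rbeta(n, h$shape1, h$shape2)
  }
}

#' Attach clinical-detection probabilities to a parameter set
#'
#' @param params A `lcs_parameters` object.
#' @param probs Named (CIS, I, II, III, IV) or positional vector of annual
#'   symptomatic-detection probabilities.
#' @return The updated parameter set.
#' @seealso [calibrate_detection()]
#' @export
set_detection <- function(params, probs) {
  stopifnot(inherits(params, "lcs_parameters"), length(probs) == 5)
  probs <- as.numeric(probs)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    abort("detection probabilities must lie in [0, 1]", class = "lcs_parameter_error")
  }
  params$detection <- setNames(probs, lcs_stages())
  params
}

#' @export
print.lcs_parameters <- function(x, ...) {
  cat("<lcs_parameters>\n")
  cat("  source:", x$meta$source, "\n")
  cat("  cohort:", format(x$economics$cohort_size, big.mark = ","),
      "heavy smokers, horizon age", x$economics$horizon_end_age, "\n")
  cat("  discount:", x$economics$discount_rate,
      "| threshold:", format(x$economics$threshold, big.mark = ","), "CNY/QALY\n")
  cat("  LDCT sens/spec:", x$ldct$sensitivity, "/", x$ldct$specificity, "\n")
  cat("  detection hazards:",
      if (is.null(x$detection)) "not calibrated" else
        paste(sprintf("%s=%.4f", names(x$detection), x$detection), collapse = " "), "\n")
  if (length(x$meta$overridden)) {
    cat("  overridden:", paste(x$meta$overridden, collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

# recursively merge user config onto defaults; user leaves win
deep_merge <- function(base, user) {
  if (!is.list(base) || !is.list(user) || is.null(names(user))) return(user)
  for (nm in names(user)) {
    base[[nm]] <- if (nm %in% names(base)) deep_merge(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

leaf_paths <- function(x, prefix = character()) {
  if (!is.list(x) || is.null(names(x)) ||
      (all(c("value", "units") %in% names(x)))) {
    return(paste(prefix, collapse = "$"))
  }
  unlist(lapply(names(x), function(nm) leaf_paths(x[[nm]], c(prefix, nm))))
}

# accept either a bare proportion or {value, units: percent}
as_proportion <- function(x, name) {
  if (is.list(x)) {
    if (!is.null(x$units)) {
      if (identical(x$units, "percent")) return(as.numeric(x$value) / 100)
      if (identical(x$units, "proportion")) return(as.numeric(x$value))
      abort(paste0(name, ": units must be 'percent' or 'proportion'"),
            class = "lcs_config_error")
    }
    if (!is.null(x$value)) x <- x$value
  }
  x <- as.numeric(x)
  if (is.finite(x) && x > 1) {
    abort(paste0(name, " = ", x, " looks like a percent; write it as ",
                 "{value: ", x, ", units: percent} or as a proportion"),
          class = "lcs_config_error")
  }
  x
}

rows_to_df <- function(rows, value_cols) {
  tibble::as_tibble(dplyr::bind_rows(lapply(rows, function(r) {
    out <- list(age_lower = as.integer(r$age_lower), age_upper = as.integer(r$age_upper))
    for (cl in value_cols) out[[cl]] <- as.numeric(r[[cl]])
    tibble::as_tibble(out)
  })))
}

df_to_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
}

# fixed order and typing for the options block, robust to YAML null handling
normalise_options <- function(opts) {
  defaults <- list(
    all_cause_interpretation = "five_year",
    rate_conversion = "exponential",
    heavy_incidence_mode = "as_printed",
    sex_mix = NULL,
    diagnosed_progression = "none",
    undiagnosed_utility = "stage",
    screen_stage_split = "never",
    band_extrapolation = "carry_forward",
    incidence_multiplier = 1,
    half_cycle_correction = FALSE
  )
  out <- defaults
  for (nm in names(defaults)) {
    if (!is.null(opts[[nm]])) out[nm] <- list(opts[[nm]])
  }
  out$sex_mix <- if (is.null(out$sex_mix)) NULL else as.numeric(out$sex_mix)
  out$incidence_multiplier <- as.numeric(out$incidence_multiplier)
  out$half_cycle_correction <- isTRUE(out$half_cycle_correction)
  out
}

canonicalise_parameters <- function(raw) {
  stage_vec <- function(x) setNames(as.numeric(unlist(x[lcs_stages()])), lcs_stages())
  all_cause <- tibble::as_tibble(dplyr::bind_rows(lapply(raw$mortality$all_cause, function(r) {
    tibble::tibble(age_lower = as.integer(r$age_lower), age_upper = as.integer(r$age_upper),
                   value = as_proportion(r[setdiff(names(r), c("age_lower", "age_upper"))],
                                         "mortality$all_cause"))
  })))
  p <- list(
    incidence = rows_to_df(raw$incidence_per_100k, c("male", "female")),
    smoking = rows_to_df(raw$smoking_rate, c("male", "female")),
    risk = list(odds_ratio_smoker = as.numeric(raw$risk$odds_ratio_smoker),
                odds_ratio_assumed = isTRUE(raw$risk$odds_ratio_assumed),
                rr_heavy = as.numeric(raw$risk$rr_heavy)),
    stage_dist = list(nonscreened = stage_vec(raw$stage_distribution$nonscreened),
                      screened = stage_vec(raw$stage_distribution$screened)),
    ldct = list(sensitivity = as_proportion(raw$ldct$sensitivity, "ldct$sensitivity"),
                specificity = as_proportion(raw$ldct$specificity, "ldct$specificity")),
    mortality = list(
      all_cause = all_cause,
      lc_rate = rows_to_df(raw$mortality$lung_cancer_per_100k, "value")
    ),
    transitions = list(
      progression = setNames(as.numeric(unlist(raw$transitions$progression[
        c("cis_to_I", "I_to_II", "I_to_III", "I_to_IV", "II_to_III", "II_to_IV", "III_to_IV")])),
        c("cis_to_I", "I_to_II", "I_to_III", "I_to_IV", "II_to_III", "II_to_IV", "III_to_IV")),
      lc_death = stage_vec(raw$transitions$lc_death)
    ),
    utilities = setNames(as.numeric(unlist(raw$utilities[c("Healthy", lcs_stages())])),
                         c("Healthy", lcs_stages())),
    costs = list(direct_screening = as.numeric(raw$costs$direct_screening),
                 indirect_screening = as.numeric(raw$costs$indirect_screening),
                 prediagnosis = as.numeric(raw$costs$prediagnosis),
                 biopsy = as.numeric(raw$costs$biopsy),
                 treatment = stage_vec(raw$costs$treatment),
                 maintenance_fraction = as.numeric(raw$costs$maintenance_fraction),
                 cpi_rate = as.numeric(raw$costs$cpi_rate)),
    economics = list(discount_rate = as.numeric(raw$economics$discount_rate),
                     threshold = as.numeric(raw$economics$threshold),
                     horizon_end_age = as.numeric(raw$economics$horizon_end_age),
                     cohort_size = as.numeric(raw$economics$cohort_size),
                     cycle_length = as.numeric(raw$economics$cycle_length)),
    psa = list(cv = as.numeric(raw$psa$cv)),
    options = normalise_options(raw$options),
    detection = if (is.null(raw$detection)) NULL else stage_vec(raw$detection),
    meta = list(overridden = character(), source = NA_character_)
  )
  class(p) <- "lcs_parameters"
  p
}

# band lookup; ages past the oldest tabulated band either reuse the last
# band (carry-forward, default) or linearly extrapolate from the last two
# band midpoints
band_row <- function(tbl, age, extrapolation = "carry_forward") {
  i <- which(age >= tbl$age_lower & age <= tbl$age_upper)
  if (length(i) > 0) return(tbl[i[1], , drop = FALSE])
  if (age < min(tbl$age_lower)) {
    abort(paste0("age ", age, " below the first tabulated band"),
          class = "lcs_parameter_error")
  }
  last <- tbl[nrow(tbl), , drop = FALSE]
  if (identical(extrapolation, "linear") && nrow(tbl) >= 2) {
    prev <- tbl[nrow(tbl) - 1, , drop = FALSE]
    mid_last <- (last$age_lower + last$age_upper) / 2
    mid_prev <- (prev$age_lower + prev$age_upper) / 2
    vcols <- setdiff(names(tbl), c("age_lower", "age_upper"))
    for (cl in vcols) {
      slope <- (last[[cl]] - prev[[cl]]) / (mid_last - mid_prev)
      last[[cl]] <- pmax(0, last[[cl]] + slope * (age - mid_last))
    }
  }
  last
}

# annual all-cause death probability at a given age, resolving the
# annual-vs-five-year reading of the published percentages
annual_all_cause <- function(params, age) {
  v <- band_row(params$mortality$all_cause, age, params$options$band_extrapolation)$value
  if (identical(params$options$all_cause_interpretation, "five_year")) {
    1 - (1 - v)^(1 / 5)
  } else {
    v
  }
}
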