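#' Split population incidence into nonsmoker and smoker incidence
#'
#' Given the general-population lung-cancer incidence `i_pop`, the smoking
#' prevalence `r_smoke` and the smoker odds ratio, returns the unique pair
#' `(i_nonsmoker, i_smoker)` satisfying the mixture identity
#' `i_pop = i_smoker * r_smoke + i_nonsmoker * (1 - r_smoke)` together with
#' `i_smoker = odds_ratio * i_nonsmoker`, i.e.
#' `i_nonsmoker = i_pop / (1 + (odds_ratio - 1) * r_smoke)`.
#'
#' @param i_pop Incidence per 100,000 person-years (>= 0). Vectorised.
#' @param r_smoke Smoking prevalence in \[0, 1\].
#' @param odds_ratio Smoker odds ratio (> 0).
#' @return A tibble with columns `i_pop`, `r_smoke`, `odds_ratio`,
#'   `i_nonsmoker`, `i_smoker`.
#' @export
#' @examples
#' decompose_incidence(81.0559, 0.60, 2.5)
decompose_incidence <- function(i_pop, r_smoke, odds_ratio) {
  if (any(!is.finite(i_pop)) || any(i_pop < 0)) {
    abort("i_pop must be a nonnegative rate", class = "lcs_parameter_error")
  }
  if (any(!is.finite(r_smoke)) || any(r_smoke < 0 | r_smoke > 1)) {
    abort("r_smoke must lie in [0, 1]", class = "lcs_parameter_error")
  }
  if (any(!is.finite(odds_ratio)) || any(odds_ratio <= 0)) {
    abort("odds_ratio must be > 0", class = "lcs_parameter_error")
  }
  i_n <- i_pop / (1 + (odds_ratio - 1) * r_smoke)
  tibble::tibble(i_pop = i_pop, r_smoke = r_smoke, odds_ratio = odds_ratio,
                 i_nonsmoker = i_n, i_smoker = odds_ratio * i_n)
}

#' Heavy-smoker lung-cancer incidence
#'
#' The base-case (`"as_printed"`) model multiplies the nonsmoker incidence
#' by the heavy-smoker relative risk: `i_heavy = i_nonsmoker * rr_heavy`.
#' The `"smoker_based"` alternative instead scales the all-smoker incidence,
#' `i_heavy = i_smoker * rr_heavy`; it is never used silently.
#'
#' @param i_nonsmoker Nonsmoker incidence per 100,000 (>= 0).
#' @param rr_heavy Relative risk for >= 20 pack-years (> 0).
#' @param mode `"as_printed"` (default) or `"smoker_based"`.
#' @param i_smoker All-smoker incidence per 100,000; required for
#'   `"smoker_based"`.
#' @return Heavy-smoker incidence per 100,000 person-years.
#' @export
heavy_smoker_incidence <- function(i_nonsmoker, rr_heavy,
                                   mode = c("as_printed", "smoker_based"),
                                   i_smoker = NULL) {
  mode <- match.arg(mode)
  if (any(!is.finite(i_nonsmoker)) || any(i_nonsmoker < 0)) {
    abort("i_nonsmoker must be a nonnegative rate", class = "lcs_parameter_error")
  }
  if (any(!is.finite(rr_heavy)) || any(rr_heavy <= 0)) {
    abort("rr_heavy must be > 0", class = "lcs_parameter_error")
  }
  if (mode == "as_printed") {
    i_nonsmoker * rr_heavy
  } else {
    if (is.null(i_smoker)) abort("smoker_based mode needs i_smoker",
                                 class = "lcs_parameter_error")
    i_smoker * rr_heavy
  }
}

#' Convert an annual event rate to an annual probability
#'
#' @param rate Events per 100,000 person-years (>= 0). Vectorised.
#' @param mode `"exponential"` (default): `1 - exp(-rate/1e5)`, the
#'   constant-hazard conversion; `"linear"`: `rate/1e5` clamped to \[0, 1\].
#' @return Annual probability in \[0, 1\].
#' @export
#' @examples
#' rate_to_annual_probability(165.098)
rate_to_annual_probability <- function(rate, mode = c("exponential", "linear")) {
  mode <- match.arg(mode)
  if (any(!is.finite(rate)) || any(rate < 0)) {
    abort("rate must be nonnegative", class = "lcs_parameter_error")
  }
  if (mode == "exponential") 1 - exp(-rate / 1e5) else pmin(rate / 1e5, 1)
}

#' Per-cycle heavy-smoker incidence schedule for a cohort
#'
#' Builds the annual probability that a heavy smoker develops lung cancer at
#' each age from `start_age` to the horizon, combining the male and female
#' pathways with a sex-mix weight. Ages beyond the oldest tabulated band
#' (75-79) reuse the 70-74 band values (last-band carry-forward).
#'
#' @param params A `lcs_parameters` object.
#' @param start_age Cohort entry age: one of 50, 55, 60, 65, 70.
#' @param sex_mix Proportion male in \[0, 1\], or `NULL` (default) to weight
#'   by smoking prevalence within the age band — the cohort is made of
#'   smokers, so the male share among smokers (e.g. 0.60 / (0.60 + 0.04))
#'   is the natural mix.
#' @return A tibble with one row per model cycle: `age`, `i_pop_male`,
#'   `i_pop_female`, `i_heavy` (sex-mixed rate per 100,000) and
#'   `annual_probability`.
#' @export
cohort_incidence_schedule <- function(params, start_age,
                                      sex_mix = params$options$sex_mix) {
  stopifnot(inherits(params, "lcs_parameters"))
  if (!start_age %in% c(50, 55, 60, 65, 70)) {
    abort("start_age must be one of 50, 55, 60, 65, 70", class = "lcs_parameter_error")
  }
  if (!is.null(sex_mix) && (sex_mix < 0 || sex_mix > 1)) {
    abort("sex_mix must lie in [0, 1]", class = "lcs_parameter_error")
  }
  mode <- params$options$heavy_incidence_mode
  conv <- params$options$rate_conversion
  or <- params$risk$odds_ratio_smoker
  rr <- params$risk$rr_heavy
  mult <- params$options$incidence_multiplier
  extrap <- params$options$band_extrapolation
  ages <- seq(start_age, params$economics$horizon_end_age)
  lookup <- function(tbl) {
    if (identical(extrap, "linear")) {
      do.call(rbind, lapply(ages, function(a) {
        r <- band_row(tbl, a, extrap)
        c(male = r$male, female = r$female)
      }))
    } else {
      i <- pmin(findInterval(ages, tbl$age_lower), nrow(tbl))
      cbind(male = tbl$male[i], female = tbl$female[i])
    }
  }
  inc <- lookup(params$incidence)
  smk <- lookup(params$smoking)
  dm <- decompose_incidence(inc[, "male"], smk[, "male"], or)
  df <- decompose_incidence(inc[, "female"], smk[, "female"], or)
  ih_m <- heavy_smoker_incidence(dm$i_nonsmoker, rr, mode, dm$i_smoker) * mult
  ih_f <- heavy_smoker_incidence(df$i_nonsmoker, rr, mode, df$i_smoker) * mult
  w <- if (is.null(sex_mix)) smk[, "male"] / (smk[, "male"] + smk[, "female"]) else sex_mix
  tibble::tibble(
    age = ages,
    i_pop_male = inc[, "male"],
    i_pop_female = inc[, "female"],
    i_heavy = w * ih_m + (1 - w) * ih_f,
    annual_probability = w * rate_to_annual_probability(ih_m, conv) +
      (1 - w) * rate_to_annual_probability(ih_f, conv)
  )
}
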