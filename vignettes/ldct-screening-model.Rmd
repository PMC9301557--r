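---
title: "A Markov cohort model of LDCT lung-cancer screening in heavy smokers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of LDCT lung-cancer screening in heavy smokers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lungscreen` implements a deterministic Markov state-transition
cost-effectiveness model of low-dose CT (LDCT) lung-cancer screening in
Chinese heavy smokers (current smokers with at least 20 pack-years). A
closed cohort of 100,000 persons enters disease-free at a start age of
50, 55, 60, 65 or 70 and is followed in annual cycles to age 79 or death,
under one of three strategies: no screening, a single LDCT screen at
entry, or annual LDCT screening. The model accrues discounted costs (CNY)
and quality-adjusted life years (QALYs), counts lung-cancer deaths, and
compares strategies by incremental cost-effectiveness ratio (ICER)
against a willingness-to-pay threshold of 212,676 CNY/QALY (three times
GDP per capita).

This vignette is the package's account of the science: the model
structure, the derivation of each input, every place where the design was
genuinely open and what was chosen, and what the synthetic-data module
does and does not emulate.

## State space and natural history

Thirteen states: `Healthy`; five undiagnosed (preclinical) cancer stages
CIS, I, II, III, IV; five diagnosed ("maintenance") stages; and two
absorbing death states (lung cancer, other cause). Preclinical disease
progresses stage-to-stage with the published annual probabilities
(CIS→I 0.098; I→II/III/IV 0.3682/0.0328/0.0745; II→III/IV 0.2260/0.1510;
III→IV 0.1455) and dies of lung cancer at stage-specific annual
probabilities (0 / 0.04 / 0.07 / 0.13 / 0.18 for CIS–IV). Competing risks
within a cycle are composed other-cause-death-first: the all-cause annual
probability is applied to every alive state, and the surviving mass is
split among progression, lung-cancer death and staying. Every transition
matrix is asserted row-stochastic to 1e-9 and cohort mass is conserved to
1e-6 per cycle.

**Diagnosed stages do not progress by default.** The input set provides
one transition table. Applying it to the diagnosed pool as well would
make detection clinically inert — screening could never avert a death or
gain a QALY, and every incremental comparison would be undefined. The
source material describes the post-diagnosis states as *maintenance*
stages, so the default freezes diagnosed patients at their stage of
diagnosis, exposed to that stage's lung-cancer death probability and
other-cause mortality. Option `diagnosed_progression = "table"` restores
the shared-table reading for sensitivity exploration. This is the model's
largest structural uncertainty.

## Incidence of lung cancer in heavy smokers

The general-population incidence `I` (per 100,000, by sex and 5-year age
band) is split into nonsmoker and smoker rates using the smoking
prevalence `R` and a smoker odds ratio `OR` via the mixture identity

    I = I_S · R + I_N · (1 − R),   I_S = OR · I_N
    ⇒ I_N = I / (1 + (OR − 1) · R)

and the heavy-smoker rate is `I_20 = I_N × RR` with `RR = 3.87`
(≥20 pack-years), exactly as the source formula prints it. Multiplying a
*nonsmoker* baseline by a smoking relative risk is epidemiologically odd;
the alternative reading `I_20 = I_S × RR` is available as
`heavy_incidence_mode = "smoker_based"` but is never used silently.

The odds ratio itself is not part of the published input table. The
packaged value **OR = 2.5 is an assumption**, flagged in
`$risk$odds_ratio_assumed`, and is a required, overridable config field.

Rates convert to annual probabilities by the constant-hazard map
`1 − exp(−rate/1e5)` (a linear mode is available; for all tabulated rates,
below 500/100k, the two agree within 1%). Male and female probabilities
are mixed with weight equal to the male share of smokers within the age
band (e.g. 0.60/(0.60+0.04) ≈ 0.94 at ages 50–64) — the cohort is a
smokers' cohort, so weighting by smoking prevalence is the natural
default; `sex_mix` can be set explicitly. Ages 75–79 have no tabulated
rates and reuse the 70–74 band (carry-forward; linear extrapolation is
available via `band_extrapolation`).

## All-cause mortality: the five-year reading

The published all-cause "mortality (%)" by age band (3.59% at 50–54 up to
21.08% at 70–74) is ambiguous between an annual and a five-year
probability. An annual 3.59% at ages 50–54 exceeds plausible Chinese
all-cause mortality several-fold, so the default reads the figures as
five-year probabilities converted by `p1 = 1 − (1 − p5)^(1/5)`
(≈0.73%/year at 50–54). `all_cause_interpretation = "annual"` switches to
the literal reading; both are unit-tested.

## Screening and clinical detection

Within each cycle the order is: maintenance billing on the diagnosed pool
entering the year → the transition matrix (incidence, progression,
deaths) → the scheduled screen, if any → symptomatic detection → accrual.
A screen scheduled in a program year is applied **after** that year's
transition: a cohort that enters disease-free would otherwise present a
one-time entry screen with nothing to find, making every one-time
comparison degenerate.

Screening (adherence 100%) charges every alive undiagnosed person the
direct plus indirect screening cost (245.86 + 23.07 CNY). Undiagnosed
cancer is detected with probability equal to LDCT sensitivity (0.79) and
pays the pre-diagnosis workup (628.36), biopsy (1232.44) and the stage
treatment cost once at diagnosis; cancer-free screenees incur the workup
as a false positive with probability 1 − specificity = 0.19. The model is
memoryless, so a person can incur false-positive workups in successive
years.

`screen_stage_split` controls the stage assigned at screen detection:

* `"never"` (default): detection is stage-preserving — the screen reveals
  the disease that is mechanistically there.
* `"entry"` / `"always"`: detections at the entry screen (or at every
  screen) are redistributed over the screened-cohort stage split
  (0.0370/0.6852/0.0370/0.1852/0.0556), the prevalence-round yield of a
  real single-round screening registry.

The default is `"never"` because a disease-free cohort's preclinical pool
is dominated by carcinoma in situ; forcing it onto the registry split
*fabricates* stage III/IV cases at detection and makes screening increase
lung-cancer deaths, reversing the direction of benefit that any
early-detection mechanism must have. The redistribution modes remain
available for prevalent-pool scenarios.

Symptomatic detection moves undiagnosed mass to the diagnosed states at
per-stage annual probabilities calibrated by `calibrate_detection()` so
that the stage distribution of clinical diagnoses in a nonscreened run
matches the published clinical split (0 / 0.190 / 0.165 / 0.346 / 0.299
for CIS–IV; carcinoma in situ is never clinically detected since its
target share is zero). Calibration is a deterministic Nelder-Mead search
on the log-odds scale. Three free proportions cannot pin down four free
hazards — solutions form a one-dimensional family differing in overall
detection *speed*. Since the target split is estimated from clinically
diagnosed patients (which presupposes that symptomatic disease does
present), the search adds a weak secondary criterion
(`identification_weight = 0.01` times the squared never-diagnosed
fraction) preferring the solution family member under which the largest
share of incident cancers is eventually diagnosed. The base-case solution
is detection probabilities ≈ (0, 0.072, 0.111, 1.00, 0.630) with the
achieved stage split within 0.004 of the target; about a third of
incident cancers are ever diagnosed, capped structurally by the ~10-year
mean preclinical CIS dwell with zero CIS detection. Hazards are
calibrated once on the base inputs and held fixed across DSA/PSA re-runs.

## Accrual, costs and discounting

QALYs accrue on end-of-cycle occupancy as occupancy × state utility ×
cycle length (1 year). Utilities: Healthy 1.0 (a convention — the input
table starts at the disease stages), CIS 0.87, I/II 0.84, III 0.87,
IV 0.75. The same stage utility applies to undiagnosed and diagnosed
occupants by default (`undiagnosed_utility = "stage"`); the
`"healthy"` alternative values preclinical disease at 1.0, but then
diagnosis itself destroys utility and early detection can lose QALYs,
violating the basic dominance direction of an early-detection model.

Costs: treatment (47,341.85 / 53,344.51 / 83,365.95 / 90,643.18 /
116,471.34 CNY for CIS–IV) is charged **once at diagnosis**; every
subsequent year alive in a diagnosed stage is billed maintenance at 10%
of that stage's treatment cost. Both flows, plus screening and workup
costs, are discounted at 5%/year with year-0 flows undiscounted
(`(1+r)^{-t}`). A CPI rate (default 0 — constant-CNY accounting)
multiplies all cost flows by `(1+cpi)^t`; it exists as a one-way
sensitivity lever (varied ±30% around a 2%/year reference) and is not
part of the base case. No half-cycle correction by default
(`half_cycle_correction = TRUE` averages start- and end-of-cycle
occupancy for QALYs).

## Evaluation and sensitivity analysis

`evaluate_grid()` runs all 15 strategy cells, reporting costs in millions
CNY per 100,000 persons and QALYs in units of 10,000 years, each
screening arm's ICER versus nonscreening and annual-versus-one-time
ICERs — always computed on unrounded totals, with a check ICER recomputed
from the rounded report cells so rounding discrepancies stay visible —
plus lung-cancer mortality reductions and ≤-threshold classifications
(ties cost-effective; dominant yes, dominated/undefined no). An
efficiency frontier across all 15 cells is provided as a clearly
supplementary output.

One-way DSA (`run_tornado()`): direct screening cost, maintenance cost
and heavy-smoker incidence (a multiplicative factor on the final
heavy-smoker schedule — the lever named by the analysis, not the
population rate) at ±30%; discount rate over 0–8%; LDCT sensitivity
0.63–0.95 and specificity 0.65–0.97; CPI as above. PSA (`run_psa()`):
every distribution-tagged parameter is drawn independently from a
moment-matched beta (probabilities, proportions, utilities; rates per
100k on the per-person scale) or gamma (costs and ratio-scale parameters
whose mean exceeds one, where a beta is infeasible) distribution with a
common coefficient of variation. **The cv = 0.1 default is an
assumption** — the analysis this re-implements does not publish standard
errors — and is configurable globally. Stage distributions are drawn
per-component and renormalised; degenerate means (0 or 1) stay fixed;
draws failing validation (e.g. sampled outgoing probabilities exceeding
one) are resampled and counted. The mean ICER is reported both as
ratio-of-means (the headline, standard practice) and mean-of-ratios,
because a Jensen gap between them is expected whenever the QALY increment
varies; the acceptability curve uses the net-monetary-benefit rule.

## Synthetic data and the microsimulation oracle

`generate_screening_registry()` emulates a single-round screening
registry: Bernoulli confirmed-cancer yield (default 65/10,175 ≈ 0.64%)
with multinomial stages over the screened-cohort split. Only confirmation
is modelled — the raw LDCT positivity rate of the real registry is not an
input — so positives coincide with confirmed cancers.
`generate_claims()` emulates stage-labelled insurance claims: multinomial
stage (clinical split) and gamma-distributed cost around the stage mean
(cv = 0.5 by default; medical costs are right-skewed). Estimators
(`estimate_detection_rate()` with exact Clopper–Pearson intervals,
`estimate_stage_costs()` with per-stage means/SEs, absent stages reported
missing rather than imputed) recover the generating parameters in seeded
tests. These generators emulate sampling noise around published summary
fractions; they do not emulate nodule-morphology follow-up protocols,
inter-hospital cost variation, or secular trends, so passing recovery
tests says nothing about those features of real data.

`microsimulate_cohort()` is an independent individual-level oracle for
the cohort engine: each person is simulated through the same annual event
sequence by explicit Bernoulli/categorical draws, with state-evolution
code written separately from the matrix engine so a shared defect cannot
validate itself. The test suite checks engine/oracle agreement of total
cost, QALYs and lung-cancer deaths within 3 Monte Carlo SEs over a seeded
battery of 10 perturbed parameter sets × both strategies × start ages 50
and 70 at 200,000 individuals per run. (At much smaller n the
lung-cancer death count in the annual/age-70 cell is a rare event and the
normal 3-SE band is unreliable; 200,000 keeps every cell in the
normal regime.)

## Problem sizes and numerical choices

Deterministic runs use the full cohort scale (100,000) — the engine is a
matrix recursion, so cohort size only rescales outputs. The test suite
uses 8–60 PSA draws for property checks (the user-facing default is
10,000), microsimulations of 2,000–200,000 individuals, and a one-million
row registry for the law-of-large-numbers check; all randomness is
seeded. Calibration uses Nelder-Mead with `reltol = 1e-12` from a fixed
start (0.1/0.1/0.3/0.6/0.8), a Brent search when only one stage is free,
and warns if the achieved stage distance exceeds 0.05. Beta
moment-matching clamps an infeasible cv downward and flags it. Percent-
style config entries require an explicit `units: percent` key; bare
values above 1 are rejected rather than guessed.

## Known limitations

* The published analysis this package re-implements reports much higher
  absolute cost levels and much smaller screening effects than this
  architecture produces; the committed deviation report
  (`results/deviation_report.md`) quantifies the differences and traces
  them to the once-at-diagnosis treatment-cost rule, the long preclinical
  CIS dwell, and horizon truncation at age 79. QALY totals and two
  mid-grid ICERs agree within 10%.
* One transition table serves undiagnosed and diagnosed disease
  (resolved by the maintenance freeze); no stage sub-splits (IA/IB,
  IIIA/IIIB), no radiation harm, no smoking-cessation dynamics, no
  individual risk factors — all outside scope.
* General-population lung-cancer mortality rates are carried as
  validation outputs only; stage-specific death probabilities drive
  cancer mortality, and using both would double-count.
* PSA draws are independent across parameters (no published correlation
  structure) and use an assumed common cv.

## A worked run

```{r}
library(lungscreen)

params <- default_parameters()
params <- set_detection(params, calibrate_detection(params)$probabilities)

grid <- evaluate_grid(params)
grid_comparisons(grid)
autoplot(grid)

tor <- run_tornado(params)
autoplot(tor)

psa <- run_psa(params, n_draws = 1000, seed = 42)
autoplot(psa); plot_ceac(psa)
```
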