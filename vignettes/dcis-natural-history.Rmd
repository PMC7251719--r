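---
title: "Modelling DCIS natural history, screening, and overdiagnosis with dcisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DCIS natural history, screening, and overdiagnosis with dcisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcisim)
```

# The modelling problem

Ductal carcinoma in situ (DCIS) is mostly detected by mammography, and in
current practice essentially every detected lesion is biopsied and excised.
The quantity clinicians need — what fraction of screen-detected DCIS would
have progressed to invasive breast cancer (IBC) if left alone, over what
time scale, and how much of it is overdiagnosed — is therefore
unobservable in any cohort. Population models bridge the gap: they posit a
latent multi-state natural history, push simulated populations through
historical screening patterns, and confront the projected incidence with
registry data. `dcisim` implements one such model family end to end, with
every input replaceable by synthetic data of known truth so that each
estimator can be validated against the parameters that generated its
input.

# The natural-history model

Each woman carries at most one lesion. Multiplicity is not modelled: all
the accounting downstream (overdiagnosis per case, progression proportions
per lesion) is per-lesion, and a single-lesion design keeps the
counterfactual bookkeeping exact.

States and transitions:

* **Onset.** Normal tissue acquires *preclinical undetectable DCIS* with an
  age-dependent hazard, piecewise constant on age bands, multiplied by a
  log-linear birth-cohort trend:
  `h(a, c) = h_band(a) * exp(slope * (c - c_ref))`. This is a deliberately
  plain age–cohort stand-in for the external age–period–cohort incidence
  inputs that production models consume; those inputs are not bundled.
  Sampling inverts the cumulative hazard exactly (no time-step
  discretisation).
* **Undetectable fate.** With probability `f` (30/50/80% in submodels
  1/2/3) the lesion becomes *screen-detectable*. The sources are silent on
  the complement, beyond drawing an undetectable-to-preclinical-IBC edge in
  the state diagram, so the remainder splits between direct progression to
  preclinical IBC (`undetectable_direct_to_ibc_frac`, default 0.5 — a free,
  calibratable parameter) and an indolent lesion that never leaves the
  state. One micro-simulation lineage also allows regression directly from
  the undetectable state, while the state diagram's regression arrow leaves
  the screen-detectable state; we follow the diagram, but expose
  `undetectable_regression_frac` (default 0) as a switch for the other
  reading.
* **Screen-detectable exit.** The exit path is multinomial over
  (P1 = preclinical IBC, P2 = clinical DCIS, P3 = regression) with
  probabilities `(p1, p2, p3)`; `p3 = 0` whenever the submodel prohibits
  regression. The sojourn is exponential with a *path-specific* mean
  (`mst1`, `mst2`, `mst3`).
* **Preclinical IBC** dwells exponentially
  (`ibc_preclinical_mean_dwell`, default 2.5 y) before surfacing as
  clinical IBC.
* Everything is truncated at an other-cause death age drawn from a cohort
  life table by inverse CDF with uniform within-year interpolation.

**Why path-conditional dwells rather than competing exponential clocks.**
The model family reports *different* mean sojourn times per exit path
within one submodel (e.g. 0.5 y to preclinical IBC but 1.9 y to clinical
DCIS in one variant). Independent competing exponential clocks cannot
produce that: the winning time's distribution is the same regardless of
which clock wins. Drawing the path first and then an exponential dwell with
the path's mean reproduces the reported structure exactly. The true dwell
families of the original models are described only in unavailable
supplements; exponential is this package's declared assumption, not
theirs.

**Default parameter values.** Mean sojourn times default to the analytic
model's published inputs per submodel (P1 path: 2.5/0.7/0.4 y in
1a/2a/3a, 1.5/0.5/0.2 y in 1b/2b/3b; P2 path: 2.5 y in submodel 1a, 1.5 in
1b, 1.9 elsewhere; P3 path: 1.5 y in all b-submodels). Exit probabilities
default to (0.8, 0.2, 0) without regression and (0.5, 0.2, 0.3) with —
inside the reported ranges (progression to IBC 64–100% without regression,
36–100% with; regression up to 56%; clinical DCIS 0–36%). The onset-band
defaults rise from 2×10⁻⁴/y at 30–34 to 3.5×10⁻³/y at 75+, chosen once so
that simulated DCIS and IBC incidence sit on the tens-to-hundreds per
100,000 scale of the observed series; they are stand-ins, not estimates.
`undetectable_mean_dwell` defaults to 2 y, on the order of the
screen-detectable sojourns.

# Screening

* **Sensitivity** is piecewise constant over calendar periods, half-open on
  the right (`[start, next_start)`): the defaults are 0.45 / 0.55 / 0.70 /
  0.85 for 1975–1984 / 1985–1999 / 2000–2009 / 2010 onwards, so 1985
  belongs to the 0.55 period. Only DCIS sensitivity is specified by the
  source material; IBC sensitivity is a configurable input defaulting to
  0.85 in all periods. Detection at a screen is an independent Bernoulli
  per screen; whether the original models correlate sensitivity across
  rounds or with lesion size is unknown, and per-screen independence is the
  declared assumption.
* **Dissemination.** A table gives, per calendar year (optionally per birth
  cohort), the cumulative probability of having ever started screening and
  the inter-screen interval. A woman's yearly conditional start probability
  is the discrete hazard of that cumulative curve, except in her *first
  eligible year*, where the full cumulative uptake applies (a woman who
  turns 40 in 2000 faces the 2000-level uptake, not the 1975 one). The
  synthetic default is a logistic ramp (plateau 0.8, midpoint 1990,
  steepness 0.25/y) frozen at its 2010 value thereafter, biennial screens,
  eligibility ages 40–74, never before calendar 1975. Screens fall at
  mid-year.
* **Detection is absorbing excision**: the first detection appends a
  `screen_detected_*` event and removes all later natural events; only
  other-cause death remains. No post-detection progression is modelled,
  consistent with the contrast between excised lesions and unexcised
  natural history. States that are not screen-detectable (undetectable
  DCIS, regressed, clinical disease) are never detected.

# The parallel-universe engine

Every woman is simulated twice — unscreened and screened — and the pair
must agree on everything except screening. `dcisim` enforces this with
stateless, keyed random streams (a counter-based splitmix64 generator in
C++): the uniform for `(seed, woman_id, stream, counter)` is a pure
function of its key. Stream 1 carries natural-history draws (cohort, death
age, onset, fates, dwells — seven fixed counters), stream 2 carries
screening attendance and detection. Consequences, all property-tested:

* the screened universe shares the unscreened trajectory exactly up to the
  first detection;
* changing any screening parameter can never perturb natural history;
* per-woman results are independent of simulation order and batch size
  (simulating woman 17 alone reproduces her rows from a 100,000-woman
  run);
* raising a sensitivity value, holding the seed, never un-detects anyone.

Simultaneous events resolve by the fixed priority other-cause death >
clinical surfacing > progression, implemented by strict truncation at the
death age; this keeps replays deterministic. Cohorts 1890–1996 get equal
weights by default (the original per-cohort population sizes are external);
a weights vector or a births-derived table can replace them.

# Outcome estimators

* **Incidence** (`compute_incidence`): diagnosis events are clinical DCIS /
  screen-detected DCIS / clinical IBC / screen-detected IBC; a woman
  contributes women-years until death or her (single) diagnosis. Cells are
  calendar year × 5-year age group (30–79) × diagnosis × mode; rates are
  per 100,000; the age-adjusted yearly rate is the weighted sum of group
  rates. The original standard population is unnamed, so the default
  weights are equal (0.1 per group) and configurable.
* **MST** (`estimate_mst`): per-path sample mean and standard error of
  (exit − entry) in the screen-detectable state, measured on the unscreened
  universe so excision cannot interrupt the sojourn. Episodes censored by
  other-cause death are excluded and reported as a censored count — so in
  old-onset populations the estimates sit slightly below the generating
  means (long sojourns censor preferentially); the acceptance suite
  therefore measures recovery in a censoring-free design (onset at 40,
  death at 95). A path with no completed episodes yields `NA` with `n = 0`,
  never a fabricated zero.
* **Progression proportions** (`progression_proportions`): among lesions of
  one birth cohort entering the screen-detectable state, the resolved-exit
  shares of P1/P2/P3 by age at entry, with the death-censored count
  reported separately.
* **Overdiagnosis** (`compute_overdiagnosis`): a screen-detected DCIS case
  is overdiagnosed iff the same woman's unscreened trajectory contains
  neither clinical DCIS nor clinical IBC before death; a screen-detected
  IBC case iff it contains no clinical IBC. Percentages divide
  overdiagnosed cases by all screen-detected plus clinically detected cases
  of that diagnosis in the screened universe. Whether the original
  percentages pool person-level cases across 1975–2015 or average annual
  percentages is unstated; this package pools cases over the simulated
  history (the zero-denominator case reports 0%). Optional stratification
  by age at detection is available.

# Goodness of fit and calibration

The published fit table labels its statistic "(observed − estimated)²" with
a chi-square p-value and 40 degrees of freedom for 41 yearly cells. Raw
squared error has no chi-square reference distribution, so `gof_deviance`
adopts the Pearson form `sum((obs − est)² / est)` on age-adjusted yearly
rates per 100,000, `df = years − 1`, upper-tail p-value. The fit is on
age-adjusted yearly rates — the quantity the incidence figures display —
not on age-specific cells. A projected rate of zero where the observed rate
is positive is a degeneracy error in the public statistic.

`calibrate` minimises the summed deviance of the chosen diagnosis classes
over a named subset of parameters. Numerical choices that matter:

* **Common random numbers:** every objective evaluation simulates with the
  same fixed seed, making the objective a deterministic function of the
  parameter vector.
* **Plateaus:** with `n_sim` simulated women, the objective is piecewise
  constant (a small parameter move flips no simulated woman). A default
  Nelder–Mead started with a tiny simplex stalls on these plateaus, so the
  package uses its own simplex with an explicit initial step of one logit
  unit on the box-transformed scale — about a quarter of the box — which
  sees the large-scale curvature. Self-calibration tests recover `p1`
  within ±0.05 and `mst1` within ±0.2 y at `n_sim = 20,000` in ~20
  evaluations.
* **Denominator floor:** inside the objective only, expected rates are
  floored at 0.5 per 100,000, so candidate parameter sets that empty a cell
  receive a finite, continuous penalty instead of aborting the search; the
  strict public statistic is unchanged.
* **Freeing `p1`** renormalises `p2 = 1 − p1 − p3` with `p3` held fixed, so
  the probability simplex is respected throughout.
* The **curvature-based standard error** (central second differences, 2% of
  the box) is meaningful only where the objective is locally smooth, i.e.
  at large `n_sim`; on plateaus it returns `NA` or an optimistic value and
  should be read as diagnostic, not inferential.

# Synthetic data: what it emulates and what it does not

`synthetic_scenario` bundles a complete stated world per submodel: true
natural-history parameters (published sojourn inputs), the default
sensitivity schedule, the logistic dissemination ramp, and a Gompertz-like
life table (`q(a) = 5×10⁻⁴ + 3×10⁻⁵ e^{0.1a}`, 0.2%/birth-year
improvement, closed at age 110; cohort-1950 life expectancy ≈ 81 y).
`make_observed_incidence` runs the full simulator at the truth and overlays
Poisson noise on counts at a declared standard population (10⁶ women per
age group), giving the fit statistic a realistic scale. Every generated
file is deterministic given the scenario seed, and a manifest records the
truth.

What a green test establishes: that the estimators recover the parameters
of *this* generating process — exponential dwells, logistic uptake,
stationary sensitivity within periods, equal cohort weights. What it does
not establish: anything about real SEER trends, real US demography, the
BCSC sensitivity estimation, or the correctness of the exponential-dwell
assumption itself. The acceptance suite accordingly targets the published
*input* quantities (sojourn inputs, progression fractions, period
sensitivities) and the *directional* findings (regression submodels
overdiagnose more; overdiagnosis rises with age); the published
overdiagnosis percentages and deviances depend on calibrated parameters
available only in unpublished supplements and are out of scope.

# Known limitations

* One lesion per woman; no grade or molecular-subtype heterogeneity.
* No breast-cancer mortality, treatment effects, false positives, or
  recall cascades.
* Exponential dwell times are an assumption of convenience; any systematic
  deviation (e.g. heavy-tailed sojourns) would change the censoring bias
  discussed above.
* The bundled onset hazard and life table are synthetic stand-ins; analyses
  of real data must supply their own via the CSV interfaces.
* MST and progression-proportion estimates condition on resolved episodes;
  in populations with late onset the death-censoring exclusion biases
  them downward by a few percent.
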