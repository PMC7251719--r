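# Synthetic ground-truth inputs: life tables (Gompertz-like), logistic
# screening dissemination, bundled scenarios mirroring the six submodels,
# and SEER-like observed incidence generated by the simulator itself with
# Poisson sampling noise.

#' Synthetic cohort life table
#'
#' Annual other-cause death probabilities
#' `q(age) = background + a * exp(b * age)`, scaled by a slow log-linear
#' improvement across birth cohorts, closed with `q = 1` at `max_age`. The
#' table is a deterministic function of its parameters.
#'
#' @param cohorts birth years (default 1890-1996)
#' @param gompertz_a,gompertz_b Gompertz level and slope
#' @param background age-constant hazard floor
#' @param cohort_improvement proportional mortality decline per birth year
#' @param max_age closing age (death certain in that year)
#' @return data.frame with columns `birth_year`, `age`, `annual_death_prob`
#' @export
make_life_table <- function(cohorts = 1890:1996, gompertz_a = 3e-5,
                            gompertz_b = 0.1, background = 5e-4,
                            cohort_improvement = 0.002, max_age = 110) {
  stopifnot(gompertz_a >= 0, background >= 0, max_age > 1)
  ages <- 0:max_age
  base <- background + gompertz_a * exp(gompertz_b * ages)
  if (any(!is.finite(base)))
    stop("life-table shape parameters overflow", call. = FALSE)
  out <- data.table::rbindlist(lapply(cohorts, function(by) {
    q <- pmin(base * exp(-cohort_improvement * (by - 1930)), 1)
    q[length(q)] <- 1
    data.table::data.table(birth_year = by, age = ages,
                           annual_death_prob = q)
  }))
  as.data.frame(out)
}

#' Life expectancy implied by a life table
#'
#' @param lt life table data.frame
#' @param birth_year cohort to evaluate
#' @return expected age at death (years)
#' @export
life_expectancy <- function(lt, birth_year) {
  sub <- lt[lt$birth_year == birth_year, ]
  sub <- sub[order(sub$age), ]
  S <- cumprod(1 - sub$annual_death_prob)
  sum((c(1, head(S, -1)) + S) / 2)  # trapezoid on yearly survival
}

#' Synthetic screening dissemination (logistic ramp)
#'
#' Cumulative ever-screening probability follows a logistic curve in
#' calendar year, frozen at its 2010 value thereafter (uptake ramps up after
#' 1980 and plateaus after 2010); screening is periodic within an age
#' eligibility window.
#'
#' @param plateau asymptotic uptake in [0, 1]
#' @param midpoint logistic midpoint calendar year
#' @param steepness logistic slope per year
#' @param interval_years inter-screen interval
#' @param age_start,age_stop eligibility ages
#' @param years calendar span of the table
#' @return a [dissemination_schedule()]
#' @export
make_dissemination <- function(plateau = 0.8, midpoint = 1990,
                               steepness = 0.25, interval_years = 2,
                               age_start = 40, age_stop = 74,
                               years = 1975:2040) {
  stopifnot(plateau >= 0, plateau <= 1)
  yy <- pmin(years, 2010)
  p <- plateau / (1 + exp(-steepness * (yy - midpoint)))
  tab <- data.frame(calendar_year = years, start_probability = p,
                    interval_years = interval_years)
  dissemination_schedule(tab, age_start = age_start, age_stop = age_stop)
}

#' Bundled synthetic scenario
#'
#' A complete stated world for one of the six submodels: true
#' natural-history parameters (with the analytic model's published mean
#' sojourn inputs), the default sensitivity schedule, a logistic
#' dissemination ramp, a Gompertz life table, and a provenance manifest
#' listing every true value.
#'
#' @param name submodel name `"1a" ... "3b"`
#' @param seed scenario seed
#' @param ... overrides forwarded to [default_nh_params()]
#' @return object of class `synthetic_scenario`
#' @examples
#' sc <- synthetic_scenario("2b", seed = 11)
#' @export
synthetic_scenario <- function(name = "2a", seed = 1L, ...) {
  config <- submodel_config(name)
  params <- default_nh_params(config, ...)
  sens <- sensitivity_schedule()
  dissem <- make_dissemination()
  lt <- make_life_table()
  manifest <- list(
    name = name, seed = seed,
    frac_to_screen_detectable = config$frac_to_screen_detectable,
    regression_allowed = config$regression_allowed,
    p1 = params$p1, p2 = params$p2, p3 = params$p3,
    mst1 = params$mst1, mst2 = params$mst2, mst3 = params$mst3,
    undetectable_mean_dwell = params$undetectable_mean_dwell,
    undetectable_direct_to_ibc_frac =
      params$undetectable_direct_to_ibc_frac,
    ibc_preclinical_mean_dwell = params$ibc_preclinical_mean_dwell,
    dcis_sensitivity = sens$periods$dcis,
    sensitivity_period_starts = sens$periods$start_year)
  structure(list(name = name, config = config, params = params,
                 sens = sens, dissem = dissem, life_table = lt,
                 seed = seed, manifest = manifest),
            class = "synthetic_scenario")
}

#' Population spec of a synthetic scenario
#'
#' @param scenario [synthetic_scenario()] object
#' @param n_women women to simulate
#' @param cohorts birth cohorts
#' @return a [population_spec()]
#' @export
scenario_spec <- function(scenario, n_women, cohorts = 1890:1996) {
  population_spec(scenario$config, scenario$params, n_women,
                  cohorts = cohorts, seed = scenario$seed,
                  sens = scenario$sens, dissem = scenario$dissem,
                  life_table = scenario$life_table)
}

#' SEER-like observed incidence with known ground truth
#'
#' Runs the full simulator at the scenario's true parameters, takes the
#' screened-universe incidence by year, age group and diagnosis, and
#' overlays Poisson sampling noise on counts at a declared standard
#' population size before converting back to rates. The scenario manifest
#' records the truth for recovery tests.
#'
#' @param scenario [synthetic_scenario()] object
#' @param n_sim women to simulate
#' @param population_size women per 5-year age group of the declared
#'   observed population (scales the Poisson noise); `Inf` disables noise
#' @param years calendar span
#' @return data.frame with columns `year`, `age_group`, `diagnosis`,
#'   `rate_per_100k`
#' @export
make_observed_incidence <- function(scenario, n_sim = 50000,
                                    population_size = 1e6,
                                    years = 1975:2015) {
  spec <- scenario_spec(scenario, n_sim)
  log <- simulate_population(spec)
  inc <- compute_incidence(log, "screened", years = years)
  cells <- inc$cells[, list(count = sum(count),
                            women_years = women_years[1]),
                     by = list(year, age_group, diagnosis)]
  cells[, rate := ifelse(women_years > 0, 1e5 * count / women_years, 0)]
  if (is.finite(population_size)) {
    lam <- cells$rate * population_size / 1e5
    noisy <- with_seed_(scenario$seed + 1L, rpois(length(lam), lam))
    cells[, rate := noisy * 1e5 / population_size]
  }
  out <- as.data.frame(cells[, list(year, age_group, diagnosis,
                                    rate_per_100k = rate)])
  out[order(out$diagnosis, out$year, out$age_group), ]
}
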