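# Outcome estimators: incidence arithmetic and tally oracle, MST estimates,
# progression proportions, overdiagnosis accounting.

# small hand-made paired log builder
hand_log <- function(events) {
  dt <- data.table::as.data.table(events)
  dt[, calendar_year := as.integer(floor(birth_year + age))]
  dt
}

test_that("incidence arithmetic: one case, one woman-year cell", {
  n <- 1000
  ev <- data.table::rbindlist(c(
    list(data.table::data.table(
      woman_id = 1L, universe = "unscreened", birth_year = 1935L,
      state = "clinical_dcis", age = 31 - 1e-9)),
    lapply(1:n, function(i) data.table::data.table(
      woman_id = i, universe = "unscreened", birth_year = 1935L,
      state = "death_other", age = 31))))
  log <- hand_log(ev)
  inc <- compute_incidence(log, "unscreened", years = 1965)
  cell <- inc$cells[diagnosis == "DCIS" & mode == "clinical" &
                      age_group == "30-34"]
  expect_equal(cell$count, 1L)
  expect_equal(cell$women_years, n, tolerance = 1e-6)
  expect_equal(cell$rate, 100, tolerance = 1e-6)
  # age-adjusted rate: only one group occupied, weight 1/10
  adj <- inc$age_adjusted[diagnosis == "DCIS"]
  expect_equal(adj$rate, 10, tolerance = 1e-6)
})

test_that("weights must sum to one; empty logs give empty tables", {
  log <- simulate_population(population_spec(
    submodel_config("1a"), default_nh_params(submodel_config("1a")),
    n_women = 100, seed = 2))
  expect_error(compute_incidence(log, "screened", weights = rep(0.2, 10)),
               "sum to 1")
  empty <- log[log$woman_id < 0, ]
  inc0 <- compute_incidence(empty, "screened")
  expect_s3_class(inc0, "incidence_table")
  expect_true(all(inc0$cells$count == 0))
})

test_that("unscreened universe has no screen-mode cases", {
  cfg <- submodel_config("2b")
  log <- simulate_population(population_spec(cfg, default_nh_params(cfg),
                                             n_women = 5000, seed = 3))
  inc <- compute_incidence(log, "unscreened")
  expect_equal(sum(inc$cells[mode == "screen", count]), 0L)
  expect_gt(sum(inc$cells[mode == "clinical", count]), 0L)
})

test_that("incidence counts equal an independent brute-force tally", {
  cfg <- submodel_config("3b")
  log <- simulate_population(population_spec(cfg, default_nh_params(cfg),
                                             n_women = 20000, seed = 4))
  for (uni in c("screened", "unscreened")) {
    inc <- compute_incidence(log, uni)
    got <- inc$cells[count > 0][order(year, age_group, diagnosis, mode)]
    oracle <- oracle_count_tally(log, uni)
    expect_equal(nrow(got), nrow(oracle))
    expect_equal(got$count, oracle$count)
    parts <- strsplit(oracle$cls, ".", fixed = TRUE)
    expect_equal(paste(got$year, got$age_group, got$diagnosis, got$mode),
                 paste(oracle$year, oracle$age_group,
                       vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2)))
  }
  # women-years oracle on a small subset: direct per-woman integration
  inc <- compute_incidence(log, "unscreened")
  dt <- data.table::as.data.table(log)[universe == "unscreened"]
  dies <- dt[state == "death_other", list(woman_id, birth_year, d = age)]
  diag <- dt[state %in% c("clinical_dcis", "ibc_clinical"),
             list(dg = min(age)), by = woman_id]
  dies <- merge(dies, diag, by = "woman_id", all.x = TRUE)
  dies[, end := pmin(d, dg, na.rm = TRUE)]
  yr <- 1990
  g <- "50-54"
  wy_oracle <- 0
  for (i in seq_len(nrow(dies))) {
    ages <- 50:54
    yrs <- dies$birth_year[i] + ages
    keep <- yrs == yr
    if (any(keep))
      wy_oracle <- wy_oracle +
        sum(pmin(pmax(dies$end[i] - ages[keep], 0), 1))
  }
  got_wy <- inc$cells[year == yr & age_group == g & diagnosis == "DCIS" &
                        mode == "clinical", women_years]
  expect_equal(got_wy, wy_oracle, tolerance = 1e-9)
})

test_that("MST estimates recover the configured sojourns", {
  cfg <- submodel_config(frac_to_screen_detectable = 1,
                         regression_allowed = FALSE)
  prm <- forced_onset_params(onset_age = 40, p1 = 0.5, p2 = 0.5, p3 = 0,
                             mst1 = 2.5, mst2 = 1.9)
  lt <- point_death_life_table(100)
  log <- simulate_population(population_spec(cfg, prm, n_women = 3e4,
                                             seed = 5, life_table = lt))
  est <- estimate_mst(log)
  e1 <- est[est$path == "P1", ]
  e2 <- est[est$path == "P2", ]
  expect_lt(abs(e1$mean - 2.5), 3 * e1$se)
  expect_lt(abs(e2$mean - 1.9), 3 * e2$se)
  # P3 is flagged absent, not zero
  e3 <- est[est$path == "P3", ]
  expect_equal(e3$n, 0L)
  expect_true(is.na(e3$mean))
})

test_that("equal path MSTs give the same pooled mean", {
  cfg <- submodel_config(frac_to_screen_detectable = 1,
                         regression_allowed = TRUE)
  prm <- forced_onset_params(onset_age = 40, p1 = 0.4, p2 = 0.3, p3 = 0.3,
                             mst1 = 1, mst2 = 1, mst3 = 1)
  lt <- point_death_life_table(100)
  log <- simulate_population(population_spec(cfg, prm, n_women = 2e4,
                                             seed = 6, life_table = lt))
  ep <- dcisim:::sd_episodes_(log)
  dwell <- ep$exit_age - ep$entry_age
  dwell <- dwell[!is.na(dwell)]
  expect_lt(abs(mean(dwell) - 1), 3 * sd(dwell) / sqrt(length(dwell)))
})

test_that("censored episodes are excluded from MST and reported", {
  # death at 45 cuts most sojourns short (entry ~41, mst 10)
  cfg <- submodel_config(frac_to_screen_detectable = 1,
                         regression_allowed = FALSE)
  prm <- forced_onset_params(onset_age = 40, p1 = 1, p2 = 0, p3 = 0,
                             mst1 = 10, mst2 = 10,
                             undetectable_mean_dwell = 0.5)
  lt <- point_death_life_table(45)
  log <- simulate_population(population_spec(cfg, prm, n_women = 5000,
                                             seed = 7, life_table = lt))
  est <- estimate_mst(log)
  expect_gt(attr(est, "censored_n"), 0)
  # completed sojourns are all shorter than the censoring window allows
  expect_lt(est[est$path == "P1", "mean"], 10)
})

test_that("progression proportions match the path probabilities", {
  cfg <- submodel_config(frac_to_screen_detectable = 1,
                         regression_allowed = FALSE)
  # degenerate: everything exits to P1
  prm <- forced_onset_params(onset_age = 45, p1 = 1, p2 = 0, p3 = 0)
  lt <- point_death_life_table(95)
  log <- simulate_population(population_spec(cfg, prm, n_women = 5000,
                                             seed = 8, cohorts = 1930,
                                             life_table = lt))
  pr <- progression_proportions(log, birth_cohort = 1930)
  expect_true(all(pr$P1[pr$n_resolved > 0] == 1))

  # the published no-regression lower bound as a test point: (64%, 36%)
  prm2 <- forced_onset_params(onset_age = 45, p1 = 0.64, p2 = 0.36, p3 = 0)
  log2 <- simulate_population(population_spec(cfg, prm2, n_women = 3e4,
                                              seed = 9, cohorts = 1930,
                                              life_table = lt))
  pr2 <- progression_proportions(log2, birth_cohort = 1930,
                                 age_breaks = c(40, 50))
  n <- pr2$n_resolved[1]
  expect_lt(abs(pr2$P1[1] - 0.64), 3 * sqrt(0.64 * 0.36 / n))
  expect_equal(pr2$P1 + pr2$P2 + pr2$P3, rep(1, nrow(pr2)))

  # proportions equal a brute-force path tally
  ep <- dcisim:::sd_episodes_(log2)
  ep <- ep[ep$birth_year == 1930 & !is.na(ep$path) &
             ep$entry_age >= 40 & ep$entry_age < 50, ]
  expect_equal(pr2$P1[1], mean(ep$path == "P1"))
  expect_equal(pr2$n_resolved[1], nrow(ep))
  # absent cohort errors
  expect_error(progression_proportions(log2, birth_cohort = 1890),
               "absent")
})

test_that("overdiagnosis: guards, regression lesions, denominators", {
  cfg <- submodel_config("2b")
  prm <- default_nh_params(cfg)
  sens0 <- sensitivity_schedule(data.frame(start_year = 1975, dcis = 0,
                                           ibc = 0))
  log0 <- simulate_population(population_spec(cfg, prm, n_women = 2000,
                                              seed = 10, sens = sens0))
  od0 <- compute_overdiagnosis(log0)
  expect_equal(od0$screen_detected, c(0L, 0L, 0L))
  expect_equal(od0$percentage, c(0, 0, 0))

  # pure-regression lesions can only ever be overdiagnosed
  cfgr <- submodel_config(frac_to_screen_detectable = 1,
                          regression_allowed = TRUE)
  prmr <- forced_onset_params(onset_age = 45, p1 = 0, p2 = 0, p3 = 1,
                              mst3 = 3)
  logr <- simulate_population(population_spec(cfgr, prmr, n_women = 5000,
                                              seed = 11,
                                              life_table =
                                                point_death_life_table(90)))
  odr <- compute_overdiagnosis(logr)
  dcis_row <- odr[odr$diagnosis == "DCIS", ]
  expect_gt(dcis_row$screen_detected, 0)
  expect_equal(dcis_row$overdiagnosed, dcis_row$screen_detected)

  # denominator conservation: screen + clinical = all diagnoses, screened
  log <- simulate_population(population_spec(cfg, prm, n_women = 10000,
                                             seed = 12))
  od <- compute_overdiagnosis(log)
  comb <- od[od$diagnosis == "combined", ]
  n_diag <- sum(log$universe == "screened" &
                  log$state %in% c("clinical_dcis", "ibc_clinical",
                                   "screen_detected_dcis",
                                   "screen_detected_ibc"))
  expect_equal(comb$screen_detected + comb$clinical, n_diag)
  expect_true(all(od$overdiagnosed <= od$screen_detected))
  # unpaired log errors
  expect_error(compute_overdiagnosis(log[log$universe == "screened", ]),
               "unpaired")
})

test_that("regression strictly raises DCIS overdiagnosis, all else fixed", {
  cfg_a <- submodel_config(frac_to_screen_detectable = 0.5,
                          regression_allowed = FALSE)
  cfg_b <- submodel_config(frac_to_screen_detectable = 0.5,
                          regression_allowed = TRUE)
  prm_a <- nh_params(p1 = 0.8, p2 = 0.2, p3 = 0, mst1 = 1.5, mst2 = 1.9)
  prm_b <- nh_params(p1 = 0.56, p2 = 0.14, p3 = 0.3, mst1 = 1.5,
                     mst2 = 1.9, mst3 = 1.5)
  od <- lapply(list(list(cfg_a, prm_a), list(cfg_b, prm_b)), function(cp) {
    log <- simulate_population(population_spec(cp[[1]], cp[[2]],
                                               n_women = 3e4, seed = 13))
    compute_overdiagnosis(log)
  })
  expect_gt(od[[2]]$percentage[1], od[[1]]$percentage[1])
})
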