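# Natural-history module: onset sampling, undetectable and screen-detectable
# fates, full lesion chains, and the transition-graph invariants.

test_that("onset sampling honours the hazard: zero, constant, banded", {
  # zero hazard: no onset, ever
  p0 <- nh_params(onset_breaks = c(0, 120), onset_rates = c(0, 0),
                  p1 = 1, p2 = 0, p3 = 0, mst1 = 1, mst2 = 1)
  set.seed(1)
  expect_true(all(is.na(sample_onset_age(p0, 1950, 100, n = 500))))

  # constant hazard h with effectively unbounded lifetime: exponential mean
  h <- 0.05
  ph <- nh_params(onset_breaks = c(0, 1e5), onset_rates = c(h, h),
                  p1 = 1, p2 = 0, p3 = 0, mst1 = 1, mst2 = 1)
  set.seed(2)
  x <- sample_onset_age(ph, 1950, Inf, n = 1e5)
  expect_true(all(!is.na(x)))
  se <- (1 / h) / sqrt(length(x))
  expect_lt(abs(mean(x) - 1 / h), 3 * se)

  # hazard supported only on [50, 51): every onset inside, truncation works
  pb <- forced_onset_params(onset_age = 50)
  set.seed(3)
  y <- sample_onset_age(pb, 1950, 80, n = 2000)
  y <- y[!is.na(y)]
  expect_gt(length(y), 0)
  expect_true(all(y >= 50 & y < 51))
})

test_that("negative onset hazard is rejected", {
  expect_error(
    nh_params(onset_breaks = c(0, 50), onset_rates = c(-0.1, 0),
              p1 = 1, p2 = 0, p3 = 0, mst1 = 1, mst2 = 1),
    "nonnegative")
})

test_that("cohort trend multiplies the onset hazard log-linearly", {
  p <- nh_params(onset_breaks = c(0, 1e5), onset_rates = c(0.01, 0.01),
                 cohort_slope = 0.02, cohort_ref = 1950,
                 p1 = 1, p2 = 0, p3 = 0, mst1 = 1, mst2 = 1)
  h <- onset_hazard(p)
  expect_equal(h(40, 1950), 0.01)
  expect_equal(h(40, 1970), 0.01 * exp(0.02 * 20))
  # mean onset age scales inversely with the multiplier
  set.seed(4)
  m1950 <- mean(sample_onset_age(p, 1950, Inf, n = 4e4))
  m1970 <- mean(sample_onset_age(p, 1970, Inf, n = 4e4))
  expect_lt(abs(m1950 / m1970 - exp(0.02 * 20)), 0.1)
})

test_that("undetectable fate splits by the configured proportions", {
  prm <- nh_params(p1 = 1, p2 = 0, p3 = 0, mst1 = 1, mst2 = 1,
                   undetectable_direct_to_ibc_frac = 1)
  n <- 1e5
  for (f in c(0.30, 0.50, 0.80)) {
    cfg <- submodel_config(frac_to_screen_detectable = f,
                           regression_allowed = FALSE)
    set.seed(10 + round(100 * f))
    fate <- sample_undetectable_fate(cfg, prm, n = n)
    phat <- mean(fate$destination == "screen_detectable")
    expect_lt(abs(phat - f), 3 * sqrt(f * (1 - f) / n))
  }
  # degenerate proportion: always screen-detectable
  cfg1 <- submodel_config(frac_to_screen_detectable = 1,
                          regression_allowed = FALSE)
  set.seed(11)
  expect_true(all(sample_undetectable_fate(cfg1, prm, n = 1000)$destination
                  == "screen_detectable"))
  # remainder routed to direct IBC when the direct fraction is 1
  cfg8 <- submodel_config(frac_to_screen_detectable = 0.80,
                          regression_allowed = FALSE)
  set.seed(12)
  fate <- sample_undetectable_fate(cfg8, prm, n = n)
  expect_lt(abs(mean(fate$destination == "ibc_direct") - 0.20),
            3 * sqrt(0.2 * 0.8 / n))
  expect_equal(sum(fate$destination == "indolent"), 0)
  # indolent lesions never leave the state
  prm0 <- nh_params(p1 = 1, p2 = 0, p3 = 0, mst1 = 1, mst2 = 1,
                    undetectable_direct_to_ibc_frac = 0)
  set.seed(13)
  f2 <- sample_undetectable_fate(cfg8, prm0, n = 1000)
  expect_true(all(is.infinite(f2$dwell[f2$destination == "indolent"])))
})

test_that("screen-detectable fate: multinomial paths, path-specific dwells", {
  cfg <- submodel_config("1b")
  prm <- nh_params(p1 = 0.5, p2 = 0.3, p3 = 0.2,
                   mst1 = 2.5, mst2 = 1.9, mst3 = 1.5)
  n <- 1e5
  set.seed(20)
  fate <- sample_screen_detectable_fate(cfg, prm, n = n)
  # multinomial frequencies within 3 binomial SEs
  for (pp in list(c("P1", 0.5), c("P2", 0.3), c("P3", 0.2))) {
    p <- as.numeric(pp[2])
    expect_lt(abs(mean(fate$path == pp[1]) - p), 3 * sqrt(p * (1 - p) / n))
  }
  # P1 dwell mean matches its configured sojourn input of 2.5 years
  d1 <- fate$dwell[fate$path == "P1"]
  expect_lt(abs(mean(d1) - 2.5), 3 * sd(d1) / sqrt(length(d1)))
  expect_true(all(fate$dwell > 0))

  # regression prohibited: P3 never drawn
  cfga <- submodel_config("1a")
  prma <- nh_params(p1 = 0.64, p2 = 0.36, p3 = 0, mst1 = 2.5, mst2 = 2.5)
  set.seed(21)
  fa <- sample_screen_detectable_fate(cfga, prma, n = 5e4)
  expect_equal(sum(fa$path == "P3"), 0)
  # p3 > 0 under a no-regression submodel is a config conflict
  expect_error(sample_screen_detectable_fate(cfga, prm, n = 10),
               "conflict")
})

test_that("simulate_lesion chains the states and truncates at death", {
  cfg <- submodel_config("1a")
  # no onset possible: only the death event
  p0 <- nh_params(onset_breaks = c(0, 120), onset_rates = c(0, 0),
                  p1 = 1, p2 = 0, p3 = 0, mst1 = 1, mst2 = 1)
  set.seed(30)
  h <- simulate_lesion(cfg, p0, 1950, 80)
  expect_identical(h$events$state, "death_other")
  expect_equal(h$events$age, 80)

  # P2-only path ends in clinical DCIS with no IBC states
  p2 <- forced_onset_params(onset_age = 50, p1 = 0, p2 = 1, p3 = 0,
                            mst1 = 1, mst2 = 1)
  cfg1 <- submodel_config(frac_to_screen_detectable = 1,
                          regression_allowed = FALSE)
  found <- 0
  set.seed(31)
  for (i in 1:200) {
    h <- simulate_lesion(cfg1, p2, 1950, 95)
    expect_false(any(grepl("ibc", h$events$state)))
    if ("clinical_dcis" %in% h$events$state) {
      found <- found + 1
      expect_identical(h$events$state[nrow(h$events) - 1], "clinical_dcis")
    }
    validate_life_history(h)
  }
  expect_gt(found, 100)

  # degenerate limit: all dwell means -> 0, onset in [50, 51): clinical
  # surfacing collapses onto the onset age
  pz <- nh_params(onset_breaks = c(0, 50, 51, 120),
                  onset_rates = c(0, 50, 0, 0),
                  undetectable_mean_dwell = 1e-9,
                  p1 = 0, p2 = 1, p3 = 0, mst1 = 1e-9, mst2 = 1e-9,
                  ibc_preclinical_mean_dwell = 1e-9)
  set.seed(32)
  h <- simulate_lesion(cfg1, pz, 1950, 95)
  surf <- h$events$age[h$events$state == "clinical_dcis"]
  expect_equal(length(surf), 1L)
  expect_lt(abs(surf - h$events$age[h$events$state == "dcis_undetectable"]),
            1e-6)
  expect_true(surf >= 50 && surf < 51)
})

test_that("transition-graph closure holds across a large simulated log", {
  cfg <- submodel_config("2b")
  spec <- population_spec(cfg, default_nh_params(cfg), n_women = 1e5,
                          seed = 99)
  log <- simulate_population(spec)
  edges <- allowed_transitions()
  ok_pairs <- paste(edges$from, edges$to)
  dt <- data.table::as.data.table(log)
  dt[, prev := data.table::shift(state, fill = "no_bc"),
     by = list(woman_id, universe)]
  expect_true(all(paste(dt$prev, dt$state) %in% ok_pairs))
  # event ages non-decreasing per woman per universe
  expect_true(all(dt[, !is.unsorted(age), by = list(woman_id, universe)]$V1))
})

test_that("optional regression from the undetectable state (default off)", {
  cfg <- submodel_config(frac_to_screen_detectable = 0.4,
                         regression_allowed = TRUE)
  prm_on <- nh_params(p1 = 0.5, p2 = 0.2, p3 = 0.3, mst1 = 1, mst2 = 1,
                      mst3 = 1, undetectable_regression_frac = 0.5,
                      undetectable_direct_to_ibc_frac = 1)
  set.seed(40)
  fate <- sample_undetectable_fate(cfg, prm_on, n = 2e4)
  # remainder 0.6 splits half to regression, rest all direct IBC
  expect_lt(abs(mean(fate$destination == "regressed") - 0.3),
            3 * sqrt(0.3 * 0.7 / 2e4))
  expect_equal(sum(fate$destination == "indolent"), 0)
  # the trajectory shows regression without a screen-detectable episode
  log <- simulate_population(population_spec(
    cfg, prm_on, n_women = 2000, seed = 41,
    life_table = point_death_life_table(95)))
  dt <- data.table::as.data.table(log)[universe == "unscreened"]
  reg_women <- dt[state == "regressed", woman_id]
  sd_women <- dt[state == "dcis_screen_detectable", woman_id]
  expect_gt(length(setdiff(reg_women, sd_women)), 0)
  # prohibited submodels reject the switch
  cfg_a <- submodel_config(frac_to_screen_detectable = 0.4,
                           regression_allowed = FALSE)
  expect_error(simulate_lesion(cfg_a,
                               nh_params(p1 = 1, p2 = 0, p3 = 0, mst1 = 1,
                                         mst2 = 1,
                                         undetectable_regression_frac = 0.2),
                               1950, 80), "conflict")
})

test_that("allowing regression strictly reduces clinical surfacing", {
  # same seed, p1:p2 ratio fixed (4:1), p3 moved 0 -> 0.3
  cfg_a <- submodel_config(frac_to_screen_detectable = 0.5,
                           regression_allowed = FALSE)
  cfg_b <- submodel_config(frac_to_screen_detectable = 0.5,
                           regression_allowed = TRUE)
  prm_a <- nh_params(p1 = 0.8, p2 = 0.2, p3 = 0, mst1 = 1, mst2 = 1)
  prm_b <- nh_params(p1 = 0.56, p2 = 0.14, p3 = 0.3, mst1 = 1, mst2 = 1,
                     mst3 = 1)
  n_clin <- sapply(list(prm_a, prm_b), function(prm) {
    cfg <- if (prm$p3 > 0) cfg_b else cfg_a
    log <- simulate_population(population_spec(cfg, prm, n_women = 3e4,
                                               seed = 7))
    sum(log$universe == "unscreened" &
          log$state %in% c("clinical_dcis", "ibc_clinical"))
  })
  expect_lt(n_clin[2], n_clin[1])
})
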