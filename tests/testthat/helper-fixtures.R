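# Shared fixtures: contrived parameter sets that force specific routes
# through the model, a low-mortality life table, and independent brute-force
# oracles written in plain base R against the event log.

# onset concentrated in one age band [a, a+1) with a high rate
forced_onset_params <- function(onset_age = 40, p1 = 0.8, p2 = 0.2, p3 = 0,
                                mst1 = 1, mst2 = 1, ...) {
  nh_params(onset_breaks = c(0, onset_age, onset_age + 1, 120),
            onset_rates = c(0, 50, 0, 0),
            p1 = p1, p2 = p2, p3 = p3, mst1 = mst1, mst2 = mst2, ...)
}

# everyone dies in the year [death_age, death_age + 1)
point_death_life_table <- function(death_age = 90, cohorts = 1890:1996) {
  do.call(rbind, lapply(cohorts, function(by) {
    data.frame(birth_year = by, age = 0:110,
               annual_death_prob = ifelse(0:110 >= death_age, 1, 0))
  }))
}

# dissemination with a flat cumulative uptake from 1975 onwards
flat_dissemination <- function(uptake = 1, interval = 2, age_start = 40,
                               age_stop = 74) {
  dissemination_schedule(
    data.frame(calendar_year = 1975:2040, start_probability = uptake,
               interval_years = interval),
    age_start = age_start, age_stop = age_stop)
}

# brute-force diagnosis-count tally (independent of compute_incidence)
oracle_count_tally <- function(log, universe, years = 1975:2015) {
  df <- as.data.frame(log)
  df <- df[df$universe == universe, ]
  map <- c(clinical_dcis = "DCIS.clinical", screen_detected_dcis =
             "DCIS.screen", ibc_clinical = "IBC.clinical",
           screen_detected_ibc = "IBC.screen")
  df <- df[df$state %in% names(map), ]
  df$year <- floor(df$birth_year + df$age)
  df$cls <- map[df$state]
  df <- df[df$age >= 30 & df$age < 80 & df$year %in% years, ]
  g <- 5 * (df$age %/% 5)
  df$age_group <- paste(g, g + 4, sep = "-")
  out <- aggregate(list(count = rep(1L, nrow(df))),
                   by = df[, c("year", "age_group", "cls")], FUN = sum)
  out[order(out$year, out$age_group, out$cls), ]
}

# brute-force per-woman counterfactual overdiagnosis check
oracle_overdiagnosis <- function(log) {
  df <- as.data.frame(log)
  idx <- split(seq_len(nrow(df)), df$woman_id)
  rows <- lapply(idx, function(ii) {
    w <- df[ii, ]
    scr <- w[w$universe == "screened", ]
    uns <- w[w$universe == "unscreened", ]
    det <- scr[scr$state %in% c("screen_detected_dcis",
                                "screen_detected_ibc"), ]
    surf_any <- any(uns$state %in% c("clinical_dcis", "ibc_clinical"))
    surf_ibc <- any(uns$state == "ibc_clinical")
    data.frame(
      scr_dcis = sum(det$state == "screen_detected_dcis"),
      scr_ibc = sum(det$state == "screen_detected_ibc"),
      clin_dcis = sum(scr$state == "clinical_dcis"),
      clin_ibc = sum(scr$state == "ibc_clinical"),
      over_dcis = sum(det$state == "screen_detected_dcis" & !surf_any),
      over_ibc = sum(det$state == "screen_detected_ibc" & !surf_ibc))
  })
  tot <- colSums(do.call(rbind, rows))
  pct <- function(ov, n) if (n > 0) 100 * ov / n else 0
  data.frame(
    diagnosis = c("DCIS", "IBC", "combined"),
    screen_detected = c(tot[["scr_dcis"]], tot[["scr_ibc"]],
                        tot[["scr_dcis"]] + tot[["scr_ibc"]]),
    clinical = c(tot[["clin_dcis"]], tot[["clin_ibc"]],
                 tot[["clin_dcis"]] + tot[["clin_ibc"]]),
    overdiagnosed = c(tot[["over_dcis"]], tot[["over_ibc"]],
                      tot[["over_dcis"]] + tot[["over_ibc"]]),
    percentage = c(
      pct(tot[["over_dcis"]], tot[["scr_dcis"]] + tot[["clin_dcis"]]),
      pct(tot[["over_ibc"]], tot[["scr_ibc"]] + tot[["clin_ibc"]]),
      pct(tot[["over_dcis"]] + tot[["over_ibc"]],
          tot[["scr_dcis"]] + tot[["scr_ibc"]] + tot[["clin_dcis"]] +
            tot[["clin_ibc"]])))
}
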