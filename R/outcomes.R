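# Outcome measures on paired event logs: incidence tables with direct age
# standardization (ages 30-79), mean sojourn times by exit path, progression
# proportions, and counterfactual overdiagnosis.

DIAG_MAP <- data.table::data.table(
  state = c("clinical_dcis", "screen_detected_dcis", "ibc_clinical",
            "screen_detected_ibc"),
  diagnosis = c("DCIS", "DCIS", "IBC", "IBC"),
  mode = c("clinical", "screen", "clinical", "screen"))

AGE_BREAKS <- seq(30, 80, by = 5)

age_group_of_ <- function(age) band_label_(age, AGE_BREAKS)

# label ages by [b_i, b_{i+1}) bands; outside the range -> NA (never drop)
band_label_ <- function(age, breaks) {
  lab <- paste(head(breaks, -1), breaks[-1] - 1, sep = "-")
  g <- findInterval(age, breaks)
  out <- rep(NA_character_, length(age))
  ok <- !is.na(g) & g >= 1 & g < length(breaks)
  out[ok] <- lab[g[ok]]
  factor(out, levels = lab)
}

#' Age-group labels of the standardization range (30-79, 5-year groups)
#' @return character vector of ten labels
#' @export
age_groups <- function() levels(age_group_of_(30))

#' Incidence table with direct age standardization
#'
#' Tabulates diagnosis events (clinical DCIS / screen-detected DCIS /
#' clinical IBC / screen-detected IBC) by calendar year, 5-year age group
#' within 30-79, diagnosis and detection mode; accumulates women-years until
#' other-cause death or diagnosis, whichever comes first; and computes the
#' age-adjusted yearly rate per 100,000 as the weighted sum of group rates.
#'
#' @param log a `paired_event_log`
#' @param universe `"unscreened"` or `"screened"`
#' @param weights standard-population weights over the ten 5-year age groups
#'   30-79 (must sum to 1); default equal weights
#' @param years calendar years to tabulate (default 1975-2015)
#' @return object of class `incidence_table`: list with `cells` (counts,
#'   women-years, rates per cell) and `age_adjusted` (year x diagnosis rates
#'   per 100,000, detection modes combined)
#' @export
compute_incidence <- function(log, universe = c("screened", "unscreened"),
                              weights = NULL, years = 1975:2015) {
  universe <- match.arg(universe)
  grp <- age_groups()
  if (is.null(weights)) weights <- rep(1 / length(grp), length(grp))
  if (abs(sum(weights) - 1) > 1e-8)
    stop("standard-population weights must sum to 1", call. = FALSE)
  uni <- universe
  dt <- data.table::as.data.table(log)
  ev <- dt[dt$universe == uni]
  empty_cells <- data.table::CJ(year = years, age_group = grp,
                                diagnosis = c("DCIS", "IBC"),
                                mode = c("clinical", "screen"))
  if (nrow(ev) == 0) {
    cells <- empty_cells[, `:=`(count = 0L, women_years = 0, rate = NA_real_)]
    adj <- data.table::CJ(year = years, diagnosis = c("DCIS", "IBC"))
    adj[, rate := NA_real_]
    return(structure(list(cells = cells[], age_adjusted = adj[],
                          weights = weights, years = years,
                          universe = universe),
                     class = "incidence_table"))
  }
  # per-woman follow-up: birth year, death age, diagnosis age (if any)
  women <- ev[state == "death_other",
              list(woman_id, birth_year, death_age = age)]
  diag <- merge(ev, DIAG_MAP, by = "state")[
    , list(woman_id, birth_year, age, diagnosis, mode)]
  data.table::setorder(diag, woman_id, age)
  first_diag <- diag[, head(.SD, 1L), by = woman_id]
  women <- merge(women, first_diag[, list(woman_id, diag_age = age)],
                 by = "woman_id", all.x = TRUE)
  women[, end := pmin(death_age, diag_age, na.rm = TRUE)]
  # women-years by (calendar year, age group), accumulated one age at a time
  wy_parts <- lapply(30:79, function(a) {
    women[, list(wy = sum(pmin(pmax(end - a, 0), 1))),
          by = birth_year][, list(year = birth_year + a,
                                  age = a, wy = wy)]
  })
  wy <- data.table::rbindlist(wy_parts)
  wy[, age_group := age_group_of_(age)]
  wy <- wy[year %in% years, list(women_years = sum(wy)),
           by = list(year, age_group)]
  # diagnosis counts by cell
  diag[, year := floor(birth_year + age)]
  diag[, age_group := age_group_of_(age)]
  cnt <- diag[!is.na(age_group) & year %in% years,
              list(count = .N), by = list(year, age_group, diagnosis, mode)]
  cells <- merge(empty_cells, cnt,
                 by = c("year", "age_group", "diagnosis", "mode"),
                 all.x = TRUE)
  cells[is.na(count), count := 0L]
  cells <- merge(cells, wy, by = c("year", "age_group"), all.x = TRUE)
  cells[is.na(women_years), women_years := 0]
  cells[, rate := ifelse(women_years > 0, 1e5 * count / women_years,
                         NA_real_)]
  # age-adjusted yearly rate per diagnosis, modes pooled
  pooled <- cells[, list(count = sum(count), women_years = women_years[1]),
                  by = list(year, diagnosis, age_group)]
  pooled[, rate := ifelse(women_years > 0, 1e5 * count / women_years, 0)]
  wtab <- data.table::data.table(age_group = factor(grp, levels = grp),
                                 weight = weights)
  adj <- merge(pooled, wtab, by = "age_group")[
    , list(rate = sum(weight * rate)), by = list(year, diagnosis)]
  data.table::setorder(adj, diagnosis, year)
  structure(list(cells = cells[], age_adjusted = adj[], weights = weights,
                 years = years, universe = universe),
            class = "incidence_table")
}

#' @export
print.incidence_table <- function(x, ...) {
  cat(sprintf("incidence_table (%s universe, %d-%d)\n", x$universe,
              min(x$years), max(x$years)))
  cat("age-adjusted rates per 100,000 (modes pooled):\n")
  print(data.table::dcast(x$age_adjusted, year ~ diagnosis,
                          value.var = "rate"), topn = 5)
  invisible(x)
}

# screen-detectable DCIS episodes (entry, exit, path) per woman, unscreened
sd_episodes_ <- function(log, universe = "unscreened") {
  uni <- universe
  dt <- data.table::as.data.table(log)
  ev <- dt[dt$universe == uni]
  entry <- ev[state == "dcis_screen_detectable",
              list(woman_id, birth_year, entry_age = age)]
  exits <- ev[state %in% c("ibc_preclinical", "clinical_dcis", "regressed"),
              list(woman_id, exit_age = age, exit_state = state)]
  ep <- merge(entry, exits, by = "woman_id", all.x = TRUE)
  # direct-route preclinical IBC precedes any screen-detectable entry and is
  # not an exit of this episode
  ep <- ep[is.na(exit_age) | exit_age > entry_age |
             abs(exit_age - entry_age) < 1e-12]
  ep[, path := c(ibc_preclinical = "P1", clinical_dcis = "P2",
                 regressed = "P3")[exit_state]]
  ep[]
}

#' Mean sojourn time in screen-detectable DCIS by exit path
#'
#' Sample mean and standard error of (exit age - entry age) in the
#' screen-detectable state per exit path, computed on the unscreened
#' universe so sojourns are uninterrupted by excision. Episodes censored by
#' other-cause death while still in the state are excluded and reported as a
#' censored count. Paths with zero completed episodes get an `NA` estimate
#' (flagged, not zero).
#'
#' @param log a `paired_event_log`
#' @param universe universe to measure (default `"unscreened"`)
#' @return object of class `mst_estimate`: data.frame with one row per path
#'   (`mean`, `se`, `n`) and attribute `censored_n`
#' @export
estimate_mst <- function(log, universe = "unscreened") {
  ep <- sd_episodes_(log, universe)
  done <- ep[!is.na(path)]
  done[, dwell := exit_age - entry_age]
  est <- done[, list(mean = mean(dwell),
                     se = stats::sd(dwell) / sqrt(.N), n = .N),
              by = path]
  out <- merge(data.table::data.table(path = c("P1", "P2", "P3")), est,
               by = "path", all.x = TRUE)
  out[is.na(n), n := 0L]
  res <- as.data.frame(out)
  attr(res, "censored_n") <- nrow(ep) - nrow(done)
  class(res) <- c("mst_estimate", "data.frame")
  res
}

#' @export
print.mst_estimate <- function(x, ...) {
  cat("mean sojourn time in screen-detectable DCIS by exit path (years)\n")
  print.data.frame(x, row.names = FALSE)
  cat("death-censored episodes:", attr(x, "censored_n"), "\n")
  invisible(x)
}

#' Progression proportions of screen-detectable DCIS by age at entry
#'
#' Among lesions of one birth cohort that enter the screen-detectable state
#' in the unscreened universe (natural history uninterrupted by screening,
#' biopsy or excision), the proportion whose resolved exit is progression to
#' preclinical IBC (P1), clinical DCIS (P2) or regression (P3), by age group
#' at entry. Proportions sum to 1 over resolved episodes; episodes censored
#' by other-cause death are reported as a separate count.
#'
#' @param log a `paired_event_log`
#' @param universe universe to measure (default `"unscreened"`)
#' @param birth_cohort birth year to condition on, or `NULL` to pool all
#' @param age_breaks age-group boundaries for the age at state entry
#' @return data.frame with columns `age_group`, `P1`, `P2`, `P3`,
#'   `n_resolved`, `n_censored`
#' @export
progression_proportions <- function(log, universe = "unscreened",
                                    birth_cohort = 1930,
                                    age_breaks = seq(30, 80, by = 10)) {
  ep <- sd_episodes_(log, universe)
  if (!is.null(birth_cohort)) {
    if (!any(log$birth_year == birth_cohort))
      stop("birth cohort ", birth_cohort, " absent from the event log",
           call. = FALSE)
    ep <- ep[birth_year == birth_cohort]
  }
  ep[, age_group := band_label_(entry_age, age_breaks)]
  ep <- ep[!is.na(age_group)]
  res <- ep[, list(
    P1 = sum(path == "P1", na.rm = TRUE) / max(sum(!is.na(path)), 1L),
    P2 = sum(path == "P2", na.rm = TRUE) / max(sum(!is.na(path)), 1L),
    P3 = sum(path == "P3", na.rm = TRUE) / max(sum(!is.na(path)), 1L),
    n_resolved = sum(!is.na(path)),
    n_censored = sum(is.na(path))), by = age_group]
  data.table::setorder(res, age_group)
  as.data.frame(res)
}

#' Counterfactual overdiagnosis accounting
#'
#' A screen-detected DCIS case is overdiagnosed when the same woman's
#' unscreened trajectory contains neither a clinical DCIS nor a clinical IBC
#' event before her other-cause death; a screen-detected IBC case, when it
#' contains no clinical IBC event. The percentage divides overdiagnosed
#' cases by all screen-detected plus clinically detected cases of that
#' diagnosis in the screened universe.
#'
#' @param log a `paired_event_log` with both universes for every woman
#' @param age_breaks optional age-group boundaries; when given, a by-age
#'   table (age at detection) is attached as attribute `by_age`
#' @return object of class `overdiagnosis_report`: data.frame with rows
#'   DCIS, IBC, combined and columns `screen_detected`, `clinical`,
#'   `overdiagnosed`, `percentage`
#' @export
compute_overdiagnosis <- function(log, age_breaks = NULL) {
  ev <- data.table::as.data.table(log)
  ids_s <- unique(ev[universe == "screened", woman_id])
  ids_u <- unique(ev[universe == "unscreened", woman_id])
  if (!setequal(ids_s, ids_u))
    stop("unpaired woman_id: every woman needs both universes",
         call. = FALSE)
  scr <- ev[universe == "screened"]
  det <- scr[state %in% c("screen_detected_dcis", "screen_detected_ibc"),
             list(woman_id, det_state = state, det_age = age)]
  surf <- ev[universe == "unscreened" &
               state %in% c("clinical_dcis", "ibc_clinical"),
             list(any_clinical = TRUE,
                  any_clin_ibc = any(state == "ibc_clinical")),
             by = woman_id]
  det <- merge(det, surf, by = "woman_id", all.x = TRUE)
  det[is.na(any_clinical), `:=`(any_clinical = FALSE, any_clin_ibc = FALSE)]
  det[, overdx := ifelse(det_state == "screen_detected_dcis",
                         !any_clinical, !any_clin_ibc)]
  clin <- scr[state %in% c("clinical_dcis", "ibc_clinical"),
              list(woman_id, diagnosis = ifelse(state == "clinical_dcis",
                                                "DCIS", "IBC"),
                   det_age = age)]
  det[, diagnosis := ifelse(det_state == "screen_detected_dcis", "DCIS",
                            "IBC")]
  tab_for <- function(d, cl) {
    row <- function(label, dd, cc) {
      sdn <- nrow(dd); cn <- nrow(cc); ov <- sum(dd$overdx)
      data.frame(diagnosis = label, screen_detected = sdn, clinical = cn,
                 overdiagnosed = ov,
                 percentage = if (sdn + cn > 0) 100 * ov / (sdn + cn) else 0)
    }
    rbind(row("DCIS", d[diagnosis == "DCIS"], cl[diagnosis == "DCIS"]),
          row("IBC", d[diagnosis == "IBC"], cl[diagnosis == "IBC"]),
          row("combined", d, cl))
  }
  out <- tab_for(det, clin)
  if (!is.null(age_breaks)) {
    lab <- paste(head(age_breaks, -1), age_breaks[-1] - 1, sep = "-")
    det[, age_group := band_label_(det_age, age_breaks)]
    clin[, age_group := band_label_(det_age, age_breaks)]
    by_age <- do.call(rbind, lapply(lab, function(g) {
      r <- tab_for(det[!is.na(age_group) & age_group == g],
                   clin[!is.na(age_group) & age_group == g])
      cbind(age_group = g, r)
    }))
    attr(out, "by_age") <- by_age
  }
  class(out) <- c("overdiagnosis_report", "data.frame")
  out
}

#' @export
print.overdiagnosis_report <- function(x, ...) {
  cat("overdiagnosis (counterfactual, parallel universes)\n")
  print.data.frame(x, row.names = FALSE)
  if (!is.null(attr(x, "by_age"))) {
    cat("\nby age at detection:\n")
    print.data.frame(attr(x, "by_age"), row.names = FALSE)
  }
  invisible(x)
}
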