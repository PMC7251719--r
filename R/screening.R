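# Mammography screening: period-specific sensitivity, dissemination-driven
# attendance, and superimposition of screen detection onto an unscreened
# trajectory. Detection is an absorbing excision: the lesion's later natural
# events are removed; other-cause death is kept.

#' Period-specific mammography sensitivity schedule
#'
#' Sensitivity is piecewise constant over calendar periods, half-open on the
#' right: a period runs from its start year to the year before the next
#' start. The default DCIS schedule is 0.45 / 0.55 / 0.70 / 0.85 for
#' 1975-1984, 1985-1999, 2000-2009 and 2010 onwards; IBC sensitivity
#' defaults to 0.85 in all periods (a configurable input — the published
#' schedule covers DCIS only).
#'
#' @param periods data.frame with columns `start_year`, `dcis`, `ibc`
#' @return object of class `sensitivity_schedule`
#' @examples
#' sensitivity_schedule()
#' @export
sensitivity_schedule <- function(periods = NULL) {
  if (is.null(periods))
    periods <- data.frame(start_year = c(1975, 1985, 2000, 2010),
                          dcis = c(0.45, 0.55, 0.70, 0.85),
                          ibc = 0.85)
  stopifnot(all(c("start_year", "dcis", "ibc") %in% names(periods)),
            !is.unsorted(periods$start_year, strictly = TRUE),
            all(periods$dcis >= 0 & periods$dcis <= 1),
            all(periods$ibc >= 0 & periods$ibc <= 1))
  structure(list(periods = periods), class = "sensitivity_schedule")
}

#' Sensitivity in force at a calendar year
#'
#' @param schedule [sensitivity_schedule()] object
#' @param calendar_year numeric vector of calendar years
#' @param diagnosis `"DCIS"` or `"IBC"`
#' @return numeric vector of sensitivities
#' @examples
#' sensitivity_at(sensitivity_schedule(), 1980, "DCIS")  # 0.45
#' sensitivity_at(sensitivity_schedule(), 2012, "DCIS")  # 0.85
#' @export
sensitivity_at <- function(schedule, calendar_year,
                           diagnosis = c("DCIS", "IBC")) {
  diagnosis <- match.arg(diagnosis)
  p <- schedule$periods
  i <- findInterval(calendar_year, p$start_year)
  if (any(i == 0))
    stop("calendar year before the first sensitivity period (",
         p$start_year[1], ")", call. = FALSE)
  if (diagnosis == "DCIS") p$dcis[i] else p$ibc[i]
}

#' Screening dissemination schedule
#'
#' Population uptake of mammography over calendar time: per calendar year
#' (optionally per birth cohort), the cumulative probability that a woman has
#' ever started screening, and the inter-screen interval in force. Uptake
#' must be non-decreasing through 2010 and is held constant afterwards;
#' screening never occurs before 1975.
#'
#' @param table data.frame with columns `calendar_year`,
#'   `start_probability`, `interval_years`, and optionally `birth_year`
#' @param age_start,age_stop age window (years) of screening eligibility
#' @return object of class `dissemination_schedule`
#' @seealso [make_dissemination()] for the synthetic logistic-ramp default
#' @export
dissemination_schedule <- function(table, age_start = 40, age_stop = 74) {
  stopifnot(all(c("calendar_year", "start_probability", "interval_years")
                %in% names(table)),
            all(table$start_probability >= 0 & table$start_probability <= 1),
            all(table$interval_years > 0))
  by_cohort <- "birth_year" %in% names(table)
  chk <- function(d) {
    d <- d[order(d$calendar_year), ]
    upto <- d$start_probability[d$calendar_year <= 2010]
    if (is.unsorted(upto))
      stop("start_probability must be non-decreasing through 2010",
           call. = FALSE)
    after <- d$start_probability[d$calendar_year >= 2010]
    if (length(after) > 1 && any(abs(diff(after)) > 1e-9))
      stop("start_probability must be constant after 2010", call. = FALSE)
  }
  if (by_cohort) invisible(lapply(split(table, table$birth_year), chk))
  else chk(table)
  structure(list(table = table, by_cohort = by_cohort,
                 age_start = age_start, age_stop = age_stop),
            class = "dissemination_schedule")
}

# cumulative start probability / interval lookup for one cohort
dissem_lookup_ <- function(dissem, birth_year) {
  tab <- dissem$table
  if (dissem$by_cohort) {
    sub <- tab[tab$birth_year == birth_year, ]
    if (nrow(sub) == 0) { # nearest available cohort
      bys <- unique(tab$birth_year)
      sub <- tab[tab$birth_year == bys[which.min(abs(bys - birth_year))], ]
    }
    tab <- sub
  }
  tab <- tab[order(tab$calendar_year), ]
  list(year = tab$calendar_year, p = tab$start_probability,
       interval = tab$interval_years)
}

step_at_ <- function(x, xs, ys, left = 0) {
  i <- findInterval(x, xs)
  out <- rep(left, length(x))
  out[i >= 1] <- ys[i[i >= 1]]
  out
}

#' Generate one woman's mammography schedule
#'
#' Walks calendar years through the woman's eligibility window; the yearly
#' conditional probability of starting is derived from the cumulative uptake
#' curve, and once started she screens at the interval in force at her start
#' year. Screens occur at mid-year, never before calendar 1975, and only
#' while she is alive.
#'
#' @param dissem [dissemination_schedule()] object
#' @param birth_year birth cohort
#' @param death_age other-cause death age
#' @param u optional uniforms, one per eligible calendar year (keyed streams)
#' @return increasing numeric vector of screen ages (possibly empty)
#' @export
generate_screen_schedule <- function(dissem, birth_year, death_age,
                                     u = NULL) {
  lk <- dissem_lookup_(dissem, birth_year)
  y0 <- max(1975, birth_year + dissem$age_start)
  y1 <- min(birth_year + dissem$age_stop, birth_year + ceiling(death_age))
  if (y0 > y1) return(numeric(0))
  years <- seq(y0, y1)
  if (is.null(u)) u <- runif(length(years))
  pc <- step_at_(years, lk$year, lk$p)        # cumulative by year
  pprev <- step_at_(years - 1, lk$year, lk$p)
  cond <- ifelse(pprev < 1, (pc - pprev) / (1 - pprev), 0)
  cond[1] <- pc[1]  # first eligible year: cumulative uptake applies whole
  cond <- pmin(pmax(cond, 0), 1)
  started <- which(u[seq_along(years)] < cond)
  if (length(started) == 0) return(numeric(0))
  ystart <- years[started[1]]
  interval <- step_at_(ystart, lk$year, lk$interval, left = 2)
  ages <- seq(ystart - birth_year + 0.5, dissem$age_stop + 0.5, by = interval)
  ages[ages < death_age & birth_year + ages >= 1975]
}

# state occupied at given ages of an unscreened trajectory
state_at_ <- function(history, ages) {
  ev <- history$events
  i <- findInterval(ages, ev$age)
  out <- rep("no_bc", length(ages))
  out[i >= 1] <- ev$state[i[i >= 1]]
  out
}

#' Superimpose screen detection onto an unscreened trajectory
#'
#' Walks the screens in order. At a screen where the woman occupies the
#' screen-detectable DCIS state, detection occurs with the DCIS sensitivity
#' in force that calendar year; in the preclinical IBC state, with the IBC
#' sensitivity. The first detection appends an absorbing
#' `screen_detected_dcis` / `screen_detected_ibc` event at that age and
#' removes all later natural events (the lesion is excised); other-cause
#' death is retained. Undetected screens leave the trajectory unchanged.
#'
#' @param history unscreened `life_history`
#' @param screens increasing vector of screen ages
#' @param sens [sensitivity_schedule()] object
#' @param u optional uniforms, one per screen (keyed streams)
#' @return a `life_history` in the screened universe
#' @export
superimpose_screening <- function(history, screens, sens, u = NULL) {
  if (length(screens) == 0) return(history)
  if (is.unsorted(screens, strictly = TRUE))
    stop("screen ages must be strictly increasing", call. = FALSE)
  if (is.null(u)) u <- runif(length(screens))
  st <- state_at_(history, screens)
  yr <- floor(history$birth_year + screens)
  p <- numeric(length(screens))
  in_dcis <- st == "dcis_screen_detectable"
  in_ibc <- st == "ibc_preclinical"
  if (any(in_dcis)) p[in_dcis] <- sensitivity_at(sens, yr[in_dcis], "DCIS")
  if (any(in_ibc)) p[in_ibc] <- sensitivity_at(sens, yr[in_ibc], "IBC")
  hit <- which(u < p & (in_dcis | in_ibc))
  if (length(hit) == 0) return(history)
  k <- hit[1]
  det_age <- screens[k]
  det_state <- if (in_dcis[k]) "screen_detected_dcis" else
    "screen_detected_ibc"
  ev <- history$events
  ev <- ev[ev$age <= det_age & ev$state != "death_other", , drop = FALSE]
  ev <- rbind(ev, data.frame(state = det_state, age = det_age),
              data.frame(state = "death_other",
                         age = history$other_cause_death_age))
  new_life_history(history$woman_id, history$birth_year,
                   history$other_cause_death_age, ev)
}
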