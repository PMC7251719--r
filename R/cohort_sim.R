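# Parallel-universe population engine. Every woman is simulated twice —
# unscreened and screened — from the same keyed random substreams: stream 1
# carries all natural-history draws, stream 2 carries screening attendance
# and detection, so the two universes share the disease trajectory exactly
# up to the first screen detection, and results do not depend on simulation
# order or batch size.

#' Population specification
#'
#' @param config [submodel_config()] object
#' @param params [nh_params()] object
#' @param n_women number of women to simulate
#' @param cohorts birth cohorts (default 1890-1996)
#' @param cohort_weights relative cohort sizes (default equal); need not sum
#'   to 1
#' @param seed master seed (integer below 2^31)
#' @param sens [sensitivity_schedule()] object
#' @param dissem [dissemination_schedule()] object
#' @param life_table data.frame with columns `birth_year`, `age`,
#'   `annual_death_prob` (see [make_life_table()])
#' @return object of class `population_spec`
#' @export
population_spec <- function(config, params, n_women, cohorts = 1890:1996,
                            cohort_weights = NULL, seed = 1L,
                            sens = sensitivity_schedule(),
                            dissem = NULL, life_table = NULL) {
  stopifnot(n_women >= 1)
  if (is.null(dissem)) dissem <- make_dissemination()
  if (is.null(life_table)) life_table <- make_life_table()
  validate_life_table(life_table)
  if (is.null(cohort_weights)) cohort_weights <- rep(1, length(cohorts))
  stopifnot(length(cohort_weights) == length(cohorts),
            all(cohort_weights >= 0), sum(cohort_weights) > 0)
  validate_nh_params(params)
  check_config_params(config, params)
  structure(list(config = config, params = params,
                 n_women = as.integer(n_women), cohorts = cohorts,
                 cohort_weights = cohort_weights, seed = seed, sens = sens,
                 dissem = dissem, life_table = life_table),
            class = "population_spec")
}

#' Validate a life table
#'
#' @param lt data.frame with columns `birth_year`, `age`,
#'   `annual_death_prob`
#' @return `TRUE` invisibly
#' @export
validate_life_table <- function(lt) {
  stopifnot(all(c("birth_year", "age", "annual_death_prob") %in% names(lt)))
  q <- lt$annual_death_prob
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stop("life-table death probabilities must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

# inverse-CDF death ages with uniform within-year interpolation; one survival
# curve per cohort, nearest cohort used when absent from the table
sample_death_ages_ <- function(life_table, birth_year, u) {
  out <- numeric(length(birth_year))
  bys <- sort(unique(life_table$birth_year))
  for (by in unique(birth_year)) {
    idx <- which(birth_year == by)
    src <- if (by %in% bys) by else bys[which.min(abs(bys - by))]
    sub <- life_table[life_table$birth_year == src, ]
    sub <- sub[order(sub$age), ]
    q <- pmin(sub$annual_death_prob, 1)
    FF <- c(0, 1 - cumprod(1 - q))
    FF[length(FF)] <- 1                       # close the distribution
    k <- findInterval(u[idx], FF, rightmost.closed = TRUE)
    k <- pmin(pmax(k, 1), length(q))
    num <- u[idx] - FF[k]
    den <- FF[k + 1] - FF[k]
    out[idx] <- sub$age[k] + ifelse(den > 0, num / den, 0.5)
  }
  out
}

#' Simulate a paired (screened / unscreened) population
#'
#' For every woman: draws her birth cohort, other-cause death age and the
#' complete unscreened disease trajectory from her natural-history
#' substream; draws a mammography schedule from the dissemination pattern
#' and applies screen detection from her screening substream; returns both
#' universes as one long event log.
#'
#' @param spec [population_spec()] object
#' @param ids optional integer ids to simulate (default `1:n_women`);
#'   per-woman results depend only on `(seed, id)`
#' @return a `paired_event_log`: data.table with columns `woman_id`,
#'   `universe` (`"unscreened"` / `"screened"`), `birth_year`, `state`,
#'   `age`, `calendar_year`
#' @examples
#' spec <- population_spec(submodel_config("2a"),
#'                         default_nh_params(submodel_config("2a")),
#'                         n_women = 500, seed = 7)
#' log <- simulate_population(spec)
#' @export
simulate_population <- function(spec, ids = NULL) {
  if (is.null(ids)) ids <- seq_len(spec$n_women)
  ids <- as.integer(ids)
  n <- length(ids)
  seed <- spec$seed
  # cohort draw (counter 8, natural-history stream)
  w <- spec$cohort_weights / sum(spec$cohort_weights)
  ucoh <- stream_uniform(seed, ids, 1L, 8)
  by <- spec$cohorts[findInterval(ucoh, cumsum(w), rightmost.closed = TRUE) +
                       1]
  by <- pmin(by, max(spec$cohorts))
  udeath <- stream_uniform(seed, ids, 1L, .CTR$death)
  death <- sample_death_ages_(spec$life_table, by, udeath)
  ctrs <- c(.CTR$onset, .CTR$dest, .CTR$udwell, .CTR$path, .CTR$pdwell,
            .CTR$ibcdwell)
  U <- matrix(0, n, length(ctrs))
  for (j in seq_along(ctrs)) U[, j] <- stream_uniform(seed, ids, 1L, ctrs[j])
  fields <- lesion_fields_(spec$config, spec$params, by, death, U)
  unscr <- lesion_events_(fields, ids)
  scr <- screened_events_(spec, ids, by, death, fields, unscr)
  unscr[, universe := "unscreened"]
  scr[, universe := "screened"]
  log <- data.table::rbindlist(list(unscr, scr), use.names = TRUE)
  bmap <- data.table::data.table(woman_id = ids, birth_year = by)
  log <- bmap[log, on = "woman_id"]
  log[, calendar_year := as.integer(floor(birth_year + age))]
  data.table::setcolorder(log, c("woman_id", "universe", "birth_year",
                                 "state", "age", "calendar_year"))
  data.table::setorder(log, woman_id, universe, age)
  data.table::setattr(log, "class",
                      c("paired_event_log", class(log)))
  data.table::setattr(log, "spec", spec)
  log[]
}

# screening attendance + detection for all women, vectorized over calendar
# years; mirrors generate_screen_schedule()/superimpose_screening() exactly
screened_events_ <- function(spec, ids, by, death, fields, unscr) {
  dis <- spec$dissem
  n <- length(ids)
  cohorts <- sort(unique(by))
  lk <- lapply(cohorts, function(b) dissem_lookup_(dis, b))
  names(lk) <- as.character(cohorts)
  ci <- match(by, cohorts)
  y_first <- pmax(1975, by + dis$age_start)
  y_last <- pmin(by + dis$age_stop, by + ceiling(death))
  start_year <- rep(NA_integer_, n)
  yr_range <- seq(min(y_first), max(y_last))
  for (y in yr_range) {
    open <- which(is.na(start_year) & y >= y_first & y <= y_last)
    if (length(open) == 0) next
    pc <- vapply(lk, function(l) step_at_(y, l$year, l$p), numeric(1))
    pp <- vapply(lk, function(l) step_at_(y - 1, l$year, l$p), numeric(1))
    cond <- ifelse(pp < 1, (pc - pp) / (1 - pp), 0)
    cond <- pmin(pmax(cond, 0), 1)[ci[open]]
    first <- y == y_first[open]  # first eligible year gets cumulative uptake
    cond[first] <- pmin(pc[ci[open]][first], 1)
    u <- stream_uniform(spec$seed, ids[open], 2L, y + .CTR$start_base)
    start_year[open[u < cond]] <- y
  }
  det <- detect_first_(spec, ids, by, death, fields, start_year, lk, ci)
  # assemble: undetected women keep the unscreened log; detected women are
  # truncated at detection with the absorbing screen_detected_* event
  if (nrow(det) == 0) return(data.table::copy(unscr))
  out <- merge(unscr, det, by = "woman_id", all.x = TRUE)
  keep <- is.na(out$det_age) |
    (out$age <= out$det_age & out$state != "death_other")
  out <- out[keep]
  i <- match(det$woman_id, ids)
  extra <- data.table::data.table(
    woman_id = c(det$woman_id, det$woman_id),
    state = c(det$det_state, rep("death_other", nrow(det))),
    age = c(det$det_age, death[i]))
  out <- data.table::rbindlist(list(out[, list(woman_id, state, age)],
                                    extra), use.names = TRUE)
  data.table::setorder(out, woman_id, age)
  out[]
}

detect_first_ <- function(spec, ids, by, death, fields, start_year, lk, ci) {
  started <- which(!is.na(start_year))
  empty <- data.table::data.table(woman_id = integer(0),
                                  det_age = numeric(0),
                                  det_state = character(0))
  if (length(started) == 0) return(empty)
  dis <- spec$dissem
  interval <- vapply(seq_along(started), function(j) {
    l <- lk[[ci[started[j]]]]
    step_at_(start_year[started[j]], l$year, l$interval, left = 2)
  }, numeric(1))
  a0 <- start_year[started] - by[started] + 0.5
  kmax <- pmax(floor((dis$age_stop + 0.5 - a0) / interval) + 1, 0)
  long <- data.table::data.table(
    i = rep(started, kmax),
    k = unlist(lapply(kmax, seq_len)),
    a0 = rep(a0, kmax), interval = rep(interval, kmax))
  if (nrow(long) == 0) return(empty)
  long[, age := a0 + (k - 1) * interval]
  long <- long[age < death[i] & by[i] + age >= 1975]
  if (nrow(long) == 0) return(empty)
  yr <- floor(by[long$i] + long$age)
  in_dcis <- !is.na(fields$sd_entry[long$i]) &
    fields$sd_entry[long$i] <= long$age &
    (is.na(fields$sd_exit[long$i]) | long$age < fields$sd_exit[long$i])
  in_ibc <- !is.na(fields$ibc_entry[long$i]) &
    fields$ibc_entry[long$i] <= long$age & long$age < fields$ibc_clin[long$i]
  p <- numeric(nrow(long))
  if (any(in_dcis)) p[in_dcis] <- sensitivity_at(spec$sens, yr[in_dcis],
                                                 "DCIS")
  if (any(in_ibc)) p[in_ibc] <- sensitivity_at(spec$sens, yr[in_ibc], "IBC")
  u <- stream_uniform(spec$seed, ids[long$i], 2L, .CTR$detect_base + long$k)
  hit <- which(u < p & (in_dcis | in_ibc))
  if (length(hit) == 0) return(empty)
  det <- data.table::data.table(
    woman_id = ids[long$i[hit]], det_age = long$age[hit],
    det_state = ifelse(in_dcis[hit], "screen_detected_dcis",
                       "screen_detected_ibc"))
  data.table::setorder(det, woman_id, det_age)
  det[, head(.SD, 1L), by = woman_id]
}

#' Extract one woman's trajectory from a paired event log
#'
#' @param log a `paired_event_log`
#' @param woman_id woman identifier
#' @param universe `"unscreened"` or `"screened"`
#' @return a `life_history`
#' @export
as_life_history <- function(log, woman_id,
                            universe = c("unscreened", "screened")) {
  uni <- match.arg(universe)
  wid <- woman_id
  df <- as.data.frame(log)
  sub <- df[df$woman_id == wid & df$universe == uni, ]
  if (nrow(sub) == 0) stop("woman_id not present in log", call. = FALSE)
  death <- sub$age[sub$state == "death_other"]
  new_life_history(wid, sub$birth_year[1], death,
                   data.frame(state = sub$state, age = sub$age))
}

#' @export
print.paired_event_log <- function(x, ...) {
  nw <- length(unique(x$woman_id))
  cat(sprintf("paired_event_log: %d women, %d events\n", nw, nrow(x)))
  NextMethod()
}
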