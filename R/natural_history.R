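# Multi-state natural history of DCIS:
#   no_bc -> dcis_undetectable -> {dcis_screen_detectable, ibc_preclinical,
#   indolent} ; dcis_screen_detectable -> {ibc_preclinical (P1),
#   clinical_dcis (P2), regressed (P3)} ; ibc_preclinical -> ibc_clinical.
# All events are truncated at other-cause death. At most one lesion per woman.

#' Disease states of the natural-history model
#' @return character vector of state labels
#' @export
dcis_states <- function() {
  c("no_bc", "dcis_undetectable", "dcis_screen_detectable", "clinical_dcis",
    "ibc_preclinical", "ibc_clinical", "regressed", "screen_detected_dcis",
    "screen_detected_ibc", "death_other")
}

#' Allowed state transitions
#'
#' Edges of the natural-history graph plus the two screen-detection absorbing
#' states; every consecutive event pair in a simulated trajectory must be one
#' of these edges.
#' @return data.frame with columns `from`, `to`
#' @export
allowed_transitions <- function() {
  rbind(
    data.frame(from = "no_bc",
               to = c("dcis_undetectable", "death_other")),
    data.frame(from = "dcis_undetectable",
               to = c("dcis_screen_detectable", "ibc_preclinical",
                      "regressed", "death_other")),
    data.frame(from = "dcis_screen_detectable",
               to = c("ibc_preclinical", "clinical_dcis", "regressed",
                      "screen_detected_dcis", "death_other")),
    data.frame(from = "ibc_preclinical",
               to = c("ibc_clinical", "screen_detected_ibc", "death_other")),
    data.frame(from = c("clinical_dcis", "ibc_clinical", "regressed",
                        "screen_detected_dcis", "screen_detected_ibc"),
               to = "death_other")
  )
}

#' Submodel configuration
#'
#' One of the six natural-history submodels: the proportion of preclinical
#' undetectable DCIS that progresses to the preclinical screen-detectable
#' state is 30% (submodel 1), 50% (submodel 2) or 80% (submodel 3); the `a`
#' variants prohibit DCIS regression and the `b` variants allow it.
#'
#' @param submodel one of `"1a","1b","2a","2b","3a","3b"`, or `NULL` to give
#'   `frac_to_screen_detectable` and `regression_allowed` directly
#' @param frac_to_screen_detectable proportion in `[0, 1]`; overrides the
#'   submodel default (arbitrary values are allowed for synthetic studies)
#' @param regression_allowed logical; overrides the submodel suffix
#' @return object of class `submodel_config`
#' @examples
#' submodel_config("2b")
#' @export
submodel_config <- function(submodel = NULL, frac_to_screen_detectable = NULL,
                            regression_allowed = NULL) {
  fracs <- c("1" = 0.30, "2" = 0.50, "3" = 0.80)
  if (!is.null(submodel)) {
    submodel <- match.arg(submodel, c("1a", "1b", "2a", "2b", "3a", "3b"))
    if (is.null(frac_to_screen_detectable))
      frac_to_screen_detectable <- unname(fracs[substr(submodel, 1, 1)])
    if (is.null(regression_allowed))
      regression_allowed <- substr(submodel, 2, 2) == "b"
  } else {
    if (is.null(frac_to_screen_detectable) || is.null(regression_allowed))
      stop("give `submodel` or both `frac_to_screen_detectable` and ",
           "`regression_allowed`", call. = FALSE)
    submodel <- NA_character_
  }
  stopifnot(is.numeric(frac_to_screen_detectable),
            frac_to_screen_detectable >= 0, frac_to_screen_detectable <= 1,
            is.logical(regression_allowed), length(regression_allowed) == 1L)
  structure(list(submodel_id = submodel,
                 frac_to_screen_detectable = frac_to_screen_detectable,
                 regression_allowed = regression_allowed),
            class = "submodel_config")
}

#' @export
print.submodel_config <- function(x, ...) {
  cat("DCIS submodel", x$submodel_id, "-",
      sprintf("%.0f%%", 100 * x$frac_to_screen_detectable),
      "undetectable -> screen-detectable; regression",
      if (x$regression_allowed) "allowed" else "prohibited", "\n")
  invisible(x)
}

#' Natural-history parameters
#'
#' All rates, probabilities and mean sojourn times governing state
#' transitions. Onset of preclinical undetectable DCIS follows a
#' piecewise-constant age hazard multiplied by a log-linear birth-cohort
#' trend. Dwell times are path-conditional exponentials: the exit path is
#' drawn first, then an exponential dwell with that path's mean, so different
#' exit paths can carry different mean sojourn times (MSTs) within one
#' submodel.
#'
#' @param onset_breaks increasing age-band lower edges starting at 0; the
#'   last band extends to infinity
#' @param onset_rates per-band onset hazards (per woman-year), one per break
#' @param cohort_slope log-linear birth-cohort trend on the onset hazard
#' @param cohort_ref reference birth year of the cohort trend
#' @param undetectable_mean_dwell mean years in the undetectable state before
#'   its fate resolves
#' @param undetectable_direct_to_ibc_frac of lesions that do not become
#'   screen-detectable, the fraction that evolves directly to preclinical
#'   invasive breast cancer (IBC); the remainder is indolent and never leaves
#'   the undetectable state
#' @param undetectable_regression_frac optional fraction of the
#'   non-screen-detectable remainder that regresses directly from the
#'   undetectable state (one micro-simulation lineage allows this; the state
#'   diagram's regression arrow leaves the screen-detectable state, so the
#'   default is 0)
#' @param p1,p2,p3 exit-path probabilities from the screen-detectable state
#'   to preclinical IBC (P1), clinical DCIS (P2) and regression (P3); must
#'   sum to 1
#' @param mst1,mst2,mst3 path-specific mean sojourn times (years) in the
#'   screen-detectable state; `mst3` may be `NA` when `p3 = 0`
#' @param ibc_preclinical_mean_dwell mean years from preclinical to clinical
#'   IBC
#' @return object of class `nh_params`
#' @examples
#' p <- nh_params(p1 = 0.8, p2 = 0.2, p3 = 0, mst1 = 2.5, mst2 = 2.5)
#' @export
nh_params <- function(onset_breaks = seq(0, 100, by = 5),
                      onset_rates = NULL,
                      cohort_slope = 0, cohort_ref = 1930,
                      undetectable_mean_dwell = 2,
                      undetectable_direct_to_ibc_frac = 0.5,
                      undetectable_regression_frac = 0,
                      p1, p2, p3,
                      mst1, mst2, mst3 = NA_real_,
                      ibc_preclinical_mean_dwell = 2.5) {
  if (is.null(onset_rates))
    onset_rates <- default_onset_rates(onset_breaks)
  p <- structure(list(
    onset_breaks = as.numeric(onset_breaks),
    onset_rates = as.numeric(onset_rates),
    cohort_slope = cohort_slope, cohort_ref = cohort_ref,
    undetectable_mean_dwell = undetectable_mean_dwell,
    undetectable_direct_to_ibc_frac = undetectable_direct_to_ibc_frac,
    undetectable_regression_frac = undetectable_regression_frac,
    p1 = p1, p2 = p2, p3 = p3,
    mst1 = mst1, mst2 = mst2, mst3 = mst3,
    ibc_preclinical_mean_dwell = ibc_preclinical_mean_dwell
  ), class = "nh_params")
  validate_nh_params(p)
  p
}

# synthetic default: hazard rising with age from 30, scaled to give
# population DCIS/IBC incidence on the observed per-100,000 order
default_onset_rates <- function(breaks) {
  f <- stats::approxfun(
    x = c(0, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 110),
    y = c(0, 0, 0.0002, 0.0005, 0.001, 0.0015, 0.002, 0.0025,
          0.003, 0.0032, 0.0034, 0.0035, 0.0035),
    method = "constant", rule = 2)
  f(breaks)
}

validate_nh_params <- function(p) {
  stopifnot(length(p$onset_rates) == length(p$onset_breaks),
            !is.unsorted(p$onset_breaks, strictly = TRUE),
            p$onset_breaks[1] >= 0)
  if (any(p$onset_rates < 0))
    stop("onset hazard values must be nonnegative", call. = FALSE)
  probs <- c(p$p1, p$p2, p$p3)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12)
    stop("p1 + p2 + p3 must equal 1 (within 1e-12) with all terms >= 0",
         call. = FALSE)
  if (p$undetectable_mean_dwell <= 0 || p$ibc_preclinical_mean_dwell <= 0)
    stop("mean dwell times must be > 0", call. = FALSE)
  if (p$undetectable_direct_to_ibc_frac < 0 ||
      p$undetectable_direct_to_ibc_frac > 1)
    stop("undetectable_direct_to_ibc_frac must lie in [0, 1]", call. = FALSE)
  r <- p$undetectable_regression_frac %||% 0
  if (r < 0 || r > 1)
    stop("undetectable_regression_frac must lie in [0, 1]", call. = FALSE)
  msts <- c(p$mst1, p$mst2, p$mst3)
  used <- probs > 0
  if (any(is.na(msts[used])) || any(msts[used] <= 0))
    stop("mean sojourn times must be > 0 on every path with positive ",
         "probability", call. = FALSE)
  invisible(p)
}

check_config_params <- function(config, params) {
  if (!config$regression_allowed && params$p3 != 0)
    stop("config conflict: p3 > 0 but the submodel prohibits regression",
         call. = FALSE)
  if (!config$regression_allowed &&
      (params$undetectable_regression_frac %||% 0) != 0)
    stop("config conflict: undetectable_regression_frac > 0 but the ",
         "submodel prohibits regression", call. = FALSE)
  invisible(TRUE)
}

#' Onset hazard evaluator
#'
#' @param params [nh_params()] object
#' @return function `(age, birth_year)` giving the onset hazard per woman-year
#' @export
onset_hazard <- function(params) {
  function(age, birth_year) {
    band <- findInterval(age, params$onset_breaks)
    r <- ifelse(band >= 1, params$onset_rates[pmax(band, 1)], 0)
    r * exp(params$cohort_slope * (birth_year - params$cohort_ref))
  }
}

# invert the cumulative onset hazard: age at which H(age) = e, NA if never
invert_onset_ <- function(params, birth_year, e) {
  m <- exp(params$cohort_slope * (birth_year - params$cohort_ref))
  b <- params$onset_breaks
  r <- params$onset_rates
  nb <- length(b)
  cumh <- c(0, cumsum(r[-nb] * diff(b)))       # base cumulative hazard at b
  e0 <- e / m                                  # cohort-standardized target
  j <- findInterval(e0, cumh)                  # duplicate edges skip 0-bands
  age <- rep(NA_real_, length(e0))
  ok <- j >= 1 & r[j] > 0
  age[ok] <- b[j[ok]] + (e0[ok] - cumh[j[ok]]) / r[j[ok]]
  # finite-band overflow with a zero tail never inverts; tail band handles
  # itself since its cumulative hazard is unbounded when r[nb] > 0
  age
}

#' Sample the age at onset of preclinical undetectable DCIS
#'
#' Draws from the piecewise-constant-by-age, cohort-trended onset hazard by
#' exponential inversion, truncated at the other-cause death age.
#'
#' @param params [nh_params()] object
#' @param birth_year birth cohort (scalar or length-`n`)
#' @param death_age other-cause death age (scalar or length-`n`)
#' @param n number of draws
#' @param u optional uniforms (for keyed streams); drawn from the session RNG
#'   when `NULL`
#' @return numeric vector of onset ages; `NA` where no onset occurs before
#'   death
#' @export
sample_onset_age <- function(params, birth_year, death_age, n = 1L,
                             u = NULL) {
  validate_nh_params(params)
  if (is.null(u)) u <- runif(n) else n <- length(u)
  e <- -log(u)
  age <- invert_onset_(params, rep_len(birth_year, n), e)
  age[!is.na(age) & age >= rep_len(death_age, n)] <- NA_real_
  age
}

#' Sample the fate of a preclinical undetectable DCIS lesion
#'
#' With probability `frac_to_screen_detectable` the lesion becomes
#' screen-detectable; the remainder splits between direct evolution to
#' preclinical IBC and an indolent lesion that never leaves the state. The
#' dwell time is exponential with mean `undetectable_mean_dwell`; indolent
#' lesions get an infinite dwell.
#'
#' @inheritParams sample_onset_age
#' @param config [submodel_config()] object
#' @param u optional 2-column matrix of uniforms (destination, dwell)
#' @return data.frame with columns `destination` (factor:
#'   `screen_detectable`, `ibc_direct`, `indolent`) and `dwell` (years)
#' @export
sample_undetectable_fate <- function(config, params, n = 1L, u = NULL) {
  validate_nh_params(params)
  if (is.null(u)) u <- cbind(runif(n), runif(n)) else n <- nrow(u)
  f <- config$frac_to_screen_detectable
  d <- params$undetectable_direct_to_ibc_frac
  r <- params$undetectable_regression_frac %||% 0
  m <- 1 - f
  # threshold order keeps draws comparable across configs (common random
  # numbers): screen-detectable, regression (optional), direct IBC, indolent
  dest <- ifelse(u[, 1] < f, "screen_detectable",
          ifelse(u[, 1] < f + m * r, "regressed",
          ifelse(u[, 1] < f + m * r + m * (1 - r) * d, "ibc_direct",
                 "indolent")))
  dwell <- -params$undetectable_mean_dwell * log(u[, 2])
  dwell[dest == "indolent"] <- Inf
  data.frame(destination = factor(dest, levels = c("screen_detectable",
                                                   "ibc_direct", "regressed",
                                                   "indolent")),
             dwell = dwell)
}

#' Sample the exit path and sojourn of screen-detectable DCIS
#'
#' The exit path is multinomial over (P1 = preclinical IBC, P2 = clinical
#' DCIS, P3 = regression); the sojourn is exponential with the path-specific
#' mean (`mst1`, `mst2`, `mst3`). Drawing the path first lets different paths
#' carry different mean sojourn times.
#'
#' @inheritParams sample_undetectable_fate
#' @return data.frame with columns `path` (factor P1/P2/P3) and `dwell`
#'   (years, > 0)
#' @export
sample_screen_detectable_fate <- function(config, params, n = 1L, u = NULL) {
  validate_nh_params(params)
  check_config_params(config, params)
  if (is.null(u)) u <- cbind(runif(n), runif(n)) else n <- nrow(u)
  path <- ifelse(u[, 1] < params$p1, "P1",
                 ifelse(u[, 1] < params$p1 + params$p2, "P2", "P3"))
  mst <- c(P1 = params$mst1, P2 = params$mst2, P3 = params$mst3)
  dwell <- -mst[path] * log(u[, 2])
  data.frame(path = factor(path, levels = c("P1", "P2", "P3")),
             dwell = unname(dwell))
}

# latent per-woman lesion quantities from a fixed 6-column uniform layout
# (onset, destination, undetectable dwell, exit path, path dwell, IBC dwell);
# the fixed layout is what keeps draws shared across counterfactual universes
lesion_fields_ <- function(config, params, birth_year, death_age, U) {
  n <- nrow(U)
  onset <- invert_onset_(params, birth_year, -log(U[, 1]))
  onset[!is.na(onset) & onset >= death_age] <- NA_real_
  fate <- sample_undetectable_fate(config, params, u = U[, c(2, 3), drop = FALSE])
  sdf <- sample_screen_detectable_fate(config, params, u = U[, c(4, 5), drop = FALSE])
  dest <- as.character(fate$destination)
  dest[is.na(onset)] <- NA_character_
  sd_entry <- ifelse(dest == "screen_detectable", onset + fate$dwell,
                     NA_real_)
  path <- ifelse(dest == "screen_detectable", as.character(sdf$path),
                 NA_character_)
  sd_exit <- sd_entry + sdf$dwell
  ibc_entry <- ifelse(!is.na(dest) & dest == "ibc_direct",
                      onset + fate$dwell,
                      ifelse(!is.na(path) & path == "P1", sd_exit, NA_real_))
  ibc_clin <- ibc_entry -
    params$ibc_preclinical_mean_dwell * log(U[, 6])
  reg_age <- ifelse(!is.na(dest) & dest == "regressed", onset + fate$dwell,
                    NA_real_)
  data.table::data.table(
    birth_year = rep_len(birth_year, n), death_age = rep_len(death_age, n),
    onset = onset, dest = dest, sd_entry = sd_entry, path = path,
    sd_exit = sd_exit, ibc_entry = ibc_entry, ibc_clin = ibc_clin,
    reg_age = reg_age)
}

# long event table (woman_id, state, age) from latent fields, truncated at
# other-cause death; chain order is the tie-break (progression before death)
lesion_events_ <- function(fields, woman_id) {
  n <- nrow(fields)
  ev <- function(state, age) {
    keep <- !is.na(age) & age < fields$death_age
    data.table::data.table(woman_id = woman_id[keep], state = state,
                           age = age[keep],
                           ord = rep(match(state, dcis_states()), sum(keep)))
  }
  exit_state <- ifelse(fields$path == "P1", "ibc_preclinical",
                       ifelse(fields$path == "P2", "clinical_dcis",
                              "regressed"))
  parts <- list(
    ev("dcis_undetectable", fields$onset),
    ev("dcis_screen_detectable", fields$sd_entry),
    # screen-detectable exit: path-specific state
    {
      keep <- !is.na(fields$sd_exit) & fields$sd_exit < fields$death_age &
        !is.na(exit_state)
      data.table::data.table(woman_id = woman_id[keep],
                             state = exit_state[keep],
                             age = fields$sd_exit[keep],
                             ord = match(exit_state[keep], dcis_states()))
    },
    # direct-to-IBC entry (P1 entry already emitted above)
    {
      keep <- !is.na(fields$dest) & fields$dest == "ibc_direct" &
        !is.na(fields$ibc_entry) & fields$ibc_entry < fields$death_age
      data.table::data.table(woman_id = woman_id[keep],
                             state = "ibc_preclinical",
                             age = fields$ibc_entry[keep],
                             ord = match("ibc_preclinical", dcis_states()))
    },
    # optional direct regression from the undetectable state
    {
      keep <- !is.na(fields$reg_age) & fields$reg_age < fields$death_age
      data.table::data.table(woman_id = woman_id[keep],
                             state = "regressed",
                             age = fields$reg_age[keep],
                             ord = match("regressed", dcis_states()))
    },
    ev("ibc_clinical", fields$ibc_clin),
    data.table::data.table(woman_id = woman_id, state = "death_other",
                           age = fields$death_age,
                           ord = match("death_other", dcis_states()))
  )
  out <- data.table::rbindlist(parts)
  data.table::setorder(out, woman_id, age, ord)
  out[, ord := NULL]
  out[]
}

#' Simulate one woman's unscreened disease trajectory
#'
#' Chains onset, undetectable fate, screen-detectable fate and (on the P1 or
#' direct-to-IBC routes) the preclinical IBC dwell, truncating everything at
#' the other-cause death age.
#'
#' @inheritParams sample_undetectable_fate
#' @param birth_year birth cohort of the woman
#' @param death_age other-cause death age (years)
#' @param woman_id integer identifier stored in the trajectory
#' @return a `life_history` object
#' @examples
#' cfg <- submodel_config("1a")
#' p <- default_nh_params(cfg)
#' set.seed(1)
#' simulate_lesion(cfg, p, birth_year = 1950, death_age = 85)
#' @export
simulate_lesion <- function(config, params, birth_year, death_age,
                            woman_id = 1L) {
  validate_nh_params(params)
  check_config_params(config, params)
  U <- matrix(runif(6), nrow = 1)
  f <- lesion_fields_(config, params, birth_year, death_age, U)
  ev <- lesion_events_(f, woman_id)
  new_life_history(woman_id, birth_year, death_age,
                   as.data.frame(ev[, list(state, age)]))
}

new_life_history <- function(woman_id, birth_year, death_age, events) {
  structure(list(woman_id = as.integer(woman_id), birth_year = birth_year,
                 other_cause_death_age = death_age, events = events),
            class = "life_history")
}

#' @export
print.life_history <- function(x, ...) {
  cat(sprintf("life_history: woman %d, born %s, other-cause death at %.1f\n",
              x$woman_id, format(x$birth_year), x$other_cause_death_age))
  print(x$events, row.names = FALSE)
  invisible(x)
}

#' Check a trajectory against the transition graph
#'
#' @param history a `life_history`
#' @return `TRUE` invisibly; errors describe the first violation
#' @export
validate_life_history <- function(history) {
  ev <- history$events
  if (nrow(ev) == 0) stop("empty event list", call. = FALSE)
  if (is.unsorted(ev$age))
    stop("event ages must be non-decreasing", call. = FALSE)
  if (any(ev$age > history$other_cause_death_age + 1e-9))
    stop("event after other-cause death", call. = FALSE)
  edges <- allowed_transitions()
  chain <- c("no_bc", ev$state)
  pairs <- paste(chain[-length(chain)], chain[-1])
  bad <- !(pairs %in% paste(edges$from, edges$to))
  if (any(bad))
    stop("disallowed transition: ", pairs[which(bad)[1]], call. = FALSE)
  invisible(TRUE)
}

#' Default natural-history parameters for a submodel
#'
#' Mean sojourn times follow the analytic model's published inputs per
#' submodel (P1-path MST 2.5/0.7/0.4 years for submodels 1a/2a/3a,
#' 1.5/0.5/0.2 for 1b/2b/3b; P2-path MST 2.5 or 1.9 years; regression MST
#' 1.5 years in all b-submodels). Exit-path probabilities default to
#' (0.8, 0.2, 0) without regression and (0.5, 0.2, 0.3) with regression,
#' inside the ranges the model family reports.
#'
#' @param config [submodel_config()] object
#' @param ... overrides passed to [nh_params()]
#' @return an `nh_params` object
#' @export
default_nh_params <- function(config, ...) {
  id <- config$submodel_id
  msts <- list(
    "1a" = c(2.5, 2.5, NA), "1b" = c(1.5, 1.5, 1.5),
    "2a" = c(0.7, 1.9, NA), "2b" = c(0.5, 1.9, 1.5),
    "3a" = c(0.4, 1.9, NA), "3b" = c(0.2, 1.9, 1.5))
  m <- if (!is.na(id) && id %in% names(msts)) msts[[id]] else c(1.5, 1.9, 1.5)
  if (config$regression_allowed) {
    pp <- c(0.5, 0.2, 0.3)
  } else {
    pp <- c(0.8, 0.2, 0)
    m[3] <- NA
  }
  defaults <- list(p1 = pp[1], p2 = pp[2], p3 = pp[3],
                   mst1 = m[1], mst2 = m[2], mst3 = m[3])
  do.call(nh_params, utils::modifyList(defaults, list(...)))
}
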