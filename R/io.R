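# Plain-text interfaces: life-table / dissemination / observed-incidence
# CSVs, a JSON model config, event-log export with a run manifest, and a
# scenario bundle writer.

#' Read / write a life table CSV
#'
#' Columns: `birth_year`, `age`, `annual_death_prob`.
#' @param path file path
#' @return data.frame (reader) or `path` invisibly (writer)
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  validate_life_table(lt)
  lt
}

#' @rdname read_life_table
#' @param lt life table data.frame
#' @export
write_life_table <- function(lt, path) {
  validate_life_table(lt)
  utils::write.csv(lt, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a dissemination CSV
#'
#' Columns: `calendar_year`, `start_probability`, `interval_years`, and
#' optionally `birth_year`.
#' @param path file path
#' @param age_start,age_stop screening eligibility ages
#' @return a [dissemination_schedule()] (reader) or `path` (writer)
#' @export
read_dissemination <- function(path, age_start = 40, age_stop = 74) {
  dissemination_schedule(utils::read.csv(path), age_start, age_stop)
}

#' @rdname read_dissemination
#' @param dissem [dissemination_schedule()] object
#' @export
write_dissemination <- function(dissem, path) {
  utils::write.csv(dissem$table, path, row.names = FALSE)
  invisible(path)
}

#' Read / write an observed-incidence CSV
#'
#' Columns: `year`, `age_group`, `diagnosis`, `rate_per_100k`.
#' @param path file path
#' @return data.frame (reader) or `path` (writer)
#' @export
read_observed_incidence <- function(path) {
  x <- utils::read.csv(path)
  stopifnot(all(c("year", "age_group", "diagnosis", "rate_per_100k")
                %in% names(x)))
  x
}

#' @rdname read_observed_incidence
#' @param x observed-incidence data.frame
#' @export
write_observed_incidence <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a model configuration (JSON)
#'
#' Bundles the submodel id, exit-path probabilities, mean sojourn times,
#' onset-hazard bands, cohort trend, and the sensitivity schedule.
#'
#' @param path file path
#' @return list with elements `config` ([submodel_config()]), `params`
#'   ([nh_params()]) and `sens` ([sensitivity_schedule()])
#' @export
read_model_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- submodel_config(
    submodel = j$submodel,
    frac_to_screen_detectable = j$frac_to_screen_detectable,
    regression_allowed = j$regression_allowed)
  pj <- j$params
  params <- nh_params(
    onset_breaks = pj$onset_breaks, onset_rates = pj$onset_rates,
    cohort_slope = pj$cohort_slope %||% 0,
    cohort_ref = pj$cohort_ref %||% 1930,
    undetectable_mean_dwell = pj$undetectable_mean_dwell,
    undetectable_direct_to_ibc_frac = pj$undetectable_direct_to_ibc_frac,
    p1 = pj$p1, p2 = pj$p2, p3 = pj$p3,
    mst1 = pj$mst1, mst2 = pj$mst2,
    mst3 = pj$mst3 %||% NA_real_,
    ibc_preclinical_mean_dwell = pj$ibc_preclinical_mean_dwell)
  sens <- if (is.null(j$sensitivity)) sensitivity_schedule() else
    sensitivity_schedule(as.data.frame(j$sensitivity))
  list(config = config, params = params, sens = sens)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_model_config
#' @param config [submodel_config()] object
#' @param params [nh_params()] object
#' @param sens [sensitivity_schedule()] object
#' @export
write_model_config <- function(config, params, sens = sensitivity_schedule(),
                               path) {
  j <- list(
    submodel = if (is.na(config$submodel_id)) NULL else config$submodel_id,
    frac_to_screen_detectable = config$frac_to_screen_detectable,
    regression_allowed = config$regression_allowed,
    params = params[names(params)],
    sensitivity = sens$periods)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a paired event log and run manifest
#'
#' Writes `events.csv` (woman_id, universe, birth_year, state, age,
#' calendar_year) and `manifest.json` (seed, size, submodel, parameter
#' values) to a directory.
#'
#' @param log a `paired_event_log`
#' @param dir output directory (created if missing)
#' @return `dir` invisibly
#' @export
write_event_log <- function(log, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(log),
                     file.path(dir, "events.csv"))
  spec <- attr(log, "spec")
  manifest <- list(n_women = length(unique(log$woman_id)),
                   n_events = nrow(log))
  if (!is.null(spec)) {
    manifest$seed <- spec$seed
    manifest$submodel <- spec$config$submodel_id
    manifest$params <- spec$params[names(spec$params)]
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a scenario bundle
#'
#' Writes the four pipeline inputs generated from a synthetic scenario —
#' life table, dissemination table, observed incidence, model config — plus
#' a `manifest.json` listing every true parameter value.
#'
#' @param scenario [synthetic_scenario()] object
#' @param dir output directory
#' @param n_sim women simulated for the observed-incidence stand-in
#' @return `dir` invisibly
#' @export
write_scenario <- function(scenario, dir, n_sim = 50000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_life_table(scenario$life_table, file.path(dir, "life_table.csv"))
  write_dissemination(scenario$dissem, file.path(dir, "dissemination.csv"))
  write_model_config(scenario$config, scenario$params, scenario$sens,
                     path = file.path(dir, "model_config.json"))
  obs <- make_observed_incidence(scenario, n_sim = n_sim)
  write_observed_incidence(obs, file.path(dir, "observed_incidence.csv"))
  jsonlite::write_json(scenario$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
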