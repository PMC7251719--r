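# Chi-square goodness of fit of projected vs observed age-adjusted incidence
# and derivative-free calibration of free natural-history parameters.

# coerce an incidence source to age-adjusted yearly rates
# (year, diagnosis, rate). Accepts incidence_table objects, already-adjusted
# data frames, or age-group-level observed tables (adjusted with `weights`).
as_adjusted_rates <- function(x, weights = NULL) {
  if (inherits(x, "incidence_table")) return(as.data.frame(x$age_adjusted))
  x <- as.data.frame(x)
  if ("rate_per_100k" %in% names(x) && !"rate" %in% names(x))
    names(x)[names(x) == "rate_per_100k"] <- "rate"
  stopifnot(all(c("year", "diagnosis", "rate") %in% names(x)))
  if ("age_group" %in% names(x)) {
    grp <- age_groups()
    if (is.null(weights)) weights <- rep(1 / length(grp), length(grp))
    w <- data.frame(age_group = grp, weight = weights)
    x <- merge(x, w, by = "age_group")
    x <- stats::aggregate(cbind(rate = rate * weight) ~ year + diagnosis,
                          data = x, FUN = sum)
  }
  x[, c("year", "diagnosis", "rate")]
}

#' Chi-square goodness of fit on age-adjusted incidence
#'
#' Pearson statistic `sum((obs - est)^2 / est)` over yearly age-adjusted
#' rates per 100,000, with df = number of compared years - 1 (40 for the
#' 1975-2015 span) and an upper-tail chi-square p-value.
#'
#' @param projected model incidence: an `incidence_table` or data.frame with
#'   `year`, `diagnosis`, `rate`
#' @param observed observed incidence in the same formats (age-group tables
#'   are age-adjusted with `weights`)
#' @param diagnosis `"DCIS"` or `"IBC"`
#' @param years year span to compare (default 1975-2015)
#' @param weights standardization weights used when `observed` is an
#'   age-group table
#' @return object of class `gof_result`: list with `statistic`, `df`,
#'   `p_value` and per-year `residuals`
#' @export
gof_deviance <- function(projected, observed, diagnosis = "DCIS",
                         years = 1975:2015, weights = NULL) {
  d <- diagnosis
  est <- as_adjusted_rates(projected, weights)
  obs <- as_adjusted_rates(observed, weights)
  est <- est[est$diagnosis == d & est$year %in% years, ]
  obs <- obs[obs$diagnosis == d & obs$year %in% years, ]
  m <- merge(obs, est, by = "year", suffixes = c("_obs", "_est"))
  if (nrow(m) != length(years))
    stop("tables do not cover the requested year span", call. = FALSE)
  if (any(m$rate_est <= 0 & m$rate_obs > 0))
    stop("degenerate expected rate: est <= 0 where obs > 0", call. = FALSE)
  ok <- m$rate_est > 0
  terms <- ifelse(ok, (m$rate_obs - m$rate_est)^2 / m$rate_est, 0)
  stat <- sum(terms)
  df <- length(years) - 1L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 residuals = data.frame(
                   year = m$year, observed = m$rate_obs,
                   projected = m$rate_est,
                   residual = ifelse(ok, (m$rate_obs - m$rate_est) /
                                       sqrt(m$rate_est), 0)),
                 diagnosis = d),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("%s deviance %.1f on %d df (p = %.3g)\n", x$diagnosis,
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# Pearson statistic with an expected-rate floor: used only inside the
# calibration objective, where candidate parameter sets can zero out cells
# that the strict public statistic would reject
pearson_floor_ <- function(obs, est, floor = 0.5) {
  # floor only the denominator: empty-empty cells contribute 0, cells the
  # candidate empties but the target fills get a finite continuous penalty
  sum((obs - est)^2 / pmax(est, floor))
}

# Nelder-Mead simplex with an explicit initial step. The stochastic
# common-random-number objective is piecewise constant on small scales, so
# the initial simplex must span a macroscopic fraction of the (transformed)
# box to see the large-scale curvature; optim() offers no such control.
nelder_mead_ <- function(fn, x0, step = 1, maxit = 200, reltol = 1e-4) {
  n <- length(x0)
  simp <- matrix(rep(x0, each = n + 1), nrow = n + 1)
  for (i in seq_len(n)) simp[i + 1, i] <- simp[i + 1, i] + step
  fv <- apply(simp, 1, fn)
  nev <- n + 1
  while (nev < maxit) {
    o <- order(fv); simp <- simp[o, , drop = FALSE]; fv <- fv[o]
    if (abs(fv[n + 1] - fv[1]) <= reltol * (abs(fv[1]) + reltol)) break
    cen <- colMeans(simp[seq_len(n), , drop = FALSE])
    xr <- cen + (cen - simp[n + 1, ]); fr <- fn(xr); nev <- nev + 1
    if (fr < fv[1]) {
      xe <- cen + 2 * (cen - simp[n + 1, ]); fe <- fn(xe); nev <- nev + 1
      if (fe < fr) { simp[n + 1, ] <- xe; fv[n + 1] <- fe }
      else { simp[n + 1, ] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {
      simp[n + 1, ] <- xr; fv[n + 1] <- fr
    } else {
      xc <- cen + 0.5 * (simp[n + 1, ] - cen); fc <- fn(xc); nev <- nev + 1
      if (fc < fv[n + 1]) { simp[n + 1, ] <- xc; fv[n + 1] <- fc }
      else {
        for (i in 2:(n + 1)) {   # shrink toward the best vertex
          simp[i, ] <- simp[1, ] + 0.5 * (simp[i, ] - simp[1, ])
          fv[i] <- fn(simp[i, ]); nev <- nev + 1
        }
      }
    }
  }
  o <- order(fv)
  list(par = simp[o[1], ], value = fv[o[1]], evaluations = nev,
       convergence = if (nev < maxit) 0L else 1L)
}

# parameters that may be freed in calibration
.FREE_OK <- c("p1", "mst1", "mst2", "mst3", "undetectable_mean_dwell",
              "undetectable_direct_to_ibc_frac",
              "ibc_preclinical_mean_dwell", "frac_to_screen_detectable")

# apply a named free-parameter vector to a population spec; freeing p1
# renormalizes p2 = 1 - p1 - p3 (p3 held fixed)
apply_free_ <- function(spec, theta) {
  p <- spec$params
  cfg <- spec$config
  for (nm in names(theta)) {
    if (nm == "frac_to_screen_detectable") {
      cfg$frac_to_screen_detectable <- theta[[nm]]
    } else if (nm == "p1") {
      p$p1 <- theta[[nm]]
      p$p2 <- 1 - p$p1 - p$p3
    } else {
      p[[nm]] <- theta[[nm]]
    }
  }
  validate_nh_params(p)
  spec$params <- p
  spec$config <- cfg
  spec
}

#' Calibrate free natural-history parameters to observed incidence
#'
#' Minimizes the summed chi-square deviance of DCIS (and optionally IBC)
#' age-adjusted incidence over a named subset of natural-history parameters,
#' using a Nelder-Mead simplex on a logit box-bound transform. Every
#' objective evaluation simulates with the same fixed seed (common random
#' numbers), so the objective is deterministic in the parameter vector.
#'
#' Freeing `p1` renormalizes `p2 = 1 - p1 - p3` with `p3` held fixed.
#'
#' @param spec [population_spec()] providing all fixed parameters
#' @param target observed incidence (see [gof_deviance()] formats)
#' @param free named numeric vector of initial values; names from
#'   `p1`, `mst1`, `mst2`, `mst3`, `undetectable_mean_dwell`,
#'   `undetectable_direct_to_ibc_frac`, `ibc_preclinical_mean_dwell`,
#'   `frac_to_screen_detectable`
#' @param lower,upper bounds, same length and order as `free`
#' @param n_sim women per objective evaluation
#' @param seed simulation seed used for every evaluation
#' @param diagnosis diagnosis classes entering the objective
#' @param years year span of the fit
#' @param max_eval simplex evaluation budget
#' @return object of class `calibration_result`: `par`, `value`,
#'   `convergence` (0 = converged), `evaluations`, `trace`,
#'   `curvature_se`, `seed`
#' @export
calibrate <- function(spec, target, free, lower, upper, n_sim = 20000,
                      seed = spec$seed, diagnosis = c("DCIS", "IBC"),
                      years = 1975:2015, max_eval = 200) {
  stopifnot(is.numeric(free))
  if (length(free) > 0) {
    stopifnot(!is.null(names(free)), all(names(free) %in% .FREE_OK),
              length(lower) == length(free), length(upper) == length(free),
              all(lower < upper), all(free > lower), all(free < upper))
  }
  target_adj <- as_adjusted_rates(target)
  sim_spec <- spec
  sim_spec$n_women <- as.integer(n_sim)
  sim_spec$seed <- seed
  trace_env <- new.env()
  trace_env$rows <- list()
  objective <- function(theta_nat) {
    s <- tryCatch(apply_free_(sim_spec, as.list(setNames(theta_nat,
                                                         names(free)))),
                  error = function(e) NULL)
    if (is.null(s)) return(1e12)
    log <- simulate_population(s)
    inc <- compute_incidence(log, "screened", years = years)
    est <- as_adjusted_rates(inc)
    val <- sum(vapply(diagnosis, function(d) {
      e <- est[est$diagnosis == d & est$year %in% years, ]
      o <- target_adj[target_adj$diagnosis == d &
                        target_adj$year %in% years, ]
      m <- merge(o, e, by = "year", suffixes = c("_obs", "_est"))
      pearson_floor_(m$rate_obs, m$rate_est)
    }, numeric(1)))
    trace_env$rows[[length(trace_env$rows) + 1L]] <-
      c(theta_nat, objective = val)
    val
  }
  if (length(free) == 0) {
    v <- objective(numeric(0))
    if (!is.finite(v))
      stop("non-finite objective at the initial point", call. = FALSE)
    return(structure(list(par = numeric(0), value = v, convergence = 0L,
                          evaluations = 1L, trace = NULL,
                          curvature_se = numeric(0), seed = seed),
                     class = "calibration_result"))
  }
  to_t <- function(x) log((x - lower) / (upper - x))        # logit box
  to_x <- function(t) lower + (upper - lower) / (1 + exp(-t))
  f0 <- objective(free)
  if (!is.finite(f0))
    stop("non-finite objective at the initial point", call. = FALSE)
  fit <- nelder_mead_(function(t) objective(to_x(t)), to_t(free),
                      step = 1, maxit = max_eval)
  par <- setNames(to_x(fit$par), names(free))
  # curvature-based approximate uncertainty: treat the objective as a
  # chi-square deviance, se_i ~ sqrt(2 / d2f/dx2)
  cse <- vapply(seq_along(par), function(i) {
    h <- 0.02 * (upper[i] - lower[i])
    xp <- par; xm <- par
    xp[i] <- min(par[i] + h, upper[i] - 1e-9)
    xm[i] <- max(par[i] - h, lower[i] + 1e-9)
    curv <- (objective(xp) - 2 * fit$value + objective(xm)) / h^2
    if (is.finite(curv) && curv > 0) sqrt(2 / curv) else NA_real_
  }, numeric(1))
  structure(list(par = par, value = fit$value,
                 convergence = fit$convergence,
                 evaluations = length(trace_env$rows),
                 trace = do.call(rbind, trace_env$rows),
                 curvature_se = setNames(cse, names(free)), seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration:", x$evaluations, "evaluations, objective",
      format(x$value, digits = 5),
      if (x$convergence == 0) "(converged)" else "(budget reached)", "\n")
  if (length(x$par)) print(rbind(estimate = x$par, approx_se = x$curvature_se))
  invisible(x)
}
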