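#' Time-varying log-hazard-ratio shapes for simulation scenarios
#'
#' `beta_constant` is a proportional-hazards effect; `beta_linear` is
#' `intercept + slope * t` (a sign-reversing effect when the line crosses
#' zero inside follow-up); `beta_spline` interpolates the given
#' (knot, value) pairs with a natural cubic spline for smooth nonlinear
#' shapes.
#'
#' @param value,intercept,slope,knots,values shape parameters (log hazard
#'   ratio per covariate unit; times in years).
#' @return A `beta_spec` object with an `eval(t)` closure.
#' @export
beta_constant <- function(value) {
  structure(list(type = "constant", value = value,
                 eval = function(t) rep(value, length(t))),
            class = "beta_spec")
}

#' @rdname beta_constant
#' @export
beta_linear <- function(intercept, slope) {
  structure(list(type = "linear", intercept = intercept, slope = slope,
                 eval = function(t) intercept + slope * t),
            class = "beta_spec")
}

#' @rdname beta_constant
#' @export
beta_spline <- function(knots, values) {
  stopifnot(length(knots) == length(values), length(knots) >= 2)
  f <- stats::splinefun(knots, values, method = "natural")
  structure(list(type = "spline", knots = knots, values = values, eval = f),
            class = "beta_spec")
}

#' Covariate generators for simulation scenarios
#'
#' `cov_bernoulli` and `cov_normal` generate fixed (baseline) covariates;
#' `cov_timeseries` generates a subject-level exposure trajectory observed
#' at study visits: subject `i`'s value at visit age `a` is
#' `b0_i + b1_i * a + noise`, with random intercept `b0 ~ N(mean,
#' sd_subject)` and random slope `b1 ~ N(slope_mean, slope_sd)`.  The
#' hazard sees the last measured value carried forward, matching how the
#' analysis handles exposure series.
#'
#' @param prob,mean,sd,sd_subject,slope_mean,slope_sd,sd_noise generator
#'   parameters.
#' @return A `cov_spec` object.
#' @export
cov_bernoulli <- function(prob) {
  structure(list(type = "bernoulli", prob = prob, time_varying = FALSE),
            class = "cov_spec")
}

#' @rdname cov_bernoulli
#' @export
cov_normal <- function(mean, sd) {
  structure(list(type = "normal", mean = mean, sd = sd,
                 time_varying = FALSE), class = "cov_spec")
}

#' @rdname cov_bernoulli
#' @export
cov_timeseries <- function(mean, sd_subject, slope_mean = 0, slope_sd = 0,
                           sd_noise = 0) {
  structure(list(type = "timeseries", mean = mean, sd_subject = sd_subject,
                 slope_mean = slope_mean, slope_sd = slope_sd,
                 sd_noise = sd_noise, time_varying = TRUE),
            class = "cov_spec")
}

#' Define a prospective-cohort simulation scenario
#'
#' The simulator emulates a visit-based prospective cohort of children at
#' risk: staggered entry between birth and `max_entry` years, a piecewise
#' constant baseline hazard on an age grid, covariate effects
#' `beta_j(t) * x_j(t)` on the log hazard, scheduled visits (default 9, 15,
#' and 24 months, then annually), event age recorded at the first visit at
#' or after true onset, censoring at the last attended visit, and subjects
#' already positive at their first visit flagged as left-censored.
#'
#' @param n_subjects cohort size.
#' @param covariates named list of [cov_bernoulli()]-style specs.
#' @param beta named list of [beta_constant()]-style specs; names must
#'   match `covariates`.
#' @param baseline list with `breaks` (increasing ages, first 0) and
#'   `rates` (per-year hazard on each interval, length
#'   `length(breaks) - 1`).
#' @param entry list with `prob_birth` (fraction entering at birth) and
#'   `max_entry`; non-birth entries are uniform on `(0, max_entry)`.
#' @param visit_schedule scheduled visit ages (years, increasing).
#' @param dropout_rate exponential dropout rate per year (non-informative).
#' @param max_follow_up administrative end of follow-up (years).
#' @param grid_step refinement step (years) for hazard inversion.
#' @param name scenario label.
#' @return A `sim_scenario` object.
#' @export
scenario <- function(n_subjects,
                     covariates,
                     beta,
                     baseline = list(breaks = c(0, 2, 6, 15),
                                     rates = c(0.05, 0.025, 0.04)),
                     entry = list(prob_birth = 0.7, max_entry = 8),
                     visit_schedule = c(0.75, 1.25, 2, 3:12),
                     dropout_rate = 0.05,
                     max_follow_up = 12,
                     grid_step = 0.05,
                     name = "custom") {
  stopifnot(n_subjects >= 0,
            length(baseline$rates) == length(baseline$breaks) - 1L,
            all(baseline$rates >= 0), all(diff(baseline$breaks) > 0),
            all(diff(visit_schedule) > 0), dropout_rate >= 0,
            grid_step > 0, max_follow_up > 0)
  if (!setequal(names(covariates), names(beta))) {
    stop("`covariates` and `beta` must have matching names")
  }
  for (cv in covariates) stopifnot(inherits(cv, "cov_spec"))
  for (b in beta) stopifnot(inherits(b, "beta_spec"))
  structure(list(n_subjects = as.integer(n_subjects),
                 covariates = covariates, beta = beta[names(covariates)],
                 baseline = baseline, entry = entry,
                 visit_schedule = visit_schedule,
                 dropout_rate = dropout_rate,
                 max_follow_up = max_follow_up,
                 grid_step = grid_step, name = name),
            class = "sim_scenario")
}

#' Named default scenarios
#'
#' Qualitative emulations of the effect shapes seen in age-heterogeneity
#' analyses of islet autoimmunity cohorts (no real-cohort parameters are
#' claimed):
#' \describe{
#'   \item{null}{binary covariate with no effect (`beta = 0`): the exact
#'     proportional-hazards null, used for type-I-error calibration.}
#'   \item{nhw-like}{binary covariate (prevalence 0.72) with a linearly
#'     declining log HR that reverses sign mid-childhood (HR above 1
#'     early, below 1 late).}
#'   \item{maternal-age-like}{continuous covariate (per 5-year units) with
#'     a smoothly nonlinear, eventually protective effect.}
#'   \item{n3fa-like}{time-varying exposure trajectory with a linearly
#'     declining log HR.}
#' }
#'
#' @param name scenario name.
#' @param n_subjects optional override of the scenario's cohort size.
#' @return A `sim_scenario`.
#' @export
default_scenario <- function(name = c("null", "nhw-like",
                                      "maternal-age-like", "n3fa-like"),
                             n_subjects = NULL) {
  name <- match.arg(name)
  sc <- switch(name,
    "null" = scenario(300L,
                      covariates = list(x = cov_bernoulli(0.7)),
                      beta = list(x = beta_constant(0)),
                      name = "null"),
    "nhw-like" = scenario(500L,
                          covariates = list(nhw = cov_bernoulli(0.72)),
                          beta = list(nhw = beta_linear(0.77, -0.111)),
                          name = "nhw-like"),
    "maternal-age-like" = scenario(
      500L,
      covariates = list(matage = cov_normal(5.96, 1.14)),
      beta = list(matage = beta_spline(c(0, 2, 6, 11),
                                       c(0.15, 0.131, 0.02, -0.186))),
      name = "maternal-age-like"),
    "n3fa-like" = scenario(
      500L,
      covariates = list(n3fa = cov_timeseries(1.1, 0.35, 0.01, 0.01, 0.2)),
      beta = list(n3fa = beta_linear(0.3617, -0.1423)),
      name = "n3fa-like"))
  if (!is.null(n_subjects)) sc$n_subjects <- as.integer(n_subjects)
  sc
}

# Piecewise-constant baseline hazard evaluated at ages t.
baseline_hazard_at <- function(baseline, t) {
  idx <- findInterval(t, baseline$breaks, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(baseline$rates)] <- length(baseline$rates)
  baseline$rates[idx]
}

#' Draw a true onset age by piecewise-exponential inversion
#'
#' The hazard `h0(t) * exp(sum_j beta_j(t) x_j(t))` is approximated as
#' constant on a refinement grid (step `grid_step`, at most 0.05 years by
#' default) from the entry age; an Exp(1) draw is inverted against the
#' cumulative hazard, with linear inversion inside the final grid cell.
#'
#' @param xfun function(t-vector) returning a `length(t) x n_covariates`
#'   matrix of covariate values at those ages (columns in scenario order).
#' @param entry_age entry age (years).
#' @param sc a `sim_scenario`.
#' @param e optional pre-drawn Exp(1) variate (for reproducibility
#'   control); drawn internally when missing.
#' @return onset age in years, or `Inf` when the subject survives past
#'   `max_follow_up`.
#' @export
simulate_event_time <- function(xfun, entry_age, sc, e = NULL) {
  pts <- unique(c(entry_age,
                  seq(entry_age, sc$max_follow_up, by = sc$grid_step),
                  sc$max_follow_up))
  pts <- sort(pts)
  mids <- (pts[-1L] + pts[-length(pts)]) / 2
  dts <- diff(pts)
  xm <- xfun(mids)
  bm <- vapply(sc$beta, function(b) b$eval(mids), numeric(length(mids)))
  if (is.null(dim(bm))) bm <- matrix(bm, nrow = length(mids))
  if (!all(is.finite(bm))) stop("non-finite beta(t) on the hazard grid")
  lp <- rowSums(bm * xm)
  rate <- baseline_hazard_at(sc$baseline, mids) * exp(lp)
  ch <- cumsum(rate * dts)
  if (is.null(e)) e <- stats::rexp(1)
  if (e >= ch[length(ch)]) return(Inf)
  cell <- which(ch >= e)[1L]
  ch0 <- if (cell == 1L) 0 else ch[cell - 1L]
  pts[cell] + (e - ch0) / rate[cell]
}

#' Apply visit-based event detection to a true onset age
#'
#' Attended visits are the scheduled ages strictly after entry, truncated
#' at the earlier of dropout and administrative follow-up.  The recorded
#' event age is the first attended visit at or after the true onset; a
#' subject whose onset precedes the first attended visit is flagged
#' positive-at-first-visit (left-censored); a subject with no detected
#' onset is censored at the last attended visit.
#'
#' @param onset true onset age (`Inf` for none).
#' @param entry_age entry age.
#' @param visit_schedule scheduled visit ages.
#' @param dropout_age dropout age (years; `Inf` for none).
#' @param max_follow_up administrative limit.
#' @return list with `entry_age`, `exit_age`, `event`,
#'   `positive_at_first_visit`, `attended` (visit ages), or `NULL` when
#'   the subject attends no visit (dropped, logged by the caller).
#' @export
apply_visit_detection <- function(onset, entry_age, visit_schedule,
                                  dropout_age, max_follow_up) {
  limit <- min(dropout_age, max_follow_up)
  attended <- visit_schedule[visit_schedule > entry_age &
                               visit_schedule <= limit]
  if (!length(attended)) return(NULL)
  first <- attended[1L]
  if (onset <= first) {
    return(list(entry_age = entry_age, exit_age = first, event = 1L,
                positive_at_first_visit = 1L, attended = attended))
  }
  pos <- attended[attended >= onset]
  if (length(pos)) {
    list(entry_age = entry_age, exit_age = pos[1L], event = 1L,
         positive_at_first_visit = 0L,
         attended = attended[attended <= pos[1L]])
  } else {
    list(entry_age = entry_age, exit_age = attended[length(attended)],
         event = 0L, positive_at_first_visit = 0L, attended = attended)
  }
}

#' Simulate a visit-based prospective cohort
#'
#' Fully reproducible from `seed`.  Returns the subject table in the
#' cohort schema (left-censored subjects included, flagged), plus a
#' long-format measurement table for any time-varying covariate, with
#' measurements emitted at attended visits up to the exit age only.
#'
#' @param sc a [scenario()] object.
#' @param seed integer seed.
#' @return list with `subjects`, `measurements` (`NULL` when all
#'   covariates are fixed), and `info` (seed, realized counts).
#' @export
simulate_cohort <- function(sc, seed) {
  stopifnot(inherits(sc, "sim_scenario"))
  with_seed(as.integer(seed), {
    n <- sc$n_subjects
    cn <- names(sc$covariates)
    if (n == 0L) {
      subjects <- data.frame(subject_id = character(),
                             entry_age = numeric(), exit_age = numeric(),
                             event = integer(),
                             positive_at_first_visit = integer())
      for (cv in cn) {
        if (!sc$covariates[[cv]]$time_varying) subjects[[cv]] <- numeric()
      }
      has_tv <- any(vapply(sc$covariates, `[[`, logical(1), "time_varying"))
      meas <- if (has_tv) {
        data.frame(subject_id = character(), age = numeric(),
                   value = numeric())
      }
      return(list(subjects = subjects, measurements = meas,
                  info = list(seed = as.integer(seed), n_dropped = 0L,
                              n_events = 0L, n_left_censored = 0L)))
    }
    entry <- ifelse(stats::runif(n) < sc$entry$prob_birth, 0,
                    stats::runif(n, 0, sc$entry$max_entry))
    dropout <- if (sc$dropout_rate > 0) {
      entry + stats::rexp(n, sc$dropout_rate)
    } else {
      rep(Inf, n)
    }
    # fixed covariate values and time-series subject parameters
    fixed_vals <- list()
    ts_pars <- list()
    for (cv in cn) {
      spec <- sc$covariates[[cv]]
      if (spec$type == "bernoulli") {
        fixed_vals[[cv]] <- stats::rbinom(n, 1L, spec$prob)
      } else if (spec$type == "normal") {
        fixed_vals[[cv]] <- stats::rnorm(n, spec$mean, spec$sd)
      } else {
        ts_pars[[cv]] <- list(
          b0 = stats::rnorm(n, spec$mean, spec$sd_subject),
          b1 = stats::rnorm(n, spec$slope_mean, spec$slope_sd))
      }
    }
    tv_names <- names(ts_pars)

    rows <- vector("list", n)
    meas_rows <- vector("list", n)
    n_dropped <- 0L
    for (i in seq_len(n)) {
      # visit values of time-varying covariates (drawn whether or not the
      # subject is ultimately retained, to keep the draw sequence simple)
      limit <- min(dropout[i], sc$max_follow_up)
      visits <- sc$visit_schedule[sc$visit_schedule > entry[i] &
                                    sc$visit_schedule <= limit]
      tv_vals <- list()
      for (cv in tv_names) {
        spec <- sc$covariates[[cv]]
        tv_vals[[cv]] <- ts_pars[[cv]]$b0[i] +
          ts_pars[[cv]]$b1[i] * visits +
          stats::rnorm(length(visits), 0, spec$sd_noise)
      }
      xfun <- local({
        fx <- vapply(cn, function(cv) {
          if (cv %in% tv_names) NA_real_ else fixed_vals[[cv]][i]
        }, numeric(1))
        vv <- visits
        tvv <- tv_vals
        function(t) {
          out <- matrix(rep(fx, each = length(t)), length(t), length(cn))
          for (cv in names(tvv)) {
            j <- match(cv, cn)
            if (!length(vv)) {
              out[, j] <- 0
            } else {
              # LOCF; before the first visit, the first value (backfill)
              idx <- pmax(findInterval(t, vv), 1L)
              out[, j] <- tvv[[cv]][idx]
            }
          }
          out
        }
      })
      onset <- if (length(visits)) {
        simulate_event_time(xfun, entry[i], sc)
      } else {
        stats::rexp(1) # burn a draw for stream stability, subject dropped
        Inf
      }
      det <- apply_visit_detection(onset, entry[i], sc$visit_schedule,
                                   dropout[i], sc$max_follow_up)
      if (is.null(det)) {
        n_dropped <- n_dropped + 1L
        next
      }
      row <- data.frame(subject_id = sprintf("S%05d", i),
                        entry_age = det$entry_age,
                        exit_age = det$exit_age,
                        event = det$event,
                        positive_at_first_visit =
                          det$positive_at_first_visit)
      for (cv in cn) {
        if (!(cv %in% tv_names)) row[[cv]] <- fixed_vals[[cv]][i]
      }
      rows[[i]] <- row
      if (length(tv_names)) {
        keep <- visits <= det$exit_age
        if (any(keep)) {
          meas_rows[[i]] <- data.frame(
            subject_id = sprintf("S%05d", i),
            age = visits[keep],
            value = tv_vals[[tv_names[1L]]][keep])
        }
      }
    }
    subjects <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(subjects) <- NULL
    meas <- NULL
    if (length(tv_names)) {
      keep <- !vapply(meas_rows, is.null, logical(1))
      meas <- do.call(rbind, meas_rows[keep])
      rownames(meas) <- NULL
    }
    if (is.null(subjects) || sum(subjects$event) == 0L) {
      warning("zero events in the realized cohort; downstream fits will ",
              "error")
    }
    list(subjects = subjects, measurements = meas,
         info = list(seed = as.integer(seed), n_dropped = n_dropped,
                     n_events = if (is.null(subjects)) 0L
                                else sum(subjects$event),
                     n_left_censored = if (is.null(subjects)) 0L
                                else sum(subjects$positive_at_first_visit)))
  })
}

# Build analysis-ready episodes for a scenario's covariate of interest:
# exclude left-censored subjects, then expand (with the measurement series
# when the covariate is time-varying).
scenario_episodes <- function(sim, sc) {
  cn <- names(sc$covariates)
  excl <- exclude_left_censored(sim$subjects)
  tv <- vapply(sc$covariates, `[[`, logical(1), "time_varying")
  if (any(tv)) {
    tvn <- cn[tv][1L]
    meas <- sim$measurements
    meas <- meas[meas$subject_id %in% excl$retained$subject_id, ,
                 drop = FALSE]
    suppressMessages(
      expand_counting_process(excl$retained, meas, tv_name = tvn,
                              on_unusable = "drop"))
  } else {
    expand_counting_process(excl$retained)
  }
}

#' Monte-Carlo rejection-rate study for a PH diagnostic
#'
#' Simulates `n_reps` cohorts from the scenario, runs the named test on the
#' scenario's covariate of interest each time, and reports the proportion
#' of p-values below `alpha` with a 95% binomial (Clopper-Pearson)
#' confidence interval.  RCS tests are computed ungated.  Replicates where
#' the test fails (e.g. a degenerate realized cohort) are dropped and
#' counted.
#'
#' @param sc a [scenario()] object.
#' @param test one of `"supremum"`, `"zph"` (individual covariate test),
#'   `"zph_global"`, `"rcs_association"`, `"rcs_nonconstant"`,
#'   `"rcs_nonlinear"`.
#' @param n_reps number of replicates.
#' @param alpha rejection level.
#' @param seed master seed; each replicate uses a derived sub-seed.
#' @param n_paths resampling size for the supremum test.
#' @return list with `test`, `n_reps`, `n_failed`, `rejection`, `ci`,
#'   `alpha`, `p_values`.
#' @export
power_study <- function(sc, test, n_reps, alpha = 0.05, seed = 1L,
                        n_paths = 1000L) {
  tests <- c("supremum", "zph", "zph_global", "rcs_association",
             "rcs_nonconstant", "rcs_nonlinear")
  if (!test %in% tests) {
    stop("unknown test '", test, "'; expected one of: ",
         paste(tests, collapse = ", "))
  }
  cov1 <- names(sc$covariates)[1L]
  pv <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    pv[r] <- tryCatch({
      sim <- simulate_cohort(sc, child_seed(seed, r))
      ep <- scenario_episodes(sim, sc)
      if (test %in% c("supremum", "zph", "zph_global")) {
        fit <- fit_cox(ep, cov1)
        if (test == "supremum") {
          supremum_test(fit, cov1, n_paths = n_paths,
                        seed = child_seed(seed, r, 1L))$p_value
        } else {
          zt <- suppressWarnings(zph_test(fit))
          row <- if (test == "zph") cov1 else "GLOBAL"
          zt$table[row, "p"]
        }
      } else {
        rf <- fit_rcs_cox(ep, cov1, k = 3L)
        ht <- hierarchical_tests(rf, gated = FALSE)
        ht[[sub("rcs_", "", test)]]$p_value
      }
    }, error = function(e) NA_real_)
  }
  ok <- !is.na(pv)
  rej <- sum(pv[ok] < alpha)
  ci <- if (any(ok)) {
    as.numeric(stats::binom.test(rej, sum(ok))$conf.int)
  } else {
    c(NA_real_, NA_real_)
  }
  list(test = test, n_reps = n_reps, n_failed = sum(!ok),
       rejection = if (any(ok)) rej / sum(ok) else NA_real_,
       ci = ci, alpha = alpha, p_values = pv)
}
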