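#' Configuration for a consolidated PH assessment
#'
#' @param covariates covariates to test for nonproportional hazards.
#' @param adjust adjustment covariates (included in every model, not
#'   themselves tested).
#' @param delta named covariate contrasts for reported hazard ratios
#'   (default 1 per covariate).
#' @param report_ages ages (years) at which HR(t) with 95% CI is reported.
#' @param screen_threshold screening threshold for the supremum and
#'   scaled-Schoenfeld verdicts (default 0.30).
#' @param hier_alpha gate level for the RCS hierarchy (default 0.05).
#' @param gated apply the RCS hierarchy gate.
#' @param ties ties method for all Cox fits.
#' @param transform time transform for the scaled-Schoenfeld test.
#' @param n_paths supremum resampling size (default 1000).
#' @param knots knot count for the RCS model; a vector of candidates
#'   triggers AIC selection.
#' @param tv_name name under which a supplied measurement series enters the
#'   models as a time-varying covariate.
#' @param tv_diagnostics also run the supremum and scaled-Schoenfeld
#'   diagnostics for time-varying covariates (an extension; default FALSE
#'   reports them as not applicable).
#' @param seed seed for the supremum resampling.
#' @return list of class `assessment_config`.
#' @export
assessment_config <- function(covariates, adjust = character(),
                              delta = NULL, report_ages = c(2, 11),
                              screen_threshold = 0.30, hier_alpha = 0.05,
                              gated = TRUE,
                              ties = c("breslow", "efron"),
                              transform = c("km", "identity", "rank",
                                            "log"),
                              n_paths = 1000L, knots = 3L,
                              tv_name = "exposure",
                              tv_diagnostics = FALSE, seed = 1L) {
  ties <- match.arg(ties)
  transform <- match.arg(transform)
  dl <- stats::setNames(rep(1, length(covariates)), covariates)
  if (!is.null(delta)) dl[names(delta)] <- delta
  structure(list(covariates = covariates, adjust = adjust, delta = dl,
                 report_ages = report_ages,
                 screen_threshold = screen_threshold,
                 hier_alpha = hier_alpha, gated = gated, ties = ties,
                 transform = transform, n_paths = as.integer(n_paths),
                 knots = as.integer(knots), tv_name = tv_name,
                 tv_diagnostics = tv_diagnostics, seed = as.integer(seed)),
            class = "assessment_config")
}

na_cell <- function(reason) list(p = NULL, reason = reason)
p_cell <- function(p) list(p = p, reason = NULL)

#' Run the consolidated proportional-hazards assessment
#'
#' Pipeline: validate the cohort, exclude left-censored cases, expand to
#' counting-process episodes, fit the Cox model per tested covariate
#' (with adjustment covariates), and run the supremum test, the
#' scaled-Schoenfeld tests (global and individual), and the hierarchical
#' RCS tests with HR(t) at the requested ages.  For a time-varying
#' covariate (one with a measurement series) the supremum and
#' scaled-Schoenfeld cells are reported as not applicable by default and
#' only the RCS route is computed.  Nonconvergence for one covariate is
#' recorded as an error entry; the run continues.
#'
#' @param subjects cohort table (data frame) or path to its CSV.
#' @param measurements optional measurement table or CSV path for one
#'   time-varying covariate (named by `config$tv_name`).
#' @param config an [assessment_config()].
#' @return Object of class `assessment_report`.
#' @export
run_assessment <- function(subjects, measurements = NULL, config) {
  stopifnot(inherits(config, "assessment_config"))
  if (is.character(subjects)) subjects <- read_cohort(subjects)
  subjects <- validate_cohort(subjects)
  if (is.character(measurements)) {
    measurements <- read_measurements(measurements)
  }
  excl <- exclude_left_censored(subjects)
  results <- list()
  for (ci in config$covariates) {
    results[[ci]] <- tryCatch(
      assess_one(ci, excl$retained, measurements, config),
      error = function(e) {
        list(covariate = ci, error = conditionMessage(e))
      })
  }
  structure(list(
    covariates = results,
    n_subjects = nrow(subjects),
    n_retained = nrow(excl$retained),
    n_left_censored = excl$n_removed,
    n_events_retained = sum(excl$retained$event),
    metadata = list(seed = config$seed, ties = config$ties,
                    transform = config$transform,
                    knots = config$knots,
                    screen_threshold = config$screen_threshold,
                    hier_alpha = config$hier_alpha,
                    version = as.character(
                      utils::packageVersion("etiohet")))
  ), class = "assessment_report")
}

assess_one <- function(ci, retained, measurements, config) {
  tv <- !is.null(measurements) && ci == config$tv_name
  if (tv) {
    meas <- measurements[
      measurements$subject_id %in% retained$subject_id, , drop = FALSE]
    ep <- suppressMessages(
      expand_counting_process(retained, meas, tv_name = ci,
                              on_unusable = "drop"))
  } else {
    ep <- expand_counting_process(retained)
  }
  covs <- c(ci, config$adjust)
  fit <- fit_cox(ep, covs, ties = config$ties)
  out <- list(covariate = ci, time_varying = tv, error = NULL)

  if (!tv || config$tv_diagnostics) {
    sup <- supremum_test(fit, ci, n_paths = config$n_paths,
                         seed = config$seed)
    zt <- suppressWarnings(zph_test(fit, transform = config$transform))
    out$supremum <- p_cell(sup$p_value)
    out$zph_global <- p_cell(unname(zt$table["GLOBAL", "p"]))
    out$zph_individual <- p_cell(unname(zt$table[ci, "p"]))
    out$zph_warnings <- zt$warnings
    out$supremum_verdict <- interpret_supremum(sup$p_value,
                                               config$screen_threshold)
    out$zph_flagged <- interpret_zph(zt, config$screen_threshold)$flagged
  } else {
    out$supremum <- na_cell("not-applicable-time-varying")
    out$zph_global <- na_cell("not-applicable-time-varying")
    out$zph_individual <- na_cell("not-applicable-time-varying")
  }

  rf <- if (length(config$knots) > 1L) {
    select_knots_by_aic(ep, ci, config$adjust,
                        candidate_k = config$knots,
                        delta = config$delta[[ci]], ties = config$ties)
  } else {
    fit_rcs_cox(ep, ci, config$adjust, k = config$knots,
                delta = config$delta[[ci]], ties = config$ties)
  }
  ht <- hierarchical_tests(rf, alpha = config$hier_alpha,
                           gated = config$gated)
  cell <- function(tt) {
    if (tt$performed) p_cell(tt$p_value) else na_cell("gated")
  }
  out$rcs_association <- cell(ht$association)
  out$rcs_nonconstant <- cell(ht$nonconstant)
  out$rcs_nonlinear <- cell(ht$nonlinear)
  out$rcs_knots <- rf$basis$knots
  out$delta <- unname(config$delta[[ci]])
  hr <- suppressWarnings(hr_curve(rf, config$report_ages))
  out$hr <- data.frame(age = hr$age, hr = hr$hr, lower = hr$lower,
                       upper = hr$upper)
  out
}

fmt_cell <- function(cl, digits = 3) {
  if (is.null(cl)) return("--")
  if (is.null(cl$p)) return(paste0("N/A(", cl$reason, ")"))
  format(cl$p, digits = digits)
}

#' @export
print.assessment_report <- function(x, digits = 3, ...) {
  cat("Proportional hazards assessment\n")
  cat(sprintf("  %d subjects (%d left-censored removed), %d events\n",
              x$n_subjects, x$n_left_censored, x$n_events_retained))
  hdr <- sprintf("  %-14s %-10s %-10s %-10s %-10s %-12s %-10s",
                 "covariate", "supremum", "zph.glob", "zph.indiv",
                 "rcs.assoc", "rcs.nonconst", "rcs.nonlin")
  cat(hdr, "\n")
  for (res in x$covariates) {
    if (!is.null(res$error)) {
      cat(sprintf("  %-14s ERROR: %s\n", res$covariate, res$error))
      next
    }
    cat(sprintf("  %-14s %-10s %-10s %-10s %-10s %-12s %-10s\n",
                res$covariate,
                fmt_cell(res$supremum, digits),
                fmt_cell(res$zph_global, digits),
                fmt_cell(res$zph_individual, digits),
                fmt_cell(res$rcs_association, digits),
                fmt_cell(res$rcs_nonconstant, digits),
                fmt_cell(res$rcs_nonlinear, digits)))
    if (!is.null(res$hr)) {
      for (r in seq_len(nrow(res$hr))) {
        cat(sprintf("      HR(age %s, delta %s) = %.2f (95%% CI %.2f, %.2f)\n",
                    format(res$hr$age[r]), format(res$delta),
                    res$hr$hr[r], res$hr$lower[r], res$hr$upper[r]))
      }
    }
  }
  invisible(x)
}

#' Serialize an assessment report to JSON (and back)
#'
#' @param report an `assessment_report`.
#' @param path optional output file.
#' @return JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "assessment_report"))
  obj <- unclass(report)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "columns")
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' Write a curve (score-process path, beta(t) smooth, HR(t) grid) as CSV
#'
#' @param curve a data frame.
#' @param path output path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
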