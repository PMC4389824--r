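#' Observed cumulative score process for one covariate
#'
#' The path of the cumulative sum of the covariate's Schoenfeld residuals
#' over ordered event times, standardized by `n^(-1/2)` where `n` is the
#' number of subjects.  Under proportional hazards the path is a tied-down
#' mean-zero process; it terminates at 0 exactly because Schoenfeld residual
#' columns sum to zero at the partial likelihood optimum.
#'
#' @param fit a converged [fit_cox()] object.
#' @param covariate covariate name.
#' @return data frame with columns `time` and `value`, one row per event.
#' @export
score_process <- function(fit, covariate) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  if (!covariate %in% fit$covariates) {
    stop("covariate '", covariate, "' not in fit")
  }
  data.frame(time = fit$schoenfeld_times,
             value = cumsum(fit$schoenfeld[, covariate]) /
               sqrt(fit$n_subjects))
}

#' Multiplier-resampling supremum test of proportional hazards
#'
#' Compares the largest absolute excursion of the observed standardized
#' score process with the suprema of `n_paths` simulated paths that embody
#' the proportional hazards null.  Simulated paths perturb each event's
#' score contribution with an independent standard normal multiplier and
#' re-center with the estimated information (accounting for the estimation
#' of the regression coefficients), so every simulated path also terminates
#' at 0.  The p-value is the proportion of simulated suprema at or above
#' the observed supremum.
#'
#' @param fit a converged [fit_cox()] object.
#' @param covariate covariate to test.
#' @param n_paths number of simulated null paths (default 1000).
#' @param seed integer seed for the multipliers; drawn and recorded when not
#'   supplied.  Identical `(data, n_paths, seed)` give identical results.
#' @return Object of class `supremum_result`: `covariate`, `path`
#'   (the observed process), `observed_sup`, `n_paths`, `seed`, `p_value`,
#'   `sim_sups` (the simulated suprema), and `time_varying` (`TRUE` when
#'   the tested covariate varies within subjects; the resampling test for
#'   that case is an extension beyond standard practice and is flagged).
#' @export
supremum_test <- function(fit, covariate, n_paths = 1000L, seed = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  if (!covariate %in% fit$covariates) {
    stop("covariate '", covariate, "' not in fit")
  }
  n_paths <- as.integer(n_paths)
  if (n_paths < 1L) stop("n_paths must be >= 1")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  seed <- as.integer(seed)

  R <- fit$schoenfeld
  D <- nrow(R)
  p <- ncol(R)
  rn <- 1 / sqrt(fit$n_subjects)
  obs_path <- cumsum(R[, covariate]) * rn
  obs_sup <- max(abs(obs_path))
  kk <- match(covariate, fit$covariates)
  # P[e, ] = row `covariate` of I_cum(t_e) %*% I^{-1}: the re-centering
  # weights for the estimated-coefficient correction.
  P <- matrix(0, D, p)
  for (e in seq_len(D)) {
    Ie <- unpack_sym(fit$Icum[e, ], p, fit$pr)
    P[e, ] <- (Ie %*% fit$var)[kk, ]
  }
  sim_sups <- with_seed(seed, {
    G <- matrix(stats::rnorm(D * n_paths), D, n_paths)
    A <- apply(R[, covariate] * G, 2L, cumsum)
    if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
    W <- (A - P %*% crossprod(R, G)) * rn
    apply(abs(W), 2L, max)
  })
  p_value <- mean(sim_sups >= obs_sup)
  structure(list(
    covariate = covariate,
    path = data.frame(time = fit$schoenfeld_times, value = obs_path),
    observed_sup = obs_sup,
    n_paths = n_paths,
    seed = seed,
    p_value = p_value,
    sim_sups = sim_sups,
    time_varying = is_time_varying(fit, covariate)
  ), class = "supremum_result")
}

#' @export
print.supremum_result <- function(x, ...) {
  cat("Supremum test of proportional hazards for '", x$covariate, "'\n",
      sep = "")
  cat("  observed sup |W| =", format(x$observed_sup, digits = 4),
      "over", nrow(x$path), "events\n")
  cat("  p-value =", format(x$p_value, digits = 4),
      paste0("(", x$n_paths, " resampled paths, seed ", x$seed, ")\n"))
  if (isTRUE(x$time_varying)) {
    cat("  note: covariate is time-varying; the resampling supremum test\n",
        "  for this case is an extension beyond standard implementations\n",
        sep = "")
  }
  invisible(x)
}

#' @export
plot.supremum_result <- function(x, ...) {
  graphics::plot(x$path$time, x$path$value, type = "s",
                 xlab = "age (years)",
                 ylab = "standardized cumulative score", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Interpret a supremum test p-value
#'
#' Applies the screening convention used for proportional-hazards checks in
#' etiologic-heterogeneity analyses: a p-value below the threshold (default
#' 0.30, deliberately liberal for a screening diagnostic) is read as
#' evidence of a PH violation.
#'
#' @param p_value p-value in `[0, 1]`.
#' @param threshold screening threshold (default 0.30); the verdict is
#'   `"violation"` iff `p_value < threshold` (strict).
#' @return `"violation"` or `"no-evidence"`.
#' @export
interpret_supremum <- function(p_value, threshold = 0.30) {
  if (!is.numeric(p_value) || is.na(p_value) || p_value < 0 || p_value > 1) {
    stop("p_value must lie in [0, 1]")
  }
  if (p_value < threshold) "violation" else "no-evidence"
}

#' Serialize a supremum result to JSON
#'
#' @param x a `supremum_result`.
#' @param path optional file to write to.
#' @return JSON string (invisibly when written to a file).
#' @export
supremum_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "supremum_result"))
  obj <- list(covariate = x$covariate,
              observed_sup = x$observed_sup,
              n_paths = x$n_paths,
              seed = x$seed,
              p_value = x$p_value,
              time_varying = x$time_varying,
              path = unname(as.matrix(x$path)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
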