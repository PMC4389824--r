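#' Scaled (weighted) Schoenfeld residuals
#'
#' Grambsch-Therneau scaling: each Schoenfeld residual row is multiplied by
#' `n_events * vcov(fit)` and offset by the coefficient estimate, so each
#' row approximates the time-varying coefficient `beta(t)` at its event
#' time.  Column means equal the fitted coefficients (to numerical
#' tolerance, because residual columns sum to zero at the optimum).
#'
#' @param fit a converged [fit_cox()] object.
#' @return events x covariates matrix of scaled residuals, ordered by event
#'   time.
#' @export
scaled_schoenfeld <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  sc <- fit$n_events * fit$schoenfeld %*% fit$var
  sweep(sc, 2L, fit$coefficients, "+")
}

# Transformed event times g(t) per individual event (uncentered), following
# the conventions of the standard scaled-Schoenfeld implementation:
# "km" maps an event time t to 1 - S(t-) where S is the overall
# Kaplan-Meier curve of the (possibly left-truncated) follow-up data.
zph_transform <- function(fit, transform) {
  te <- fit$event_times
  J <- length(te)
  jj <- match(fit$schoenfeld_times, te)
  switch(transform,
    identity = fit$schoenfeld_times,
    log = log(fit$schoenfeld_times),
    rank = rank(fit$episodes$stop)[
      match(fit$schoenfeld_times, fit$episodes$stop)],
    km = {
      nrisk <- drop(risk_sums(matrix(rep(1, fit$n)), fit$lo, fit$hi, J))
      surv <- cumprod(1 - fit$d / nrisk)
      (1 - c(1, surv)[jj])
    },
    stop("unknown time transform '", transform, "'"))
}

#' Test proportional hazards via scaled Schoenfeld residuals
#'
#' Score test for a zero slope of the scaled Schoenfeld residuals on
#' transformed event time, per covariate (1 df each) and globally (df =
#' number of covariates).  The test is the exact score test for adding the
#' interaction `x * g(t)` to the fitted model, evaluated at the fitted
#' coefficients: with centered transform `g`, the score for the added
#' parameters is `u = sum_j g_j r_j` (Schoenfeld residuals `r_j`) and the
#' statistic is `u' (I22 - I21 I11^-1 I12)^-1 u` built from the
#' per-event-time information increments.
#'
#' For a time-varying covariate the scaling behind the test assumes its
#' risk-set variance is roughly constant over time; when the empirical
#' risk-set variance differs by more than `var_ratio` across time terciles
#' the result carries a reliability warning.
#'
#' @param fit a converged [fit_cox()] object with at least 3 events.
#' @param transform time transform: `"km"` (default), `"identity"`,
#'   `"rank"`, or `"log"`.
#' @param var_ratio tercile variance-ratio threshold for the time-varying
#'   covariate reliability warning.
#' @return Object of class `zph_result`: `table` (chisq, df, p per
#'   covariate plus a GLOBAL row), `transform`, `time` (event times), `x`
#'   (transformed, uncentered), `scaled` (scaled residuals), `warnings`.
#' @export
zph_test <- function(fit, transform = c("km", "identity", "rank", "log"),
                     var_ratio = 4) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  transform <- match.arg(transform)
  D <- fit$n_events
  if (D < 3L) stop("insufficient events for slope test (need >= 3)")
  p <- length(fit$covariates)

  g_raw <- zph_transform(fit, transform)
  gc <- g_raw - mean(g_raw)
  if (all(abs(gc) < 1e-12)) {
    stop("degenerate time transform: transformed event times are constant")
  }

  u2 <- drop(crossprod(fit$schoenfeld, gc))
  I11 <- fit$info
  I12v <- colSums(gc * fit$vinc_event)
  I22v <- colSums(gc^2 * fit$vinc_event)
  I12 <- unpack_sym(I12v, p, fit$pr)
  I22 <- unpack_sym(I22v, p, fit$pr)

  K <- solve(I11, I12)              # I11^{-1} I12
  chisq <- numeric(p + 1L)
  df <- c(rep(1L, p), p)
  for (k in seq_len(p)) {
    denom <- I22[k, k] - drop(crossprod(I12[, k], K[, k]))
    chisq[k] <- u2[k]^2 / denom
  }
  Schur <- I22 - crossprod(I12, K)
  Schur <- (Schur + t(Schur)) / 2
  chisq[p + 1L] <- drop(crossprod(u2, solve(Schur, u2)))
  pv <- stats::pchisq(chisq, df, lower.tail = FALSE)
  tab <- cbind(chisq = chisq, df = df, p = pv)
  rownames(tab) <- c(fit$covariates, "GLOBAL")

  warnings <- character()
  for (cv in fit$covariates) {
    if (is_time_varying(fit, cv)) {
      ratio <- riskset_variance_ratio(fit, cv)
      if (is.finite(ratio) && ratio > var_ratio) {
        warnings <- c(warnings, sprintf(
          "risk-set variance of time-varying covariate '%s' varies by factor %.1f across time terciles; the scaled-Schoenfeld test assumes it constant and may be unreliable",
          cv, ratio))
      }
    }
  }
  for (w in warnings) warning(w, call. = FALSE)

  structure(list(
    table = tab,
    transform = transform,
    time = fit$schoenfeld_times,
    x = g_raw,
    scaled = scaled_schoenfeld(fit),
    coefficients = fit$coefficients,
    n_events = D,
    warnings = warnings
  ), class = "zph_result")
}

# Ratio of max/min pooled risk-set variance of a covariate across event-time
# terciles (death-weighted).
riskset_variance_ratio <- function(fit, covariate) {
  J <- length(fit$event_times)
  if (J < 3L) return(NA_real_)
  x <- fit$episodes[[covariate]] - fit$xcen[covariate]
  N0 <- drop(risk_sums(matrix(rep(1, fit$n)), fit$lo, fit$hi, J))
  N1 <- drop(risk_sums(matrix(x), fit$lo, fit$hi, J))
  N2 <- drop(risk_sums(matrix(x^2), fit$lo, fit$hi, J))
  vx <- N2 / N0 - (N1 / N0)^2
  terc <- cut(seq_len(J), breaks = 3L, labels = FALSE)
  pooled <- vapply(split(seq_len(J), terc), function(ix) {
    stats::weighted.mean(vx[ix], fit$d[ix])
  }, numeric(1))
  if (any(pooled <= 0)) return(Inf)
  max(pooled) / min(pooled)
}

#' @export
print.zph_result <- function(x, digits = 4, ...) {
  cat("Scaled Schoenfeld residual test of proportional hazards ",
      "(transform: ", x$transform, ")\n", sep = "")
  print(round(x$table, digits))
  if (length(x$warnings)) {
    cat("Warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Gated interpretation of a scaled-Schoenfeld test
#'
#' Screening convention: the global test is consulted first; only when its
#' p-value is below `threshold` are the individual covariate tests used to
#' identify the source(s) of nonproportionality.
#'
#' @param result a [zph_test()] result.
#' @param threshold screening threshold (default 0.30).
#' @return list with `global_p`, `screened` (was the global gate passed),
#'   and `flagged` (covariates with individual p below threshold; empty
#'   when the gate is not passed).
#' @export
interpret_zph <- function(result, threshold = 0.30) {
  stopifnot(inherits(result, "zph_result"))
  tab <- result$table
  global_p <- tab["GLOBAL", "p"]
  screened <- global_p < threshold
  flagged <- character()
  if (screened) {
    indiv <- tab[rownames(tab) != "GLOBAL", , drop = FALSE]
    flagged <- rownames(indiv)[indiv[, "p"] < threshold]
  }
  list(global_p = unname(global_p), screened = screened, flagged = flagged)
}

#' Smoothed beta(t) curve from scaled Schoenfeld residuals
#'
#' Local linear regression (loess, degree 1) of a covariate's scaled
#' Schoenfeld residuals on transformed event time, with a pointwise
#' plus/minus 2 standard error band.  The smooth visualizes how the
#' regression coefficient varies with time; under proportional hazards it
#' is flat at the fitted coefficient.
#'
#' @param result a [zph_test()] result.
#' @param covariate covariate name.
#' @param span loess span in `(0, 1]` (default 0.75).
#' @return data frame of class `beta_t_curve` with columns `time`
#'   (event time), `x` (transformed time), `beta`, `lower`, `upper`.
#' @export
smooth_beta_t <- function(result, covariate, span = 0.75) {
  stopifnot(inherits(result, "zph_result"))
  if (!is.numeric(span) || span <= 0 || span > 1) {
    stop("span must lie in (0, 1]")
  }
  if (!covariate %in% colnames(result$scaled)) {
    stop("covariate '", covariate, "' not in result")
  }
  y <- result$scaled[, covariate]
  x <- result$x
  lf <- stats::loess(y ~ x, span = span, degree = 1, family = "gaussian",
                     control = stats::loess.control(surface = "direct",
                                                    statistics = "exact"))
  prd <- stats::predict(lf, se = TRUE)
  out <- data.frame(time = result$time, x = x, beta = prd$fit,
                    lower = prd$fit - 2 * prd$se.fit,
                    upper = prd$fit + 2 * prd$se.fit)
  out <- out[order(out$x), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "covariate") <- covariate
  attr(out, "span") <- span
  class(out) <- c("beta_t_curve", "data.frame")
  out
}

#' @export
plot.beta_t_curve <- function(x, ...) {
  graphics::plot(x$time, x$beta, type = "l",
                 ylim = range(x$lower, x$upper),
                 xlab = "age (years)",
                 ylab = paste0("beta(t) for ", attr(x, "covariate")), ...)
  graphics::lines(x$time, x$lower, lty = 2)
  graphics::lines(x$time, x$upper, lty = 2)
  invisible(x)
}
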