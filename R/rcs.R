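default_knot_percentiles <- function(k) {
  switch(as.character(k),
         "3" = c(5, 50, 95),
         "4" = c(5, 35, 65, 95),
         "5" = c(5, 27.5, 50, 72.5, 95),
         stop("no default knot percentiles for k = ", k,
              "; supply `percentiles`"))
}

#' Place restricted cubic spline knots at event-age percentiles
#'
#' Knots are placed at empirical percentiles of the event ages only
#' (censored ages are excluded); the default for 3 knots is the 5th, 50th,
#' and 95th percentile, which keeps the number of spline coefficients small
#' when events are limited.  The quantile convention is linear interpolation
#' between order statistics.
#'
#' @param event_ages ages at which events occurred.
#' @param k number of knots (>= 3).
#' @param percentiles optional percentile vector of length `k`; defaults
#'   follow standard placements for k = 3, 4, 5.
#' @return Object of class `rcs_basis`: `knots` (strictly increasing ages)
#'   and `scale` (the squared knot range used to normalize the cubic
#'   terms).
#' @export
place_knots <- function(event_ages, k = 3L, percentiles = NULL) {
  k <- as.integer(k)
  if (k < 3L) stop("a restricted cubic spline needs k >= 3 knots")
  event_ages <- event_ages[is.finite(event_ages)]
  if (length(unique(event_ages)) < k) {
    stop("need at least ", k, " distinct event ages to place ", k, " knots")
  }
  if (is.null(percentiles)) percentiles <- default_knot_percentiles(k)
  if (length(percentiles) != k) {
    stop("`percentiles` must have length k")
  }
  knots <- unname(stats::quantile(event_ages, percentiles / 100, type = 7))
  if (any(diff(knots) <= 0)) {
    stop("duplicate knots: event-age distribution too degenerate for k = ",
         k)
  }
  structure(list(knots = knots, scale = (knots[k] - knots[1L])^2),
            class = "rcs_basis")
}

#' Evaluate the restricted cubic spline basis
#'
#' Harrell-form basis with `k - 1` columns: the first is the identity
#' (linear term); the remaining `k - 2` are restricted truncated-cubic
#' terms, scaled by the squared knot range so all columns have comparable
#' magnitude.  The implied function of any coefficient combination is
#' linear beyond the boundary knots and has continuous value, first, and
#' second derivatives at the knots.
#'
#' @param t evaluation times (finite).
#' @param basis an [place_knots()] object.
#' @return length(t) x (k-1) matrix.
#' @export
rcs_basis_eval <- function(t, basis) {
  stopifnot(inherits(basis, "rcs_basis"))
  if (!all(is.finite(t))) stop("t must be finite")
  K <- basis$knots
  k <- length(K)
  tp <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(t), k - 1L)
  B[, 1L] <- t
  for (j in seq_len(k - 2L)) {
    B[, j + 1L] <- (tp(t - K[j]) -
                      tp(t - K[k - 1L]) * (K[k] - K[j]) / (K[k] - K[k - 1L]) +
                      tp(t - K[k]) * (K[k - 1L] - K[j]) / (K[k] - K[k - 1L])
                    ) / basis$scale
  }
  colnames(B) <- c("t", if (k > 2L) paste0("rcs", seq_len(k - 2L)))
  B
}

#' Fit a Cox model with a restricted-cubic-spline time-by-covariate
#' interaction
#'
#' Models the covariate effect as `beta(t) * x` with
#' `beta(t) = theta_0 + theta_1 b_1(t) + ... + theta_{k-1} b_{k-1}(t)`
#' in the RCS basis (`theta_0` is the covariate main effect, `theta_1` the
#' linear time interaction, the rest the nonlinear terms).  Episodes are
#' split at every distinct event time and the basis is evaluated at the
#' episode stop, so each risk set sees the interaction evaluated exactly at
#' the event time; because the covariate value enters from the episode it
#' is current at that time, the construction is valid for time-varying
#' covariates as well (an extension of the fixed-covariate spline
#' methodology, flagged via `time_varying`).
#'
#' @param episodes episode data frame.
#' @param covariate covariate of interest.
#' @param adjust character vector of adjustment covariates (fixed effects,
#'   no time interaction).
#' @param basis optional [place_knots()] basis; by default knots are placed
#'   from the event ages with `k` knots.
#' @param k number of knots when `basis` is not supplied.
#' @param delta covariate contrast for reported hazard ratios (e.g. 5 for
#'   "per 5 years"); must be positive.  The fitted coefficients are per
#'   unit of the covariate; `delta` scales [hr_curve()] output.
#' @param ties,control passed to [fit_cox()].
#' @return Object of class `rcs_fit` with `theta` (time-interaction
#'   coefficients), `var_theta`, `adjust_coef`, `basis`, `delta`, `loglik`,
#'   `AIC` (`-2 loglik + 2 * n free parameters`), `fit` (the underlying
#'   `cox_fit`), `follow_up` (time range of the episode data) and
#'   `time_varying`.
#' @export
fit_rcs_cox <- function(episodes, covariate, adjust = character(),
                        basis = NULL, k = 3L, delta = 1,
                        ties = c("breslow", "efron"),
                        control = cox_control()) {
  ties <- match.arg(ties)
  if (!is.numeric(delta) || delta <= 0) stop("delta must be positive")
  ep <- validate_episodes(episodes, c(covariate, adjust))
  event_ages <- ep$stop[ep$event == 1L]
  if (is.null(basis)) basis <- place_knots(event_ages, k = k)
  follow_up <- c(min(ep$start), max(ep$stop))
  if (basis$knots[1L] < follow_up[1L] ||
      basis$knots[length(basis$knots)] > follow_up[2L]) {
    stop("basis knots fall outside the follow-up range")
  }
  tt <- sort(unique(event_ages))
  ep2 <- split_episodes_at(ep, tt)
  B <- rcs_basis_eval(ep2$stop, basis)
  x <- as.numeric(ep2[[covariate]])
  int_names <- c(covariate, paste0(covariate, ":", colnames(B)))
  for (m in seq_len(ncol(B))) ep2[[int_names[m + 1L]]] <- x * B[, m]
  fit <- fit_cox(ep2, c(adjust, int_names), ties = ties, control = control)
  kk <- length(basis$knots)
  theta <- fit$coefficients[int_names]
  v_idx <- match(int_names, fit$covariates)
  structure(list(
    covariate = covariate,
    adjust = adjust,
    adjust_coef = fit$coefficients[adjust],
    theta = theta,
    var_theta = fit$var[v_idx, v_idx, drop = FALSE],
    var = fit$var,
    basis = basis,
    delta = delta,
    loglik = fit$loglik[2L],
    AIC = -2 * fit$loglik[2L] + 2 * length(fit$coefficients),
    n_events = fit$n_events,
    follow_up = follow_up,
    time_varying = is_time_varying(fit, covariate),
    int_names = int_names,
    fit = fit
  ), class = "rcs_fit")
}

#' Evaluate the fitted time-varying coefficient beta(t)
#'
#' @param rcsfit an [fit_rcs_cox()] object.
#' @param t times (years).
#' @return per-unit `beta(t)` values (not scaled by `delta`).
#' @export
beta_t <- function(rcsfit, t) {
  stopifnot(inherits(rcsfit, "rcs_fit"))
  drop(cbind(1, rcs_basis_eval(t, rcsfit$basis)) %*% rcsfit$theta)
}

#' @export
print.rcs_fit <- function(x, digits = 4, ...) {
  k <- length(x$basis$knots)
  cat("Restricted cubic spline time-interaction Cox model for '",
      x$covariate, "' (", k, " knots at ",
      paste(format(x$basis$knots, digits = 3), collapse = ", "),
      ")\n", sep = "")
  if (isTRUE(x$time_varying)) {
    cat("  covariate is time-varying (counting-process extension)\n")
  }
  cat("  theta (constant, linear, nonlinear...):\n")
  print(round(x$theta, digits))
  cat("  AIC:", format(x$AIC, digits = digits + 2), "\n")
  invisible(x)
}

#' Hierarchical association / nonconstancy / nonlinearity tests
#'
#' Wald tests of nested null hypotheses on the time-interaction
#' coefficients of an RCS fit with `k` knots: association tests all `k`
#' parameters jointly (df `k`); nonconstancy tests the `k - 1` time terms
#' (df `k - 1`, a violation of proportional hazards when rejected);
#' nonlinearity tests the `k - 2` nonlinear terms (df `k - 2`).  Each later
#' test is performed only when the earlier null was rejected at `alpha`
#' (set `gated = FALSE` to compute all three regardless); tests not
#' performed are reported as N/A.
#'
#' @param rcsfit an [fit_rcs_cox()] object.
#' @param alpha gate level (default 0.05).
#' @param gated apply the hierarchy gate.
#' @return Object of class `rcs_hierarchy`: a list with elements
#'   `association`, `nonconstant`, `nonlinear`, each containing
#'   `statistic`, `df`, `p_value`, `performed`.
#' @export
hierarchical_tests <- function(rcsfit, alpha = 0.05, gated = TRUE) {
  stopifnot(inherits(rcsfit, "rcs_fit"))
  V <- rcsfit$var_theta
  if (anyNA(V)) stop("missing covariance in fit")
  th <- rcsfit$theta
  k <- length(rcsfit$basis$knots)
  one <- function(idx) {
    stat <- wald_quadform(th[idx], V[idx, idx, drop = FALSE])
    list(statistic = stat, df = length(idx),
         p_value = stats::pchisq(stat, length(idx), lower.tail = FALSE),
         performed = TRUE)
  }
  na_test <- function(df) {
    list(statistic = NA_real_, df = df, p_value = NA_real_,
         performed = FALSE)
  }
  assoc <- one(seq_len(k))
  noncon <- if (!gated || assoc$p_value < alpha) {
    one(2:k)
  } else {
    na_test(k - 1L)
  }
  nonlin <- if (!gated || (noncon$performed &&
                           isTRUE(noncon$p_value < alpha))) {
    one(3:k)
  } else {
    na_test(k - 2L)
  }
  structure(list(association = assoc, nonconstant = noncon,
                 nonlinear = nonlin, alpha = alpha, gated = gated,
                 covariate = rcsfit$covariate),
            class = "rcs_hierarchy")
}

#' @export
print.rcs_hierarchy <- function(x, digits = 4, ...) {
  cat("Hierarchical RCS tests for '", x$covariate, "' (gate alpha = ",
      x$alpha, if (!x$gated) ", gating disabled", ")\n", sep = "")
  for (nm in c("association", "nonconstant", "nonlinear")) {
    tt <- x[[nm]]
    if (tt$performed) {
      cat(sprintf("  %-12s chisq = %s, df = %d, p = %s\n", nm,
                  format(tt$statistic, digits = digits), tt$df,
                  format(tt$p_value, digits = digits)))
    } else {
      cat(sprintf("  %-12s N/A (prior null not rejected), df = %d\n",
                  nm, tt$df))
    }
  }
  invisible(x)
}

#' Select the number of knots by AIC
#'
#' Fits the RCS time-interaction model for each candidate knot count and
#' returns the fit with the lowest AIC; exact ties are broken toward fewer
#' knots.  Candidates that fail (too few distinct event ages,
#' nonconvergence) are skipped; if all fail the last error is propagated.
#'
#' @inheritParams fit_rcs_cox
#' @param candidate_k candidate knot counts (default 3, 4, 5).
#' @return The best `rcs_fit`, with an `aic_table` attribute listing every
#'   candidate.
#' @export
select_knots_by_aic <- function(episodes, covariate, adjust = character(),
                                candidate_k = c(3L, 4L, 5L), delta = 1,
                                ties = c("breslow", "efron"),
                                control = cox_control()) {
  ties <- match.arg(ties)
  candidate_k <- sort(unique(as.integer(candidate_k)))
  best <- NULL
  last_err <- NULL
  tab <- data.frame(k = candidate_k, AIC = NA_real_,
                    error = NA_character_)
  for (i in seq_along(candidate_k)) {
    res <- tryCatch(
      fit_rcs_cox(episodes, covariate, adjust, k = candidate_k[i],
                  delta = delta, ties = ties, control = control),
      error = function(e) e)
    if (inherits(res, "error")) {
      last_err <- res
      tab$error[i] <- conditionMessage(res)
      next
    }
    tab$AIC[i] <- res$AIC
    if (is.null(best) || res$AIC < best$AIC) best <- res
  }
  if (is.null(best)) stop(last_err)
  attr(best, "aic_table") <- tab
  best
}

#' Hazard ratio as a function of time, with confidence band
#'
#' `HR(t) = exp(delta * beta(t))` for the fitted RCS coefficient function,
#' with a pointwise delta-method band on the linear predictor:
#' `exp(delta * (beta(t) +/- z * SE(t)))`, `SE(t)^2` the quadratic form of
#' the basis vector with the theta covariance.  Ages outside the follow-up
#' range are extrapolated linearly (the spline is linear beyond the
#' boundary knots) and flagged, with a warning.
#'
#' @param rcsfit an [fit_rcs_cox()] object.
#' @param ages evaluation grid (years).
#' @param conf_level confidence level for the band (default 0.95).
#' @return data frame of class `hr_curve`: `age`, `beta` (per unit),
#'   `hr`, `lower`, `upper`, `extrapolated`.
#' @export
hr_curve <- function(rcsfit, ages, conf_level = 0.95) {
  stopifnot(inherits(rcsfit, "rcs_fit"))
  extrap <- ages < rcsfit$follow_up[1L] | ages > rcsfit$follow_up[2L]
  if (any(extrap)) {
    warning("grid age(s) outside the follow-up range [",
            format(rcsfit$follow_up[1L], digits = 3), ", ",
            format(rcsfit$follow_up[2L], digits = 3),
            "]: extrapolating linearly (tail-linearity of the spline)")
  }
  B1 <- cbind(1, rcs_basis_eval(ages, rcsfit$basis))
  bt <- drop(B1 %*% rcsfit$theta)
  se <- sqrt(rowSums((B1 %*% rcsfit$var_theta) * B1))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  dl <- rcsfit$delta
  out <- data.frame(age = ages, beta = bt,
                    hr = exp(dl * bt),
                    lower = exp(dl * bt - z * dl * se),
                    upper = exp(dl * bt + z * dl * se),
                    extrapolated = extrap)
  attr(out, "delta") <- dl
  attr(out, "covariate") <- rcsfit$covariate
  class(out) <- c("hr_curve", "data.frame")
  out
}

#' @export
plot.hr_curve <- function(x, log = "y", ...) {
  graphics::plot(x$age, x$hr, type = "l", log = log,
                 ylim = range(x$lower, x$upper),
                 xlab = "age (years)",
                 ylab = paste0("hazard ratio (delta = ",
                               attr(x, "delta"), ")"), ...)
  graphics::lines(x$age, x$lower, lty = 2)
  graphics::lines(x$age, x$upper, lty = 2)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
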