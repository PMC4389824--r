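#' Control parameters for the Cox partial likelihood optimizer
#'
#' Newton-Raphson with step-halving; iteration stops when the largest score
#' component falls below `tol`.  Estimates wandering beyond `beta_max` in
#' absolute value are reported as nonconvergence (monotone likelihood).
#'
#' @param tol convergence tolerance on `max |score|`.
#' @param max_iter maximum Newton iterations.
#' @param beta_max divergence guard on coefficients.
#' @export
cox_control <- function(tol = 1e-8, max_iter = 50L, beta_max = 20) {
  stopifnot(tol > 0, max_iter >= 1, beta_max > 0)
  list(tol = tol, max_iter = as.integer(max_iter), beta_max = beta_max)
}

#' Fit a Cox model on counting-process episodes
#'
#' Maximizes the Cox partial likelihood over risk sets defined by
#' `start < t <= stop`, so delayed entry (left truncation) and time-varying
#' covariates represented as episodes are handled by construction.  Ties are
#' handled by the Breslow (default) or Efron approximation.  The returned
#' fit carries everything the nonproportional-hazards diagnostics consume:
#' per-event Schoenfeld residuals, per-event-time information increments,
#' the Breslow baseline hazard, and per-subject martingale residuals.
#'
#' @param episodes episode data frame (see [expand_counting_process()]).
#' @param covariates character vector of covariate column names.
#' @param ties `"breslow"` or `"efron"`.
#' @param control see [cox_control()].
#' @return An object of class `cox_fit` with components `coefficients`,
#'   `var` (inverse observed information), `info`, `loglik` (length 2:
#'   null and maximized), `score`, `iter`, `converged`, `n`, `n_subjects`,
#'   `n_events`, `event_times`, `d` (death counts per distinct time),
#'   `schoenfeld` (events x covariates, ordered by event time),
#'   `schoenfeld_times`, `cumhaz` (Breslow baseline), `martingale`
#'   (named per-subject residuals), and bookkeeping needed by
#'   [supremum_test()] and [zph_test()].
#' @export
fit_cox <- function(episodes, covariates, ties = c("breslow", "efron"),
                    control = cox_control()) {
  ties <- match.arg(ties)
  if (length(covariates) < 1L) stop("at least one covariate is required")
  ep <- validate_episodes(episodes, covariates)
  X <- do.call(cbind, lapply(ep[covariates], as.numeric))
  colnames(X) <- covariates
  p <- ncol(X)
  event <- ep$event == 1L
  D <- sum(event)
  if (D == 0L) stop("zero events: cannot fit a partial likelihood")

  te <- sort(unique(ep$stop[event]))
  J <- length(te)
  lo <- findInterval(ep$start, te)
  hi <- findInterval(ep$stop, te)
  xcen <- colMeans(X)
  Xc <- sweep(X, 2L, xcen, "-")
  pr <- sym_pairs(p)
  npr <- nrow(pr)
  X2 <- Xc[, pr[, 1L], drop = FALSE] * Xc[, pr[, 2L], drop = FALSE]
  ev_j <- match(ep$stop[event], te)
  d <- tabulate(ev_j, J)
  sum_x_ev <- rowsum(Xc[event, , drop = FALSE], ev_j)

  derivs <- function(beta) {
    eta <- drop(Xc %*% beta)
    w <- exp(eta)
    S0 <- drop(risk_sums(matrix(w), lo, hi, J))
    S1 <- risk_sums(Xc * w, lo, hi, J)
    S2 <- risk_sums(X2 * w, lo, hi, J)
    if (any(S0 <= 0)) return(list(ll = -Inf))
    if (ties == "breslow" || max(d) == 1L) {
      xbar <- S1 / S0
      ll <- sum(eta[event]) - sum(d * log(S0))
      U <- colSums(sum_x_ev) - colSums(d * xbar)
      xbar2 <- xbar[, pr[, 1L], drop = FALSE] * xbar[, pr[, 2L], drop = FALSE]
      Vinc <- d * (S2 / S0 - xbar2)
      Ivec <- colSums(Vinc)
    } else {
      wev <- w[event]
      S0d <- drop(rowsum(wev, ev_j))
      S1d <- rowsum((Xc * w)[event, , drop = FALSE], ev_j)
      S2d <- rowsum((X2 * w)[event, , drop = FALSE], ev_j)
      ll <- sum(eta[event])
      U <- colSums(sum_x_ev)
      Vinc <- matrix(0, J, npr)
      xbar <- matrix(0, J, p)
      for (j in seq_len(J)) {
        phi <- (seq_len(d[j]) - 1) / d[j]
        s0l <- S0[j] - phi * S0d[j]
        if (any(s0l <= 0)) return(list(ll = -Inf))
        s1l <- matrix(S1[j, ], d[j], p, byrow = TRUE) - outer(phi, S1d[j, ])
        s2l <- matrix(S2[j, ], d[j], npr, byrow = TRUE) - outer(phi, S2d[j, ])
        ml <- s1l / s0l
        ll <- ll - sum(log(s0l))
        U <- U - colSums(ml)
        m2 <- ml[, pr[, 1L], drop = FALSE] * ml[, pr[, 2L], drop = FALSE]
        Vinc[j, ] <- colSums(s2l / s0l - m2)
        xbar[j, ] <- colMeans(ml)
      }
      Ivec <- colSums(Vinc)
    }
    list(ll = ll, U = U, I = unpack_sym(Ivec, p, pr), S0 = S0,
         xbar = xbar, Vinc = Vinc)
  }

  beta <- numeric(p)
  dv <- derivs(beta)
  ll_null <- dv$ll
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    if (max(abs(dv$U)) < control$tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(dv$I, dv$U), error = function(e) {
      stop("singular information matrix: a covariate has no contrast ",
           "within risk sets", call. = FALSE)
    })
    beta_new <- beta + step
    dv_new <- derivs(beta_new)
    halv <- 0L
    while ((!is.finite(dv_new$ll) || dv_new$ll < dv$ll - 1e-12) &&
           halv < 30L) {
      beta_new <- (beta + beta_new) / 2
      dv_new <- derivs(beta_new)
      halv <- halv + 1L
    }
    beta <- beta_new
    dv <- dv_new
    if (any(abs(beta) > control$beta_max)) {
      stop("nonconvergence: infinite estimate (a covariate may perfectly ",
           "separate events)", call. = FALSE)
    }
  }
  if (!converged && max(abs(dv$U)) < control$tol) converged <- TRUE
  if (!converged) {
    stop("nonconvergence: score not reduced below tolerance in ",
         control$max_iter, " iterations", call. = FALSE)
  }
  if (any(abs(beta) > control$beta_max * 0.75)) {
    # a monotone likelihood flattens out: the score can pass the tolerance
    # while the estimate runs away, so a huge coefficient is diagnostic
    stop("nonconvergence: infinite estimate (a covariate may perfectly ",
         "separate events)", call. = FALSE)
  }
  var <- tryCatch(solve(dv$I), error = function(e) {
    stop("singular information matrix at the optimum", call. = FALSE)
  })
  var <- (var + t(var)) / 2
  names(beta) <- covariates
  dimnames(var) <- list(covariates, covariates)

  # Schoenfeld residuals per individual event, ordered by event time
  eo <- which(event)[order(ep$stop[event])]
  r_times <- ep$stop[eo]
  jj <- match(r_times, te)
  sch <- Xc[eo, , drop = FALSE] - dv$xbar[jj, , drop = FALSE]
  dimnames(sch) <- list(NULL, covariates)
  # per-event share of the information increment (ties split evenly)
  vinc_event <- dv$Vinc[jj, , drop = FALSE] / d[jj]
  Icum <- apply(vinc_event, 2L, cumsum)
  if (is.null(dim(Icum))) Icum <- matrix(Icum, nrow = 1L)

  # Breslow baseline hazard and per-subject martingale residuals
  h <- d / dv$S0
  Hc <- c(0, cumsum(h))
  acc_ep <- exp(drop(Xc %*% beta)) * (Hc[hi + 1L] - Hc[lo + 1L])
  sid <- as.character(ep$subject_id)
  acc <- rowsum(acc_ep, sid)
  evs <- rowsum(as.numeric(event), sid)
  mart <- drop(evs - acc)
  names(mart) <- rownames(acc)

  structure(list(
    coefficients = beta,
    var = var,
    info = dv$I,
    loglik = c(ll_null, dv$ll),
    score = dv$U,
    iter = iter,
    converged = converged,
    ties = ties,
    n = nrow(ep),
    n_subjects = length(unique(sid)),
    n_events = D,
    event_times = te,
    d = d,
    schoenfeld = sch,
    schoenfeld_times = r_times,
    schoenfeld_subject = sid[eo],
    vinc_event = vinc_event,
    Icum = Icum,
    pr = pr,
    S0 = dv$S0,
    xbar = dv$xbar,
    cumhaz = data.frame(time = te, hazard = h, cumhaz = cumsum(h)),
    martingale = mart,
    covariates = covariates,
    xcen = xcen,
    lo = lo,
    hi = hi,
    episodes = ep
  ), class = "cox_fit")
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$var

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik[2L], df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat("Cox counting-process fit (", x$ties, " ties), ",
      x$n_subjects, " subjects, ", x$n_events, " events\n", sep = "")
  se <- sqrt(diag(x$var))
  z <- x$coefficients / se
  tab <- cbind(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
               `se(coef)` = se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  print(round(tab, digits))
  cat("log partial likelihood:", format(x$loglik[2L], digits = digits + 2),
      " (null ", format(x$loglik[1L], digits = digits + 2), ")\n", sep = "")
  invisible(x)
}

#' Residuals from a Cox counting-process fit
#'
#' Martingale residuals are per subject: observed event count minus the
#' model-estimated cumulative hazard accrued over the subject's episodes
#' (Breslow baseline).  Schoenfeld residuals are per event: the event
#' subject's covariate value minus the risk-set weighted mean, ordered by
#' event time; scaled Schoenfeld residuals are the Grambsch-Therneau
#' transformation that approximates beta(t) (see [scaled_schoenfeld()]).
#'
#' @param object a `cox_fit`.
#' @param type residual type.
#' @param ... unused.
#' @export
residuals.cox_fit <- function(object,
                              type = c("martingale", "schoenfeld",
                                       "scaled_schoenfeld"), ...) {
  type <- match.arg(type)
  switch(type,
         martingale = martingale_residuals(object),
         schoenfeld = schoenfeld_residuals(object),
         scaled_schoenfeld = scaled_schoenfeld(object))
}

#' @rdname residuals.cox_fit
#' @param fit a converged `cox_fit`.
#' @export
martingale_residuals <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  fit$martingale
}

#' @rdname residuals.cox_fit
#' @export
schoenfeld_residuals <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  fit$schoenfeld
}

# Does `covariate` vary within any subject across episodes?
is_time_varying <- function(fit, covariate) {
  x <- fit$episodes[[covariate]]
  sid <- as.character(fit$episodes$subject_id)
  any(vapply(split(x, sid), function(v) length(unique(v)) > 1L, logical(1)))
}
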