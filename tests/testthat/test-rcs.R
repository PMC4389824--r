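test_that("knots land on independently computed event-age percentiles", {
  ages <- 1:20
  b <- place_knots(ages, k = 3)
  # linear-interpolation quantiles computed from first principles:
  # h = (n-1) p + 1, value = x[floor(h)] + (h - floor(h)) (x[ceil(h)] - ...)
  manual <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[pmin(lo + 1, length(x))] - x[lo])
  }
  expect_equal(b$knots, manual(ages, c(0.05, 0.5, 0.95)),
               tolerance = 1e-12)
  expect_equal(b$knots, c(1.95, 10.5, 19.05), tolerance = 1e-12)
  expect_equal(b$scale, (19.05 - 1.95)^2)
  expect_error(place_knots(rep(2, 10), k = 3), "distinct event ages")
  expect_error(place_knots(c(1, 1, 1, 1, 1, 1, 1, 1, 2, 3), k = 3),
               "duplicate knots")
  expect_error(place_knots(1:20, k = 2), "k >= 3")
})

test_that("the spline basis is restricted: zero below the first knot,
           linear beyond the last", {
  b <- structure(list(knots = c(2, 6, 10), scale = 64),
                 class = "rcs_basis")
  B <- rcs_basis_eval(c(0, 1, 2), b)
  expect_equal(B[, 1], c(0, 1, 2))
  expect_equal(B[, 2], c(0, 0, 0))
  # third differences vanish on an equally spaced grid past the last knot
  tt <- seq(10, 20, by = 0.5)
  Bt <- rcs_basis_eval(tt, b)
  expect_equal(max(abs(diff(Bt[, 2], differences = 3))), 0,
               tolerance = 1e-9)
  # closed-form truncated-power value at the middle knot:
  # ((6-2)^3 - 0 + 0) / (10-2)^2 = 1
  expect_equal(unname(rcs_basis_eval(6, b)[1, 2]), 1, tolerance = 1e-12)
  # second derivative is continuous at each knot (one-sided second
  # differences from the two sides agree)
  h <- 1e-4
  for (kn in b$knots) {
    fl <- rcs_basis_eval(kn - c(2, 1, 0) * h, b)[, 2]
    fr <- rcs_basis_eval(kn + c(0, 1, 2) * h, b)[, 2]
    d2l <- (fl[3] - 2 * fl[2] + fl[1]) / h^2
    d2r <- (fr[3] - 2 * fr[2] + fr[1]) / h^2
    expect_equal(d2l, d2r, tolerance = 1e-2)
  }
  expect_error(rcs_basis_eval(c(1, NA), b), "finite")
})

sim_episodes <- function(name = "null", n = 300, seed = 81) {
  sim <- simulate_cohort(default_scenario(name, n), seed)
  expand_counting_process(exclude_left_censored(sim$subjects)$retained)
}

test_that("the RCS model nests the standard Cox model", {
  ep <- sim_episodes()
  rf <- fit_rcs_cox(ep, "x", k = 3)
  f0 <- fit_cox(ep, "x")
  # dropping all time terms reproduces the standard fit exactly
  ep2 <- etiohet:::split_episodes_at(ep, sort(unique(ep$stop[ep$event == 1])))
  f0b <- fit_cox(ep2, "x")
  expect_equal(coef(f0), coef(f0b), tolerance = 1e-8)
  # nesting: the full model's likelihood dominates; LR stat >= 0
  expect_gte(rf$loglik, f0$loglik[2] - 1e-10)
  expect_equal(rf$AIC, -2 * rf$loglik + 2 * length(rf$theta))
})

test_that("delta rescales the reported curve, not the fit", {
  ep <- sim_episodes(seed = 82)
  r1 <- fit_rcs_cox(ep, "x", delta = 1)
  r5 <- fit_rcs_cox(ep, "x", delta = 5)
  expect_equal(r1$theta, r5$theta, tolerance = 1e-12)
  ages <- c(2, 5, 8)
  h1 <- hr_curve(r1, ages)
  h5 <- hr_curve(r5, ages)
  expect_equal(h5$hr, h1$hr^5, tolerance = 1e-10)
  expect_equal(h5$beta, h1$beta, tolerance = 1e-12)
  expect_error(fit_rcs_cox(ep, "x", delta = -1), "positive")
})

test_that("hierarchical tests have the k, k-1, k-2 df structure and the
           Wald statistics match an independent quadratic form", {
  ep <- sim_episodes(seed = 83)
  rf <- fit_rcs_cox(ep, "x", k = 3)
  ht <- hierarchical_tests(rf, gated = FALSE)
  expect_equal(ht$association$df, 3L)
  expect_equal(ht$nonconstant$df, 2L)
  expect_equal(ht$nonlinear$df, 1L)
  th <- rf$theta
  V <- rf$var_theta
  expect_equal(ht$association$statistic,
               drop(t(th) %*% solve(V) %*% th), tolerance = 1e-10)
  expect_equal(ht$nonconstant$statistic,
               drop(t(th[2:3]) %*% solve(V[2:3, 2:3]) %*% th[2:3]),
               tolerance = 1e-10)
  expect_equal(ht$nonlinear$statistic, unname(th[3]^2 / V[3, 3]),
               tolerance = 1e-10)
  rf4 <- fit_rcs_cox(ep, "x", k = 4)
  ht4 <- hierarchical_tests(rf4, gated = FALSE)
  expect_equal(c(ht4$association$df, ht4$nonconstant$df,
                 ht4$nonlinear$df), c(4L, 3L, 2L))
})

test_that("the hierarchy gate suppresses later tests", {
  ep <- sim_episodes(seed = 84)   # null effect: association should be weak
  rf <- fit_rcs_cox(ep, "x", k = 3)
  ht_all <- hierarchical_tests(rf, gated = FALSE)
  if (ht_all$association$p_value >= 0.05) {
    ht <- hierarchical_tests(rf, alpha = 0.05, gated = TRUE)
    expect_false(ht$nonconstant$performed)
    expect_false(ht$nonlinear$performed)
    expect_true(is.na(ht$nonconstant$p_value))
  }
  # with an absurdly liberal gate everything runs
  ht2 <- hierarchical_tests(rf, alpha = 1, gated = TRUE)
  expect_true(ht2$nonconstant$performed)
  expect_true(ht2$nonlinear$performed)
})

test_that("AIC knot selection returns the single viable candidate and
           tracks the minimum", {
  # only 3 distinct event ages: k = 4, 5 must fail, k = 3 is returned
  ep <- data.frame(subject_id = sprintf("s%02d", 1:30), start = 0,
                   stop = rep(c(2, 4, 6, 7.5, 9), 6),
                   event = rep(c(1L, 1L, 1L, 0L, 0L), 6),
                   x = rnorm(30, sd = 0.5) + rep(c(0, 1, 0, 1, 0), 6))
  best <- select_knots_by_aic(ep, "x", candidate_k = c(3, 4, 5))
  expect_equal(length(best$basis$knots), 3L)
  tab <- attr(best, "aic_table")
  expect_true(all(!is.na(tab$error[tab$k > 3])))
  # with a richer event-age distribution the chosen AIC is the minimum
  ep2 <- sim_episodes("nhw-like", 400, seed = 85)
  best2 <- select_knots_by_aic(ep2, "nhw", candidate_k = c(3, 4, 5))
  tab2 <- attr(best2, "aic_table")
  expect_equal(best2$AIC, min(tab2$AIC, na.rm = TRUE))
})

test_that("HR(t) curves: degenerate spline, unit crossing, extrapolation,
           and delta-method bands against a sampling oracle", {
  ep <- sim_episodes("nhw-like", 600, seed = 86)
  rf <- fit_rcs_cox(ep, "nhw", k = 3)
  # constant-beta degenerate version: only theta_0 nonzero
  rfc <- rf
  rfc$theta[2:3] <- 0
  rfc$var_theta[, 2:3] <- 0
  rfc$var_theta[2:3, ] <- 0
  hc <- hr_curve(rfc, c(2, 5, 8))
  expect_equal(hc$hr, rep(unname(exp(rfc$theta[1])), 3),
               tolerance = 1e-12)
  expect_equal(hc$upper / hc$lower,
               rep((hc$upper / hc$lower)[1], 3), tolerance = 1e-10)
  # HR is exactly 1 where the fitted beta(t) crosses zero
  cross <- uniroot(function(t) beta_t(rf, t), c(1, 12), tol = 1e-12)$root
  expect_equal(hr_curve(rf, cross)$hr, 1, tolerance = 1e-8)
  # outside follow-up: warning + flag, linear extrapolation
  expect_warning(hx <- hr_curve(rf, c(2, 30)), "extrapolat")
  expect_true(hx$extrapolated[2])
  expect_false(hx$extrapolated[1])
  # delta-method SE vs Monte-Carlo propagation of the coefficient
  # distribution (1e5 draws)
  ages <- c(2, 6, 10)
  B1 <- cbind(1, rcs_basis_eval(ages, rf$basis))
  se_analytic <- sqrt(rowSums((B1 %*% rf$var_theta) * B1))
  set.seed(1)
  L <- chol(rf$var_theta)
  draws <- matrix(rnorm(1e5 * 3), 1e5, 3) %*% L
  bt_draws <- draws %*% t(B1)
  se_mc <- apply(bt_draws, 2, sd)
  expect_equal(se_analytic, se_mc, tolerance = 0.02)
})

test_that("a constant measurement series reproduces the fixed-covariate
           fit exactly", {
  set.seed(87)
  n <- 150
  rec <- data.frame(subject_id = sprintf("s%03d", 1:n), entry_age = 0,
                    exit_age = runif(n, 2, 10),
                    event = rbinom(n, 1, 0.5),
                    positive_at_first_visit = 0L,
                    w = rnorm(n))
  meas <- do.call(rbind, lapply(1:n, function(i) {
    ages <- c(0, seq(1, rec$exit_age[i] - 0.01, by = 2))
    data.frame(subject_id = rec$subject_id[i], age = ages,
               value = rec$w[i])
  }))
  ep_tv <- expand_counting_process(rec, meas, tv_name = "w")
  ep_fx <- expand_counting_process(rec)
  r_tv <- fit_rcs_cox(ep_tv, "w", k = 3)
  r_fx <- fit_rcs_cox(ep_fx, "w", k = 3)
  expect_equal(r_tv$theta, r_fx$theta, tolerance = 1e-8)
  expect_equal(r_tv$loglik, r_fx$loglik, tolerance = 1e-8)
  expect_true(r_tv$time_varying == FALSE)  # constant within subject
})

test_that("nonconstancy power is monotone in the beta(t) slope; the
           nonlinear test stays near its level under a linear effect", {
  slopes <- c(0, -0.055, -0.111)
  rej_nc <- numeric(3)
  pv_nl <- c()
  for (s in seq_along(slopes)) {
    # anchor beta at mid-follow-up (6 y) to 0.1 so only the slope varies
    sc <- scenario(400L,
                   covariates = list(g = cov_bernoulli(0.72)),
                   beta = list(g = beta_linear(0.1 - 6 * slopes[s],
                                               slopes[s])),
                   name = "slope-study")
    nrep <- 40L
    pnc <- pnl <- rep(NA_real_, nrep)
    for (r in seq_len(nrep)) {
      res <- tryCatch({
        sim <- simulate_cohort(sc, etiohet:::child_seed(91 + s, r))
        ep <- expand_counting_process(
          exclude_left_censored(sim$subjects)$retained)
        ht <- hierarchical_tests(fit_rcs_cox(ep, "g", k = 3),
                                 gated = FALSE)
        c(ht$nonconstant$p_value, ht$nonlinear$p_value)
      }, error = function(e) c(NA_real_, NA_real_))
      pnc[r] <- res[1]; pnl[r] <- res[2]
    }
    rej_nc[s] <- mean(pnc < 0.05, na.rm = TRUE)
    if (slopes[s] != 0) pv_nl <- c(pv_nl, pnl[!is.na(pnl)])
  }
  expect_true(rej_nc[1] <= rej_nc[2] + 0.05)
  expect_true(rej_nc[2] <= rej_nc[3] + 0.05)
  expect_gt(rej_nc[3], rej_nc[1])
  # nonlinear test under genuinely linear beta(t): near-nominal rejection
  expect_lt(mean(pv_nl < 0.05), 0.15)
})

test_that("the crossing age of a sign-reversing effect is recovered
           consistently on the recorded-age scale", {
  # truth: the generating log HR crosses zero at 6.94 on the onset scale;
  # detection at annual visits shifts the recorded-scale crossing by about
  # half a visit interval, to ~7.4
  crs <- vapply(1:30, function(r) {
    sim <- simulate_cohort(default_scenario("nhw-like", 1000),
                           etiohet:::child_seed(95, r))
    ep <- expand_counting_process(
      exclude_left_censored(sim$subjects)$retained)
    rf <- fit_rcs_cox(ep, "nhw", k = 3)
    tryCatch(uniroot(function(t) beta_t(rf, t), c(0.8, 12))$root,
             error = function(e) NA_real_)
  }, numeric(1))
  expect_lt(abs(median(crs, na.rm = TRUE) - 7.44), 1.5)
  expect_lt(sum(is.na(crs)), 10)
})
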