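test_that("with no covariate effect and a constant baseline, onset ages
           from birth are exponential", {
  sc <- scenario(10L, covariates = list(x = cov_bernoulli(0.5)),
                 beta = list(x = beta_constant(0)),
                 baseline = list(breaks = c(0, 40), rates = 0.3),
                 max_follow_up = 40, name = "exp-check")
  set.seed(301)
  onsets <- vapply(1:5000, function(i) {
    simulate_event_time(function(t) matrix(1, length(t), 1), 0, sc)
  }, numeric(1))
  expect_lt(mean(!is.finite(onsets)), 0.01)
  ks <- suppressWarnings(
    stats::ks.test(onsets[is.finite(onsets)], "pexp", rate = 0.3))
  expect_gt(ks$p.value, 0.01)
})

test_that("the inversion sampler agrees in distribution with a thinning
           oracle under a time-varying effect", {
  sc <- scenario(10L, covariates = list(x = cov_bernoulli(0.5)),
                 beta = list(x = beta_linear(0.7, -0.12)),
                 baseline = list(breaks = c(0, 2, 6, 15),
                                 rates = c(0.05, 0.025, 0.04)),
                 name = "lin-check")
  xf <- function(t) matrix(1, length(t), 1)
  set.seed(302)
  a <- vapply(1:2000, function(i) simulate_event_time(xf, 0, sc),
              numeric(1))
  hfun <- function(t) {
    etiohet:::baseline_hazard_at(sc$baseline, t) * exp(0.7 - 0.12 * t)
  }
  M <- max(hfun(seq(0, 12, by = 0.01))) * 1.01
  b <- vapply(1:2000, function(i) {
    oracle_thinning_onset(hfun, 0, 12, M)
  }, numeric(1))
  # compare finite onsets plus the censoring mass
  expect_lt(abs(mean(is.finite(a)) - mean(is.finite(b))), 0.05)
  ks <- suppressWarnings(stats::ks.test(a[is.finite(a)], b[is.finite(b)]))
  expect_gt(ks$p.value, 0.01)
})

test_that("visit detection records events at the first visit at or after
           onset", {
  sched <- c(0.75, 1.25, 2, 3:12)
  d <- apply_visit_detection(1.6, 0, sched, Inf, 12)
  expect_equal(d$exit_age, 2)
  expect_equal(d$event, 1L)
  expect_equal(d$positive_at_first_visit, 0L)
  # onset before the first attended visit: left-censored flag
  d2 <- apply_visit_detection(0.3, 0, sched, Inf, 12)
  expect_equal(d2$positive_at_first_visit, 1L)
  expect_equal(d2$exit_age, 0.75)
  # no onset, dropout at 6.4 with annual visits: censored at 6
  d3 <- apply_visit_detection(Inf, 0, sched, 6.4, 12)
  expect_equal(d3$event, 0L)
  expect_equal(d3$exit_age, 6)
  # dropout before any visit: subject unusable
  expect_null(apply_visit_detection(Inf, 0, sched, 0.5, 12))
})

test_that("detection lag is nonnegative and bounded by the widest
           inter-visit gap", {
  sched <- c(0.75, 1.25, 2, 3:12)
  gap <- max(diff(c(0, sched)))
  set.seed(303)
  for (i in 1:200) {
    onset <- runif(1, 0, 13)
    entry <- ifelse(runif(1) < 0.7, 0, runif(1, 0, 8))
    dropout <- entry + rexp(1, 0.05)
    d <- apply_visit_detection(onset, entry, sched, dropout, 12)
    if (is.null(d) || d$event == 0L) next
    if (d$positive_at_first_visit == 0L) {
      expect_gte(d$exit_age, onset)
      expect_lte(d$exit_age - onset, gap + 1e-12)
    }
  }
})

test_that("simulated cohorts are reproducible and write byte-identical
           CSVs", {
  sc <- default_scenario("n3fa-like", 120)
  s1 <- simulate_cohort(sc, 42)
  s2 <- simulate_cohort(sc, 42)
  expect_identical(s1, s2)
  s3 <- simulate_cohort(sc, 43)
  expect_false(identical(s1$subjects, s3$subjects))
  f1 <- tempfile(); f2 <- tempfile()
  write_cohort(s1$subjects, f1)
  write_cohort(s2$subjects, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  # measurement ages do not exceed the exit age
  mm <- merge(s1$measurements, s1$subjects[c("subject_id", "exit_age")])
  expect_true(all(mm$age <= mm$exit_age))
})

test_that("realized event counts match an independent oracle simulation
           within 3 SD", {
  sc <- default_scenario("null", 2500)
  sim <- simulate_cohort(sc, 311)
  # oracle: thinning sampler + the same detection rule, many subjects
  hfun <- function(t) etiohet:::baseline_hazard_at(sc$baseline, t)
  M <- max(hfun(seq(0, 12, 0.01))) * 1.01
  set.seed(312)
  n_or <- 6000
  ev <- logical(n_or)
  for (i in seq_len(n_or)) {
    entry <- ifelse(runif(1) < sc$entry$prob_birth, 0, runif(1, 0, 8))
    dropout <- entry + rexp(1, sc$dropout_rate)
    onset <- oracle_thinning_onset(hfun, entry, sc$max_follow_up, M)
    d <- apply_visit_detection(onset, entry, sc$visit_schedule, dropout,
                               sc$max_follow_up)
    ev[i] <- !is.null(d) && d$event == 1L
  }
  p_hat <- mean(ev)
  n <- nrow(sim$subjects) + sim$info$n_dropped
  sd_tot <- sqrt(n * p_hat * (1 - p_hat) + n^2 * p_hat * (1 - p_hat) / n_or)
  expect_lt(abs(sim$info$n_events - n * p_hat), 3 * sd_tot)
})

test_that("scaling the baseline hazard raises expected event counts", {
  sc1 <- default_scenario("null", 400)
  sc2 <- sc1
  sc2$baseline$rates <- sc2$baseline$rates * 2
  e1 <- mean(vapply(1:3, function(s) {
    simulate_cohort(sc1, 320 + s)$info$n_events
  }, numeric(1)))
  e2 <- mean(vapply(1:3, function(s) {
    simulate_cohort(sc2, 320 + s)$info$n_events
  }, numeric(1)))
  expect_gt(e2, e1)
})

test_that("edge cases: empty cohort, single-replicate power, unknown
           test", {
  sc <- default_scenario("null", 0)
  s0 <- simulate_cohort(sc, 1)
  expect_equal(nrow(s0$subjects), 0L)
  ps <- power_study(default_scenario("null", 200), "zph", n_reps = 1,
                    seed = 5)
  expect_true(ps$rejection %in% c(0, 1))
  expect_error(power_study(default_scenario("null"), "banana", 2),
               "unknown test")
})

test_that("scenario validation rejects malformed inputs", {
  expect_error(scenario(10, covariates = list(x = cov_bernoulli(0.5)),
                        beta = list(y = beta_constant(0))),
               "matching names")
  expect_error(scenario(10, covariates = list(x = cov_bernoulli(0.5)),
                        beta = list(x = beta_constant(0)),
                        baseline = list(breaks = c(0, 5), rates = -1)))
  expect_error(default_scenario("nope"))
})
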