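# Brute-force oracles and tiny fixtures, independent of the package's
# computational path: risk sets are enumerated with explicit loops and the
# partial likelihood is written out in closed form.

# --- worked fixtures -------------------------------------------------------

# Three subjects, no delayed entry, one binary covariate.  The Breslow
# partial likelihood is (b - log(2 e^b + 1)) + (0 - log(1 + e^b)), maximized
# at b = -log(2)/2, with closed-form residuals (frozen from the enumerated
# oracle below; several have exact surd forms).
fix3 <- function() {
  data.frame(subject_id = c("A", "B", "C"),
             start = c(0, 0, 0), stop = c(1, 2, 3),
             event = c(1L, 1L, 0L), x = c(1, 0, 1))
}
fix3_beta <- -log(2) / 2                      # -0.346573590279973
fix3_loglik <- -1.76274717403909
fix3_schoenfeld <- c(sqrt(2) - 1, -(sqrt(2) - 1))   # +-0.414213562...
fix3_martingale <- c(A = 1 / sqrt(2), B = 0, C = -1 / sqrt(2))

# Four subjects with staggered entry, two events; maximizer e^b = sqrt(2).
fix4 <- function() {
  data.frame(subject_id = c("D", "E", "F", "G"),
             start = c(0, 0, 1, 2.5), stop = c(2, 4, 3, 5),
             event = c(1L, 1L, 0L, 0L), x = c(1, 0, 0, 1))
}
fix4_beta <- log(2) / 2

# --- enumerated-risk-set oracles ------------------------------------------

oracle_loglik <- function(beta, ep, covs) {
  X <- as.matrix(ep[covs])
  beta <- as.numeric(beta)
  ll <- 0
  for (e in which(ep$event == 1)) {
    t <- ep$stop[e]
    risk <- which(ep$start < t & t <= ep$stop)
    ll <- ll + sum(X[e, ] * beta) -
      log(sum(exp(X[risk, , drop = FALSE] %*% beta)))
  }
  ll
}

oracle_fit <- function(ep, covs) {
  if (length(covs) == 1L) {
    stats::optimize(function(b) -oracle_loglik(b, ep, covs),
                    c(-8, 8), tol = 1e-10)$minimum
  } else {
    stats::optim(rep(0, length(covs)),
                 function(b) -oracle_loglik(b, ep, covs),
                 method = "BFGS",
                 control = list(reltol = 1e-14))$par
  }
}

oracle_schoenfeld <- function(ep, beta, covs) {
  X <- as.matrix(ep[covs])
  evt <- which(ep$event == 1)
  evt <- evt[order(ep$stop[evt])]
  out <- matrix(NA_real_, length(evt), length(covs))
  for (i in seq_along(evt)) {
    e <- evt[i]
    t <- ep$stop[e]
    risk <- which(ep$start < t & t <= ep$stop)
    w <- exp(drop(X[risk, , drop = FALSE] %*% beta))
    xbar <- colSums(X[risk, , drop = FALSE] * w) / sum(w)
    out[i, ] <- X[e, ] - xbar
  }
  colnames(out) <- covs
  out
}

oracle_martingale <- function(ep, beta, covs) {
  X <- as.matrix(ep[covs])
  te <- sort(unique(ep$stop[ep$event == 1]))
  h <- vapply(te, function(t) {
    risk <- which(ep$start < t & t <= ep$stop)
    sum(ep$event == 1 & ep$stop == t) /
      sum(exp(drop(X[risk, , drop = FALSE] %*% beta)))
  }, numeric(1))
  sid <- unique(as.character(ep$subject_id))
  out <- vapply(sid, function(s) {
    rows <- which(as.character(ep$subject_id) == s)
    acc <- 0
    for (i in rows) {
      at <- te > ep$start[i] & te <= ep$stop[i]
      acc <- acc + exp(sum(X[i, ] * beta)) * sum(h[at])
    }
    sum(ep$event[rows]) - acc
  }, numeric(1))
  out
}

# --- alternative event-time sampler (thinning), used as a distributional
#     oracle for the piecewise-exponential inversion sampler --------------

oracle_thinning_onset <- function(hfun, entry, max_fu, M) {
  t <- entry
  repeat {
    t <- t + stats::rexp(1, M)
    if (t > max_fu) return(Inf)
    if (stats::runif(1) < hfun(t) / M) return(t)
  }
}

# small random counting-process datasets for reference comparisons
random_dataset <- function(n, seed, staggered = FALSE, p = 2L,
                           tie_times = FALSE) {
  set.seed(seed)
  d <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                  start = if (staggered) runif(n, 0, 2) else rep(0, n),
                  event = rbinom(n, 1L, 0.6),
                  x = rnorm(n))
  if (p >= 2L) d$z <- rbinom(n, 1L, 0.5)
  dur <- rexp(n, 0.3) + 0.05
  if (tie_times) dur <- ceiling(dur)
  d$stop <- d$start + dur
  d
}
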