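# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Range-sum trick for counting-process risk sets.  Episode i is at risk at the
# j-th distinct event time iff lo_i < j <= hi_i (half-open (start, stop]
# intervals, lo = #{event times <= start}, hi = #{event times <= stop}).
# Returns the J x k matrix of per-event-time column sums of `vals` over the
# episodes at risk, in O(n k + J k) via a difference array + cumsum.
risk_sums <- function(vals, lo, hi, J) {
  vals <- as.matrix(vals)
  k <- ncol(vals)
  keep <- hi > lo
  if (!any(keep)) return(matrix(0, J, k))
  v <- vals[keep, , drop = FALSE]
  inc <- rowsum(rbind(v, -v), c(lo[keep] + 1L, hi[keep] + 1L))
  out <- matrix(0, J + 1L, k)
  out[as.integer(rownames(inc)), ] <- inc
  res <- apply(out, 2L, cumsum)
  res[seq_len(J), , drop = FALSE]
}

# Packed storage for symmetric p x p matrices: index pairs (row <= col),
# ordered column-major over the upper triangle.
sym_pairs <- function(p) {
  idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

unpack_sym <- function(v, p, pr) {
  M <- matrix(0, p, p)
  M[pr] <- v
  M[pr[, c(2L, 1L), drop = FALSE]] <- v
  M
}

# Wald quadratic form theta' V^{-1} theta.
wald_quadform <- function(theta, V) {
  drop(crossprod(theta, solve(V, theta)))
}

# Derive a bounded child seed from a master seed (kept well below 2^31).
child_seed <- function(seed, i, stream = 0L) {
  as.integer((as.numeric(seed) + 104729 * i + 7919 * stream) %% 2147483629)
}
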