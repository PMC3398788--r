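# Independent oracles used across test files.

# Partial rank correlation via the precision matrix of the rank-correlation
# matrix: an algebraic route entirely independent of the residual-regression
# implementation.
prccPrecisionOracle <- function(X, y) {
  k <- ncol(X)
  R <- stats::cor(cbind(apply(X, 2, rank), rank(y)))
  P <- solve(R)
  -P[seq_len(k), k + 1L] / sqrt(diag(P)[seq_len(k)] * P[k + 1L, k + 1L])
}

# Savage scores by direct summation (no vectorised shortcuts).
savageBrute <- function(ranks) {
  n <- length(ranks)
  vapply(ranks, function(r) sum(1 / seq.int(r, n)), numeric(1))
}

# Pearson correlation written out as explicit sums.
pearsonBrute <- function(a, b) {
  am <- sum(a) / length(a); bm <- sum(b) / length(b)
  sum((a - am) * (b - bm)) /
    sqrt(sum((a - am)^2) * sum((b - bm)^2))
}
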