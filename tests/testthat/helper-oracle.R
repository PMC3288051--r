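# Independent oracles, coded naively in data space (explicit score
# vectors, cov/cor/lm), against which the correlation-matrix core is
# checked.

# Naive two-block reflective Lohmoeller loop: latent scores recomputed
# from the data each iteration, outer weights as covariances with the
# inner estimate, path coefficient by an explicit OLS of one score on the
# other.
oracle_two_block <- function(x, p1, tol = 1e-10, maxit = 1000) {
  n <- nrow(x)
  xs <- scale(x)
  X1 <- xs[, 1:p1, drop = FALSE]
  X2 <- xs[, (p1 + 1):ncol(xs), drop = FALSE]
  unit <- function(X, w) w / stats::sd(drop(X %*% w))
  w1 <- unit(X1, rep(1, ncol(X1)))
  w2 <- unit(X2, rep(1, ncol(X2)))
  for (it in seq_len(maxit)) {
    y1 <- drop(X1 %*% w1)
    y2 <- drop(X2 %*% w2)
    s <- sign(stats::cor(y1, y2))
    w1n <- unit(X1, drop(stats::cov(X1, s * y2)))
    w2n <- unit(X2, drop(stats::cov(X2, s * y1)))
    d <- max(abs(c(w1n - w1, w2n - w2)))
    w1 <- w1n; w2 <- w2n
    if (d < tol) break
  }
  y1 <- drop(X1 %*% w1); y2 <- drop(X2 %*% w2)
  lam1 <- drop(stats::cor(X1, y1)); lam2 <- drop(stats::cor(X2, y2))
  if (sum(lam1) < 0) { y1 <- -y1; lam1 <- -lam1; w1 <- -w1 }
  if (sum(lam2) < 0) { y2 <- -y2; lam2 <- -lam2; w2 <- -w2 }
  beta <- unname(stats::coef(stats::lm(y2 ~ y1))[2L])
  list(beta = beta, loadings = c(lam1, lam2), scores = cbind(y1, y2))
}

# Closed-form OLS via the normal equations, for regression oracles.
oracle_ols <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  drop(solve(crossprod(X), crossprod(X, y)))
}
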