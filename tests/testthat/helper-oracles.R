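# Independent oracles for the solver and sampler checks.

# brute-force solution of the penalised least-squares problem
#   min ||y - X s - Z b||^2 + ridge_j b_j^2
# through the pseudoinverse of the augmented design — an independent route
# that never touches the mixed-model equations the implementation solves
ginv_oracle <- function(Z, y, X, ridge) {
  p <- ncol(Z); q <- ncol(X)
  M <- rbind(cbind(X, Z),
             cbind(matrix(0, p, q), diag(sqrt(ridge), p)))
  sol <- MASS::ginv(M) %*% c(y, rep(0, p))
  list(fixed = sol[1:q], b = sol[(q + 1):(q + p)])
}

# conjugate closed form for the Gibbs sampler with all variances fixed:
# the joint posterior of (s, b) is normal with mean solve(C) rhs and
# covariance solve(C) * s2e
conjugate_posterior <- function(Z, y, X, s2b, s2e) {
  M <- cbind(X, Z)
  C <- crossprod(M)
  idx <- (ncol(X) + 1):ncol(M)
  diag(C)[idx] <- diag(C)[idx] + s2e / s2b
  list(mean = as.vector(solve(C, crossprod(M, y))),
       cov = solve(C) * s2e)
}

# batch-means Monte-Carlo standard error of a chain's mean
mcse_batch <- function(draws, n_batch = 20) {
  bm <- tapply(draws, rep(seq_len(n_batch), each = length(draws) / n_batch),
               mean)
  sd(bm) / sqrt(n_batch)
}
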