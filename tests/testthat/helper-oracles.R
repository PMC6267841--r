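# Independent brute-force oracles, kept free of the package's computational
# paths (the package uses the hypergeometric law and the closed-form variance;
# these enumerate tuples and build covariance matrices explicitly).

# pmf of the squared imbalance among the first r entries of a uniformly drawn
# k:1-balanced tuple of length b, by full enumeration of {1,2}^b
oracle_imbalance_pmf <- function(b, k, r) {
  grid <- as.matrix(expand.grid(rep(list(1:2), b)))
  tuples <- grid[rowSums(grid == 1) == k * b / (k + 1), , drop = FALSE]
  j <- rowSums(tuples[, seq_len(r), drop = FALSE] == 1)
  d2 <- (j / k - (r - j))^2
  tab <- tapply(rep(1 / nrow(tuples), nrow(tuples)), round(d2 * k^2), sum)
  list(support = as.numeric(names(tab)) / k^2, probs = unname(as.numeric(tab)))
}

oracle_expected_imbalance <- function(b, k, r) {
  pmf <- oracle_imbalance_pmf(b, k, r)
  sum(pmf$support * pmf$probs)
}

# Var(mu_hat) as the quadratic form w' Sigma w with Sigma the block-diagonal
# random-intercept covariance and w the pooled-mean contrast
oracle_var_mu_hat <- function(sigma2, tau2, n1, n2) {
  N1 <- sum(n1); N2 <- sum(n2)
  N <- N1 + N2
  Sigma <- matrix(0, N, N)
  at <- 0L
  for (j in seq_along(n1)) {
    nj <- n1[j] + n2[j]
    if (nj == 0) next
    idx <- at + seq_len(nj)
    Sigma[idx, idx] <- sigma2 * diag(nj) + tau2 * matrix(1, nj, nj)
    at <- at + nj
  }
  w <- unlist(lapply(seq_along(n1), function(j)
    c(rep(-1 / N1, n1[j]), rep(1 / N2, n2[j]))))
  drop(t(w) %*% Sigma %*% w)
}

# valid (b, k) block schemes up to a maximum block length
scheme_grid <- function(b_max, k_values = 1:3) {
  out <- expand.grid(b = 2:b_max, k = k_values)
  out[out$b %% (out$k + 1) == 0, ]
}
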