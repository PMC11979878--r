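# shared helpers: small random datasets and correlation matrices built in
# code under fixed seeds

random_ancova <- function(seed, a = 3, n = NULL, m = 1,
                          heteroscedastic = TRUE) {
  set.seed(seed)
  if (is.null(n)) n <- sample(6:12, a, replace = TRUE)
  g <- rep(seq_len(a), times = n)
  N <- sum(n)
  M <- if (m > 0) matrix(rnorm(N * m, 7, 1), N, m) else NULL
  sd_g <- if (heteroscedastic) runif(a, 0.5, 2.5) else rep(1, a)
  y <- rep(rnorm(a, 10, 1), times = n) +
    (if (m > 0) as.numeric(M %*% runif(m, 0, 2)) else 0) +
    rnorm(N, 0, sd_g[g])
  ancova_data(y, factor(g), covariates = M)
}

random_corr <- function(seed, q) {
  set.seed(seed)
  A <- matrix(rnorm(q * (q + 2)), q + 2, q)
  stats::cov2cor(crossprod(A))
}

# independent normal-equations oracle for the stacked OLS/GLS ANCOVA fit:
# solves the weighted least squares problem on B = (X, M) directly
stacked_lm_oracle <- function(data, weights = NULL) {
  g <- as.integer(data$groups)
  N <- data$N
  X <- matrix(0, N, data$a)
  X[cbind(seq_len(N), g)] <- 1
  B <- cbind(X, data$covariates)
  w <- if (is.null(weights)) rep(1, N) else weights
  coef <- solve(crossprod(B, w * B), crossprod(B, w * data$y))
  list(b = coef[seq_len(data$a)],
       p = if (ncol(data$covariates)) coef[-seq_len(data$a)] else numeric(0))
}
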