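#' Design and projection matrices of the ANCOVA model
#'
#' Builds the block design matrix \eqn{X = \oplus_i 1_{n_i}}, the covariate
#' matrix M, the projections \eqn{P = X(X'X)^{-1}X'} and \eqn{Q = I - P},
#' the stacked regressor matrix \eqn{B = (X, M)} and the hat-matrix diagonal
#' \eqn{p_{ij}} of \eqn{B(B'B)^{-1}B'} used by the wild bootstrap.
#'
#' @param data an [ancova_data()] object.
#' @return An object of class `"ancova_design"`: list with `X`, `M`, `P`,
#'   `Q` (dense only for moderate N), `B`, `hat_diag`, `group_index`, `n`,
#'   `a`, `rank_B` and `PB` (\eqn{(B'B)^{-1}B'}).
#' @examples
#' d <- ancova_data(rnorm(9), gl(3, 3), covariates = 1:9)
#' des <- build_design(d)
#' max(abs(des$Q %*% des$X))  # Q annihilates X
#' @export
build_design <- function(data) {
  stopifnot(inherits(data, "ancova_data"))
  N <- data$N
  a <- data$a
  g <- as.integer(data$groups)
  X <- matrix(0, N, a)
  X[cbind(seq_len(N), g)] <- 1
  colnames(X) <- levels(data$groups)
  M <- data$covariates
  B <- cbind(X, M)

  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    bad <- colnames(B)[qrB$pivot[(qrB$rank + 1L):ncol(B)]]
    stop("design matrix (X, M) is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }

  # P projects onto the group indicators (block averaging); the dense N x N
  # projections are kept for inspection at moderate N, while all estimators
  # use the equivalent group-mean operations directly
  n_i <- data$n
  if (N <= 2000L) {
    P <- tcrossprod(sweep(X, 2, sqrt(n_i), "/"))
    Q <- diag(N) - P
  } else {
    P <- Q <- NULL
  }

  BtB <- crossprod(B)
  PB <- solve(BtB, t(B))           # (B'B)^{-1} B'
  hat_diag <- rowSums(B * t(PB))   # diag of B (B'B)^{-1} B'

  structure(list(X = X, M = M, P = P, Q = Q, B = B, PB = PB,
                 hat_diag = hat_diag, group_index = g, n = n_i, a = a,
                 rank_B = qrB$rank, group_levels = levels(data$groups)),
            class = "ancova_design")
}
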