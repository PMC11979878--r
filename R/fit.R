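#' Generating matrices of the effect and coefficient estimators
#'
#' Computes the matrices A and D for which \eqn{\hat p = AY} and
#' \eqn{\hat b = DY}:
#' \deqn{A = (M'Q\Sigma^{-1}M)^{-1} M'Q\Sigma^{-1},}
#' \deqn{D = (X'\Sigma^{-1}X)^{-1}X'\Sigma^{-1} -
#'          (X'\Sigma^{-1}X)^{-1}X'\Sigma^{-1} M A,}
#' with Q the unweighted projection complement \eqn{I - X(X'X)^{-1}X'}.
#' Passing `variance = NULL` sets \eqn{\Sigma = I} and yields the OLS
#' estimators. With no covariates A is empty and D is the group-mean
#' operator (weighted group means for general \eqn{\Sigma}).
#'
#' @param design an [build_design()] object.
#' @param variance an `"ancova_variance"` object supplying the diagonal of
#'   \eqn{\hat\Sigma}, or `NULL` for identity weights (OLS).
#' @return list with `A` (M x N), `D` (a x N) and `sigma_diag` (the diagonal
#'   used, length N).
#' @export
generating_matrices <- function(design, variance = NULL) {
  stopifnot(inherits(design, "ancova_design"))
  N <- nrow(design$B)
  if (is.null(variance)) {
    sdiag <- rep(1, N)
  } else {
    stopifnot(inherits(variance, "ancova_variance"))
    sdiag <- variance$diag
    if (any(sdiag <= 0))
      stop("variance diagonal must be strictly positive for GLS plug-in ",
           "weights (zero entries at rows: ",
           paste(utils::head(which(sdiag <= 0), 5L), collapse = ", "), ")")
  }
  w <- 1 / sdiag
  X <- design$X
  M <- design$M
  a <- design$a
  g <- design$group_index

  # (X' S^-1 X)^{-1} X' S^-1 : row-normalized weighted indicator matrix
  wX <- t(X) * rep(w, each = a)           # a x N, = X' Sigma^-1
  gw <- as.numeric(wX %*% rep(1, N))      # group weight sums
  D0 <- wX / gw                           # (X'S^-1X)^{-1} X'S^-1

  if (ncol(M) == 0L) {
    A <- matrix(numeric(0), nrow = 0L, ncol = N)
    D <- D0
  } else {
    # M'Q = (M - group means of M)' without forming the dense projection
    Mbar <- rowsum(M, g) / design$n
    MtQ <- t(M - Mbar[g, , drop = FALSE])  # M'Q, M x N
    MtQS <- MtQ * rep(w, each = nrow(MtQ))  # M'Q Sigma^-1
    G <- MtQS %*% M                       # M'Q Sigma^-1 M
    A <- tryCatch(solve(G, MtQS),
                  error = function(e)
                    stop("M'Q Sigma^-1 M is singular: covariates are ",
                         "collinear with the group indicators", call. = FALSE))
    D <- D0 - (D0 %*% M) %*% A
  }
  rownames(D) <- design$group_levels
  list(A = A, D = D, sigma_diag = sdiag)
}

#' Fit the heteroscedastic ANCOVA model
#'
#' Two-pass estimation of the treatment effects b and covariate coefficients
#' p with sandwich covariance estimators. Pass one is an OLS fit
#' (\eqn{\Sigma = I}), providing residuals. Pass two estimates the error
#' variances: `mode = "groupwise"` uses the unbiased per-group estimator
#' ([estimate_sigma_groupwise()]), `mode = "subjectwise"` squares the OLS
#' residuals ([estimate_sigma_subjectwise()]). With
#' `estimator = "gls_plugin"` the effects are then re-estimated with
#' \eqn{\hat\Sigma} plugged into the generating matrices; with
#' `estimator = "ols"` the OLS point estimates are kept. In either case
#' \deqn{\hat\Psi = D\hat\Sigma D', \qquad \hat\Xi = A\hat\Sigma A'}
#' with the final A, D and \eqn{\hat\Sigma}.
#'
#' The default pairing follows the inferential methods built on the fit:
#' group-wise variances with GLS plug-in effects (multivariate-t MCTP), and
#' subject-wise variances with OLS effects (wild-bootstrap MCTP).
#'
#' @param data an [ancova_data()] object.
#' @param mode `"groupwise"` or `"subjectwise"` variance structure.
#' @param estimator `"gls_plugin"` or `"ols"`; default depends on `mode` as
#'   described above.
#' @return An object of class `"ancova_fit"`: list with `b_hat`, `p_hat`,
#'   `Psi_hat` (a x a), `Xi_hat` (M x M), `residuals` (from the final
#'   estimates), `variance`, `estimator`, `mode`, `D`, `A` and `design`.
#' @examples
#' d <- make_fixture("three_group", seed = 1)
#' f <- fit_ancova(d)
#' f$b_hat
#' @export
fit_ancova <- function(data, mode = c("groupwise", "subjectwise"),
                       estimator = NULL) {
  mode <- match.arg(mode)
  if (is.null(estimator))
    estimator <- if (mode == "groupwise") "gls_plugin" else "ols"
  estimator <- match.arg(estimator, c("gls_plugin", "ols"))
  design <- build_design(data)

  gm0 <- generating_matrices(design, NULL)
  b0 <- as.numeric(gm0$D %*% data$y)
  p0 <- if (ncol(design$M)) as.numeric(gm0$A %*% data$y) else numeric(0)
  res0 <- data$y - b0[design$group_index] -
    if (ncol(design$M)) as.numeric(design$M %*% p0) else 0

  variance <- switch(mode,
    groupwise   = estimate_sigma_groupwise(data, design),
    subjectwise = estimate_sigma_subjectwise(res0, design))

  if (estimator == "gls_plugin") {
    gm <- generating_matrices(design, variance)
    b_hat <- as.numeric(gm$D %*% data$y)
    p_hat <- if (ncol(design$M)) as.numeric(gm$A %*% data$y) else numeric(0)
  } else {
    gm <- gm0
    b_hat <- b0
    p_hat <- p0
  }
  D <- gm$D
  A <- gm$A
  sdiag <- variance$diag
  Psi_hat <- D %*% (sdiag * t(D))
  Psi_hat <- (Psi_hat + t(Psi_hat)) / 2
  Xi_hat <- if (ncol(design$M)) {
    Xi <- A %*% (sdiag * t(A))
    (Xi + t(Xi)) / 2
  } else matrix(numeric(0), 0, 0)

  residuals <- data$y - b_hat[design$group_index] -
    if (ncol(design$M)) as.numeric(design$M %*% p_hat) else 0
  names(b_hat) <- design$group_levels
  dimnames(Psi_hat) <- list(design$group_levels, design$group_levels)
  if (length(p_hat)) names(p_hat) <- colnames(design$M)

  structure(list(b_hat = b_hat, p_hat = p_hat, Psi_hat = Psi_hat,
                 Xi_hat = Xi_hat, residuals = residuals, variance = variance,
                 estimator = estimator, mode = mode, D = D, A = A,
                 design = design, y = data$y),
            class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat("Heteroscedastic ANCOVA fit (", x$mode, " variances, ", x$estimator,
      " estimator)\n", sep = "")
  cat("effects b_hat:\n")
  print(round(x$b_hat, 4))
  if (length(x$p_hat)) {
    cat("covariate coefficients p_hat:\n")
    print(round(x$p_hat, 4))
  }
  invisible(x)
}
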