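#' Group-wise variance estimator (Behrens-Fisher setting)
#'
#' Unbiased moment estimator of the group variances \eqn{\sigma_i^2}:
#' \deqn{\hat\sigma_i^2 = Y_i' Q_i Y_i / (n_i - 1 - \mathrm{rank}(M_i)),}
#' where \eqn{Q_i} is the projection complement of the group-specific
#' regressor block \eqn{B_i = (1_{n_i}, M_i)}. This is the residual mean
#' square of the per-group regression of the response on an intercept and the
#' group's covariates, with a rank-aware denominator.
#'
#' @param data an [ancova_data()] object.
#' @param design the matching [build_design()] object.
#' @return An object of class `"ancova_variance"` with `mode = "groupwise"`,
#'   the N-vector `diag` (constant within groups), `group_sigma2` and
#'   `group_df` (\eqn{n_i - 1 - \mathrm{rank}(M_i)}).
#' @seealso [estimate_sigma_subjectwise()]
#' @export
estimate_sigma_groupwise <- function(data, design) {
  stopifnot(inherits(data, "ancova_data"), inherits(design, "ancova_design"))
  a <- design$a
  g <- design$group_index
  sigma2 <- numeric(a)
  df <- numeric(a)
  for (i in seq_len(a)) {
    idx <- which(g == i)
    yi <- data$y[idx]
    ni <- length(idx)
    Mi <- design$M[idx, , drop = FALSE]
    rk <- .num_rank(Mi)
    df[i] <- ni - 1 - rk
    if (df[i] < 1)
      stop("group '", design$group_levels[i], "' has n - 1 - rank(M) = ",
           df[i], " residual degrees of freedom; the group-wise variance ",
           "estimator is undefined (need at least 1)")
    Bi <- cbind(1, Mi)
    res <- stats::lsfit(Bi, yi, intercept = FALSE)$residuals
    ssq <- sum(res^2)
    if (ssq < -1e-8) stop("negative quadratic form in group variance")
    sigma2[i] <- max(ssq, 0) / df[i]
  }
  names(sigma2) <- design$group_levels
  structure(list(mode = "groupwise", diag = unname(sigma2[g]),
                 group_sigma2 = sigma2, group_df = df),
            class = "ancova_variance")
}

#' Subject-wise variance estimator (White / HC)
#'
#' Heteroscedasticity-consistent estimator of the complete-heteroscedasticity
#' covariance: the diagonal matrix of squared ANCOVA residuals
#' \eqn{\hat\epsilon_{ij}^2}, one entry per subject.
#'
#' @param residuals numeric vector of OLS ANCOVA residuals from the same
#'   design.
#' @param design the matching [build_design()] object.
#' @return An `"ancova_variance"` object with `mode = "subjectwise"` and
#'   `diag` the squared residuals.
#' @export
estimate_sigma_subjectwise <- function(residuals, design) {
  stopifnot(inherits(design, "ancova_design"))
  if (length(residuals) != nrow(design$B))
    stop("residual vector length (", length(residuals),
         ") does not match the design (", nrow(design$B), " rows)")
  structure(list(mode = "subjectwise", diag = as.numeric(residuals)^2,
                 group_sigma2 = NULL, group_df = NULL),
            class = "ancova_variance")
}

# numerical rank with the standard SVD tolerance max(dim) * eps * s_1
.num_rank <- function(A) {
  if (ncol(A) == 0L || nrow(A) == 0L) return(0L)
  s <- svd(A, nu = 0, nv = 0)$d
  if (s[1] == 0) return(0L)
  sum(s > max(dim(A)) * .Machine$double.eps * s[1])
}
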