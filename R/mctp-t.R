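#' Contrast test statistics
#'
#' Standardized contrast statistics
#' \eqn{T_\ell = c_\ell'\hat b / \sqrt{c_\ell'\hat\Psi c_\ell}} and the
#' max-type global statistic \eqn{T_0 = \max_\ell |T_\ell|}.
#'
#' @param fit an [fit_ancova()] object.
#' @param C a contrast matrix (q x a).
#' @return list with `estimates` (\eqn{c_\ell'\hat b}), `se`, `statistics`
#'   and `T0`.
#' @export
test_statistics <- function(fit, C) {
  stopifnot(inherits(fit, "ancova_fit"))
  C <- .conform_contrast(C, fit$design)
  est <- as.numeric(C %*% fit$b_hat)
  v <- rowSums((C %*% fit$Psi_hat) * C)
  if (any(v <= 0))
    stop("zero variance for contrast row(s): ",
         paste(rownames(C)[v <= 0], collapse = ", "))
  stat <- as.numeric(est / sqrt(unname(v)))
  list(estimates = est, se = sqrt(unname(v)), statistics = stat, T0 = max(abs(stat)))
}

#' Correlation matrix of the contrast statistics
#'
#' \deqn{\hat R = \mathrm{diag}(C\hat\Psi C')^{-1/2}\, C\hat\Psi C'\,
#'       \mathrm{diag}(C\hat\Psi C')^{-1/2}.}
#'
#' @param Psi_hat a x a covariance matrix of the effect estimates.
#' @param C contrast matrix (q x a).
#' @return q x q unit-diagonal correlation matrix (singular for linearly
#'   dependent contrast rows such as the grand-mean family).
#' @export
correlation_matrix <- function(Psi_hat, C) {
  C <- as.matrix(C)
  V <- C %*% Psi_hat %*% t(C)
  d <- diag(V)
  if (any(d <= 0))
    stop("zero variance for contrast row(s): ",
         paste(which(d <= 0), collapse = ", "))
  R <- V / sqrt(outer(d, d))
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Box-type (Satterthwaite) degrees of freedom per contrast
#'
#' Approximates the distribution of each estimated contrast variance
#' \eqn{c_\ell'\hat\Psi c_\ell} by a scaled chi-square matching the first two
#' moments. With \eqn{w_\ell = c_\ell'D} and the per-group leverage sums
#' \eqn{s_{\ell i} = \sum_{j \in i} w_{\ell j}^2} (the i-th entry of
#' \eqn{k_\ell'X}, \eqn{k_\ell} the elementwise square of \eqn{w_\ell}),
#' \deqn{\nu_\ell = \frac{(c_\ell'\hat\Psi c_\ell)^2}
#'   {\sum_i s_{\ell i}^2\,\hat\sigma_i^4 / (n_i - 1 - \mathrm{rank}(M_i))}.}
#' For a = 2 with no covariates this is exactly the Welch-Satterthwaite
#' degree of freedom.
#'
#' @param fit an [fit_ancova()] object with `mode = "groupwise"`.
#' @param C contrast matrix (q x a).
#' @return numeric vector of q candidate degrees of freedom.
#' @export
box_df <- function(fit, C) {
  stopifnot(inherits(fit, "ancova_fit"))
  if (fit$variance$mode != "groupwise")
    stop("Box-type degrees of freedom require group-wise variance estimation")
  C <- .conform_contrast(C, fit$design)
  W <- C %*% fit$D                       # q x N rows w_l = c_l' D
  K <- W^2
  S <- K %*% fit$design$X                # q x a, s_{l i}
  sigma2 <- fit$variance$group_sigma2
  gdf <- fit$variance$group_df
  if (any(gdf <= 0)) stop("non-positive group degrees of freedom")
  num <- as.numeric(rowSums((C %*% fit$Psi_hat) * C))^2
  den <- as.numeric(S^2 %*% (sigma2^2 / gdf))
  nu <- num / den
  names(nu) <- rownames(C)
  nu
}

#' Select the joint degrees of freedom from the per-contrast candidates
#'
#' The joint multivariate t reference distribution is homoscedastic, so a
#' single degree of freedom must represent the q candidates: the minimum or
#' maximum candidate (real-valued), or their arithmetic mean rounded to the
#' nearest integer (half away from zero). Smaller df give larger critical
#' values, so the min rule is the most conservative choice.
#'
#' @param df_candidates numeric vector of candidate degrees of freedom.
#' @param rule `"min"`, `"mean"` or `"max"`.
#' @return scalar degrees of freedom.
#' @export
select_df <- function(df_candidates, rule = c("mean", "min", "max")) {
  rule <- match.arg(rule)
  if (length(df_candidates) == 0L) stop("empty degree-of-freedom candidates")
  if (any(df_candidates < 1)) stop("degree-of-freedom candidates must be >= 1")
  switch(rule,
         min  = min(df_candidates),
         max  = max(df_candidates),
         mean = {
           m <- mean(df_candidates)
           sign(m) * floor(abs(m) + 0.5)  # round half away from zero
         })
}

#' Compatible simultaneous confidence intervals
#'
#' \deqn{CI_\ell = c_\ell'\hat b \pm t_{crit}\sqrt{c_\ell'\hat\Psi c_\ell}.}
#' Zero lies outside \eqn{CI_\ell} exactly when \eqn{|T_\ell| >} `critical`,
#' so interval exclusion of zero and test rejection coincide.
#'
#' @param fit an [fit_ancova()] object.
#' @param C contrast matrix.
#' @param critical positive critical value (equicoordinate quantile or
#'   bootstrap quantile).
#' @return q x 2 matrix with columns `lower`, `upper`.
#' @export
simultaneous_ci <- function(fit, C, critical) {
  if (!is.numeric(critical) || critical <= 0)
    stop("critical value must be positive")
  ts <- test_statistics(fit, C)
  ci <- cbind(lower = ts$estimates - critical * ts$se,
              upper = ts$estimates + critical * ts$se)
  rownames(ci) <- rownames(.conform_contrast(C, fit$design))
  ci
}

#' Multivariate-t multiple contrast test for heteroscedastic ANCOVA
#'
#' Tests the individual null hypotheses \eqn{c_\ell'b = 0} and the global
#' hypothesis \eqn{Cb = 0} in the heteroscedastic ANCOVA model, with
#' group-wise variance estimation. The joint distribution of the contrast
#' statistics is approximated by a central multivariate
#' \eqn{t(\nu, \hat R)} distribution; \eqn{\nu} is chosen from the
#' per-contrast Box-type candidates by `df_rule` (`"asymptotic"` skips the
#' small-sample correction and uses the multivariate normal limit).
#' Adjusted p-values, the equicoordinate critical value and compatible
#' simultaneous confidence intervals are returned; the global test rejects
#' iff any individual hypothesis is rejected (consonance).
#'
#' @param data an [ancova_data()] object.
#' @param C contrast matrix from [build_contrast()], [factorial_contrast()]
#'   or [contrast_matrix()]; a family name (`"dunnett"`, `"tukey"`,
#'   `"grandmean"`) is also accepted.
#' @param alpha familywise level, default 0.05.
#' @param df_rule `"mean"` (default), `"min"`, `"max"` or `"asymptotic"`.
#' @param estimator `"gls_plugin"` (default) or `"ols"` point estimates.
#' @return An object of class `"mctp_t"` with fields `estimates`,
#'   `statistics`, `T0`, `R_hat`, `df_candidates`, `df_used`, `df_rule`,
#'   `critical`, `p_adjusted`, `sci`, `alpha`, `reject`, `reject_global`
#'   and the underlying `fit`.
#' @examples
#' d <- make_fixture("three_group", seed = 7)
#' mctp_t_test(d, "dunnett")
#' @export
mctp_t_test <- function(data, C = "dunnett", alpha = 0.05,
                        df_rule = c("mean", "min", "max", "asymptotic"),
                        estimator = c("gls_plugin", "ols")) {
  df_rule <- match.arg(df_rule)
  estimator <- match.arg(estimator)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  fit <- fit_ancova(data, mode = "groupwise", estimator = estimator)
  C <- .conform_contrast(C, fit$design)
  ts <- test_statistics(fit, C)
  R_hat <- correlation_matrix(fit$Psi_hat, C)
  if (df_rule == "asymptotic") {
    df_candidates <- rep(Inf, nrow(C))
    nu <- Inf
  } else {
    df_candidates <- box_df(fit, C)
    nu <- select_df(df_candidates, df_rule)
  }
  critical <- equicoordinate_quantile(R_hat, nu, alpha)
  p_adj <- adjusted_pvalues(ts$statistics, R_hat, nu)
  sci <- cbind(lower = ts$estimates - critical * ts$se,
               upper = ts$estimates + critical * ts$se)
  rownames(sci) <- rownames(C)
  reject <- abs(ts$statistics) >= critical

  structure(list(estimates = stats::setNames(ts$estimates, rownames(C)),
                 se = ts$se, statistics = ts$statistics, T0 = ts$T0,
                 R_hat = R_hat, df_candidates = df_candidates, df_used = nu,
                 df_rule = df_rule, critical = critical, p_adjusted = p_adj,
                 sci = sci, alpha = alpha, reject = reject,
                 reject_global = any(reject), contrast = C, fit = fit,
                 method = "mvt"),
            class = "mctp_t")
}

# resolve family names, check dimensions against the design
.conform_contrast <- function(C, design) {
  if (is.character(C) && length(C) == 1L)
    C <- build_contrast(C, design$a, labels = design$group_levels)
  C <- as.matrix(C)
  if (ncol(C) != design$a)
    stop("contrast matrix has ", ncol(C), " columns but the design has ",
         design$a, " cells")
  if (is.null(rownames(C))) rownames(C) <- paste0("c", seq_len(nrow(C)))
  C
}

#' @export
print.mctp_t <- function(x, digits = 4, ...) {
  cat("Multiple contrast test, multivariate-t approximation\n")
  cat(sprintf("df rule: %s (nu = %s), alpha = %g, critical value = %.4f\n",
              x$df_rule, format(x$df_used, digits = 5), x$alpha, x$critical))
  tab <- data.frame(estimate = x$estimates, lower = x$sci[, "lower"],
                    upper = x$sci[, "upper"], statistic = x$statistics,
                    p_adjusted = x$p_adjusted,
                    row.names = rownames(x$contrast))
  print(round(tab, digits))
  cat(sprintf("Global max statistic T0 = %.4f: %s H0 at level %g\n",
              x$T0, if (x$reject_global) "reject" else "do not reject",
              x$alpha))
  invisible(x)
}
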