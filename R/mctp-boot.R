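#' Wild-bootstrap resampling variables
#'
#' Multiplies leverage-scaled ANCOVA residuals by independent Rademacher
#' signs: \eqn{Y_{ij}^* = \hat\epsilon_{ij} W_{ij} (1 - p_{ij})^{-1/2}},
#' with \eqn{p_{ij}} the hat-matrix diagonal of the full regressor matrix
#' B = (X, M). Draws consume the caller's RNG stream, so reproducibility is
#' controlled by `set.seed()` before the call.
#'
#' @param residuals numeric vector of OLS ANCOVA residuals.
#' @param hat_diag leverage vector of the same length, all entries < 1.
#' @param weights optional fixed sign vector (testing hook); by default
#'   Rademacher signs are drawn.
#' @return numeric vector of resampling responses.
#' @export
wild_sample <- function(residuals, hat_diag, weights = NULL) {
  if (length(residuals) != length(hat_diag))
    stop("residuals and hat_diag must have the same length")
  if (any(hat_diag >= 1))
    stop("leverage >= 1 at rows: ",
         paste(which(hat_diag >= 1), collapse = ", "))
  if (is.null(weights))
    weights <- sample(c(-1, 1), length(residuals), replace = TRUE)
  residuals * weights / sqrt(1 - hat_diag)
}

#' Max contrast statistic of one wild-bootstrap sample
#'
#' Recomputes the OLS effects, the subject-wise (White) covariance and the
#' contrast statistics on a resampling vector \eqn{Y^*}:
#' \eqn{\hat b^*} is the first a entries of \eqn{(B'B)^{-1}B'Y^*},
#' \eqn{\hat\Psi^*} the upper-left a x a block of
#' \eqn{(B'B)^{-1}B'\,\hat\Sigma^*\,B(B'B)^{-1}} with \eqn{\hat\Sigma^*} the
#' diagonal of squared OLS residuals of the resample. Returns
#' \eqn{T_0^* = \max_\ell |c_\ell'\hat b^*| / \sqrt{c_\ell'\hat\Psi^* c_\ell}}.
#' A resample with zero contrast variance is degenerate and yields `Inf`
#' (conservative).
#'
#' @param sample numeric resampling vector \eqn{Y^*} of length N.
#' @param design an [build_design()] object.
#' @param C contrast matrix (q x a).
#' @return scalar \eqn{T_0^*}.
#' @export
boot_statistic <- function(sample, design, C) {
  stopifnot(inherits(design, "ancova_design"))
  C <- .conform_contrast(C, design)
  .boot_T0(matrix(sample, ncol = 1L), design, C)[1L]
}

# vectorized bootstrap kernel: Ystar is N x nboot, returns T0* per column
.boot_T0 <- function(Ystar, design, C) {
  a <- design$a
  PB <- design$PB                         # (a+M) x N
  coefs <- PB %*% Ystar                   # (a+M) x nboot
  res <- Ystar - design$B %*% coefs       # OLS residuals per resample
  R2 <- res * res                         # Sigma* diagonals
  CP <- C %*% PB[seq_len(a), , drop = FALSE]  # q x N
  num <- CP %*% Ystar                     # c' b*  (q x nboot)
  V <- (CP * CP) %*% R2                   # c' Psi* c (q x nboot)
  T2 <- ifelse(V > 0, abs(num) / sqrt(V), Inf)
  T2[num == 0 & V == 0] <- Inf            # fully degenerate resample
  apply(T2, 2L, max)
}

#' Wild-bootstrap multiple contrast test (complete heteroscedasticity)
#'
#' Tests \eqn{c_\ell'b = 0} and the global hypothesis in the ANCOVA model
#' under complete (subject-wise) heteroscedasticity. The observed statistics
#' use the OLS effects with White's covariance estimator; the null
#' distribution of the max statistic is approximated by the wild bootstrap
#' with Rademacher weights: each of `nboot` resamples multiplies the
#' leverage-scaled residuals by random signs and recomputes \eqn{T_0^*}.
#' The critical value is the \eqn{\lceil(1-\alpha)(nboot+1)\rceil}-th order
#' statistic of the bootstrap draws — the empirical \eqn{(1-\alpha)} quantile
#' under the convention that makes the critical-value rule and the p-value
#' rule \eqn{p_\ell = (1 + \#\{T_{0,b}^* \ge |T_\ell|\})/(nboot+1)} coincide.
#' The correlation between contrasts is never estimated: it is carried
#' implicitly by the joint resampling distribution.
#'
#' @param data an [ancova_data()] object.
#' @param C contrast matrix or family name.
#' @param alpha familywise level.
#' @param nboot number of bootstrap samples (>= 100), default 10000.
#' @param seed integer seed; mandatory for reproducibility.
#' @param keep_draws keep the vector of \eqn{T_{0,b}^*} in the result.
#' @return An object of class `"mctp_boot"` with `estimates`, `statistics`,
#'   `T0`, `critical`, `p_adjusted`, `sci`, `reject`, `reject_global`,
#'   `nboot`, `seed`, `n_degenerate` and optionally `boot_draws`.
#' @examples
#' d <- make_fixture("three_group", seed = 3)
#' boot_mctp(d, "dunnett", nboot = 500, seed = 42)
#' @export
boot_mctp <- function(data, C = "dunnett", alpha = 0.05, nboot = 10000L,
                      seed, keep_draws = FALSE) {
  if (missing(seed) || !is.numeric(seed))
    stop("an integer `seed` is required for a reproducible bootstrap")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  nboot <- as.integer(nboot)
  if (nboot < 100L) stop("nboot must be at least 100")

  fit <- fit_ancova(data, mode = "subjectwise", estimator = "ols")
  design <- fit$design
  C <- .conform_contrast(C, design)
  ts <- test_statistics(fit, C)

  scaled <- fit$residuals / sqrt(1 - design$hat_diag)
  N <- length(scaled)
  set.seed(as.integer(seed))
  # blocks keep memory flat for large nboot
  block <- max(1L, min(nboot, as.integer(2e6 / N)))
  draws <- numeric(nboot)
  done <- 0L
  while (done < nboot) {
    nb <- min(block, nboot - done)
    W <- matrix(sample(c(-1, 1), N * nb, replace = TRUE), N, nb)
    draws[done + seq_len(nb)] <- .boot_T0(scaled * W, design, C)
    done <- done + nb
  }
  n_degenerate <- sum(!is.finite(draws))

  sorted <- sort(draws)                  # +Inf sorts last
  k <- min(nboot, as.integer(ceiling((1 - alpha) * (nboot + 1))))
  critical <- sorted[k]
  p_adj <- vapply(abs(ts$statistics),
                  function(t) (1 + sum(draws >= t)) / (nboot + 1), numeric(1))
  names(p_adj) <- rownames(C)
  sci <- cbind(lower = ts$estimates - critical * ts$se,
               upper = ts$estimates + critical * ts$se)
  rownames(sci) <- rownames(C)
  reject <- p_adj <= alpha

  structure(list(estimates = stats::setNames(ts$estimates, rownames(C)),
                 se = ts$se, statistics = ts$statistics, T0 = ts$T0,
                 critical = critical, p_adjusted = p_adj, sci = sci,
                 alpha = alpha, reject = reject,
                 reject_global = any(reject), nboot = nboot,
                 seed = as.integer(seed), n_degenerate = n_degenerate,
                 boot_draws = if (keep_draws) draws else NULL,
                 contrast = C, fit = fit, method = "boot"),
            class = "mctp_boot")
}

#' @export
print.mctp_boot <- function(x, digits = 4, ...) {
  cat("Multiple contrast test, wild bootstrap (Rademacher weights)\n")
  cat(sprintf("nboot = %d, seed = %d, alpha = %g, critical value = %.4f\n",
              x$nboot, x$seed, x$alpha, x$critical))
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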