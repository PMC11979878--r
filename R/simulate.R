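#' Simulation scenario configuration
#'
#' Describes one Monte-Carlo scenario of the type-I-error / power study:
#' a groups with sample sizes from one of three allocation schemes, errors
#' from a standardized distribution, one of three variance regimes, a
#' contrast family, an inferential method and an alternative. The data
#' generating process is
#' \deqn{Y_{ik} = b_i + M_{ik}'p + \sigma_{ik}(Z_{ik} - EZ)/\mathrm{sd}(Z),}
#' with m = 4 covariates drawn from N(7, 1), covariate effects
#' p = (0.2, 1, 1.5, 2)' and baseline \eqn{b_i = 7} under the null.
#'
#' Allocation schemes: `balanced` is (8, ..., 8) + r; `unbalanced_np`
#' (negative pairing: largest variance with smallest group) is
#' (8, 10, 13, 17, 20) + r; `unbalanced_pp` is (20, 17, 13, 10, 8) + r;
#' vectors are truncated to the first a entries. Variance regimes:
#' `homoscedastic` sets all \eqn{\sigma = 1}; `groupwise` uses
#' \eqn{(\sigma_1, 1.5, 1, 0.5, 0.75)} truncated to a with
#' \eqn{\sigma_1 \in \{2, 4, 6\}}; `complete` draws
#' \eqn{\sigma_{ik} \sim U(0.5, 4)} per subject. Alternatives shift the
#' baseline: `alt1` \eqn{b = (7 - \delta, 7, \dots)}, `alt2`
#' \eqn{b = (7 - \delta, 7 + \delta, 7, \dots)}.
#'
#' @param a number of groups (2..5 with the printed sigma/n vectors).
#' @param n_scheme `"balanced"`, `"unbalanced_np"` or `"unbalanced_pp"`.
#' @param r nonnegative even sample-size offset.
#' @param error_dist `"normal"`, `"t5"`, `"chisq12"` or `"exp1"`.
#' @param variance `"homoscedastic"`, `"groupwise"` or `"complete"`.
#' @param sigma1 first-group standard deviation in the groupwise regime
#'   (2, 4 or 6).
#' @param contrast contrast family name or matrix.
#' @param method `"t_mean"`, `"t_min"`, `"t_max"`, `"asymptotic"` or
#'   `"boot"`.
#' @param alpha nominal familywise level.
#' @param nsim number of Monte-Carlo replicates.
#' @param nboot bootstrap samples per replicate (boot method only).
#' @param seed master seed; every replicate seed derives from it.
#' @param alternative `"null"`, `"alt1"` or `"alt2"`.
#' @param delta effect size in [0, 2].
#' @param m number of covariates; `p`, `b0` the covariate effects and
#'   baseline.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(a = 3, n_scheme = c("balanced", "unbalanced_np",
                                           "unbalanced_pp"),
                       r = 0, error_dist = c("normal", "t5", "chisq12",
                                             "exp1"),
                       variance = c("homoscedastic", "groupwise", "complete"),
                       sigma1 = 2, contrast = "dunnett",
                       method = c("t_mean", "t_min", "t_max", "asymptotic",
                                  "boot"),
                       alpha = 0.05, nsim = 1000L, nboot = 1000L, seed = 1L,
                       alternative = c("null", "alt1", "alt2"), delta = 0,
                       m = 4L, p = c(0.2, 1, 1.5, 2), b0 = 7) {
  n_scheme <- match.arg(n_scheme)
  error_dist <- match.arg(error_dist)
  variance <- match.arg(variance)
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (a < 2 || a > 5) stop("a must be between 2 and 5")
  if (r < 0 || r != round(r) || r %% 2 != 0)
    stop("r must be a nonnegative even integer")
  if (variance == "groupwise" && !sigma1 %in% c(2, 4, 6))
    stop("sigma1 must be 2, 4 or 6 in the groupwise regime")
  if (delta < 0 || delta > 2) stop("delta must lie in [0, 2]")
  if (alternative == "null" && delta != 0)
    stop("delta must be 0 under the null")
  if (length(p) != m) stop("p must have length m")
  n <- switch(n_scheme,
              balanced      = rep(8L, 5L),
              unbalanced_np = c(8L, 10L, 13L, 17L, 20L),
              unbalanced_pp = c(20L, 17L, 13L, 10L, 8L))[seq_len(a)] + r
  sigma <- switch(variance,
                  homoscedastic = rep(1, a),
                  groupwise     = c(sigma1, 1.5, 1, 0.5, 0.75)[seq_len(a)],
                  complete      = NULL)
  structure(list(a = a, n_scheme = n_scheme, r = r, n = n,
                 error_dist = error_dist, variance = variance,
                 sigma = sigma, contrast = contrast, method = method,
                 alpha = alpha, nsim = as.integer(nsim),
                 nboot = as.integer(nboot), seed = as.integer(seed),
                 alternative = alternative, delta = delta, m = as.integer(m),
                 p = p, b0 = b0),
            class = "sim_config")
}

#' Table-1 simulation settings
#'
#' Shorthand for the five benchmark scenarios: (1) a = 3, unbalanced NP,
#' group-wise heteroscedasticity; (2) a = 5, balanced, complete
#' heteroscedasticity; (3) a = 3, balanced, homoscedastic; (4) a = 4,
#' unbalanced NP, homoscedastic; (5) a = 3, unbalanced PP, complete
#' heteroscedasticity.
#'
#' @param setting integer 1..5.
#' @param ... further arguments passed to [sim_config()] (e.g. `r`,
#'   `error_dist`, `contrast`, `method`, `nsim`, `seed`).
#' @return a `"sim_config"`.
#' @export
sim_setting <- function(setting, ...) {
  stopifnot(setting %in% 1:5)
  base <- switch(setting,
    list(a = 3, n_scheme = "unbalanced_np", variance = "groupwise"),
    list(a = 5, n_scheme = "balanced",      variance = "complete"),
    list(a = 3, n_scheme = "balanced",      variance = "homoscedastic"),
    list(a = 4, n_scheme = "unbalanced_np", variance = "homoscedastic"),
    list(a = 3, n_scheme = "unbalanced_pp", variance = "complete"))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Generate one synthetic ANCOVA dataset
#'
#' Draws one dataset from the configured data generating process. Errors are
#' standardized analytically — \eqn{Z} is centered by its mean and scaled by
#' its standard deviation (t5: sd \eqn{\sqrt{5/3}}; \eqn{\chi^2_{12}}: mean
#' 12, sd \eqn{\sqrt{24}}; Exp(1): mean 1, sd 1) — then multiplied by
#' \eqn{\sigma_{ik}} of the variance regime. Covariates are redrawn on every
#' call. Consumes the caller's RNG stream.
#'
#' @param config a [sim_config()].
#' @return an [ancova_data()] object.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  N <- sum(n)
  a <- config$a
  g <- rep(seq_len(a), times = n)
  b <- rep(config$b0, a)
  if (config$alternative == "alt1") b[1L] <- config$b0 - config$delta
  if (config$alternative == "alt2") {
    b[1L] <- config$b0 - config$delta
    b[2L] <- config$b0 + config$delta
  }
  M <- matrix(stats::rnorm(N * config$m, mean = 7, sd = 1), N, config$m)
  Z <- switch(config$error_dist,
              normal  = stats::rnorm(N),
              t5      = stats::rt(N, df = 5) / sqrt(5 / 3),
              chisq12 = (stats::rchisq(N, df = 12) - 12) / sqrt(24),
              exp1    = stats::rexp(N, rate = 1) - 1)
  sik <- if (config$variance == "complete")
    stats::runif(N, 0.5, 4) else config$sigma[g]
  y <- b[g] + as.numeric(M %*% config$p) + sik * Z
  ancova_data(y, factor(g, levels = seq_len(a)), covariates = M)
}

# run the configured test on one dataset; returns global and per-contrast
# rejection flags (boot seeds are drawn by the caller)
.run_method <- function(data, config, boot_seed = NULL) {
  Cm <- if (is.character(config$contrast) && length(config$contrast) == 1L)
    build_contrast(config$contrast, config$a) else config$contrast
  if (config$method == "boot") {
    res <- boot_mctp(data, Cm, alpha = config$alpha, nboot = config$nboot,
                     seed = boot_seed)
    return(list(global = res$reject_global, individual = res$reject))
  }
  fit <- fit_ancova(data, mode = "groupwise", estimator = "gls_plugin")
  ts <- test_statistics(fit, Cm)
  R_hat <- correlation_matrix(fit$Psi_hat, Cm)
  nu <- if (config$method == "asymptotic") Inf else
    select_df(box_df(fit, Cm), sub("^t_", "", config$method))
  p <- adjusted_pvalues(ts$statistics, R_hat, nu)
  list(global = min(p) <= config$alpha, individual = p <= config$alpha)
}

#' Monte-Carlo type-I-error study
#'
#' Runs `nsim` independent generate-and-test cycles under the null and
#' reports the global familywise rejection proportion with its binomial
#' Monte-Carlo standard error, plus per-contrast rejection rates. Replicate
#' seeds are derived deterministically from the master seed, so the result
#' is a pure function of the configuration. Replicates that fail (e.g.
#' degenerate degrees of freedom) are counted and reported; more than 1%
#' failures aborts the study.
#'
#' @param config a [sim_config()] with `alternative = "null"`.
#' @return list of class `"sim_result"`: `rejection_rate`, `mc_se`,
#'   `per_contrast`, `n_failed`, `config`.
#' @export
type1_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$alternative != "null")
    stop("type1_study requires alternative = 'null'; use power_study")
  .mc_study(config)
}

#' Monte-Carlo power study over an effect-size grid
#'
#' One [type1_study()]-style run per value of delta under the configured
#' alternative; the delta = 0 entry doubles as a type-I-error check.
#'
#' @param config a [sim_config()] with `alternative` `"alt1"` or `"alt2"`.
#' @param delta_grid numeric vector of effect sizes in [0, 2]; default the
#'   grid 0, 0.2, ..., 2.
#' @return list of `"sim_result"` objects, one per delta.
#' @export
power_study <- function(config, delta_grid = seq(0, 2, by = 0.2)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$alternative == "null")
    stop("power_study requires alternative 'alt1' or 'alt2'")
  lapply(delta_grid, function(d) {
    cfg <- config
    cfg$delta <- d
    .mc_study(cfg)
  })
}

.mc_study <- function(config) {
  nsim <- config$nsim
  set.seed(config$seed)
  data_seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  boot_seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  q <- if (is.character(config$contrast))
    nrow(build_contrast(config$contrast, config$a)) else
      nrow(config$contrast)
  global <- logical(nsim)
  indiv <- matrix(FALSE, nsim, q)
  failed <- 0L
  for (s in seq_len(nsim)) {
    set.seed(data_seeds[s])
    out <- tryCatch({
      dat <- generate_dataset(config)
      .run_method(dat, config, boot_seed = boot_seeds[s])
    }, error = function(e) e)
    if (inherits(out, "error")) {
      failed <- failed + 1L
      if (failed > 0.01 * nsim)
        stop("more than 1% of replicates failed; last error: ",
             conditionMessage(out))
      global[s] <- NA
    } else {
      global[s] <- out$global
      indiv[s, ] <- out$individual
    }
  }
  ok <- !is.na(global)
  rate <- mean(global[ok])
  structure(list(rejection_rate = rate,
                 mc_se = sqrt(rate * (1 - rate) / sum(ok)),
                 per_contrast = colMeans(indiv[ok, , drop = FALSE]),
                 n_failed = failed, nsim_effective = sum(ok),
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo study: %d replicates, method %s, %s contrast\n",
    x$config$nsim, x$config$method,
    if (is.character(x$config$contrast)) x$config$contrast else "custom"))
  cat(sprintf("global rejection rate %.4f (MC SE %.4f), %d failed\n",
              x$rejection_rate, x$mc_se, x$n_failed))
  invisible(x)
}
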