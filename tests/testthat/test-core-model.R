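test_that("design matrices: projections, hat diagonal and error handling", {
  # two balanced groups, no covariates: leverage is 1/n within each group
  d <- ancova_data(c(1, 2, 3, 4), rep(c("g1", "g2"), each = 2))
  des <- build_design(d)
  expect_equal(unname(des$X),
               matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2))
  expect_equal(des$hat_diag, rep(0.5, 4))

  # projection identities on a batch of random designs
  for (seed in 1:5) {
    dat <- random_ancova(seed, a = sample(2:4, 1), m = sample(0:2, 1))
    ds <- build_design(dat)
    expect_lt(max(abs(ds$Q %*% ds$X)), 1e-10)
    expect_lt(max(abs(ds$P %*% ds$P - ds$P)), 1e-10)
    expect_lt(max(abs(ds$P + ds$Q - diag(dat$N))), 1e-10)
    expect_true(all(ds$hat_diag >= 0 & ds$hat_diag < 1))
    expect_equal(sum(ds$hat_diag), ds$rank_B)
  }

  # leverage matches the normal-equations oracle for per-group intercepts
  # plus a common slope
  d3 <- ancova_data(rnorm(9), gl(3, 3), covariates = cbind(x = 1:9))
  ds3 <- build_design(d3)
  B <- ds3$B
  lev_oracle <- diag(B %*% solve(crossprod(B)) %*% t(B))
  expect_equal(ds3$hat_diag, lev_oracle, tolerance = 1e-12)

  # covariate collinear with the group indicators -> rank error naming it
  bad <- ancova_data(rnorm(6), gl(2, 3),
                     covariates = cbind(flat = rep(c(1, 5), each = 3)))
  expect_error(build_design(bad), "rank deficient.*flat")
})

test_that("group-wise variance estimator: exactness, df rule, unbiasedness", {
  # no covariates: reduces to the textbook sample variance
  d <- ancova_data(c(1, 2, 3, 4, 0, 0, 1, 1), rep(1:2, each = 4))
  v <- estimate_sigma_groupwise(d, build_design(d))
  expect_equal(unname(v$group_sigma2[1]), 5 / 3)
  expect_equal(v$group_df, c(3, 3))
  expect_equal(v$diag, rep(unname(v$group_sigma2), each = 4))

  # responses exactly linear in the covariate -> zero variance
  x <- c(1, 2, 3, 4, 5)
  d0 <- ancova_data(c(2 + 3 * x, rnorm(5)), rep(1:2, each = 5),
                    covariates = c(x, rnorm(5)))
  v0 <- estimate_sigma_groupwise(d0, build_design(d0))
  expect_equal(unname(v0$group_sigma2[1]), 0, tolerance = 1e-20)

  # equals the residual mean square of the per-group regression (lm oracle)
  dat <- random_ancova(11, a = 3, m = 2)
  vv <- estimate_sigma_groupwise(dat, build_design(dat))
  for (i in 1:3) {
    idx <- as.integer(dat$groups) == i
    fit <- lm(dat$y[idx] ~ dat$covariates[idx, ])
    expect_equal(unname(vv$group_sigma2[i]),
                 sum(resid(fit)^2) / fit$df.residual, tolerance = 1e-10)
  }

  # degenerate group is a hard error naming the group
  small <- ancova_data(rnorm(7), rep(c("tiny", "big"), c(2, 5)),
                       covariates = rnorm(7))
  expect_error(estimate_sigma_groupwise(small, build_design(small)),
               "tiny")

  # Monte-Carlo unbiasedness: mean of sigma_hat^2 within 3 MC SEs
  set.seed(404)
  sig <- c(2, 1, 0.5)
  nrep <- 3000L
  est <- matrix(0, nrep, 3)
  for (r in seq_len(nrep)) {
    dr <- ancova_data(rnorm(90, sd = rep(sig, each = 30)), gl(3, 30),
                      covariates = rnorm(90))
    est[r, ] <- estimate_sigma_groupwise(dr, build_design(dr))$group_sigma2
  }
  for (i in 1:3) {
    se <- sd(est[, i]) / sqrt(nrep)
    expect_lt(abs(mean(est[, i]) - sig[i]^2), 3 * se)
  }
})

test_that("subject-wise variance estimator squares the residuals", {
  d <- ancova_data(rnorm(6), gl(2, 3))
  des <- build_design(d)
  v <- estimate_sigma_subjectwise(c(1, -2, 3, 0, 0, 0), des)
  expect_equal(v$diag, c(1, 4, 9, 0, 0, 0))
  expect_identical(v$mode, "subjectwise")
  expect_error(estimate_sigma_subjectwise(1:5, des), "length")

  # residuals from a real OLS fit agree with the elementwise-square oracle
  dat <- random_ancova(21, m = 1)
  f <- fit_ancova(dat, mode = "subjectwise", estimator = "ols")
  expect_equal(f$variance$diag, f$residuals^2, tolerance = 1e-12)
})

test_that("generating matrices satisfy the unbiasedness identities", {
  # Sigma = I, no covariates: D Y gives the group means
  d <- random_ancova(31, a = 3, m = 0)
  des <- build_design(d)
  gm <- generating_matrices(des)
  expect_equal(as.numeric(gm$D %*% d$y),
               as.numeric(tapply(d$y, d$groups, mean)), tolerance = 1e-12)
  expect_equal(nrow(gm$A), 0L)

  # Sigma = I with covariates: DX = I, DM = 0, AX = 0
  d2 <- random_ancova(32, a = 4, m = 2)
  des2 <- build_design(d2)
  gm2 <- generating_matrices(des2)
  expect_lt(max(abs(gm2$D %*% des2$X - diag(4))), 1e-10)
  expect_lt(max(abs(gm2$D %*% des2$M)), 1e-10)
  expect_lt(max(abs(gm2$A %*% des2$X)), 1e-10)

  # p_hat = AY is invariant to shifts in the X-space
  gamma <- c(3, -1, 2, 0.5)
  y_shift <- d2$y + gamma[as.integer(d2$groups)]
  expect_equal(as.numeric(gm2$A %*% d2$y),
               as.numeric(gm2$A %*% y_shift), tolerance = 1e-10)

  # strictly positive variance required in GLS mode
  v <- estimate_sigma_subjectwise(rep(0, d2$N), des2)
  expect_error(generating_matrices(des2, v), "strictly positive")
})

test_that("fit_ancova: Welch reduction, oracles and residual identity", {
  # two groups, no covariates: group means and diag(sigma_i^2 / n_i)
  d <- make_fixture("welch_pair", seed = 5)
  f <- fit_ancova(d)
  mns <- tapply(d$y, d$groups, mean)
  vrs <- tapply(d$y, d$groups, var)
  expect_equal(unname(f$b_hat), as.numeric(mns), tolerance = 1e-12)
  expect_equal(unname(diag(f$Psi_hat)), as.numeric(vrs / d$n),
               tolerance = 1e-12)
  expect_lt(max(abs(f$Psi_hat[1, 2])), 1e-15)

  # residual identity y = X b + M p + residuals for both estimators
  for (est in c("gls_plugin", "ols")) {
    dat <- random_ancova(41, a = 3, m = 2)
    ff <- fit_ancova(dat, mode = "groupwise", estimator = est)
    recon <- ff$b_hat[as.integer(dat$groups)] +
      as.numeric(dat$covariates %*% ff$p_hat) + ff$residuals
    expect_equal(unname(recon), dat$y, tolerance = 1e-10)
    expect_true(all(eigen(ff$Psi_hat, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))
  }

  # OLS point estimates equal the single stacked least-squares solve
  dat <- random_ancova(42, a = 3, m = 2)
  f_ols <- fit_ancova(dat, mode = "subjectwise", estimator = "ols")
  orc <- stacked_lm_oracle(dat)
  expect_equal(unname(f_ols$b_hat), as.numeric(orc$b), tolerance = 1e-10)
  expect_equal(unname(f_ols$p_hat), as.numeric(orc$p), tolerance = 1e-10)

  # GLS plug-in agrees with a naive transcription of the printed formulas
  # (explicit inverses, independent code path), N = 9, a = 3, 1 covariate
  set.seed(43)
  d9 <- ancova_data(rnorm(9, rep(c(1, 2, 3), each = 3)), gl(3, 3),
                    covariates = cbind(x = rnorm(9, 7)))
  f9 <- fit_ancova(d9, mode = "groupwise", estimator = "gls_plugin")
  des9 <- build_design(d9)
  Sinv <- diag(1 / f9$variance$diag)
  X <- des9$X; M <- des9$M; Q <- des9$Q
  A_naive <- solve(t(M) %*% Q %*% Sinv %*% M) %*% t(M) %*% Q %*% Sinv
  XtS <- solve(t(X) %*% Sinv %*% X) %*% t(X) %*% Sinv
  D_naive <- XtS - XtS %*% M %*% A_naive
  expect_equal(unname(f9$p_hat), as.numeric(A_naive %*% d9$y),
               tolerance = 1e-10)
  expect_equal(unname(f9$b_hat), as.numeric(D_naive %*% d9$y),
               tolerance = 1e-10)

  # parameter recovery at n = 200 per group: p_hat within 3 SEs of p
  set.seed(44)
  cfg <- sim_config(a = 3, variance = "homoscedastic", nsim = 1,
                    seed = 99, m = 4, p = c(0.2, 1, 1.5, 2))
  cfg$n <- rep(200L, 3)
  dat200 <- generate_dataset(cfg)
  fr <- fit_ancova(dat200)
  se <- sqrt(diag(fr$Xi_hat))
  expect_true(all(abs(fr$p_hat - c(0.2, 1, 1.5, 2)) <= 3 * se))
})
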