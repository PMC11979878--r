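test_that("contrast statistics and correlation matrix", {
  d <- random_ancova(1, a = 3, m = 1)
  f <- fit_ancova(d)
  C <- build_contrast("dunnett", 3)
  ts <- test_statistics(f, C)
  expect_equal(ts$statistics,
               as.numeric(C %*% f$b_hat) /
                 unname(sqrt(diag(C %*% f$Psi_hat %*% t(C)))),
               tolerance = 1e-12)
  expect_equal(ts$T0, max(abs(ts$statistics)))

  # a contrast row orthogonal to b_hat gives a zero statistic
  b <- f$b_hat
  row <- c(b[2] - b[3], b[3] - b[1], b[1] - b[2])  # c'b = 0 and sums to 0
  ts0 <- test_statistics(f, contrast_matrix(rbind(row)))
  expect_equal(ts0$statistics, 0, tolerance = 1e-10)

  # classical Dunnett correlation 0.5 under balance without covariates
  set.seed(2)
  db <- ancova_data(rnorm(30), gl(3, 10))
  fb <- fit_ancova(db)
  Psi_bal <- diag(rep(mean(diag(fb$Psi_hat)), 3))  # force equal variances
  Rb <- correlation_matrix(Psi_bal, build_contrast("dunnett", 3))
  expect_equal(Rb[1, 2], 0.5, tolerance = 1e-12)

  # random PSD Psi: agreement with the cov-to-corr oracle
  set.seed(3)
  A <- matrix(rnorm(16), 4)
  Psi <- crossprod(A)
  C4 <- build_contrast("tukey", 4)
  R <- correlation_matrix(Psi, C4)
  V <- C4 %*% Psi %*% t(C4)
  expect_equal(R, cov2cor(V), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(diag(R)), rep(1, 6))
})

test_that("Box df reproduces Welch-Satterthwaite and closed forms", {
  # two groups, no covariates: the textbook Welch df formula
  d <- make_fixture("welch_pair", seed = 9)
  f <- fit_ancova(d)
  nu <- box_df(f, build_contrast("dunnett", 2))
  v <- tapply(d$y, d$groups, var); n <- d$n
  welch <- (v[1] / n[1] + v[2] / n[2])^2 /
    (v[1]^2 / (n[1]^2 * (n[1] - 1)) + v[2]^2 / (n[2]^2 * (n[2] - 1)))
  expect_equal(unname(nu), unname(welch), tolerance = 1e-9)

  # equal variances, balanced: nu = 2(n - 1) exactly
  set.seed(10)
  y <- rnorm(16)
  y2 <- c(y[1:8], y[1:8] + 1)           # identical group variances
  db <- ancova_data(y2, gl(2, 8))
  fb <- fit_ancova(db)
  nub <- box_df(fb, build_contrast("dunnett", 2))
  expect_equal(unname(nub), 2 * (8 - 1), tolerance = 1e-9)

  # grand-mean row, three groups, no covariates: independent symbolic oracle
  set.seed(11)
  d3 <- ancova_data(rnorm(24, sd = rep(c(1, 2, 0.5), times = c(7, 8, 9))),
                    rep(1:3, times = c(7, 8, 9)))
  f3 <- fit_ancova(d3)
  C3 <- build_contrast("grandmean", 3)
  nu3 <- box_df(f3, C3)
  # oracle built from first principles with the group-mean operator
  n <- d3$n; s2 <- f3$variance$group_sigma2
  for (l in 1:3) {
    cl <- C3[l, ]
    var_l <- sum(cl^2 * s2 / n)
    den <- sum((cl^2 / n)^2 * s2^2 / (n - 1))
    expect_equal(unname(nu3[l]), var_l^2 / den, tolerance = 1e-9)
  }

  # groupwise mode required
  fs <- fit_ancova(d3, mode = "subjectwise")
  expect_error(box_df(fs, C3), "group-wise")
})

test_that("df selection rules", {
  cand <- c(3.2, 5.8, 4.0)
  expect_identical(select_df(cand, "mean"), 4)
  expect_identical(select_df(cand, "min"), 3.2)
  expect_identical(select_df(cand, "max"), 5.8)
  expect_equal(select_df(c(2.5, 2.5), "mean"), 3)  # half away from zero
  expect_error(select_df(numeric(0)), "empty")
  expect_error(select_df(c(0.5, 3), "min"), ">= 1")
  # ordering: min <= rounded mean + 0.5 and mean - 0.5 <= max
  for (s in 1:10) {
    set.seed(s)
    cc <- runif(4, 1, 30)
    expect_lte(select_df(cc, "min"), select_df(cc, "mean") + 0.5)
    expect_gte(select_df(cc, "max"), select_df(cc, "mean") - 0.5)
  }
})

test_that("simultaneous confidence intervals are compatible", {
  d <- random_ancova(12, a = 4, m = 1)
  f <- fit_ancova(d)
  C <- build_contrast("tukey", 4)
  ts <- test_statistics(f, C)
  crit <- 2.5
  ci <- simultaneous_ci(f, C, crit)
  expect_true(all(ci[, "lower"] <= ts$estimates &
                    ts$estimates <= ci[, "upper"]))
  excl <- ci[, "lower"] > 0 | ci[, "upper"] < 0
  expect_equal(excl, abs(ts$statistics) > crit, ignore_attr = TRUE)
  # widths scale linearly in the critical value
  ci2 <- simultaneous_ci(f, C, 2 * crit)
  expect_equal(ci2[, "upper"] - ci2[, "lower"],
               2 * (ci[, "upper"] - ci[, "lower"]), tolerance = 1e-12)
  expect_error(simultaneous_ci(f, C, -1), "positive")
})

test_that("mctp_t_test: Welch reduction, determinism, df-rule ordering", {
  # a = 2 reduces to the Welch-Satterthwaite t test
  d <- make_fixture("welch_pair", seed = 13)
  r <- mctp_t_test(d, "dunnett", df_rule = "min")
  tt <- t.test(d$y[d$groups == "B"], d$y[d$groups == "A"])
  expect_equal(unname(r$statistics), unname(tt$statistic), tolerance = 1e-6)
  expect_equal(unname(r$df_used), unname(tt$parameter), tolerance = 1e-6)
  expect_equal(unname(r$p_adjusted), tt$p.value, tolerance = 1e-3)

  # identical input twice: bit-identical output
  d3 <- make_fixture("three_group", seed = 14)
  r1 <- mctp_t_test(d3, "tukey")
  r2 <- mctp_t_test(d3, "tukey")
  expect_identical(r1$p_adjusted, r2$p_adjusted)
  expect_identical(r1$critical, r2$critical)

  # min rule is most conservative: smallest df, largest critical value
  rmin <- mctp_t_test(d3, "tukey", df_rule = "min")
  rmean <- mctp_t_test(d3, "tukey", df_rule = "mean")
  rmax <- mctp_t_test(d3, "tukey", df_rule = "max")
  rasy <- mctp_t_test(d3, "tukey", df_rule = "asymptotic")
  expect_lte(rmin$df_used, rmean$df_used + 0.5)
  expect_lte(rmean$df_used - 0.5, rmax$df_used)
  expect_gte(rmin$critical, rmean$critical - 1e-6)
  expect_gte(rmean$critical, rmax$critical - 1e-3)
  expect_gte(rmax$critical, rasy$critical - 1e-6)
})

test_that("consonance and SCI compatibility hold on randomized fixtures", {
  # deeper sweep lives in the acceptance suite; a quick pass here
  for (s in 1:25) {
    dat <- random_ancova(100 + s, a = sample(2:4, 1), m = sample(0:1, 1))
    fam <- sample(c("dunnett", "tukey", "grandmean"), 1)
    r <- mctp_t_test(dat, fam, alpha = 0.05)
    expect_identical(r$reject_global, any(r$reject))
    expect_equal(unname(r$reject), unname(abs(r$statistics) >= r$critical))
    excl <- r$sci[, "lower"] > 0 | r$sci[, "upper"] < 0
    expect_equal(unname(excl), unname(abs(r$statistics) > r$critical))
  }
})
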