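---
title: "Multiple contrast tests for heteroscedastic ANCOVA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple contrast tests for heteroscedastic ANCOVA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetmctp)
```

## The model and why it is needed

Randomized multi-arm experiments — pre-clinical dose studies, multi-arm
clinical trials — usually need treatment effects adjusted for covariates
such as baseline measurements or body weight, and real data rarely offer
the homoscedastic normal errors the classical ANCOVA F-test assumes.
`hetmctp` works in the general heteroscedastic ANCOVA model

$$Y_{ij} = b_i + \sum_{l=1}^{M} p_l M_{ij}^{(l)} + \epsilon_{ij},
  \qquad i = 1, \dots, a,\; j = 1, \dots, n_i,$$

with independent mean-zero errors whose variances may differ **between
groups** ($\mathrm{Var}(\epsilon_{ij}) = \sigma_i^2$, the Behrens–Fisher
setting typical of pre-clinical trials) or **between subjects**
($\sigma_{ij}^2$, *complete* heteroscedasticity, typical of observational
data). Two-way and higher layouts are handled by sub-indexing $i$, i.e. by
crossing the factors into cells.

A global F-type test answers only "is there any difference?". The multiple
contrast test procedure (MCTP) instead tests $q$ user-chosen linear
hypotheses $H_0^{(\ell)}: c_\ell' b = 0$ jointly, through the max-type
statistic $T_0 = \max_\ell |T_\ell|$ with
$T_\ell = c_\ell'\hat b / \sqrt{c_\ell'\hat\Psi c_\ell}$. Because critical
values come from the joint distribution of $(T_1, \dots, T_q)$, the global
decision is consonant with the individual ones, and the simultaneous
confidence intervals are compatible: an interval excludes zero exactly when
the corresponding hypothesis is rejected.

## Estimation

Effects are linear in the data, $\hat b = DY$ and $\hat p = AY$, with
generating matrices

$$A = (M'Q\Sigma^{-1}M)^{-1} M'Q\Sigma^{-1}, \qquad
  D = (X'\Sigma^{-1}X)^{-1}X'\Sigma^{-1}(I - MA),$$

where $X$ is the block design matrix, $Q = I - X(X'X)^{-1}X'$ the
(unweighted) projection complement, and $\Sigma$ either the identity (OLS)
or a plug-in variance estimate (GLS). Covariances follow the sandwich form
$\hat\Psi = D\hat\Sigma D'$, $\hat\Xi = A\hat\Sigma A'$. Two variance
estimators are available:

* **group-wise**: $\hat\sigma_i^2 = Y_i'Q_iY_i / (n_i - 1 -
  \mathrm{rank}(M_i))$, the unbiased residual mean square of the per-group
  regression on an intercept and the group's covariates;
* **subject-wise**: White's heteroscedasticity-consistent diagonal of
  squared OLS residuals.

Note that $Q$ in the generating matrices is the unweighted complement; with
$\Sigma = I$ this yields the exact unbiasedness identities $DX = I$,
$DM = 0$, $AX = 0$ (verified in the test suite). For general plug-in
$\Sigma$ the estimator remains a consistent linear estimator but is not the
fully iterated GLS solution; we implement the formulas exactly as stated
above. Both point-estimator pairings are available; the defaults couple
group-wise variances with the GLS plug-in effects and subject-wise
variances with OLS effects, matching the inferential theory built on each.

Degenerate groups with $n_i - 1 - \mathrm{rank}(M_i) < 1$ raise an error
rather than falling back to pooling: the group-wise estimator is undefined
there, and silent pooling would change the method. Ranks are numerical
(SVD with tolerance $\max(n_i, M)\,\varepsilon\, s_1$), and all linear
systems are solved by factorization, never by forming explicit inverses.

## Small-sample inference

**Multivariate-t approximation** (group-wise heteroscedasticity). The
vector of statistics is approximated by a central $t(\nu, \hat R)$
distribution with $\hat R$ the correlation matrix of $C\hat\Psi C'$.
Because the contrasts differ in their degrees of heteroscedasticity, a
Box-type (Satterthwaite) candidate is computed per contrast,

$$\nu_\ell = \frac{(c_\ell'\hat\Psi c_\ell)^2}
  {\sum_i s_{\ell i}^2 \hat\sigma_i^4 / (n_i - 1 - \mathrm{rank}(M_i))},
  \qquad s_{\ell i} = \sum_{j \in i} (c_\ell'D)_j^2,$$

which reduces exactly to the Welch–Satterthwaite degree of freedom in the
two-sample case without covariates — the construction's motivating
benchmark, and the criterion we used to fix the exact algebraic reading of
the formula. One of the $q$ candidates is then selected by rule: `min`
(most conservative), `max`, or `mean` rounded to the nearest integer (the
default; rounding attaches only to the mean rule, min/max stay
real-valued). An `asymptotic` rule skips the correction and uses the
multivariate normal limit.

**Wild bootstrap** (complete heteroscedasticity). Resampling responses
$Y_{ij}^* = \hat\epsilon_{ij} W_{ij} (1 - p_{ij})^{-1/2}$ multiply
leverage-scaled OLS residuals by Rademacher signs
($P(W = \pm 1) = 1/2$); each of `nboot` resamples recomputes the OLS
effects, White covariance and max statistic $T_0^*$. No correlation matrix
is ever estimated on this path — the dependence between contrasts is
carried by the joint resampling distribution.

## Numerical choices

* Equicoordinate rectangle probabilities use randomized quasi-Monte-Carlo
  integration (absolute tolerance $5\times10^{-4}$) under a fixed internal
  seed, with the caller's RNG state saved and restored; results are
  bit-reproducible and user simulations are never perturbed. Univariate
  cases use closed forms.
* The rectangle integrator accepts only integer degrees of freedom, so
  real-valued df (min/max rules) are handled by mixing the normal rectangle
  probability over the chi-square scale $S = \sqrt{\chi^2_\nu/\nu}$ with
  48-node Gauss–Legendre quadrature; the two paths agree at integer df.
* Singular correlation matrices (the grand-mean family keeps all $a$
  linearly dependent rows, as is conventional) are integrated without
  regularization; positive semi-definiteness is checked with an eigenvalue
  floor of $-10^{-8}$.
* The bootstrap critical value is the
  $\lceil (1-\alpha)(nboot+1)\rceil$-th order statistic of the draws. We
  chose this convention over interpolating quantile definitions because it
  is the unique one under which the critical-value rule, the p-value rule
  $p_\ell = (1 + \#\{T^*_{0,b} \ge |T_\ell|\})/(nboot+1)$, and the global
  decision coincide (up to ties of probability zero), so rejection flags,
  adjusted p-values and interval coverage can never disagree. The
  `(1+count)/(nboot+1)` p-value keeps $p > 0$ at finite `nboot`.
* Degenerate bootstrap draws (zero contrast variance in a resample) are
  mapped to $+\infty$ rather than dropped — conservative, and `nboot`
  stays fixed.
* Group levels are ordered by first appearance in the input and recorded
  in every result; with two factors, cells are crossed with the first
  factor varying slowest, a convention shared by the reader and
  `factorial_contrast()` so the contrast columns always align with the
  cells.

## Contrasts

`build_contrast()` provides Dunnett (many-to-one), Tukey (all-pairwise)
and grand-mean (centering matrix $P_a = I_a - J_a/a$) families. For
two-way layouts, `factorial_contrast()` builds Kronecker products of
centering matrices and averaging vectors: $P_{a_1} \otimes 1'_{a_2}/a_2$
(first main effect), $1'_{a_1}/a_1 \otimes P_{a_2}$ (second main effect),
$P_{a_1} \otimes P_{a_2}$ (interaction). This is the standard factorial
decomposition of the cell-means space; main-effect rows compare each
level's average over the other factor against the grand mean. Custom
matrices are accepted; rows that do not sum to zero are allowed with a
warning since the statistics are defined for arbitrary rows.

## The simulation engine and what it emulates

`sim_config()` / `sim_setting()` describe Monte-Carlo scenarios:
$a \in \{3,4,5\}$ groups with balanced $(8,\dots,8)+r$ or unbalanced
$(8,10,13,17,20)+r$ (negative pairing) / $(20,17,13,10,8)+r$ (positive
pairing) allocations, four standardized error laws (normal, $t_5$,
$\chi^2_{12}$, Exp(1) — standardization is analytic, so skewness and
kurtosis are preserved while variances stay controlled), and three
variance regimes: homoscedastic ($\sigma = 1$), group-wise
($(\sigma_1, 1.5, 1, 0.5, 0.75)$ with $\sigma_1 \in \{2,4,6\}$), and
complete ($\sigma_{ik} \sim U(0.5, 4)$). Four covariates are drawn from
$N(7, 1)$ with effects $p = (0.2, 1, 1.5, 2)'$ and baseline $b_i = 7$;
alternatives shift the first group by $-\delta$ (`alt1`) or additionally
the second by $+\delta$ (`alt2`), $\delta \in [0, 2]$.

Covariates are redrawn in every replicate — the unconditional reading of
the generator; conditioning on a fixed covariate matrix would estimate a
slightly different (conditional) error rate. Replicate seeds are derived
deterministically from the master seed, so a study is a pure function of
its configuration regardless of execution order. Failed replicates (e.g.
degenerate degrees of freedom) are counted, and more than 1% failures
aborts the study.

The generator emulates independent subjects with linear covariate effects
and error laws of controlled shape. It does not emulate measurement error
in covariates, covariate-treatment interactions, dependence between
subjects, or missing data — passing operating-characteristic checks here
says nothing about those complications on real data.

Default desk-scale study sizes are `nsim = 5000` replicates for the
t-approximation checks and `nsim = 1000` with `nboot = 1000` for bootstrap
checks — enough for a binomial Monte-Carlo standard error of about 0.3–0.7
percentage points at the 5% level, which is the resolution at which the
operating characteristics are stated. Larger runs are a matter of raising
`nsim`/`nboot`.

## Worked example

```{r example}
d <- make_fixture("three_group", seed = 7)
mctp_t_test(d, "dunnett", df_rule = "mean")
```

The bootstrap analogue, valid under complete heteroscedasticity:

```{r boot}
boot_mctp(d, "dunnett", nboot = 2000, seed = 42)
```

A two-way layout with six dose levels and two sexes, testing the dose main
effect against the grand mean:

```{r factorial}
f <- make_fixture("factorial_2x6", seed = 1)
C_dose <- factorial_contrast(c(2, 6), "main_second",
                             labels = list(c("f", "m"),
                                           c("0", "50", "100",
                                             "250", "500", "1000")))
mctp_t_test(f, C_dose, df_rule = "min")
```

## Known limitations

* All tests are two-sided; one-sided variants are not provided.
* The min/mean/max selection collapses $q$ heteroscedastic degrees of
  freedom into one; with many groups and very small samples the mean and
  max rules can be liberal, the min rule conservative. The bootstrap is
  the better choice for very small samples, skewed errors, or many groups.
* Strongly skewed error laws combined with negatively correlated contrast
  families (grand mean) leave a residual liberality that disappears only
  slowly with $n$; with moderate group sizes the rejection rate can sit
  near 8% instead of 5%, a limit the simulation engine reproduces.
* Group-wise variance estimation needs $n_i - 1 - \mathrm{rank}(M_i) \ge
  1$ in every group; there is deliberately no pooled fallback.
```
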