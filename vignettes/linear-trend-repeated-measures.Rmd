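---
title: "Testing time, group and interaction effects in linear-trend repeated measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing time, group and interaction effects in linear-trend repeated measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linetrend)
```

## The data and the model

linetrend targets studies in which a continuous response is measured
repeatedly on each subject and the subject profiles are linear, or at least
monotone, in time. The canonical representation is long format — one row per
measurement, columns `subject`, `group`, `time`, `response` (`rm_data()`,
`read_rm()`). Long format is deliberately primary: two of the three analysis
routes accept unbalanced profiles and subject-specific measurement times, so
balance is checked only where a method actually needs it (`as_wide()`
constructs the subject-by-time matrix and fails, naming the offending
subjects, when any cell is missing; `complete_subjects()` extracts the
complete-case subset first).

The generating model used throughout the simulation machinery, and the
implicit working model of all three routes, is a linear trend with a subject
random intercept:

$$Y_{ij} = \beta_0 + \beta_1 X_i + \beta_2 t_{ij} + \beta_3 (t_{ij} X_i)
          + b_{0i} + \varepsilon_{ij},$$

with $X_i \in \{0, 1\}$ a two-group indicator, $b_{0i} \sim N(0,
\sigma_b^2)$ independent of the errors, and $\varepsilon_i$ multivariate
normal with one of three covariance structures: independent
($\sigma^2 I$), first-order autoregressive ($\sigma^2 [\rho^{|j-j'|}]$,
geometric decay in the time-grid position), or unstructured (an arbitrary
positive-definite matrix). The three effects of interest map onto the
coefficients: time $\leftrightarrow \beta_2$, group $\leftrightarrow
\beta_1$, interaction $\leftrightarrow \beta_3$.

## The three analysis routes

**Summary measures (SMA).** Each subject is reduced to a least-squares slope
(rate of change; defined whenever the subject has two distinct times) and a
mean over time (overall level). Under no time effect the population mean
slope is zero, so the time test is a one-sample $t$ on the pooled slopes
(`sma_time_test()`). Under no interaction the group slope distributions share
a mean, so the interaction test is an ordinary k-sample comparison of slopes
(`sma_interaction_test()`); the group test applies the same machinery to the
subject means (`sma_group_test()`). Variants: pooled-variance Student $t$
(two groups), one-way ANOVA $F$, Wilcoxon–Mann–Whitney / Kruskal–Wallis on
midranks with the usual large-sample approximations, and a permutation test.
Because the summaries are computed per subject, the SMA tolerates unbalanced
and incomplete profiles, and its tests are exact under normality of the
summaries regardless of the within-subject error covariance — the property
that makes it robust where a misspecified mixed model is not.

**Profile analysis (UMA).** The wide response matrix is transformed by a
contrast matrix $C$ ((m−1)×m, rows summing to zero, rank m−1; adjacent
differences by default, `adjacent_contrast()`). Parallelism of the group
profiles is a one-way MANOVA on the transformed variables: Wilks'
$\Lambda = \det(E)/\det(E+H)$ with Rao's $F$ approximation, which is exact
for $k = 2$ (where it coincides with a two-sample Hotelling $T^2$) and for
$m - 1 \le 2$. The time test is a one-sample Hotelling $T^2$ on the pooled
differences with $F = \frac{N-m+1}{(N-1)(m-1)} T^2$ on $(m-1, N-m+1)$ df.
The group test delegates to the SMA mean test, which is generally more
efficient than a MANOVA comparison of full mean vectors. All results are
invariant to the choice of $C$ (asserted numerically in the tests), to a
common shift of all responses, and — for the contrast-based tests — to
subject-specific shifts.

**Linear mixed models.** `lmm_fit()` estimates the model by REML through
`nlme::lme` — the standard tool for structured residual covariances — with a
random intercept or random intercept + slope (unstructured 2×2 G), and IND /
AR1 / UNS error structures (AR1 via `corAR1` on the time-grid position, UNS
via `corSymm` plus `varIdent`, i.e. a full correlation matrix with
heterogeneous variances). Wald $F$ tests are marginal (Type III) with
inner–outer denominator df: between-subject terms (group) are tested against
$N - p_{between}$ df, within-subject terms (time, interaction) against
$N_{obs} - N - p_{within}$. With two groups every term has a single
numerator df, so the marginal/sequential distinction is inert for the
standard model; marginal tests are the package convention. A random
intercept with IND errors implies compound symmetry of the marginal
covariance — equal variances, equal covariances $\sigma_b^2$ — which the
test suite asserts on the fitted covariance.

## Tunable parameters

* `alpha` (default 0.05) — nominal level; only affects the `reject` flag.
* `variant` (default `"t"`, two groups) — k-sample test for the
  interaction/group effects. The parametric variants assume normal summaries
  with equal group variances; rank variants drop normality; the permutation
  variant drops both at the cost of Monte Carlo error.
* `perm_reps` (default 9999) and `seed` — the permutation test permutes group
  labels of the summaries and recomputes the parametric statistic; the
  two-sided p-value is $(1 + \#\{|T^*| \ge |T|\})/(1 + B)$, bounded below by
  $1/(B+1)$. When two groups admit at most `perm_reps` distinct label
  assignments, all of them are enumerated and the exact conditional p-value
  is returned instead.
* `random`, `structure` (`lmm_fit`) — random-effects and error-covariance
  structures. The UNS structure has $m(m+1)/2$ free parameters and is only
  identified with balanced complete data and more subjects than time points.
* `ref_level` — group reference level for the fixed-effect coding;
  lexicographic by default. Test statistics for the three effects do not
  depend on it.
* Simulation: `m`, `n_per_group`, `beta`, `b0_sd` (default 0.25), `sigma2`
  (default 0.5), `rho` (default 0.7), `uns_R`. The defaults are the study
  conditions of the reference design: times $t_j = 2j$, $\beta_0 = 2$, two
  equal groups, with power settings pairing $\beta_1$ with an $m$-adjusted
  $\beta_2$ (0.040/0.020/0.010 halving as $m$ doubles) and interaction rows
  using $\beta_3$ alone (`trend_study_grid()`).

## What the simulation emulates — and what it does not

`simulate_trend_data()` draws exactly from the model above: normal random
intercepts, jointly normal errors generated through the Cholesky factor of
the structure's covariance, a shared equally spaced time grid, no missing
data. Passing tests therefore demonstrate correct behaviour under ideal
linear-trend conditions; they say nothing about non-normal errors, dropout or
informative missingness, nonlinear profiles, or heterogeneous group
covariances — all of which occur in real longitudinal data. The generator's
per-replicate RNG substream is derived deterministically from
`(seed, config_id, rep_index)`, so any single replicate can be regenerated in
isolation and full studies are byte-reproducible under a fixed seed.

The unstructured-errors simulation arm needs a generating covariance matrix;
`default_uns_matrix()` supplies a reproducible synthetic one (variances
uniform in [0.25, 1], correlations decaying geometrically with base 0.6).
It is a documented stand-in — conclusions about the UNS-true arm are
qualitative, not tied to any published matrix.

## Numerical choices and degenerate inputs

* **Feasibility is an error, never silent imputation.** The parallelism test
  requires $N - k > m - 1$; the Hotelling time test requires $N > m$ (the
  boundary case $N = m$ leaves a single denominator df and a numerically
  fragile covariance, and is treated as infeasible, matching the behaviour of
  the multivariate route in sparse designs); the UNS mixed model requires
  complete balanced data, more subjects than time points and fewer covariance
  parameters than observations. Inside the simulation engine these surface as
  `NA` cells with reason codes and are excluded from rate denominators
  (`n_valid`/`n_failed`).
* **Degenerate tests** (zero slope variance, zero pooled variance, fewer than
  two distinct times for a slope) raise errors rather than returning NaN.
* **Mixed-model non-convergence** is caught per replicate: the fit is flagged
  (`converged = FALSE`) with the optimizer message; study cells count such
  replicates in `n_failed`. Variance components may legitimately reach the
  boundary ($\hat\sigma_b^2 \approx 0$); `lme`'s log-parameterisation keeps
  them nonnegative.
* **Information criteria**: AIC $= -2\ell_R + 2d$ and BIC
  $= -2\ell_R + d\log N_{obs}$ with $d$ = fixed effects + free
  variance-covariance parameters (including the residual SD). Conventions for
  the BIC sample size differ across software (some use $N_{obs} - p$ under
  REML, and parameter-counting conventions for heavily parameterised
  unstructured fits differ by ±2); the package states and tests its own
  convention rather than chasing any particular one. REML criteria are
  comparable across covariance structures at a fixed fixed-effects
  specification, which is how `lmm_menu()` uses them.
* **All-flat profiles** in the Hotelling test (every subject constant) give
  $T^2 = 0$, $p = 1$ — no evidence of a time effect — instead of a singular
  covariance error.

## Scale of the bundled experiments

The acceptance script (`scripts/acceptance.R`) reproduces the headline
rejection-rate cells at 1000 replicates for the SMA/UMA tests and 400–500
replicates for the two mixed-model cells — enough for a Monte Carlo SE of
about 0.007–0.025 depending on the rate, which is the package's chosen
precision/runtime balance. The test suite compares such estimates against
reference rates (themselves 1000-replicate Monte Carlo values) using three
standard errors of the *difference* of two independent binomial proportions;
a one-sided band around a noisy reference would reject a correct
implementation too often.

## Known limitations

* Exactly one grouping factor; no additional covariates, no baseline
  adjustment, no multiple response variables.
* The SMA weighs every subject's summary equally; with wildly different
  per-subject measurement counts a weighted analysis would be more efficient.
* Rank-based variants use large-sample approximations; exact small-sample
  permutation distributions are available only through the permutation
  variant.
* Satterthwaite/Kenward–Roger denominator df are not provided; the
  inner–outer rule is the single, documented convention, and p-values for
  small unbalanced designs inherit its known crudeness.
* The simulation engine generates two groups; k > 2 group simulation is out
  of scope (the analysis functions themselves accept any k).
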