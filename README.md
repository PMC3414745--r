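# linetrend

Analysis of repeated-measures data whose subject profiles follow a linear
trend — the situation of growth curves, washout experiments, or any study
where a response is measured on each subject at a series of time points and
the questions are:

* **time** — does the response change over time at all?
* **group** — do the groups differ in overall level?
* **group × time (interaction)** — do the groups change at different rates?

The package implements and compares three analysis routes for such data, plus
a Monte Carlo engine for studying their type-I error and power:

1. **Summary-measure approach (SMA).** Each subject's profile is reduced to a
   single number and ordinary univariate tests are applied:
   * time: one-sample *t* on the per-subject least-squares slopes
     *b*ᵢ = Σ(t−t̄)(y−ȳ) / Σ(t−t̄)², pooled over groups, against 0;
   * interaction: two-sample pooled *t* (or one-way ANOVA *F*,
     Wilcoxon–Mann–Whitney, Kruskal–Wallis, or a label-permutation test) on
     the slopes across groups;
   * group: the same k-sample tests applied to each subject's mean response
     over time.
   The SMA handles unbalanced and incomplete profiles and needs no covariance
   modelling; it is the safe default when the number of measurements is large
   relative to the sample size.
2. **Unstructured multivariate approach (UMA, profile analysis).** The m time
   points are an unordered multivariate response with common covariance Σ:
   parallelism (interaction) is a one-way MANOVA on contrast-transformed
   responses using Wilks' Λ = det(E)/det(E+H) with Rao's F approximation
   (exact for two groups); the time effect is a one-sample Hotelling
   T² = N·d̄ᵀS⁻¹d̄ on the m−1 adjacent differences with
   F = (N−m+1)/((N−1)(m−1))·T²; the group effect uses the SMA mean test.
   Requires balanced complete data with more subjects than time points.
3. **Linear mixed models (LMM).** Yᵢ = Xᵢβ + Zᵢbᵢ + εᵢ fitted by REML
   (via nlme) with a random intercept or random intercept + slope and an
   independent (IND), first-order autoregressive (AR1, corr ρ^|j−j′|) or
   unstructured (UNS) within-subject error covariance. Wald F tests use
   inner–outer denominator degrees of freedom; competing covariance
   structures are ranked by AIC/BIC through a six-model menu.

The simulation module generates data from the linear-trend random-intercept
model Y.ij = β₀ + β₁Xᵢ + β₂t.j + β₃t.jXᵢ + b₀ᵢ + ε.ij (t.j = 2j, two groups)
under the three error structures and tabulates empirical rejection rates per
method and effect — the machinery used to demonstrate that the SMA holds its
size under every covariance structure while an LMM with a misspecified error
structure can badly inflate type-I error.

## Worked example

Simulate a small two-group growth study (4 visits, 14 subjects per group,
AR(1) errors, faster growth in group 1) and analyse it:

```r
library(linetrend)
cfg <- sim_config(m = 4, n_per_group = 14, beta = c(16, 1.2, 0.45, 0.25),
                  b0_sd = 1.5, sigma2 = 1, structure = "ar1")
ds  <- simulate_trend_data(cfg, rep_index = 1, seed = 20)

sma_time_test(ds)
#> time effect [sma-t]: t = 14.3740, df = 27, p = 3.595e-14 (reject at alpha = 0.05)
sma_interaction_test(ds)
#> interaction effect [sma-t]: t = -3.2151, df = 26, p = 0.00347 (reject at alpha = 0.05)
uma_parallelism_test(ds)
#> interaction effect [uma-wilks]: F = 3.4501, df = (3, 24), p = 0.03242 (reject at alpha = 0.05)

lmm_fit(ds, random = "intercept", structure = "ar1")
#> Linear mixed model: random intercept, AR1 errors (REML)
#> Fixed effects:
#> (Intercept)      group1        time group1:time
#>     16.0981      1.8657      0.4404      0.2201
#> sigma = 1.1406, rho = 0.8293
#> REML logLik = -143.74, d = 7, AIC = 301.48, BIC = 320.51
```

The mean slope is clearly nonzero (time effect), and both the slope *t* test
and the Wilks parallelism test detect the interaction — group 1 gains about
0.22 response units per time unit more than group 0, matching the generating
β₃ = 0.25. `analysis_report(ds)` assembles the full side-by-side table
(six LMMs with AIC/BIC plus SMA and UMA p-values per effect); here the AR1
random-intercept model wins both criteria (AIC 301, BIC 321), as it should
since it is the generating structure.

A rejection-rate study over many replicates:

```r
run_power_study(sim_config(5, 50, beta = c(2, 0.35, 0.040, 0)),
                methods = c("sma", "uma"), reps = 1000, seed = 1)
# one row per (method, effect): empirical rejection rate at alpha = 0.05,
# with n_valid / n_failed accounting for infeasible or non-converged cells
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/linetrend.R` (subcommands `sma`, `uma`, `lmm`, `report`,
`simulate`; see the script header for flags).

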