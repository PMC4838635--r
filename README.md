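# pmlfa — pairwise maximum likelihood factor analysis of ordinal data

Factor analysis of questionnaire items with ordered response scales
usually assumes that each observed code is a discretized, normally
distributed continuous score: item *i* shows category *x* when its
latent score falls between the thresholds τ<sub>x−1</sub> and
τ<sub>x</sub>. Full-information maximum likelihood for this model needs
one *k*-dimensional normal integral per response pattern and is
infeasible beyond a few items. **Pairwise maximum likelihood (PML)**
replaces the full-pattern likelihood with the sum of all bivariate
log-likelihoods,

ℓ(ρ, τ) = N Σ<sub>i&lt;j</sub> Σ<sub>x_i</sub> Σ<sub>x_j</sub>
p<sub>x_i x_j</sub> ln π<sub>x_i x_j</sub>(ρ<sub>ij</sub>, τ_i, τ_j),

which requires only bivariate normal rectangle probabilities and is
maximized in a single step over thresholds and structural parameters.

The hard part is assessing *model fit* after composite-likelihood
estimation. This package implements three likelihood-ratio statistics
computed at the PML estimates, for psychometricians and simulation
methodologists who need calibrated goodness-of-fit decisions for
ordinal confirmatory factor models:

| statistic | compares | df | caveat |
|---|---|---|---|
| `CF` | observed vs model-implied full-pattern proportions | m^k − n − 1 (or u_r − n − 1 on observed patterns) | breaks down when m^k ≫ N (sparseness) |
| `CM` | model of interest vs the baseline (all polychorics free) | k(k−1)/2 + k(m−1) − n₁ | pattern-table biases largely cancel |
| `CP` | max over pairs of bivariate LR statistics | m² − 2m, Bonferroni α* = 2α/(k(k−1)) | undefined for dichotomous items |

A synthetic-data generator (two-factor population model, fixed
discretization thresholds) and a Monte Carlo harness reproduce
calibration (type I error) and power studies of these statistics.

## Worked example

Generate 500 respondents on 6 three-category items from the two-factor
population model, then test the true two-factor model and a misspecified
one-factor model:

```r
library(pmlfa)
dat <- simulate_ordinal(generation_config(n = 500, m = 3, seed = 2026))
dat
#> Ordinal dataset: n = 500 respondents, k = 6 items, m = 3 categories
#>   distinct observed response patterns u_r = 191 (of 729 possible)

gof <- pml_gof(dat, "two_factor", alpha = 0.05)
gof$fit
#> PML fit of 'two_factor' model (k = 6, m = 3), N = 500
#>   objective (N-scale): -15170.0175   converged: TRUE   |grad|: 1.22e-07
#>   loadings:
#>       [,1]  [,2]
#> [1,] 0.906 0.000
#> [2,] 0.832 0.000
#> [3,] 0.708 0.529
#> [4,] 0.000 0.618
#> [5,] 0.000 0.706
#> [6,] 0.000 0.783
#>   factor correlation(s): 0.415
gof$statistics$CP
#> CP: max over 15 pairs = 6.850 at pair (4,5), df = 3
#>   Bonferroni alpha* = 0.00333 (family alpha = 0.050): retain

pml_gof(dat, "one_factor", alpha = 0.05)$statistics$CP
#> CP: max over 15 pairs = 38.165 at pair (1,2), df = 3
#>   Bonferroni alpha* = 0.00333 (family alpha = 0.050): reject
```

The loading estimates sit close to the population values (0.9, 0.8,
0.7 | 0.5, 0.6, 0.7, 0.8, factor correlation 0.5). The maximum pairwise
statistic retains the true model (6.85 on 3 df is far from the
Bonferroni-adjusted critical value) and rejects the one-factor model,
whose worst pair — the two strongest factor-1 items — misfits badly.

Monte Carlo studies run through the harness:

```r
des <- study_design(replications = 200, base_seed = 1, profile = "desk")
res <- run_study(des)        # rejection rates, CIs, statistic moments
accuracy_summary(run_condition(des, 1000, 3))   # loading bias / SD
```

A thin command-line wrapper with `fit`, `gof` and `study` subcommands is
installed at `inst/scripts/pmlfa.R`.

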