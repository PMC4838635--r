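---
title: "Pairwise maximum likelihood for ordinal factor models and its fit statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise maximum likelihood for ordinal factor models and its fit statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Questionnaire items with $m$ ordered response options are modelled as
discretizations of unobserved continuous scores. For item $i$, the
observed code $x_i \in \{1, \dots, m\}$ arises from a latent standard
normal score $x_i^*$ through thresholds
$-\infty = \tau_0 < \tau_1 < \dots < \tau_{m-1} < \tau_m = \infty$:

$$X_i = x_i \iff \tau_{x_i - 1} < x_i^* \le \tau_{x_i}.$$

The latent vector $(x_1^*, \dots, x_k^*)$ is multivariate normal with a
correlation matrix that is either unrestricted (the *baseline* model:
all $k(k-1)/2$ polychoric correlations free) or structured by a factor
model, $\Sigma = \Lambda \Phi \Lambda' + \Theta$ with
$\Theta = I - \mathrm{diag}(\Lambda \Phi \Lambda')$ so the latent
variances are 1. Identification fixes the latent means and variances
(zero/unit) and leaves all thresholds free; the alternative convention
(fixing two thresholds, freeing the variance) is not implemented because
it is unavailable for dichotomous items.

Full-information maximum likelihood would maximize the likelihood of
complete $k$-dimensional response patterns, which requires one
$k$-variate normal rectangle integral per pattern and is infeasible
beyond a handful of items. Pairwise maximum likelihood (PML) instead
maximizes, in a single step over thresholds and structural parameters
jointly,

$$\ell(\theta) = N \sum_{i<j} \sum_{x_i=1}^{m} \sum_{x_j=1}^{m}
  p_{x_i x_j} \ln \pi_{x_i x_j}(\rho_{ij}, \tau_i, \tau_j),$$

where $p_{x_i x_j}$ are observed pairwise proportions and
$\pi_{x_i x_j}$ bivariate normal rectangle probabilities. Only 2-D
integrals are ever needed for estimation. The multinomial constant is
dropped everywhere, consistently across models, so objective
*differences* are unaffected.

## Fit statistics

Because the distribution of the maximized composite likelihood itself is
not usable for testing, three likelihood-ratio statistics are computed
from a PML fit:

* **CF** compares observed full-pattern proportions $p_r$ with the
  model-implied pattern probabilities $\hat\pi_r$ evaluated at the PML
  estimates: $C_F = 2N \sum_r p_r \ln (p_r / \hat\pi_r)$, referred to a
  chi-square on $df_F = m^k - n - 1$ (all patterns) or
  $df_F^* = u_r - n - 1$ (observed patterns only). In the sparse regime
  $m^k \gg N$ both versions are known to behave badly; the package
  reproduces exactly that behaviour.
* **CM** is the difference of CF between the model of interest and the
  baseline model, on $df_M = k(k-1)/2 + k(m-1) - n_1$ degrees of
  freedom. The pattern-table biases largely cancel in the difference.
  $\hat\pi_r$ for each model comes from that model's *own* PML
  estimates. Because PML does not maximize the full-pattern likelihood,
  $C_M$ can be negative in finite samples; it is reported as-is with a
  flag (p-value 1), never truncated, so rejection-rate calibration is
  unaffected.
* **CP** avoids full patterns entirely: for every pair,
  $C_{P_{ij}} = 2N \sum p \ln(p/\hat\pi)$ on $df_P = m^2 - 2m$; the
  overall statistic is $\max_{ij} C_{P_{ij}}$, tested at the Bonferroni
  level $\alpha^* = 2\alpha / (k(k-1))$. For $m = 2$, $df_P = 0$ — the
  bivariate-normality hypothesis is saturated — and the function
  refuses. Ties in the maximum (probability-zero events) are reported
  as the first pair in $(i<j)$ order; the decision depends only on the
  maximum value.

## Numerical choices

* **Bivariate probabilities.** Every cell probability is a double
  difference of bivariate normal CDF values. These are computed by a
  vectorized implementation of the classical single-integral reduction
  (24-point Gauss–Legendre on the arcsine-transformed integrand),
  accurate to about 1e-10 for $|\rho| \le 0.925$; larger $|\rho|$
  falls back to deterministic Miwa quadrature from **mvtnorm**. The
  vectorization matters: one Monte Carlo study evaluates the kernel
  hundreds of millions of times.
* **Pattern probabilities.** $k$-variate rectangles use the Genz–Bretz
  randomized quasi-Monte Carlo algorithm of **mvtnorm** under a fixed
  internal seed (restored afterwards), so pattern tables are
  reproducible and do not perturb simulation streams. The default
  per-pattern absolute tolerance is 1e-6; the simulation harness uses
  1e-5, which keeps integration error roughly three orders of magnitude
  below the Monte Carlo spread of CF while making replicated
  64-pattern tables affordable. The full table is renormalized to sum
  to 1 before use in CF/CM (the raw deficit is recorded), because the
  accumulated per-pattern error would otherwise enter the likelihood
  ratio directly. Tables beyond 2e5 patterns are refused rather than
  attempted.
* **Optimization.** Parameters are transformed to enforce constraints
  smoothly: each item's thresholds become (first threshold, log-gaps),
  correlation-type parameters pass through $\tanh^{-1}$; loadings are
  unconstrained. The implied-correlation map is linear in
  $\Lambda \Phi \Lambda'$, so analytic gradients of the objective are
  available in closed form (bivariate densities for $\partial/\partial
  \rho$, conditional-normal CDF differences for thresholds) and are
  verified against numerical differentiation in the tests. L-BFGS-B
  with these gradients, plus a PORT polish when needed, drives the
  projected gradient of the per-observation objective below 1e-6
  (typically 1e-7).
* **Communalities above 1.** The population model itself gives item 3 a
  communality of 1.09 (negative residual variance) while its implied
  correlation matrix stays positive definite. Fitting therefore imposes
  no communality bound; `implied_correlations()` warns on improper
  values and errors only when an implied correlation reaches $\pm 1$.
* **Degenerate data.** Samples with an empty boundary category are kept
  (redrawing would bias rejection rates); the unidentified thresholds
  are pinned at $\pm 6$ and the fit flagged. Cell probabilities are
  floored at 1e-12 inside logarithms during line search; final fits are
  re-checked and flagged if a floored cell carries observed mass. A
  baseline polychoric estimate that fails positive definiteness (its 15
  correlations are unconstrained) is repaired by eigenvalue clipping
  before pattern integration, with a warning.
* **Starting values.** Thresholds from inverse-normal cumulative
  marginals; baseline correlations from a cheap per-pair profile
  maximization at those thresholds; loadings 0.5 and factor correlation
  0.25 for structured models. These are inside the parameter space and
  robust across all study conditions.

## What the generator emulates — and what it does not

`simulate_ordinal()` draws latent scores from the two-factor population
model (loadings 0.9/0.8/0.7 on factor 1 for items 1–3; 0.5/0.6/0.7/0.8
on factor 2 for items 3–6; factor correlation 0.5) and discretizes at
fixed common thresholds: 0 for $m=2$ (expected proportions .50/.50),
$\pm 0.6$ for $m=3$ (.27/.45/.27), and $-1.2, 0, 1.2$ for $m=4$
(.11/.39/.39/.11). Scores exactly at a cut-point (a probability-zero
event) go to the lower category.

The generator is faithful to exact underlying normality, equal
thresholds across items, and complete data. It does *not* emulate
skewed or heavy-tailed latent distributions, item-specific response
styles, missing responses, or unequal category counts across items — so
calibrated rejection rates here demonstrate correctness of the
statistics *under the model*, not robustness to violations of it.

## The Monte Carlo harness and problem sizes

`run_condition()`/`run_study()` reproduce the crossed design: sample
sizes 200/500/1000 by 2/3/4 response categories, three fitted models
per dataset, statistics aggregated into rejection rates with Wald
intervals $\widehat{RR} \pm 1.96\sqrt{\widehat{RR}(1-\widehat{RR})/R}$
(no continuity correction) plus statistic means and SDs. Replication
$r$ always uses seed `base_seed + r`, making single replications
individually reproducible and giving conditions common random numbers.
Non-converged fits still contribute their (computable) statistics and
are counted; hard failures are excluded with the denominator reported.

Two profiles are built in. The `desk` profile (the default: $R = 200$,
full-pattern statistics only for $m = 2$, where the table has 64 cells)
runs a full design in well under an hour on one core. The `full`
profile ($R = 1000$, CF/CM in all conditions) is the complete study; at
$m = 4$ it needs 4096 six-dimensional integrals per model per
replication and is intended for a cluster-scale run rather than a
desktop session. The package's own verification uses deliberately
scaled-down replication counts — e.g. $R = 500$ for calibration of the
maximum pairwise statistic (Monte Carlo SE of its mean
$\approx 2.85/\sqrt{500} \approx 0.13$), $R = 300$ for its small-sample
power, $R = 200$ for CM power at $m = 2$, and $9 \times R = 100$ for
efficiency of the loading estimates (Monte Carlo SE of an SD at
$R = 100$ is about $\mathrm{SD}/\sqrt{2 \cdot 99}$, i.e. roughly 7% of
its value) — with tolerances set from those Monte Carlo standard
errors, not from runtime considerations.

## Design choices where the design was open

* **Two-factor loading pattern.** The structural pattern (item 3
  cross-loading, 7 free loadings) is pinned down by the parameter-count
  bookkeeping: only this pattern yields $df_M = 7$ and
  $df_F = m^k - 15$ for the two-factor model. It is recorded here as a
  derived convention.
* **Scale of the convergence criterion.** Gradient tolerances are
  defined on the per-observation objective ($\ell / N$), so the same
  tolerance means the same estimation precision at every sample size.
* **One condition, one stream.** A counter-based seeding scheme
  (`base_seed + r`) was chosen over a single long stream so that any
  replication can be re-run in isolation when diagnosing a flagged fit.

## Known limitations

* No standard errors for PML estimates (sandwich/Godambe machinery is
  out of scope), and no robust weighted-least-squares comparison arm.
* CF/CM require an enumerable pattern table; $k$ or $m$ combinations
  beyond the ceiling are refused by design.
* The two-factor `study_model()` pattern is defined for $k = 6$;
  custom masks handle other designs.
* Missing data, per-item category counts, multi-group and longitudinal
  structures are not supported.
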