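---
title: "Liability-threshold ACE models for binary twin phenotypes: methods"
author: "twinliab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-threshold ACE models for binary twin phenotypes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinliab)
```

## The model

`twinliab` analyses a binary phenotype (here framed around smoking
initiation in young-adult twins) under the liability-threshold model: each
individual has a latent, standard-normal liability, and the observed 0/1
phenotype indicates whether the liability exceeds a threshold $\tau$. The
threshold is the normal quantile of one minus the prevalence, so testing
threshold equality between groups is exactly testing prevalence equality.

A pair of twins has bivariate-normal liabilities with correlation $\rho$
determined by the variance decomposition. With standardized variance
shares $A$ (additive genetic), $C$ (common environment) and $E$ (unique
environment), $A + C + E = 1$:

* MZ same-sex pairs: $\rho = A + C$ (MZ twins share all segregating
  genes and the common environment),
* DZ same-sex pairs: $\rho = \tfrac{1}{2}A + C$ (DZ twins share on
  average half their segregating genes),
* DZ opposite-sex (DOS) pairs: $\rho = \tfrac{1}{2} a_M a_F +
  R_{c,dos}\, c_M c_F$ with $a = \sqrt{A}$, $c = \sqrt{C}$ per sex.

$R_{c,dos}$ is the correlation between the male and female
shared-environment factors. $R_{c,dos} = 1$ means the same environmental
factors act in both sexes (no qualitative sex difference); the DOS group
is the only group informative about it. The DOS additive-genetic
correlation is fixed at 0.5 — qualitative sex differences are modelled on
C only.

All five zygosity-sex groups (MZM, DZM, MZF, DZF, DOS) from both birth
cohorts are fitted jointly by full-information maximum likelihood on the
raw pair records: a complete pair contributes the log of its joint cell
probability (a bivariate-normal orthant probability), a singleton twin
contributes its Bernoulli margin. Cohort moderation — the gene-environment
interaction question — enters by letting every share differ by cohort and
then testing the equalities.

## The model ladder

Eight nested specifications are compared by likelihood-ratio tests, each
sub-model against its parent (2 vs 1; 3, 4, 5 vs 2; 6 vs 5; 7, 8 vs 6),
with twice the log-likelihood difference referred to a chi-square with the
df difference. The decision threshold is $\alpha = 0.01$ throughout.

| # | specification | free parameters |
|---|---------------|-----------------|
| 1 | full ACE, sex- and cohort-specific, free $R_{c,dos}$ | 22 |
| 2 | $R_{c,dos} = 1$ | 20 |
| 3 | men's A, C, E equated over cohorts | 17 |
| 4 | women's A, C, E equated over cohorts | 17 |
| 5 | both sexes equated over cohorts | 14 |
| 6 | no sex differences | 11 |
| 7 | model 6 with A dropped | 10 |
| 8 | model 6 with C dropped | 10 |

Degrees of freedom are reported in the convention of the classical Mx
treatment of this design: `df = n_individuals - n_free + n_constraints`,
where the free count treats $a, c, e$ per equality class as separate
parameters and the constraint count is one unit-variance equation per sex
$\times$ cohort cell (4 with two cohorts). Thresholds stay free per sex
$\times$ zygosity $\times$ cohort (8 with two cohorts) in every model:
prevalence differences between cohorts are real and are tested separately,
so the ladder never equates thresholds across cohorts.

## Numerical choices

**Orthant probabilities.** The bivariate-normal upper tail is computed by
the Drezner–Wesolowsky-style Gauss–Legendre quadrature with the
high-correlation ($|\rho| \ge 0.925$) reformulation of Genz, using a
20-point rule throughout; against an adaptive-quadrature oracle the
absolute error is at machine precision, far below the 1e-10 the profile
likelihoods need. Correlations within 1e-12 of $\pm 1$ short-circuit to
the degenerate closed forms so likelihoods stay finite near boundary
correlations.

**Share parameterization.** Internally the optimizer works on a
stick-breaking logit scale: $A = \mathrm{logit}^{-1}(x)$, $C = (1 -
A)\,\mathrm{logit}^{-1}(y)$, $E$ the remainder. This keeps every iterate
inside the admissible simplex (a per-path logit cannot guarantee $a^2 +
c^2 \le 1$), while the reported df keep the free-$a,c,e$-plus-constraints
convention above. Negative variance components are out of model.

**$R_{c,dos}$.** The likelihood depends on $R_{c,dos}$ only through the
implied DOS correlation, so when free it is optimized directly on
$\mathrm{atanh}(\rho_{DOS})$ and $R_{c,dos}$ is derived afterwards. Two
consequences are intended. First, the ridge $R_{c,dos}\, c_M c_F$ that
appears when $C$ approaches zero is avoided. Second, $R_{c,dos}$ is not
clamped to $[-1, 1]$: when the truth is $R_{c,dos} = 1$, a hard bound
would put the null hypothesis of the model-2 comparison on the parameter
boundary and turn its likelihood-ratio statistic into a chi-bar-square
mixture; leaving the DOS correlation free preserves the regular
$\chi^2_2$ null that the ladder's p-values assume. Reported
$R_{c,dos}$ estimates can therefore exceed 1 when $\hat{C}$ is tiny; the
implied correlation, which is what the data identify, stays in $(-1, 1)$.

**Optimization.** Quasi-Newton (BFGS) on the transformed parameters with
convergence at relative tolerance 1e-12 on the deviance, from a fixed
five-point multi-start schedule over $(A, C, R_{c,dos})$ with thresholds
always started at the sample-prevalence quantiles; the best deviance wins,
ties broken by start order, so fits are deterministic given data and
spec. `run_ladder()` warm-starts every sub-model from its parent's
estimates. Likelihood-ratio statistics that come out negative within
optimizer tolerance (1e-6) are clamped to zero and flagged.

**Profile confidence intervals.** 95% intervals are likelihood-based: the
set of component values whose constrained deviance (all other free
parameters re-optimized) stays within 3.84 of the minimum. The search
scans outward from the MLE in eighths of the distance to the boundary and
refines by bisection (tolerance 1e-3 for ACE shares, 1e-4 for
tetrachoric correlations); intervals truncate at [0, 1] for shares and
$[-1, 1]$ for correlations, matching the boundary-touching intervals this
design typically produces for the smaller variance components.

**Tetrachoric estimation.** Per-group correlations maximize the
multinomial likelihood with thresholds free, jointly with $r$ on the
Fisher-z scale from three deterministic starts — mirroring the saturated
threshold model fitted before the structural models. Same-sex co-twins
share one threshold; DOS estimates separate male and female thresholds.
When pooling cohorts into a combined column the thresholds stay
cohort-specific (one correlation fitted jointly across per-cohort tables);
`pool_thresholds = TRUE` collapses to a single table instead, which is
slightly more constrained — the difference is negligible unless cohort
prevalences differ strongly, which here they do.

## The synthetic generator

The registry data the analysis is designed for are not redistributable,
so `synthetic_data` generates cohorts with the exact statistical structure
the analysis assumes: bivariate-normal liabilities at the implied
correlations, dichotomized at the configured thresholds, with singletons
drawn from the margins. One RNG stream per group $\times$ cohort is
derived from the master seed, so changing one group's counts never
perturbs another group's draws.

The `preset_paper_combined()` configuration encodes the study conditions:
two cohorts of 2669 and 2339 individuals in five groups (206/178/326/227/377
and 105/74/269/149/166 pairs, the remainder singletons), per-cell
prevalences from the printed prevalence table (same-sex and opposite-sex
DZ pooled per sex, e.g. 45.8% for MZ men in the first cohort, 14.6% in
the second), and generating shares at the combined-cohort estimates $A =
0.55$, $C = 0.23$, with $E = 0.22$ absorbing the one-point rounding
remainder so the liability variance is exactly 1; $R_{c,dos} = 1$. The
published group counts are internally inconsistent by a few individuals
with the published cohort totals; the preset keeps the published pair
counts and absorbs the difference into DOS singletons so the cohort
totals (2669, 2339, hence 5008 individuals and the printed df column) are
exact. DOS singleton sex is drawn with a configurable male fraction
(default 0.5).

What the generator deliberately does not emulate: survey item structure,
non-response and attrition, age heterogeneity within the 18–25 band,
zygosity misclassification, and longitudinal dependence between waves.
Passing tests therefore validate the estimation machinery under the
model's own assumptions — they cannot detect misspecification that real
registry data might exhibit.

## Validation strategy and problem sizes

The test suite checks, at sizes chosen to keep the full run in a few
minutes of one CPU:

* exact reproduction of every printed quantity that is a function of
  printed inputs (prevalence percentages, the df column, the
  likelihood-ratio arithmetic, the Falconer moment identities);
* the orthant probability against 1-D adaptive quadrature (1000 random
  inputs, absolute error below 1e-9);
* the tetrachoric optimizer against a brute-force profile grid search
  (20 random tables, grid step 1e-3);
* parameter recovery for the no-sex-difference model at 20,000 pairs per
  group (heritability within $\pm 0.03$) and 95% profile-CI coverage in
  the 93–97% band over 200 replications at the preset's own sample
  sizes;
* calibration of the ladder: the model-2 p-value is uniform under a true
  model-2 generating process (Kolmogorov–Smirnov over 300 replications),
  and at ten times the preset size the ladder accepts the true equalities
  and rejects dropping A or C in at least 90% of 20 seeds.

## Known limitations

* No ADE models, dominance, or continuous moderation of the paths;
  cohort moderation is categorical.
* Binary phenotypes only — no ordinal (multi-threshold) liabilities, and
  no covariates on thresholds.
* The asymptotic $\chi^2$ reference for the ladder is used as-is; for the
  boundary nulls of models 7 and 8 (a share fixed at zero) the test is
  conservative.
* Falconer decompositions are algebraic cross-checks and can leave the
  parameter space; the FIML estimates are the inferential results.
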