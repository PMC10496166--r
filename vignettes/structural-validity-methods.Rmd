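---
title: "Methods: structural validity of the IKDC with bifactor models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural validity of the IKDC with bifactor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promstruct)
```

## The scientific question

The IKDC Subjective Knee Form is an 18-item (plus one unscored item)
knee questionnaire scored as a single 0-100 total. Whether one number is
the right summary is a question of *structural validity*: do the item
covariances behave as if one latent construct generated them, or do the
items cluster into distinct subscales that deserve their own scores?
`promstruct` implements the full chain used to answer this: exploratory
factor analysis with a parallel-analysis retention rule, confirmatory
maximum-likelihood fits of competing structures (one-factor, two-factor,
four-factor, bifactor), the standard fit battery, and bifactor
reliability indices that quantify how much of the reliable variance a
single general factor carries.

The bifactor model is the centerpiece. Every item loads on a general
factor (the construct the total score is meant to measure) and on
exactly one of four orthogonal specific factors reflecting content and
wording clusters: symptoms (items 2, 3, 4, 6), activity level (1, 5, 7,
8, 10b), activities of daily living (9a-9f), and sport (9g-9i). If the
general factor dominates — high hierarchical omega, high explained
common variance, factor determinacy above 0.9 — the instrument is
"essentially unidimensional" and the single score is defensible even
when a plain one-factor model fits poorly.

## The estimation engine

All confirmatory models minimize the maximum-likelihood discrepancy

$$F_{ML} = \log|\Sigma(\theta)| + \operatorname{tr}\!\big(S\,\Sigma(\theta)^{-1}\big) - \log|S| - p,$$

with $\Sigma(\theta) = \Lambda \Phi \Lambda' + \Theta$ over the free
loadings, residual (co)variances, and factor correlations. Items are
treated as continuous: the raw 0-based category codes enter the sample
covariance $S$ with the unbiased $N-1$ denominator. No categorical
(threshold/WLSMV) estimation is provided; the attenuation that coarse
categories induce in product-moment correlations is accepted as part of
the method, and the synthetic-data generator reproduces it (see below).

Numerical choices:

* **Identification.** Factor variances are fixed to 1 by default, so the
  factor metric is standardized; the marker-loading convention (first
  loading fixed to 1, variances free) is available and yields the same
  discrepancy and the same standardized solution (checked to 1e-8 in the
  tests).
* **Parameterization.** Residual variances are log-transformed so
  $\Theta$ stays positive; free factor correlations travel through a
  row-normalized Cholesky factor, which keeps $\Phi$ a positive-definite
  correlation matrix at every iterate without constraints.
* **Optimizer.** Quasi-Newton (`nlminb`) with the analytic gradient
  $\partial F/\partial \Sigma = \Sigma^{-1}(\Sigma - S)\Sigma^{-1}$
  chained through the parameterization, followed by a BFGS polish if
  needed. Convergence requires a gradient max-norm below 1e-6; a fit
  that misses it is returned flagged (`converged = FALSE`), never
  silently.
* **Start values.** Loadings start at 0.7 times the item standard
  deviation (0.6/0.35 general/specific split for bifactor specs),
  residual variances at half the item variance, factor correlations at
  zero.
* **Sign convention.** Each loading column is flipped, if needed, so its
  sum is positive; $\Phi$ is flipped conformably.
* **Inadmissible solutions.** With log-parameterized variances a Heywood
  case appears as a residual variance driven to the zero boundary; the
  fit is flagged when a residual variance drops below 1e-6 of the item
  variance or a standardized loading exceeds 1 in magnitude.
* **Chi-square dialect.** $\chi^2 = (N-1)\,F_{ML}$ (Wishart convention)
  by default; a switch selects the $N$ multiplier used by some SEM
  programs. All indices inherit the chosen multiplier.

Degrees of freedom are counted from the specification alone:
$p(p+1)/2$ moments minus free parameters. For the four IKDC fixtures
over the 18 scored items this gives 135 (one-factor), 134 (two-factor),
129 (four correlated factors) and 117 (bifactor); a two-factor
exploratory solution has $171 - (36 + 18 - 1) = 118$.

One deliberate fixture decision: published item lists for the
two-factor structure leave item 3 (severity of pain) unassigned. A
two-factor model over all 18 items is required for the 134-df structure,
and item 3 belongs with the other pain items, so the fixture assigns it
to the symptoms factor.

## Exploratory analysis

`ml_efa()` is canonical ML factor analysis of the correlation matrix:
the discrepancy is concentrated over uniquenesses (given uniquenesses,
the optimal loadings follow from the eigen-decomposition of
$\Psi^{-1/2} R \Psi^{-1/2}$), and the profiled objective is minimized
over the uniquenesses with a 0.005 lower bound (hitting it raises a
Heywood warning). Because EFA and CFA minimize the same discrepancy, a
one-factor EFA and a one-factor CFA are the same fit — an identity the
test suite enforces to 1e-6, with `stats::factanal` as an independent
cross-check of the minimizer.

Oblique rotation uses gradient projection with the geomin criterion
($\epsilon = 0.01$, the common software default) or quartimin
(`"oblimin"`); ten random starts guard against geomin's local minima,
and a fixed rotation seed keeps results reproducible. Rotation never
touches the fit statistics.

`parallel_analysis()` implements Horn's procedure: 500 null datasets of
the same $N \times p$ shape (independent standard normals by default; a
column-permutation variant is available since published reports rarely
say which was used), the 95th percentile of each eigenvalue rank as the
reference, and retention from the top for as long as the observed
eigenvalue exceeds its reference. The sequential rule is used rather
than counting exceedances anywhere in the spectrum: under pure noise the
observed and reference spectra are draws from the same distribution, so
a non-leading rank exceeds its 95th percentile about 5% of the time and
a global count would suggest spurious factors; the sequential rule keeps
the null false-retention rate at the nominal level, which the
calibration tests verify (0 factors on noise in at least 19 of 20
seeds, 2 factors on clean two-factor data in at least 18 of 20).

## Fit indices

`compute_indices()` reports the chi-square test plus CFI, TLI, RMSEA
with a 90% interval, and SRMR against the independence baseline (free
variances, zero covariances; its ML solution is closed form with
$F_b = -\log|R|$ and $p(p-1)/2$ df):

* CFI with the conventional non-negativity flooring (clamped to [0, 1]
  by construction); TLI unclamped, since values outside [0, 1] are
  informative about baseline strength.
* RMSEA $= \sqrt{\max(\chi^2 - df, 0) / (df \cdot n)}$; interval limits
  solve for the noncentrality at which the observed $\chi^2$ sits at the
  0.95/0.05 quantiles of the noncentral chi-square, by bisection to
  1e-8 with the search bounded at $10\chi^2$. With $df = 0$ RMSEA and
  TLI are reported as undefined.
* SRMR on the correlation metric (residual moments standardized by the
  observed standard deviations), diagonal included by default; an
  off-diagonal-only switch covers the other common dialect, since
  published reports rarely say which was computed.

Adequacy verdicts use the conventional thresholds: CFI and TLI above
0.9, RMSEA and SRMR below 0.08, all standardized loadings above 0.3,
all factor correlations below 0.85.

Modification indices are univariate score tests: for each fixed residual
covariance or cross-loading, the expected chi-square drop
$\tfrac{n}{2} g_j^2 / (E_{jj} - E_{jf} E_{ff}^{-1} E_{fj})$ with $g$ the
discrepancy gradient and $E$ the expected information. They are ranked
descending; the engine can free them iteratively, but no claim is made
that any particular freed set reproduces someone else's overfitted
model.

## Bifactor reliability indices

On the standardized orthogonal solution with general loadings
$\lambda_g$, specific loadings $\lambda_s$ grouped by factor, and
residual variances $\theta$:

* $\omega = \big[(\sum\lambda_g)^2 + \sum_k (\sum_{i \in k}\lambda_s)^2\big] / \big[\text{same} + \sum\theta\big]$,
  with subscale versions restricting all sums to group $k$;
* $\omega_H = (\sum\lambda_g)^2 / \text{(the } \omega \text{ denominator)}$,
  and $\omega_{HS}$ per group analogously;
* $\omega_R = \omega_H / \omega$;
* $ECV_g = \sum\lambda_g^2 / (\sum\lambda_g^2 + \sum_k\sum\lambda_{s,k}^2)$,
  with the per-factor entries summing to one;
* $PUC$ = fraction of item pairs from different specific groups — purely
  structural, $119/153 \approx 0.778$ for the 4/5/6/3 partition over 18
  items;
* factor determinacy = square roots of
  $\operatorname{diag}(\Phi \Lambda' \Sigma^{-1} \Lambda \Phi)$.

These formulas assume bifactor orthogonality and the functions refuse
correlated-factor input. The "essentially unidimensional" flag emitted
by `bifactor_report()` ($\omega_H > 0.8$ for the general factor and
determinacy above 0.9) is an interpretive heuristic, marked as such, not
a statistical test.

## The synthetic cohort generator

Because respondent-level trial data are not redistributable, every
downstream stage is exercised on synthetic cohorts. `simulate_responses()`
draws orthogonal standard-normal factor scores (general first, then the
specifics), forms continuous latent responses
$y^* = \lambda_g \eta_g + \lambda_s \eta_k + \varepsilon$ with residual
variance $\theta = 1 - \lambda_g^2 - \lambda_s^2$, and discretizes each
item through its thresholds. Draw order (factors before residuals,
items in instrument order) is fixed so a seed pins the matrix exactly;
the caller's RNG state is saved and restored.

Default conditions:

* **Structure.** The four-group IKDC partition above.
* **Loadings.** General loadings 0.40-0.75 (mean about 0.6), specific
  loadings 0.25-0.55, fixed per-item vectors. They vary *within* groups
  deliberately: if loadings are constant inside a group, the bifactor
  population is algebraically equivalent to a correlated four-factor
  model (each group is tau-equivalent and the cross-group covariance is
  a rank-one product), and the model comparison the pipeline exists to
  perform would be undecidable even at the population level.
* **Thresholds.** Equal-probability cuts of the latent normal for each
  item's category count (2, 5 or 11), so category use is near-uniform
  and every category is populated at moderate $N$ — the friendliest
  regime for testing. A `skewed = TRUE` preset shifts all cuts by +0.8
  latent SD to mimic the low score profile of recently injured
  respondents.

What the generator emulates: realistic category coarseness (including
the dichotomous locking item), the attenuation continuous-ML analysis
suffers on ordinal codes, bifactor and correlated-factor dependence, and
reproducible seeds. What it does not emulate: non-normal latents,
informative missingness (only MCAR deletion is modeled), local item
dependence beyond the specified residual correlations, and longitudinal
drift. Passing recovery tests on these cohorts therefore shows the
estimator chain is correct under its own assumptions, not that any real
dataset satisfies them.

## Problem sizes and verification

The test battery uses cohort sizes chosen to keep each check sharp at
desk scale: $N = 5000$ for parameter-recovery and model-ranking checks
(general-loading mean absolute error under 0.05 despite ordinal
attenuation), $N = 1000$ for the 20-seed parallel-analysis calibration
and for the 10-cohort cross-check against `stats::factanal`,
$N = 20000$ for independence limits, $N = 50000$ for the
category-frequency goodness-of-fit battery, and one $N = 200000$
brute-force Monte-Carlo oracle for the attenuated correlation
structure. Structure-only quantities (model df, PUC, relative omega,
the nested chi-square arithmetic, completeness percentages) need no
data at all.

## Known limitations

* Continuous-ML treatment of ordinal codes is the method implemented,
  as in the analysis it mirrors; loadings are attenuated relative to a
  categorical (polychoric) treatment, most visibly for the dichotomous
  item.
* Missing data are handled by complete-case filtering (plus the
  optional mean-substitution scoring rule); there is no full-information
  ML.
* Robust (mean/variance-adjusted) corrections to the fit indices are
  not implemented; all indices are plain ML.
* The two-factor fixture resolves the published item-3 ambiguity by
  content, as described above.
* Geomin rotation can have local minima; ten random starts make the
  reported solution stable in practice but global optimality is not
  guaranteed.
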