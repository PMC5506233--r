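---
title: "Methods: summary-data Mendelian randomization in summarymr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-data Mendelian randomization in summarymr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(summarymr)
```

## The model

Mendelian randomization treats genetic variants as instrumental variables for
a modifiable risk factor. For variant $j$ ($j = 1, \dots, J$) the observed
inputs are the association $\hat\beta_{Xj}$ with the risk factor and the
association $\hat\beta_{Yj}$ with the outcome, each with a standard error,
estimated in two non-overlapping samples. All relationships are assumed
linear without effect modification, and the reported standard errors are
treated as known. The outcome association decomposes as

$$\beta_{Yj} = \alpha_j + \theta\,\beta_{Xj},$$

where $\theta$ is the causal effect of interest and $\alpha_j$ is the direct
(pleiotropic) effect of variant $j$ on the outcome, not mediated by the risk
factor. A variant is a valid instrument when $\alpha_j = 0$.

**IVW.** With valid instruments, each variant gives a ratio estimate
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order variance
$\mathrm{se}(\hat\beta_{Yj})^2/\hat\beta_{Xj}^2$. Their inverse-variance
weighted average,

$$\hat\theta_{IVW} =
  \frac{\sum_j \hat\beta_{Yj}\hat\beta_{Xj}\,\mathrm{se}(\hat\beta_{Yj})^{-2}}
       {\sum_j \hat\beta_{Xj}^2\,\mathrm{se}(\hat\beta_{Yj})^{-2}},$$

is identical to the slope of the weighted no-intercept regression of
$\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with weights
$\mathrm{se}(\hat\beta_{Yj})^{-2}$, provided the regression's residual
standard error is fixed at one. Both formulations are implemented and tested
for agreement; the closed form is used.

**MR-Egger.** Freeing the intercept in that regression gives the MR-Egger
model: the intercept $\hat\theta_{0E}$ estimates the average pleiotropic
effect of the included variants (the *intercept test* for directional
pleiotropy, i.e. for bias in IVW), and the slope $\hat\theta_{1E}$ estimates
$\theta$ (the *causal test*) under the InSIDE assumption — that the
$\alpha_j$ are distributed independently of the instrument strengths
$\beta_{Xj}$. For a fixed variant set the slope is consistent exactly when
the inverse-variance weighted covariance between the $\alpha_j$ and the
$\beta_{Xj}$ vanishes; the simulator reports this quantity for every
generated dataset.

**Medians.** The simple median of the $\hat\theta_j$ is consistent when at
least half the variants are valid instruments; the weighted median gives
precision-proportional influence. Both use an interpolated weighted-median
definition: sort the ratio estimates (ties broken by variant id for
determinism), normalize the weights, form cumulative midpoints
$s_j = \sum_{k \le j} w_{(k)} - w_{(j)}/2$, and interpolate linearly where
$s$ crosses one half. With equal weights this reproduces the usual sample
median, including the mean of the two central order statistics at even $J$.

**Robust IVW.** An MM-type robust version of the no-intercept weighted
regression bounds the contribution of any single variant: residuals on the
weight-transformed scale enter through Tukey's bisquare objective
(tuning constant 4.685, 95% Gaussian efficiency), with a least-absolute-
deviations initial estimate (for this one-parameter regression, the weighted
median of $y_j/x_j$ with weights $|x_j|$), a fixed MAD scale, and IRLS to a
$10^{-10}$ tolerance with at most 200 iterations. These constants are the
package's own choices; only the objective is prescribed by the methodology.

## Variance models and inference

The fixed-effect model sets the residual standard error $\sigma = 1$,
matching a fixed-effect meta-analysis of the ratio estimates and asserting
no heterogeneity between them. The multiplicative random-effects model
estimates $\sigma$ from the residuals; $\hat\sigma > 1$ reflects
overdispersion, which pleiotropy is expected to produce. Because no
biological mechanism yields underdispersion of uncorrelated genetic
associations, coefficient standard errors divide by
$\min(\hat\sigma, 1)$ — equivalently the SE multiplier is
$\max(\hat\sigma, 1)$ — so the random-effects analysis is never more precise
than the fixed-effect one. The untruncated $\hat\sigma$ is always reported:
persistent underdispersion can signal an inappropriately homogeneous variant
selection. With correlated variants the truncation is still applied but is
flagged in the summary, because genuine underdispersion is possible there.

The random-effects model is the package default; it is the recommended
choice whenever pleiotropy is plausible, and always for MR-Egger.

Inference defaults to $t$ quantiles with the residual degrees of freedom
($J-1$ for IVW, $J-2$ for MR-Egger), matching standard weighted-regression
output; a normal option exists for large-$J$ work or for reproducing results
computed with normal quantiles. Published analyses rarely state which
convention they used, so point estimates — not interval endpoints — are the
quantities one should expect to reproduce exactly. Median-method standard
errors come from a parametric bootstrap (default 10,000 iterations, seeded):
each iteration redraws every $\hat\beta_{Xj}$ and $\hat\beta_{Yj}$ from
normal distributions centred at the estimates with their reported SEs and
recomputes the median; the SE is the standard deviation across iterations
and the CI is a normal approximation. There is no standard analytic SE for
the median estimators, and the bootstrap is exactly reproducible under a
fixed seed.

## Orientation

Per-allele associations can be reported against either allele; flipping the
reference allele negates both associations. The IVW estimate is invariant to
such flips, but the MR-Egger intercept is not, so `orient_variants()`
recodes every variant to the risk-factor-increasing allele (all
$\hat\beta_{Xj} \ge 0$) before an MR-Egger analysis, and `mr_fit()` warns if
it sees unoriented data. When a correlation matrix accompanies the data, the
off-diagonal entries of a flipped variant change sign, since recoding an
allele negates its allele-count correlation with other variants. A variant
with $\hat\beta_{Xj}$ exactly zero cannot be oriented: it is left unchanged
with a warning, and is likewise excluded (with a warning) from the median
estimators, whose per-variant ratios it leaves undefined. This is a boundary
case the methodology does not address — instruments are chosen for robust
risk-factor associations — so the package flags rather than guesses.

## Diagnostics

The instrument-strength $I^2$ statistic,
$\max\{0, (Q - (J-1))/Q\}$ with
$Q = \sum_j w_j (\hat\beta_{Xj} - \bar\beta_X)^2$, measures the spread of
exposure associations relative to their precision; values near one mean the
MR-Egger slope is not attenuated by weak-instrument (regression-dilution)
bias, and exactly equal exposure associations give $I^2 = 0$ with neither
MR-Egger parameter identified. The default weights are
$\mathrm{se}(\hat\beta_{Xj})^{-2}$, the instrument-strength convention; an
$\mathrm{se}(\hat\beta_{Yj})^{-2}$ option matches the weighting used in the
MR-Egger variance formula, and the pipeline reports both.

Influence diagnostics use the standard weighted-least-squares machinery of
the underlying regression: leverages from the weighted hat matrix (summing
to the parameter count), Cook's distances, externally studentized residuals,
and a leave-one-out analysis re-fitting the estimator $J$ times. No
automatic outlier removal is performed — the measures rank variants for
inspection, with the conventional reference points $4/J$ and $|t| > 3$
printed as annotations only, since no decision threshold is part of the
methodology. For an exact fit the influence statistics are reported as zero
(the textbook formulas are 0/0 there), and a variant with leverage one is
reported as infinitely influential with a warning rather than an error.

The heterogeneity statistic
$Q = \sum_j w_j (\hat\beta_{Yj} - \hat\beta_{Yj}^{fit})^2$ is referred to a
$\chi^2$ distribution on the residual degrees of freedom; $Q/(J-p)$ is
identically $\hat\sigma^2$, which the tests verify.

## Correlated variants

With variants in linkage disequilibrium, generalized weighted least squares
replaces the diagonal weights by
$\Omega^{-1}$, $\Omega_{j_1 j_2} =
\mathrm{se}(\hat\beta_{Yj_1})\mathrm{se}(\hat\beta_{Yj_2})\rho_{j_1 j_2}$.
Two algebraically identical routes are implemented — premultiplication by
the inverse lower Cholesky factor of $\Omega$ followed by ordinary least
squares (default), and the direct matrix-algebra solve — and their agreement
to $10^{-10}$ is part of the test suite, as is the reduction to the
uncorrelated estimators at $\rho = I$. Supplied LD matrices are often
numerically indefinite: eigenvalues are clipped at $10^{-8}$ and the
diagonal rescaled to one, with a warning. Estimating $\rho$ from reference
panels is out of scope.

## The simulator

`simulate_mr()` generates summarized datasets directly: true instrument
strengths $\beta_{Xj} \sim U(0.05, 0.15)$ (risk-factor SD units per allele),
direct effects $\alpha_j$ per scenario, true outcome associations from the
decomposition above, and observed estimates equal to truth plus independent
normal noise at the configured SEs ($\mathrm{se}_x = 0.005$,
$\mathrm{se}_y = 0.01$ by default, reported as known). Five scenarios cover
the canonical pleiotropy structures: none; balanced direct
($\alpha_j \sim N(0, 0.004^2)$); directional direct
($\alpha_j \sim N(0.01, 0.004^2)$, InSIDE satisfied); and pleiotropy acting
through one shared confounder or through per-variant confounders (variant
effects on confounders $\gamma_j \sim N(0.05, 0.02^2)$; in the shared case
the confounder's effects on risk factor and outcome are common to all
variants, in the per-variant case each confounder gets its own multipliers
drawn $U(0.5, 1.5)$) — in both confounder scenarios $\alpha_j$ and
$\beta_{Xj}$ rise together and InSIDE fails. Defaults are fixed at values
that make the phenomena visible at desk scale (J = 25, effects an order of
magnitude above the sampling noise); they parameterize the study conditions
and are not tuned per analysis.

The simulator emulates the summary-statistic level only. It does not model
individual-level genotypes, allele-frequency-dependent precision, sample
overlap between the two studies, case-control ascertainment, LD-structured
noise, winner's-curse selection of instruments, or non-normal sampling
error. Passing tests therefore demonstrate correctness of the estimators
under the stated two-sample summary model, not robustness to those
real-data complications.

`mr_bias_study()` derives replicate $r$'s seed as master seed $+ r$ (and the
per-replicate bootstrap seed as master $+ r + 5\cdot10^5$), making every
Monte-Carlo table a pure function of its configuration. The calibration
study shipped with the package uses $J = 50$ and 500 replicates — enough for
a Monte-Carlo SE near $4\times10^{-4}$ on bias and $\pm 0.01$ on rejection
rates — and analyzes the no-pleiotropy null under the fixed-effect model,
which is the model matched to that generating process (no overdispersion,
known SEs; the truncated random-effects test is deliberately conservative
and would sit below the nominal level by construction). The
directional-pleiotropy study uses the default random-effects model, the
recommended analysis when pleiotropy is present.

## Numerical choices and edge cases

* Ties in the median order statistics are broken by a stable sort on
  (ratio, variant id), so results never depend on input order beyond the
  data themselves.
* Exact ratio weights for the weighted median use the first-order
  delta-method variance; a second-order option (adding
  $\hat\beta_{Yj}^2\mathrm{se}(\hat\beta_{Xj})^2/\hat\beta_{Xj}^4$) is
  available but off by default, consistent with the weighting used by IVW.
* A single-variant dataset supports only the ratio/IVW estimate with the
  fixed model (no residual degrees of freedom); MR-Egger requires
  $J \ge 3$, leave-one-out requires one more than the per-fit minimum.
* `mr_fit()` reports `sigma_hat` untruncated even when the truncation rule
  alters the SEs, so over/underdispersion is always visible.
* File round trips write 17 significant digits, preserving numeric fields
  to better than $10^{-12}$.

## Known limitations

The urate–CHD and HDL–CHD analyses that motivate the method are supported
end to end (log-odds outcome scale, odds-ratio reporting, the full
estimator quartet), but their per-variant inputs are distributed as
supplementary/consortium data and are not redistributed here; the
acceptance check for the urate example activates when the user supplies
`inst/extdata/urate_chd_web_table_a1.csv`. No SIMEX correction for
weak-instrument bias in MR-Egger, no mode-based estimators, no multivariable
MR, and no individual-level-data methods are included.
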