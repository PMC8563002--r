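---
title: "Methods: sibling-matched analysis of landscape fire smoke and birthweight"
author: "firesib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sibling-matched analysis of landscape fire smoke and birthweight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firesib)
```

## The scientific problem

Landscape fires (wildfires, deforestation and agricultural burning) episodically
raise ambient fine particulate matter (PM2.5) over large regions of the tropics.
Gestational exposure to this fire-sourced PM2.5 has been linked to reduced
birthweight, but the underlying survey data — geocoded Demographic and Health
Survey (DHS) birth records — are access-controlled, and the exposure itself is
not directly measurable: it must be reconstructed from chemical-transport-model
(CTM) simulations fused with satellite products.

`firesib` implements this full analysis as a reusable, tested pipeline:

1. an **exposure-assessment chain** that turns paired fire-on/fire-off CTM runs
   plus an annual satellite PM2.5 product into monthly fire-sourced and
   non-fire-sourced PM2.5 surfaces, and averages them over gestational windows;
2. a **sibling-matched inference suite**: within-mother fixed-effects Gaussian
   regression for birthweight, exact conditional logistic regression for low
   (LBW, < 2500 g) and very low (VLBW, < 1500 g) birthweight, distributed-lag,
   nonlinear, and baseline-varying effect models;
3. a **calibrated synthetic cohort generator** that reproduces the published
   cohort's variance structure and outcome prevalences, so that every estimator
   can be validated by parameter recovery without restricted data.

## Exposure assessment

With `on`/`off` superscripts denoting the paired CTM runs, month $m$ and year
$y$:

* fire-attributable fraction
  $\rho_{m,y} = (\mathrm{PM}^{on}_{m,y} - \mathrm{PM}^{off}_{m,y}) / \mathrm{PM}^{on}_{m,y}$,
  set to 0 where $\mathrm{PM}^{on} = 0$ and clamped to $[0,1]$ (transport
  chemistry can make $off > on$ in isolated cells; a fraction outside the unit
  interval is physically uninterpretable, and clamp counts are logged);
* annual bias-correction rate
  $\eta_y = \mathrm{PM}^{sat}_{y} \big/ \tfrac{1}{12}\sum_m \mathrm{PM}^{on}_{m,y}$
  on the fine (satellite) grid, with $\eta = 1$ where the denominator is below
  $10^{-6}$ and clamping to $[0.1, 10]$ to cap pathological cells;
* the split
  $\mathrm{FirePM}_{m,y} = \eta_y\,\rho_{m,y}\,\mathrm{PM}^{on}_{m,y}$ and
  $\mathrm{NonfirePM}_{m,y} = \eta_y\,(1-\rho_{m,y})\,\mathrm{PM}^{on}_{m,y}$,
  which conserves $\eta\,\mathrm{PM}^{on}$ cell by cell (tested to $10^{-10}$).

Coarse fields are moved to the fine grid by inverse-distance-weighted (IDW)
interpolation over the $k$ nearest coarse centres with weights $d^{-p}$.
Defaults are $p = 2$ and $k = 4$, standard practice for this kind of
downscaling, and distances are great-circle (the study domain spans the
tropics, where planar distance distorts longitudes). A fine centre coinciding
with a coarse centre takes its value exactly. The implementation is tested
against an all-pairs brute-force computation to $10^{-12}$.

Gestational exposure is the arithmetic mean of the **3, 6 or 9 calendar months
strictly preceding the birth month** (the birth month is excluded; the surveys
record no gestation length, so 9 months is the primary window). A record whose
window leaves the corrected period is treated as missing exposure and excluded
by the inclusion criteria, never silently filled. Smoke at a pixel whose own
burned area is zero through the window is flagged as *transported* — smoke that
arrived by atmospheric transport rather than local burning.

## Study design and estimators

Children of the same mother form a family group; groups need at least two
valid records (valid birthweight, GPS, a birthdate inside the 5-year recall
window, and valid exposure — all exclusions are counted by reason). The model
is

$$y_{i,j} \sim x_{i,j}\,\beta + \mathbf{z}_{i,j}\,\boldsymbol\gamma + \theta_i,$$

with group fixed effects $\theta_i$ absorbing everything constant within a
family (genetics, socioeconomic position, local care quality). For the
Gaussian response the fit demeans $y$, $x$ and $\mathbf z$ within groups; the
point estimates equal the explicit dummy-per-group regression (tested to
$10^{-10}$) without materializing $10^5$ intercepts. The headline standard
error is group-clustered (CR1); because the absorbed intercepts are nested
within the clusters they are not counted in the small-sample correction,
while the classical SE (reported alongside) does count them in the residual
degrees of freedom.

For the binary outcomes the group effects are eliminated exactly by
conditioning on each group's case count: a group with $k$ cases among $n$
siblings contributes
$\exp(\sum_{cases} x\beta) / \sum_{|S|=k}\exp(\sum_{S} x\beta)$. Concordant
groups drop out (counts logged). The maximizer is Newton–Raphson with the
analytic gradient and observed information, organised by $(n, k)$ strata so
the subset enumeration is dense matrix algebra. This conditional form avoids
the incidental-parameter bias of per-group dummies and is feasible because
sibling groups are small; an unconditional dummy fit was considered and
rejected for that bias. The fit is verified against a brute-force enumerated
likelihood (to $10^{-6}$) and against an independent implementation in the
`survival` package. Separation is detected through the conditional
likelihood's supremum (which is 0 exactly when every discordant group is
predicted perfectly) and reported as a non-finite estimate with diagnostics,
never as a spuriously huge finite coefficient.

Associations with the binary outcomes are summarized as **excess risk**
$(\mathrm e^{\beta} - 1)\times 100\%$ per 1 µg/m³. The sign convention is
chosen so that a harmful coefficient ($\beta > 0$) yields a positive excess
risk, consistent with the reported positive excess risks for LBW and VLBW.

### Covariate adjustment

The full adjustment set is maternal age, child sex, multiple birth, non-fire
PM2.5, natural cubic splines of birth order (5 df), temperature (3 df),
humidity (3 df), calendar year (5 df) and month index (4 df), and
country-by-year indicator cells. Knots sit at equally spaced quantiles with
boundary knots at the data range — the published analysis names only "spline
terms", so the natural-cubic family is this package's choice. The month
spline is non-cyclic by default, matching the printed 4 df; a cyclic
(sine/cosine) basis is available behind `cyclic_month = TRUE`. Columns that
become collinear after within-group demeaning (a country-year cell a family
never leaves, a constant covariate) are dropped with a log entry rather than
silently regularized.

## Sensitivity machinery

**Distributed lags.** The nine monthly exposures before birth enter through a
cross-basis $Z = L B$ where $B$ is a lag basis — by default a natural cubic
spline over lag 1..9 with an explicit constant column (4 columns total), with
the identity basis available for audit. Per-lag effects are $B\hat\theta$
with delta-method SEs; the cumulative effect is their sum. With a constant
basis the model collapses algebraically to the 9-month-window fit (tested
exactly), and with the identity basis it equals nine free lag regressors.

**Nonlinear exposure–response.** The linear term is replaced by a thin-plate
spline basis whose columns are demeaned within groups, so the curve is
identified purely by within-family contrasts; the penalty weight is chosen by
generalized cross-validation over a log-spaced grid (a fixed `lambda`
override exists). The curve is anchored to zero effect at zero exposure and
monotonicity is *not* imposed. Because siblings differ by only a few µg/m³,
the curve far from the bulk of exposure is identified by chaining local
contrasts, and its pointwise confidence band widens accordingly — recovery
tests for the saturation plateau therefore use a generator setting with a
larger within-family exposure spread.

**Baseline-varying effects.** Writing $\bar y_i$ for the family mean
birthweight and $\Delta y_{i,j} = y_{i,j} - \bar y_i$, the model
$\Delta y_{i,j} \sim f(\bar y_i)\,x_{i,j} + \mathbf z_{i,j}\gamma + \theta_i^*$
lets the exposure coefficient vary smoothly with the family baseline. $f$ is
a natural spline in $\bar y$ (5 columns including its constant) multiplied by
the within-family exposure deviation; because those deviations sum to zero
within each family, the interaction columns are exactly orthogonal to the
nuisance intercepts, which are absorbed rather than re-estimated (the
alternative — re-estimating $\theta^*_i$ — is algebraically redundant here).
The relative effect at baseline $\bar y$ is reported as
$\beta(\bar y)/\bar y \times 100$ % per µg/m³ (and its negation as a relative
*reduction*); this is the only definition consistent with the published
absolute/relative contrast. Anchors outside the observed $\bar y$ range are
refused — no extrapolation. With a constant $f$ the fit collapses to the
headline estimator (tested), and identification comes solely from
within-family exposure variation interacting with the between-family
baseline.

## The synthetic cohort generator

The generator is the package's stand-in for the restricted DHS extract. Its
defaults are the published descriptive statistics: 9-month fire-PM2.5 mean
4.29 µg/m³ with between/within-family SDs 5.30/1.59 µg/m³ (about 92% of the
exposure variance between families), mean birthweight 3082 g with SDs
613/386 g, LBW and VLBW prevalences 31,854/227,948 and 2,912/227,948, and a
mean sibling-group size of 2.13 (SD ≈ 0.37 implied by the one-parameter
truncated-Poisson family tuned to that mean; the alternative mean 227,948 /
109,137 ≈ 2.089 implied by the published counts is exposed as
`group_size_mode = "ratio"` since the two printed figures are mutually
inconsistent).

**Variance accounting.** The published between/within SDs are *empirical*
population-denominator components. With mean group size $\bar n$, independent
within-family noise of variance $\sigma^2_w$ inflates the empirical between
component by $\sigma^2_w/\bar n$ and deflates the empirical within component
by the factor $(1 - 1/\bar n)$. The generator inverts this accounting: for
birthweight the latent within-family SD solving
$\sigma_w\sqrt{1 - 1/2.13} = 386$ is ≈ 530 g, and the latent family-level
variance is $613^2 - \sigma_w^2/2.13$. Hitting the published *empirical*
decomposition at the configured group size, rather than using 613/386 as
latent parameters, is what makes the recovery experiments honest: the
estimators see data whose descriptive table matches the published one.

**Exposure.** Family mean exposures are gamma distributed (right-skewed and
non-negative, as fire-sourced PM2.5 is) and child exposures are the family
mean times a lognormal multiplier with unit mean; the gamma variance and the
lognormal relative variance solve the two moment equations above exactly.
Each record carries a consistent monthly series for the 12 months before
birth (positive month-to-month variation rescaled so the 9-month mean equals
the drawn exposure), so the exposure module's window averaging reproduces the
generator's exposure and the distributed-lag model has genuine lag variation.
When gridded fields are supplied, exposures are instead read from the
exposure chain at family locations sampled preferentially near high fire
activity; the statistical calibration then holds only approximately, so the
calibrated mode is the default for recovery experiments.

**Birthweight.** A Gaussian with the published mean and SD implies ~21%
below 2500 g against the observed ~14%, so no Gaussian (and no 3-parameter
skew family, which cannot meet four constraints at the required $10^{-6}$
tolerance) can reproduce the printed mean, SD and both tail probabilities.
`calibrate_birthweight_distribution()` therefore solves a three-component
Gaussian mixture — a central component, a low component carrying the VLBW
tail, and a high component supplying the upper spread — by penalized least
squares on the four moment/tail residuals, to $10^{-6}$ on the probability
scale (with an exact single-Gaussian shortcut when the targets are
Gaussian-feasible, and an explicit error when the constraint set is
infeasible). Family clustering is then induced by a Gaussian copula: sibling
latent normals share a family factor, and the copula correlation is solved
(by dense two-dimensional quadrature on the transformed covariance; Hermite
polynomial quadrature is unreliable for mixture quantile transforms) so the
empirical within-group SD equals 386 g at the configured group size. Because
every marginal draw passes through the calibrated quantile transform, the
mean, SD and both tail prevalences are exact by construction at any sample
size.

**Effects.** The configured continuous effect multiplies the exposure
deviation from the *realized* family mean, so the within-family estimand
equals the configured truth exactly and the marginal calibration is
untouched (the deviations sum to zero within families). The baseline-varying
mode evaluates the truth curve at the realized pre-effect family mean — the
same quantity the estimator conditions on — so anchor recovery is free of
errors-in-variables attenuation by construction; published anchor
reductions are interpolated monotonically on the log scale. In
`direct-logit` mode, LBW and VLBW are drawn from within-family logistic
models with normally distributed family intercepts whose grand intercept is
solved numerically to hit the published prevalences; the two endpoints are
drawn independently, so VLBW ⊆ LBW holds only in threshold mode.

**Covariates** (sex, multiple birth, maternal age, parity, employment,
cooking fuel, non-fire PM2.5) carry modest default effects — the published
analysis reports no covariate coefficients — applied as contributions centred
at their realized means. They are deliberately small (at most ~100 g, summing
to < 500 g² of variance) so that the covariate noise they add on top of the
copula draw cannot push the calibrated tail prevalences outside their
sampling bands; larger values are available through `covar_effects_bw` for
experiments that do not rely on tail calibration.

**What the generator does not emulate.** Spatial autocorrelation of exposure
beyond the family level, seasonality shared between exposure and outcome
(month effects exist in the design but carry no generated confounding),
survey weights and multi-stage sampling, birthweight heaping to round values,
and country-level demography. Passing recovery tests therefore demonstrates
that the estimators are correct and calibrated under the published variance
structure — not that the original epidemiological estimates are unbiased in
the face of, say, recall error, which is exactly why the original design
carries its own sensitivity analyses (replicated here as machinery, not as
evidence).

## Numerical choices

* Mixture quantile inversion: dense-grid interpolation seeding 4 Newton steps
  on the analytic CDF/density (exact to ~$10^{-15}$ on the probability
  scale).
* Fixed-effects OLS: normal equations with BLAS crossproducts; rank
  detection on the correlation-scaled Gram matrix (tolerance $10^{-9}$) with
  named dropped columns.
* Conditional logit: Newton with step halving, convergence on the relative
  gradient at $10^{-10}$.
* Truncated uniform-baseline draws keep birthweights inside 500–6500 g so
  validity filtering cannot distort designed experiments.
* Degenerate inputs: zero CTM cells give $\rho = 0$ and $\eta = 1$ by rule;
  incomplete windows give missing exposure; validation never throws.

## Problem sizes

The test suite validates calibration at 50,000 families and recovery with
replicate batches of 8,000–40,000 families (3 Monte-Carlo-SE bands), plus a
200-replicate null-calibration study at 400 families checking that all three
estimators' 95% intervals cover zero at least 90% of the time. The
acceptance script re-runs the recovery experiments at 20,000–50,000 families
with 20–100 seeded replicates, sizes at which the Monte-Carlo standard error
of each reported mean is a few percent of the target or less.

## Known limitations

* The three-component birthweight mixture is a calibration device, not a
  demographic model; its components should not be interpreted as biological
  subpopulations.
* The conditional logit enumerates case subsets, which is exact but assumes
  small groups (fine here: sibling groups of 2–5).
* Cluster-robust intervals rely on many families; with very few families
  (tens) the null-calibration guarantees do not apply.
* The spatial cohort mode demonstrates the full chain end to end but is not
  calibrated to the published descriptive table; calibrated and spatial
  modes are deliberately separate.
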