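---
title: "Modelling antenatal depression as a stress process: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling antenatal depression as a stress process: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressproc)
```

## The model

`stressproc` analyses screening cohorts of pregnant women under the
stress-process framework: adverse exposures (*stressors* — difficulty
accessing food, unplanned pregnancy, fear of giving birth, a history of
common mental disorder) affect depressive symptoms both directly and
through intervening *resources* (marital agreement, partner support,
social support), with depression itself treated as a latent variable
measured by three parcels of EPDS items.

The model lives in RAM (reticular action model) form. Collect the observed
and latent variables in one vector v; a directed-path matrix A (entry
`A[i, j]` is the coefficient of the path j → i, holding factor loadings
and structural coefficients), a symmetric matrix S (exogenous variances
and covariances, residual variances) and a filter F selecting the observed
rows give the implied covariance

$$\Sigma(\theta) = F\,(I-A)^{-1} S (I-A)^{-T} F^{T}.$$

Estimation minimizes the normal-theory maximum-likelihood discrepancy

$$F_{ML}(\theta) = \ln|\Sigma(\theta)| + \mathrm{tr}\,(S_n \Sigma(\theta)^{-1})
  - \ln|S_n| - p,$$

where $S_n$ is the sample covariance (n − 1 denominator) of the p observed
variables, so $\chi^2_{ML} = (n-1) F_{ML}(\hat\theta)$. The structural
part must be recursive (acyclic); this is validated at specification time,
and model degrees of freedom $p(p+1)/2 - q$ are checked to be
non-negative before fitting.

**Assumptions.** Complete cases; ordinal mediators treated as continuous
scores (matching how per-scale coefficients are reported in this
literature); linearity of all structural relations; a single depression
factor behind the three parcels with parcel residuals mutually
uncorrelated. Normality of indicators is *not* assumed for inference on
overall fit — that is the point of the robust statistic below — but the
point estimates are normal-theory ML.

## Robust fit and fit indices

EPDS parcels are sums of skewed 0–3 items and are visibly non-normal, so
the test of overall fit uses the Satorra–Bentler scaled statistic. With
$\hat\Gamma$ the sample asymptotic covariance of $\mathrm{vech}(S_n)$
(fourth-order moments of the raw data), W the normal-theory weight matrix
$\tfrac12 D^T(\hat\Sigma^{-1}\otimes\hat\Sigma^{-1})D$, and
$\Delta = \partial\,\mathrm{vech}\,\Sigma/\partial\theta$,

$$U = W - W\Delta(\Delta^TW\Delta)^{-1}\Delta^TW,\qquad
  c = \mathrm{tr}(U\hat\Gamma)/df,\qquad
  \chi^2_{SB} = \chi^2_{ML}/c.$$

Standard errors use the inverse information $(\Delta^TW\Delta)^{-1}/(n-1)$.
RMSEA uses the (n − 1) convention consistently with the chi-square; CFI
and TLI compare against the independence baseline (all covariances fixed
at zero, fitted in closed form); SRMR averages squared correlation-metric
residuals including the diagonal; the coefficient of determination is
$1 - \det(\hat\Theta_{endo})/\det(\hat\Sigma_{endo})$ over the endogenous
observed variables. Because it is not standard practice to state which
variant a published index battery used, both ML and SB-scaled variants are
always reported.

## Effects

Direct, indirect and total standardized effects on the depression factor
are computed from the standardized structural matrix B:
total $= (I-B)^{-1} - I$, direct $=$ the paths into the outcome, indirect
$=$ total − direct, which equals the sum over all mediated path products
because a recursive B is nilpotent. Standard errors follow the first-order
delta method: each standardized effect is differentiated numerically
(central differences, step $10^{-5}$ scaled by parameter magnitude)
through the full estimation covariance. The identity
`total = direct + indirect` is exact by construction and asserted
throughout the test suite.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| EPDS possible-depression cutoff | 12 | analysis classification (validated urban Ethiopian cutoff) |
| EPDS exclusion cutoff | 17 | likely serious depression; removed before analysis |
| EPDS referral threshold | 13 (or any item-10 endorsement) | clinical referral flag, kept separate from the analysis cutoff because the two serve different purposes |
| OSSS-3 "poor support" cutoff | total < 9 | scale range 3–14 |
| MUAC rule set | `"printed"` | see below |
| screening retention threshold | p < 0.05 | both stages of the variable screen |
| identification | first loading fixed at 1 | per latent; latent-variance identification available |
| convergence | gradient norm < 10⁻⁶ | with discrepancy tolerances 10⁻¹² (relative), 10⁻¹⁴ (absolute) |

**The MUAC rule.** The protocol this implements prints 18–22 cm as
"normal" and 22.5–31 cm as "underweight", which inverts usual
anthropometric practice and leaves 22–22.5 cm unassigned. The printed rule
is preserved verbatim behind a named rule set (`"printed"`), values in the
gap return `"out_of_range"`, and a `"conventional"` rule set with the
labels swapped is provided for sensitivity analyses.

**Screening model.** The literature this serves describes "higher odds"
while naming a linear mixed-effects model on the EPDS score; the package
follows the named model (linear random intercept on the continuous score,
ML not REML since fixed effects are compared, Wald normal p-values). The
outcome column is configurable, so a binary indicator can be screened
instead.

**Numerical choices.** Start values are deterministic: free loadings 0.5,
structural paths 0, free variances at half the corresponding sample
variances, free covariances at half the sample covariances (keeping the
starting exogenous block positive-definite). The quasi-Newton run is
restarted (with an unconstrained BFGS polish) until the gradient criterion
is met. Heywood cases — negative estimated residual variances — are
reported with the offending parameter rather than constrained away, so the
likelihood surface stays honest; `constrain_variances = TRUE` retries with
a 10⁻⁶ variance floor. Fisher's exact test enumerates all tables with the
observed margins and applies the probability-mass two-sided rule with a
10⁻¹² relative tie tolerance; enumeration is guarded and falls back to
Pearson when infeasible.

## The synthetic cohort generator

No raw data from such screening studies are publicly deposited, so the
generator is a first-class, tested module that emulates the documented
statistical structure; every claim the test suite makes about the pipeline
is a claim about data with *this* structure.

Per subject, in order:

1. **Clusters.** One of six kebeles, uniform; cluster intercepts are drawn
   normal and standardized across the drawn clusters to mean 0 and SD
   exactly `cluster_sd` (default 0.1). With only six clusters, raw draws
   would leave each cohort a large shared mean shift that no within-cohort
   quantity could average away; standardizing pins the between-cluster
   variance at its configured value. No intraclass statistic is published
   for such cohorts, so the default is deliberately small.
2. **Stressors.** Four latent normals with exchangeable correlation 0.15
   (a modest positive dependence among adversities — only the margins are
   published, so the joint structure is a documented modelling choice),
   thresholded at the configured prevalences (food-access difficulty
   4.2 %, un-timed 13.4 %, unintended 1.8 %, fear of birth 21.3 %, history
   of common mental disorder 6.9 %). Un-timed and unintended pregnancies
   pool into the `unplanned` model variable; food access enters the model
   as *adequate* access, matching the published sign convention.
3. **Mediators.** Marital agreement (4 categories), partner support (5)
   and the social-support total (3–14) arise by thresholding a latent
   propensity that is linear in the standardized upstream scores. Category
   probabilities follow the published margins; the partner-support
   "never" category, absorbed into "rarely" in published tables, is
   assigned 0.5 %. Because a path coefficient is attenuated when its
   target is discretized, propensity coefficients are the target
   standardized coefficients divided by the analytic attenuation factor
   λ = corr(propensity, discretized score); for strong *binary* predictors
   this Gaussian approximation overshoots, so `calibrate_generator()`
   refines the coefficients by simulation (regress each standardized
   observed mediator on its predictors at n = 4·10⁵, rescale by
   target/realized, iterate). The refined constants are frozen into
   `default_config()` so default generation is cheap and deterministic;
   the routine is exported for recalibrating custom configurations.
4. **Structural paths.** `calibrate_paths()` inverts the effect
   decomposition: direct paths into depression are set to the published
   direct effects, and the stressor→mediator and mediator→mediator
   coefficients are solved by least squares so the implied indirect
   effects reproduce the published indirect column (residual ~10⁻¹⁰ for
   the default topology). One path — marital agreement → partner support —
   is fixed at 0.30 to make the remaining coefficients exactly identified;
   the published table pins only each predictor's total mediation, not its
   route. The default topology routes food access and pregnancy intention
   through marital agreement, and fear of birth and CMD history through
   social support.
5. **Latent depression.** A linear function of the seven standardized
   observed scores plus the cluster effect and Gaussian noise. The
   residual variance is *solved from the explained-variance constraint*
   R² = 0.35 rather than set directly. This is one fewer free knob, but it
   has a consequence worth stating: with the published path coefficients
   and the correlations they imply, the explained variance on a
   unit-variance outcome would be ≈ 0.377, so imposing R² = 0.35 gives the
   latent a variance of ≈ 1.078 and shrinks realized standardized paths
   by ≈ 3.8 % relative to their nominal values (e.g. fear of birth ≈ 0.28
   rather than 0.29). The published numbers do not admit both exactly; the
   package follows the R² constraint and reports the rescaled values as
   the generating truth.
6. **EPDS items.** Ten items load equally (0.545) on the *standardized*
   latent, with shared thresholds (0.497, 1.247, 1.947) on the item
   propensities. Loading and thresholds were calibrated jointly by
   simulation so the generated scale shows internal consistency α ≈ 0.74
   and an EPDS ≥ 12 rate ≈ 6.9 %; the resulting total-score distribution
   is strongly right-skewed (median ≈ 3–4, lower quartile at or near 0),
   which is exactly the shape published summaries describe. Items are
   conditionally independent given the latent, so the parcel measurement
   model holds by construction.
7. **Covariates.** Age, income (log-normal matched to the published mean
   and SD), education, occupation, religion, marital status, parity,
   gestational week (trimester mixture), MUAC (normal 24.1 ± 1.7, clamped
   to the instrument range) and PCI-4 coping items (common factor 0.5,
   median total ≈ 8) from the published marginal summaries. OSSS-3 item
   responses are drawn uniformly from the item triples consistent with
   each subject's total.

**What the generator does not emulate.** Real item-level EPDS structure
(all items share one threshold set, so item 10 — thoughts of self-harm —
is endorsed as often as any other item, making referral counts unrealistically
high); missingness (the generator is complete-case by design, as is the
analysis); any nonlinearity or interaction among stressors; informative
cluster sizes; measurement error in the stressor reports. Passing tests
therefore demonstrate that the pipeline recovers the structure it assumes,
not that real cohorts satisfy those assumptions.

A residual diagnostic worth knowing: because the items are *nonlinear*
(thresholded) functions of the latent, the best-fitting linear factor is a
mildly nonlinear transform of the generating latent, which inflates the
fitted explained variance by ≈ 0.02–0.03 and biases a few
binary-stressor coefficients upward by ≈ 0.02 at the default settings.
This is a property of fitting linear SEMs to coarse ordinal data, not an
implementation artifact, and is visible in `recovery_experiment()` output.

## Problem sizes used in the test suite

Unit tests run on cohorts of 200–5 000 subjects; the recovery study uses
100 replicates of n = 916; robust-statistic calibration uses one n = 5 000
sample and 200 normal replicates of n = 916; generator calibration checks
use one n = 50 000 cohort; large-sample moment checks use up to 4·10⁵
draws inside `calibrate_generator()`. The full suite completes in a few
minutes on one CPU.

## Known limitations and open choices

* The two-proportion sample-size helper implements the Fleiss
  continuity-corrected formula with unequal allocation; published sample
  sizes computed from "a difference of 1.5" are ambiguous between a risk
  ratio and another effect metric, so the effect interpretation is an
  explicit argument (`risk_ratio` default, `absolute_difference`
  alternative) and no published total is asserted.
* Published screening-table p-values are not always reproducible from the
  printed counts (one trimester table prints p = 0.170 where the counts
  imply ≈ 0.048); all tests validate against independent statistical
  oracles, not printed p-values.
* The analysis cutoff (12) and referral threshold (13) are both retained;
  the source protocols use both numbers for different purposes and do not
  reconcile them.
* Random parceling is a uniform partition with near-equal sizes; no
  content-balanced strategies are provided.
* No polychoric/WLSMV estimation for ordinal indicators, no multi-group or
  longitudinal SEM, no modification indices; model iteration is manual via
  the YAML model file, with the pipeline reporting the fit verdict for
  whatever topology it is given.
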