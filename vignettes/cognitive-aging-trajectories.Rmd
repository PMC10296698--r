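---
title: "Methods: cognitive aging trajectories, practice effects, and the frailty index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cognitive aging trajectories, practice effects, and the frailty index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical methods in `cogfrail`: the model
and its assumptions, what each tunable parameter does, what the synthetic
cohort generator does and does not emulate, and the numerical and design
choices made where more than one defensible option existed.

## Why intercepts and slopes are modeled separately

In repeated neuropsychological testing, scores typically *rise* over
follow-up because participants learn the tests. The within-person slope
therefore confounds true cognitive change with this practice effect,
while the first assessment — before any exposure to the instruments — is
the cleanest available between-person signal. The model accordingly
summarizes each participant's visits as a latent intercept $\alpha_i$
(their practice-free starting level, here called the cross-sectional
score) and a latent slope $\beta_i$ (change per month, confounded with
practice, the longitudinal score), and analyzes the two at a second
level:

$$y_{it} = \alpha_i + \beta_i\,\text{month}_{it} + \varepsilon_{it},
  \qquad \varepsilon_{it} \sim N(0, \sigma_\varepsilon^2)$$

$$\alpha_i = \gamma_{00} + \gamma_{01} c_i + \gamma_{02} c_i^2
  + S_i(\gamma_{03} + \gamma_{04} c_i + \gamma_{05} c_i^2) + u_i$$

$$\beta_i = \gamma_{10} + \gamma_{11} S_i
  + \sum_{k=2}^{4} (\gamma_{12.k} Q_{ik} + \gamma_{13.k} S_i Q_{ik}) + v_i$$

with $(u_i, v_i)$ bivariate normal: SDs $\sigma_\alpha$, $\sigma_\beta$
and correlation $\rho$ (the covariance $\Omega$). A positive $\rho$ means
participants who start higher also gain more from repeated testing.

Intercepts follow *continuous* quadratic age trends — one curve per
cohort — because the scientific question is how the survivor−control gap
varies over the age span, and categorical age bins would discard exactly
that resolution. Slopes, by contrast, are structured by *categorical*
baseline age quartiles: time already enters level 1, and modeling slopes
by continuous age as well would count age twice; the quartile contrasts
answer the narrower question of whether practice differs across age
cohorts.

Assumptions worth stating plainly: Gaussian residuals on the outcome
scale (for the DAFI in $[0,1]$ this is an approximation, adopted
deliberately — see below), linear within-person change over a 24-month
window, exchangeable participants given the design, and missingness
ignorable given the observed covariates (dropout depends on nothing
latent).

## Parameters, units, defaults

| Parameter | Units | Meaning |
|---|---|---|
| $\gamma_{01}$ | outcome/year | cross-sectional aging slope in controls; ×10 = per-decade effect |
| $\gamma_{02}$ | outcome/year² | curvature of the control aging trend |
| $\gamma_{03}$–$\gamma_{05}$ | outcome, /yr, /yr² | survivor−control difference as a quadratic in centered age |
| $\gamma_{10}$ | outcome/month | practice-effect slope, youngest quartile controls |
| $\gamma_{12.k}, \gamma_{13.k}$ | outcome/month | quartile and group×quartile slope contrasts |
| $\sigma_\alpha, \sigma_\beta$ | outcome, outcome/month | person-level SDs |
| $\rho$ | — | intercept–slope correlation |
| $\sigma_\varepsilon$ | outcome | visit-level residual SD |

Age is centered before the quadratic is formed; `center = "auto"`
(default) uses the sample mean age rounded to 0.1 years, and any fixed
value can be supplied. Months are raw months since baseline (0, 8, 16,
24), so $\gamma_{10}$ is per month; no rescaling is applied. Quartile
bins default to 60–68, 69–72, 73–76, 77–89 and are configurable.

Priors are weakly informative and autoscaled, in the spirit of rstanarm
defaults: fixed effects get $N(0, (2.5\,\text{sd}(y)/\text{sd}(x))^2)$
(slope-block columns additionally divided by $\text{sd}(\text{month})$,
since those coefficients act per month), the three SDs get half-normal
priors with scale $2.5\,\text{sd}(y)$ (again month-scaled for
$\sigma_\beta$), and $\rho$ is uniform. Every element can be overridden
via the `priors` argument.

Two MCMC presets are provided: `"test"` (4 chains × 2,000 iterations,
500 warmup, no thinning) for desk-scale work and the package's test
suite, and `"paper"` (4 chains × 60,000, 10,000 warmup, thinning 5) for
publication-grade runs. Convergence is summarized by split R-hat per
parameter; any value above the threshold (default 1.01) raises a warning
and is flagged in the fit object — never silently. At desk scale the
weakly identified variance-component block ($\sigma_\beta$, $\rho$) often
carries R-hat above 1.01 even when the fixed effects have converged; the
heavyweight preset resolves this.

## Domain scoring decisions

*Normality screen.* A sample is flagged for transformation when its
absolute sample skewness exceeds 1 (configurable). A fixed skewness rule
was chosen over a significance test because the latter's verdict depends
on sample size: with several hundred reference observations, formal
tests reject departures far too small to matter for z-scoring.

*Box–Cox fitting.* The transformation parameter is fitted by profile
likelihood on a grid over $[-3, 3]$ with step 0.01. Non-positive samples
are first shifted so the minimum becomes 1. If the likelihood-optimal
$\lambda$ fails to reduce absolute skewness (possible in small, oddly
shaped samples), the grid value minimizing post-transform skewness is
used instead, so the transformation can never make things worse.

*Reference population.* Transformations and z-scoring references are
fitted on **baseline control visits only**, then applied to all groups
and visits. The reference population defines the measurement scale;
fitting it on pooled data would leak group differences and practice
effects into the transform. Baseline (rather than all control visits)
avoids practice-effect contamination of the reference itself. Reference
samples smaller than the screen's minimum (20) are left untransformed.

*Direction.* Timed tests, where larger raw scores mean worse
performance, have their z-scores negated so that higher always means
better — the standard composite convention.

*Minimum tests per composite.* A domain mean is reported when at least
half the member tests (rounded up) are present, otherwise missing. The
half-rule is a default, overridable per domain.

## The frailty index

The DAFI is $\sum_j x_j / (2 n)$ over the $n$ assessed indicators
$x_j \in \{0, 1, 2\}$; a missing indicator leaves both numerator and
denominator, which makes the score invariant to duplicating indicators
and equivalent between "missing" and "absent from the instrument".
Uniform 0–2 coding for all 44 indicators is assumed throughout. Scores
require ≥ 35 assessed indicators to be valid. The category boundaries are
half-open — robust $[0, 0.2)$, pre-frail $[0.2, 0.35)$, frail
$[0.35, 1]$ — resolving boundary ambiguity in favor of the unambiguous
outer definitions ("robust < 0.2", "frail ≥ 0.35"). The index is scored
at every visit with identical rules, and the same growth model applies
to the DAFI series on its raw $[0,1]$ scale — a Gaussian approximation
that is adequate for population contrasts away from the boundaries but
should not be pushed to individual-level prediction near 0 or 1.

## Post-hoc curves

The survivor−control gap $\Delta(a)$ is evaluated per posterior draw on
an age grid (default 60–89, step 0.1 years) and summarized by the mean
and a per-age 95% HDI computed from the draw-level distribution of
$\Delta(a)$ — not by combining parameter-wise intervals — so posterior
correlations among $\gamma_{03}$–$\gamma_{05}$ are respected.

The null-crossing age is the first grid age, scanning upward, at which
the band contains zero. When the band contains zero from the grid start
the start age is returned with an explicit flag, and when it never
contains zero the crossing is `NA`; the full per-age significance vector
is kept on the curve so other patterns — e.g. a significant window at
intermediate ages — are recoverable as interval endpoints. Crossings are
reported at grid resolution (one decimal at the default step).

## The synthetic generator

The generator exists so that every downstream stage has inputs with
known ground truth. It emulates: two cohorts (defaults 328 survivors,
158 controls); enrollment ages from a truncated normal on 60–89 with
mean 72.5 and SD 5.8; visits at months 0, 8, 16, 24; per-domain latent
intercepts and slopes following the level-2 model exactly, with the
default fixed effects set to the APE and LM posterior means of the
motivating cohort study so that ground truth is realistic in magnitude;
correlated random effects; raw tests as per-test affine transforms of
the domain value plus noise, with a sinh–arcsinh tilt
($\sinh(\text{asinh}(Z) + s)$, exactly Gaussian at $s = 0$) so that some
tests are visibly skewed and the Box–Cox step has real work to do;
ordinal frailty indicators from an ordered-logit model with baseline
prevalence, a survivor shift, an age gradient and a small per-month
drift; independent item missingness; and monotone dropout with a
constant per-visit hazard (default 0.05 — a plausible attrition level
for an older cohort over 8-month intervals; the motivating study does
not report its visit-level attrition).

One published internal inconsistency deserves note: the motivating
study's table prints the APE quadratic survivor difference as −0.01 with
an HDI of (−0.004, 0.002), which cannot all be true at once; the value
−0.001 is consistent with both the interval and the reported age-65 gap
of 0.31, and is used as the generator default. Summary writers in this
package carry full precision to avoid creating such artifacts.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: real instruments' score ranges,
floors and ceilings; dependence among frailty indicators beyond shared
group/age effects; a group×age interaction in indicator prevalence (the
synthetic survivor−control frailty gap is constant on the logit scale,
so a synthetic DAFI gap curve may exclude zero over the whole grid and
have no crossing age); informative dropout; visit-date jitter (visits
fall exactly on the scheduled months, as the month offsets are the only
time information the model uses); and cohort effects confounded with
age. Parameter-recovery results on synthetic data demonstrate that the
implementation estimates what it claims to estimate, not that the model
is correct for any particular real cohort.

A related scale point: the scored test composite is a noisy, rescaled
proxy of the latent domain (z-scoring divides by a reference SD that
includes test measurement noise), so level-2 coefficients fitted to the
composite are attenuated relative to the domain-scale generating values.
Parameter-recovery checks therefore fit the model to the generator's
domain observations, while the scoring pipeline is validated by its own
invariants (reference idempotence, affine invariance, direction
handling) and by the composite's correlation with the domain truth.

## Numerical choices

- **Random-effect parameterization.** The bivariate $(u_i, v_i)$ normal
  is written as a marginal normal for the intercept deviation and a
  conditional normal for the slope deviation (regression coefficient
  $\rho\sigma_\beta/\sigma_\alpha$). This is algebraically identical to
  the joint $\Omega$ form and samples roughly an order of magnitude
  faster under JAGS's `glm` module than per-person bivariate nodes.
- **Stability floors.** The half-normal scale priors are truncated below
  at 0.1% of their prior scale and $\rho$ is bounded to
  $(-0.999, 0.999)$. Without these, degenerate inputs (e.g. an outcome
  that is identically zero) drive variance components to zero, the
  conditional precision overflows, and the sampler aborts. The floors
  are far below any scientifically meaningful value.
- **Degenerate designs.** Zero-variance design columns (all ages equal,
  single-visit data) keep unit prior scale rather than exploding the
  autoscaled prior; single-visit data additionally raise an explicit
  non-identified-slope flag while completing the fit.
- **HDI.** The shortest window of sorted draws containing
  $\lceil p\,n \rceil$ values; ties broken at the lowest start, so the
  interval is deterministic given draws.
- **Split R-hat.** Each chain is halved before computing the
  potential-scale-reduction statistic, so within-chain drift inflates
  the diagnostic as well as between-chain disagreement.
- **Seeds.** One root seed drives the generator; the sampler derives one
  RNG stream per chain from its own seed, and both are recorded in the
  artifacts, so every table in a pipeline run is exactly reproducible.

## Problem sizes used in validation

The package's own validation uses cohorts of roughly 200–500
participants with four visits: parameter-recovery checks run 20
replicates at 300 participants with the `"test"` MCMC preset and require
each fixed effect's 95% HDI to cover its generating value in at least
16 of 20 replicates (the binomial tolerance for 20 draws at nominal 95%
coverage), with the sign of $\rho$ recovered on average. Exhaustive
brute-force checks back the DAFI arithmetic on all short indicator
vectors, and analytic oracles back the gap curve and crossing logic.
These sizes were chosen as the smallest at which the covering behavior
of the intervals is meaningfully testable.

## Known limitations

- The Gaussian likelihood treats the DAFI like an unbounded outcome; a
  beta or logit-normal observation model would respect the boundaries at
  the cost of the shared model structure across outcomes.
- Practice effects are modeled as linear in months within 24 months;
  the first retest typically yields the largest gain, which a
  retest-indicator term would capture.
- The model assumes ignorable dropout; the generator can produce only
  non-informative attrition, so sensitivity to informative dropout is
  untested here.
- Crossing ages are read off per-age intervals, not a joint band over
  the age grid; simultaneous-band semantics would give systematically
  later crossings.
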