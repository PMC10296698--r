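# cogfrail

Cognitive aging trajectories and deficit-accumulation frailty in
survivorship cohorts.

## The problem

Did cancer and its treatment alter the trajectory of cognitive aging?
Longitudinal neuropsychological studies of older cancer survivors face a
stubborn confound: repeated testing produces practice effects, so observed
scores *improve* over follow-up even as true cognition declines with age.
One way out is to treat the **first assessment** (free of practice) as a
cross-sectional proxy for the aging trend, model it continuously over
chronological age, and model the **longitudinal slope** (confounded with
practice) separately but simultaneously.

`cogfrail` implements that analysis as a reusable, tested pipeline for
two-cohort (survivor vs. control) longitudinal studies:

1. **Domain scoring** — raw neuropsychological test scores are screened
   for non-normality, Box–Cox transformed where needed, z-standardized
   against the healthy-control baseline, sign-aligned (timed tests are
   negated so higher is always better), and averaged into two composites:
   APE (attention / processing speed / executive function) and LM
   (learning and memory).
2. **DAFI** — the Deficit Accumulation Frailty Index: up to 44 ordinal
   indicators coded 0/1/2 (absent / intermediate / most adverse), summed
   and divided by the maximum possible sum; missing items drop out of
   numerator and denominator; scores are valid only with ≥ 35 assessed
   indicators; categories robust (< 0.2), pre-frail ([0.2, 0.35)), frail
   (≥ 0.35).
3. **The growth model** — a Bayesian varying-intercepts/varying-slopes
   model fitted by MCMC (JAGS).
4. **Post-hoc curves** — per-decade effect conversions, survivor−control
   gap curves over age with 95% highest-density bands, and the
   null-crossing age at which the gap stops being discernible.
5. **A synthetic-cohort generator** with known ground truth, so every
   stage is testable without patient data.

## The model

For participant *i* at visit time *t* (months since baseline):

```
y_it = α_i + β_i · month_it + ε_it,          ε_it ~ N(0, σ_ε²)

α_i = γ00 + γ01·c_i + γ02·c_i² + S_i·(γ03 + γ04·c_i + γ05·c_i²) + u_i
β_i = γ10 + γ11·S_i + Σ_k (γ12.k·Q_ik + γ13.k·S_i·Q_ik) + v_i,  k = 2,3,4

(u_i, v_i) ~ N(0, Ω),   Ω = [σ_α², ρσ_ασ_β; ρσ_ασ_β, σ_β²]
```

where `c_i` is enrollment age centered (default: sample mean, e.g. 72.5),
`S_i` indicates survivor, and `Q_ik` are baseline age-quartile indicators
(default bins 60–68, 69–72, 73–76, 77–89; youngest is the reference).
So γ01 is the cross-sectional aging slope per year (×10 for the
per-decade effect), γ03–γ05 describe the survivor−control difference as a
quadratic in age, γ10 is the practice-effect slope per month, and ρ links
a person's starting level to their longitudinal change. Priors are weakly
informative and autoscaled; convergence is monitored by split R-hat
against the conventional 1.01 threshold.

The survivor−control gap at age *a* is evaluated per posterior draw,

```
Δ(a) = γ03 + γ04·(a − center) + γ05·(a − center)²,
```

and summarized as a mean curve with a per-age 95% HDI band; the
null-crossing age is the first age (scanning upward) at which the band
contains zero.

## Worked example

```r
library(cogfrail)
library(dplyr)

cfg <- cohort_config(n_survivors = 150, n_controls = 100, seed = 42)
sim <- simulate_cohort(cfg)
sim
#> <cohort_sim>
#>   250 participants, 911 visit records, 16 tests, 44 indicators

# frailty index at baseline
d <- dafi_scores(sim$indicators)
table(d$category[d$month == 0])
#>     frail pre_frail    robust
#>         2        77       171

# growth model on the APE domain outcome
panel <- left_join(sim$latent,
                   distinct(sim$scores, participant_id, group, age_enroll),
                   by = "participant_id")
fit <- fit_trajectory_model(build_design(panel, "APE"),
                            mcmc = "test", seed = 1)
tidy(fit)
#> # A tibble: 18 x 6
#>   term    estimate std.error hdi_lower hdi_upper  rhat
#> 1 gamma00  0.0989    0.0752   -0.0489   0.244     1.00
#> 2 gamma01 -0.0419    0.0115   -0.0645  -0.0196    1.01
#> 3 gamma02 -0.00279   0.00175  -0.00599  0.000785  1.01
#> 4 gamma03 -0.275     0.0973   -0.456   -0.0790    1.00
#> 5 gamma04  0.00922   0.0143   -0.0190   0.0370    1.01
#> # ... 13 more rows

per_decade_effect(tidy(fit)$estimate[2])
#> [1] -0.419    # cross-sectional decline in z-units per decade of aging

cv <- gap_curve(fit, ages = seq(62, 87, 0.1))
cv[cv$age == 72.5, ]
#>     age mean_diff hdi_lo  hdi_hi significant
#>    72.5    -0.278 -0.464  -0.089        TRUE
autoplot(cv)      # gap curve with band and crossing
autoplot(fit)     # trajectory panel (cross-sectional curves + quartile slopes)
```

In this run the fitted gap is reliably negative (survivors below
controls) in a mid-age window — the `significant` column of the curve
recovers the window's endpoints — and the band includes zero at the
sparse ends of the age range, the same qualitative behavior the method is
designed to expose.

The whole pipeline (simulate → score → DAFI → fit → report, with CSV
artifacts, figures, a resolved-config snapshot and a log) also runs as
one call, or from the shell via the thin wrapper in `inst/cli/cogfrail`:

```r
run_pipeline("all", run_config(outdir = "run1", seed = 7))
```

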