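# echosens

Longitudinal analysis of echocardiographic parameters in randomized trials
of transthyretin amyloidosis with cardiomyopathy (ATTR-CM), for trial
statisticians and cardiovascular-imaging researchers. The package covers the
complete analysis chain of a contemporary ATTR-CM trial:

1. **Parameter derivation** from raw echo measurements — Devereux LV mass
   indexed to body surface area, biplane Simpson volumes and LVEF, LVOT
   stroke volume `π(d/2)²·VTI`, mean LV wall thickness, relative wall
   thickness, E/A and E/e′ ratios — with a registry that records each
   parameter's units and "worse direction".
2. **The primary repeated-measures model (MMRM)**: change from baseline
   `y_iv = x_iv'β + ε_i`, `ε_i ~ N(0, Σ_{J_i})`, with an unstructured 4×4
   within-patient covariance `Σ` fitted by REML over its log-Cholesky
   parameters (compiled objective and analytic gradient), fixed effects for
   visit, treatment-by-visit, baseline, ATTR type and age group (plus
   baseline tafamidis use and its treatment interaction in the overall
   population), and least-squares mean treatment contrasts with
   Satterthwaite degrees of freedom.
3. **A four-pattern pattern-mixture multiple-imputation sensitivity
   analysis**: missing cells after death are sampled from the worst decile
   of observed changes; on-treatment missingness (within 126 days of the
   last dose, 1.5× the 84-day dosing interval) is imputed as
   missing-at-random by MCMC data augmentation; off-treatment missingness is
   imputed from retrieved dropouts when at least 10 exist at month 30, and
   otherwise by copy reference from placebo; every imputed change is capped
   at `0 − baseline`. Each of `m = 100` completed datasets is analysed by a
   month-30 ANCOVA and pooled by Rubin's rules
   (`T = ū + (1 + 1/m)·b`, Barnard–Rubin df).
4. **A seeded synthetic-trial generator** that emulates the trial structure
   (two arms of 326, visits at days 0/365/548/730/913, stratification
   factors, deaths, treatment discontinuation, MCAR/MAR/MNAR mechanisms)
   with known ground truth, so the whole chain is testable without the
   access-restricted patient-level data.

## Worked example

Simulate an LVEF trial at the default study conditions (a configured
month-30 placebo-corrected difference of about +2 LVEF points), analyse it
with the primary MMRM, and run the sensitivity analysis:

```r
library(echosens)

cfg   <- trial_config("lvef", missingness_mode = "mar",
                      missingness_rate = 0.04, seed = 42)
trial <- apply_missingness(simulate_trial(cfg), cfg)

tab <- run_primary(trial, mmrm_spec(parameter = "lvef"))
tab[, c("visit", "ls_mean_placebo", "ls_mean_vutrisiran",
        "difference", "se", "ci_low", "ci_high", "p_value")]
#>   visit ls_mean_placebo ls_mean_vutrisiran difference    se  ci_low ci_high p_value
#> 1   m12           -2.07              -1.65       0.42 0.692 -0.9387    1.78  0.5442
#> 2   m18           -4.13              -2.33       1.80 0.799  0.2326    3.37  0.0245
#> 3   m24           -5.38              -4.12       1.26 0.857 -0.4220    2.95  0.1415
#> 4   m30           -6.18              -4.38       1.79 0.922 -0.0165    3.61  0.0521
```

Each row is one visit: LS-mean change from baseline per arm (LVEF
percentage points; both arms decline, the treated arm less), the
placebo-corrected difference with its standard error, 95% CI and p-value.
The month-30 difference of +1.79 (true configured value 2.1) illustrates
the sampling noise of a single simulated trial.

```r
sens <- run_sensitivity(trial, mmrm_spec(parameter = "lvef"),
                        m = 100, seed = 43)
sens[, c("q_bar", "se", "ci_low", "ci_high", "df", "p_value", "m")]
#>   q_bar    se ci_low ci_high  df p_value   m
#> 1  1.67 0.984 -0.258    3.61 467  0.0893 100

table(attr(sens, "run")$patterns$pattern)
#>              P1_death P2_vutri_on_treatment   P3i_vutri_retrieved
#>                   151                   109                    66
#>      P4ii_placebo_mar
#>                   212
```

The pooled sensitivity estimate (+1.67) sits close to the primary MMRM
difference, as expected when the pattern-specific assumptions are mild; the
pattern table shows how the 538 missing cells were routed (deaths,
on-treatment MAR, retrieved dropouts, placebo MAR).

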