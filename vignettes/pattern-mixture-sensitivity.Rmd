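---
title: "Longitudinal echocardiographic analysis with pattern-mixture sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal echocardiographic analysis with pattern-mixture sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echosens)
```

## The analysis problem

Transthyretin amyloidosis with cardiomyopathy (ATTR-CM) progresses on
echocardiography as gradually increasing left-ventricular wall thickness and
mass and deteriorating systolic and diastolic function. A randomized trial of
a disease-modifying agent therefore asks a longitudinal question: does active
treatment attenuate the change from baseline in each echocardiographic
parameter over a 30-month follow-up with assessments at months 12, 18, 24 and
30?

Two features make the statistics non-trivial. First, the within-patient
correlation of repeated echo measurements is strong and irregular, so the
primary model is a mixed model for repeated measures (MMRM) with a fully
unstructured 4x4 covariance estimated by REML. Second, missing assessments
are frequent and structured — patients die, discontinue the study drug,
or miss visits — and death and treatment discontinuation are plainly not
"missing at random". The package therefore pairs the MMRM with a
pattern-mixture multiple-imputation sensitivity analysis in which each
missing cell is imputed under an assumption appropriate to *why* it is
missing, and the imputed analyses are pooled by Rubin's rules.

`echosens` implements the full chain — parameter derivation, primary model,
sensitivity analysis — together with a seeded synthetic-trial generator, so
that every stage is testable without access to patient-level trial data
(which for this indication are access-restricted).

## Echocardiographic parameters

Raw measurements are converted to derived parameters with the standard
formulas:

* mean LV wall thickness \((\mathrm{IVSd} + \mathrm{PWd})/2\) and relative
  wall thickness \(2\,\mathrm{PWd}/\mathrm{LVEDD}\);
* LV mass by the Devereux linear-dimension formula
  \(0.8 \cdot 1.04\left[(\mathrm{IVSd}+\mathrm{LVEDD}+\mathrm{PWd})^3 -
  \mathrm{LVEDD}^3\right] + 0.6\) g (inputs in cm), indexed to body surface
  area (Du Bois by default, Mosteller available — the choice is configurable
  because reporting conventions vary);
* LV volumes by the modified biplane Simpson method of discs,
  \(V = \tfrac{\pi}{4}\sum_{i=1}^{20} a_i b_i \cdot L/20\), and
  \(\mathrm{LVEF} = 100\,(\mathrm{EDV}-\mathrm{ESV})/\mathrm{EDV}\);
* LV outflow-tract stroke volume \(\pi (d/2)^2 \cdot \mathrm{VTI}\);
* Doppler ratios E/A and E/e' (lateral, septal, and average, where the
  average divides E by the mean of the lateral and septal e' — the averaging
  convention is rarely printed, so it is stated here and fixed).

Units are enforced at the boundary: linear dimensions in mm, Simpson and
LVOT quantities in cm. A record whose values are plausible only on the other
scale is rejected, never silently converted. Global longitudinal strain
enters as a supplied signed value and is stored as a magnitude ("absolute
GLS"), so that a decrease is unambiguously a deterioration.

Every parameter is registered with a "worse direction"
(`echo_registry()`): function measures (LVEF, absolute GLS, stroke volume,
tissue velocities, A wave, deceleration time) worsen downward;
hypertrophy/congestion measures (wall thickness, mass index, E/e', E/A,
atrial size, end-systolic volume, RV areas, IVC diameter, TR velocity)
worsen upward. The registry drives the worst-decile imputation rule below;
because direction assignments are an interpretation rather than a printed
convention, they are overridable per parameter.

## The repeated-measures model

For one parameter, let \(y_{iv}\) be patient \(i\)'s change from baseline at
post-baseline visit \(v \in \{12, 18, 24, 30\}\) months. The model is

\[
y_{iv} = x_{iv}^\top\beta + \varepsilon_i, \qquad
\varepsilon_i \sim \mathcal N(0, \Sigma_{J_i}),
\]

with fixed effects for visit, treatment-by-visit, baseline value, ATTR type
(wild-type/variant) and age group (<75/>=75); in the overall population,
baseline tafamidis use and its interaction with treatment are added, and
they are removed in the monotherapy (tafamidis non-user) and tafamidis
subgroups. \(\Sigma\) is a fully unstructured 4x4 covariance and
\(\Sigma_{J_i}\) its submatrix at patient \(i\)'s observed visits — patients
contribute whatever visits they have, with no imputation in the primary
analysis. Baseline is a covariate and only post-baseline visits are modelled:
since the baseline change is identically zero and baseline already enters as
a covariate, this is the only self-consistent reading of a "visit" factor
that nominally includes baseline.

Treatment-by-visit uses cell-means coding by default (one treated-arm dummy
per visit), so the month-30 treatment coefficient *is* the month-30
contrast; the equivalent main-effect-plus-interaction coding is available
and spans the same column space.

### Estimation

\(\Sigma\) is parameterized by its log-Cholesky factor (logged diagonal,
free lower triangle), which keeps it positive definite by construction.
For fixed \(\Sigma\) the fixed effects are profiled out by generalized least
squares, and the restricted likelihood

\[
-2\ell_R(\theta) = \sum_i \log\lvert\Sigma_{J_i}\rvert
 + \log\lvert X^\top W X\rvert + r^\top W r
\]

is minimized over the ten covariance parameters by BFGS with the analytic
gradient, followed by a few damped Newton steps (finite-difference Hessian
of the analytic gradient) that drive the gradient to about \(10^{-10}\) so
closed-form equivalences hold to tight numerical tolerance. Patient
contributions are pre-aggregated by missingness pattern into sufficient
statistics, making the per-iteration cost independent of the number of
patients; the heavy inner loop is compiled (RcppArmadillo). Starting values
come from the pairwise-complete covariance of ordinary-least-squares
residuals, eigenvalue-floored at \(10^{-6}\) of the largest eigenvalue to
ensure positive definiteness. A fit that does not converge is returned
flagged, with its optimizer trace, and refuses to produce contrasts.

### Least-squares means and inference

LS means are model predictions with classification factors weighted equally
across levels and the baseline covariate at its analysis-set mean (the
default convention of the common trial-analysis software). The placebo-
corrected difference at a visit is the treated-minus-placebo LS-mean
contrast \(c^\top\hat\beta\) with standard error
\(\sqrt{c^\top \widehat{\mathrm{Var}}(\hat\beta)\, c}\). Degrees of freedom
use the Satterthwaite approximation,
\(\nu = 2 f^2 / (g^\top V_\theta\, g)\) with \(f = c^\top (X^\top W X)^{-1}
c\), \(g\) its gradient in the covariance parameters and \(V_\theta\) the
inverse observed information; a residual-df option is provided. Intervals
are two-sided at \(\alpha = 0.05\) with no multiplicity adjustment,
matching the exploratory character of the endpoints.

## The pattern-mixture sensitivity analysis

Every missing post-baseline cell is classified into one of four patterns
(`classify_patterns()`), using a 126-day on-treatment window — 1.5 times
the 84-day dosing interval:

1. **Death** (including transplant and LV-assist-device placement, which are
   treated identically) before the month-30 visit: cells at or after the
   death day are imputed by sampling with replacement from the *worst 10%*
   of observed changes at the same visit, arm and baseline-tafamidis group,
   worst as defined by the registry's direction. The decile holds
   \(\lceil 0.1 n \rceil\) donors (never empty); an empty
   visit/arm/tafamidis pool falls back to the arm-level pool and is flagged
   in the provenance.
2. **Treated arm, on treatment** (missing within 126 days of the last
   dose): missing at random; imputed by multiple imputation estimated from
   treated-arm data collected on treatment in the same tafamidis group —
   observed off-treatment values are masked out of the estimation sample.
3. **Treated arm, off treatment** (more than 126 days after the last
   dose): if at least 10 *retrieved dropouts* exist at month 30 in the
   tafamidis group (patients who discontinued treatment yet provided a
   month-30 assessment more than 126 days after their last dose), the cell
   is imputed from the retrieved dropouts; otherwise by **copy reference**
   from placebo.
4. **Placebo**: off-treatment cells with a sufficient placebo
   retrieved-dropout pool use retrieved-dropout imputation; all other
   placebo cells are missing at random, imputed from all placebo patients
   in the tafamidis group. (Sufficiency is the stated subtype rule; the
   window decides which cells can be anchored by off-treatment data, which
   is why on-treatment placebo cells always route to the MAR branch.)

Death takes precedence over the window rules. By default pattern 1 covers
cells at or after the death day — a visit missed while the patient was
alive is routed by the window rules — with a switch
(`pattern1_all_missing`) for the stricter reading that assigns all of a
decedent's missing cells to pattern 1.

Every imputed change, from any method, is capped at the patient's worst
possible change, \(0 - \text{baseline}\), so an imputed post-baseline value
can never fall below zero. Taken literally this cap can only bind for
parameters whose deterioration is a decrease; it is applied uniformly, as
stated, for all parameters.

### Imputation engines

*MAR multiple imputation* uses Markov-chain Monte Carlo data augmentation
for a multivariate normal regression of the four changes on ATTR type,
NYHA class, age group, NT-proBNP stratum and the baseline value, run
separately by arm and tafamidis group because within-patient missingness
can be nonmonotone. The I-step draws each patient's missing cells from
their conditional normal given the observed cells; the P-step draws the
coefficient matrix and covariance from the conjugate
normal-inverse-Wishart posterior under the Jeffreys prior
\(p(B, \Sigma) \propto \lvert\Sigma\rvert^{-(d+1)/2}\). The chain uses 500
burn-in iterations and retains one draw per imputation index every 100
iterations — long spacing bought cheaply by the compiled chain — so
retained draws are effectively independent.

*Retrieved-dropout imputation* is Bayesian normal-regression imputation of
the missing visit's change on the covariates and baseline, estimated solely
from retrieved-dropout observations at that visit: residual variance from
its scaled inverse-chi-squared posterior, coefficients from their
conditional normal, and the value from the posterior predictive. If the
visit's donor design is singular or too small the model falls back to
intercept-plus-baseline, then to the pooled off-treatment donor
observations, recorded in the provenance.

*Copy reference* takes the deviating treated patient's whole outcome
distribution from placebo: the placebo mean structure (a multivariate
regression on baseline) and covariance are drawn fresh from their posterior
at each imputation index — estimated from complete-case placebo patients in
the same tafamidis group — and the missing cells are drawn from the
reference conditional normal given the patient's observed post-baseline
changes and baseline. Conditioning on observed cells only (never on other
imputed cells) keeps the draw a coherent marginal of the reference joint.

Reproducibility: one seed determines the whole run. The MCMC chains consume
a master stream; each imputation index then receives its own derived seed,
so imputation indices are mutually independent streams and the run is
byte-reproducible.

### Pooling

Each completed dataset is analysed by the month-30 ANCOVA — change on
baseline, treatment, tafamidis, treatment-by-tafamidis, ATTR type and age
group (tafamidis terms dropped outside the overall population), with the
same equal-weighting LS-mean convention as the MMRM, assumed to match the
repeated-measures convention. The \(m = 100\) estimates are combined by
Rubin's rules: \(\bar q\), within-variance \(\bar u\), between-variance
\(b\), total \(T = \bar u + (1 + 1/m)b\), and degrees of freedom by the
Barnard–Rubin small-sample formula anchored at the ANCOVA residual df.

## The synthetic-trial generator

`trial_config()` / `simulate_trial()` generate a two-arm trial: 326
patients per arm; baseline tafamidis 40%; wild-type ATTR 88%; NYHA III 9%;
NT-proBNP above 3,000 ng/l 27%; age 75 or older 55% — a contemporary
ATTR-CM population. Changes from baseline are multivariate normal around
arm-specific mean profiles with an unstructured covariance; presets for
LVEF, stroke volume, mean LV wall thickness and LV mass index carry
baseline distributions, mean trajectories and change-score variances on the
scale reported for such populations (for example LVEF baseline 55.8 (12.5),
placebo declining to -6.2 by month 30 against -4.1 on treatment; month-30
change SD near 10). Visits are fixed at nominal days 0/365/548/730/913 —
exact visit days, no windows — because the 126-day dosing arithmetic needs
day-level anchors. Dosing is every 84 days; death and discontinuation are
exponential (defaults: about 8% deaths and 12% discontinuations by month
30); off-treatment visits are retained with probability 0.5, which is what
creates retrieved dropouts. Missingness mechanisms: MCAR (independent
deletion), MAR (monotone dropout with hazard logistic in the previous
observed change), and MNAR (deletion probability logistic in the deleted
value itself, oriented toward the registry's worse direction) — the MNAR
mode exists precisely to create detectable violations of the primary
model's assumption.

What the generator does *not* emulate: it simulates one parameter per run
(no cross-parameter correlation), Gaussian trajectories with no floor or
ceiling effects, exponential event times independent of the outcome
trajectory unless the MNAR mode is used, and exact visit attendance.
Passing tests therefore demonstrate correctness of the estimators and of
the imputation logic under the stated data-generating conditions — not
robustness to measurement artefacts, informative visit timing, or
heavy-tailed measurement error found in real core-lab data.

## Validation

The test suite computes, among others: exact agreement of the REML fit with
the pooled within-arm covariance closed form on complete balanced data
(tolerance 1e-8, 40 subjects); type-I error of the month-30 contrast under
a null trial with MAR dropout (1,000 replicates at 100 per arm, acceptance
band 3.7–6.5%); recovery of a configured 4.1 ml stroke-volume effect with
CI coverage (500 replicates at 300 per arm, band 93–97%); calibration of
the MAR multiple imputation (200 replicates, 400 patients, 30% monotone
dropout, m = 20, coverage band 92–98%); exhaustiveness of pattern routing
and the cap invariant over randomized death/dosing configurations;
uniformity of the worst-decile sampler; and the direction and monotonicity
of the copy-reference attenuation under treated-arm informative dropout.
Replication counts are the package's validation sizes, chosen to keep the
Monte-Carlo error well inside each acceptance band.

## Known limitations

* Satterthwaite degrees of freedom are implemented; Kenward–Roger is not.
* The MMRM assumes a common unstructured covariance across arms.
* Copy-reference reference parameters are estimated from complete-case
  placebo patients; under very heavy placebo missingness this loses
  information (the MAR chain could in principle supply completed reference
  data).
* The cap rule is applied literally for increase-is-worse parameters, where
  it can never bind; whether the original convention differed there is not
  determinable from public descriptions.
* GLS is accepted as a supplied value; no strain computation from images is
  attempted, and no valve-disease grading is included.
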