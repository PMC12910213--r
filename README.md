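# mipdsim

Model-informed precision dosing (MIPD) computation for vancomycin and
amikacin therapeutic drug monitoring (TDM) in critically ill children, with
a synthetic virtual-patient PICU cohort so the complete analysis runs with
no patient data. The package is aimed at pharmacometricians and clinical
pharmacologists who want an open, tested implementation of the
MAP-Bayesian forecasting workflow that commercial dosing platforms provide
as a black box — and at methodologists who want to study its predictive
performance under controlled conditions.

**Research software: nothing here is clinical dosing advice.** The shipped
model parameter values are synthetic defaults for simulation and testing.

## What it computes

* **Population PK prediction.** One-compartment (CL, V) and two-compartment
  (CL, V1, V2, Q) IV-infusion models with closed-form solutions, multi-dose
  superposition, log-normal interindividual variability
  (`P_i = TVP · g(cov) · e^η`, `η ~ N(0, Ω)`) and multiplicative covariate
  models (allometric weight, serum creatinine, age).
* **MAP Bayesian updating.** `map_fit()` minimizes
  `Σ_i [(c_obs,i − c_pred,i(η))²/σ_i² + ln σ_i²] + ηᵀΩ⁻¹η` with
  `σ_i² = σ_add² + (σ_prop·c_pred,i)²`, giving the a posteriori individual
  parameters; `η = 0` is the a priori case. The fit is a classed object with
  `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
  `simulate` and `logLik` methods.
* **Exposure-target dose optimization.** Steady-state AUC24 (= daily
  dose/CL), Cmax, trough and %fT>MIC; grid search for the smallest daily
  dose meeting AUC/MIC ≥ 400 (vancomycin) or Cmax/MIC ≥ 8 with trough
  < 5 mg/L (amikacin) under pediatric safety caps; plus the trough-guided
  proportional standard-of-care adjustment rule as comparator.
* **Evaluation.** MAE / MdAE / MdE prediction-error metrics, paired
  a priori vs a posteriori tables stratified by arm and drug, model-fit
  classification (good / intermediate / poor), percentile bootstrap CIs.
* **Synthetic cohort.** A seeded PICU virtual-patient generator (default
  n = 41, median age 38.6 months, 56.1% female, 23/41 vancomycin, 12/41
  MIPD arm) driving the full study pipeline via `run_study()`.

## Worked example

Fit one vancomycin patient from a single trough, then optimize the dose:

```r
library(mipdsim)

model <- pk_model_vancomycin()                  # synthetic default config
cov   <- patient_covariates(age_months = 30, weight_kg = 12, scr_mg_dl = 0.35)
reg   <- regimen(180, interval_h = 6, infusion_duration_h = 1, n_doses = 4)
obs   <- observations(time_h = 17.95, concentration_mg_L = 14.2)

fit <- map_fit(model, cov, reg, obs)
fit
#> MAP Bayesian fit (vancomycin, one_compartment)
#>   observations used: 1
#>   eta_MAP: CL = -0.3656, V = 0.04028
#>   individual parameters: CL = 1.381, V = 8.745
#>   -2 log-posterior: 2.4288
```

The observed trough (14.2 mg/L) sits above the population prediction, so the
MAP estimate lowers this child's clearance to 1.38 L/h (a −37% η on the
log scale) and the a posteriori curve now passes near the measurement.
Dose optimization then inverts the exposure target for those individual
parameters:

```r
recommend_dose(model, cov, coef(fit, "eta"), vancomycin_target())
#> Dose recommendation: 93 mg q4h (558 mg/day)
#> Steady-state exposure: AUC24 = 404.0 mg*h/L, Cmax = 21.01 mg/L, trough = 13.08 mg/L
#>   AUC/MIC = 404.0, Cmax/MIC = 21.01, %fT>MIC = 100.0%
```

558 mg/day is the smallest grid dose reaching AUC/MIC ≥ 400 for a
clearance of 1.38 L/h (400 × 1.38 ≈ 553 mg/day), with the predicted trough
inside the supportive 10–15 mg/L band. A full synthetic study reproduces
the paired evaluation layout:

```r
study <- run_study(cohort_config(n = 41, seed = 1))
study
#> Synthetic MIPD study: n = 41 patients, seed = 1
#>   arms: 14 MIPD / 27 SoC;  drugs: 23 vancomycin / 18 amikacin
#>   prediction pairs: 55 ( 14 second-sample )
#>
#>  timepoint   prediction  n    mae   mdae      mde
#>          1     a_priori 41 2.7460 0.8184  0.09979
#>          1 a_posteriori 41 0.5996 0.1968 -0.06089
#>          2     a_priori 14 1.3298 0.3204  0.08623
#>          2 a_posteriori 14 0.7268 0.3826  0.02358
```

Assimilating a single trough cuts the first-sample median absolute error
from 0.82 to 0.20 mg/L on this seed — the within-patient a priori →
a posteriori improvement the evaluation layer is built to measure. (The
second-sample rows use parameters updated with the first TDM concentration
and, with only 14 pairs, are noisier.)

A thin command-line wrapper over the same functions lives at
`inst/cli/mipd.R` (`simulate`, `forecast`, `optimize`, `evaluate`,
`run-study`).

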