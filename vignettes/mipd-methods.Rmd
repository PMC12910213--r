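---
title: "Methods: MAP Bayesian forecasting and dose optimization for pediatric TDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MAP Bayesian forecasting and dose optimization for pediatric TDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipdsim)
```

## The problem

Vancomycin and amikacin have narrow therapeutic windows, and in critically
ill children the pharmacokinetic (PK) variability between patients is large
enough that weight-based dosing frequently misses its exposure targets.
Model-informed precision dosing (MIPD) addresses this by combining a
population PK model, the patient's covariates, and sparse therapeutic drug
monitoring (TDM) concentrations through Bayesian updating, so that dose
adjustment can be individualized before steady-state sampling alone would
allow it.

This package implements that computation end to end — population PK
prediction, maximum a posteriori (MAP) estimation of individual parameters,
exposure-target dose optimization, model-fit classification, and paired
a priori vs a posteriori predictive-performance evaluation — together with a
synthetic virtual-patient PICU cohort generator, so the whole analysis is
reproducible without access to patient data. All outputs are research
simulation artifacts, not clinical dosing advice.

## Population PK models

Two structures are supported, both for intravenous infusion:

* **one-compartment** (vancomycin convention): parameters CL (L/h) and V
  (L), elimination rate $k_e = CL/V$. During an infusion at rate $R_0$,
  $c(t) = (R_0/CL)\,(1 - e^{-k_e t})$, with exponential decay afterwards.
* **two-compartment** (amikacin convention): CL, central volume $V_1$,
  peripheral volume $V_2$, intercompartmental clearance $Q$. The closed form
  is the standard bi-exponential macro-constant solution with hybrid rate
  constants $\alpha,\beta$ derived from $k_{10}, k_{12}, k_{21}$. The
  macro-constant route was chosen over a matrix exponential for speed; an
  independent ODE integration oracle in the test suite guards its
  correctness to $10^{-6}$ relative error.

Multi-dose histories are handled by superposition (linear PK), and
steady-state profiles close the superposition series analytically with the
geometric accumulation factor $e^{-\lambda\tau}/(1-e^{-\lambda\tau})$ per
exponential term.

Individual parameters follow the standard nonlinear mixed-effects
convention $P_i = TVP \cdot g(\text{cov}) \cdot e^{\eta_P}$ with log-normal
random effects $\eta \sim N(0, \Omega)$ on the parameters that carry
interindividual variability (IIV): CL and V for vancomycin, CL for
amikacin. Covariate effects are multiplicative: allometric weight scaling
(exponent 0.75 on clearances, 1.0 on volumes), an inverse-power serum
creatinine term on vancomycin clearance, and a mild age power term as a
maturation proxy. All functional forms and values are configuration.

**The shipped model values are synthetic defaults.** The published pediatric
models this workflow would use in practice do not have their numeric
estimates reproduced here; `pk_model_vancomycin()` and `pk_model_amikacin()`
carry the correct skeleton (structure, covariates, IIV placement, residual
model) with plausible but synthetic numbers chosen once for simulation and
testing: vancomycin CL 2.2 L/h and V 9.8 L at the 14 kg reference
($\omega^2$ 0.20 and 0.10, roughly 45% and 30% CV, typical of critically
ill pediatric popPK), amikacin CL 1.7 L/h, $V_1$ 4.5 L, $V_2$ 3.5 L, Q
1.2 L/h ($\omega^2_{CL}$ 0.15). Residual error is combined additive +
proportional for both drugs (vancomycin 1.0 mg/L + 15%, amikacin 0.3 mg/L +
20%); the vancomycin residual model is not fixed by the reference skeleton,
so the combined form was adopted for symmetry and is overridable.

## MAP estimation

`map_fit()` minimizes, over $\eta$,

$$-2\log L(\eta) = \sum_i \left[
  \frac{(c_{obs,i} - c_{pred,i}(\eta))^2}{\sigma_i^2} + \ln \sigma_i^2
  \right] + \eta^\top \Omega^{-1} \eta, \qquad
  \sigma_i^2 = \sigma_{add}^2 + (\sigma_{prop}\, c_{pred,i})^2 .$$

Numerical choices:

* The $\ln \sigma_i^2$ term is **kept**. It is constant only when the error
  is purely additive; with a proportional component it couples the variance
  to the prediction and shifts the mode. Many MAP implementations drop it,
  so `map_control(keep_log_sigma = FALSE)` exposes the alternative.
* Optimizer: quasi-Newton BFGS from the prior mode $\eta = 0$ with
  finite-difference gradients, relative objective tolerance $10^{-10}$. The
  fit never returns a point worse than the start, and an explicit
  finite-difference gradient-norm check backs the `converged` flag.
* Trial points with $|\eta_j| > 50$ or overflowing predictions get a large
  finite penalty rather than an error, which keeps line searches stable
  without affecting the optimum.
* With no usable observations the prior mode $\eta = 0$ is returned exactly
  — that is the **a priori** case (covariates and dosing only). The
  **a posteriori** prediction plugs in $\eta_{MAP}$.
* Observations below the limit of quantification are excluded by default;
  `map_control(blq = "loq2")` substitutes LOQ/2 instead. Neither choice is
  dictated by the reference workflow, so both are exposed.
* Full posterior sampling and credible intervals are deliberately out of
  scope: the platform behavior being emulated is empirical-Bayes mode
  estimation.

## Exposure metrics and dose optimization

`steady_state_metrics()` computes, for one steady-state interval: AUC24 by
the exact linear-PK identity $\text{AUC24} = \text{daily dose}/CL$; Cmax at
end of infusion (the aminoglycoside convention; a `peak_delay_h` option
reads it later for post-distribution two-compartment peaks); trough
immediately pre-dose; and %fT>MIC by bracketing the steady-state profile on
a 201-point grid and refining each crossing with `uniroot`.

`recommend_dose()` searches candidate (dose, interval) pairs: vancomycin
intervals {4, 6, 8, 12, 24} h, amikacin {24, 36, 48} h, dose increment
10 mg at or above 100 mg and 1 mg below, 1 h infusions. Targets follow the
clinical conventions: vancomycin AUC/MIC $\ge 400$ with the 10--15 mg/L
trough band advisory by default (the band is supportive monitoring, not the
optimization target; `trough_band_hard = TRUE` makes it a constraint);
amikacin Cmax/MIC $\ge 8$ with trough < 5 mg/L; MIC fixed at 1 mg/L as a
standardization convention, not a breakpoint. Safety caps (defaults:
vancomycin 80 mg/kg/day and 4 g/day, amikacin 30 mg/kg/day — placeholders,
not clinical limits) are enforced before feasibility. Among feasible
candidates the smallest total daily dose wins, ties broken toward the
longer interval; when nothing is feasible the candidate minimizing a summed
relative shortfall/excess score is returned flagged infeasible, and
`capped` records whether an uncapped grid would have reached the target.
Because concentrations are linear in dose, the grid is priced from one
unit-dose profile per interval; the test suite re-enumerates the grid
candidate by candidate as an independent brute-force oracle.

The comparator standard-of-care rule (`soc_adjust()`) is trough-guided
proportional adjustment: below-band troughs scale the daily dose by band
midpoint / observed trough, supratherapeutic troughs scale it down the same
way, and a trough above twice the band ceiling also extends the interval to
the next candidate. The scaling factor is capped at 3 so a near-zero trough
cannot explode the dose, and adjusted doses round to a 5 mg increment.

## Evaluation layer

`error_metrics()` implements MAE (mean |predicted − observed|), MdAE
(median absolute error) and MdE (signed median error); the median of an
even count is the midpoint of the central order statistics. MdAE is the
primary summary because of its robustness to outliers — a property the test
suite asserts directly. `paired_evaluation()` aggregates paired
within-patient comparisons at the same observation timepoint into the
stratified table (total / arm / drug, first and second sample, a priori vs
a posteriori). `classify_fit()` labels agreement good / intermediate / poor
at 20% and 50% relative error; commercial platforms do not publish their
cutoffs, so these defaults are package conventions, config-exposed, and a
documented absolute-difference fallback (1 and 3 mg/L) covers observed
zeros. Percentile bootstrap intervals (`boot_error_ci()`) are provided for
exploration only and never gate anything.

## The synthetic cohort

`simulate_cohort()` emulates the structure of a PICU TDM cohort: n = 41 by
default, age log-normal calibrated to median 38.6 and IQR 81.7 months
(clamped to 1--216 months; clamping preserves the median), 56.1% female,
drug mix 23/41 vancomycin, arm split 12/41 MIPD, and a second TDM sample
with probability 15/41. Weight uses the transparent rule
$(\text{age}_{yr} + 4) \times 2$ kg with 15% log-normal scatter; serum
creatinine is an age-dependent log-normal with median
$0.25 + 0.04\,\text{age}_{yr}$ mg/dL. Initial dosing is 15 mg/kg q6h
(vancomycin) and 15 mg/kg q24h (amikacin), 1 h infusions. Troughs are drawn
3 minutes before the fourth dose (vancomycin) or third dose (amikacin),
perturbed by the residual model, truncated at zero and flagged below-LOQ
when negative. Each patient owns an RNG stream split from the master seed,
so the full pipeline is deterministic and insensitive to patient order.

What the generator does **not** emulate: real covariate joint
distributions (growth standards, renal disease trajectories), non-trough
sampling-time noise, assay-specific LOQ behavior, clinician overrides,
augmented renal clearance, or the pragmatic arm reassignment of a real
implementation study. Passing tests on this cohort therefore demonstrate
the correctness and internal consistency of the computation and the
expected *direction* of the Bayesian-updating benefit, not clinical
performance on real patients.

`run_study()` chains the whole pipeline per patient: initial regimen, first
trough, paired predictions, arm-specific adjustment, optional second trough
under the adjusted regimen with predictions from first-sample-updated
parameters, fit categories and the stratified error table.

## Problem sizes and numerical tolerances

The test suite works at deliberately modest sizes chosen to make every
check sharp: closed forms vs a `deSolve` ODE oracle at $10^{-6}$ relative
on randomized instances; superposition at $10^{-10}$; the AUC identity vs
trapezoid integration at 0.1%; MAP vs a $10^{-4}$-resolution grid oracle
within $2\times10^{-4}$; parameter recovery over 200 simulated patients (8
rich samples vs 1 trough, requiring at least a 50% RMSE reduction); and the
within-patient improvement direction over 20 master seeds of n = 100
cohorts, required in at least 95% of seeds at both sampling points. The
second-sample direction is the least identified quantity — roughly 37 pairs
per cohort — and is the check most sensitive to the residual-noise and IIV
magnitudes above.

## Known limitations

* The shipped model parameter values are synthetic; conclusions about real
  vancomycin or amikacin exposure require transcribing a published model
  into `pk_model()`.
* One- and two-compartment IV infusion only: no absorption models, no
  saturable elimination, no continuous infusions, no loading-dose design.
* MAP point estimation only; no posterior uncertainty on $\eta$.
* MIC is a fixed scalar; probability of target attainment across MIC
  distributions is out of scope.
* The SoC rule is a stylized version of trough-guided practice; real
  adjustment behavior is heterogeneous.
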