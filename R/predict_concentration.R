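# Closed-form concentration solutions for IV infusion.
#
# Both structures reduce to a sum of exponential terms. For an infusion at
# rate R0 starting at 0 with duration Tinf the concentration is
#   t <= Tinf:  sum_j A_j (1 - exp(-l_j t))
#   t  > Tinf:  sum_j A_j (1 - exp(-l_j Tinf)) exp(-l_j (t - Tinf))
# with one term (A = R0/CL, l = ke = CL/V) for the one-compartment model and
# two macro-constant terms for the two-compartment model. Multi-dose profiles
# are superpositions of shifted single-dose solutions (linear PK).

# exponential-term coefficients (A_j, lambda_j) for a unit infusion rate
unit_rate_terms <- function(values, structure) {
  if (structure == "one_compartment_iv_infusion") {
    CL <- values$CL; V <- values$V
    list(A = 1 / CL, lambda = CL / V)
  } else {
    CL <- values$CL; V1 <- values$V1; V2 <- values$V2; Q <- values$Q
    k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
    s <- k10 + k12 + k21
    disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
    alpha <- (s + disc) / 2
    beta <- (s - disc) / 2
    if (alpha - beta < 1e-12 * alpha)
      stop("degenerate two-compartment parameters (alpha ~ beta)", call. = FALSE)
    list(A = c((alpha - k21) / (V1 * alpha * (alpha - beta)),
               (k21 - beta) / (V1 * beta * (alpha - beta))),
         lambda = c(alpha, beta))
  }
}

# single-dose concentration at times t (>= 0 relative to infusion start)
single_dose_conc <- function(terms, rate, tinf, t) {
  out <- numeric(length(t))
  for (j in seq_along(terms$lambda)) {
    A <- rate * terms$A[j]; l <- terms$lambda[j]
    during <- t >= 0 & t <= tinf
    after <- t > tinf
    out[during] <- out[during] + A * (1 - exp(-l * t[during]))
    out[after] <- out[after] +
      A * (1 - exp(-l * tinf)) * exp(-l * (t[after] - tinf))
  }
  out
}

#' Predict concentrations for a dosing history
#'
#' Closed-form concentration-time prediction for an individualized model and
#' an arbitrary IV-infusion regimen, by superposition of single-infusion
#' solutions (linear PK). Times strictly before the first dose yield 0.
#'
#' @param params An `individual_parameters` object from [individualize()].
#' @param model The [pk_model()] the parameters belong to (supplies the
#'   structure).
#' @param regimen A [regimen()] object.
#' @param times Numeric vector of times in hours from the regimen origin
#'   (>= 0).
#' @return Numeric vector of concentrations, mg/L (non-negative).
#' @examples
#' m <- pk_model_vancomycin()
#' p <- individualize(m, patient_covariates(38.6, 14, 0.4))
#' r <- regimen(210, 6, 1, n_doses = 4)
#' predict_concentration(p, m, r, times = c(1, 6, 18.9))
#' @export
predict_concentration <- function(params, model, regimen, times) {
  if (!inherits(params, "individual_parameters"))
    stop("params must come from individualize()", call. = FALSE)
  if (!inherits(regimen, "regimen"))
    stop("regimen must be a regimen object", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and >= 0 (hours from regimen origin)",
         call. = FALSE)
  terms <- unit_rate_terms(params$values, model$structure)
  conc <- numeric(length(times))
  for (ev in regimen$events) {
    rel <- times - ev$start_time_h
    idx <- rel > 0
    if (!any(idx)) next
    rate <- ev$amount_mg / ev$infusion_duration_h
    conc[idx] <- conc[idx] +
      single_dose_conc(terms, rate, ev$infusion_duration_h, rel[idx])
  }
  pmax(conc, 0)
}

# steady-state concentration within one dosing interval, t in [0, tau].
# Accumulation closes the superposition series analytically: each
# post-infusion exponential term of the preceding doses sums to a geometric
# factor r/(1-r) with r = exp(-lambda tau).
steady_state_conc <- function(params, model, dose_mg, interval_h,
                              infusion_duration_h, t) {
  if (interval_h <= infusion_duration_h)
    stop("interval_h must exceed infusion_duration_h", call. = FALSE)
  if (any(t < 0) || any(t > interval_h + 1e-9))
    stop("t must lie within one dosing interval", call. = FALSE)
  terms <- unit_rate_terms(params$values, model$structure)
  rate <- dose_mg / infusion_duration_h
  conc <- single_dose_conc(terms, rate, infusion_duration_h, t)
  for (j in seq_along(terms$lambda)) {
    l <- terms$lambda[j]
    r <- exp(-l * interval_h)
    conc <- conc + rate * terms$A[j] * (1 - exp(-l * infusion_duration_h)) *
      exp(-l * (t - infusion_duration_h)) * r / (1 - r)
  }
  pmax(conc, 0)
}
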