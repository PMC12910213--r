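# Shared fixtures: small models built in code, plus an independent numerical
# ODE oracle (deSolve) for the closed-form concentration solutions.

library(deSolve)

# one-compartment model with IIV on CL only (1-D toy for grid-search checks)
toy_1cpt <- function(CL = 5, V = 20, omega_cl = 0.09, sigma_add = 1,
                     sigma_prop = 0) {
  pk_model("one_compartment_iv_infusion",
           typical_values = list(CL = CL, V = V),
           omega = matrix(omega_cl, 1, 1, dimnames = list("CL", "CL")),
           residual = residual_error(sigma_add, sigma_prop))
}

ref_cov <- function() patient_covariates(38.6, 14, 0.40)

# numerical oracle: integrates the infusion ODE segment by segment with a
# constant rate per segment, at tight tolerance; independent of the
# closed-form superposition path it checks.
ode_oracle <- function(values, structure, regimen, times) {
  ev <- as.data.frame(regimen)
  breaks <- sort(unique(c(0, ev$start_time_h,
                          ev$start_time_h + ev$infusion_duration_h, times)))
  rate_at <- function(t) {
    active <- t >= ev$start_time_h - 1e-12 &
      t < ev$start_time_h + ev$infusion_duration_h - 1e-12
    sum(ev$amount_mg[active] / ev$infusion_duration_h[active])
  }
  if (structure == "one_compartment_iv_infusion") {
    deriv <- function(t, y, p) list(p$R - values$CL / values$V * y)
    state <- 0
    vol <- values$V
    central <- 1L
  } else {
    k10 <- values$CL / values$V1
    k12 <- values$Q / values$V1
    k21 <- values$Q / values$V2
    deriv <- function(t, y, p)
      list(c(p$R - (k10 + k12) * y[1] + k21 * y[2],
             k12 * y[1] - k21 * y[2]))
    state <- c(0, 0)
    vol <- values$V1
    central <- 1L
  }
  out <- stats::setNames(numeric(length(times)), NULL)
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    R <- rate_at((t0 + t1) / 2)
    sol <- deSolve::lsoda(state, c(t0, t1), deriv, parms = list(R = R),
                          rtol = 1e-12, atol = 1e-12)
    state <- as.numeric(sol[nrow(sol), -1])
    hit <- which(abs(times - t1) < 1e-12)
    if (length(hit)) out[hit] <- state[central] / vol
  }
  hit0 <- which(abs(times - 0) < 1e-12)
  if (length(hit0)) out[hit0] <- 0
  out
}

# random parameter set + regimen for a given structure, drawn from the
# current RNG state
random_pk_case <- function(structure) {
  if (structure == "one_compartment_iv_infusion") {
    values <- list(CL = runif(1, 0.5, 10), V = runif(1, 3, 40))
  } else {
    values <- list(CL = runif(1, 0.5, 8), V1 = runif(1, 3, 20),
                   V2 = runif(1, 2, 25), Q = runif(1, 0.3, 6))
  }
  tinf <- runif(1, 0.5, 2)
  tau <- tinf + runif(1, 3, 23)
  reg <- regimen(runif(1, 50, 1000), tau, tinf,
                 n_doses = sample(2:6, 1))
  model <- if (structure == "one_compartment_iv_infusion")
    pk_model(structure, values,
             omega = matrix(0.1, 1, 1, dimnames = list("CL", "CL")),
             residual = residual_error(1, 0.1))
  else
    pk_model(structure, values,
             omega = matrix(0.1, 1, 1, dimnames = list("CL", "CL")),
             residual = residual_error(1, 0.1), drug = "amikacin")
  params <- individualize(model, ref_cov_neutral(), rep(0, 1))
  # bypass covariate effects: none registered, so params equal typical values
  list(model = model, params = params, regimen = reg, values = values)
}

# covariates for models with no covariate effects (values are irrelevant)
ref_cov_neutral <- function() patient_covariates(24, 10, 0.5)
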