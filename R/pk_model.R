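#' Covariate effect on a PK parameter
#'
#' Describes one multiplicative covariate relationship applied to a typical
#' parameter value. Supported forms:
#' \describe{
#'   \item{`allometric_power`, `power`}{multiplier `(x / reference)^exponent`}
#'   \item{`inverse`}{multiplier `(reference / x)^exponent`}
#'   \item{`proportional`}{multiplier `1 + slope * (x - reference)`}
#' }
#' The composed multiplier must be strictly positive for valid covariates;
#' a non-positive proportional multiplier is rejected at evaluation time.
#'
#' @param parameter Name of the PK parameter the effect scales (e.g. `"CL"`).
#' @param covariate Covariate field name (`"weight_kg"`, `"age_months"`,
#'   `"scr_mg_dl"`, `"height_cm"`).
#' @param form One of `"allometric_power"`, `"power"`, `"inverse"`,
#'   `"proportional"`.
#' @param reference_value Covariate reference (> 0) at which the multiplier
#'   is 1.
#' @param exponent_or_slope Exponent (power forms) or slope (proportional).
#' @return An object of class `covariate_effect`.
#' @export
covariate_effect <- function(parameter, covariate,
                             form = c("allometric_power", "power", "inverse",
                                      "proportional"),
                             reference_value, exponent_or_slope) {
  form <- match.arg(form)
  if (!is.finite(reference_value) || reference_value <= 0)
    stop("reference_value must be > 0", call. = FALSE)
  structure(list(parameter = parameter, covariate = covariate, form = form,
                 reference_value = as.numeric(reference_value),
                 exponent_or_slope = as.numeric(exponent_or_slope)),
            class = "covariate_effect")
}

effect_multiplier <- function(effect, cov) {
  x <- cov[[effect$covariate]]
  if (is.null(x) || !is.finite(x) || x <= 0)
    stop("covariate '", effect$covariate, "' is missing or non-positive",
         call. = FALSE)
  m <- switch(effect$form,
    allometric_power = ,
    power = (x / effect$reference_value)^effect$exponent_or_slope,
    inverse = (effect$reference_value / x)^effect$exponent_or_slope,
    proportional = 1 + effect$exponent_or_slope * (x - effect$reference_value))
  if (!is.finite(m) || m <= 0)
    stop("covariate effect on '", effect$parameter,
         "' yields a non-positive multiplier", call. = FALSE)
  m
}

#' Residual-error specification
#'
#' Combined additive + proportional residual model: the variance of an
#' observation with model prediction `c` is
#' `sigma_add^2 + (sigma_prop * c)^2`. A degenerate all-zero specification is
#' rejected because it leaves the estimation objective undefined.
#'
#' @param sigma_add Additive standard deviation, mg/L (>= 0).
#' @param sigma_prop Proportional standard deviation, fraction (>= 0).
#' @return An object of class `residual_error`.
#' @export
residual_error <- function(sigma_add, sigma_prop) {
  if (sigma_add < 0 || sigma_prop < 0)
    stop("residual sigmas must be >= 0", call. = FALSE)
  if (sigma_add + sigma_prop <= 0)
    stop("residual error model must have sigma_add + sigma_prop > 0",
         call. = FALSE)
  structure(list(sigma_add = as.numeric(sigma_add),
                 sigma_prop = as.numeric(sigma_prop)),
            class = "residual_error")
}

#' Population-PK structural model
#'
#' Defines a population pharmacokinetic model for IV infusion: structure
#' (one- or two-compartment), typical parameter values, multiplicative
#' covariate effects, the interindividual-variability (IIV) covariance
#' `omega` of the log-normal random effects eta, and the residual-error
#' model. Individual parameters are
#' `P_i = TVP * covariate multipliers * exp(eta_P)` for parameters carrying
#' IIV, and `P_i = TVP * covariate multipliers` otherwise.
#'
#' @param structure `"one_compartment_iv_infusion"` (parameters CL, V) or
#'   `"two_compartment_iv_infusion"` (CL, V1, V2, Q).
#' @param typical_values Named list of positive typical values. Units: CL and
#'   Q in L/h, volumes in L.
#' @param covariate_effects List of [covariate_effect()] objects.
#' @param omega Symmetric positive semi-definite matrix with dimnames naming
#'   the parameters that carry IIV (variances of log-scale eta).
#' @param residual Residual-error model, a [residual_error()] object.
#' @param drug `"vancomycin"` or `"amikacin"`.
#' @return An object of class `pk_model`.
#' @seealso [pk_model_vancomycin()], [pk_model_amikacin()] for the shipped
#'   default configurations.
#' @export
pk_model <- function(structure = c("one_compartment_iv_infusion",
                                   "two_compartment_iv_infusion"),
                     typical_values, covariate_effects = list(), omega,
                     residual, drug = c("vancomycin", "amikacin")) {
  structure <- match.arg(structure)
  drug <- match.arg(drug)
  need <- if (structure == "one_compartment_iv_infusion") c("CL", "V")
          else c("CL", "V1", "V2", "Q")
  if (!setequal(names(typical_values), need))
    stop("typical_values must name exactly: ", paste(need, collapse = ", "),
         call. = FALSE)
  tv <- unlist(typical_values)[need]
  if (any(!is.finite(tv)) || any(tv <= 0))
    stop("all typical values must be positive", call. = FALSE)
  omega <- as.matrix(omega)
  if (is.null(rownames(omega)))
    stop("omega must carry parameter names as dimnames", call. = FALSE)
  if (!isSymmetric(unname(omega)))
    stop("omega must be symmetric", call. = FALSE)
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("omega must be positive semi-definite", call. = FALSE)
  if (anyDuplicated(rownames(omega)) || !all(rownames(omega) %in% need))
    stop("omega parameters must map uniquely onto model parameters",
         call. = FALSE)
  if (!inherits(residual, "residual_error"))
    stop("residual must be a residual_error object", call. = FALSE)
  base::structure(
    list(structure = structure, typical_values = as.list(tv),
         covariate_effects = covariate_effects, omega = omega,
         residual = residual, drug = drug),
    class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat("Population-PK model (", x$drug, "): ", x$structure, "\n", sep = "")
  cat("  typical values:",
      paste(names(x$typical_values), signif(unlist(x$typical_values), 4),
            sep = " = ", collapse = ", "), "\n")
  cat("  IIV on:", paste(rownames(x$omega), collapse = ", "),
      " (omega diag ", paste(signif(diag(x$omega), 3), collapse = ", "), ")\n",
      sep = "")
  cat("  residual: sigma_add =", x$residual$sigma_add,
      "mg/L, sigma_prop =", x$residual$sigma_prop, "\n")
  invisible(x)
}

#' Default vancomycin model configuration (synthetic values)
#'
#' One-compartment IV-infusion model with IIV on CL and V, allometric weight
#' scaling (0.75 on CL, 1.0 on V), an inverse-power serum-creatinine effect
#' and a mild age-maturation power term on CL, and a combined residual-error
#' model. The skeleton (structure, covariates, IIV placement) follows
#' published pediatric vancomycin models; the numeric values are synthetic
#' defaults for simulation and testing, not clinical estimates, and every
#' field can be overridden.
#'
#' @param typical_values,omega,residual Optional overrides.
#' @return A [pk_model()] object.
#' @export
pk_model_vancomycin <- function(typical_values = list(CL = 2.2, V = 9.8),
                                omega = NULL, residual = NULL) {
  if (is.null(omega)) {
    omega <- diag(c(CL = 0.20, V = 0.10))
    dimnames(omega) <- list(c("CL", "V"), c("CL", "V"))
  }
  if (is.null(residual)) residual <- residual_error(1.0, 0.15)
  pk_model(
    structure = "one_compartment_iv_infusion",
    typical_values = typical_values,
    covariate_effects = list(
      covariate_effect("CL", "weight_kg", "allometric_power", 14, 0.75),
      covariate_effect("V",  "weight_kg", "allometric_power", 14, 1.0),
      covariate_effect("CL", "scr_mg_dl", "inverse", 0.40, 0.4),
      covariate_effect("CL", "age_months", "power", 38.6, 0.15)
    ),
    omega = omega, residual = residual, drug = "vancomycin")
}

#' Default amikacin model configuration (synthetic values)
#'
#' Two-compartment IV-infusion model with IIV on CL only, allometric weight
#' scaling on all parameters, and combined additive + proportional residual
#' error. As with the vancomycin default, the structure mirrors published
#' pediatric amikacin models while the numeric values are synthetic defaults
#' for simulation and testing, not clinical estimates.
#'
#' @param typical_values,omega,residual Optional overrides.
#' @return A [pk_model()] object.
#' @export
pk_model_amikacin <- function(typical_values = list(CL = 1.7, V1 = 4.5,
                                                    V2 = 3.5, Q = 1.2),
                              omega = NULL, residual = NULL) {
  if (is.null(omega)) {
    omega <- matrix(0.15, 1, 1, dimnames = list("CL", "CL"))
  }
  if (is.null(residual)) residual <- residual_error(0.3, 0.2)
  pk_model(
    structure = "two_compartment_iv_infusion",
    typical_values = typical_values,
    covariate_effects = list(
      covariate_effect("CL", "weight_kg", "allometric_power", 14, 0.75),
      covariate_effect("V1", "weight_kg", "allometric_power", 14, 1.0),
      covariate_effect("V2", "weight_kg", "allometric_power", 14, 1.0),
      covariate_effect("Q",  "weight_kg", "allometric_power", 14, 0.75)
    ),
    omega = omega, residual = residual, drug = "amikacin")
}

#' Individualize a population model
#'
#' Applies covariate effects and log-normal random effects to the typical
#' values: `P_i = TVP(cov) * exp(eta_P)` for parameters with IIV,
#' `P_i = TVP(cov)` otherwise. Deterministic in all inputs.
#'
#' @param model A [pk_model()].
#' @param cov A [patient_covariates()] object.
#' @param eta Numeric vector of log-scale deviations; its length must equal
#'   the dimension of the model's omega matrix. Defaults to 0 (the typical
#'   subject, i.e. the a priori case).
#' @return An object of class `individual_parameters`: list with `eta` and
#'   `values` (named list of strictly positive individual parameters).
#' @examples
#' m <- pk_model_vancomycin()
#' cov <- patient_covariates(38.6, 14, 0.40)
#' individualize(m, cov)$values
#' @export
individualize <- function(model, cov, eta = NULL) {
  k <- nrow(model$omega)
  if (is.null(eta)) eta <- rep(0, k)
  if (length(eta) != k)
    stop("eta has length ", length(eta), " but omega dimension is ", k,
         call. = FALSE)
  if (!inherits(cov, "patient_covariates"))
    stop("cov must be a patient_covariates object", call. = FALSE)
  eta <- as.numeric(eta)
  names(eta) <- rownames(model$omega)
  values <- model$typical_values
  for (ef in model$covariate_effects)
    values[[ef$parameter]] <- values[[ef$parameter]] * effect_multiplier(ef, cov)
  for (p in names(eta))
    values[[p]] <- values[[p]] * exp(eta[[p]])
  v <- unlist(values)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("individualized parameters must be strictly positive", call. = FALSE)
  structure(list(eta = eta, values = values),
            class = "individual_parameters")
}
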