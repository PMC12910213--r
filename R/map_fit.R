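#' Control parameters for MAP estimation
#'
#' @param reltol Relative convergence tolerance on the objective passed to
#'   the quasi-Newton optimizer.
#' @param maxit Maximum iterations.
#' @param blq Handling of observations flagged below the limit of
#'   quantification: `"exclude"` drops them from the objective (default),
#'   `"loq2"` substitutes `loq / 2`.
#' @param loq Limit of quantification in mg/L, used by `blq = "loq2"`.
#' @param keep_log_sigma Keep the `log(sigma^2)` term in the objective. It
#'   matters whenever the residual variance depends on the prediction through
#'   the proportional component; many MAP implementations drop it, so it is
#'   exposed explicitly.
#' @return A list of class `map_control`.
#' @export
map_control <- function(reltol = 1e-10, maxit = 500,
                        blq = c("exclude", "loq2"), loq = 0.5,
                        keep_log_sigma = TRUE) {
  structure(list(reltol = reltol, maxit = maxit, blq = match.arg(blq),
                 loq = loq, keep_log_sigma = keep_log_sigma),
            class = "map_control")
}

# observations as used in the objective, after BLQ policy
effective_obs <- function(obs, control) {
  if (is.null(obs) || nrow(obs) == 0L) return(obs[0, , drop = FALSE])
  if (control$blq == "exclude") {
    obs[!obs$below_loq, , drop = FALSE]
  } else {
    obs$concentration_mg_L[obs$below_loq] <- control$loq / 2
    obs
  }
}

#' MAP objective: -2 log-posterior (up to a constant)
#'
#' The estimation objective minimized by [map_fit()]:
#' \deqn{\sum_i \left[ \frac{(c_{obs,i} - c_{pred,i}(\eta))^2}{\sigma_i^2}
#'   + \log \sigma_i^2 \right] + \eta^T \Omega^{-1} \eta}
#' with \eqn{\sigma_i^2 = \sigma_{add}^2 + (\sigma_{prop} c_{pred,i})^2}.
#' With no observations this reduces to the prior quadratic form, and it is 0
#' at `eta = 0`.
#'
#' @param eta Numeric vector, length equal to the omega dimension.
#' @param model,cov,regimen As in [map_fit()].
#' @param obs A [observations()] data frame (may be empty).
#' @param control A [map_control()] list.
#' @return A single number; deterministic in all inputs.
#' @export
neg2_log_posterior <- function(eta, model, cov, regimen, obs = NULL,
                               control = map_control()) {
  omega <- model$omega
  if (length(eta) != nrow(omega))
    stop("eta length must equal the omega dimension", call. = FALSE)
  oinv <- tryCatch(solve(omega), error = function(e)
    stop("omega is singular; cannot form the prior term", call. = FALSE))
  # extreme trial points from line searches: a large finite value keeps the
  # optimizer inside the sane region without aborting the fit
  if (any(!is.finite(eta)) || any(abs(eta) > 50)) return(1e12)
  val <- drop(t(eta) %*% oinv %*% eta)
  obs <- effective_obs(obs, control)
  if (!is.null(obs) && nrow(obs) > 0L) {
    params <- individualize(model, cov, eta)
    pred <- predict_concentration(params, model, regimen, obs$time_h)
    s2 <- model$residual$sigma_add^2 + (model$residual$sigma_prop * pred)^2
    if (any(!is.finite(s2))) return(1e12)
    if (any(s2 <= 0))
      stop("zero predicted concentration with proportional-only residual ",
           "error: observation variance undefined", call. = FALSE)
    val <- val + sum((obs$concentration_mg_L - pred)^2 / s2)
    if (control$keep_log_sigma) val <- val + sum(log(s2))
  }
  val
}

#' MAP Bayesian estimation of individual PK parameters
#'
#' Fits the individual random effects eta by maximum a posteriori (MAP)
#' estimation: the population model supplies an informative log-normal prior
#' (`eta ~ N(0, Omega)`), the observed TDM concentrations enter through the
#' combined residual-error likelihood, and the mode is located with a
#' quasi-Newton (BFGS) search started at `eta = 0`. With no usable
#' observations the prior mode `eta = 0` is returned exactly — this is the a
#' priori case. The fitted object supports the usual modelling methods
#' (`print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
#' `simulate`, `logLik`).
#'
#' @param model A [pk_model()].
#' @param cov A [patient_covariates()] object.
#' @param regimen A [regimen()] object (the administered dosing history).
#' @param obs A [observations()] data frame; may be empty or `NULL`.
#' @param control A [map_control()] list.
#' @return An object of class `mipd_fit` with components `eta_map`,
#'   `objective_value`, `converged`, `params` (individualized parameters at
#'   the mode), `n_obs_used`, and the inputs.
#' @examples
#' m <- pk_model_vancomycin()
#' cov <- patient_covariates(38.6, 14, 0.4)
#' reg <- regimen(210, 6, 1, n_doses = 4)
#' obs <- observations(18, 9.5)
#' fit <- map_fit(m, cov, reg, obs)
#' coef(fit)
#' @export
map_fit <- function(model, cov, regimen, obs = NULL, control = map_control()) {
  if (is.null(obs)) obs <- empty_observations()
  k <- nrow(model$omega)
  used <- effective_obs(obs, control)
  obj <- function(eta) neg2_log_posterior(eta, model, cov, regimen, obs,
                                          control)
  obj0 <- obj(rep(0, k))  # 0 unless observations contribute

  if (nrow(used) == 0L) {
    eta_map <- rep(0, k)
    res <- list(value = obj0, convergence = 0L)
  } else {
    res <- stats::optim(rep(0, k), obj, method = "BFGS",
                        control = list(reltol = control$reltol,
                                       maxit = control$maxit))
    eta_map <- res$par
    if (res$value > obj0) {  # never accept a point worse than the start
      eta_map <- rep(0, k)
      res$value <- obj0
      res$convergence <- 1L
    }
  }
  # convergence check: optimizer status plus a finite-difference gradient norm
  gnorm <- max(abs(numeric_gradient(obj, eta_map)))
  converged <- res$convergence == 0L && gnorm < 1e-3 * (1 + abs(res$value))
  params <- individualize(model, cov, eta_map)
  structure(list(eta_map = stats::setNames(eta_map, rownames(model$omega)),
                 objective_value = res$value, converged = converged,
                 params = params, n_obs_used = nrow(used),
                 model = model, cov = cov, regimen = regimen, obs = obs,
                 control = control),
            class = "mipd_fit")
}

numeric_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
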