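# S3 methods for the fitted MAP object.

#' @export
print.mipd_fit <- function(x, ...) {
  cat("MAP Bayesian fit (", x$model$drug, ", ",
      sub("_iv_infusion", "", x$model$structure), ")\n", sep = "")
  cat("  observations used:", x$n_obs_used,
      if (x$n_obs_used == 0L) "(a priori: prior mode eta = 0)", "\n")
  cat("  eta_MAP: ",
      paste(names(x$eta_map), signif(x$eta_map, 4), sep = " = ",
            collapse = ", "), "\n", sep = "")
  cat("  individual parameters: ",
      paste(names(x$params$values), signif(unlist(x$params$values), 4),
            sep = " = ", collapse = ", "), "\n", sep = "")
  cat("  -2 log-posterior:", signif(x$objective_value, 6),
      if (!x$converged) " (NOT converged)", "\n")
  invisible(x)
}

#' Extract coefficients from a MAP fit
#'
#' @param object A `mipd_fit`.
#' @param type `"parameters"` returns the individualized PK parameters;
#'   `"eta"` returns the log-scale random-effect estimates.
#' @param ... Unused.
#' @export
coef.mipd_fit <- function(object, type = c("parameters", "eta"), ...) {
  type <- match.arg(type)
  if (type == "eta") object$eta_map
  else unlist(object$params$values)
}

#' Predict concentrations from a MAP fit
#'
#' @param object A `mipd_fit`.
#' @param times Times in hours from the regimen origin; defaults to the
#'   observation times.
#' @param mode `"a_posteriori"` uses the MAP individual parameters;
#'   `"a_priori"` uses eta = 0 (covariates and dosing only). The a posteriori
#'   mode requires that the fit used at least one observation.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations, mg/L.
#' @export
predict.mipd_fit <- function(object, times = NULL,
                             mode = c("a_posteriori", "a_priori"), ...) {
  mode <- match.arg(mode)
  if (is.null(times)) times <- object$obs$time_h
  if (mode == "a_posteriori" && object$n_obs_used == 0L && nrow(object$obs) == 0L)
    stop("a posteriori prediction requires observations", call. = FALSE)
  params <- if (mode == "a_priori") individualize(object$model, object$cov)
            else object$params
  predict_concentration(params, object$model, object$regimen, times)
}

#' @export
fitted.mipd_fit <- function(object, ...) {
  predict(object, mode = "a_posteriori")
}

#' Residuals of a MAP fit
#'
#' @param object A `mipd_fit`.
#' @param type `"response"` gives observed minus predicted;
#'   `"standardized"` divides by the residual standard deviation
#'   `sqrt(sigma_add^2 + (sigma_prop * pred)^2)`.
#' @param ... Unused.
#' @export
residuals.mipd_fit <- function(object, type = c("response", "standardized"),
                               ...) {
  type <- match.arg(type)
  pred <- fitted(object)
  r <- object$obs$concentration_mg_L - pred
  if (type == "standardized") {
    s <- sqrt(object$model$residual$sigma_add^2 +
                (object$model$residual$sigma_prop * pred)^2)
    r <- r / s
  }
  r
}

#' @export
logLik.mipd_fit <- function(object, ...) {
  # -objective/2 up to the usual additive constant
  structure(-object$objective_value / 2, df = length(object$eta_map),
            class = "logLik")
}

#' @export
summary.mipd_fit <- function(object, ...) {
  n_eta <- length(object$eta_map)
  shrink <- 1 - abs(object$eta_map) / sqrt(diag(object$model$omega))
  out <- list(fit = object,
              table = data.frame(
                parameter = names(object$eta_map),
                eta_map = as.numeric(object$eta_map),
                omega_sd = sqrt(diag(object$model$omega)),
                individual = unlist(object$params$values)[names(object$eta_map)],
                row.names = NULL),
              residuals = if (nrow(object$obs)) residuals(object) else numeric(0))
  class(out) <- "summary.mipd_fit"
  out
}

#' @export
print.summary.mipd_fit <- function(x, ...) {
  print(x$fit)
  cat("\nRandom effects:\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (length(x$residuals)) {
    cat("\nResiduals (observed - a posteriori predicted, mg/L):\n")
    print(summary(x$residuals))
  }
  invisible(x)
}

#' Plot a MAP fit
#'
#' Concentration-time profile under the administered regimen: a priori
#' (population, eta = 0) and a posteriori (MAP) curves with the observed
#' concentrations overlaid.
#'
#' @param x A `mipd_fit`.
#' @param n_grid Number of time points on the curve.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mipd_fit <- function(x, n_grid = 400, ...) {
  ev <- as.data.frame(x$regimen)
  t_end <- max(ev$start_time_h + ev$infusion_duration_h) +
    if (nrow(ev) > 1) diff(ev$start_time_h[1:2]) else 12
  tt <- seq(0, max(t_end, max(x$obs$time_h, 0)), length.out = n_grid)
  prior <- predict(x, tt, mode = "a_priori")
  post <- predict(x, tt, mode = "a_posteriori")
  graphics::plot(tt, prior, type = "l", lty = 2, col = "grey40",
                 xlab = "Time (h)", ylab = "Concentration (mg/L)",
                 ylim = range(0, prior, post, x$obs$concentration_mg_L), ...)
  graphics::lines(tt, post, col = "firebrick")
  if (nrow(x$obs))
    graphics::points(x$obs$time_h, x$obs$concentration_mg_L, pch = 19)
  graphics::legend("topright", bty = "n", lty = c(2, 1, NA),
                   pch = c(NA, NA, 19),
                   col = c("grey40", "firebrick", "black"),
                   legend = c("a priori", "a posteriori (MAP)", "observed"))
  invisible(x)
}

#' Simulate observations from a MAP fit
#'
#' Draws new noisy observations at the fit's observation times (or `times`)
#' from the individualized model plus the combined residual-error model.
#'
#' @param object A `mipd_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param times Sampling times; defaults to the observation times.
#' @param ... Unused.
#' @return A data frame with one column per replicate (`sim_1`, ...).
#' @export
simulate.mipd_fit <- function(object, nsim = 1, seed = NULL, times = NULL,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(times)) times <- object$obs$time_h
  pred <- predict(object, times, mode = "a_posteriori")
  s <- sqrt(object$model$residual$sigma_add^2 +
              (object$model$residual$sigma_prop * pred)^2)
  out <- as.data.frame(lapply(seq_len(nsim), function(i)
    pmax(pred + stats::rnorm(length(pred), 0, s), 0)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
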