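#' Prediction-error metrics
#'
#' Summarizes predicted-minus-observed concentration errors with the mean
#' absolute error (MAE), median absolute error (MdAE) and signed median error
#' (MdE):
#' \deqn{MAE = \frac{1}{n}\sum_i |p_i - o_i|, \quad
#'       MdAE = median\,|p_i - o_i|, \quad MdE = median\,(p_i - o_i)}
#' The median of an even count is the midpoint of the two central order
#' statistics. MdAE is the usual primary summary because it is robust to
#' outliers; MdE retains the sign and so indicates directional bias.
#'
#' @param predicted,observed Numeric vectors of equal, positive length
#'   (mg/L).
#' @return An object of class `error_summary`: `n`, `mae`, `mdae`, `mde`.
#' @examples
#' error_metrics(predicted = c(10, 12), observed = c(8, 16))
#' @export
error_metrics <- function(predicted, observed) {
  if (length(predicted) == 0L)
    stop("error_metrics requires at least one pair", call. = FALSE)
  if (length(predicted) != length(observed))
    stop("predicted and observed lengths differ", call. = FALSE)
  e <- predicted - observed
  structure(list(n = length(e), mae = mean(abs(e)),
                 mdae = stats::median(abs(e)), mde = stats::median(e)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("n = %d  MAE = %.3f  MdAE = %.3f  MdE = %.3f (mg/L)\n",
              x$n, x$mae, x$mdae, x$mde))
  invisible(x)
}

#' Classify model fit from one observation
#'
#' Relative-error classification of the agreement between an observed and a
#' model-predicted concentration: `good` if
#' `|predicted - observed| / observed <= thresholds[1]`, `intermediate` if
#' `<= thresholds[2]`, otherwise `poor`. The default cutoffs (20% / 50%) are
#' a package convention exposed for configuration; commercial forecasting
#' platforms do not publish theirs. When the observed value is 0 the relative
#' error is undefined and the classification falls back to the absolute
#' difference against `abs_thresholds` (mg/L).
#'
#' @param observed,predicted Non-negative concentrations, mg/L.
#' @param thresholds Length-2 increasing relative-error cutoffs.
#' @param abs_thresholds Length-2 increasing absolute-difference cutoffs used
#'   only when `observed == 0`.
#' @return A list of class `fit_category`: `label` and `relative_error`
#'   (`NA` under the absolute fallback).
#' @examples
#' classify_fit(observed = 10, predicted = 12.5)
#' @export
classify_fit <- function(observed, predicted, thresholds = c(0.20, 0.50),
                         abs_thresholds = c(1, 3)) {
  if (!is.finite(observed) || !is.finite(predicted) || observed < 0 ||
      predicted < 0)
    stop("observed and predicted must be finite and >= 0", call. = FALSE)
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2])
    stop("thresholds must be increasing (t1 < t2)", call. = FALSE)
  if (observed > 0) {
    rel <- abs(predicted - observed) / observed
    label <- if (rel <= thresholds[1]) "good"
             else if (rel <= thresholds[2]) "intermediate" else "poor"
  } else {
    rel <- NA_real_
    d <- abs(predicted - observed)
    label <- if (d <= abs_thresholds[1]) "good"
             else if (d <= abs_thresholds[2]) "intermediate" else "poor"
  }
  structure(list(label = label, relative_error = rel), class = "fit_category")
}

#' Paired a priori vs a posteriori evaluation table
#'
#' Aggregates paired within-patient prediction errors into the stratified
#' summary layout of the study's predictive-performance table: for each
#' timepoint and prediction type (a priori / a posteriori), one `Total` row
#' plus one row per level of each requested stratification key.
#'
#' @param pairs A data frame with columns `observed`, `predicted_a_priori`,
#'   `predicted_a_posteriori`, `timepoint_index`, plus any stratification
#'   columns (typically `group` and `drug`).
#' @param strata Character vector of column names to stratify by.
#' @return A data frame with columns `timepoint`, `prediction`, `stratum`,
#'   `level`, `n`, `mae`, `mdae`, `mde`.
#' @export
paired_evaluation <- function(pairs, strata = c("group", "drug")) {
  need <- c("observed", "predicted_a_priori", "predicted_a_posteriori",
            "timepoint_index")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop("pairs is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(strata, names(pairs))
  if (length(bad))
    stop("unknown stratum key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  rows <- list()
  add_row <- function(tp, prediction, stratum, level, sub) {
    pred <- if (prediction == "a_priori") sub$predicted_a_priori
            else sub$predicted_a_posteriori
    em <- error_metrics(pred, sub$observed)
    rows[[length(rows) + 1L]] <<- data.frame(
      timepoint = tp, prediction = prediction, stratum = stratum,
      level = level, n = em$n, mae = em$mae, mdae = em$mdae, mde = em$mde)
  }
  for (tp in sort(unique(pairs$timepoint_index))) {
    sub_tp <- pairs[pairs$timepoint_index == tp, , drop = FALSE]
    for (prediction in c("a_priori", "a_posteriori")) {
      add_row(tp, prediction, "total", "total", sub_tp)
      for (key in strata) {
        for (lev in sort(unique(as.character(sub_tp[[key]])))) {
          sub <- sub_tp[sub_tp[[key]] == lev, , drop = FALSE]
          if (nrow(sub)) add_row(tp, prediction, key, lev, sub)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Percentile bootstrap intervals for error metrics
#'
#' Exploratory percentile bootstrap confidence intervals for MAE, MdAE and
#' MdE. Resampling uses the current RNG state; set a seed for
#' reproducibility. These intervals are descriptive and are never used as a
#' pass/fail device.
#'
#' @param predicted,observed Paired numeric vectors.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param conf Confidence level.
#' @return A data frame with rows `mae`, `mdae`, `mde` and columns
#'   `estimate`, `lower`, `upper`.
#' @export
boot_error_ci <- function(predicted, observed, n_boot = 2000, conf = 0.95) {
  est <- error_metrics(predicted, observed)
  n <- length(predicted)
  stat <- matrix(NA_real_, n_boot, 3)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    em <- error_metrics(predicted[idx], observed[idx])
    stat[b, ] <- c(em$mae, em$mdae, em$mde)
  }
  a <- (1 - conf) / 2
  q <- apply(stat, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(metric = c("mae", "mdae", "mde"),
             estimate = c(est$mae, est$mdae, est$mde),
             lower = q[1, ], upper = q[2, ])
}
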