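#' PK/PD target specification
#'
#' At least one criterion must be present. The vancomycin convention targets
#' steady-state AUC24/MIC with the trough band as a supportive (advisory)
#' range; the amikacin convention targets Cmax/MIC with a trough ceiling.
#'
#' @param drug `"vancomycin"` or `"amikacin"`.
#' @param auc_over_mic_min Minimum AUC24/MIC, or `NULL`.
#' @param trough_band_mg_L Length-2 numeric `(low, high)` trough band, or
#'   `NULL`.
#' @param cmax_over_mic_min Minimum Cmax/MIC, or `NULL`.
#' @param trough_max_mg_L Maximum trough, or `NULL`.
#' @param mic_mg_L Assumed MIC, default 1 mg/L (a standardization convention,
#'   not a clinical breakpoint).
#' @param trough_band_hard Whether the trough band is a hard feasibility
#'   constraint (`TRUE`) or advisory only (`FALSE`, default).
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(drug = c("vancomycin", "amikacin"),
                        auc_over_mic_min = NULL, trough_band_mg_L = NULL,
                        cmax_over_mic_min = NULL, trough_max_mg_L = NULL,
                        mic_mg_L = 1, trough_band_hard = FALSE) {
  drug <- match.arg(drug)
  if (is.null(auc_over_mic_min) && is.null(trough_band_mg_L) &&
      is.null(cmax_over_mic_min) && is.null(trough_max_mg_L))
    stop("a target_spec needs at least one criterion", call. = FALSE)
  if (!is.null(trough_band_mg_L)) {
    if (length(trough_band_mg_L) != 2L ||
        trough_band_mg_L[1] >= trough_band_mg_L[2])
      stop("trough_band_mg_L must be (low, high) with low < high",
           call. = FALSE)
  }
  if (mic_mg_L <= 0) stop("mic_mg_L must be > 0", call. = FALSE)
  structure(list(drug = drug, auc_over_mic_min = auc_over_mic_min,
                 trough_band_mg_L = trough_band_mg_L,
                 cmax_over_mic_min = cmax_over_mic_min,
                 trough_max_mg_L = trough_max_mg_L, mic_mg_L = mic_mg_L,
                 trough_band_hard = trough_band_hard),
            class = "target_spec")
}

#' @rdname target_spec
#' @export
vancomycin_target <- function(mic_mg_L = 1, trough_band_hard = FALSE) {
  target_spec("vancomycin", auc_over_mic_min = 400,
              trough_band_mg_L = c(10, 15), mic_mg_L = mic_mg_L,
              trough_band_hard = trough_band_hard)
}

#' @rdname target_spec
#' @export
amikacin_target <- function(mic_mg_L = 1) {
  target_spec("amikacin", cmax_over_mic_min = 8, trough_max_mg_L = 5,
              mic_mg_L = mic_mg_L)
}

#' Steady-state exposure metrics
#'
#' Computes the model-derived exposure metrics for one steady-state dosing
#' interval: AUC24 from the analytic linear-PK identity
#' `AUC24 = daily dose / CL`, Cmax at the end of infusion (standard
#' convention; `peak_delay_h` shifts it later for post-distribution
#' two-compartment peaks), trough immediately pre-dose, and the percent of
#' the interval spent above the MIC by bracketed root finding on the
#' steady-state profile.
#'
#' @param params An `individual_parameters` object.
#' @param model The matching [pk_model()].
#' @param dose_mg Dose per administration, mg.
#' @param interval_h Dosing interval, h (> infusion duration).
#' @param infusion_duration_h Infusion duration, h.
#' @param mic MIC in mg/L.
#' @param peak_delay_h Time after end of infusion at which Cmax is read.
#' @return An object of class `exposure_metrics`: `auc24`, `cmax`, `trough`,
#'   `auc_over_mic`, `cmax_over_mic`, `ft_above_mic_pct`.
#' @export
steady_state_metrics <- function(params, model, dose_mg, interval_h,
                                 infusion_duration_h = 1, mic = 1,
                                 peak_delay_h = 0) {
  if (!is.finite(interval_h) || interval_h <= 0)
    stop("interval_h must be positive", call. = FALSE)
  if (interval_h <= infusion_duration_h)
    stop("interval_h must exceed infusion_duration_h", call. = FALSE)
  CL <- params$values$CL
  auc24 <- dose_mg * (24 / interval_h) / CL
  css <- function(t) steady_state_conc(params, model, dose_mg, interval_h,
                                       infusion_duration_h, t)
  cmax <- css(min(infusion_duration_h + peak_delay_h, interval_h))
  trough <- css(interval_h)
  ft <- ft_above_mic(css, interval_h, mic)
  structure(list(auc24 = auc24, cmax = cmax, trough = trough,
                 auc_over_mic = auc24 / mic, cmax_over_mic = cmax / mic,
                 ft_above_mic_pct = ft),
            class = "exposure_metrics")
}

#' @export
print.exposure_metrics <- function(x, ...) {
  cat(sprintf(paste0("Steady-state exposure: AUC24 = %.1f mg*h/L, ",
                     "Cmax = %.2f mg/L, trough = %.2f mg/L\n"),
              x$auc24, x$cmax, x$trough))
  cat(sprintf("  AUC/MIC = %.1f, Cmax/MIC = %.2f, %%fT>MIC = %.1f%%\n",
              x$auc_over_mic, x$cmax_over_mic, x$ft_above_mic_pct))
  invisible(x)
}

# percent of the interval with concentration above MIC, via a coarse grid to
# bracket crossings and uniroot to refine them
ft_above_mic <- function(css, interval_h, mic) {
  tt <- seq(0, interval_h, length.out = 201)
  cc <- css(tt)
  above <- cc > mic
  if (all(above)) return(100)
  if (!any(above)) return(0)
  f <- function(t) css(t) - mic
  time_above <- 0
  for (i in seq_len(length(tt) - 1L)) {
    if (above[i] && above[i + 1L]) {
      time_above <- time_above + (tt[i + 1L] - tt[i])
    } else if (xor(above[i], above[i + 1L])) {
      root <- stats::uniroot(f, c(tt[i], tt[i + 1L]), tol = 1e-9)$root
      time_above <- time_above +
        if (above[i]) root - tt[i] else tt[i + 1L] - root
    }
  }
  100 * time_above / interval_h
}

#' Dose-search constraints
#'
#' Candidate grids and pediatric safety caps for [recommend_dose()]. The
#' default caps are placeholders for testing, not clinical limits.
#'
#' @param weight_kg Patient weight, used for per-kg caps.
#' @param intervals_h Candidate dosing intervals, h.
#' @param infusion_duration_h Infusion duration, h.
#' @param max_mg_kg_day Per-kg daily cap, mg/kg/day.
#' @param max_mg_day Absolute daily cap, mg/day.
#' @param increment_mg Dose rounding increment; `NULL` picks 10 mg for doses
#'   >= 100 mg and 1 mg below.
#' @return A list of class `dose_constraints`.
#' @export
dose_constraints <- function(weight_kg, intervals_h = NULL,
                             infusion_duration_h = 1, max_mg_kg_day = NULL,
                             max_mg_day = Inf, increment_mg = NULL) {
  structure(list(weight_kg = weight_kg, intervals_h = intervals_h,
                 infusion_duration_h = infusion_duration_h,
                 max_mg_kg_day = max_mg_kg_day, max_mg_day = max_mg_day,
                 increment_mg = increment_mg),
            class = "dose_constraints")
}

default_constraints <- function(drug, weight_kg) {
  if (drug == "vancomycin")
    dose_constraints(weight_kg, intervals_h = c(4, 6, 8, 12, 24),
                     max_mg_kg_day = 80, max_mg_day = 4000)
  else
    dose_constraints(weight_kg, intervals_h = c(24, 36, 48),
                     max_mg_kg_day = 30, max_mg_day = Inf)
}

round_to_increment <- function(dose) {
  inc <- ifelse(dose >= 100, 10, 1)
  pmax(round(dose / inc) * inc, 1)
}

#' Recommend a dose meeting PK/PD targets
#'
#' Grid search over candidate (dose, interval) pairs against a
#' [target_spec()], with pediatric safety caps enforced before feasibility
#' evaluation. Among feasible candidates the smallest total daily dose wins,
#' ties broken in favour of the longer interval. If no candidate is feasible
#' the least-deficient candidate is returned with `feasible = FALSE` (the
#' deficiency score is the summed relative shortfall/excess over the active
#' criteria). `capped = TRUE` flags that the safety caps removed candidates
#' that would otherwise have improved the recommendation.
#'
#' @param model A [pk_model()].
#' @param cov A [patient_covariates()] object.
#' @param eta Individual random effects (e.g. `coef(fit, "eta")` from a MAP
#'   fit); defaults to 0.
#' @param target A [target_spec()].
#' @param constraints A [dose_constraints()] list; defaults to the drug's
#'   built-in grid and caps with the patient's weight.
#' @return An object of class `dose_recommendation`: `dose_mg`, `interval_h`,
#'   `infusion_duration_h`, `daily_dose_mg`, `predicted`
#'   ([steady_state_metrics()] at the recommendation), `feasible`, `capped`.
#' @export
recommend_dose <- function(model, cov, eta = NULL, target, constraints = NULL) {
  if (is.null(constraints))
    constraints <- default_constraints(model$drug, cov$weight_kg)
  params <- individualize(model, cov, eta)
  cap_daily <- min(constraints$max_mg_day,
                   if (is.null(constraints$max_mg_kg_day)) Inf
                   else constraints$max_mg_kg_day * constraints$weight_kg)
  tinf <- constraints$infusion_duration_h
  pick <- search_grid(params, model, target, constraints, cap_daily)
  # caps are binding if the uncapped grid would have found a feasible
  # candidate that the caps excluded
  capped <- FALSE
  if (!pick$feasible && is.finite(cap_daily)) {
    unc <- search_grid(params, model, target, constraints, Inf,
                       max_daily_hint = max(50 * cap_daily, 2 * pick$daily))
    capped <- unc$feasible
  }
  m <- steady_state_metrics(params, model, pick$dose, pick$interval, tinf,
                            target$mic_mg_L)
  structure(list(dose_mg = pick$dose, interval_h = pick$interval,
                 infusion_duration_h = tinf,
                 daily_dose_mg = pick$daily, predicted = m,
                 feasible = pick$feasible, capped = capped,
                 target = target),
            class = "dose_recommendation")
}

# Evaluate the whole candidate grid. Linear PK makes cmax and trough
# proportional to dose for a fixed interval, so one unit-dose profile per
# interval prices every candidate; AUC24 is the analytic identity.
search_grid <- function(params, model, target, constraints, cap_daily,
                        max_daily_hint = NULL) {
  cand <- candidate_grid(constraints, cap_daily, max_daily_hint)
  if (nrow(cand) == 0L)
    stop("empty candidate grid: caps exclude every dose", call. = FALSE)
  tinf <- constraints$infusion_duration_h
  CL <- params$values$CL
  unit <- lapply(unique(cand$interval), function(tau) {
    list(interval = tau,
         cmax = steady_state_conc(params, model, 1, tau, tinf, tinf),
         trough = steady_state_conc(params, model, 1, tau, tinf, tau))
  })
  names(unit) <- as.character(unique(cand$interval))
  u <- unit[as.character(cand$interval)]
  cmax <- cand$dose * vapply(u, `[[`, numeric(1), "cmax")
  trough <- cand$dose * vapply(u, `[[`, numeric(1), "trough")
  daily <- cand$dose * 24 / cand$interval
  auc <- daily / CL
  mic <- target$mic_mg_L
  feasible <- rep(TRUE, nrow(cand))
  score <- rep(0, nrow(cand))
  if (!is.null(target$auc_over_mic_min)) {
    feasible <- feasible & auc / mic >= target$auc_over_mic_min
    score <- score + pmax(0, (target$auc_over_mic_min - auc / mic) /
                               target$auc_over_mic_min)
  }
  if (!is.null(target$cmax_over_mic_min)) {
    feasible <- feasible & cmax / mic >= target$cmax_over_mic_min
    score <- score + pmax(0, (target$cmax_over_mic_min - cmax / mic) /
                               target$cmax_over_mic_min)
  }
  if (!is.null(target$trough_max_mg_L)) {
    feasible <- feasible & trough < target$trough_max_mg_L
    score <- score + pmax(0, (trough - target$trough_max_mg_L) /
                               target$trough_max_mg_L)
  }
  if (!is.null(target$trough_band_mg_L) && isTRUE(target$trough_band_hard)) {
    lo <- target$trough_band_mg_L[1]; hi <- target$trough_band_mg_L[2]
    feasible <- feasible & trough >= lo & trough <= hi
    score <- score + pmax(0, (lo - trough) / lo) +
      pmax(0, (trough - hi) / hi)
  }
  if (any(feasible)) {
    idx <- which(feasible)
    o <- idx[order(daily[idx], -cand$interval[idx])][1L]
    list(dose = cand$dose[o], interval = cand$interval[o], daily = daily[o],
         feasible = TRUE)
  } else {
    o <- order(score, daily)[1L]
    list(dose = cand$dose[o], interval = cand$interval[o], daily = daily[o],
         feasible = FALSE)
  }
}

candidate_grid <- function(constraints, cap_daily, max_daily_hint = NULL) {
  if (is.null(constraints$intervals_h))
    stop("constraints must provide candidate intervals", call. = FALSE)
  lim <- if (is.finite(cap_daily)) cap_daily else
    if (!is.null(max_daily_hint)) max_daily_hint else 6000
  out <- list()
  for (tau in constraints$intervals_h) {
    if (tau <= constraints$infusion_duration_h) next
    max_dose <- lim * tau / 24
    inc <- constraints$increment_mg
    doses <- if (is.null(inc)) {
      c(seq(1, min(99, max_dose), by = 1),
        if (max_dose >= 100) seq(100, max_dose, by = 10))
    } else {
      seq(inc, max_dose, by = inc)
    }
    if (length(doses))
      out[[length(out) + 1L]] <- data.frame(dose = doses, interval = tau)
  }
  if (length(out) == 0L) return(data.frame(dose = numeric(0),
                                           interval = numeric(0)))
  do.call(rbind, out)
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf("Dose recommendation: %g mg q%gh (%.0f mg/day)%s%s\n",
              x$dose_mg, x$interval_h, x$daily_dose_mg,
              if (x$feasible) "" else "  [target NOT attainable on grid]",
              if (x$capped) "  [safety cap binding]" else ""))
  print(x$predicted)
  invisible(x)
}

#' Trough-guided standard-of-care dose adjustment
#'
#' The comparator-arm rule: a trough below the band scales the total daily
#' dose up proportionally by (band midpoint / observed trough); a trough
#' above the band scales it down by the same rule, and a trough more than
#' twice the band's upper bound additionally extends the dosing interval to
#' the next candidate. In-band troughs leave the regimen unchanged. The
#' scaling factor is capped (default 3x) so a zero or near-zero trough cannot
#' explode the dose; the cap is flagged in the result.
#'
#' @param dose_mg,interval_h Current regimen.
#' @param trough_obs Observed trough, mg/L (>= 0).
#' @param target A [target_spec()] with a trough band.
#' @param increment_mg Rounding increment for the adjusted dose (default 5).
#' @param intervals_h Ordered candidate intervals used when extending.
#' @param max_factor Cap on the proportional scaling factor.
#' @return A list: `dose_mg`, `interval_h`, `changed`, `factor_capped`.
#' @examples
#' soc_adjust(250, 6, trough_obs = 5, target = vancomycin_target())
#' @export
soc_adjust <- function(dose_mg, interval_h, trough_obs, target,
                       increment_mg = 5,
                       intervals_h = c(4, 6, 8, 12, 24, 36, 48),
                       max_factor = 3) {
  if (is.null(target$trough_band_mg_L))
    stop("soc_adjust requires a target with a trough band", call. = FALSE)
  if (!is.finite(trough_obs) || trough_obs < 0)
    stop("trough_obs must be >= 0", call. = FALSE)
  lo <- target$trough_band_mg_L[1]; hi <- target$trough_band_mg_L[2]
  mid <- (lo + hi) / 2
  if (trough_obs >= lo && trough_obs <= hi)
    return(list(dose_mg = dose_mg, interval_h = interval_h, changed = FALSE,
                factor_capped = FALSE))
  factor <- if (trough_obs > 0) mid / trough_obs else Inf
  capped <- factor > max_factor
  factor <- min(factor, max_factor)
  new_dose <- max(round(dose_mg * factor / increment_mg) * increment_mg,
                  increment_mg)
  new_interval <- interval_h
  if (trough_obs > 2 * hi) {
    nxt <- intervals_h[intervals_h > interval_h]
    if (length(nxt)) new_interval <- min(nxt)
  }
  list(dose_mg = new_dose, interval_h = new_interval, changed = TRUE,
       factor_capped = capped)
}
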