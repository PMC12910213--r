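#' Configuration of the synthetic PICU cohort
#'
#' Defines the virtual-patient generator. The defaults emulate the study
#' conditions: 41 patients with median (IQR) age 38.6 (81.7) months, 56.1%
#' female, 23/41 on vancomycin, a 12/41 model-informed (MIPD) arm, and a
#' second TDM sample in 15/41 of patients. Ages are drawn from a log-normal
#' calibrated to the configured median and IQR and clamped to 1--216 months;
#' weight follows the transparent pediatric approximation
#' `(age_years + 4) * 2` kg with multiplicative log-normal scatter; serum
#' creatinine is an age-dependent log-normal. These generators are documented
#' toys, not growth or renal standards.
#'
#' @param n Number of virtual patients.
#' @param seed Master seed; every stream in the simulation derives from it.
#' @param drug_mix_vancomycin Probability a patient receives vancomycin.
#' @param mipd_fraction Probability of assignment to the MIPD arm.
#' @param second_sample_prob Probability a second TDM sample exists.
#' @param age_median_months,age_iqr_months Age distribution calibration.
#' @param female_fraction Bernoulli probability of female sex.
#' @param weight_cv Log-normal coefficient of variation of weight scatter.
#' @param scr_base,scr_slope_per_year,scr_sdlog Serum-creatinine generator:
#'   median `scr_base + scr_slope_per_year * age_years` mg/dL with log-scale
#'   SD `scr_sdlog`.
#' @param initial_mg_kg Named initial doses, mg/kg per administration.
#' @param initial_interval_h Named initial dosing intervals, h.
#' @param infusion_duration_h Infusion duration, h.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 41, seed = 1,
                          drug_mix_vancomycin = 23 / 41,
                          mipd_fraction = 12 / 41,
                          second_sample_prob = 15 / 41,
                          age_median_months = 38.6, age_iqr_months = 81.7,
                          female_fraction = 0.561, weight_cv = 0.15,
                          scr_base = 0.25, scr_slope_per_year = 0.04,
                          scr_sdlog = 0.35,
                          initial_mg_kg = c(vancomycin = 15, amikacin = 15),
                          initial_interval_h = c(vancomycin = 6,
                                                 amikacin = 24),
                          infusion_duration_h = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  for (p in c(drug_mix_vancomycin, mipd_fraction, second_sample_prob,
              female_fraction))
    if (p < 0 || p > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (age_median_months <= 0 || age_iqr_months <= 0 || weight_cv <= 0 ||
      scr_base <= 0 || scr_sdlog <= 0)
    stop("distribution parameters must be positive", call. = FALSE)
  structure(as.list(environment()), class = "cohort_config")
}

# log-normal (meanlog, sdlog) matching a target median and IQR
lnorm_from_median_iqr <- function(med, iqr) {
  z <- stats::qnorm(0.75)
  list(meanlog = log(med), sdlog = asinh(iqr / (2 * med)) / z)
}

sample_covariates_impl <- function(config, n) {
  age_par <- lnorm_from_median_iqr(config$age_median_months,
                                   config$age_iqr_months)
  ages <- stats::rlnorm(n, age_par$meanlog, age_par$sdlog)
  ages <- pmin(pmax(ages, 1), 216)  # clamp to 1 month -- 18 years
  wt_sdlog <- sqrt(log(1 + config$weight_cv^2))
  weights <- (ages / 12 + 4) * 2 *
    stats::rlnorm(n, -wt_sdlog^2 / 2, wt_sdlog)
  scr_med <- config$scr_base + config$scr_slope_per_year * ages / 12
  scr <- stats::rlnorm(n, log(scr_med), config$scr_sdlog)
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  lapply(seq_len(n), function(i)
    patient_covariates(ages[i], weights[i], scr[i], sex = sex[i]))
}

#' Sample virtual-patient covariates
#'
#' Draws `config$n` covariate sets from the generators described in
#' [cohort_config()], seeded by `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list of [patient_covariates()] objects.
#' @export
sample_covariates <- function(config) {
  set.seed(config$seed)
  sample_covariates_impl(config, config$n)
}

#' TDM sampling policy
#'
#' Trough sampling at steady state: immediately before the fourth dose for
#' vancomycin and before the third dose for amikacin, drawn
#' `trough_offset_h` hours (default 3 minutes) ahead of the infusion start.
#'
#' @param trough_before_dose Named integer vector of dose indices.
#' @param trough_offset_h Pre-dose sampling offset, hours (> 0).
#' @return A list of class `tdm_policy`.
#' @export
tdm_policy <- function(trough_before_dose = c(vancomycin = 4L,
                                              amikacin = 3L),
                       trough_offset_h = 0.05) {
  if (trough_offset_h <= 0)
    stop("trough_offset_h must be > 0 (a trough precedes the dose)",
         call. = FALSE)
  structure(list(trough_before_dose = trough_before_dose,
                 trough_offset_h = trough_offset_h),
            class = "tdm_policy")
}

#' Generate a virtual cohort
#'
#' Draws covariates, drug, study arm, true individual random effects
#' (`eta ~ N(0, Omega)` of the drug's model), the weight-based initial
#' regimen, and a per-patient RNG seed split from the master seed.
#'
#' @param config A [cohort_config()].
#' @param models Named list with `vancomycin` and `amikacin` [pk_model()]s.
#' @return A list of class `mipd_cohort`: `config` plus `patients`, each a
#'   `virtual_patient` list (`id`, `covariates`, `drug`, `group`,
#'   `true_eta`, `regimen`, `observations`, `second_sample`, `seed`).
#' @export
simulate_cohort <- function(config = cohort_config(),
                            models = list(vancomycin = pk_model_vancomycin(),
                                          amikacin = pk_model_amikacin())) {
  set.seed(config$seed)
  n <- config$n
  pat_seed <- sample.int(.Machine$integer.max - 1L, n)
  drugs <- ifelse(stats::runif(n) < config$drug_mix_vancomycin,
                  "vancomycin", "amikacin")
  groups <- ifelse(stats::runif(n) < config$mipd_fraction, "MIPD", "SoC")
  second <- stats::runif(n) < config$second_sample_prob
  covs <- sample_covariates_impl(config, n)
  policy <- tdm_policy()
  patients <- lapply(seq_len(n), function(i) {
    model <- models[[drugs[i]]]
    L <- chol(model$omega + diag(1e-12, nrow(model$omega)))
    eta <- drop(t(L) %*% stats::rnorm(nrow(model$omega)))
    names(eta) <- rownames(model$omega)
    dose <- round_to_increment(config$initial_mg_kg[[drugs[i]]] *
                                 covs[[i]]$weight_kg)
    idx <- policy$trough_before_dose[[drugs[i]]]
    reg <- regimen(dose, config$initial_interval_h[[drugs[i]]],
                   config$infusion_duration_h, n_doses = idx,
                   drug = drugs[i])
    structure(list(id = sprintf("P%03d", i), covariates = covs[[i]],
                   drug = drugs[i], group = groups[i], true_eta = eta,
                   regimen = reg, observations = empty_observations(),
                   second_sample = second[i], seed = pat_seed[i]),
              class = "virtual_patient")
  })
  structure(list(config = config, patients = patients),
            class = "mipd_cohort")
}

#' Simulate TDM observations for one virtual patient
#'
#' Draws the policy trough: the sampling time is the start of the indexed
#' dose (at which that dose has contributed nothing yet, i.e. a true trough),
#' the observed value is the model prediction at the patient's true eta
#' perturbed by the combined residual-error model. Negative draws are
#' truncated at 0 and flagged `below_loq`. The caller controls the RNG state.
#'
#' @param patient A `virtual_patient` from [simulate_cohort()].
#' @param model The drug's [pk_model()].
#' @param policy A [tdm_policy()].
#' @return A one-row [observations()] data frame.
#' @export
simulate_tdm <- function(patient, model, policy = tdm_policy()) {
  idx <- policy$trough_before_dose[[patient$drug]]
  ev <- patient$regimen$events
  if (idx > length(ev))
    stop("policy dose index ", idx, " exceeds regimen length ", length(ev),
         call. = FALSE)
  t_obs <- ev[[idx]]$start_time_h - policy$trough_offset_h
  params <- individualize(model, patient$covariates, patient$true_eta)
  pred <- predict_concentration(params, model, patient$regimen, t_obs)
  s <- sqrt(model$residual$sigma_add^2 +
              (model$residual$sigma_prop * pred)^2)
  y <- pred + stats::rnorm(1, 0, s)
  observations(t_obs, max(y, 0), below_loq = y < 0)
}

#' Run the full synthetic MIPD study
#'
#' Executes the study-shaped pipeline on a virtual cohort: weight-based
#' initial dosing; first trough per the TDM policy; paired a priori (eta = 0)
#' and a posteriori (MAP-updated) predictions at the observation time;
#' arm-specific adjustment (MIPD: exposure-target [recommend_dose()] with the
#' MAP eta; SoC: trough-guided [soc_adjust()]); for the subset with a second
#' sample, a second trough under the adjusted regimen with predictions from
#' the first-sample-updated parameters versus a priori; model-fit
#' classification at each sample; and the stratified error-summary table.
#' The whole pipeline is deterministic given the master seed (RNG streams
#' are split per patient).
#'
#' @param config A [cohort_config()].
#' @param models Named list of [pk_model()]s per drug.
#' @param targets Named list of [target_spec()]s used by the MIPD arm.
#' @param soc_targets Named list of trough-band targets for the SoC rule.
#' @param fit_thresholds Relative-error cutoffs for [classify_fit()].
#' @return An object of class `mipd_study`: `config`, `patients` (summary
#'   data frame), `pairs` (prediction pairs), `summary`
#'   ([paired_evaluation()] table), `fit_counts`, `cohort`.
#' @examples
#' \donttest{
#' study <- run_study(cohort_config(n = 10, seed = 42))
#' study$summary
#' }
#' @export
run_study <- function(config = cohort_config(),
                      models = list(vancomycin = pk_model_vancomycin(),
                                    amikacin = pk_model_amikacin()),
                      targets = list(vancomycin = vancomycin_target(),
                                     amikacin = amikacin_target()),
                      soc_targets = list(
                        vancomycin = target_spec("vancomycin",
                                                 trough_band_mg_L = c(10, 15)),
                        amikacin = target_spec("amikacin",
                                               trough_band_mg_L = c(0, 5))),
                      fit_thresholds = c(0.20, 0.50)) {
  cohort <- simulate_cohort(config, models)
  policy <- tdm_policy()
  pairs <- list(); prows <- list()
  for (patient in cohort$patients) {
    model <- models[[patient$drug]]
    set.seed(patient$seed)
    obs1 <- simulate_tdm(patient, model, policy)
    t1 <- obs1$time_h
    prior_params <- individualize(model, patient$covariates)
    apriori1 <- predict_concentration(prior_params, model, patient$regimen, t1)
    fit1 <- map_fit(model, patient$covariates, patient$regimen, obs1)
    apost1 <- predict_concentration(fit1$params, model, patient$regimen, t1)
    cat1 <- classify_fit(obs1$concentration_mg_L, apost1,
                         thresholds = fit_thresholds)$label

    cur_dose <- patient$regimen$events[[1]]$amount_mg
    cur_int <- diff(vapply(patient$regimen$events[1:2], `[[`, numeric(1),
                           "start_time_h"))
    rec <- NULL
    if (patient$group == "MIPD") {
      rec <- recommend_dose(model, patient$covariates, fit1$eta_map,
                            targets[[patient$drug]])
      new_dose <- rec$dose_mg; new_int <- rec$interval_h
    } else {
      adj <- soc_adjust(cur_dose, cur_int, obs1$concentration_mg_L,
                        soc_targets[[patient$drug]])
      new_dose <- adj$dose_mg; new_int <- adj$interval_h
    }

    obs2 <- NULL; apriori2 <- NA_real_; apost2 <- NA_real_
    cat2 <- NA_character_; t2 <- NA_real_
    if (patient$second_sample) {
      idx2 <- policy$trough_before_dose[[patient$drug]]
      adj_start <- t1 + cur_int
      new_ev <- lapply(seq_len(idx2) - 1L, function(k)
        dose_event(adj_start + k * new_int, new_dose,
                   config$infusion_duration_h, patient$drug))
      reg2 <- regimen_from_events(c(patient$regimen$events, new_ev))
      t2 <- new_ev[[idx2]]$start_time_h - policy$trough_offset_h
      true_params <- individualize(model, patient$covariates,
                                   patient$true_eta)
      pred2 <- predict_concentration(true_params, model, reg2, t2)
      s <- sqrt(model$residual$sigma_add^2 +
                  (model$residual$sigma_prop * pred2)^2)
      y2 <- pred2 + stats::rnorm(1, 0, s)
      obs2 <- observations(t2, max(y2, 0), below_loq = y2 < 0)
      apriori2 <- predict_concentration(prior_params, model, reg2, t2)
      apost2 <- predict_concentration(fit1$params, model, reg2, t2)
      cat2 <- classify_fit(obs2$concentration_mg_L, apost2,
                           thresholds = fit_thresholds)$label
    }

    pairs[[length(pairs) + 1L]] <- data.frame(
      patient_id = patient$id, timepoint_index = 1L,
      observed = obs1$concentration_mg_L,
      predicted_a_priori = apriori1, predicted_a_posteriori = apost1,
      group = patient$group, drug = patient$drug)
    if (!is.null(obs2))
      pairs[[length(pairs) + 1L]] <- data.frame(
        patient_id = patient$id, timepoint_index = 2L,
        observed = obs2$concentration_mg_L,
        predicted_a_priori = apriori2, predicted_a_posteriori = apost2,
        group = patient$group, drug = patient$drug)

    prows[[length(prows) + 1L]] <- data.frame(
      id = patient$id, group = patient$group, drug = patient$drug,
      age_months = patient$covariates$age_months,
      weight_kg = patient$covariates$weight_kg,
      scr_mg_dl = patient$covariates$scr_mg_dl,
      sex = patient$covariates$sex,
      initial_dose_mg = cur_dose, initial_interval_h = cur_int,
      trough1_mg_L = obs1$concentration_mg_L, t1_h = t1,
      adjusted_dose_mg = new_dose, adjusted_interval_h = new_int,
      feasible = if (is.null(rec)) NA else rec$feasible,
      capped = if (is.null(rec)) NA else rec$capped,
      fit_category_1 = cat1, fit_category_2 = cat2,
      trough2_mg_L = if (is.null(obs2)) NA_real_
                     else obs2$concentration_mg_L,
      t2_h = t2)
  }
  pairs <- do.call(rbind, pairs)
  patients <- do.call(rbind, prows)
  fit_counts <- fit_count_table(patients)
  structure(list(config = config, patients = patients, pairs = pairs,
                 summary = paired_evaluation(pairs), fit_counts = fit_counts,
                 cohort = cohort),
            class = "mipd_study")
}

fit_count_table <- function(patients) {
  out <- list()
  for (tp in 1:2) {
    col <- paste0("fit_category_", tp)
    sub <- patients[!is.na(patients[[col]]), , drop = FALSE]
    if (!nrow(sub)) next
    tab <- as.data.frame(table(drug = sub$drug, group = sub$group,
                               label = factor(sub[[col]],
                                              levels = c("good",
                                                         "intermediate",
                                                         "poor"))))
    tab$timepoint <- tp
    out[[length(out) + 1L]] <- tab
  }
  do.call(rbind, out)
}

#' @export
print.mipd_study <- function(x, ...) {
  cat("Synthetic MIPD study: n =", x$config$n, "patients, seed =",
      x$config$seed, "\n")
  cat("  arms:", sum(x$patients$group == "MIPD"), "MIPD /",
      sum(x$patients$group == "SoC"), "SoC;  drugs:",
      sum(x$patients$drug == "vancomycin"), "vancomycin /",
      sum(x$patients$drug == "amikacin"), "amikacin\n")
  cat("  prediction pairs:", nrow(x$pairs), "(",
      sum(x$pairs$timepoint_index == 2L), "second-sample )\n\n")
  tot <- x$summary[x$summary$stratum == "total", ]
  print(tot[, c("timepoint", "prediction", "n", "mae", "mdae", "mde")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
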