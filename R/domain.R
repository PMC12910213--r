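#' Patient covariates
#'
#' Container for the demographic and renal covariates consumed by the
#' population-PK covariate models: age, body weight, height (optional) and
#' serum creatinine, plus sex.
#'
#' @param age_months Age in months; must be positive.
#' @param weight_kg Body weight in kg; must be positive.
#' @param scr_mg_dl Serum creatinine in mg/dL; must be positive.
#' @param height_cm Height in cm, or `NA` if unavailable.
#' @param sex `"male"` or `"female"`.
#'
#' @return An object of class `patient_covariates` (a named list).
#' @examples
#' patient_covariates(age_months = 38.6, weight_kg = 14, scr_mg_dl = 0.4)
#' @export
patient_covariates <- function(age_months, weight_kg, scr_mg_dl,
                               height_cm = NA_real_,
                               sex = c("female", "male")) {
  sex <- match.arg(sex)
  for (nm in c("age_months", "weight_kg", "scr_mg_dl")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("covariate '", nm, "' must be a single positive number", call. = FALSE)
  }
  structure(list(age_months = as.numeric(age_months),
                 weight_kg = as.numeric(weight_kg),
                 height_cm = as.numeric(height_cm),
                 scr_mg_dl = as.numeric(scr_mg_dl),
                 sex = sex),
            class = "patient_covariates")
}

#' Single IV-infusion dose event
#'
#' @param start_time_h Infusion start, hours from the regimen origin (>= 0).
#' @param amount_mg Dose amount in mg (> 0).
#' @param infusion_duration_h Infusion duration in hours (> 0); both drugs are
#'   modelled as infusions, a bolus is not supported.
#' @param drug `"vancomycin"` or `"amikacin"`.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(start_time_h, amount_mg, infusion_duration_h = 1,
                       drug = c("vancomycin", "amikacin")) {
  drug <- match.arg(drug)
  if (!is.finite(start_time_h) || start_time_h < 0)
    stop("start_time_h must be >= 0", call. = FALSE)
  if (!is.finite(amount_mg) || amount_mg <= 0)
    stop("amount_mg must be > 0", call. = FALSE)
  if (!is.finite(infusion_duration_h) || infusion_duration_h <= 0)
    stop("infusion_duration_h must be > 0", call. = FALSE)
  structure(list(start_time_h = as.numeric(start_time_h),
                 amount_mg = as.numeric(amount_mg),
                 infusion_duration_h = as.numeric(infusion_duration_h),
                 drug = drug),
            class = "dose_event")
}

#' Dosing regimen
#'
#' A regimen is an ordered sequence of IV-infusion dose events. The
#' convenience constructor builds a regular multi-dose schedule; arbitrary
#' event lists (e.g. a dose change mid-course) go through
#' [regimen_from_events()].
#'
#' @param dose_mg Dose per administration, mg.
#' @param interval_h Dosing interval, hours; must exceed the infusion duration.
#' @param infusion_duration_h Infusion duration, hours.
#' @param n_doses Number of doses.
#' @param drug `"vancomycin"` or `"amikacin"`.
#' @param start_time_h Start of the first infusion (regimen origin is 0).
#' @return An object of class `regimen`: a list with an `events` list.
#' @examples
#' regimen(210, interval_h = 6, infusion_duration_h = 1, n_doses = 4)
#' @export
regimen <- function(dose_mg, interval_h, infusion_duration_h = 1, n_doses = 1,
                    drug = c("vancomycin", "amikacin"), start_time_h = 0) {
  drug <- match.arg(drug)
  if (!is.finite(interval_h) || interval_h <= infusion_duration_h)
    stop("interval_h must exceed infusion_duration_h", call. = FALSE)
  if (n_doses < 1) stop("n_doses must be >= 1", call. = FALSE)
  ev <- lapply(seq_len(n_doses) - 1L, function(k)
    dose_event(start_time_h + k * interval_h, dose_mg, infusion_duration_h, drug))
  regimen_from_events(ev)
}

#' @param events A list of [dose_event()] objects, sorted by start time.
#' @rdname regimen
#' @export
regimen_from_events <- function(events) {
  if (length(events) == 0L) stop("a regimen needs at least one dose", call. = FALSE)
  if (!all(vapply(events, inherits, logical(1), "dose_event")))
    stop("events must be dose_event objects", call. = FALSE)
  st <- vapply(events, `[[`, numeric(1), "start_time_h")
  if (is.unsorted(st, strictly = FALSE))
    stop("dose events must be sorted by start_time_h", call. = FALSE)
  en <- st + vapply(events, `[[`, numeric(1), "infusion_duration_h")
  if (length(events) > 1L && any(en[-length(en)] > st[-1] + 1e-9))
    stop("consecutive infusions overlap", call. = FALSE)
  structure(list(events = events), class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  df <- as.data.frame(x)
  cat("IV-infusion regimen:", nrow(df), "dose(s) of",
      df$drug[1], "\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.regimen <- function(x, ...) {
  data.frame(
    start_time_h = vapply(x$events, `[[`, numeric(1), "start_time_h"),
    amount_mg = vapply(x$events, `[[`, numeric(1), "amount_mg"),
    infusion_duration_h = vapply(x$events, `[[`, numeric(1), "infusion_duration_h"),
    drug = vapply(x$events, `[[`, character(1), "drug")
  )
}

#' TDM observations
#'
#' Builds the observed-concentration table that MAP estimation consumes.
#' Concentrations flagged `below_loq` (e.g. a trough reported as 0 after
#' truncation at the assay limit) are by default excluded from the fit.
#'
#' @param time_h Sampling times, hours from the regimen origin (>= 0).
#' @param concentration_mg_L Observed concentrations, mg/L (>= 0, finite).
#' @param below_loq Logical, below the limit of quantification.
#' @return A `data.frame` with class `tdm_observations`.
#' @export
observations <- function(time_h, concentration_mg_L, below_loq = FALSE) {
  n <- length(time_h)
  below_loq <- rep_len(as.logical(below_loq), n)
  if (length(concentration_mg_L) != n)
    stop("time_h and concentration_mg_L lengths differ", call. = FALSE)
  if (n && (any(!is.finite(time_h)) || any(time_h < 0)))
    stop("observation times must be finite and >= 0", call. = FALSE)
  if (n && (any(!is.finite(concentration_mg_L)) || any(concentration_mg_L < 0)))
    stop("observed concentrations must be finite and >= 0", call. = FALSE)
  out <- data.frame(time_h = as.numeric(time_h),
                    concentration_mg_L = as.numeric(concentration_mg_L),
                    below_loq = below_loq)
  class(out) <- c("tdm_observations", "data.frame")
  out
}

# empty observation set (the a priori case)
empty_observations <- function() observations(numeric(0), numeric(0), logical(0))
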