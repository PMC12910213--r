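# CSV interchange for cohorts and study results.
#
# Plain CSV with a sidecar JSON schema (columns, units, time origin) keeps
# fixtures diffable; no standard format exists for dosing histories at this
# scale. All times are hours from the regimen origin (start of the first
# infusion), never calendar timestamps; converting clock times is the
# caller's responsibility.

patients_cols <- c("id", "age_months", "weight_kg", "height_cm", "scr_mg_dl",
                   "sex", "group", "drug")
doses_cols <- c("patient_id", "start_time_h", "amount_mg",
                "infusion_duration_h")
levels_cols <- c("patient_id", "time_h", "concentration_mg_L", "below_loq")

cohort_schema <- function() {
  list(
    time_origin = "hours from start of the first infusion",
    units = list(amount_mg = "mg", time = "h", concentration = "mg/L",
                 scr = "mg/dL", weight = "kg", age = "months"),
    files = list(patients = patients_cols, doses = doses_cols,
                 levels = levels_cols))
}

#' Write a cohort to CSV files
#'
#' Writes `patients.csv`, `doses.csv`, `levels.csv` and a `schema.json`
#' sidecar into `dir`. Inputs are never mutated.
#'
#' @param cohort A `mipd_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pts <- do.call(rbind, lapply(cohort$patients, function(p) data.frame(
    id = p$id, age_months = p$covariates$age_months,
    weight_kg = p$covariates$weight_kg,
    height_cm = p$covariates$height_cm,
    scr_mg_dl = p$covariates$scr_mg_dl, sex = p$covariates$sex,
    group = p$group, drug = p$drug)))
  doses <- do.call(rbind, lapply(cohort$patients, function(p) {
    d <- as.data.frame(p$regimen)
    data.frame(patient_id = p$id, start_time_h = d$start_time_h,
               amount_mg = d$amount_mg,
               infusion_duration_h = d$infusion_duration_h)
  }))
  levels <- do.call(rbind, lapply(cohort$patients, function(p) {
    if (nrow(p$observations) == 0L) return(NULL)
    data.frame(patient_id = p$id, time_h = p$observations$time_h,
               concentration_mg_L = p$observations$concentration_mg_L,
               below_loq = p$observations$below_loq)
  }))
  if (is.null(levels))
    levels <- data.frame(patient_id = character(0), time_h = numeric(0),
                         concentration_mg_L = numeric(0),
                         below_loq = logical(0))
  utils::write.csv(pts, file.path(dir, "patients.csv"), row.names = FALSE)
  utils::write.csv(doses, file.path(dir, "doses.csv"), row.names = FALSE)
  utils::write.csv(levels, file.path(dir, "levels.csv"), row.names = FALSE)
  jsonlite::write_json(cohort_schema(), file.path(dir, "schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

check_columns <- function(df, expected, file) {
  extra <- setdiff(names(df), expected)
  miss <- setdiff(expected, names(df))
  if (length(extra))
    stop(file, ": unknown column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (length(miss))
    stop(file, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

#' Read a cohort from CSV files
#'
#' Validates and loads the `patients.csv` / `doses.csv` / `levels.csv`
#' schema written by [write_cohort()]. Row-level violations (non-positive
#' dose amounts, unsorted dose times, unknown columns) are rejected with the
#' offending file and row named. Units are those of the sidecar schema: mg,
#' hours, mg/L, mg/dL.
#'
#' @param dir Directory containing the CSV files.
#' @return A list with `patients` (list of `id`, [patient_covariates()],
#'   `group`, `drug`, [regimen()], [observations()]).
#' @export
read_cohort <- function(dir) {
  pts <- utils::read.csv(file.path(dir, "patients.csv"),
                         stringsAsFactors = FALSE)
  doses <- utils::read.csv(file.path(dir, "doses.csv"),
                           stringsAsFactors = FALSE)
  levels <- utils::read.csv(file.path(dir, "levels.csv"),
                            stringsAsFactors = FALSE)
  check_columns(pts, patients_cols, "patients.csv")
  check_columns(doses, doses_cols, "doses.csv")
  check_columns(levels, levels_cols, "levels.csv")
  bad <- which(!is.finite(doses$amount_mg) | doses$amount_mg <= 0)
  if (length(bad))
    stop("doses.csv: amount_mg must be > 0 (row ", bad[1], ")",
         call. = FALSE)
  patients <- lapply(seq_len(nrow(pts)), function(i) {
    row <- pts[i, ]
    cov <- patient_covariates(row$age_months, row$weight_kg, row$scr_mg_dl,
                              height_cm = row$height_cm, sex = row$sex)
    d <- doses[doses$patient_id == row$id, , drop = FALSE]
    if (nrow(d) == 0L)
      stop("doses.csv: no doses for patient ", row$id, call. = FALSE)
    if (is.unsorted(d$start_time_h))
      stop("doses.csv: dose times unsorted for patient ", row$id,
           call. = FALSE)
    reg <- regimen_from_events(lapply(seq_len(nrow(d)), function(j)
      dose_event(d$start_time_h[j], d$amount_mg[j],
                 d$infusion_duration_h[j], drug = row$drug)))
    l <- levels[levels$patient_id == row$id, , drop = FALSE]
    obs <- observations(l$time_h, l$concentration_mg_L,
                        as.logical(l$below_loq))
    list(id = row$id, covariates = cov, group = row$group, drug = row$drug,
         regimen = reg, observations = obs)
  })
  list(patients = patients)
}

# FNV-1a over a string; enough to fingerprint a config in run logs.
# Kept in doubles with split multiplication so the 32-bit state never loses
# precision or hits R's integer range.
fnv1a <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write study result tables
#'
#' Writes the result tables of a [run_study()] bundle (`patients.csv`,
#' `pairs.csv`, `summary.csv`, `fit_counts.csv`) and a `run_info.json`
#' recording the seed, a config fingerprint and the package version. Output
#' is a pure function of the study object: identical studies produce
#' byte-identical files.
#'
#' @param study A `mipd_study` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(study$pairs, file.path(dir, "pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(study$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(study$fit_counts, file.path(dir, "fit_counts.csv"),
                   row.names = FALSE)
  cfg_json <- jsonlite::toJSON(study$config[order(names(study$config))],
                               auto_unbox = TRUE, digits = NA)
  info <- list(
    seed = study$config$seed, n = study$config$n,
    config_hash = fnv1a(as.character(cfg_json)),
    package_version = as.character(utils::packageVersion("mipdsim")),
    note = "research simulation output; not for clinical use")
  jsonlite::write_json(info, file.path(dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
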