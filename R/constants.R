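# Shared vocabularies: outcome, biomarker, medication and history-flag names,
# and the cohort CSV column sets. Everything else keys off these vectors, so
# they are defined once here.

#' Modelled outcomes
#'
#' The 13 outcomes the risk-equation set covers: all-cause mortality, four
#' macrovascular events, seven microvascular events, and development of
#' diabetes (applicable to prediabetes only).
#'
#' @return Character vector of outcome identifiers.
#' @export
outcome_names <- function() {
  c("mortality", "mi", "ihd", "heart_failure", "cerebrovascular",
    "pvd", "neuropathy", "amputation", "skin_ulcer", "renal_failure",
    "cataract", "retinopathy", "diabetes_onset")
}

# Cycle draw order: mortality first, remaining outcomes alphabetically.
outcome_draw_order <- function() {
  others <- setdiff(outcome_names(), "mortality")
  c("mortality", sort(others))
}

#' Biomarker names
#'
#' @param progressed If `TRUE` (default) the 7 biomarkers with trajectory
#'   equations; if `FALSE` all 10 biomarkers used as risk-equation covariates
#'   (eGFR, hemoglobin and white-cell count are covariates but are held at
#'   baseline during simulation).
#' @return Character vector.
#' @export
biomarker_names <- function(progressed = TRUE) {
  prog <- c("hba1c", "sbp", "dbp", "hdl", "ldl", "triglycerides", "bmi")
  if (progressed) prog else c(prog, "egfr", "hemoglobin", "wbc")
}

medication_names <- function() {
  c("insulin", "oha", "antihypertensive", "statin")
}

# Pre-existing condition flags carried as covariates. Eleven of these are also
# modelled outcomes; atrial fibrillation and hemodialysis are covariates only.
history_names <- function() {
  c("atrial_fibrillation", "mi", "ihd", "heart_failure", "cerebrovascular",
    "pvd", "neuropathy", "amputation", "renal_failure", "hemodialysis",
    "retinopathy", "cataract", "skin_ulcer")
}

history_cols <- function() paste0("hist_", history_names())

# Outcomes that become an absorbing history flag after first occurrence.
absorbing_outcomes <- function() {
  intersect(outcome_names(), history_names())
}

baseline_columns <- function() {
  c("id", "age", "sex", "glycemic_status", "duration", "smoking",
    biomarker_names(progressed = FALSE), medication_names(), history_cols())
}

event_cols <- function() paste0("event_", outcome_names())

panel_columns <- function() {
  c(baseline_columns(), "year", event_cols(), "censored")
}

aft_families <- function() {
  c("exponential", "weibull", "loglogistic", "lognormal")
}
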