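# Readers/writers for the two cohort CSV layouts (baseline and person-year
# panel) and the model-coefficient JSON format.

#' Read a cohort CSV
#'
#' Two layouts are supported. `"baseline"`: one row per individual with
#' demographics, biomarkers, medications and 13 pre-existing condition flags
#' (`hist_*`). `"panel"`: baseline columns plus `year` (integer cycle),
#' 13 incident-event flags (`event_*`) and a `censored` indicator, one row
#' per person-year (or more, if a biomarker was measured repeatedly within a
#' year; [build_person_periods()] averages those).
#'
#' Rows violating the population invariants (age below 20, non-positive
#' biomarker values, positive diabetes duration without diabetes) are
#' dropped with a warning, mirroring the development cohort's exclusion
#' rules. Unknown columns are ignored with a warning.
#'
#' @param path CSV file path.
#' @param schema `"baseline"` or `"panel"`.
#' @param complete_cases Drop rows with any missing biomarker value.
#'   Defaults to `TRUE` for the panel layout (estimation uses complete-case
#'   analysis) and `FALSE` for baseline cohorts (simulation needs explicit
#'   complete states, so missingness is surfaced to the caller instead).
#' @return Data frame in the requested layout. For panel data rows are
#'   ordered by (id, year). Rows with missing biomarkers (when kept) are
#'   flagged in the logical attribute `"incomplete"`.
#' @export
read_cohort <- function(path, schema = c("baseline", "panel"),
                        complete_cases = NULL) {
  schema <- match.arg(schema)
  if (is.null(complete_cases)) complete_cases <- schema == "panel"
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  wanted <- if (schema == "baseline") baseline_columns() else panel_columns()
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols)) {
    stop("cohort file '", path, "' (schema ", schema, ") is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), wanted)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    raw <- raw[wanted]
  }
  # numeric coercion with row-indexed parse errors for biomarkers
  num_cols <- c("age", "duration", biomarker_names(progressed = FALSE))
  for (cl in num_cols) {
    v <- raw[[cl]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v) & trimws(v) != "")
      if (length(bad)) {
        stop("non-numeric value in column '", cl, "' at row ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      raw[[cl]] <- coerced
    }
  }
  flag_cols <- c(medication_names(), history_cols())
  if (schema == "panel") flag_cols <- c(flag_cols, event_cols(), "censored")
  for (cl in flag_cols) raw[[cl]] <- as.integer(raw[[cl]])
  raw$sex <- match_levels(raw$sex, c("female", "male"), "sex")
  raw$smoking <- match_levels(raw$smoking, c("never", "past", "current"), "smoking")
  raw$glycemic_status <- match_levels(raw$glycemic_status,
                                      c("prediabetes", "diabetes"), "glycemic_status")

  viol <- cohort_violations(raw)
  if (length(viol)) {
    bad_rows <- unique(as.integer(sub("^row (\\d+):.*$", "\\1", viol)))
    warning(length(bad_rows), " row(s) dropped for invariant violations: ",
            paste(utils::head(viol, 5L), collapse = "; "),
            if (length(viol) > 5L) " ...", call. = FALSE)
    raw <- raw[-bad_rows, , drop = FALSE]
  }

  incomplete <- Reduce(`|`, lapply(biomarker_names(FALSE), function(bm) is.na(raw[[bm]])))
  if (complete_cases && any(incomplete)) {
    raw <- raw[!incomplete, , drop = FALSE]
    incomplete <- rep(FALSE, nrow(raw))
  }
  if (schema == "panel") {
    ord <- order(raw$id, raw$year)
    raw <- raw[ord, , drop = FALSE]
    incomplete <- incomplete[ord]
  }
  rownames(raw) <- NULL
  attr(raw, "incomplete") <- incomplete
  raw
}

match_levels <- function(x, levels, what) {
  x <- as.character(x)
  bad <- which(!x %in% levels)
  if (length(bad)) {
    stop("invalid ", what, " value '", x[bad[1L]], "' at row ", bad[1L],
         " (expected one of ", paste(levels, collapse = ", "), ")", call. = FALSE)
  }
  x
}

#' Write a cohort data frame to CSV
#'
#' @param states Data frame in baseline or panel layout.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(states, path) {
  utils::write.csv(states, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a model bundle to JSON
#'
#' The JSON schema holds `risk_equations` (outcome, family, intercept, scale,
#' population and per-term variable/transform/knots/coefficient),
#' `biomarker_equations` and free-form `metadata`. Coefficients are written
#' at full precision so `read_model(write_model(b))` reproduces `b` exactly.
#'
#' @param bundle A [model_bundle()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  payload <- list(
    risk_equations = lapply(unname(bundle$risk_equations), function(eq) {
      list(outcome = eq$outcome, family = eq$family,
           intercept = eq$intercept, scale = eq$scale,
           population = eq$population,
           terms = lapply(eq$terms, function(tm) {
             out <- list(variable = tm$variable, transform = tm$transform,
                         coefficient = tm$coefficient)
             if (!is.null(tm$knots)) out$knots <- I(tm$knots)
             out
           }))
    }),
    biomarker_equations = lapply(unname(bundle$biomarker_equations), function(eq) {
      list(biomarker = eq$biomarker, intercept = eq$intercept,
           coefficients = as.list(eq$coefficients), rmse = eq$rmse)
    }),
    metadata = bundle$metadata
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a model bundle from JSON
#'
#' @param path JSON file written by [write_model()] (or hand-authored to the
#'   same schema).
#' @return A validated [model_bundle()].
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(payload$risk_equations) || is.null(payload$biomarker_equations)) {
    stop("model file '", path,
         "' lacks risk_equations/biomarker_equations", call. = FALSE)
  }
  req <- lapply(payload$risk_equations, function(e) {
    if (!e$family %in% aft_families()) {
      stop("unknown survival family '", e$family, "' for outcome '",
           e$outcome, "'", call. = FALSE)
    }
    risk_equation(
      outcome = e$outcome, family = e$family, intercept = e$intercept,
      scale = e$scale, population = e$population,
      terms = lapply(e$terms, function(tm) {
        term(tm$variable, tm$coefficient, tm$transform,
             knots = if (!is.null(tm$knots)) unlist(tm$knots))
      }))
  })
  got <- vapply(req, function(e) e$outcome, character(1))
  missing <- setdiff(outcome_names(), got)
  if (length(missing)) {
    stop("model file is missing outcome equation(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  beq <- lapply(payload$biomarker_equations, function(e) {
    biomarker_equation(e$biomarker, e$intercept,
                       unlist(e$coefficients), e$rmse)
  })
  meta <- payload$metadata
  if (is.null(meta)) meta <- list()
  model_bundle(req, beq, metadata = meta)
}
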