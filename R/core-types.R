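# Domain types: model terms, risk equations (AFT), biomarker trajectory
# equations, and the bundle holding one equation per outcome and biomarker.
# All are lightweight S3 lists with constructors that validate invariants.

#' Construct a risk-equation term
#'
#' One predictor's contribution to an accelerated-failure-time linear
#' predictor. A `spline_nonlinear` term carries the nonlinear restricted
#' cubic spline component for its variable; the corresponding linear
#' component is a separate `linear` term on the same variable.
#'
#' @param variable Name of the model variable (see [model_frame()] for the
#'   derived design variables, e.g. `female`, `diabetes`, `smoking_current`).
#' @param coefficient Coefficient on the log survival-time scale, so
#'   `exp(coefficient)` is the survival time ratio for a one-unit increase.
#' @param transform One of `"linear"`, `"spline_nonlinear"`, `"indicator"`.
#' @param knots For `spline_nonlinear` only: three strictly ascending knots.
#' @return An object of class `"ds_term"`.
#' @export
term <- function(variable, coefficient, transform = "linear", knots = NULL) {
  stopifnot(is.character(variable), length(variable) == 1L,
            is.numeric(coefficient), length(coefficient) == 1L,
            is.finite(coefficient))
  transform <- match.arg(transform, c("linear", "spline_nonlinear", "indicator"))
  if (transform == "spline_nonlinear") {
    if (is.null(knots) || length(knots) != 3L || !is.numeric(knots)) {
      stop("spline_nonlinear term on '", variable,
           "' requires exactly 3 numeric knots", call. = FALSE)
    }
    if (!all(diff(knots) > 0)) {
      stop("knots for '", variable, "' must be strictly ascending", call. = FALSE)
    }
    knots <- as.numeric(knots)
  } else {
    knots <- NULL
  }
  structure(list(variable = variable, transform = transform,
                 knots = knots, coefficient = as.numeric(coefficient)),
            class = "ds_term")
}

#' Construct a parametric survival risk equation
#'
#' An accelerated-failure-time (AFT) model for one outcome:
#' `log T = intercept + sum(coefficient_j * x_j) + sigma * W`, where the
#' distribution of `W` is set by `family`. `exp(coefficient)` is a survival
#' time ratio (values above 1 are protective).
#'
#' @param outcome One of [outcome_names()].
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`.
#' @param intercept Intercept on the log-time scale.
#' @param scale Scale parameter sigma (> 0); forced to 1 for exponential.
#' @param terms List of [term()] objects.
#' @param population `"both"` or `"prediabetes_only"` (development of
#'   diabetes is only defined for prediabetes).
#' @return Object of class `"risk_equation"`.
#' @export
risk_equation <- function(outcome, family, intercept, scale = 1,
                          terms = list(), population = c("both", "prediabetes_only")) {
  outcome <- match.arg(outcome, outcome_names())
  family <- match.arg(family, aft_families())
  population <- match.arg(population)
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept),
            is.numeric(scale), length(scale) == 1L)
  if (family == "exponential") {
    scale <- 1
  } else if (scale <= 0) {
    stop("scale must be > 0 for family '", family, "'", call. = FALSE)
  }
  if (outcome == "diabetes_onset" && population != "prediabetes_only") {
    stop("diabetes_onset equation must have population = 'prediabetes_only'",
         call. = FALSE)
  }
  terms <- lapply(terms, function(tm) {
    if (!inherits(tm, "ds_term")) {
      tm <- term(tm$variable, tm$coefficient, tm$transform, tm$knots)
    }
    tm
  })
  structure(list(outcome = outcome, family = family,
                 intercept = as.numeric(intercept), scale = as.numeric(scale),
                 terms = terms, population = population),
            class = "risk_equation")
}

#' @export
print.risk_equation <- function(x, ...) {
  cat(sprintf("Risk equation: %s (%s AFT, sigma = %.4g, %s)\n",
              x$outcome, x$family, x$scale, x$population))
  cat(sprintf("  intercept %.4g and %d terms\n", x$intercept, length(x$terms)))
  for (tm in x$terms) {
    cat(sprintf("    %-22s %-16s beta = %+.4g  (time ratio %.3f)\n",
                tm$variable, tm$transform, tm$coefficient, exp(tm$coefficient)))
  }
  invisible(x)
}

#' Construct a biomarker trajectory equation
#'
#' Linear model for next year's annual-average biomarker value given the
#' lagged averages of the previous two years, demographics, diabetes
#' duration, and medication use.
#'
#' @param biomarker One of the 7 progressed biomarkers ([biomarker_names()]).
#' @param intercept Numeric intercept.
#' @param coefficients Named numeric vector with elements `lag1_mean`,
#'   `lag2_mean`, `age`, `female`, `duration`, `statin`, `oha_or_insulin`,
#'   `antihypertensive`.
#' @param rmse Residual root-mean-square error (>= 0), used for stochastic
#'   progression draws.
#' @return Object of class `"biomarker_equation"`.
#' @export
biomarker_equation <- function(biomarker, intercept, coefficients, rmse) {
  biomarker <- match.arg(biomarker, biomarker_names(progressed = TRUE))
  needed <- biomarker_coef_names()
  if (!all(needed %in% names(coefficients))) {
    stop("biomarker coefficients must be named; missing: ",
         paste(setdiff(needed, names(coefficients)), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(is.numeric(rmse), length(rmse) == 1L)
  if (rmse < 0) stop("rmse must be >= 0", call. = FALSE)
  structure(list(biomarker = biomarker, intercept = as.numeric(intercept),
                 coefficients = as.numeric(coefficients[needed]) |>
                   stats::setNames(needed),
                 rmse = as.numeric(rmse)),
            class = "biomarker_equation")
}

biomarker_coef_names <- function() {
  c("lag1_mean", "lag2_mean", "age", "female", "duration",
    "statin", "oha_or_insulin", "antihypertensive")
}

#' Bundle the full equation set
#'
#' @param risk_equations List of 13 [risk_equation()] objects, exactly one
#'   per outcome.
#' @param biomarker_equations List of 7 [biomarker_equation()] objects,
#'   exactly one per progressed biomarker.
#' @param metadata Optional list (fit provenance, seed, knot percentiles).
#' @return Object of class `"model_bundle"`.
#' @export
model_bundle <- function(risk_equations, biomarker_equations, metadata = list()) {
  ro <- vapply(risk_equations, function(e) e$outcome, character(1))
  if (!setequal(ro, outcome_names()) || anyDuplicated(ro)) {
    missing <- setdiff(outcome_names(), ro)
    extra_or_dup <- c(setdiff(ro, outcome_names()), ro[duplicated(ro)])
    stop("model bundle needs exactly one risk equation per outcome",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra_or_dup)) paste0("; unexpected/duplicated: ",
                                          paste(extra_or_dup, collapse = ", ")),
         call. = FALSE)
  }
  bo <- vapply(biomarker_equations, function(e) e$biomarker, character(1))
  if (!setequal(bo, biomarker_names(TRUE)) || anyDuplicated(bo)) {
    stop("model bundle needs exactly one trajectory equation per progressed ",
         "biomarker; got: ", paste(bo, collapse = ", "), call. = FALSE)
  }
  structure(list(risk_equations = stats::setNames(risk_equations, ro),
                 biomarker_equations = stats::setNames(biomarker_equations, bo),
                 metadata = metadata),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  fams <- vapply(x$risk_equations, function(e) e$family, character(1))
  cat("Model bundle: 13 risk equations + 7 biomarker equations\n")
  cat("  families:", paste(sprintf("%s=%s", names(fams), fams), collapse = ", "), "\n")
  invisible(x)
}

#' Derive the design variables used by the equations from cohort columns
#'
#' Maps the raw cohort representation (sex/smoking/glycemic status as
#' categories) onto the numeric design variables the equations reference:
#' `female` (1 = female), `diabetes` (1 = diabetes), `smoking_current` and
#' `smoking_past` indicators (never-smoker baseline), `oha_or_insulin`, the
#' biomarkers, medications and `hist_*` flags unchanged.
#'
#' @param states Data frame in cohort layout (see [read_cohort()]).
#' @return Data frame of numeric design variables, one row per individual.
#' @export
model_frame <- function(states) {
  out <- data.frame(
    age = as.numeric(states$age),
    female = as.numeric(states$sex == "female"),
    diabetes = as.numeric(states$glycemic_status == "diabetes"),
    duration = as.numeric(states$duration),
    smoking_current = as.numeric(states$smoking == "current"),
    smoking_past = as.numeric(states$smoking == "past")
  )
  for (bm in biomarker_names(progressed = FALSE)) out[[bm]] <- as.numeric(states[[bm]])
  for (md in medication_names()) out[[md]] <- as.numeric(states[[md]])
  out$oha_or_insulin <- as.numeric(states$oha | states$insulin)
  for (hc in history_cols()) out[[hc]] <- as.numeric(states[[hc]])
  out
}

# Invariant checks on a baseline cohort data.frame; returns a character
# vector of violation messages (empty when valid), one entry per bad row.
cohort_violations <- function(states) {
  msgs <- character(0)
  bad_age <- which(states$age < 20)
  if (length(bad_age)) {
    msgs <- c(msgs, sprintf("row %d: age %.1f below minimum age 20",
                            bad_age, states$age[bad_age]))
  }
  bad_dur <- which(states$duration < 0 |
                     (states$duration > 0 & states$glycemic_status != "diabetes"))
  if (length(bad_dur)) {
    msgs <- c(msgs, sprintf("row %d: invalid duration/glycemic status", bad_dur))
  }
  for (bm in biomarker_names(progressed = FALSE)) {
    bad <- which(!is.na(states[[bm]]) & states[[bm]] <= 0)
    if (length(bad)) {
      msgs <- c(msgs, sprintf("row %d: %s must be > 0", bad, bm))
    }
  }
  msgs
}
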