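# Simulated trial-arm cohorts from published aggregate baseline summaries:
# truncated-normal sampling for continuous variables, Bernoulli sampling for
# binary ones, protocol bounds from inclusion/exclusion criteria, and a
# step treatment-effect schedule reaching the full effect in year 2.

#' Sample from a truncated normal distribution
#'
#' Rejection sampling of i.i.d. Normal(mean, sd) draws restricted to
#' `[lower, upper]`, as used to reconstruct continuous baseline variables
#' from a trial's reported mean/SD under its protocol bounds.
#'
#' @param mean,sd Reported mean and standard deviation (`sd >= 0`).
#' @param lower,upper Bounds (default unbounded). With `sd = 0` all values
#'   equal `mean` (which must respect the bounds).
#' @param n Number of draws (>= 1).
#' @return Numeric vector of length `n`, all within the bounds.
#' @export
sample_truncated_normal <- function(mean, sd, lower = -Inf, upper = Inf, n) {
  stopifnot(n >= 1L, sd >= 0, lower < upper)
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("sd = 0 with mean ", mean, " outside bounds [", lower, ", ",
           upper, "]", call. = FALSE)
    }
    return(rep(mean, n))
  }
  mass <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  if (mass < 0.001) {
    stop("bounds [", lower, ", ", upper, "] exclude > 99.9% of the ",
         "Normal(", mean, ", ", sd, ") mass; check the arm specification",
         call. = FALSE)
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(ceiling((n - length(out)) / mass * 1.1) + 10L, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Sample binary baseline flags
#'
#' Bernoulli draws with the reported prevalence as sampling probability.
#'
#' @param p Probability in `[0, 1]`.
#' @param n Number of draws.
#' @return Integer 0/1 vector.
#' @export
sample_binary <- function(p, n) {
  if (!is.numeric(p) || p < 0 || p > 1) {
    stop("sampling probability must be in [0, 1]", call. = FALSE)
  }
  as.integer(stats::runif(n) < p)
}

#' Relative treatment effect from an absolute change
#'
#' A trial's full treatment effect on a biomarker (an absolute change from
#' baseline) expressed as a fraction of the baseline mean, e.g. a 0.05
#' percentage-point HbA1c reduction from a baseline mean of 5.9% is a
#' relative decrease of 0.05/5.9 = 0.85%.
#'
#' @param absolute_change Absolute reduction in the biomarker's units.
#' @param baseline_mean Arm baseline mean (nonzero).
#' @return Fraction (e.g. 0.0085).
#' @export
relative_effect <- function(absolute_change, baseline_mean) {
  if (baseline_mean == 0) stop("baseline mean must be nonzero", call. = FALSE)
  absolute_change / baseline_mean
}

#' Apply the step treatment-effect schedule to a biomarker value
#'
#' The full effect is reached in year 2 and stable thereafter: years 0-1
#' return the value unadjusted; from year 2 the year-1 value is reduced by
#' the relative effect fraction before entering the risk equations.
#'
#' @param year1_value Biomarker value in trial year 1.
#' @param effect Relative effect fraction ([relative_effect()]).
#' @param year Trial year (integer >= 0).
#' @return Adjusted value.
#' @export
apply_treatment_schedule <- function(year1_value, effect, year) {
  ifelse(year >= 2, year1_value * (1 - effect), year1_value)
}

#' Read a trial-arm specification (JSON)
#'
#' Schema: `name`; `n_simulated` (default 100000); `follow_up` (years);
#' `population` ("prediabetes" or "diabetes"); `continuous`, a map variable
#' -> {mean, sd, lower?, upper?}; `binary`, a map variable -> sampling
#' probability (supports the medication flags, `hist_*` flags,
#' `smoking_current`/`smoking_past` and `female`); `defaults`, explicit
#' fill-in constants for variables the trial did not report; and
#' `treatment_effects`, a map biomarker -> {absolute_change, baseline_mean}.
#'
#' An optional `endpoints` array names the outcomes the trial reports (the
#' endpoint table and convergence diagnostic are restricted to them).
#'
#' @param path JSON file.
#' @return List of class `"trial_arm_spec"`.
#' @export
read_trial_spec <- function(path) {
  sp <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_trial_spec(sp)
}

validate_trial_spec <- function(sp) {
  sp$n_simulated <- sp$n_simulated %||% 100000L
  sp$continuous <- sp$continuous %||% list()
  sp$binary <- sp$binary %||% list()
  sp$defaults <- sp$defaults %||% list()
  sp$treatment_effects <- sp$treatment_effects %||% list()
  if (is.null(sp$follow_up) || sp$follow_up < 1) {
    stop("trial spec needs follow_up >= 1 year", call. = FALSE)
  }
  if (is.null(sp$population) ||
      !sp$population %in% c("prediabetes", "diabetes")) {
    stop("trial spec needs population 'prediabetes' or 'diabetes'", call. = FALSE)
  }
  for (v in names(sp$continuous)) {
    cv <- sp$continuous[[v]]
    if (is.null(cv$mean) || is.null(cv$sd) || cv$sd < 0) {
      stop("continuous variable '", v, "' needs mean and sd >= 0", call. = FALSE)
    }
    lo <- cv$lower %||% -Inf; hi <- cv$upper %||% Inf
    if (lo >= hi) stop("inconsistent bounds for '", v, "'", call. = FALSE)
  }
  for (v in names(sp$binary)) {
    p <- sp$binary[[v]]
    if (p < 0 || p > 1) {
      stop("binary probability for '", v, "' outside [0, 1]", call. = FALSE)
    }
  }
  class(sp) <- "trial_arm_spec"
  sp
}

# Baseline cohort columns the arm spec must cover one way or another.
trial_required_vars <- function() {
  c("age", "duration", biomarker_names(progressed = FALSE))
}

#' Sample a baseline cohort from a trial-arm specification
#'
#' @param spec A `"trial_arm_spec"`.
#' @param n Cohort size (defaults to `spec$n_simulated`).
#' @return Baseline cohort data frame.
#' @export
sample_trial_baseline <- function(spec, n = NULL) {
  n <- n %||% spec$n_simulated
  provided <- c(names(spec$continuous), names(spec$binary), names(spec$defaults))
  need <- trial_required_vars()
  if (spec$population == "prediabetes") {
    need <- setdiff(need, "duration")
  }
  gaps <- setdiff(need, provided)
  if (length(gaps)) {
    stop("trial spec does not cover model covariate(s): ",
         paste(gaps, collapse = ", "),
         " (add them to continuous/binary/defaults explicitly)", call. = FALSE)
  }
  cols <- list(id = seq_len(n))
  for (v in names(spec$continuous)) {
    cv <- spec$continuous[[v]]
    cols[[v]] <- sample_truncated_normal(cv$mean, cv$sd,
                                         cv$lower %||% -Inf,
                                         cv$upper %||% Inf, n)
  }
  for (v in names(spec$binary)) {
    cols[[v]] <- sample_binary(spec$binary[[v]], n)
  }
  for (v in names(spec$defaults)) {
    if (is.null(cols[[v]])) cols[[v]] <- rep(spec$defaults[[v]], n)
  }
  df <- as.data.frame(cols)
  df$sex <- ifelse((df$female %||% rep(0L, n)) == 1L, "female", "male")
  df$female <- NULL
  cur <- df$smoking_current %||% rep(0L, n)
  pst <- df$smoking_past %||% rep(0L, n)
  pst[cur == 1L] <- 0L     # categories are exclusive; current wins
  df$smoking <- ifelse(cur == 1L, "current", ifelse(pst == 1L, "past", "never"))
  df$smoking_current <- NULL; df$smoking_past <- NULL
  df$glycemic_status <- spec$population
  if (spec$population == "prediabetes") df$duration <- 0
  df$duration <- pmax(df$duration, 0)
  for (cl in c(medication_names(), history_cols())) {
    if (is.null(df[[cl]])) df[[cl]] <- 0L
  }
  df[baseline_columns()]
}

#' Generate and simulate one trial arm
#'
#' Samples the arm's baseline cohort from the aggregate summaries, applies
#' the treatment-effect schedule, simulates to the trial's follow-up, and
#' reports endpoint cumulative-incidence percentages together with an
#' S3-Fig-style convergence diagnostic (running endpoint mean against the
#' number of participants simulated).
#'
#' @param spec A `"trial_arm_spec"` (see [read_trial_spec()]).
#' @param model A [model_bundle()].
#' @param seed Integer seed.
#' @param n Override `spec$n_simulated` (a warning is issued below 100,000;
#'   at least 1,000 required).
#' @return List of class `"trial_arm_result"`: `endpoints` (named percent
#'   vector), `convergence` (data frame of running means at checkpoints),
#'   `simulation` (the [simulate_cohort()] result), `spec_name`.
#' @export
generate_arm <- function(spec, model, seed = 1L, n = NULL) {
  n <- n %||% spec$n_simulated
  if (n < 1000L) stop("need at least 1,000 simulated participants", call. = FALSE)
  if (n < 100000L) {
    warning("fewer than 100,000 simulated participants; endpoint estimates ",
            "may not be converged", call. = FALSE)
  }
  set.seed(seed)
  baseline <- sample_trial_baseline(spec, n)
  effects <- vapply(spec$treatment_effects, function(e) {
    relative_effect(e$absolute_change, e$baseline_mean)
  }, numeric(1))
  sim <- simulate_cohort(baseline, model, horizon = ceiling(spec$follow_up),
                         seed = seed + 1L,
                         treatment = if (length(effects)) effects else NULL)
  eps <- unlist(spec$endpoints) %||% outcome_names()
  endpoints <- 100 * sim$cumulative_incidence[eps]
  checkpoints <- unique(pmin(n, round(seq(0.1, 1, by = 0.05) * n)))
  conv <- lapply(eps, function(oc) {
    hit <- !is.na(sim$individuals[[paste0("time_to_", oc)]])
    data.frame(outcome = oc, n = checkpoints,
               running_pct = 100 * cumsum(hit)[checkpoints] / checkpoints)
  })
  structure(list(endpoints = endpoints,
                 convergence = do.call(rbind, conv),
                 simulation = sim, spec_name = spec$name %||% "arm"),
            class = "trial_arm_result")
}

#' @export
print.trial_arm_result <- function(x, ...) {
  cat(sprintf("Trial arm '%s': %d simulated participants, %d-year follow-up\n",
              x$spec_name, x$simulation$n, x$simulation$horizon))
  cat("Endpoint cumulative incidence (%):\n")
  print(round(sort(x$endpoints, decreasing = TRUE), 2))
  invisible(x)
}
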