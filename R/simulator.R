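# The annual discrete-time individual-level engine. Each cycle: evaluate the
# annual probability of every applicable outcome, draw events (mortality
# first, remaining outcomes in fixed alphabetical order; every draw is made
# even when death fires in the same cycle, so times to other outcomes in the
# death cycle are still recorded), then update survivors' age, time since
# enrollment, diabetes status/duration, event histories and biomarkers for
# entry into the next cycle.

# Attach the simulation bookkeeping columns to a baseline cohort.
init_sim_state <- function(cohort) {
  st <- cohort
  st$alive <- TRUE
  st$time_since_enrollment <- 0L
  for (oc in outcome_names()) st[[paste0("time_to_", oc)]] <- NA_real_
  for (bm in biomarker_names(TRUE)) st[[paste0("prev_", bm)]] <- st[[bm]]
  st
}

#' Advance a cohort state by one annual cycle
#'
#' Draws all applicable outcomes for one cycle and updates state in place.
#' Uniform draws are taken per outcome in a fixed order (mortality first,
#' then the other outcomes alphabetically) over the full cohort vector, so a
#' fixed seed yields identical trajectories regardless of cohort subsetting
#' order, and two arms of equal size simulated from the same seed share
#' random numbers.
#'
#' @param state Cohort data frame (bookkeeping columns are added on first
#'   call), all rows at the same time since enrollment.
#' @param model A [model_bundle()].
#' @param stochastic_biomarkers Add residual noise to biomarker progression.
#' @param treatment Optional named vector of relative treatment-effect
#'   fractions per biomarker (see [relative_effect()]); applied from year 2
#'   onward to the year-1 value.
#' @param update_covariates When `FALSE`, covariates (age, duration,
#'   biomarkers, histories, glycemic status) are frozen at their current
#'   values between cycles, so the drawn event process follows the
#'   closed-form parametric survival curves exactly; the default `TRUE` is
#'   the full annual state-update model.
#' @return List: `state` (advanced cohort) and `incident` (logical matrix,
#'   row per individual, column per outcome).
#' @export
run_cycle <- function(state, model, stochastic_biomarkers = FALSE,
                      treatment = NULL, update_covariates = TRUE) {
  if (is.null(state$alive)) state <- init_sim_state(state)
  n <- nrow(state)
  u <- state$time_since_enrollment[1L]
  alive0 <- state$alive

  mf <- model_frame(state)
  incident <- matrix(FALSE, n, length(outcome_names()),
                     dimnames = list(NULL, outcome_names()))
  for (oc in outcome_draw_order()) {
    eq <- model$risk_equations[[oc]]
    applicable <- alive0
    if (oc %in% absorbing_outcomes()) {
      applicable <- applicable & state[[paste0("hist_", oc)]] == 0L
    }
    if (oc == "diabetes_onset") {
      applicable <- applicable & state$glycemic_status == "prediabetes"
    }
    draw <- stats::runif(n)
    if (any(applicable)) {
      p <- annual_event_probability(eq, mf[applicable, , drop = FALSE], u)
      if (any(p < 0 | p > 1)) {
        stop("internal error: annual probability outside [0, 1] for ", oc)
      }
      hit <- rep(FALSE, n)
      hit[applicable] <- draw[applicable] < p
      incident[, oc] <- hit
      tcol <- paste0("time_to_", oc)
      newly <- hit & is.na(state[[tcol]])
      state[[tcol]][newly] <- u + 1
    }
  }

  died <- incident[, "mortality"]
  surv <- alive0 & !died
  state$alive[died] <- FALSE

  if (!update_covariates) {
    state$time_since_enrollment <- u + 1L
    return(list(state = state, incident = incident))
  }

  # biomarker progression (computed for all rows so the stream stays aligned;
  # applied to survivors only), lag structure shifted one year
  new_vals <- lapply(biomarker_names(TRUE), function(bm) {
    predict_next(model$biomarker_equations[[bm]], mf,
                 lag1 = state[[bm]], lag2 = state[[paste0("prev_", bm)]],
                 stochastic = stochastic_biomarkers)
  })
  names(new_vals) <- biomarker_names(TRUE)
  for (bm in biomarker_names(TRUE)) {
    pcol <- paste0("prev_", bm)
    state[[pcol]][surv] <- state[[bm]][surv]
    state[[bm]][surv] <- new_vals[[bm]][surv]
  }

  # step treatment schedule: the value entering every cycle from year 2 on is
  # the year-1 value reduced by the full relative effect, stable thereafter
  if (!is.null(treatment)) {
    for (bm in names(treatment)) {
      y1col <- paste0("year1_", bm)
      if (u == 0L) state[[y1col]] <- state[[bm]]
      else state[[bm]] <- state[[y1col]] * (1 - treatment[[bm]])
    }
  }

  for (oc in absorbing_outcomes()) {
    hc <- paste0("hist_", oc)
    state[[hc]] <- as.integer(state[[hc]] == 1L | incident[, oc])
  }
  state$age[surv] <- state$age[surv] + 1
  diab <- surv & state$glycemic_status == "diabetes"
  state$duration[diab] <- state$duration[diab] + 1
  onset <- surv & incident[, "diabetes_onset"]
  state$glycemic_status[onset] <- "diabetes"
  state$duration[onset] <- 0
  state$time_since_enrollment <- u + 1L  # shared cohort clock

  list(state = state, incident = incident)
}

#' Simulate a cohort over an annual-cycle horizon
#'
#' Runs the discrete-time engine for `horizon` cycles, recording time to
#' death, time to first occurrence of each outcome (integer years, censored
#' at the horizon), annual incidence per outcome, and mean biomarker
#' trajectories. With `replicates > 1` the same cohort is re-simulated with
#' independent streams derived from `seed`, giving first-order (Monte
#' Carlo) uncertainty; passing `bundles` (for example from
#' [bootstrap_coefficients()]) instead re-simulates under each coefficient
#' set for second-order uncertainty.
#'
#' @param cohort Baseline cohort data frame ([read_cohort()] layout).
#'   Rows violating the state invariants are skipped with a warning.
#' @param model A [model_bundle()].
#' @param horizon Number of annual cycles (>= 1).
#' @param seed Integer seed; a fixed seed reproduces results bit-for-bit.
#' @param replicates Number of Monte Carlo replicates (default 1).
#' @param stochastic_biomarkers Add residual noise to biomarker updates.
#' @param treatment Named vector of relative effect fractions (see
#'   [run_cycle()]).
#' @param bundles Optional list of [model_bundle()]s for second-order
#'   uncertainty; overrides `replicates`.
#' @param keep_history Keep the cycle-start state of every cycle (needed to
#'   assemble panels; memory-heavy for large cohorts).
#' @param update_covariates See [run_cycle()]; `FALSE` freezes covariates
#'   between cycles (closed-form verification mode).
#' @return Object of class `"simulation_result"`: `individuals` (per-person
#'   times), `incidence` (cycle x outcome event proportions among those at
#'   risk), `cumulative_incidence` (per outcome at horizon),
#'   `biomarker_means` (cycle x biomarker among the living), `n`, `horizon`,
#'   `seed`; `replicates` holds per-replicate results when more than one.
#' @export
simulate_cohort <- function(cohort, model, horizon, seed = 1L,
                            replicates = 1L, stochastic_biomarkers = FALSE,
                            treatment = NULL, bundles = NULL,
                            keep_history = FALSE, update_covariates = TRUE) {
  stopifnot(horizon >= 1L)
  viol <- cohort_violations(cohort)
  if (length(viol)) {
    bad <- unique(as.integer(sub("^row (\\d+):.*$", "\\1", viol)))
    warning(length(bad), " individual(s) failed state invariants and were ",
            "skipped: ", paste(utils::head(viol, 3L), collapse = "; "),
            if (length(viol) > 3L) " ...", call. = FALSE)
    cohort <- cohort[-bad, , drop = FALSE]
  }
  runs <- if (!is.null(bundles)) length(bundles) else replicates
  if (runs > 1L) {
    reps <- lapply(seq_len(runs), function(r) {
      simulate_one(cohort, if (!is.null(bundles)) bundles[[r]] else model,
                   horizon, seed = seed + r - 1L,
                   stochastic_biomarkers = stochastic_biomarkers,
                   treatment = treatment, keep_history = FALSE,
                   update_covariates = update_covariates)
    })
    out <- reps[[1L]]
    out$replicates <- reps
    ci <- do.call(rbind, lapply(reps, function(r) r$cumulative_incidence))
    out$cumulative_incidence <- colMeans(ci)
    out$cumulative_incidence_sd <- apply(ci, 2, stats::sd)
    return(out)
  }
  simulate_one(cohort, model, horizon, seed, stochastic_biomarkers,
               treatment, keep_history, update_covariates)
}

simulate_one <- function(cohort, model, horizon, seed,
                         stochastic_biomarkers, treatment, keep_history,
                         update_covariates = TRUE) {
  set.seed(seed)
  state <- init_sim_state(cohort)
  n <- nrow(state)
  ocs <- outcome_names()
  incidence <- matrix(NA_real_, horizon, length(ocs),
                      dimnames = list(NULL, ocs))
  at_risk_n <- incidence
  bms <- biomarker_names(TRUE)
  biomarker_means <- matrix(NA_real_, horizon + 1L, length(bms),
                            dimnames = list(NULL, bms))
  biomarker_means[1L, ] <- vapply(bms, function(b) mean(state[[b]]), numeric(1))
  history <- if (keep_history) vector("list", horizon) else NULL

  for (u in seq_len(horizon) - 1L) {
    if (!any(state$alive)) break
    alive0 <- state$alive
    if (keep_history) history[[u + 1L]] <- state
    pre <- state   # cycle-start state for at-risk accounting
    step <- run_cycle(state, model, stochastic_biomarkers, treatment,
                      update_covariates)
    for (oc in ocs) {
      # at-risk: alive at cycle start, no prior history, correct status
      ar_oc <- alive0
      if (oc %in% absorbing_outcomes()) {
        ar_oc <- ar_oc & pre[[paste0("hist_", oc)]] == 0L
      }
      if (oc == "diabetes_onset") {
        ar_oc <- ar_oc & pre$glycemic_status == "prediabetes"
      }
      nr <- sum(ar_oc)
      incidence[u + 1L, oc] <- if (nr) sum(step$incident[ar_oc, oc]) / nr else NA
      at_risk_n[u + 1L, oc] <- nr
    }
    state <- step$state
    biomarker_means[u + 2L, ] <- vapply(bms, function(b)
      if (any(state$alive)) mean(state[[b]][state$alive]) else NA_real_,
      numeric(1))
  }

  indiv <- data.frame(id = state$id)
  for (oc in ocs) indiv[[paste0("time_to_", oc)]] <- state[[paste0("time_to_", oc)]]
  indiv$alive_at_horizon <- state$alive
  indiv$followup <- ifelse(is.na(indiv$time_to_mortality), horizon,
                           indiv$time_to_mortality)
  cum <- vapply(ocs, function(oc) mean(!is.na(indiv[[paste0("time_to_", oc)]])),
                numeric(1))
  structure(list(individuals = indiv, incidence = incidence,
                 at_risk = at_risk_n, cumulative_incidence = cum,
                 biomarker_means = biomarker_means, final_state = state,
                 n = n, horizon = horizon, seed = seed,
                 history = history),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Simulation: %d individuals, %d annual cycles (seed %d)\n",
              x$n, x$horizon, x$seed))
  ci <- sort(x$cumulative_incidence, decreasing = TRUE)
  cat("Cumulative incidence at horizon:\n")
  print(round(ci, 4))
  invisible(x)
}
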