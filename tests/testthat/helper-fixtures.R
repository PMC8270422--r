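# Shared fixtures built in code: minimal valid cohorts, intercept-only
# "null" bundles with controllable hazards, and an inverse-transform AFT
# sampler used as the independent data-generating oracle for recovery tests.

# Minimal valid baseline cohort; any column can be overridden.
tiny_baseline <- function(n = 1, ...) {
  df <- data.frame(
    id = seq_len(n), age = 60, sex = "male", glycemic_status = "prediabetes",
    duration = 0, smoking = "never",
    bmi = 25, hba1c = 6, sbp = 130, dbp = 78, hdl = 1.3, ldl = 3,
    triglycerides = 1.5, egfr = 90, hemoglobin = 13.5, wbc = 7.5,
    insulin = 0L, oha = 0L, antihypertensive = 0L, statin = 0L,
    stringsAsFactors = FALSE
  )
  for (hc in diabsim:::history_cols()) df[[hc]] <- 0L
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df[diabsim:::baseline_columns()]
}

# Identity biomarker equation: next value = lag1, no noise.
identity_biomarker_eq <- function(bm) {
  co <- stats::setNames(rep(0, 8), diabsim:::biomarker_coef_names())
  co["lag1_mean"] <- 1
  biomarker_equation(bm, intercept = 0, coefficients = co, rmse = 0)
}

# Intercept-only bundle: every outcome exponential with eta = eta_default
# (p ~ 0 at +20); per-outcome overrides as
# list(mortality = list(family=, intercept=, scale=)).
null_bundle <- function(eta_default = 20, overrides = list()) {
  reqs <- lapply(outcome_names(), function(oc) {
    ov <- overrides[[oc]]
    risk_equation(
      oc,
      family = ov$family %||% "exponential",
      intercept = ov$intercept %||% eta_default,
      scale = ov$scale %||% 1,
      population = if (oc == "diabetes_onset") "prediabetes_only" else "both")
  })
  beqs <- lapply(biomarker_names(TRUE), identity_biomarker_eq)
  model_bundle(reqs, beqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Intercept that makes the constant annual probability of an exponential
# equation equal p.
eta_for_annual_p <- function(p) -log(-log(1 - p))

# Inverse-transform sampler from the AFT families (independent of the
# package's survival code paths beyond the shared parameterization).
draw_aft_times <- function(family, eta, sigma, n) {
  u <- stats::runif(n)
  switch(family,
         exponential = exp(eta) * (-log(u)),
         weibull = exp(eta) * (-log(u))^sigma,
         loglogistic = exp(eta) * (u / (1 - u))^sigma,
         lognormal = exp(eta + sigma * stats::qnorm(u)))
}

# Single-spell episode data frame from exact times with administrative
# censoring at the empirical (1 - cens_frac) quantile.
make_spell_data <- function(family, beta0, beta, sigma, n, cens_frac = 0.3) {
  x1 <- stats::rnorm(n)
  x2 <- stats::rbinom(n, 1, 0.5)
  eta <- beta0 + beta[1] * x1 + beta[2] * x2
  tt <- draw_aft_times(family, eta, sigma, n)
  cpoint <- unname(stats::quantile(tt, 1 - cens_frac))
  data.frame(tstart = 0, tstop = pmin(tt, cpoint),
             event = as.integer(tt <= cpoint), x1 = x1, x2 = x2,
             female = 0)  # marks the frame as design-variable layout
}

# Independent O(n^2) double-loop oracle for Harrell's C: a pair is usable
# iff the strictly shorter time is an event; score ties count 0.5.
harrell_c_oracle <- function(times, events, scores) {
  conc <- 0; usable <- 0
  n <- length(times)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (times[i] == times[j]) next
      s <- if (times[i] < times[j]) i else j   # shorter
      l <- if (s == i) j else i
      if (events[s] != 1) next
      usable <- usable + 1
      if (scores[s] > scores[l]) conc <- conc + 1
      else if (scores[s] == scores[l]) conc <- conc + 0.5
    }
  }
  conc / usable
}
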