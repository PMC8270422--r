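# Person-period construction, knot placement, censored AFT likelihood,
# AIC family and backwards selection, bootstrap, optimism correction.

make_panel <- function(rows) {
  # rows: list of lists with id, year, optional overrides
  do.call(rbind, lapply(rows, function(r) {
    p <- tiny_baseline(n = 1)
    p$id <- r$id; p$year <- r$year
    for (ec in diabsim:::event_cols()) p[[ec]] <- 0L
    p$censored <- 0L
    for (nm in setdiff(names(r), c("id", "year"))) p[[nm]] <- r[[nm]]
    p
  }))
}

test_that("person-period construction smooths, propagates history, stops at death", {
  panel <- make_panel(list(
    list(id = 1, year = 0),
    list(id = 1, year = 1, hba1c = 7.0),
    list(id = 1, year = 1, hba1c = 8.0),       # duplicate year-1 measurement
    list(id = 1, year = 2, event_mi = 1L),
    list(id = 1, year = 3),
    list(id = 1, year = 4, event_mortality = 1L),
    list(id = 1, year = 5)                      # after death: must vanish
  ))
  tab <- build_person_periods(panel)
  expect_equal(tab$hba1c[tab$year == 1], 7.5)
  # an event in year 2 becomes history from the year-3 row onward
  expect_equal(tab$hist_mi[order(tab$year)], c(0L, 0L, 0L, 1L, 1L))
  expect_equal(max(tab$year), 4L)
  # at-risk for MI requires no MI history
  expect_equal(tab$at_risk_mi[order(tab$year)], c(1L, 1L, 1L, 0L, 0L))
  # history flags are monotone within person
  for (oc in diabsim:::absorbing_outcomes()) {
    expect_true(all(diff(tab[[paste0("hist_", oc)]][order(tab$year)]) >= 0))
  }
})

test_that("gap years carry the last smoothed value forward with a flag", {
  panel <- make_panel(list(
    list(id = 1, year = 0, sbp = 120),
    list(id = 1, year = 3, sbp = 140)
  ))
  tab <- build_person_periods(panel)
  expect_equal(tab$year, 0:3)
  expect_equal(tab$sbp, c(120, 120, 120, 140))
  expect_equal(tab$carried, c(0L, 1L, 1L, 0L))
})

test_that("diabetes-onset risk set is restricted to prediabetes", {
  panel <- make_panel(list(
    list(id = 1, year = 0),
    list(id = 2, year = 0, glycemic_status = "diabetes", duration = 3)
  ))
  tab <- build_person_periods(panel)
  expect_equal(tab$at_risk_diabetes_onset, c(1L, 0L))
})

test_that("knots sit at the type-7 10/50/90 percentiles, with demotion rules", {
  expect_equal(compute_knots(1:100), c(10.9, 50.5, 90.1))
  expect_warning(k <- compute_knots(rep(5, 50)), "demoted")
  expect_null(k)
  k10 <- compute_knots(1:10)
  expect_true(all(diff(k10) > 0))
})

test_that("exponential MLE on exact-time spells matches log(total time / events)", {
  d <- data.frame(tstart = 0, tstop = rep(2, 10), event = 1L, female = 0)
  f <- fit_aft(d, "mortality", "exponential", timing = "exact")
  expect_equal(unname(f$coefficients["(Intercept)"]), log(2), tolerance = 1e-6)
  # add 10 spells censored at 2.0: rate = 10 / 40
  d2 <- rbind(d, transform(d, event = 0L))
  f2 <- fit_aft(d2, "mortality", "exponential", timing = "exact")
  expect_equal(unname(f2$coefficients["(Intercept)"]), log(4), tolerance = 1e-6)
  expect_true(f2$converged)
  expect_equal(f2$aic, 2 * 1 - 2 * f2$loglik)
})

test_that("weibull fit on censored spells agrees with survreg", {
  skip_if_not_installed("survival")
  set.seed(11)
  d <- make_spell_data("weibull", beta0 = 2, beta = c(0.4, -0.5),
                       sigma = 0.6, n = 4000)
  f <- fit_aft(d, "mortality", "weibull",
               term_set(linear = c("x1", "x2")), timing = "exact")
  sr <- survival::survreg(survival::Surv(tstop, event) ~ x1 + x2,
                          data = d, dist = "weibull")
  expect_equal(unname(f$coefficients), unname(stats::coef(sr)), tolerance = 1e-4)
  expect_equal(f$equation$scale, sr$scale, tolerance = 1e-4)
  # survival time ratios live in the equation terms
  trs <- vapply(f$equation$terms, function(tm) exp(tm$coefficient), numeric(1))
  expect_equal(trs, exp(unname(stats::coef(sr))[-1]), tolerance = 1e-4)
})

test_that("interval-timing likelihood recovers parameters from cycle-Bernoulli data", {
  # events only known to the annual cycle, generated from the discrete hazard
  set.seed(21)
  n <- 8000
  x1 <- stats::rnorm(n)
  eta <- 2.6 + 0.4 * x1
  alive <- rep(TRUE, n)
  rows <- list()
  for (u in 0:7) {
    idx <- which(alive)
    p <- 1 - aft_survival("weibull", eta[idx], 0.7, u + 1) /
      aft_survival("weibull", eta[idx], 0.7, u)
    hit <- stats::runif(length(idx)) < p
    rows[[u + 1]] <- data.frame(tstart = u, tstop = u + 1,
                                event = as.integer(hit),
                                x1 = x1[idx], female = 0)
    alive[idx[hit]] <- FALSE
  }
  d <- do.call(rbind, rows)
  f <- fit_aft(d, "mortality", "weibull", term_set(linear = "x1"),
               timing = "interval")
  expect_lt(abs(f$coefficients["(Intercept)"] - 2.6),
            3 * f$se["(Intercept)"] + 1e-9)
  expect_lt(abs(f$coefficients["x1"] - 0.4), 3 * f$se["x1"] + 1e-9)
  expect_equal(f$equation$scale, 0.7, tolerance = 0.1)
})

test_that("rank-deficient designs are rejected with the covariates named", {
  set.seed(3)
  d <- make_spell_data("weibull", 2, c(0.3, -0.3), 0.6, n = 300)
  d$x3 <- d$x1
  expect_error(fit_aft(d, "mortality", "weibull",
                       term_set(linear = c("x1", "x3")), timing = "exact"),
               "rank deficient")
})

test_that("AIC family selection finds the generating family and honors nesting", {
  set.seed(31)
  d <- make_spell_data("weibull", 2, c(0.4, -0.5), sigma = 0.5, n = 5000)
  sel <- select_family(d, "mortality", term_set(linear = c("x1", "x2")),
                       timing = "exact")
  expect_identical(sel$family, "weibull")
  tab <- attr(sel, "aic_table")
  others <- tab$aic[tab$family != "weibull"]
  expect_true(all(others - sel$aic > 10))

  # exponential data: weibull collapses to sigma ~ 1, AIC within ~2
  set.seed(32)
  de <- make_spell_data("exponential", 2, c(0.4, -0.5), sigma = 1, n = 5000)
  sele <- select_family(de, "mortality", term_set(linear = c("x1", "x2")),
                        timing = "exact")
  expect_true(sele$family %in% c("exponential", "weibull"))
  tabe <- attr(sele, "aic_table")
  fw <- fit_aft(de, "mortality", "weibull", term_set(linear = c("x1", "x2")),
                timing = "exact")
  expect_equal(fw$equation$scale, 1, tolerance = 0.05)
  expect_lt(abs(tabe$aic[tabe$family == "weibull"] -
                  tabe$aic[tabe$family == "exponential"]), 2.5)
})

test_that("backwards selection drops pure-noise covariates and keeps real ones", {
  set.seed(41)
  d <- make_spell_data("weibull", 2, c(0.5, -0.5), 0.6, n = 5000)
  d$noise <- stats::rnorm(nrow(d))
  full <- fit_aft(d, "mortality", "weibull",
                  term_set(linear = c("x1", "x2", "noise")), timing = "exact")
  red <- backwards_select(full, d)
  kept <- vapply(red$terms, function(tm) tm$variable, character(1))
  expect_setequal(kept, c("x1", "x2"))
  # the redundant covariate costs ~2 AIC
  expect_equal(full$aic - red$aic, 2, tolerance = 2)
  # strong-effect model is a fixpoint
  red2 <- backwards_select(red, d)
  expect_equal(vapply(red2$terms, function(tm) tm$variable, character(1)), kept)
  # intercept-only input returned unchanged
  i0 <- fit_aft(d, "mortality", "weibull", timing = "exact")
  expect_identical(backwards_select(i0, d)$coefficients, i0$coefficients)
})

test_that("bootstrap replicates are reproducible and identity resampling returns the fit", {
  set.seed(51)
  d <- make_spell_data("weibull", 2, c(0.5, -0.5), 0.6, n = 800)
  d$id <- seq_len(nrow(d))
  f <- fit_aft(d, "mortality", "weibull", term_set(linear = c("x1", "x2")),
               timing = "exact")
  ident <- bootstrap_coefficients(d, "mortality", "weibull",
                                  term_set(linear = c("x1", "x2")),
                                  B = 1, seed = 1, timing = "exact",
                                  resample_fn = identity)
  expect_equal(ident[[1]]$intercept, f$equation$intercept, tolerance = 1e-6)
  expect_equal(vapply(ident[[1]]$terms, `[[`, numeric(1), "coefficient"),
               vapply(f$equation$terms, `[[`, numeric(1), "coefficient"),
               tolerance = 1e-6)

  b1 <- bootstrap_coefficients(d, "mortality", "weibull",
                               term_set(linear = c("x1", "x2")),
                               B = 5, seed = 9, timing = "exact")
  b2 <- bootstrap_coefficients(d, "mortality", "weibull",
                               term_set(linear = c("x1", "x2")),
                               B = 5, seed = 9, timing = "exact")
  expect_identical(lapply(b1, unclass), lapply(b2, unclass))

  # bootstrap spread tracks the analytic standard error
  b <- bootstrap_coefficients(d, "mortality", "weibull",
                              term_set(linear = c("x1", "x2")),
                              B = 60, seed = 5, timing = "exact")
  sd_x1 <- stats::sd(vapply(b, function(e) e$terms[[1]]$coefficient, numeric(1)))
  expect_lt(abs(sd_x1 - f$se["x1"]) / f$se["x1"], 0.5)
})

test_that("optimism correction degenerates to apparent at B = 0 and shrinks overfitting", {
  set.seed(61)
  d <- make_spell_data("weibull", 2, c(0.5, -0.5), 0.6, n = 500)
  d$id <- seq_len(nrow(d))
  a <- optimism_corrected_c(d, "mortality", "weibull",
                            term_set(linear = c("x1", "x2")), B = 0,
                            horizon = 10, timing = "exact")
  expect_identical(a$c_corrected, a$c_apparent)
  expect_identical(a$brier_corrected, a$brier_apparent)

  # heavily overfitted model: many pure-noise covariates, few subjects
  set.seed(62)
  d2 <- make_spell_data("weibull", 2, c(0, 0), 0.6, n = 220)
  for (j in 1:15) d2[[paste0("z", j)]] <- stats::rnorm(nrow(d2))
  d2$id <- seq_len(nrow(d2))
  o <- optimism_corrected_c(d2, "mortality", "weibull",
                            term_set(linear = paste0("z", 1:15)),
                            B = 15, horizon = 10, seed = 2, timing = "exact")
  expect_lt(o$c_corrected, o$c_apparent)
  expect_gt(o$optimism_c, 0)
  expect_error(
    optimism_corrected_c(d2[d2$event == 0, ], "mortality", "weibull",
                         B = 0, timing = "exact"),
    "fewer than 5 events|no events")
})
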