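# Glycemic classification and the ground-truth cohort generator.

test_that("glycemic classification follows the diagnostic thresholds exactly", {
  expect_identical(classify_glycemic(hba1c = 6.0), "prediabetes")
  expect_identical(classify_glycemic(hba1c = 6.5), "diabetes")
  expect_identical(classify_glycemic(hba1c = 5.5, fpg = 5.0), "normal")
  # boundary grid: hba1c then fpg then ogtt
  expect_identical(classify_glycemic(hba1c = 5.7), "prediabetes")
  expect_identical(classify_glycemic(hba1c = 6.4), "prediabetes")
  expect_identical(classify_glycemic(fpg = 5.6), "prediabetes")
  expect_identical(classify_glycemic(fpg = 7.0), "diabetes")  # >= 7.0 wins
  expect_identical(classify_glycemic(ogtt = 7.8), "prediabetes")
  expect_identical(classify_glycemic(ogtt = 11.1), "diabetes")
  expect_identical(classify_glycemic(ogtt = 11.0), "prediabetes")
  # medication or diagnosis code dominate any lab value
  expect_identical(classify_glycemic(hba1c = 5.0, on_meds = TRUE), "diabetes")
  expect_identical(classify_glycemic(hba1c = 5.0, dx_code = TRUE), "diabetes")
  # vectorized and total on its grid
  grid <- expand.grid(hba1c = c(NA, 5.5, 6.0, 7.0), fpg = c(NA, 5.0, 6.0, 8.0))
  grid <- grid[!(is.na(grid$hba1c) & is.na(grid$fpg)), ]
  out <- classify_glycemic(grid$hba1c, grid$fpg)
  expect_true(all(out %in% c("normal", "prediabetes", "diabetes")))
  expect_error(classify_glycemic(), "at least one")
})

test_that("the generated cohort is reproducible and respects the baseline anchors", {
  prof <- cohort_profile(n = 2000, follow_up = 6)
  s1 <- generate_cohort(prof, seed = 42)
  s2 <- generate_cohort(prof, seed = 42)
  expect_identical(s1$baseline, s2$baseline)
  expect_identical(s1$panel, s2$panel)
  s3 <- generate_cohort(prof, seed = 43)
  expect_false(identical(s1$panel, s3$panel))

  base <- s1$baseline
  expect_equal(mean(base$glycemic_status == "diabetes"), 0.435, tolerance = 0.01)
  expect_gte(min(base$age), 20)
  pre <- base[base$glycemic_status == "prediabetes", ]
  dia <- base[base$glycemic_status == "diabetes", ]
  expect_equal(mean(pre$hba1c), 5.9, tolerance = 0.05)
  expect_equal(mean(dia$hba1c), 7.8, tolerance = 0.15)
  expect_true(all(pre$duration == 0))
  expect_identical(diabsim:::cohort_violations(base), character(0))
})

test_that("the panel is a valid person-period file consistent with its events", {
  prof <- cohort_profile(n = 1500, follow_up = 8)
  syn <- generate_cohort(prof, seed = 7)
  panel <- syn$panel
  expect_true(all(panel$year >= 0 & panel$year < 8))
  # no rows after a death
  deaths <- panel[panel$event_mortality == 1, c("id", "year")]
  for (i in seq_len(min(nrow(deaths), 50))) {
    after <- panel[panel$id == deaths$id[i] & panel$year > deaths$year[i], ]
    expect_identical(nrow(after), 0L)
  }
  # administrative censoring honors the recorded per-person caps
  expect_true(all(tapply(panel$year, panel$id, max) <
                    syn$censor_time[unique(panel$id)] + 1))
  # the panel round-trips through the CSV layer
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(panel, path)
  got <- read_cohort(path, "panel")
  expect_equal(nrow(got), nrow(panel))
})

test_that("the crude death rate matches the generator's own closed form", {
  prof <- cohort_profile(n = 12000, follow_up = 10, accrual_years = 0)
  syn <- generate_cohort(prof, seed = 13)
  eq <- prof$bundle$risk_equations$mortality
  # year-0 comparison: simulated event fraction vs mean annual probability
  p0 <- annual_event_probability(eq, syn$baseline, 0L)
  y0 <- syn$panel[syn$panel$year == 0, ]
  mc_se <- sqrt(mean(p0) * (1 - mean(p0)) / nrow(y0))
  expect_lt(abs(mean(y0$event_mortality) - mean(p0)), 4 * mc_se)
  # and the overall crude rate sits near the anchored 0.025 per person-year
  crude <- sum(syn$panel$event_mortality) / nrow(syn$panel)
  expect_equal(crude, 0.025, tolerance = 0.3)
})

test_that("zero-noise identity progression keeps trajectories constant", {
  base <- tiny_baseline(n = 10, hba1c = seq(5, 9.5, by = 0.5))
  sim <- simulate_cohort(base, null_bundle(), horizon = 6, seed = 2,
                         stochastic_biomarkers = TRUE, keep_history = TRUE)
  for (u in 1:6) {
    expect_identical(sim$history[[u]]$hba1c, base$hba1c)
  }
  expect_identical(sim$final_state$hba1c, base$hba1c)
})

test_that("equations refitted on a large synthetic cohort recover the truth", {
  # end-to-end: generate -> person-periods -> censored MLE, interval timing
  prof <- cohort_profile(n = 20000, follow_up = 12)
  syn <- generate_cohort(prof, seed = 99)
  tab <- build_person_periods(syn$panel)
  ids <- unique(tab$id)
  tab_fit <- tab[tab$id %in% ids[seq(1, length(ids), by = 2)], ]
  truth <- prof$bundle$risk_equations$mortality
  tm <- lapply(truth$terms, function(t) { t$coefficient <- 0; t })
  f <- fit_aft(tab_fit, "mortality", truth$family, tm, timing = "interval")
  true_beta <- c(truth$intercept,
                 vapply(truth$terms, `[[`, numeric(1), "coefficient"))
  expect_true(f$converged)
  for (j in seq_along(true_beta)) {
    expect_lt(abs(f$coefficients[j] - true_beta[j]),
              3 * f$se[j] + 1e-9)
  }
  # the generating equation's per-cycle probabilities are calibrated on the
  # held-out half (the fitted equation adds estimation noise of ~0.1-0.2 in
  # the decile slope at this n, dominated by the weakly identified spline)
  hold <- tab[tab$id %in% ids[seq(2, length(ids), by = 2)], ]
  p_true <- annual_event_probability(truth, hold, hold$year)
  cal <- calibration(p_true, hold$event_mortality)
  expect_gt(cal$slope, 0.9); expect_lt(cal$slope, 1.1)
  expect_lt(abs(cal$intercept), 0.01)
  # the fitted equation's predictions track the true ones closely
  p_hat <- annual_event_probability(f$equation, hold, hold$year)
  expect_lt(mean(abs(p_hat - p_true)), 0.005)
})
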