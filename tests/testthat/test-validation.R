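# Discrimination and calibration metrics.

test_that("Harrell's C handles the worked pair-counting examples", {
  # perfect ordering, all events
  p <- harrell_c(times = c(1, 2, 3, 4), events = rep(1, 4),
                 scores = c(0.9, 0.7, 0.5, 0.3), B = 0)
  expect_identical(p$c, 1)
  # mixed censoring: 3 usable pairs, 2 concordant
  r <- harrell_c(times = c(5, 3, 8, 2), events = c(1, 1, 1, 0),
                 scores = c(0.8, 0.9, 0.85, 0.7), B = 0)
  expect_equal(r$n_pairs, 3)
  expect_equal(r$c, 2 / 3)
  # all scores tied
  t0 <- harrell_c(times = 1:5, events = rep(1, 5), scores = rep(0.4, 5), B = 0)
  expect_identical(t0$c, 0.5)
  expect_error(harrell_c(c(2, 2), c(0, 0), c(0.1, 0.2), B = 0), "usable")
})

test_that("Harrell's C equals the exhaustive pair-enumeration oracle", {
  set.seed(111)
  for (rep in 1:25) {
    n <- sample(5:120, 1)
    times <- sample(1:15, n, replace = TRUE)
    events <- stats::rbinom(n, 1, 0.6)
    scores <- round(stats::runif(n), 2)   # ties in score occur
    if (sum(events) == 0) next
    got <- tryCatch(harrell_c(times, events, scores, B = 0)$c,
                    error = function(e) NA_real_)
    ora <- tryCatch(harrell_c_oracle(times, events, scores),
                    error = function(e) NA_real_)
    expect_equal(got, ora)
  }
})

test_that("Harrell's C agrees with the survival package on untied data", {
  skip_if_not_installed("survival")
  set.seed(112)
  n <- 400
  times <- stats::rexp(n)
  events <- stats::rbinom(n, 1, 0.7)
  scores <- stats::runif(n)
  got <- harrell_c(times, events, scores, B = 0)$c
  cc <- survival::concordance(survival::Surv(times, events) ~ scores,
                              reverse = TRUE)
  expect_equal(got, unname(cc$concordance))
})

test_that("bootstrap CI is reproducible and brackets the point estimate", {
  set.seed(113)
  n <- 300
  times <- stats::rexp(n); events <- stats::rbinom(n, 1, 0.7)
  scores <- -times + stats::rnorm(n, 0, 0.5)
  r1 <- harrell_c(times, events, scores, B = 50, seed = 4)
  r2 <- harrell_c(times, events, scores, B = 50, seed = 4)
  expect_identical(r1$ci, r2$ci)
  expect_lt(r1$ci[1], r1$c); expect_gt(r1$ci[2], r1$c)
})

test_that("calibration recovers slope 1 / intercept 0 for well-calibrated risks", {
  set.seed(114)
  n <- 50000
  pred <- stats::runif(n, 0.01, 0.4)
  obs <- stats::rbinom(n, 1, pred)
  cal <- calibration(pred, obs)
  expect_equal(cal$g, 10L)
  expect_gt(cal$slope, 0.9); expect_lt(cal$slope, 1.1)
  expect_lt(abs(cal$intercept), 0.01)
  # doubling predictions roughly halves the slope
  cal2 <- calibration(pmin(2 * pred, 1), obs)
  expect_equal(cal2$slope, cal$slope / 2, tolerance = 0.1)
})

test_that("calibration regroups until every group has 5 events (floor 3 groups)", {
  set.seed(115)
  n <- 2000
  pred <- stats::runif(n, 0, 0.08)
  obs <- stats::rbinom(n, 1, pred * 0.5)   # sparse events in low deciles
  cal <- calibration(pred, obs)
  expect_true(cal$g >= 3 && cal$g <= 10)
  if (cal$g > 3) expect_true(all(cal$groups$events >= 5))
  # with barely more than the minimum events the floor engages
  pred2 <- stats::runif(500, 0, 0.05)
  obs2 <- as.integer(seq_len(500) %in% sample(500, 6))
  cal2 <- calibration(pred2, obs2)
  expect_identical(cal2$g, 3L)
  expect_error(calibration(stats::runif(100), rep(0, 100)), "fewer than 5")
  expect_error(calibration(stats::runif(10), rep(1, 10)), "at least 30")
})

test_that("RMSPE and R-squared reproduce their worked examples", {
  expect_identical(rmspe(c(3, 4), c(3, 4)), 0)
  expect_equal(rmspe(c(10, 20), c(12, 16)), sqrt(10))
  expect_equal(rmspe(5, 9), 4)
  expect_error(rmspe(1:3, 1:2), "same length")
  # relative mode divides by the observed value
  expect_equal(rmspe(c(11, 22), c(10, 20), mode = "relative"), 0.1)

  expect_identical(r_squared(c(1, 2, 4), c(1, 2, 4)), 1)
  obs <- c(1, 2, 4)
  expect_identical(r_squared(rep(mean(obs), 3), obs), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 1 - 1 / (14 / 3))
  expect_error(r_squared(1:3, rep(2, 3)), "zero variance")
  # order invariance
  set.seed(116)
  a <- stats::runif(20); b <- stats::runif(20)
  perm <- sample(20)
  expect_equal(rmspe(a, b), rmspe(a[perm], b[perm]))
  expect_equal(r_squared(a, b), r_squared(a[perm], b[perm]))
})

test_that("multi-model comparison reports per-outcome rows and flags gaps", {
  set.seed(117)
  n <- 600
  obs <- data.frame(id = seq_len(n))
  true_risk <- stats::runif(n, 0.05, 0.6)
  obs$event_mortality <- stats::rbinom(n, 1, true_risk)
  obs$time_mortality <- ifelse(obs$event_mortality == 1,
                               sample(1:10, n, TRUE), 12)
  obs$event_mi <- stats::rbinom(n, 1, 0.1)
  obs$time_mi <- ifelse(obs$event_mi == 1, sample(1:10, n, TRUE), 12)

  good <- data.frame(id = obs$id, mortality = true_risk, mi = 0.1)
  partial <- data.frame(id = obs$id, mortality = stats::runif(n))
  rep <- compare_models(obs, list(good = good, partial = partial),
                        horizon = 10, ci_B = 10)
  expect_equal(nrow(rep$by_outcome), 4L)   # 2 models x 2 outcomes
  miss <- rep$by_outcome[rep$by_outcome$model == "partial" &
                           rep$by_outcome$outcome == "mi", ]
  expect_true(is.na(miss$c))
  expect_equal(rep$by_model$model, c("good", "partial"))
  expect_lt(rep$by_model$rmspe[1], rep$by_model$rmspe[2] + 100)  # both finite
  # a perfectly informed model discriminates better than a random one
  cg <- rep$by_outcome[rep$by_outcome$model == "good" &
                         rep$by_outcome$outcome == "mortality", "c"]
  cp <- rep$by_outcome[rep$by_outcome$model == "partial" &
                         rep$by_outcome$outcome == "mortality", "c"]
  expect_gt(cg, cp)

  short <- good[-1, ]
  expect_error(compare_models(obs, list(m = short)), "lacks predictions")
})
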