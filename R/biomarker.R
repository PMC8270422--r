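# Biomarker trajectory equations: ordinary least squares on the lagged
# annual averages of the previous two years plus demographics, duration and
# medication use; applied each cycle to advance risk-factor values.

#' Build the lagged biomarker fitting rows
#'
#' From a smoothed person-period table, rows for years `u >= 2` of each
#' individual, pairing the current annual average with the averages of the
#' previous year (`lag1_mean`) and the year before (`lag2_mean`). Years 0-1
#' lack full lag history and are excluded.
#'
#' @param table A [build_person_periods()] table (or panel-layout data frame
#'   already smoothed to one row per person-year).
#' @param biomarker One of the 7 progressed biomarkers.
#' @return Data frame with `value`, `lag1_mean`, `lag2_mean` and the
#'   trajectory covariates.
#' @export
biomarker_panel <- function(table, biomarker) {
  biomarker <- match.arg(biomarker, biomarker_names(TRUE))
  tab <- table[order(table$id, table$year), , drop = FALSE]
  mf <- model_frame(tab)
  by_id <- split(seq_len(nrow(tab)), tab$id)
  rows <- lapply(by_id, function(ix) {
    yrs <- tab$year[ix]
    vals <- as.numeric(tab[[biomarker]][ix])
    i1 <- match(yrs - 1L, yrs); i2 <- match(yrs - 2L, yrs)
    ok <- !is.na(i1) & !is.na(i2) & !is.na(vals)
    if (!any(ok)) return(NULL)
    data.frame(value = vals[ok],
               lag1_mean = vals[i1[ok]], lag2_mean = vals[i2[ok]],
               age = mf$age[ix][ok], female = mf$female[ix][ok],
               duration = mf$duration[ix][ok], statin = mf$statin[ix][ok],
               oha_or_insulin = mf$oha_or_insulin[ix][ok],
               antihypertensive = mf$antihypertensive[ix][ok])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a biomarker trajectory equation
#'
#' OLS regression of the current annual-average value on `lag1_mean`,
#' `lag2_mean`, age, sex, diabetes duration, and the three medication
#' classes. Fit quality is summarized by the residual root-mean-square
#' error, which also drives stochastic progression draws.
#'
#' @inheritParams biomarker_panel
#' @return A [biomarker_equation()].
#' @export
fit_biomarker <- function(table, biomarker) {
  dat <- if (all(c("value", "lag1_mean", "lag2_mean") %in% names(table)))
    table else biomarker_panel(table, biomarker)
  if (is.null(dat) || nrow(dat) < 50L) {
    stop("need at least 50 usable lagged rows to fit '", biomarker, "'",
         call. = FALSE)
  }
  rhs <- biomarker_coef_names()
  X <- cbind("(Intercept)" = 1, as.matrix(dat[rhs]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    if (any(c("lag1_mean", "lag2_mean") %in% dropped)) {
      stop("rank-deficient trajectory design for '", biomarker,
           "'; collinear column(s): ", paste(dropped, collapse = ", "),
           call. = FALSE)
    }
    # constant covariates (e.g. duration in an all-prediabetes cohort) are
    # unidentifiable but harmless: fit without them, coefficient 0
    warning("dropping unidentifiable trajectory covariate(s) for '",
            biomarker, "': ", paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  }
  fit <- stats::lm.fit(X, dat$value)
  co <- stats::setNames(rep(0, length(rhs) + 1L), c("(Intercept)", rhs))
  co[colnames(X)] <- fit$coefficients
  biomarker_equation(biomarker, intercept = unname(co[1L]),
                     coefficients = co[-1L],
                     rmse = sqrt(mean(fit$residuals^2)))
}

#' Predict a biomarker's next annual value
#'
#' The conditional mean given the two lagged annual averages and the
#' individual's covariates; with `stochastic = TRUE` a Normal(0, rmse)
#' residual draw is added. Values are floored at a small positivity epsilon
#' (biomarkers are strictly positive quantities).
#'
#' @param eq A [biomarker_equation()].
#' @param state Cohort or design-variable data frame (vectorized over rows).
#' @param lag1,lag2 Annual averages of the previous year and the year before
#'   (at the first simulated cycle both are initialized to the baseline
#'   value).
#' @param stochastic Add the residual draw.
#' @return Numeric vector of next-cycle values.
#' @export
predict_next <- function(eq, state, lag1, lag2, stochastic = FALSE) {
  stopifnot(inherits(eq, "biomarker_equation"))
  mf <- if ("female" %in% names(state)) state else model_frame(state)
  co <- eq$coefficients
  mu <- eq$intercept + co["lag1_mean"] * lag1 + co["lag2_mean"] * lag2 +
    co["age"] * mf$age + co["female"] * mf$female +
    co["duration"] * mf$duration + co["statin"] * mf$statin +
    co["oha_or_insulin"] * mf$oha_or_insulin +
    co["antihypertensive"] * mf$antihypertensive
  mu <- unname(mu)
  if (stochastic && eq$rmse > 0) {
    mu <- mu + stats::rnorm(length(mu), 0, eq$rmse)
  }
  pmax(mu, biomarker_floor(eq$biomarker))
}

# Positivity floors, well below any physiological value.
biomarker_floor <- function(biomarker) {
  switch(biomarker,
         hba1c = 2, sbp = 50, dbp = 30, hdl = 0.1, ldl = 0.1,
         triglycerides = 0.1, bmi = 10, 1e-6)
}
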