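# Estimation of the risk equations from a person-period panel: biomarker
# smoothing and history bookkeeping, spline knot placement, censored
# maximum-likelihood AFT fitting with time-varying covariates entered as
# (start, stop] episodes, AIC family selection, optional AIC backwards
# selection, bootstrap resampling of individuals, and optimism-corrected
# discrimination statistics.

#' Build the person-period table used for fitting
#'
#' Prepares a raw panel for estimation: multiple measurements within one
#' (id, year) are averaged (this is the annual moving-average smoothing of
#' the biomarkers), gap years are filled by carrying the last smoothed
#' values forward (flagged in `carried`), history flags are propagated
#' forward monotonically (an event at baseline or in any earlier cycle
#' counts as history for the current cycle), rows after death are dropped,
#' and per-outcome at-risk indicators are added (`at_risk_*`): alive, no
#' prior history of that event, and — for development of diabetes — still
#' prediabetic at cycle start.
#'
#' @param panel Data frame in panel layout (see [read_cohort()]).
#' @return Data frame of class `"person_period_table"`, one row per
#'   person-year, ordered by (id, year).
#' @export
build_person_periods <- function(panel) {
  stopifnot(all(c("id", "year") %in% names(panel)))
  panel <- panel[order(panel$id, panel$year), , drop = FALSE]

  # within-year smoothing: average biomarkers, OR event flags, first otherwise
  key <- paste(panel$id, panel$year, sep = "\r")
  if (anyDuplicated(key)) {
    num_cols <- biomarker_names(progressed = FALSE)
    flag <- c(event_cols(), "censored")
    keep <- !duplicated(key)
    agg <- panel[keep, , drop = FALSE]
    for (cl in num_cols) {
      agg[[cl]] <- as.numeric(tapply(panel[[cl]], key, mean, na.rm = TRUE)[key[keep]])
    }
    for (cl in flag) {
      agg[[cl]] <- as.integer(tapply(panel[[cl]], key, max)[key[keep]])
    }
    panel <- agg[order(agg$id, agg$year), , drop = FALSE]
  }
  panel$carried <- 0L

  out <- lapply(split(panel, panel$id), function(pp) {
    pp <- pp[order(pp$year), , drop = FALSE]
    # truncate after death
    died <- which(pp$event_mortality == 1L)
    if (length(died)) pp <- pp[seq_len(died[1L]), , drop = FALSE]
    # fill gap years, carrying smoothed biomarkers forward
    yrs <- pp$year
    full <- seq(min(yrs), max(yrs))
    if (length(full) > nrow(pp)) {
      idx <- findInterval(full, yrs)   # last observed row at or before year
      filled <- pp[idx, , drop = FALSE]
      filled$year <- full
      gap <- !(full %in% yrs)
      filled$carried[gap] <- 1L
      filled[gap, event_cols()] <- 0L
      pp <- filled
    }
    # monotone history propagation from baseline flags + earlier events
    for (oc in absorbing_outcomes()) {
      hc <- paste0("hist_", oc)
      prior_event <- c(0L, cummax(pp[[paste0("event_", oc)]])[-nrow(pp)])
      pp[[hc]] <- as.integer(cummax(pp[[hc]]) | prior_event)
    }
    pp
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL

  for (oc in outcome_names()) {
    ar <- rep(1L, nrow(tab))
    if (oc %in% absorbing_outcomes()) ar <- ar & tab[[paste0("hist_", oc)]] == 0L
    if (oc == "diabetes_onset") ar <- ar & tab$glycemic_status == "prediabetes"
    tab[[paste0("at_risk_", oc)]] <- as.integer(ar)
  }
  class(tab) <- c("person_period_table", "data.frame")
  tab
}

#' Spline knots at the 10th, 50th and 90th percentiles
#'
#' @param values Numeric vector of development-data values (>= 10 distinct
#'   values required).
#' @return Numeric vector `(k1, k2, k3)` (type-7 linear-interpolation
#'   percentiles), or `NULL` with a warning when fewer than 3 distinct
#'   percentile values exist — the caller then demotes the variable to
#'   linear.
#' @export
compute_knots <- function(values) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 10L) {
    warning("fewer than 10 distinct values; variable demoted to linear",
            call. = FALSE)
    return(NULL)
  }
  k <- unname(stats::quantile(values, c(0.1, 0.5, 0.9), type = 7))
  if (length(unique(k)) < 3L) {
    warning("degenerate percentiles (", paste(signif(k, 6), collapse = ", "),
            "); variable demoted to linear", call. = FALSE)
    return(NULL)
  }
  k
}

#' Declare the candidate terms of a risk equation
#'
#' @param linear Character vector of variables entering linearly.
#' @param indicator Character vector of 0/1 variables.
#' @param spline Named list: variable -> 3 knots, or `NA`/`NULL` entry to
#'   place knots at the data's 10/50/90 percentiles during fitting.
#' @return List of [term()] templates (coefficients 0, to be fitted).
#' @export
term_set <- function(linear = character(), indicator = character(),
                     spline = list()) {
  tms <- c(
    lapply(linear, function(v) term(v, 0, "linear")),
    lapply(indicator, function(v) term(v, 0, "indicator"))
  )
  for (v in names(spline)) {
    kn <- spline[[v]]
    tms <- c(tms, list(term(v, 0, "linear")))
    if (is.null(kn) || all(is.na(kn))) {
      tm <- term(v, 0, "linear")      # knots resolved from data at fit time
      tm$transform <- "spline_nonlinear"
      tm$knots <- NULL
      tms <- c(tms, list(tm))
    } else {
      tms <- c(tms, list(term(v, 0, "spline_nonlinear", knots = kn)))
    }
  }
  tms
}

# Resolve data-driven knots and drop demoted nonlinear terms.
resolve_knots <- function(terms, mf) {
  keep <- logical(length(terms))
  for (i in seq_along(terms)) {
    tm <- terms[[i]]
    if (tm$transform == "spline_nonlinear" && is.null(tm$knots)) {
      kn <- compute_knots(mf[[tm$variable]])
      if (is.null(kn)) { keep[i] <- FALSE; next }
      tm$knots <- kn
      terms[[i]] <- tm
    }
    keep[i] <- TRUE
  }
  terms[keep]
}

design_colname <- function(tm) {
  if (tm$transform == "spline_nonlinear") paste0(tm$variable, "'") else tm$variable
}

# Design matrix (no intercept column) for a term list over a model frame.
build_design <- function(mf, terms) {
  cols <- lapply(terms, function(tm) {
    x <- mf[[tm$variable]]
    if (is.null(x)) {
      stop("data is missing covariate '", tm$variable, "'", call. = FALSE)
    }
    x <- as.numeric(x)
    if (tm$transform == "spline_nonlinear") rcs_nonlinear(x, tm$knots) else x
  })
  X <- do.call(cbind, c(cols, list(deparse.level = 0)))
  if (is.null(X)) X <- matrix(numeric(0), nrow = nrow(mf), ncol = 0)
  colnames(X) <- vapply(terms, design_colname, character(1))
  X
}

# Episode negative log-likelihood. ep: list(start, stop, event); X design
# matrix without intercept; par = c(beta0, beta, [log sigma]).
aft_negloglik <- function(par, X, ep, family, timing) {
  k <- ncol(X)
  beta0 <- par[1L]
  eta <- beta0 + if (k) drop(X %*% par[2:(k + 1L)]) else 0
  sigma <- if (family == "exponential") 1 else exp(par[length(par)])
  ls_start <- aft_log_survival(family, eta, sigma, ep$start)
  ev <- ep$event == 1L
  ll <- numeric(length(eta))
  if (any(!ev)) {
    ll[!ev] <- aft_log_survival(family, eta[!ev], sigma, ep$stop[!ev]) -
      ls_start[!ev]
  }
  if (any(ev)) {
    if (timing == "exact") {
      ll[ev] <- aft_log_density(family, eta[ev], sigma, ep$stop[ev]) -
        ls_start[ev]
    } else {
      # conditional on being event-free at the episode start:
      # log[(S(start) - S(stop)) / S(start)] = log(1 - exp(lS_stop - lS_start))
      ls_b <- aft_log_survival(family, eta[ev], sigma, ep$stop[ev])
      d <- pmin(ls_b - ls_start[ev], -1e-300)
      ll[ev] <- log(-expm1(d))
    }
  }
  nll <- -sum(ll)
  if (!is.finite(nll)) nll <- 1e12
  nll
}

#' Fit one accelerated-failure-time risk equation
#'
#' Censored maximum-likelihood fit of an AFT model on (start, stop] episode
#' data, the standard embedding for time-varying covariates: each
#' person-period contributes `log S(stop) - log S(start)` while event-free;
#' the event episode contributes the exact-time log density (`timing =
#' "exact"`, for data with continuously observed event times) or the
#' within-cycle probability mass `log(S(start) - S(stop))` (`timing =
#' "interval"`, the default, correct for annual panels where events are only
#' known to the cycle).
#'
#' @param table A [build_person_periods()] table, or any data frame with
#'   columns `tstart`, `tstop`, `event` plus the covariates (a person-period
#'   table supplies `tstart = year`, `tstop = year + 1`,
#'   `event = event_<outcome>` on the outcome's at-risk rows).
#' @param outcome Outcome name (selects episodes and labels the equation).
#' @param family AFT family.
#' @param terms Term templates from [term_set()].
#' @param timing `"interval"` or `"exact"` event-time likelihood.
#' @param control List: `maxit` (default 200) and `reltol` (default 1e-10)
#'   passed to [stats::optim()] (BFGS).
#' @return Object of class `"aft_fit"`: `equation` ([risk_equation()]),
#'   `coefficients`, `se`, `vcov`, `loglik`, `aic`, `n_events`,
#'   `n_at_risk`, `converged`, `terms`, `timing`.
#' @export
fit_aft <- function(table, outcome, family, terms = list(),
                    timing = c("interval", "exact"),
                    control = list()) {
  timing <- match.arg(timing)
  family <- match.arg(family, aft_families())
  maxit <- control$maxit %||% 200L
  reltol <- control$reltol %||% 1e-10

  ep <- extract_episodes(table, outcome)
  n_events <- sum(ep$event)
  if (n_events < 1L) {
    stop("no events for outcome '", outcome, "'; cannot fit", call. = FALSE)
  }
  mf <- ep$mf
  terms <- resolve_knots(terms, mf)
  X <- build_design(mf, terms)
  if (ncol(X)) {
    qr_rank <- qr(cbind(1, X))$rank
    if (qr_rank < ncol(X) + 1L) {
      stop("design matrix is rank deficient; check covariates: ",
           paste(colnames(X), collapse = ", "), call. = FALSE)
    }
  }

  exposure <- sum(ep$stop - ep$start)
  start <- c(log(exposure / max(n_events, 1L)), rep(0, ncol(X)))
  if (family != "exponential") start <- c(start, 0)  # log sigma

  opt <- stats::optim(start, aft_negloglik, X = X, ep = ep, family = family,
                      timing = timing, method = "BFGS", hessian = TRUE,
                      control = list(maxit = maxit, reltol = reltol))
  k_par <- length(start)
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, k_par, k_par)
  })
  sigma <- if (family == "exponential") 1 else exp(opt$par[k_par])
  beta <- opt$par[seq_len(ncol(X) + 1L)]
  names(beta) <- c("(Intercept)", colnames(X))
  se <- sqrt(pmax(diag(vc)[seq_len(ncol(X) + 1L)], 0))
  names(se) <- names(beta)

  fitted_terms <- terms
  for (i in seq_along(fitted_terms)) {
    fitted_terms[[i]]$coefficient <- unname(beta[i + 1L])
  }
  eq <- risk_equation(outcome, family, intercept = unname(beta[1L]),
                      scale = sigma, terms = fitted_terms,
                      population = if (outcome == "diabetes_onset")
                        "prediabetes_only" else "both")
  loglik <- -opt$value
  structure(list(
    equation = eq, coefficients = beta, se = se, vcov = vc,
    loglik = loglik, aic = 2 * k_par - 2 * loglik,
    n_events = n_events, n_at_risk = length(unique(ep$id)),
    converged = opt$convergence == 0L, terms = fitted_terms,
    family = family, outcome = outcome, timing = timing
  ), class = "aft_fit")
}

#' @export
print.aft_fit <- function(x, ...) {
  cat(sprintf("AFT fit: %s, family %s (%s timing)\n", x$outcome, x$family, x$timing))
  cat(sprintf("  n at risk %d, events %d, loglik %.2f, AIC %.2f%s\n",
              x$n_at_risk, x$n_events, x$loglik, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(cbind(coef = round(x$coefficients, 5), se = round(x$se, 5)))
  invisible(x)
}

# Episode extraction shared by the fitters: from a person-period table the
# outcome's at-risk rows become (year, year+1] episodes; a plain data frame
# with tstart/tstop/event columns is passed through.
extract_episodes <- function(table, outcome) {
  if (all(c("tstart", "tstop", "event") %in% names(table))) {
    mf <- if ("female" %in% names(table)) table else
      tryCatch(model_frame(table), error = function(e) table)
    return(list(start = as.numeric(table$tstart), stop = as.numeric(table$tstop),
                event = as.integer(table$event),
                id = if (!is.null(table$id)) table$id else seq_len(nrow(table)),
                mf = mf))
  }
  arc <- paste0("at_risk_", outcome)
  evc <- paste0("event_", outcome)
  if (!all(c(arc, evc, "year") %in% names(table))) {
    stop("table must be a person_period_table or supply tstart/tstop/event",
         call. = FALSE)
  }
  rows <- table[table[[arc]] == 1L, , drop = FALSE]
  list(start = as.numeric(rows$year), stop = as.numeric(rows$year) + 1,
       event = as.integer(rows[[evc]]), id = rows$id, mf = model_frame(rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the AFT family by AIC
#'
#' Fits all four families and returns the minimum-AIC fit; exact ties are
#' broken by simplicity: exponential, then weibull, log-logistic,
#' log-normal.
#'
#' @inheritParams fit_aft
#' @param verbose Print the per-family AIC table.
#' @return The winning `"aft_fit"`, with the AIC table in attribute
#'   `"aic_table"`.
#' @export
select_family <- function(table, outcome, terms = list(),
                          timing = c("interval", "exact"), verbose = FALSE) {
  timing <- match.arg(timing)
  fams <- aft_families()
  fits <- lapply(fams, function(fm) {
    tryCatch(fit_aft(table, outcome, fm, terms, timing = timing),
             error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) {
    stop("all families failed for outcome '", outcome, "': ",
         paste(vapply(fits, conditionMessage, character(1)), collapse = " | "),
         call. = FALSE)
  }
  aics <- ifelse(ok, vapply(fits, function(f) if (inherits(f, "aft_fit")) f$aic
                            else Inf, numeric(1)), Inf)
  tab <- data.frame(family = fams, aic = aics, converged = ok)
  if (verbose) print(tab)
  best <- which(aics == min(aics))[1L]   # fams ordered simplest-first
  out <- fits[[best]]
  attr(out, "aic_table") <- tab
  out
}

#' Backwards selection by AIC
#'
#' Iteratively removes the term whose removal most decreases AIC, until no
#' removal decreases it. A variable's spline pair (linear + nonlinear) is
#' droppable as a unit; the nonlinear component alone is also a candidate
#' (demoting the variable to linear).
#'
#' @param fit A fitted `"aft_fit"`.
#' @param table The data the model was fitted on.
#' @return An `"aft_fit"` for the selected model (possibly `fit` unchanged).
#' @export
backwards_select <- function(fit, table) {
  stopifnot(inherits(fit, "aft_fit"))
  current <- fit
  repeat {
    terms <- current$terms
    if (!length(terms)) return(current)
    vars <- vapply(terms, function(tm) tm$variable, character(1))
    trans <- vapply(terms, function(tm) tm$transform, character(1))
    candidates <- list()
    for (v in unique(vars)) {
      idx <- which(vars == v)
      candidates <- c(candidates, list(setdiff(seq_along(terms), idx)))
      nl <- idx[trans[idx] == "spline_nonlinear"]
      if (length(nl) && length(idx) > length(nl)) {
        candidates <- c(candidates, list(setdiff(seq_along(terms), nl)))
      }
    }
    refits <- lapply(candidates, function(keep) {
      tryCatch(fit_aft(table, current$outcome, current$family, terms[keep],
                       timing = current$timing),
               error = function(e) NULL)
    })
    aics <- vapply(refits, function(f) if (is.null(f)) Inf else f$aic, numeric(1))
    if (!length(aics) || min(aics) >= current$aic) return(current)
    current <- refits[[which.min(aics)]]
  }
}

#' Bootstrap the risk-equation coefficients
#'
#' Second-order (parameter) uncertainty: individuals are resampled with
#' replacement — each resampled individual brings all their person-periods —
#' and the equation is refitted on each replicate.
#'
#' @inheritParams fit_aft
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the replicate set is reproducible given it.
#' @param resample_fn Advanced: function(ids) returning the resampled id
#'   vector; defaults to sampling with replacement. Passing `identity`
#'   reproduces the original fit (used in tests).
#' @return List of [risk_equation()] objects (one per converged replicate);
#'   attribute `"n_dropped"` counts non-converged replicates.
#' @export
bootstrap_coefficients <- function(table, outcome, family, terms = list(),
                                   B = 100L, seed = 1L,
                                   timing = c("interval", "exact"),
                                   resample_fn = NULL) {
  timing <- match.arg(timing)
  stopifnot(B >= 1L)
  set.seed(seed)
  ids <- unique(table$id)
  if (is.null(resample_fn)) {
    resample_fn <- function(x) sample(x, length(x), replace = TRUE)
  }
  out <- vector("list", B)
  dropped <- 0L
  for (b in seq_len(B)) {
    take <- resample_fn(ids)
    boot <- resample_individuals(table, take)
    f <- tryCatch(fit_aft(boot, outcome, family, terms, timing = timing),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) dropped <- dropped + 1L
    else out[[b]] <- f$equation
  }
  out <- Filter(Negate(is.null), out)
  attr(out, "n_dropped") <- dropped
  out
}

# Stack the person-periods of each (possibly repeated) resampled id, giving
# each copy a fresh id so downstream grouping stays correct.
resample_individuals <- function(table, take) {
  idx <- split(seq_len(nrow(table)), table$id)
  pieces <- lapply(seq_along(take), function(j) {
    rows <- table[idx[[as.character(take[j])]], , drop = FALSE]
    rows$id <- paste0("b", j)
    rows
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- class(table)
  out
}

#' Predicted cumulative event risk at a horizon
#'
#' `1 - S(horizon | eta(state))` for each row of `state`.
#'
#' @param eq A [risk_equation()] (or an `"aft_fit"`, whose equation is used).
#' @param state Cohort or design-variable data frame.
#' @param horizon Years (> 0).
#' @return Risk in `[0, 1]` per row.
#' @export
predict_risk <- function(eq, state, horizon = 10) {
  if (inherits(eq, "aft_fit")) eq <- eq$equation
  stopifnot(horizon > 0)
  eta <- linear_predictor(state, eq)
  1 - aft_survival(eq$family, eta, eq$scale, horizon)
}

#' Optimism-corrected Harrell's C and Brier score
#'
#' Harrell's bootstrap optimism procedure at a fixed horizon: the apparent
#' statistics come from evaluating the model on its own development data;
#' for each bootstrap replicate the equation is refitted on the resampled
#' individuals and the optimism is (performance on the bootstrap sample)
#' minus (performance of the bootstrap model on the original data);
#' corrected = apparent - mean optimism. The Brier score compares predicted
#' and observed cumulative incidence at the horizon among individuals with
#' an event by the horizon or follow-up reaching it.
#'
#' @inheritParams fit_aft
#' @param B Bootstrap replicates (default 100); `B = 0` returns the
#'   apparent values.
#' @param horizon Evaluation horizon in years (default 10).
#' @param seed Integer seed for the bootstrap.
#' @return List: `c_apparent`, `c_corrected`, `brier_apparent`,
#'   `brier_corrected`, `optimism_c`, `optimism_brier`, `B_used`.
#' @export
optimism_corrected_c <- function(table, outcome, family, terms = list(),
                                 B = 100L, horizon = 10, seed = 1L,
                                 timing = c("interval", "exact")) {
  timing <- match.arg(timing)
  ep <- extract_episodes(table, outcome)
  if (sum(ep$event) < 5L) {
    stop("outcome '", outcome, "' has fewer than 5 events; ",
         "discrimination statistics would be unstable", call. = FALSE)
  }
  fit0 <- fit_aft(table, outcome, family, terms, timing = timing)

  stats0 <- horizon_stats(fit0$equation, table, outcome, horizon)
  if (B == 0L) {
    return(list(c_apparent = stats0$c, c_corrected = stats0$c,
                brier_apparent = stats0$brier, brier_corrected = stats0$brier,
                optimism_c = 0, optimism_brier = 0, B_used = 0L))
  }
  set.seed(seed)
  ids <- unique(table$id)
  opt_c <- opt_b <- numeric(0)
  for (b in seq_len(B)) {
    boot <- resample_individuals(table, sample(ids, length(ids), replace = TRUE))
    fb <- tryCatch(fit_aft(boot, outcome, family, terms, timing = timing),
                   error = function(e) NULL)
    if (is.null(fb)) next
    sb <- tryCatch(horizon_stats(fb$equation, boot, outcome, horizon),
                   error = function(e) NULL)
    so <- tryCatch(horizon_stats(fb$equation, table, outcome, horizon),
                   error = function(e) NULL)
    if (is.null(sb) || is.null(so)) next
    opt_c <- c(opt_c, sb$c - so$c)
    opt_b <- c(opt_b, sb$brier - so$brier)
  }
  list(c_apparent = stats0$c,
       c_corrected = stats0$c - mean(opt_c),
       brier_apparent = stats0$brier,
       brier_corrected = stats0$brier - mean(opt_b),
       optimism_c = mean(opt_c), optimism_brier = mean(opt_b),
       B_used = length(opt_c))
}

# Per-individual follow-up summary for one outcome from an episode set:
# time = end of last at-risk episode, event = event in it; risk score from
# the first episode's covariates.
horizon_stats <- function(eq, table, outcome, horizon) {
  ep <- extract_episodes(table, outcome)
  o <- order(ep$id, ep$stop)
  id <- ep$id[o]
  last <- !duplicated(id, fromLast = TRUE)
  first <- !duplicated(id)
  times <- ep$stop[o][last]
  events <- ep$event[o][last]
  scores <- predict_risk(eq, ep$mf[o, , drop = FALSE][first, , drop = FALSE],
                         horizon)
  cstat <- harrell_c(times, events, scores, B = 0L)$c
  evaluable <- (events == 1L & times <= horizon) | times >= horizon
  obs <- as.numeric(events == 1L & times <= horizon)[evaluable]
  list(c = cstat, brier = mean((scores[evaluable] - obs)^2))
}
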