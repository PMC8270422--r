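# Discrimination and calibration battery: Harrell's C with bootstrap CI,
# calibration slope/intercept by risk deciles with the small-count
# regrouping rule, Brier score, RMSPE, R-squared about the identity line,
# and the multi-model comparison report.

#' Harrell's C-statistic for survival data
#'
#' Concordance over usable pairs: a pair is usable iff one follow-up time is
#' strictly shorter and that shorter time ended in an event; the pair is
#' concordant when the shorter-time individual has the higher risk score.
#' Ties in score count 0.5. The confidence interval is a percentile
#' bootstrap over individuals.
#'
#' @param times Follow-up times.
#' @param events 0/1 event indicators.
#' @param scores Predicted risk scores (higher = higher risk).
#' @param B Bootstrap replicates for the CI (default 100; `B = 0` skips it).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return List: `c`, `ci` (length-2 or `NULL`), `n_pairs` (usable pairs).
#' @export
harrell_c <- function(times, events, scores, B = 100L, conf = 0.95, seed = 1L) {
  stopifnot(length(times) == length(events), length(times) == length(scores))
  res <- concordance_counts(times, events, scores)
  if (res$usable < 1) {
    stop("no usable pairs (need an event with another individual at risk ",
         "beyond it)", call. = FALSE)
  }
  cstat <- res$concordant / res$usable
  ci <- NULL
  if (B > 0L) {
    set.seed(seed)
    n <- length(times)
    cb <- vapply(seq_len(B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      r <- concordance_counts(times[i], events[i], scores[i])
      if (r$usable < 1) NA_real_ else r$concordant / r$usable
    }, numeric(1))
    cb <- cb[!is.na(cb)]
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(cb, c(a, 1 - a), type = 7))
  }
  list(c = cstat, ci = ci, n_pairs = res$usable)
}

# O(E * n) vectorized pair counting: loop only over event subjects.
concordance_counts <- function(times, events, scores) {
  ev <- which(events == 1)
  concordant <- 0
  usable <- 0
  for (i in ev) {
    longer <- times > times[i]
    m <- sum(longer)
    if (!m) next
    usable <- usable + m
    concordant <- concordant + sum(scores[i] > scores[longer]) +
      0.5 * sum(scores[i] == scores[longer])
  }
  list(concordant = concordant, usable = usable)
}

#' Calibration slope and intercept by risk groups
#'
#' Individuals are grouped into quantiles of predicted risk, starting at 10
#' groups (deciles); while any group has fewer than 5 observed events and
#' more than 3 groups remain, the number of groups is reduced by one and the
#' grouping redone (3 groups is the floor). The slope and intercept come
#' from an OLS line of observed event proportion on mean predicted risk
#' across groups (ideal slope 1, intercept 0).
#'
#' @param predicted Predicted risks in `[0, 1]`.
#' @param observed 0/1 observed event indicators at the same horizon.
#' @return Object of class `"calibration_table"`: `groups` data frame
#'   (`mean_predicted`, `observed_proportion`, `n`, `events`), `g`, `slope`,
#'   `intercept`.
#' @export
calibration <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  if (length(predicted) < 30L) {
    stop("calibration needs at least 30 individuals", call. = FALSE)
  }
  if (sum(observed) < 5L) {
    stop("fewer than 5 total events; calibration is not estimable", call. = FALSE)
  }
  g <- 10L
  repeat {
    grp <- quantile_groups(predicted, g)
    ev <- tapply(observed, grp, sum)
    if (all(ev >= 5L) || g <= 3L) break
    g <- g - 1L
  }
  tab <- data.frame(
    mean_predicted = as.numeric(tapply(predicted, grp, mean)),
    observed_proportion = as.numeric(tapply(observed, grp, mean)),
    n = as.integer(table(grp)),
    events = as.integer(tapply(observed, grp, sum))
  )
  line <- stats::lm(observed_proportion ~ mean_predicted, data = tab)
  structure(list(groups = tab, g = g,
                 slope = unname(stats::coef(line)[2L]),
                 intercept = unname(stats::coef(line)[1L])),
            class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("Calibration: %d groups, slope %.3f, intercept %.4f\n",
              x$g, x$slope, x$intercept))
  print(x$groups, digits = 4)
  invisible(x)
}

# Quantile grouping robust to heavy ties: rank-based cut into g groups.
quantile_groups <- function(x, g) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * g / length(x)))
}

#' Brier score at a fixed horizon
#'
#' Mean squared difference between predicted risk and observed 0/1 status.
#'
#' @inheritParams calibration
#' @return Numeric scalar.
#' @export
brier_score <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  mean((predicted - observed)^2)
}

#' Root mean square percentage error between endpoint percentages
#'
#' `sqrt(mean((pred - obs)^2))` with both vectors on the percentage scale,
#' so the result is in percentage points (absolute mode, the default). The
#' relative mode divides each error by the observed value first.
#'
#' @param predicted,observed Paired endpoint percentages, equal length >= 1.
#' @param mode `"absolute"` (percentage points) or `"relative"`.
#' @return Numeric scalar.
#' @export
rmspe <- function(predicted, observed, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have the same length", call. = FALSE)
  }
  if (length(predicted) < 1L) stop("need at least one pair", call. = FALSE)
  err <- predicted - observed
  if (mode == "relative") {
    if (any(observed == 0)) stop("relative mode needs nonzero observed values",
                                 call. = FALSE)
    err <- err / observed
  }
  sqrt(mean(err^2))
}

#' Coefficient of determination about the identity line
#'
#' `1 - SSres / SStot` where residuals are taken against the identity
#' (predicted-versus-observed scatter), not a refitted line.
#'
#' @inheritParams rmspe
#' @return Numeric scalar (can be negative for poor predictions).
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have the same length", call. = FALSE)
  }
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) stop("observed values have zero variance", call. = FALSE)
  1 - sum((observed - predicted)^2) / sstot
}

#' Multi-model validation report
#'
#' Builds a comparison table across models supplied as per-individual
#' predicted risks: per model and outcome, Harrell's C (with CI) and
#' calibration slope/intercept; per model, RMSPE and R-squared over the
#' endpoint percentages. External models' predictions are ingested as data
#' frames (for example read from CSV) — this package does not reimplement
#' them.
#'
#' @param observed Data frame with columns `id`, and per outcome
#'   `time_<outcome>` (follow-up time) and `event_<outcome>` (0/1).
#' @param predictions Named list of data frames, one per model, each with
#'   `id` and one risk column per predicted outcome, named by outcome.
#'   Outcomes missing from a model are reported as missing cells.
#' @param horizon Evaluation horizon in years (default 10).
#' @param ci_B Bootstrap replicates for the C-statistic CI.
#' @param rmspe_mode Passed to [rmspe()].
#' @return List: `by_outcome` data frame (model, outcome, c, c_lo, c_hi,
#'   slope, intercept), `by_model` data frame (model, rmspe, r_squared).
#' @export
compare_models <- function(observed, predictions, horizon = 10, ci_B = 100L,
                           rmspe_mode = c("absolute", "relative")) {
  rmspe_mode <- match.arg(rmspe_mode)
  stopifnot(is.list(predictions), length(predictions) >= 1L,
            !is.null(names(predictions)))
  outcomes <- sub("^event_", "", grep("^event_", names(observed), value = TRUE))
  rows <- list(); summ <- list()
  for (mname in names(predictions)) {
    pred <- predictions[[mname]]
    missing_ids <- setdiff(observed$id, pred$id)
    if (length(missing_ids)) {
      stop("model '", mname, "' lacks predictions for id(s): ",
           paste(utils::head(missing_ids, 10L), collapse = ", "),
           if (length(missing_ids) > 10L) " ...", call. = FALSE)
    }
    pred <- pred[match(observed$id, pred$id), , drop = FALSE]
    pct_pred <- pct_obs <- numeric(0)
    for (oc in outcomes) {
      tcol <- paste0("time_", oc); ecol <- paste0("event_", oc)
      if (!oc %in% names(pred)) {
        rows[[length(rows) + 1L]] <- data.frame(
          model = mname, outcome = oc, c = NA_real_, c_lo = NA_real_,
          c_hi = NA_real_, slope = NA_real_, intercept = NA_real_)
        next
      }
      times <- observed[[tcol]]; events <- observed[[ecol]]
      risks <- pred[[oc]]
      hc <- harrell_c(times, events, risks, B = ci_B)
      evaluable <- (events == 1 & times <= horizon) | times >= horizon
      obs01 <- as.numeric(events == 1 & times <= horizon)[evaluable]
      cal <- tryCatch(calibration(risks[evaluable], obs01),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        model = mname, outcome = oc, c = hc$c,
        c_lo = if (is.null(hc$ci)) NA_real_ else hc$ci[1L],
        c_hi = if (is.null(hc$ci)) NA_real_ else hc$ci[2L],
        slope = if (is.null(cal)) NA_real_ else cal$slope,
        intercept = if (is.null(cal)) NA_real_ else cal$intercept)
      pct_pred <- c(pct_pred, 100 * mean(risks[evaluable]))
      pct_obs <- c(pct_obs, 100 * mean(obs01))
    }
    summ[[length(summ) + 1L]] <- data.frame(
      model = mname,
      rmspe = if (length(pct_pred)) rmspe(pct_pred, pct_obs, rmspe_mode)
              else NA_real_,
      r_squared = if (length(pct_pred) >= 2L)
        tryCatch(r_squared(pct_pred, pct_obs), error = function(e) NA_real_)
        else NA_real_)
  }
  list(by_outcome = do.call(rbind, rows), by_model = do.call(rbind, summ))
}
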