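# Spline basis, AFT linear predictors, the four parametric survival
# functions, and the conversion to annual event probabilities used by the
# discrete-time engine.

#' Nonlinear component of a 3-knot restricted cubic spline
#'
#' Harrell (rms-convention) normalization: with knots `k1 < k2 < k3`,
#' \deqn{[(x-k_1)_+^3 - (x-k_2)_+^3 (k_3-k_1)/(k_3-k_2)
#'       + (x-k_3)_+^3 (k_2-k_1)/(k_3-k_2)] / (k_3-k_1)^2.}
#' Zero for `x <= k1` and linear in `x` beyond `k3`, so a continuous
#' variable enters an equation as its raw value plus this one nonlinear
#' basis column.
#'
#' @param x Numeric vector.
#' @param knots Three strictly ascending knots.
#' @return Numeric vector, same length as `x`.
#' @export
rcs_nonlinear <- function(x, knots) {
  if (length(knots) != 3L || !all(diff(knots) > 0)) {
    stop("knots must be 3 strictly ascending values", call. = FALSE)
  }
  k1 <- knots[1L]; k2 <- knots[2L]; k3 <- knots[3L]
  cub <- function(u) pmax(u, 0)^3
  (cub(x - k1) - cub(x - k2) * (k3 - k1) / (k3 - k2) +
      cub(x - k3) * (k2 - k1) / (k3 - k2)) / (k3 - k1)^2
}

#' AFT linear predictor for a risk equation
#'
#' Computes `eta = intercept + sum_j beta_j * transform_j(x_j)` for each row
#' of a cohort. Categorical cohort columns are first expanded to the design
#' variables via [model_frame()]; a data frame already in design-variable
#' layout is used as-is.
#'
#' @param state Cohort data frame (1 or more rows) or a design-variable
#'   data frame from [model_frame()].
#' @param eq A [risk_equation()].
#' @return Numeric vector of linear predictors, one per row.
#' @export
linear_predictor <- function(state, eq) {
  mf <- if ("female" %in% names(state)) state else model_frame(state)
  eta <- rep(eq$intercept, nrow(mf))
  for (tm in eq$terms) {
    if (is.null(mf[[tm$variable]])) {
      stop("state is missing covariate '", tm$variable,
           "' required by the ", eq$outcome, " equation", call. = FALSE)
    }
    x <- as.numeric(mf[[tm$variable]])
    v <- if (tm$transform == "spline_nonlinear") rcs_nonlinear(x, tm$knots) else x
    eta <- eta + tm$coefficient * v
  }
  eta
}

#' Parametric AFT survival function
#'
#' `S(t)` for the four supported families, parameterized on the log-time
#' scale: with `w = (log t - eta) / sigma`, weibull `exp(-exp(w))`
#' (exponential is weibull with sigma = 1), log-logistic `1/(1 + exp(w))`,
#' log-normal `1 - Phi(w)`. `S(0) = 1` for every family.
#'
#' @param family One of [aft_families()].
#' @param eta Linear predictor(s) on the log-time scale.
#' @param sigma Scale parameter (> 0; ignored and fixed at 1 for
#'   exponential).
#' @param t Time(s) >= 0 in years. `eta` and `t` recycle against each other.
#' @return Survival probabilities in `[0, 1]`.
#' @export
aft_survival <- function(family, eta, sigma, t) {
  family <- match.arg(family, aft_families())
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (family == "exponential") sigma <- 1
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  n <- max(length(eta), length(t))
  eta <- rep_len(eta, n); t <- rep_len(t, n)
  s <- numeric(n)
  pos <- t > 0
  if (any(pos)) {
    w <- (log(t[pos]) - eta[pos]) / sigma
    s[pos] <- switch(family,
      exponential = ,
      weibull = exp(-exp(w)),
      loglogistic = 1 / (1 + exp(w)),
      lognormal = stats::pnorm(w, lower.tail = FALSE))
  }
  s[!pos] <- 1
  s
}

# log S(t); exact at t = 0 and numerically stable in the tails.
aft_log_survival <- function(family, eta, sigma, t) {
  n <- max(length(eta), length(t))
  eta <- rep_len(eta, n); t <- rep_len(t, n)
  ls <- numeric(n)
  pos <- t > 0
  if (any(pos)) {
    w <- (log(t[pos]) - eta[pos]) / sigma
    ls[pos] <- switch(family,
      exponential = ,
      weibull = -exp(w),
      loglogistic = -log1p(exp(w)),
      lognormal = stats::pnorm(w, lower.tail = FALSE, log.p = TRUE))
  }
  ls
}

# log f(t) for the event-episode likelihood contribution.
aft_log_density <- function(family, eta, sigma, t) {
  w <- (log(t) - eta) / sigma
  base <- -log(sigma) - log(t)
  base + switch(family,
    exponential = ,
    weibull = w - exp(w),
    loglogistic = w - 2 * log1p(exp(w)),
    lognormal = stats::dnorm(w, log = TRUE))
}

#' Annual event probability from a risk equation
#'
#' Discrete-time embedding of the continuous AFT model: the probability of
#' the event in cycle `[u, u+1)` conditional on being event-free at `u`,
#' with covariates frozen at their cycle-start values,
#' `p = 1 - S(u + 1 | eta) / S(u | eta)`.
#'
#' @param eq A [risk_equation()].
#' @param state Cohort or design-variable data frame (vectorized over rows).
#' @param u Integer years since enrollment (cycle start), >= 0; recycled
#'   against rows of `state`.
#' @return Probabilities in `[0, 1]`. If `S(u)` underflows to zero the
#'   probability is floored to 1 with a warning.
#' @export
annual_event_probability <- function(eq, state, u) {
  if (any(u < 0)) stop("u must be >= 0", call. = FALSE)
  eta <- linear_predictor(state, eq)
  ls_u <- aft_log_survival(eq$family, eta, eq$scale, u)
  ls_u1 <- aft_log_survival(eq$family, eta, eq$scale, u + 1)
  p <- -expm1(ls_u1 - ls_u)
  dead_scale <- !is.finite(ls_u) | exp(ls_u) == 0
  if (any(dead_scale)) {
    warning("S(u) underflowed to 0 for ", sum(dead_scale),
            " individual(s); annual probability floored to 1", call. = FALSE)
    p[dead_scale] <- 1
  }
  pmin(pmax(p, 0), 1)
}
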