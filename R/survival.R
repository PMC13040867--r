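#' Gompertz survival with a cure plateau
#'
#' Survival function `S(t) = exp(-(rate/shape) * (exp(shape * t) - 1))` with
#' time in weeks. A negative shape gives a hazard decaying to zero, so the
#' survival curve plateaus at `exp(rate/shape)`: the cure fraction used for
#' event-free survival extrapolation. Shapes within `1e-8` of zero are
#' evaluated through the exponential limit `exp(-rate * t)` to avoid 0/0.
#'
#' @param t Time in weeks, non-negative, vectorised.
#' @param shape Gompertz shape per week (may be negative).
#' @param rate Gompertz rate per week, non-negative.
#' @return Survival probabilities.
#' @export
#' @examples
#' gompertz_survival(0:5, shape = -0.02525, rate = 0.02062)
gompertz_survival <- function(t, shape, rate) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (rate < 0) stop("`rate` must be non-negative", call. = FALSE)
  if (abs(shape) < 1e-8) {
    # first-order series in shape, exact at shape = 0
    return(exp(-rate * t * (1 + shape * t / 2)))
  }
  exp(-(rate / shape) * expm1(shape * t))
}

#' Cure fraction implied by a Gompertz fit
#'
#' `exp(rate/shape)` for negative shapes, 0 otherwise.
#'
#' @inheritParams gompertz_survival
#' @return Plateau survival probability in \[0, 1\].
#' @export
gompertz_cure_fraction <- function(shape, rate) {
  if (shape < 0) exp(rate / shape) else 0
}

#' Per-cycle event probability from a Gompertz curve
#'
#' Conditional probability of an event during cycle `k` (weeks `k` to
#' `k + 1`) given event-free at `k`: `q_k = 1 - S(k+1)/S(k)`.
#'
#' @inheritParams gompertz_survival
#' @param k Cycle index (0-based), vectorised.
#' @return Probabilities in \[0, 1\].
#' @export
gompertz_cycle_prob <- function(shape, rate, k) {
  if (any(k < 0)) stop("`k` must be non-negative", call. = FALSE)
  if (rate < 0) stop("`rate` must be non-negative", call. = FALSE)
  # cumulative-hazard increment over [k, k+1], written without cancellation:
  # H(k+1) - H(k) = (rate/shape) * exp(shape k) * (exp(shape) - 1)
  dH <- if (abs(shape) < 1e-8) {
    rep(rate, length(k))
  } else {
    (rate / shape) * exp(shape * k) * expm1(shape)
  }
  if (any(!is.finite(dH))) {
    stop("survival is degenerate within the requested cycles", call. = FALSE)
  }
  -expm1(-dH)
}

#' Apply a proportional hazard to a Gompertz curve
#'
#' Under proportional hazards the Gompertz family is closed: multiplying the
#' rate by the hazard ratio gives `S_new(t) = S_old(t)^hr` exactly, with the
#' shape (and hence the hazard's time course) unchanged.
#'
#' @param shape,rate Gompertz parameters per week.
#' @param hr Hazard ratio, > 0.
#' @return Named numeric vector `c(shape =, rate =)`.
#' @export
apply_hazard_ratio <- function(shape, rate, hr) {
  if (!is.finite(hr) || hr <= 0) stop("`hr` must be positive", call. = FALSE)
  c(shape = shape, rate = rate * hr)
}

#' Weekly transition probability from an exponential rate
#'
#' @param rate Non-negative weekly rate.
#' @return `1 - exp(-rate)`.
#' @export
exp_rate_to_weekly_prob <- function(rate) {
  if (any(rate < 0)) stop("`rate` must be non-negative", call. = FALSE)
  -expm1(-rate)
}

#' Fit a parametric survival model to (pseudo) individual-patient data
#'
#' Maximum-likelihood fit of a Gompertz, exponential or Weibull model via
#' [flexsurv::flexsurvreg()], returning the natural-scale estimates, their
#' observed-information covariance, the log-likelihood and the BIC
#' (`-2 loglik + k log(n)` with `n` the number of subjects).
#'
#' @param ipd Data frame with columns `time_weeks` (>= 0) and `event`
#'   (1 = event, 0 = censored).
#' @param family One of `"gompertz"`, `"exponential"`, `"weibull"`.
#' @return List with elements `family`, `params` (named vector), `vcov`
#'   (natural-scale covariance), `loglik`, `bic`, `n`, `n_events` and `fit`
#'   (the underlying `flexsurvreg` object).
#' @export
fit_parametric <- function(ipd, family = c("gompertz", "exponential", "weibull")) {
  family <- match.arg(family)
  stopifnot(all(c("time_weeks", "event") %in% names(ipd)))
  if (any(ipd$time_weeks < 0)) stop("event times must be non-negative", call. = FALSE)
  n_events <- sum(ipd$event == 1)
  if (n_events < 10) {
    stop(sprintf("need at least 10 events to fit, got %d", n_events), call. = FALSE)
  }
  dist <- switch(family, gompertz = "gompertz", exponential = "exp",
                 weibull = "weibull")
  fit <- tryCatch(
    flexsurv::flexsurvreg(
      survival::Surv(time_weeks, event) ~ 1, data = ipd, dist = dist),
    error = function(e) stop("parametric fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  est <- fit$res[, "est"]
  k <- length(est)
  n <- nrow(ipd)
  # delta-method covariance on the natural scale
  vc <- tryCatch({
    tr <- vapply(seq_len(k), function(i) {
      inv <- fit$dlist$inv.transforms[[i]]
      # derivative of the inverse transform at the working-scale estimate
      x <- fit$res.t[i, "est"]
      if (identical(inv, exp)) exp(x) else 1
    }, numeric(1))
    diag(tr, k) %*% fit$cov %*% diag(tr, k)
  }, error = function(e) matrix(NA_real_, k, k))
  dimnames(vc) <- list(names(est), names(est))
  list(family = family, params = est, vcov = vc,
       loglik = fit$loglik, bic = -2 * fit$loglik + k * log(n),
       n = n, n_events = n_events, fit = fit)
}

#' Select a survival family by BIC
#'
#' Minimal BIC wins; exact ties go to the family with fewer parameters.
#'
#' @param fits List of results from [fit_parametric()] on the same data.
#' @return The name of the selected family.
#' @export
select_by_bic <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits to compare", call. = FALSE)
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  npar <- vapply(fits, function(f) length(f$params), integer(1))
  ord <- order(bic, npar)
  fits[[ord[1]]]$family
}

#' Reconstruct pseudo individual-patient data from Kaplan-Meier coordinates
#'
#' Inverts the product-limit estimate interval by interval. With a
#' numbers-at-risk table, events at each published time are
#' `round(n_i * (1 - S_i / S_{i-1}))` and the risk-set deficit to the next
#' interval is attributed to censoring at the interval midpoint. Without a
#' risk table, no within-follow-up censoring is assumed and survivors are
#' administratively censored at the last published time. This is the
#' single-interval special case of the published reconstruction algorithm,
#' sufficient for curves with risk-set counts at every coordinate.
#'
#' @param km_points Data frame with columns `time_weeks` (non-decreasing,
#'   starting at 0) and `survival` (non-increasing, starting at 1).
#' @param n_at_risk Optional data frame with columns `time_weeks` and
#'   `n_at_risk` aligned with `km_points`.
#' @param n Initial cohort size; required when `n_at_risk` is absent.
#' @return Data frame with columns `time_weeks` and `event` (1/0), whose
#'   Kaplan-Meier estimate matches the input within 1/n at each input time.
#' @export
reconstruct_ipd <- function(km_points, n_at_risk = NULL, n = NULL) {
  stopifnot(all(c("time_weeks", "survival") %in% names(km_points)))
  tt <- km_points$time_weeks
  ss <- km_points$survival
  if (is.unsorted(tt)) stop("KM times must be non-decreasing", call. = FALSE)
  if (any(diff(ss) > 1e-12)) {
    stop("KM survival must be non-increasing", call. = FALSE)
  }
  if (tt[1] != 0 || abs(ss[1] - 1) > 1e-12) {
    stop("KM input must start at (time 0, survival 1)", call. = FALSE)
  }
  if (is.null(n_at_risk)) {
    if (is.null(n)) stop("supply `n_at_risk` or `n`", call. = FALSE)
    risk <- round(n * ss)
    # events per interval from the marginal survival drop
    times <- c(); events <- c()
    for (i in seq_along(tt)[-1]) {
      d <- round(n * (ss[i - 1] - ss[i]))
      if (d > 0) { times <- c(times, rep(tt[i], d)); events <- c(events, rep(1, d)) }
    }
    surv_left <- n - length(times)
    if (surv_left > 0) {
      times <- c(times, rep(tt[length(tt)], surv_left))
      events <- c(events, rep(0, surv_left))
    }
    return(data.frame(time_weeks = times, event = events))
  }
  stopifnot(all(c("time_weeks", "n_at_risk") %in% names(n_at_risk)))
  nar <- n_at_risk$n_at_risk[match(tt, n_at_risk$time_weeks)]
  if (any(is.na(nar))) stop("`n_at_risk` must cover every KM time", call. = FALSE)
  times <- c(); events <- c()
  alive <- nar[1] # risk set carried forward; totals telescope to nar[1]
  d_prev <- 0
  for (i in seq_along(tt)[-1]) {
    after_prev <- alive - d_prev
    # risk-set deficit between the knots is censoring, placed mid-interval
    cens <- max(0, after_prev - nar[i])
    if (cens > 0) {
      times <- c(times, rep((tt[i - 1] + tt[i]) / 2, cens))
      events <- c(events, rep(0, cens))
    }
    r_i <- after_prev - cens
    # events at t_i happen to the risk set just before the published drop
    d <- max(0, min(round(r_i * (1 - ss[i] / ss[i - 1])), r_i))
    if (d > 0) { times <- c(times, rep(tt[i], d)); events <- c(events, rep(1, d)) }
    alive <- r_i
    d_prev <- d
  }
  tail_n <- alive - d_prev
  if (tail_n > 0) {
    times <- c(times, rep(tt[length(tt)], tail_n))
    events <- c(events, rep(0, tail_n))
  }
  data.frame(time_weeks = times, event = events)
}
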