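#' Simulate individual-patient event-free survival data
#'
#' Draws event times by inverse-transform sampling from a Gompertz survival
#' curve. With a negative shape the curve plateaus at the cure fraction
#' `exp(rate/shape)`; draws landing on the plateau never experience the
#' event and are administratively censored at the end of follow-up. Uniform
#' accrual over `accrual_weeks` shortens each subject's follow-up, emulating
#' staggered trial entry.
#'
#' @param n Number of subjects.
#' @param shape,rate Gompertz parameters per week.
#' @param max_followup_weeks Administrative censoring time from accrual.
#' @param accrual_weeks Width of the uniform accrual window (0 = simultaneous
#'   entry).
#' @param seed Integer seed; the dataset is reproducible given the seed.
#' @return Data frame with columns `time_weeks` and `event` (1/0).
#' @export
#' @examples
#' ipd <- simulate_ipd(500, shape = -0.04236, rate = 0.01408, seed = 1)
#' mean(ipd$event)
simulate_ipd <- function(n, shape, rate, max_followup_weeks = 260,
                         accrual_weeks = 0, seed = 1L) {
  stopifnot(n > 0, max_followup_weeks > 0, accrual_weeks >= 0, rate >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  u <- stats::runif(n)
  followup <- max_followup_weeks - stats::runif(n, 0, accrual_weeks)
  event_time <- gompertz_quantile_from_survival(u, shape, rate)
  time <- pmin(event_time, followup)
  data.frame(time_weeks = time, event = as.integer(event_time <= followup))
}

# Solve S(t) = u for t; Inf where u is below the cure plateau.
gompertz_quantile_from_survival <- function(u, shape, rate) {
  if (rate == 0) return(rep(Inf, length(u)))
  if (abs(shape) < 1e-8) return(-log(u) / rate)
  arg <- 1 - (shape / rate) * log(u)
  t <- rep(Inf, length(u))
  ok <- arg > 0
  t[ok] <- log(arg[ok]) / shape
  t
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic age-indexed background-mortality life table
#'
#' A Gompertz-Makeham annual hazard
#' `h(a) = makeham + base_annual_mortality * 2^((a - reference_age) / doubling_years)`
#' converted to annual probabilities `1 - exp(-h)` and then to weekly
#' probabilities `1 - (1 - q_annual)^(1/52)`. The bundled fixture uses the
#' package defaults; it is a synthetic stand-in with a plausible age
#' gradient, not an official national life table, and any two-column CSV
#' (`age_years`, `weekly_mortality_probability`) can be dropped in instead.
#'
#' @param start_age,end_age Age range in whole years.
#' @param base_annual_mortality Annual Gompertz hazard at `reference_age`.
#' @param doubling_years Years over which the age-dependent hazard doubles.
#' @param makeham Age-independent annual hazard component.
#' @param reference_age Age anchoring `base_annual_mortality`.
#' @return Data frame of class `perio_life_table` with columns `age_years`
#'   and `weekly_mortality_probability`.
#' @export
make_life_table <- function(start_age = 0, end_age = 110,
                            base_annual_mortality = 0.0085,
                            doubling_years = 8, makeham = 0.0005,
                            reference_age = 62) {
  stopifnot(end_age > start_age, doubling_years > 0)
  ages <- seq.int(start_age, end_age)
  h <- makeham + base_annual_mortality * 2^((ages - reference_age) / doubling_years)
  q_annual <- -expm1(-h)
  q_week <- 1 - (1 - q_annual)^(1 / 52)
  lt <- data.frame(age_years = ages, weekly_mortality_probability = q_week)
  class(lt) <- c("perio_life_table", "data.frame")
  lt
}

#' Kaplan-Meier curve and risk table from individual-patient data
#'
#' Product-limit estimate (via [survival::survfit()]) evaluated at the
#' requested grid, with the number at risk at each grid time. The returned
#' coordinates are the fixture input for [reconstruct_ipd()].
#'
#' @param ipd Data frame with columns `time_weeks`, `event`.
#' @param grid_weeks Evaluation times (week 0 is prepended if absent).
#' @return List with data frames `km` (`time_weeks`, `survival`) and
#'   `risk` (`time_weeks`, `n_at_risk`).
#' @export
make_km_points <- function(ipd, grid_weeks) {
  stopifnot(nrow(ipd) > 0)
  grid_weeks <- sort(unique(c(0, grid_weeks)))
  fit <- survival::survfit(survival::Surv(time_weeks, event) ~ 1, data = ipd)
  sm <- summary(fit, times = grid_weeks, extend = TRUE)
  list(
    km = data.frame(time_weeks = grid_weeks, survival = sm$surv),
    risk = data.frame(time_weeks = grid_weeks, n_at_risk = sm$n.risk)
  )
}
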