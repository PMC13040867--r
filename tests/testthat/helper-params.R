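# Shared fixtures. Parameter sets are loaded once per session; the bundled
# configurations warn about the three utility rows whose printed base lies
# outside the printed range, which is expected.
.param_cache <- new.env(parent = emptyenv())

base_params <- function(model_id) {
  key <- paste0("m", model_id)
  if (is.null(.param_cache[[key]])) {
    .param_cache[[key]] <- suppressWarnings(load_parameters(model_id = model_id))
  }
  .param_cache[[key]]
}

# Parameter set with every hazard and background mortality switched off:
# the cohort stays event-free, so scheduled costs accrue in full.
inert_params <- function(model_id, discount = 0) {
  ps <- base_params(model_id)
  ps$settings$discount_rate_annual <- discount
  zero <- grep("^(tp_|met_pfs_rate|met_os_rate)", names(ps$params), value = TRUE)
  ps <- set_param_values(ps, stats::setNames(rep(0, length(zero)), zero))
  gomp <- grep("^gomp_rate_", names(ps$params), value = TRUE)
  ps <- set_param_values(ps, stats::setNames(rep(0, length(gomp)), gomp))
  ps$life_table$weekly_mortality_probability[] <- 0
  ps
}

fake_trace <- function(total_cost, qaly, arm_id = "arm") {
  structure(list(
    arm_id = arm_id, subgroup = "aggregate",
    cost = c(neoadjuvant = 0, surgery = 0, adjuvant = 0,
             before_recurrence = 0, after_recurrence = total_cost),
    total_cost = total_cost, qaly = qaly, ly_disc = qaly, ly_undisc = qaly,
    met_entrants = 0), class = "perio_trace")
}

# Hand-written Gompertz log-likelihood: the independent cross-check for the
# flexsurv-backed fitting route.
gompertz_loglik <- function(shape, rate, time, event) {
  h <- log(rate) + shape * time
  cumh <- if (abs(shape) < 1e-8) rate * time else (rate / shape) * expm1(shape * time)
  sum(event * h) - sum(cumh)
}
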