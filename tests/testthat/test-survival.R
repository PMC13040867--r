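# The four published Gompertz event-free-survival fits (weekly time unit).
gomp_pairs <- list(
  adj_nivo_mut = c(shape = -0.02525, rate = 0.02062),
  adj_nivo_wt = c(shape = -0.01980, rate = 0.01373),
  perio_pembro = c(shape = -0.04236, rate = 0.01408),
  adj_pembro = c(shape = -0.01515, rate = 0.01392)
)

test_that("Gompertz survival starts at 1, is non-increasing and plateaus at the cure fraction", {
  for (p in gomp_pairs) {
    s <- gompertz_survival(0:2080, p[["shape"]], p[["rate"]])
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 0))
    plateau <- exp(p[["rate"]] / p[["shape"]])
    expect_true(all(s >= plateau - 1e-12))
    # numerical evaluation far in the tail vs the closed-form plateau
    expect_equal(gompertz_survival(1e6, p[["shape"]], p[["rate"]]), plateau,
                 tolerance = 1e-10)
    expect_equal(gompertz_cure_fraction(p[["shape"]], p[["rate"]]), plateau)
  }
  expect_error(gompertz_survival(-1, -0.02, 0.02), "non-negative")
})

test_that("the shape -> 0 limit is exponential survival", {
  t <- c(0, 1, 10, 100, 520)
  expect_equal(gompertz_survival(t, 1e-12, 0.01), exp(-0.01 * t),
               tolerance = 1e-10)
  expect_equal(gompertz_cure_fraction(0.01, 0.01), 0)
})

test_that("cycle probabilities chain back to the survival curve and decay under cure", {
  for (p in gomp_pairs) {
    q <- gompertz_cycle_prob(p[["shape"]], p[["rate"]], 0:2079)
    expect_true(all(q >= 0 & q <= 1))
    expect_true(all(diff(q) < 0)) # strictly decreasing hazard (shape < 0)
    expect_equal(prod(1 - q), gompertz_survival(2080, p[["shape"]], p[["rate"]]),
                 tolerance = 1e-9)
  }
  p <- gomp_pairs$adj_nivo_mut
  expect_equal(gompertz_cycle_prob(p[["shape"]], p[["rate"]], 0),
               1 - gompertz_survival(1, p[["shape"]], p[["rate"]]))
  expect_equal(gompertz_cycle_prob(-0.02, 0, 0:10), rep(0, 11))
})

test_that("hazard-ratio application scales the rate and powers the survival curve", {
  p <- gomp_pairs$adj_nivo_mut
  expect_equal(apply_hazard_ratio(p[["shape"]], p[["rate"]], 1), p)
  adj <- apply_hazard_ratio(p[["shape"]], p[["rate"]], 0.29)
  expect_equal(adj[["shape"]], -0.02525)
  expect_equal(adj[["rate"]], 0.02062 * 0.29)
  grid <- seq(0, 2080, length.out = 100)
  for (hr in c(0.29, 0.35, 2)) {
    for (p in gomp_pairs[c("adj_nivo_mut", "adj_nivo_wt")]) {
      adj <- apply_hazard_ratio(p[["shape"]], p[["rate"]], hr)
      expect_equal(gompertz_survival(grid, adj[["shape"]], adj[["rate"]]),
                   gompertz_survival(grid, p[["shape"]], p[["rate"]])^hr,
                   tolerance = 1e-12)
    }
  }
  expect_error(apply_hazard_ratio(-0.02, 0.02, 0), "positive")
})

test_that("exponential rates convert to weekly probabilities", {
  expect_equal(exp_rate_to_weekly_prob(0), 0)
  expect_equal(exp_rate_to_weekly_prob(0.00296), 1 - exp(-0.00296),
               tolerance = 1e-12)
  expect_equal(exp_rate_to_weekly_prob(1e6), 1)
  r <- seq(0, 0.1, by = 0.01)
  expect_true(all(diff(exp_rate_to_weekly_prob(r)) > 0))
  expect_error(exp_rate_to_weekly_prob(-0.1), "non-negative")
})

test_that("maximum-likelihood fitting recovers generating Gompertz parameters", {
  p <- gomp_pairs$perio_pembro
  ipd <- simulate_ipd(2000, p[["shape"]], p[["rate"]], max_followup_weeks = 260,
                      seed = 101)
  fit <- fit_parametric(ipd, "gompertz")
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$params[["shape"]] - p[["shape"]]), 3 * se[["shape"]])
  expect_lt(abs(fit$params[["rate"]] - p[["rate"]]), 3 * se[["rate"]])
  # independent oracle: hand-written Gompertz log-likelihood at the MLE
  expect_equal(fit$loglik,
               gompertz_loglik(fit$params[["shape"]], fit$params[["rate"]],
                               ipd$time_weeks, ipd$event),
               tolerance = 1e-6)
  expect_equal(fit$bic, -2 * fit$loglik + 2 * log(2000))
})

test_that("fitting a Gompertz to exponential data recovers a near-zero shape", {
  set.seed(77)
  ipd <- data.frame(time_weeks = rexp(2000, 0.01), event = 1)
  fit <- fit_parametric(ipd, "gompertz")
  expect_lt(abs(fit$params[["shape"]]), 2 * sqrt(fit$vcov["shape", "shape"]))
})

test_that("fitting requires enough events", {
  ipd <- data.frame(time_weeks = c(5, rep(50, 30)), event = c(1, rep(0, 30)))
  expect_error(fit_parametric(ipd, "gompertz"), "at least 10 events")
})

test_that("parameter recovery bias shrinks with sample size", {
  p <- gomp_pairs$adj_nivo_mut
  bias <- vapply(c(200, 2000, 20000), function(n) {
    ipd <- simulate_ipd(n, p[["shape"]], p[["rate"]], max_followup_weeks = 400,
                        seed = 500 + n)
    fit <- fit_parametric(ipd, "gompertz")
    abs(fit$params[["shape"]] - p[["shape"]]) +
      abs(fit$params[["rate"]] - p[["rate"]])
  }, numeric(1))
  expect_lt(bias[3], bias[1])
})

test_that("BIC selection identifies the generating family", {
  p <- gomp_pairs$adj_pembro
  ipd <- simulate_ipd(2000, p[["shape"]], p[["rate"]], max_followup_weeks = 260,
                      seed = 202)
  fits <- lapply(c("gompertz", "exponential", "weibull"), fit_parametric,
                 ipd = ipd)
  expect_identical(select_by_bic(fits), "gompertz")
  # exponential data: the one-parameter family should win in most replicates
  wins <- vapply(1:20, function(i) {
    set.seed(3000 + i)
    e <- data.frame(time_weeks = rexp(400, 0.01), event = 1)
    select_by_bic(list(fit_parametric(e, "exponential"),
                       fit_parametric(e, "gompertz"))) == "exponential"
  }, logical(1))
  expect_gt(mean(wins), 0.5)
  # exact BIC tie goes to the family with fewer parameters
  tie <- list(list(family = "gompertz", params = c(a = 1, b = 2), bic = 100),
              list(family = "exponential", params = c(a = 1), bic = 100))
  expect_identical(select_by_bic(tie), "exponential")
  expect_error(select_by_bic(tie[1]), "at least two")
})

test_that("pseudo-IPD reconstruction inverts the product-limit estimate", {
  # known 20-subject dataset with events and censoring
  truth <- data.frame(
    time_weeks = c(rep(10, 4), rep(20, 3), rep(25, 2), rep(30, 5), rep(40, 6)),
    event = c(rep(1, 4), rep(1, 3), rep(0, 2), rep(1, 5), rep(0, 6)))
  grid <- c(0, 10, 20, 30, 40)
  km <- make_km_points(truth, grid)
  rec <- reconstruct_ipd(km$km, n_at_risk = km$risk)
  expect_equal(nrow(rec), 20)
  # event counts per published time recovered exactly
  for (tt in c(10, 20, 30)) {
    expect_equal(sum(rec$event == 1 & rec$time_weeks == tt),
                 sum(truth$event == 1 & truth$time_weeks == tt))
  }
  # and the reconstructed KM matches the input within 1/n at each input time
  refit <- survival::survfit(survival::Surv(time_weeks, event) ~ 1, data = rec)
  s_rec <- summary(refit, times = grid, extend = TRUE)$surv
  expect_true(all(abs(s_rec - km$km$survival) <= 1 / 20 + 1e-12))
})

test_that("reconstruction without censoring allocates n * dS events per interval", {
  km <- data.frame(time_weeks = c(0, 10, 20), survival = c(1, 0.75, 0.5))
  rec <- reconstruct_ipd(km, n = 40)
  expect_equal(sum(rec$event == 1 & rec$time_weeks == 10), 10) # 40 * 0.25
  expect_equal(sum(rec$event == 1 & rec$time_weeks == 20), 10)
  expect_equal(sum(rec$event == 0), 20)
})

test_that("degenerate and invalid KM inputs are handled", {
  flat <- data.frame(time_weeks = c(0, 20, 40), survival = c(1, 1, 1))
  rec <- reconstruct_ipd(flat, n = 15)
  expect_true(all(rec$event == 0))
  expect_equal(nrow(rec), 15)
  bad <- data.frame(time_weeks = c(0, 10, 20), survival = c(1, 0.6, 0.7))
  expect_error(reconstruct_ipd(bad, n = 10), "non-increasing")
})
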