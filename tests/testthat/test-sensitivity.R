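draw_many <- function(rec, n, u = NULL) {
  vapply(seq_len(n), function(i) sample_distribution(rec, u = u), numeric(1))
}

test_that("sampling distributions match their moments and respect their supports", {
  set.seed(1)
  n <- 2e4
  beta_rec <- list(name = "p", base = 0.45, low = 0.39, high = 0.66, dist = "beta")
  x <- draw_many(beta_rec, n)
  expect_true(all(x > 0 & x < 1))
  expect_lt(abs(mean(x) - 0.45), 4 * sd(x) / sqrt(n))
  expect_lt(abs(sd(x) - (0.66 - 0.39) / (2 * qnorm(0.975))), 0.01)
  gamma_rec <- list(name = "c", base = 180, low = 144, high = 216, dist = "gamma")
  g <- draw_many(gamma_rec, n)
  expect_true(all(g > 0))
  expect_lt(abs(mean(g) - 180), 4 * sd(g) / sqrt(n))
  disu_rec <- list(name = "d", base = -0.047, low = -0.056, high = -0.038,
                   dist = "beta")
  d <- draw_many(disu_rec, n)
  expect_true(all(d <= 0 & d >= -1))
  expect_lt(abs(mean(d) + 0.047), 4 * sd(d) / sqrt(n))
  hr_rec <- list(name = "hr", base = 1.09, low = 0.68, high = 1.85,
                 dist = "beta-range")
  h <- draw_many(hr_rec, n)
  expect_true(all(h >= 0.68 & h <= 1.85))
  expect_lt(abs(mean(h) - 1.09), 4 * sd(h) / sqrt(n))
  util_rec <- list(name = "u", base = 0.913, low = 0.904, high = 0.920,
                   dist = "beta")
  u <- draw_many(util_rec, n)
  expect_true(all(u > 0 & u <= 1))
  # degenerate range collapses to the base value
  expect_equal(draw_many(list(name = "f", base = 2, low = 2, high = 2,
                              dist = "gamma"), 5), rep(2, 5))
  # infeasible beta moments fall back to a range draw, with a warning
  wide <- list(name = "w", base = 0.5, low = -3, high = 4, dist = "beta")
  expect_warning(w <- sample_distribution(wide), "infeasible")
})

test_that("a shared quantile couples PFS/OS draws comonotonically", {
  ps <- base_params(1)
  set.seed(42)
  viol <- 0
  for (i in 1:200) {
    drawn <- suppressWarnings(sample_parameter_set(ps))
    if (param_value(drawn, "met_pfs_rate_mut") <
          param_value(drawn, "met_os_rate_mut") * 0.95) viol <- viol + 1
  }
  expect_lt(viol / 200, 0.05)
})

test_that("joint draws respect structural constraints", {
  ps <- base_params(1)
  set.seed(7)
  for (i in 1:25) {
    drawn <- suppressWarnings(sample_parameter_set(ps))
    for (grp in c("mut", "wt")) {
      shares <- vapply(paste0("share_", grp, "_", c("dabtram", "nivoipi", "pembro")),
                       function(nm) param_value(drawn, nm), numeric(1))
      expect_equal(sum(shares), 1, tolerance = 1e-12)
    }
    expect_equal(param_value(drawn, "share_wt_dabtram"), 0) # structural zero
    expect_gt(param_value(drawn, "gomp_rate_adj_nivo_mut"), 0)
    expect_true(param_value(drawn, "u_event_free") <= 1)
    expect_true(param_value(drawn, "disu_rash") <= 0)
  }
})

test_that("one-way analysis brackets the base case and matches brute-force evaluation", {
  ps <- base_params(1)
  ow <- suppressWarnings(one_way(ps))
  expect_setequal(ow$parameter, names(ps$params))
  base_nmb <- net_monetary_benefit(evaluate_model(ps)$result, ps$settings$wtp)
  # brute-force oracle for two parameters
  for (nm in c("cost_surgery", "u_event_free")) {
    rec <- ps$params[[nm]]
    lo <- evaluate_model(set_param_values(ps, setNames(rec$low, nm)))$result
    hi <- evaluate_model(set_param_values(ps, setNames(rec$high, nm)))$result
    row <- ow[ow$parameter == nm, ]
    expect_equal(row$nmb_low, net_monetary_benefit(lo, ps$settings$wtp))
    expect_equal(row$nmb_high, net_monetary_benefit(hi, ps$settings$wtp))
  }
  # degenerate ranges reproduce the base case exactly
  fixed_rows <- ow[ow$low == ow$high, ]
  expect_gt(nrow(fixed_rows), 0)
  expect_true(all(fixed_rows$nmb_low == base_nmb))
  expect_true(all(fixed_rows$nmb_high == base_nmb))
  # sorted by envelope width
  expect_true(all(diff(ow$width) <= 1e-9))
})

test_that("all-degenerate distributions collapse the PSA onto the base case exactly", {
  ps <- base_params(2)
  for (nm in names(ps$params)) ps$params[[nm]]$dist <- "fixed"
  base <- evaluate_model(ps)$result
  psa <- run_psa(ps, n_draws = 3, seed = 99)
  expect_equal(unique(psa$samples$delta_cost), base$delta_cost)
  expect_equal(unique(psa$samples$delta_qaly), base$delta_qaly)
  expect_equal(psa$summary$mean_delta_qaly, base$delta_qaly)
})

test_that("the PSA is reproducible, and single draws give degenerate curves", {
  ps <- base_params(1)
  a <- suppressWarnings(run_psa(ps, n_draws = 25, seed = 123))
  b <- suppressWarnings(run_psa(ps, n_draws = 25, seed = 123))
  expect_identical(a$samples, b$samples)
  expect_false(identical(
    a$samples, suppressWarnings(run_psa(ps, n_draws = 25, seed = 124))$samples))
  one <- suppressWarnings(run_psa(ps, n_draws = 1, seed = 5))
  expect_true(all(one$ceac$prob_cost_effective %in% c(0, 1)))
})

test_that("seeded model-1 draws concentrate in the dominant quadrant", {
  ps <- base_params(1)
  psa <- suppressWarnings(run_psa(ps, n_draws = 200, seed = 31))
  sc <- scatter_export(psa)
  expect_equal(nrow(sc), 200)
  expect_true(all(sc$delta_qaly > 0))
  expect_gte(mean(sc$delta_cost < 0), 0.99)
  expect_equal(psa$summary$prob_cost_effective_at_wtp, 1)
  # with every draw gaining QALYs the acceptability curve is non-decreasing
  # in the threshold, and flat at 1 from the first threshold where every
  # draw has positive net monetary benefit
  expect_true(all(diff(psa$ceac$prob_cost_effective) >= 0))
  expect_true(all(psa$ceac$prob_cost_effective[psa$ceac$wtp >= 1e5] == 1))
  expect_equal(attr(sc, "wtp"), 1e5)
})
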