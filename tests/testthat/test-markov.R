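all_arm_subgroups <- function() {
  out <- list()
  for (mid in 1:2) {
    ps <- base_params(mid)
    for (arm in model_arms(mid)) {
      strat <- build_strategy(arm, ps)
      for (sg in strat$subgroups) {
        out[[paste(mid, arm, sg$label, sep = "/")]] <-
          list(ps = ps, strat = strat, label = sg$label)
      }
    }
  }
  out
}

test_that("competing disease and background mortality combine multiplicatively", {
  expect_equal(combine_mortality(0, 0.0002), 0.0002)
  expect_equal(combine_mortality(0.00009, 0.0002),
               1 - (1 - 0.00009) * (1 - 0.0002))
  expect_equal(combine_mortality(1, 0.5), 1)
  expect_error(combine_mortality(-0.1, 0.5))
})

test_that("published BRAF-group metastatic rates are consistent with the therapy-mix hazard ratios", {
  ps <- base_params(1)
  # hand-computed share-weighted HRs
  whr_pfs_mut <- 0.68 * 0.46 + 0.19 * 0.74 + 0.13 * 1
  whr_pfs_wt <- 0.71 * 0.74 + 0.29 * 1
  expect_equal(therapy_weighted_hr(0.46, 0.74, 0.68, 0.19, 0.13), whr_pfs_mut)
  expect_equal(therapy_weighted_hr(0.46, 0.74, 0, 0.71, 0.29), whr_pfs_wt)
  # both published PFS rates imply the same pembrolizumab reference rate
  expect_equal((0.00296 / whr_pfs_mut) / (0.00414 / whr_pfs_wt), 1,
               tolerance = 0.01)
  whr_os_mut <- 0.68 * 1.09 + 0.19 * 0.79 + 0.13 * 1
  whr_os_wt <- 0.71 * 0.79 + 0.29 * 1
  expect_equal((0.00285 / whr_os_mut) / (0.00237 / whr_os_wt), 1,
               tolerance = 0.01)
})

test_that("metastatic split uses the published rates at base and responds to HR perturbation", {
  ps <- base_params(1)
  m <- metastatic_split(ps, "mut")
  expect_equal(m$p_death_pf, 1 - exp(-0.00285))
  expect_equal(m$p_death_prog, m$p_death_pf)
  expect_equal(m$p_progress, max(0, (1 - exp(-0.00296)) - (1 - exp(-0.00285))))
  # per-therapy HRs all set to 1: both subgroups collapse onto the implied
  # pembrolizumab reference rate
  ps1 <- set_param_values(ps, c(hr_pfs_dabtram = 1, hr_pfs_nivoipi = 1,
                                hr_os_dabtram = 1, hr_os_nivoipi = 1))
  mm <- metastatic_split(ps1, "mut")
  mw <- metastatic_split(ps1, "wt")
  expect_equal(mm$pfs_rate, mw$pfs_rate, tolerance = 0.01)
  expect_equal(mm$os_rate, mw$os_rate, tolerance = 0.01)
  # a sampled OS-derived probability above the PFS-derived one is clamped
  ps2 <- set_param_values(ps, c(met_os_rate_mut = 0.004))
  expect_warning(m2 <- metastatic_split(ps2, "mut"), "clamped")
  expect_equal(m2$p_progress, 0)
})

test_that("transition matrices are row-stochastic with an absorbing death state", {
  for (cfg in all_arm_subgroups()) {
    tp <- periomel:::transition_probs(cfg$strat, cfg$label, cfg$ps)
    # vectorised exhaustive row-sum identity over all 2080 cycles
    ef_row <- tp$p_ef_lr + tp$p_ef_met + tp$p_ef_death
    expect_true(all(ef_row >= 0 & ef_row <= 1))
    expect_true(all(tp$p_rem_met + tp$p_rem_death <= 1))
    expect_true(all(tp$p_met_prog + tp$p_met_death <= 1))
    for (k in c(0, 1, 519, 2079)) {
      m <- build_transition_matrix(cfg$strat, cfg$label, cfg$ps, k)
      expect_equal(rowSums(m), rep(1, 6), ignore_attr = TRUE, tolerance = 1e-12)
      expect_true(all(m >= 0))
      expect_equal(m["death", ], c(0, 0, 0, 0, 0, 1), ignore_attr = TRUE)
    }
  }
  ps <- base_params(1)
  strat <- build_strategy("adj_nivo", ps)
  expect_error(build_transition_matrix(strat, "braf_mutant", ps, 2080), "range")
})

test_that("the published week-0 metastasis probability is honoured exactly", {
  ps2 <- base_params(2)
  strat <- build_strategy("adj_pembro", ps2)
  m0 <- build_transition_matrix(strat, "braf_mutant", ps2, 0)
  expect_equal(m0["event_free", "metastatic_progression_free"], 0.0068,
               tolerance = 1e-12)
})

test_that("cohort traces conserve occupancy with monotone death and sensible accrual ordering", {
  for (mid in 1:2) {
    ps <- base_params(mid)
    for (arm in model_arms(mid)) {
      tr <- run_arm(arm, ps, keep_trace = TRUE)
      expect_equal(rowSums(tr$occupancy), rep(1, 2080), tolerance = 1e-9)
      expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-12))
      expect_lt(tr$ly_disc, tr$ly_undisc)
      expect_lt(tr$qaly, tr$ly_disc) # all utilities below 1
      expect_equal(tr$total_cost, sum(tr$cost))
    }
  }
})

test_that("a zero discount rate makes discounted and undiscounted life-years equal", {
  ps <- base_params(1)
  ps$settings$discount_rate_annual <- 0
  tr <- run_arm("adj_nivo", ps)
  expect_identical(tr$ly_disc, tr$ly_undisc)
})

test_that("with all hazards off, QALYs reduce to a discounted utility annuity", {
  ps <- inert_params(1, discount = 0.03)
  tr <- run_cohort(build_strategy("adj_nivo", ps), "braf_wild_type", ps)
  annuity <- sum(1.03^(-(0:2079) / 52)) / 52
  ade_decrement <- (0.006 * 0.047 + 0.024 * 0.033) * 4 / 52 *
    1.03^(-6 / 52) # charged at the first adjuvant administration, week 6
  expect_equal(tr$qaly, 0.9130 * annuity - ade_decrement, tolerance = 1e-9)
  expect_equal(tr$ly_undisc, 40)
})

test_that("the cohort engine agrees with explicit matrix multiplication", {
  ps <- base_params(1)
  strat <- build_strategy("adj_nivo", ps)
  tr <- run_cohort(strat, "braf_mutant", ps, keep_trace = TRUE)
  occ <- c(1, 0, 0, 0, 0, 0)
  for (k in 0:119) {
    expect_equal(unname(tr$occupancy[k + 1, ]), unname(occ), tolerance = 1e-10)
    occ <- as.numeric(occ %*% build_transition_matrix(strat, "braf_mutant", ps, k))
  }
})

test_that("subgroup aggregation is the weighted mixture of traces", {
  ps <- base_params(1)
  strat <- build_strategy("perio_nivo_ipi", ps)
  traces <- lapply(strat$subgroups, function(sg) run_cohort(strat, sg$label, ps))
  single <- aggregate_subgroups(traces[1], 1)
  expect_equal(single$total_cost, traces[[1]]$total_cost)
  half <- aggregate_subgroups(traces[1:2], c(0.5, 0.5))
  expect_equal(half$qaly, (traces[[1]]$qaly + traces[[2]]$qaly) / 2)
  w <- vapply(strat$subgroups, `[[`, numeric(1), "weight")
  agg <- aggregate_subgroups(traces, w)
  expect_equal(agg$total_cost, sum(w * vapply(traces, `[[`, numeric(1), "total_cost")),
               tolerance = 1e-9)
  expect_error(aggregate_subgroups(traces, c(0.5, 0.5)), "one weight per trace")
  expect_error(aggregate_subgroups(traces[1:2], c(0.6, 0.6)), "sum to 1")
})

test_that("with unit EFS hazard ratios the two model-1 arms share their event-free exits", {
  ps <- set_param_values(base_params(1),
                         c(efs_hr_braf_mutant = 1, efs_hr_braf_wt = 1))
  adj <- build_strategy("adj_nivo", ps)
  per <- build_strategy("perio_nivo_ipi", ps)
  tp_a <- periomel:::transition_probs(adj, "braf_mutant", ps)
  tp_p <- periomel:::transition_probs(per, "braf_mutant_prnr", ps)
  expect_equal(tp_p$p_ef_lr + tp_p$p_ef_met, tp_a$p_ef_lr + tp_a$p_ef_met,
               tolerance = 1e-12)
  expect_equal(tp_p$p_ef_death, tp_a$p_ef_death, tolerance = 1e-15)
  # cost structure still differs between the arms
  ev <- evaluate_model(ps)
  expect_gt(ev$arms$perioperative$cost[["neoadjuvant"]], 40000)
  expect_equal(ev$arms$adjuvant$cost[["neoadjuvant"]], 0)
})

test_that("modelled event-free survival starts at 1 and is non-increasing", {
  ps <- base_params(2)
  for (arm in model_arms(2)) {
    efs <- modelled_efs(arm, ps, weeks = seq(0, 520, by = 4))
    expect_equal(efs$efs[1], 1)
    expect_true(all(diff(efs$efs) <= 0))
  }
})
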