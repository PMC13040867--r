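#' Cohort engine
#'
#' Six-state weekly-cycle Markov cohort simulation: event-free,
#' locoregional recurrence (a one-cycle tunnel through salvage surgery),
#' locoregional remission, metastatic progression-free, metastatic disease
#' progression, and death. The whole cohort enters event-free. Event-free
#' exits follow the arm's Gompertz event-free survival curve, split between
#' distant metastasis and locoregional recurrence in the fixed proportion
#' implied by the arm's published weekly metastasis probability; background
#' mortality from the age-indexed life table is combined with the
#' trial-derived death probabilities in the pre-metastatic states, while the
#' metastatic states use the all-cause overall-survival-derived weekly
#' probability directly.
#'
#' @name markov_engine
NULL

HEALTH_STATES <- c("event_free", "locoregional_recurrence",
                   "locoregional_remission", "metastatic_progression_free",
                   "metastatic_disease_progression", "death")

COST_CATEGORIES <- c("neoadjuvant", "surgery", "adjuvant",
                     "before_recurrence", "after_recurrence")

#' Combine disease-specific and background mortality
#'
#' Independent competing weekly probabilities:
#' `1 - (1 - p_disease) * (1 - p_background)`, capped at 1.
#'
#' @param p_disease,p_background Weekly probabilities in \[0, 1\].
#' @return Combined weekly probability.
#' @export
combine_mortality <- function(p_disease, p_background) {
  stopifnot(all(p_disease >= 0 & p_disease <= 1),
            all(p_background >= 0 & p_background <= 1))
  pmin(1, 1 - (1 - p_disease) * (1 - p_background))
}

#' Share-weighted hazard ratio across systemic therapies
#'
#' The metastatic-phase survival of each BRAF group reflects a mix of
#' systemic therapies (dabrafenib+trametinib, nivolumab+ipilimumab,
#' pembrolizumab as reference) weighted by their usage shares:
#' `sum(share_i * HR_i)` with pembrolizumab at HR 1.
#'
#' @param hr_dabtram,hr_nivoipi Hazard ratios versus pembrolizumab.
#' @param share_dabtram,share_nivoipi,share_pembro Usage shares summing to 1.
#' @return Weighted hazard ratio.
#' @export
therapy_weighted_hr <- function(hr_dabtram, hr_nivoipi,
                                share_dabtram, share_nivoipi, share_pembro) {
  shares <- c(share_dabtram, share_nivoipi, share_pembro)
  if (abs(sum(shares) - 1) > 1e-6) stop("shares must sum to 1", call. = FALSE)
  share_dabtram * hr_dabtram + share_nivoipi * hr_nivoipi + share_pembro * 1
}

#' Weekly metastatic-phase transition probabilities for a BRAF group
#'
#' The published BRAF-group exponential PFS/OS rates already incorporate the
#' therapy-mix hazard ratios, so at base case they are converted directly to
#' weekly probabilities. When the hazard-ratio or share parameters are
#' perturbed (one-way or probabilistic analysis), the rates are rescaled by
#' the ratio of the current to the base share-weighted hazard ratio, which
#' leaves the base case untouched and propagates HR variation coherently.
#' Progression is the excess of PFS events over deaths,
#' `max(0, q_PFS - q_OS)` (clamped at 0 with a warning when the sampled
#' PFS-derived probability falls below the OS-derived one); death from
#' either metastatic state uses the OS-derived weekly probability.
#'
#' @param ps A `perio_params` object.
#' @param braf `"mut"` or `"wt"`.
#' @return List with `p_progress`, `p_death_pf`, `p_death_prog` (weekly
#'   probabilities, before any background-mortality combination) and the
#'   adjusted `pfs_rate`/`os_rate`.
#' @export
metastatic_split <- function(ps, braf = c("mut", "wt")) {
  braf <- match.arg(braf)
  sh <- function(f, nm) f(ps, paste0("share_", braf, "_", nm))
  hr <- function(f, endp, nm) f(ps, paste0("hr_", endp, "_", nm))
  ratio <- function(endp) {
    cur <- therapy_weighted_hr(hr(param_value, endp, "dabtram"),
                               hr(param_value, endp, "nivoipi"),
                               sh(param_value, "dabtram"),
                               sh(param_value, "nivoipi"),
                               sh(param_value, "pembro"))
    base <- therapy_weighted_hr(hr(param_base, endp, "dabtram"),
                                hr(param_base, endp, "nivoipi"),
                                sh(param_base, "dabtram"),
                                sh(param_base, "nivoipi"),
                                sh(param_base, "pembro"))
    cur / base
  }
  pfs_rate <- param_value(ps, paste0("met_pfs_rate_", braf)) * ratio("pfs")
  os_rate <- param_value(ps, paste0("met_os_rate_", braf)) * ratio("os")
  q_pfs <- exp_rate_to_weekly_prob(pfs_rate)
  q_os <- exp_rate_to_weekly_prob(os_rate)
  if (q_pfs < q_os) {
    warning(sprintf(
      "PFS-derived weekly probability (%.5g) below OS-derived (%.5g) for BRAF %s; progression clamped to 0",
      q_pfs, q_os, braf), call. = FALSE)
  }
  list(p_progress = max(0, q_pfs - q_os), p_death_pf = q_os,
       p_death_prog = q_os, pfs_rate = pfs_rate, os_rate = os_rate)
}

# Weekly background mortality for every cycle, advancing cohort age from the
# start age; ages beyond the table reuse its last row.
background_mortality <- function(ps, n_cycles) {
  lt <- ps$life_table
  age <- floor(ps$settings$start_age_years + (seq_len(n_cycles) - 1) / 52)
  idx <- match(pmin(age, max(lt$age_years)), lt$age_years)
  if (anyNA(idx)) stop("life table does not cover the cohort age range", call. = FALSE)
  lt$weekly_mortality_probability[idx]
}

discount_factors <- function(ps, n_cycles) {
  (1 + ps$settings$discount_rate_annual)^(-(0:n_cycles) / 52)
}

model_horizon <- function(ps) as.integer(ps$settings$horizon_years * 52)

# Per-cycle transition probability vectors for one subgroup; the single
# source of transition logic used by both build_transition_matrix() and
# run_cohort().
transition_probs <- function(strategy, subgroup, ps) {
  sg <- resolve_subgroup(strategy, subgroup)
  H <- model_horizon(ps)
  bg <- background_mortality(ps, H)
  q_efs <- gompertz_cycle_prob(sg$gompertz[["shape"]], sg$gompertz[["rate"]],
                               0:(H - 1))
  death_ef_trial <- param_value(ps, "tp_death_ef")
  p_ef_death <- combine_mortality(death_ef_trial, bg)
  # disease exits beyond the trial death floor, split between distant
  # metastasis and locoregional recurrence in the proportion implied by the
  # published week-0 metastasis probability
  disease <- pmax(0, q_efs - death_ef_trial)
  met_share <- param_value(ps, sg$ef_met_ref) / max(disease[1], 1e-12)
  if (met_share > 1) {
    warning(sprintf(
      "published EF->metastatic probability exceeds week-0 event probability for %s/%s; share capped at 1",
      strategy$arm_id, sg$label), call. = FALSE)
    met_share <- 1
  }
  p_lr_death <- combine_mortality(param_value(ps, "tp_death_lr"), bg)
  met <- metastatic_split(ps, sg$braf)
  in_met_bg <- isTRUE(ps$settings$background_in_metastatic)
  list(
    p_ef_lr = (1 - met_share) * disease,
    p_ef_met = met_share * disease,
    p_ef_death = p_ef_death,
    p_lr_death = p_lr_death,
    p_rem_met = param_value(ps, "tp_rem_met"),
    p_rem_death = p_lr_death,
    p_met_prog = met$p_progress,
    p_met_death = if (in_met_bg) combine_mortality(met$p_death_pf, bg) else
      rep(met$p_death_pf, H),
    p_prog_death = if (in_met_bg) combine_mortality(met$p_death_prog, bg) else
      rep(met$p_death_prog, H),
    cure_fraction = gompertz_cure_fraction(sg$gompertz[["shape"]],
                                           sg$gompertz[["rate"]])
  )
}

#' Transition matrix for one cycle
#'
#' Assembles the 6x6 row-stochastic transition matrix of a subgroup at
#' cycle `k` from the same per-cycle probabilities the cohort engine uses.
#'
#' @param strategy A `perio_strategy`.
#' @param subgroup Subgroup label or index.
#' @param ps The matching `perio_params`.
#' @param k Cycle index, 0-based, below the horizon.
#' @return 6x6 matrix with dimnames `HEALTH_STATES`; rows sum to 1.
#' @export
build_transition_matrix <- function(strategy, subgroup, ps, k) {
  H <- model_horizon(ps)
  if (k < 0 || k >= H) stop("cycle index out of range", call. = FALSE)
  tp <- transition_probs(strategy, subgroup, ps)
  i <- k + 1
  m <- matrix(0, 6, 6, dimnames = list(HEALTH_STATES, HEALTH_STATES))
  m[1, 2] <- tp$p_ef_lr[i]
  m[1, 4] <- tp$p_ef_met[i]
  m[1, 6] <- tp$p_ef_death[i]
  m[1, 1] <- 1 - sum(m[1, ])
  m[2, 6] <- tp$p_lr_death[i]
  m[2, 3] <- 1 - m[2, 6]
  m[3, 4] <- tp$p_rem_met
  m[3, 6] <- tp$p_rem_death[i]
  m[3, 3] <- 1 - m[3, 4] - m[3, 6]
  m[4, 5] <- tp$p_met_prog
  m[4, 6] <- tp$p_met_death[i]
  m[4, 4] <- 1 - m[4, 5] - m[4, 6]
  m[5, 6] <- tp$p_prog_death[i]
  m[5, 5] <- 1 - m[5, 6]
  m[6, 6] <- 1
  if (any(m < -1e-12) || any(abs(rowSums(m) - 1) > 1e-12)) {
    stop("constructed transition matrix is not row-stochastic", call. = FALSE)
  }
  m
}

# Per-cycle event-free cost and QALY-penalty streams (unconditioned,
# undiscounted; the kernel multiplies by occupancy and discount).
accrual_streams <- function(strategy, subgroup, ps) {
  sg <- resolve_subgroup(strategy, subgroup)
  H <- model_horizon(ps)
  neo <- numeric(H); surg <- numeric(H); adj <- numeric(H); qpen <- numeric(H)
  stream <- drug_cost_stream(strategy, sg$label, ps)
  has_neo <- any(stream$neoadjuvant > 0)
  idx <- stream$week + 1
  neo[idx] <- neo[idx] + stream$neoadjuvant
  adj[idx] <- adj[idx] + stream$adjuvant
  surg[strategy$surgery_week + 1] <- param_value(ps, "cost_surgery")
  burden <- ade_expected_burden(strategy, ps)
  first_week <- if (nrow(stream)) min(stream$week) else 0L
  treat_cat <- if (has_neo) "neo" else "adj"
  if (treat_cat == "neo") {
    neo[first_week + 1] <- neo[first_week + 1] + burden[["cost"]]
  } else {
    adj[first_week + 1] <- adj[first_week + 1] + burden[["cost"]]
  }
  qpen[first_week + 1] <- burden[["qaly_decrement"]]
  # BRAF testing once at model entry, reported with the first treatment phase
  if (treat_cat == "neo") {
    neo[1] <- neo[1] + param_value(ps, "cost_braf_test")
  } else {
    adj[1] <- adj[1] + param_value(ps, "cost_braf_test")
  }
  list(neo = neo, surg = surg, adj = adj, qaly_penalty = qpen)
}

#' Run the cohort simulation for one subgroup
#'
#' @param strategy A `perio_strategy`.
#' @param subgroup Subgroup label or index.
#' @param ps The matching `perio_params`.
#' @param keep_trace Keep the full state-occupancy matrix?
#' @return Object of class `perio_trace`: list with `cost` (named by
#'   category), `total_cost`, `qaly`, `ly_disc`, `ly_undisc`,
#'   `met_entrants`, and (if requested) the cycles x states `occupancy`
#'   matrix.
#' @export
run_cohort <- function(strategy, subgroup, ps, keep_trace = FALSE) {
  sg <- resolve_subgroup(strategy, subgroup)
  tp <- transition_probs(strategy, sg$label, ps)
  st <- accrual_streams(strategy, sg$label, ps)
  H <- model_horizon(ps)
  u <- c(param_value(ps, "u_event_free"), param_value(ps, "u_lr_recurrence"),
         param_value(ps, "u_lr_remission"), param_value(ps, "u_met_pf"),
         param_value(ps, "u_met_prog"), 0)
  mpf_mgmt <- if (isTRUE(ps$settings$mpf_management_weekly)) {
    param_value(ps, "mgmt_met_pf")
  } else 0
  systemic <- param_value(ps, paste0("cost_systemic_", sg$braf))
  res <- cohort_core(
    tp$p_ef_lr, tp$p_ef_met, tp$p_ef_death, tp$p_lr_death, tp$p_rem_met,
    tp$p_rem_death, tp$p_met_prog, tp$p_met_death, tp$p_prog_death,
    discount_factors(ps, H),
    st$neo, st$surg, st$adj, st$qaly_penalty,
    param_value(ps, "mgmt_event_free"), param_value(ps, "mgmt_lr_recurrence"),
    param_value(ps, "mgmt_lr_remission"), mpf_mgmt,
    param_value(ps, "mgmt_met_prog"), u,
    param_value(ps, "cost_surgery"), systemic,
    tp$cure_fraction, keep_trace)
  trace <- list(arm_id = strategy$arm_id, subgroup = sg$label,
                cost = res$cost, total_cost = sum(res$cost),
                qaly = res$qaly, ly_disc = res$ly_disc,
                ly_undisc = res$ly_undisc, met_entrants = res$met_entrants)
  if (keep_trace) {
    colnames(res$occupancy) <- HEALTH_STATES
    trace$occupancy <- res$occupancy
  }
  class(trace) <- "perio_trace"
  trace
}

#' Mixture of subgroup traces
#'
#' Weighted expectation of every accrual (and occupancy, where present)
#' over a subgroup mixture.
#'
#' @param traces List of `perio_trace` objects.
#' @param weights Non-negative weights summing to 1.
#' @return A `perio_trace` for the mixture.
#' @export
aggregate_subgroups <- function(traces, weights) {
  if (length(traces) != length(weights)) {
    stop("one weight per trace required", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1", call. = FALSE)
  wsum <- function(f) Reduce(`+`, Map(function(tr, w) w * tr[[f]], traces, weights))
  out <- list(arm_id = traces[[1]]$arm_id, subgroup = "aggregate",
              cost = wsum("cost"), total_cost = wsum("total_cost"),
              qaly = wsum("qaly"), ly_disc = wsum("ly_disc"),
              ly_undisc = wsum("ly_undisc"), met_entrants = wsum("met_entrants"))
  if (!is.null(traces[[1]]$occupancy)) out$occupancy <- wsum("occupancy")
  class(out) <- "perio_trace"
  out
}

#' Run one arm: build its pathway, run every subgroup, aggregate
#'
#' @param arm_id Arm identifier from [model_arms()].
#' @param ps A `perio_params` object.
#' @param keep_trace Keep occupancy matrices?
#' @return Aggregate `perio_trace` for the arm.
#' @export
run_arm <- function(arm_id, ps, keep_trace = FALSE) {
  strat <- build_strategy(arm_id, ps)
  traces <- lapply(strat$subgroups, function(sg)
    run_cohort(strat, sg$label, ps, keep_trace = keep_trace))
  aggregate_subgroups(traces, vapply(strat$subgroups, `[[`, numeric(1), "weight"))
}

#' Evaluate a full model: both arms plus the incremental comparison
#'
#' @param ps A `perio_params` object.
#' @param keep_trace Keep occupancy matrices?
#' @return List with `arms` (named `perio_trace`s, `perioperative` and
#'   `adjuvant`) and `result` (a `perio_cea` from [compare_arms()]).
#' @export
evaluate_model <- function(ps, keep_trace = FALSE) {
  arms <- model_arms(ps$model_id)
  perio <- run_arm(arms[1], ps, keep_trace)
  adj <- run_arm(arms[2], ps, keep_trace)
  list(arms = list(perioperative = perio, adjuvant = adj),
       result = compare_arms(perio, adj, wtp = ps$settings$wtp))
}

#' Modelled event-free survival curve of an arm
#'
#' Subgroup-weighted Gompertz event-free survival over the model horizon,
#' the quantity plotted against the trial Kaplan-Meier curves for internal
#' validation.
#'
#' @param arm_id Arm identifier.
#' @param ps A `perio_params` object.
#' @param weeks Evaluation grid (defaults to every cycle).
#' @return Data frame with columns `week` and `efs`.
#' @export
modelled_efs <- function(arm_id, ps, weeks = 0:model_horizon(ps)) {
  strat <- build_strategy(arm_id, ps)
  efs <- Reduce(`+`, lapply(strat$subgroups, function(sg) {
    sg$weight * gompertz_survival(weeks, sg$gompertz[["shape"]],
                                  sg$gompertz[["rate"]])
  }))
  data.frame(week = weeks, efs = efs)
}

#' @export
print.perio_trace <- function(x, ...) {
  cat(sprintf("<perio_trace> %s/%s: cost %.0f USD, QALY %.3f, LY (disc) %.3f\n",
              x$arm_id, x$subgroup, x$total_cost, x$qaly, x$ly_disc))
  invisible(x)
}
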