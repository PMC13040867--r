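#' Treatment-arm pathways
#'
#' A strategy pathway encodes one arm's dosing schedule (drug, mg, week),
#' surgery timing, subgroup structure (BRAF status, and for the
#' response-adapted perioperative nivolumab+ipilimumab arm, pathological
#' response), the event-free survival source per subgroup, and the arm's
#' adverse-drug-event profile. Unit costs are referenced by parameter name
#' and resolved at evaluation time, so the same pathway serves base-case,
#' one-way and probabilistic analyses.
#'
#' @name strategy_pathways
NULL

ARM_IDS <- list(`1` = c("perio_nivo_ipi", "adj_nivo"),
                `2` = c("perio_pembro", "adj_pembro"))

#' Arm identifiers for a model
#' @inheritParams required_parameters
#' @return Character vector `c(perioperative, adjuvant)`.
#' @export
model_arms <- function(model_id) ARM_IDS[[as.character(match_model_id(model_id))]]

dose_table <- function(week, drug, mg, ref, phase) {
  data.frame(week = as.integer(week), drug = drug, mg = mg,
             unit_cost_ref = ref, phase = phase, stringsAsFactors = FALSE)
}

# weekly oral dosing costed per week: dabrafenib 150 mg twice daily,
# trametinib 2 mg once daily
dabtram_weekly <- function(weeks) {
  rbind(
    dose_table(weeks, "dabrafenib", 7 * 2 * 150, "cost_dabrafenib_mg", "adjuvant"),
    dose_table(weeks, "trametinib", 7 * 2, "cost_trametinib_mg", "adjuvant")
  )
}

#' Build a strategy pathway
#'
#' Schedules follow the source trials: the perioperative
#' nivolumab+ipilimumab arm gives neoadjuvant ipilimumab 80 mg plus
#' nivolumab 240 mg every 3 weeks for 2 cycles, surgery at week 6, then
#' response-adapted adjuvant therapy (none after a complete response;
#' dabrafenib+trametinib for 46 weeks if BRAF-mutant, nivolumab 480 mg every
#' 4 weeks for 11 cycles if wild-type). The adjuvant nivolumab arm has
#' surgery at week 0 and nivolumab 480 mg every 4 weeks for 12 cycles. The
#' perioperative pembrolizumab arm gives 200 mg every 3 weeks for 3 cycles,
#' surgery at week 9, then 15 adjuvant cycles; the adjuvant pembrolizumab
#' arm, surgery at week 0 then 18 cycles. Adjuvant therapy starts
#' `adjuvant_delay_weeks` (a setting) after surgery.
#'
#' @param arm_id One of the identifiers from [model_arms()].
#' @param ps A `perio_params` object for the matching model.
#' @return Object of class `perio_strategy` with elements `arm_id`,
#'   `surgery_week`, `ade` (event/probability/cost/disutility references) and
#'   `subgroups` (each with `label`, `weight`, `braf`, `gompertz`,
#'   `ef_met_ref` and a dose table).
#' @export
build_strategy <- function(arm_id, ps) {
  stopifnot(inherits(ps, "perio_params"))
  delay <- ps$settings$adjuvant_delay_weeks
  braf <- param_value(ps, "braf_mutant_prop")

  if (arm_id %in% c("perio_nivo_ipi", "adj_nivo") && ps$model_id != 1L ||
      arm_id %in% c("perio_pembro", "adj_pembro") && ps$model_id != 2L) {
    stop(sprintf("arm '%s' does not belong to model %d", arm_id, ps$model_id),
         call. = FALSE)
  }

  if (arm_id == "adj_nivo") {
    surgery_week <- 0L
    doses <- dose_table(surgery_week + delay + 4 * (0:11), "nivolumab", 480,
                        "cost_nivolumab_mg", "adjuvant")
    gm <- c(shape = param_value(ps, "gomp_shape_adj_nivo_mut"),
            rate = param_value(ps, "gomp_rate_adj_nivo_mut"))
    gw <- c(shape = param_value(ps, "gomp_shape_adj_nivo_wt"),
            rate = param_value(ps, "gomp_rate_adj_nivo_wt"))
    subgroups <- list(
      list(label = "braf_mutant", weight = braf, braf = "mut", gompertz = gm,
           ef_met_ref = "tp_ef_met_adj_nivo_mut", doses = doses),
      list(label = "braf_wild_type", weight = 1 - braf, braf = "wt", gompertz = gw,
           ef_met_ref = "tp_ef_met_adj_nivo_wt", doses = doses)
    )
    ade <- data.frame(event = c("diarrhea", "rash"),
                      prob_ref = c("ade_diarrhea_adj_nivo", "ade_rash_adj_nivo"),
                      cost_ref = c("cost_ade_diarrhea", "cost_ade_rash"),
                      disu_ref = c("disu_diarrhea", "disu_rash"))
  } else if (arm_id == "perio_nivo_ipi") {
    surgery_week <- 6L
    neo <- rbind(
      dose_table(c(0, 3), "nivolumab", 240, "cost_nivolumab_mg", "neoadjuvant"),
      dose_table(c(0, 3), "ipilimumab", 80, "cost_ipilimumab_mg", "neoadjuvant")
    )
    adj_start <- surgery_week + delay
    prnr_m <- param_value(ps, "prnr_braf_mutant")
    prnr_w <- param_value(ps, "prnr_braf_wt")
    gm <- apply_hazard_ratio(param_value(ps, "gomp_shape_adj_nivo_mut"),
                             param_value(ps, "gomp_rate_adj_nivo_mut"),
                             param_value(ps, "efs_hr_braf_mutant"))
    gw <- apply_hazard_ratio(param_value(ps, "gomp_shape_adj_nivo_wt"),
                             param_value(ps, "gomp_rate_adj_nivo_wt"),
                             param_value(ps, "efs_hr_braf_wt"))
    subgroups <- list(
      list(label = "braf_mutant_pcr", weight = braf * (1 - prnr_m), braf = "mut",
           gompertz = gm, ef_met_ref = "tp_ef_met_perio_nivoipi_mut", doses = neo),
      list(label = "braf_mutant_prnr", weight = braf * prnr_m, braf = "mut",
           gompertz = gm, ef_met_ref = "tp_ef_met_perio_nivoipi_mut",
           doses = rbind(neo, dabtram_weekly(adj_start + 0:45))),
      list(label = "braf_wild_type_pcr", weight = (1 - braf) * (1 - prnr_w),
           braf = "wt", gompertz = gw,
           ef_met_ref = "tp_ef_met_perio_nivoipi_wt", doses = neo),
      list(label = "braf_wild_type_prnr", weight = (1 - braf) * prnr_w,
           braf = "wt", gompertz = gw,
           ef_met_ref = "tp_ef_met_perio_nivoipi_wt",
           doses = rbind(neo, dose_table(adj_start + 4 * (0:10), "nivolumab",
                                         480, "cost_nivolumab_mg", "adjuvant")))
    )
    ade <- data.frame(event = c("diarrhea", "rash"),
                      prob_ref = c("ade_diarrhea_perio_nivoipi", "ade_rash_perio_nivoipi"),
                      cost_ref = c("cost_ade_diarrhea", "cost_ade_rash"),
                      disu_ref = c("disu_diarrhea", "disu_rash"))
  } else if (arm_id == "adj_pembro") {
    surgery_week <- 0L
    doses <- dose_table(surgery_week + delay + 3 * (0:17), "pembrolizumab", 200,
                        "cost_pembrolizumab_mg", "adjuvant")
    g <- c(shape = param_value(ps, "gomp_shape_adj_pembro"),
           rate = param_value(ps, "gomp_rate_adj_pembro"))
    subgroups <- list(
      list(label = "braf_mutant", weight = braf, braf = "mut", gompertz = g,
           ef_met_ref = "tp_ef_met_adj_pembro", doses = doses),
      list(label = "braf_wild_type", weight = 1 - braf, braf = "wt", gompertz = g,
           ef_met_ref = "tp_ef_met_adj_pembro", doses = doses)
    )
    ade <- data.frame(
      event = c("diarrhea", "rash", "vomiting"),
      prob_ref = c("ade_diarrhea_adj_pembro", "ade_rash_adj_pembro",
                   "ade_vomiting_adj_pembro"),
      cost_ref = c("cost_ade_diarrhea", "cost_ade_rash", "cost_ade_vomiting"),
      disu_ref = c("disu_diarrhea", "disu_rash", "disu_vomiting"))
  } else if (arm_id == "perio_pembro") {
    surgery_week <- 9L
    doses <- rbind(
      dose_table(c(0, 3, 6), "pembrolizumab", 200, "cost_pembrolizumab_mg",
                 "neoadjuvant"),
      dose_table(surgery_week + delay + 3 * (0:14), "pembrolizumab", 200,
                 "cost_pembrolizumab_mg", "adjuvant")
    )
    g <- c(shape = param_value(ps, "gomp_shape_perio_pembro"),
           rate = param_value(ps, "gomp_rate_perio_pembro"))
    subgroups <- list(
      list(label = "braf_mutant", weight = braf, braf = "mut", gompertz = g,
           ef_met_ref = "tp_ef_met_perio_pembro", doses = doses),
      list(label = "braf_wild_type", weight = 1 - braf, braf = "wt", gompertz = g,
           ef_met_ref = "tp_ef_met_perio_pembro", doses = doses)
    )
    ade <- data.frame(
      event = c("diarrhea", "rash", "vomiting"),
      prob_ref = c("ade_diarrhea_perio_pembro", "ade_rash_perio_pembro",
                   "ade_vomiting_perio_pembro"),
      cost_ref = c("cost_ade_diarrhea", "cost_ade_rash", "cost_ade_vomiting"),
      disu_ref = c("disu_diarrhea", "disu_rash", "disu_vomiting"))
  } else {
    stop("unknown arm_id: ", arm_id, call. = FALSE)
  }

  w <- vapply(subgroups, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) {
    stop(sprintf("subgroup weights for '%s' sum to %g", arm_id, sum(w)),
         call. = FALSE)
  }
  structure(list(arm_id = arm_id, model_id = ps$model_id,
                 surgery_week = surgery_week, subgroups = subgroups, ade = ade),
            class = "perio_strategy")
}

#' Weekly drug acquisition cost stream for a subgroup
#'
#' Resolves each dose event's per-mg unit cost against the parameter set and
#' returns undiscounted, unconditioned cost per week (the cohort engine
#' conditions on event-free occupancy and discounts).
#'
#' @param strategy A `perio_strategy`.
#' @param subgroup Subgroup label or index.
#' @param ps The `perio_params` the strategy was built from.
#' @return Data frame with columns `week`, `neoadjuvant`, `adjuvant` (USD),
#'   one row per scheduled week.
#' @export
drug_cost_stream <- function(strategy, subgroup, ps) {
  sg <- resolve_subgroup(strategy, subgroup)
  d <- sg$doses
  if (nrow(d) == 0) {
    return(data.frame(week = integer(), neoadjuvant = numeric(),
                      adjuvant = numeric()))
  }
  d$cost <- d$mg * vapply(d$unit_cost_ref, function(r) param_value(ps, r),
                          numeric(1))
  weeks <- sort(unique(d$week))
  out <- data.frame(week = weeks, neoadjuvant = 0, adjuvant = 0)
  for (ph in c("neoadjuvant", "adjuvant")) {
    sub <- d[d$phase == ph, ]
    if (nrow(sub)) {
      agg <- tapply(sub$cost, sub$week, sum)
      out[[ph]][match(as.integer(names(agg)), weeks)] <- as.numeric(agg)
    }
  }
  out
}

resolve_subgroup <- function(strategy, subgroup) {
  if (is.numeric(subgroup)) return(strategy$subgroups[[subgroup]])
  labels <- vapply(strategy$subgroups, `[[`, character(1), "label")
  i <- match(subgroup, labels)
  if (is.na(i)) stop("unknown subgroup: ", subgroup, call. = FALSE)
  strategy$subgroups[[i]]
}

#' Expected one-time adverse-event burden of an arm
#'
#' Expected cost `sum(p_e * cost_e)` and expected QALY decrement
#' `sum(p_e * |disutility_e|) * ade_duration_weeks / 52`, both applied once
#' at treatment start on the event-free cohort.
#'
#' @param strategy A `perio_strategy`.
#' @param ps The matching `perio_params`.
#' @return Named numeric vector `c(cost =, qaly_decrement =)`.
#' @export
ade_expected_burden <- function(strategy, ps) {
  p <- vapply(strategy$ade$prob_ref, function(r) param_value(ps, r), numeric(1))
  cost <- vapply(strategy$ade$cost_ref, function(r) param_value(ps, r), numeric(1))
  disu <- vapply(strategy$ade$disu_ref, function(r) param_value(ps, r), numeric(1))
  dur <- ps$settings$ade_duration_weeks / 52
  c(cost = sum(p * cost), qaly_decrement = sum(p * abs(disu)) * dur)
}

#' @export
print.perio_strategy <- function(x, ...) {
  cat(sprintf("<perio_strategy> %s (model %d): surgery week %d, %d subgroup(s)\n",
              x$arm_id, x$model_id, x$surgery_week, length(x$subgroups)))
  for (sg in x$subgroups) {
    cat(sprintf("  %-22s weight %.4f, %d dose event(s)\n",
                sg$label, sg$weight, nrow(sg$doses)))
  }
  invisible(x)
}
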