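#' Sensitivity analyses
#'
#' One-way deterministic analysis sweeps each input to its published low and
#' high bound with everything else at base, reporting the incremental net
#' monetary benefit envelope (tornado input) and whether the decision flips
#' within the range. Probabilistic analysis redraws every input jointly from
#' its assigned distribution (beta and gamma moment-matched to base value
#' and range, range-scaled beta for hazard ratios, Dirichlet for therapy
#' shares, correlated bivariate normal for Gompertz shape/rate pairs),
#' re-evaluates both arms per draw, and summarises the incremental cloud
#' and the cost-effectiveness acceptability curve.
#'
#' @name sensitivity
NULL

Z95 <- stats::qnorm(0.975)

#' Draw one value from a parameter's sampling distribution
#'
#' The low/high range is interpreted as a 95% interval, so the sampling
#' standard deviation is `(high - low) / (2 * 1.96)`. Beta and gamma are
#' parameterised by moment matching to mean = base; negative inputs
#' (disutilities) are sampled on their magnitude and negated; `beta-range`
#' rescales a beta draw onto `[low, high]` (used for hazard ratios whose
#' printed interval exceeds 1). Infeasible beta moments fall back to a
#' uniform draw on the range, with a warning. Degenerate ranges return the
#' base value.
#'
#' @param rec A parameter record (element of `perio_params$params`).
#' @param settings The parameter set's settings list (unused for scalar
#'   families; kept for interface symmetry).
#' @param u Optional uniform quantile in (0, 1); draws are produced by
#'   inverting the distribution at `u`, so parameters that share a quantile
#'   (see the `couple` record field) are sampled comonotonically.
#' @return One numeric draw, within the distribution's support.
#' @export
sample_distribution <- function(rec, settings = NULL, u = NULL) {
  base <- rec$base; low <- rec$low; high <- rec$high
  dist <- rec$dist %||% "fixed"
  if (dist == "fixed" || high - low <= 0) return(base)
  if (is.null(u)) u <- stats::runif(1)
  sdev <- (high - low) / (2 * Z95)
  neg <- base < 0 && dist == "beta"
  m <- if (neg) -base else base
  draw <- switch(
    dist,
    beta = {
      v <- sdev^2
      if (v >= m * (1 - m) || m <= 0 || m >= 1) {
        warning(sprintf("infeasible beta moments for '%s'; using range-truncated draw",
                        rec$name), call. = FALSE)
        stats::qunif(u, min(abs(c(low, high))), max(abs(c(low, high))))
      } else {
        k <- m * (1 - m) / v - 1
        stats::qbeta(u, m * k, (1 - m) * k)
      }
    },
    `beta-range` = {
      mu <- (base - low) / (high - low)
      vu <- (sdev / (high - low))^2
      if (vu >= mu * (1 - mu) || mu <= 0 || mu >= 1) {
        warning(sprintf("infeasible beta moments for '%s'; using range-truncated draw",
                        rec$name), call. = FALSE)
        stats::qunif(u, low, high)
      } else {
        k <- mu * (1 - mu) / vu - 1
        low + (high - low) * stats::qbeta(u, mu * k, (1 - mu) * k)
      }
    },
    gamma = {
      v <- sdev^2
      if (m <= 0 || v <= 0) base else
        stats::qgamma(u, shape = m^2 / v, rate = m / v)
    },
    stop("no scalar sampler for distribution '", dist, "'", call. = FALSE)
  )
  if (neg) -draw else draw
}

# Correlated draw of a Gompertz (shape, rate) pair: marginal SDs from the
# printed ranges as 95% intervals, correlation from the settings, rate
# floored at a tiny positive value.
sample_gompertz_pair <- function(shape_rec, rate_rec, rho) {
  sd_s <- (shape_rec$high - shape_rec$low) / (2 * Z95)
  sd_r <- (rate_rec$high - rate_rec$low) / (2 * Z95)
  z <- stats::rnorm(2)
  shape <- shape_rec$base + sd_s * z[1]
  rate <- rate_rec$base + sd_r * (rho * z[1] + sqrt(1 - rho^2) * z[2])
  c(shape = shape, rate = max(rate, 1e-12))
}

# Dirichlet draw with concentration = base shares * effective sample size;
# structural-zero components stay zero.
sample_dirichlet <- function(bases, ess) {
  g <- vapply(bases * ess, function(a) if (a <= 0) 0 else stats::rgamma(1, a),
              numeric(1))
  if (sum(g) == 0) bases else g / sum(g)
}

#' Sample a full parameter set for one PSA draw
#'
#' Draws every non-fixed parameter: scalars in alphabetical order, then
#' Gompertz pairs, then Dirichlet share groups (each block alphabetical), so
#' a given RNG state maps deterministically to a draw. Records sharing a
#' `couple` field (the PFS/OS rate and hazard-ratio pairs, which are
#' estimated from the same trials) are sampled comonotonically through a
#' shared uniform quantile, keeping each draw's PFS-derived event
#' probability coherent with (at least as large as) its OS-derived one.
#'
#' @param ps A `perio_params` object (base values are the sampling means).
#' @return `ps` with the `value` slots replaced by the draw.
#' @export
sample_parameter_set <- function(ps) {
  recs <- ps$params
  scalars <- sort(names(recs)[vapply(recs, function(r)
    !r$dist %in% c("mvn-cholesky", "dirichlet"), logical(1))])
  couple_u <- list()
  for (nm in scalars) {
    cpl <- recs[[nm]]$couple
    u <- if (is.null(cpl)) NULL else {
      if (is.null(couple_u[[cpl]])) couple_u[[cpl]] <- stats::runif(1)
      couple_u[[cpl]]
    }
    ps$params[[nm]]$value <- sample_distribution(recs[[nm]], ps$settings, u = u)
  }
  pairs <- unique(sort(unlist(lapply(recs, `[[`, "pair"))))
  rho <- ps$settings$gompertz_correlation %||% -0.5
  for (pr in pairs) {
    members <- names(recs)[vapply(recs, function(r) identical(r$pair, pr), logical(1))]
    if (all(vapply(recs[members], function(r) r$dist == "fixed", logical(1)))) next
    roles <- vapply(recs[members], `[[`, character(1), "role")
    draw <- sample_gompertz_pair(recs[[members[roles == "shape"]]],
                                 recs[[members[roles == "rate"]]], rho)
    ps$params[[members[roles == "shape"]]]$value <- draw[["shape"]]
    ps$params[[members[roles == "rate"]]]$value <- draw[["rate"]]
  }
  groups <- unique(sort(unlist(lapply(recs, `[[`, "group"))))
  ess <- ps$settings$dirichlet_ess %||% 100
  for (grp in groups) {
    members <- sort(param_group(ps, grp))
    if (all(vapply(recs[members], function(r) r$dist == "fixed", logical(1)))) next
    bases <- vapply(recs[members], `[[`, numeric(1), "base")
    draw <- sample_dirichlet(bases, ess)
    for (i in seq_along(members)) ps$params[[members[i]]]$value <- unname(draw[i])
  }
  ps
}

#' One-way deterministic sensitivity analysis
#'
#' Each parameter is set to its low and then its high bound (all others at
#' base) and the full model re-evaluated; parameters marked `owsa: fixed`
#' or with degenerate ranges contribute zero-width entries. Entries are
#' sorted by the width of their incremental-NMB envelope (tornado order).
#'
#' @param ps A `perio_params` object at base case.
#' @param wtp Willingness-to-pay for the NMB metric.
#' @return Data frame with one row per parameter: `parameter`, `low`,
#'   `high`, `nmb_low`, `nmb_high`, `delta_cost_low/high`,
#'   `delta_qaly_low/high`, `width`, `crosses_zero`.
#' @export
one_way <- function(ps, wtp = ps$settings$wtp) {
  base_eval <- evaluate_model(ps)
  entries <- lapply(names(ps$params), function(nm) {
    rec <- ps$params[[nm]]
    fixed <- identical(rec$owsa, "fixed") || rec$high - rec$low <= 0
    if (fixed) {
      nmb <- net_monetary_benefit(base_eval$result, wtp)
      return(data.frame(parameter = nm, low = rec$base, high = rec$base,
                        nmb_low = nmb, nmb_high = nmb,
                        delta_cost_low = base_eval$result$delta_cost,
                        delta_cost_high = base_eval$result$delta_cost,
                        delta_qaly_low = base_eval$result$delta_qaly,
                        delta_qaly_high = base_eval$result$delta_qaly,
                        evaluable = TRUE))
    }
    at <- function(v) {
      res <- tryCatch(
        evaluate_model(set_param_values(ps, stats::setNames(v, nm)))$result,
        error = function(e) NULL)
      if (is.null(res)) c(NA_real_, NA_real_, NA_real_) else
        c(net_monetary_benefit(res, wtp), res$delta_cost, res$delta_qaly)
    }
    lo <- at(rec$low); hi <- at(rec$high)
    data.frame(parameter = nm, low = rec$low, high = rec$high,
               nmb_low = lo[1], nmb_high = hi[1],
               delta_cost_low = lo[2], delta_cost_high = hi[2],
               delta_qaly_low = lo[3], delta_qaly_high = hi[3],
               evaluable = !anyNA(c(lo, hi)))
  })
  out <- do.call(rbind, entries)
  out$width <- abs(out$nmb_high - out$nmb_low)
  out$crosses_zero <- pmin(out$nmb_low, out$nmb_high) < 0 &
    pmax(out$nmb_low, out$nmb_high) > 0
  out[order(-out$width), ]
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo re-evaluation of both arms under joint parameter
#' uncertainty. Each draw uses its own RNG stream seeded from a
#' draw-indexed seed table derived from `seed`, so results are reproducible
#' and independent of execution order. Draws that fail to evaluate are
#' redrawn from a perturbed stream (count reported).
#'
#' @param ps A `perio_params` object at base case.
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Integer master seed.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @return Object of class `perio_psa`: list with `samples` (data frame:
#'   draw, per-arm cost/QALY, `delta_cost`, `delta_qaly`), `ceac`
#'   (`wtp`, `prob_cost_effective`), `summary` (means and percentile 95%
#'   CIs of the increments, fraction cost-effective at the base WTP) and
#'   `n_resampled`.
#' @export
run_psa <- function(ps, n_draws = 10000, seed = 1L,
                    wtp_grid = seq(0, 150000, by = 5000)) {
  stopifnot(n_draws >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draw_seeds <- sample.int(.Machine$integer.max - 1L, n_draws)
  cols <- c("cost_perio", "qaly_perio", "cost_adj", "qaly_adj")
  m <- matrix(NA_real_, n_draws, length(cols), dimnames = list(NULL, cols))
  n_resampled <- 0L
  for (i in seq_len(n_draws)) {
    attempt <- 0L
    repeat {
      set.seed(draw_seeds[i] + attempt)
      drawn <- suppressWarnings(sample_parameter_set(ps))
      ev <- tryCatch(suppressWarnings(evaluate_model(drawn)),
                     error = function(e) NULL)
      if (!is.null(ev)) break
      attempt <- attempt + 1L
      n_resampled <- n_resampled + 1L
      if (attempt > 100L) stop("PSA draw ", i, " failed repeatedly", call. = FALSE)
    }
    m[i, ] <- c(ev$arms$perioperative$total_cost, ev$arms$perioperative$qaly,
                ev$arms$adjuvant$total_cost, ev$arms$adjuvant$qaly)
  }
  samples <- data.frame(draw = seq_len(n_draws), m)
  samples$delta_cost <- samples$cost_perio - samples$cost_adj
  samples$delta_qaly <- samples$qaly_perio - samples$qaly_adj
  ceac <- data.frame(
    wtp = wtp_grid,
    prob_cost_effective = vapply(wtp_grid, function(w)
      mean(w * samples$delta_qaly - samples$delta_cost > 0), numeric(1)))
  wtp0 <- ps$settings$wtp
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  summary <- list(
    n_draws = n_draws, seed = seed,
    mean_delta_qaly = mean(samples$delta_qaly),
    ci_delta_qaly = ci(samples$delta_qaly),
    mean_delta_cost = mean(samples$delta_cost),
    ci_delta_cost = ci(samples$delta_cost),
    mean_cost_saving = -mean(samples$delta_cost),
    prob_cost_effective_at_wtp = mean(
      wtp0 * samples$delta_qaly - samples$delta_cost > 0),
    wtp = wtp0)
  structure(list(samples = samples, ceac = ceac, summary = summary,
                 n_resampled = n_resampled, model_id = ps$model_id),
            class = "perio_psa")
}

#' Incremental scatter table from a PSA
#'
#' One row per draw (`delta_qaly`, `delta_cost`), with the willingness-to-pay
#' reference line carried as an attribute for plotting.
#'
#' @param psa A `perio_psa` object.
#' @return Data frame with attribute `wtp`.
#' @export
scatter_export <- function(psa) {
  stopifnot(inherits(psa, "perio_psa"))
  if (nrow(psa$samples) == 0) stop("PSA contains no samples", call. = FALSE)
  out <- psa$samples[, c("draw", "delta_qaly", "delta_cost")]
  attr(out, "wtp") <- psa$summary$wtp
  out
}

#' @export
print.perio_psa <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<perio_psa> model %d, %d draws (seed %d)\n  mean dQALY %.4f (95%% CI %.4f-%.4f)\n  mean dCost %.0f USD (95%% CI %.0f-%.0f)\n  P(cost-effective at %.0f USD/QALY) = %.4f\n",
    x$model_id, s$n_draws, s$seed, s$mean_delta_qaly, s$ci_delta_qaly[1],
    s$ci_delta_qaly[2], s$mean_delta_cost, s$ci_delta_cost[1],
    s$ci_delta_cost[2], s$wtp, s$prob_cost_effective_at_wtp))
  invisible(x)
}
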