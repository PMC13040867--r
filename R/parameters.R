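#' Model input parameters
#'
#' Every model input (clinical transition inputs, utilities, unit costs) is a
#' typed record with a base-case value, a low/high sensitivity range and a
#' sampling distribution for probabilistic analysis. The two bundled
#' configurations (one per model) transcribe the published input table; a
#' `ParameterSet` additionally carries run settings (discount rate, weekly
#' cycle, 40-year horizon, start age, willingness-to-pay) and the background
#' life table.
#'
#' @name parameters
NULL

PARAM_SECTIONS <- c("clinical", "utilities", "costs")

# parameters every configuration must define, regardless of model
.shared_keys <- c(
  "braf_mutant_prop",
  "tp_rem_met", "tp_death_ef", "tp_death_lr",
  "met_pfs_rate_mut", "met_os_rate_mut", "met_pfs_rate_wt", "met_os_rate_wt",
  "hr_pfs_dabtram", "hr_pfs_nivoipi", "hr_os_dabtram", "hr_os_nivoipi",
  "share_mut_dabtram", "share_mut_nivoipi", "share_mut_pembro",
  "share_wt_dabtram", "share_wt_nivoipi", "share_wt_pembro",
  "u_event_free", "u_lr_recurrence", "u_lr_remission", "u_met_pf", "u_met_prog",
  "disu_diarrhea", "disu_rash", "disu_vomiting",
  "cost_dabrafenib_mg", "cost_trametinib_mg", "cost_nivolumab_mg",
  "cost_ipilimumab_mg", "cost_pembrolizumab_mg", "cost_tvec_mg",
  "cost_braf_test",
  "mgmt_event_free", "mgmt_lr_recurrence", "mgmt_lr_remission",
  "mgmt_met_pf", "mgmt_met_prog",
  "cost_surgery", "cost_systemic_mut", "cost_systemic_wt",
  "cost_ade_diarrhea", "cost_ade_rash", "cost_ade_vomiting"
)

.model1_keys <- c(
  "prnr_braf_mutant", "prnr_braf_wt",
  "efs_hr_braf_mutant", "efs_hr_braf_wt",
  "gomp_shape_adj_nivo_mut", "gomp_rate_adj_nivo_mut",
  "gomp_shape_adj_nivo_wt", "gomp_rate_adj_nivo_wt",
  "ade_diarrhea_perio_nivoipi", "ade_rash_perio_nivoipi",
  "ade_diarrhea_adj_nivo", "ade_rash_adj_nivo",
  "tp_ef_met_perio_nivoipi_mut", "tp_ef_met_perio_nivoipi_wt",
  "tp_ef_met_adj_nivo_mut", "tp_ef_met_adj_nivo_wt"
)

.model2_keys <- c(
  "gomp_shape_perio_pembro", "gomp_rate_perio_pembro",
  "gomp_shape_adj_pembro", "gomp_rate_adj_pembro",
  "ade_diarrhea_perio_pembro", "ade_rash_perio_pembro", "ade_vomiting_perio_pembro",
  "ade_diarrhea_adj_pembro", "ade_rash_adj_pembro", "ade_vomiting_adj_pembro",
  "tp_ef_met_perio_pembro", "tp_ef_met_adj_pembro"
)

#' Names of the parameters a model configuration must provide
#'
#' @param model_id 1 (perioperative nivolumab+ipilimumab vs adjuvant
#'   nivolumab) or 2 (perioperative vs adjuvant pembrolizumab).
#' @return Character vector of parameter names.
#' @export
required_parameters <- function(model_id) {
  model_id <- match_model_id(model_id)
  c(.shared_keys, if (model_id == 1L) .model1_keys else .model2_keys)
}

match_model_id <- function(model_id) {
  if (length(model_id) != 1L || !model_id %in% c(1, 2)) {
    stop("`model_id` must be 1 or 2", call. = FALSE)
  }
  as.integer(model_id)
}

#' Path to a bundled model configuration
#'
#' @inheritParams required_parameters
#' @return Path to the packaged YAML configuration.
#' @export
default_config <- function(model_id) {
  model_id <- match_model_id(model_id)
  system.file("extdata", sprintf("model%d.yaml", model_id),
              package = "periomel", mustWork = TRUE)
}

#' Load and validate a model parameter set
#'
#' Reads a YAML/JSON configuration, checks completeness against
#' [required_parameters()], validates every record's invariants
#' (`low <= base <= high` where a real range exists, probabilities and
#' utilities in \[0, 1\], non-negative costs and rates, non-positive
#' disutilities) and attaches the background life table. Records whose
#' printed base value falls outside the printed sensitivity range are kept
#' as printed but reported via a warning, mirroring the source table's known
#' inconsistencies.
#'
#' @param config Path to a YAML (or JSON) configuration document. `NULL`
#'   loads the bundled configuration for `model_id`.
#' @inheritParams required_parameters
#' @param life_table Optional data frame with columns `age_years` and
#'   `weekly_mortality_probability`, overriding the configured life table.
#' @return An object of class `perio_params`: list with elements `model_id`,
#'   `params` (named list of parameter records; each has `name`, `base`,
#'   `low`, `high`, `dist`, `value` and optional `pair`/`role`/`group`/
#'   `owsa` fields), `settings` and `life_table`.
#' @export
#' @examples
#' ps <- load_parameters(model_id = 1)
#' param_value(ps, "cost_ipilimumab_mg")
load_parameters <- function(config = NULL, model_id, life_table = NULL) {
  model_id <- match_model_id(model_id)
  if (is.null(config)) config <- default_config(model_id)
  doc <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
    jsonlite::read_json(config, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(config)
  }
  if (!identical(as.integer(doc$model_id), model_id)) {
    stop(sprintf("configuration declares model_id %s, requested %d",
                 doc$model_id %||% "<missing>", model_id), call. = FALSE)
  }
  params <- list()
  for (section in PARAM_SECTIONS) {
    sec <- doc[[section]]
    for (nm in names(sec)) {
      rec <- sec[[nm]]
      rec$name <- nm
      rec$section <- section
      rec$value <- rec$base
      params[[nm]] <- rec
    }
  }
  missing <- setdiff(required_parameters(model_id), names(params))
  if (length(missing)) {
    stop("configuration is missing required parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ps <- structure(
    list(model_id = model_id, params = params,
         settings = doc$settings, life_table = NULL),
    class = "perio_params"
  )
  ps$life_table <- life_table %||% resolve_life_table(ps, dirname(config))
  validate_parameters(ps)
  ps
}

`%||%` <- function(x, y) if (is.null(x)) y else x

resolve_life_table <- function(ps, config_dir) {
  lt <- ps$settings$life_table %||% "life_table_synthetic.csv"
  candidates <- c(lt, file.path(config_dir, lt),
                  system.file("extdata", lt, package = "periomel"))
  path <- candidates[file.exists(candidates) & !dir.exists(candidates)][1]
  if (is.na(path)) stop("life table not found: ", lt, call. = FALSE)
  load_life_table(path)
}

#' Read a life table from CSV
#'
#' @param path CSV with columns `age_years`, `weekly_mortality_probability`.
#' @return Data frame of class `perio_life_table`.
#' @export
load_life_table <- function(path) {
  lt <- utils::read.csv(path)
  need <- c("age_years", "weekly_mortality_probability")
  if (!all(need %in% names(lt))) {
    stop("life table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(lt$weekly_mortality_probability < 0 |
            lt$weekly_mortality_probability > 1)) {
    stop("life-table weekly mortality probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  class(lt) <- c("perio_life_table", "data.frame")
  lt
}

#' Validate a parameter set
#'
#' Checks every record's invariants, reporting all violations at once, each
#' by parameter name. Printed base values lying outside their printed range
#' (a known inconsistency of three utility rows in the source table) are
#' surfaced as a warning, not an error.
#'
#' @param ps A `perio_params` object.
#' @return `ps`, invisibly, on success.
#' @export
validate_parameters <- function(ps) {
  stopifnot(inherits(ps, "perio_params"))
  errors <- character()
  flagged <- character()
  for (rec in ps$params) {
    nm <- rec$name
    vals <- c(rec$base, rec$low, rec$high)
    if (any(!is.finite(vals))) {
      errors <- c(errors, sprintf("%s: non-finite base/low/high", nm))
      next
    }
    if (rec$low > rec$high) {
      errors <- c(errors, sprintf("%s: low (%g) > high (%g)", nm, rec$low, rec$high))
    }
    in01 <- grepl("^(u_|ade_|tp_|prnr_|braf_|share_)", nm)
    if (in01 && (rec$base < 0 || rec$base > 1)) {
      errors <- c(errors, sprintf(
        "%s: probability/utility %g outside [0, 1]", nm, rec$base))
    }
    if (grepl("^(cost_|mgmt_|met_)", nm) && rec$base < 0) {
      errors <- c(errors, sprintf("%s: negative cost/rate %g", nm, rec$base))
    }
    if (grepl("^disu_", nm) && rec$base > 0) {
      errors <- c(errors, sprintf("%s: disutility must be <= 0, got %g", nm, rec$base))
    }
    if (grepl("^(hr_|efs_hr_)", nm) && rec$base <= 0) {
      errors <- c(errors, sprintf("%s: hazard ratio must be > 0", nm))
    }
    if (rec$base < rec$low || rec$base > rec$high) {
      flagged <- c(flagged, sprintf("%s: base %g outside printed range [%g, %g]",
                                    nm, rec$base, rec$low, rec$high))
    }
  }
  for (grp in c("share_mut", "share_wt")) {
    shares <- vapply(ps$params[param_group(ps, grp)], `[[`, numeric(1), "base")
    if (abs(sum(shares) - 1) > 1e-9) {
      errors <- c(errors, sprintf("systemic-therapy shares '%s' sum to %g, not 1",
                                  grp, sum(shares)))
    }
  }
  horizon <- ps$settings$horizon_years * 52L
  if (!identical(as.integer(horizon), 2080L)) {
    errors <- c(errors, sprintf("horizon is %d weekly cycles, expected 2080", horizon))
  }
  if (length(errors)) {
    stop("parameter validation failed:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  if (length(flagged)) {
    warning("base value outside printed sensitivity range (kept as printed):\n  ",
            paste(flagged, collapse = "\n  "), call. = FALSE)
  }
  invisible(ps)
}

param_group <- function(ps, group) {
  names(ps$params)[vapply(ps$params, function(r) identical(r$group, group), logical(1))]
}

#' Current value of a parameter
#'
#' Returns the record's `value` slot, which equals `base` unless the set has
#' been perturbed by the one-way or probabilistic sensitivity machinery.
#'
#' @param ps A `perio_params` object.
#' @param name Parameter name.
#' @return Numeric scalar.
#' @export
param_value <- function(ps, name) {
  rec <- ps$params[[name]]
  if (is.null(rec)) stop("unknown parameter: ", name, call. = FALSE)
  rec$value
}

#' Base-case value of a parameter
#' @inheritParams param_value
#' @return Numeric scalar.
#' @export
param_base <- function(ps, name) {
  rec <- ps$params[[name]]
  if (is.null(rec)) stop("unknown parameter: ", name, call. = FALSE)
  rec$base
}

#' Replace parameter values
#'
#' @param ps A `perio_params` object.
#' @param values Named numeric vector or list of replacement values.
#' @return The modified `perio_params` object.
#' @export
set_param_values <- function(ps, values) {
  for (nm in names(values)) {
    if (is.null(ps$params[[nm]])) stop("unknown parameter: ", nm, call. = FALSE)
    ps$params[[nm]]$value <- as.numeric(values[[nm]])
  }
  ps
}

#' Default +/-20% sensitivity range
#'
#' For inputs without a reported interval, the sensitivity range is 20%
#' either side of the base value, sign-aware so that `low <= high` also for
#' negative inputs such as disutilities.
#'
#' @param base Finite numeric scalar.
#' @return Numeric vector `c(low, high)`.
#' @export
#' @examples
#' range_from_default(100)    # c(80, 120)
#' range_from_default(-0.047) # c(-0.0564, -0.0376)
range_from_default <- function(base) {
  stopifnot(is.finite(base))
  sort(c(0.8, 1.2) * base)
}

#' Serialise a parameter set back to YAML
#'
#' Writes the current records and settings so that [load_parameters()] on
#' the result reproduces the set (round-trip identity up to the attached
#' life table, which is referenced by file name).
#'
#' @param ps A `perio_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path) {
  doc <- list(model_id = ps$model_id, settings = ps$settings)
  for (section in PARAM_SECTIONS) {
    recs <- Filter(function(r) identical(r$section, section), ps$params)
    doc[[section]] <- lapply(recs, function(r) {
      r$section <- NULL
      r$name <- NULL
      r$value <- NULL
      r
    })
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.perio_params <- function(x, ...) {
  cat(sprintf("<perio_params> model %d: %d parameters, start age %s, %s-year horizon\n",
              x$model_id, length(x$params), x$settings$start_age_years,
              x$settings$horizon_years))
  invisible(x)
}
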