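## Deterministic sensitivity analysis: one-way (tornado) ranges and the
## published intervention-cost and horizon scenarios.

# default one-way range for a parameter: its 95% CI, except the intervention
# cost, whose published one-way analysis spans the scenario costs up to $3,304
.dsa_range <- function(params, name) {
  est <- params$estimates
  row <- est[est$name == name, ]
  if (nrow(row) != 1 || is.na(row$ci_low) || is.na(row$ci_high))
    stop("parameter '", name, "' has no range for one-way sensitivity analysis")
  if (name == "c_intervention") c(row$ci_low, 3304)
  else c(row$ci_low, row$ci_high)
}

# parameters eligible for one-way analysis (those carrying a CI)
.dsa_parameters <- function(params) {
  est <- params$estimates
  est$name[!is.na(est$ci_low) & !is.na(est$ci_high) &
             !est$family %in% c("fixed", "complement")]
}

# pin one parameter to a value, keeping the major/minor splits summing to 1
.pin_parameter <- function(params, name, value) {
  params[[name]] <- value
  if (name == "p_fx_major") params$p_fx_minor <- 1 - value
  if (name == "p_inj_major") params$p_inj_minor <- 1 - value
  validate_parameters(params)
  params
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full base case twice per parameter with the parameter pinned to
#' the ends of its one-way range (all other parameters at their means) and
#' records the incremental net monetary benefit at each end. Ranges default to
#' the published 95% CI bounds; the intervention cost ranges up to the largest
#' published scenario cost ($3,304) since that is the variation the published
#' one-way analysis explored. The major fracture/injury shares move their
#' minor complements with them so the splits keep summing to one.
#'
#' @param params An `adt_params` parameter set.
#' @param parameters Character vector of parameter names; default all
#'   parameters carrying a confidence interval.
#' @return Tibble sorted by decreasing spread with columns `parameter`,
#'   `low_value`, `high_value`, `inmb_at_low`, `inmb_at_high`, `spread`.
#' @export
univariate_sa <- function(params, parameters = NULL) {
  validate_parameters(params)
  if (is.null(parameters)) parameters <- .dsa_parameters(params)
  rows <- lapply(parameters, function(nm) {
    rng <- .dsa_range(params, nm)
    lo <- run_cua(.pin_parameter(params, nm, rng[1]))$inmb
    hi <- run_cua(.pin_parameter(params, nm, rng[2]))$inmb
    tibble::tibble(parameter = nm, low_value = rng[1], high_value = rng[2],
                   inmb_at_low = lo, inmb_at_high = hi, spread = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out[order(-out$spread, out$parameter), ]
}

#' Run a named scenario
#'
#' Applies a [scenario_override()] to the base parameter set and runs the full
#' cost-utility pipeline on the result.
#'
#' @param params An `adt_params` parameter set.
#' @param scenario An `adt_scenario`; see [named_scenarios()] for the
#'   published intervention-cost scenarios.
#' @return A `cua_result`.
#' @export
run_scenario <- function(params, scenario) {
  run_cua(apply_override(params, scenario))
}

#' Scenario summary table
#'
#' Runs a list of scenarios and collects their headline results next to the
#' base case.
#'
#' @param params An `adt_params` parameter set.
#' @param scenarios List of `adt_scenario` objects; defaults to the published
#'   intervention-cost scenarios of [named_scenarios()].
#' @return Tibble with one row per scenario (base case first): overridden
#'   values, increments, iNMB and dominance.
#' @export
scenario_table <- function(params, scenarios = named_scenarios()) {
  base <- run_cua(params)
  row <- function(name, overrides, res) tibble::tibble(
    scenario = name,
    overrides = if (length(overrides) == 0) "" else
      paste(names(overrides), unlist(overrides), sep = "=", collapse = "; "),
    cost_control = res$control$total_cost,
    cost_intervention = res$intervention$total_cost,
    qalys_control = res$control$total_qalys,
    qalys_intervention = res$intervention$total_qalys,
    delta_cost = res$delta_cost, delta_qalys = res$delta_qalys,
    inmb = res$inmb, dominance = res$dominance
  )
  out <- list(row("base", list(), base))
  for (sc in scenarios)
    out[[length(out) + 1]] <- row(sc$name, sc$overrides,
                                  run_scenario(params, sc))
  do.call(rbind, out)
}
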