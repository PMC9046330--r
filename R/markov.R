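## Cohort engine: per-cycle transition dynamics over the seven operational
## states and accumulation of discounted, half-cycle-corrected rewards.
##
## State layout (fixed order used by every matrix and trace):
##   1 at_risk_first      pre-fall "well" state, everyone starts here
##   2 at_risk_recurrent  post-fall state carrying the fear-of-falling utility
##   3 fracture_major     ┐
##   4 fracture_minor     │ single-cycle tunnel states entered on a fall;
##   5 injury_major       │ one-off treatment cost charged on entry
##   6 injury_minor       ┘ (minor injury also holds uninjured fallers)
##   7 dead               absorbing

#' Health state labels in canonical order
#' @return Character vector of the seven state names.
#' @export
health_states <- function() {
  c("at_risk_first", "at_risk_recurrent", "fracture_major", "fracture_minor",
    "injury_major", "injury_minor", "dead")
}

#' Convert an annual probability to a shorter cycle
#'
#' Constant-rate (exponential) conversion: `1 - (1 - p)^f` for a cycle that is
#' fraction `f` of a year. Monotone in both arguments and exact at the
#' endpoints 0 and 1.
#'
#' @param p_annual Annual probability in [0, 1].
#' @param cycle_fraction Cycle length as a fraction of a year, in (0, 1].
#' @return Per-cycle probability.
#' @examples
#' annual_to_cycle_prob(0.36, 0.25) # 1 - 0.64^0.25 = 0.105573
#' @export
annual_to_cycle_prob <- function(p_annual, cycle_fraction) {
  if (any(p_annual < 0 | p_annual > 1))
    stop("p_annual must be in [0, 1]")
  if (any(cycle_fraction <= 0 | cycle_fraction > 1))
    stop("cycle_fraction must be in (0, 1]")
  1 - (1 - p_annual)^cycle_fraction
}

# age-band lookup for the probability of death given a major fall event
.fall_death_prob <- function(params, age) {
  if (age < 60) stop("no fall-death probability defined below age 60")
  if (age < 65) return(params$p_death_fall_60_64)
  if (age < 70) return(params$p_death_fall_65_69)
  if (age < 75) return(params$p_death_fall_70_74)
  stop("no fall-death probability defined at age ", age)
}

# exercise-arm relative risks, active only while the effect lasts
.arm_rr <- function(params, arm, years_elapsed) {
  active <- arm == "intervention" && years_elapsed < params$effect_years
  list(
    fall = if (active) params$rr_fall_exercise else 1,
    fx   = if (active) params$rr_fracture_exercise else 1,
    inj  = if (active) params$rr_injury_exercise else 1
  )
}

#' Distribution of outcomes conditional on a fall
#'
#' Given that a fall occurs, the faller is routed through the event tree:
#' fracture with probability `p_fracture` (split major/minor), otherwise a
#' non-fracture injury that is major with probability
#' `p_nonfx_injury * p_inj_major` and minor otherwise — the minor-injury state
#' also receives fallers without a treated injury, whose utility and averaged
#' treatment cost the minor-injury state represents. Only major events carry a
#' risk of death, with the age-band probability of death given a major event.
#'
#' In the exercise arm the conditional branch probabilities are scaled by
#' `rr_outcome / rr_fall` while the intervention effect lasts, so that the
#' published marginal annual relative risks for fractures and injuries are
#' preserved after the fall probability itself is reduced by `rr_fall`. A
#' scaled conditional fracture probability above one is an error (the
#' decomposition is infeasible); the injury branch instead saturates at one,
#' the ceiling at which every non-fracture faller is injured.
#'
#' @param params An `adt_params` parameter set.
#' @param arm `"control"` or `"intervention"`.
#' @param age Current (possibly fractional) age in years.
#' @param years_elapsed Model time in years since baseline (drives the
#'   intervention effect window); default 0.
#' @return Named probability vector over `dead`, `fracture_major`,
#'   `fracture_minor`, `injury_major`, `injury_minor`, `at_risk_recurrent`,
#'   summing to 1.
#' @export
fall_outcome_distribution <- function(params, arm = c("control", "intervention"),
                                      age, years_elapsed = 0) {
  arm <- match.arg(arm)
  rr <- .arm_rr(params, arm, years_elapsed)
  pd <- .fall_death_prob(params, age)
  q_fx <- params$p_fracture * rr$fx / rr$fall
  if (q_fx > 1)
    stop("infeasible decomposition: conditional fracture probability ",
         signif(q_fx, 4), " = p_fracture * rr_fracture / rr_fall exceeds 1")
  # the injury pathway saturates when every non-fracture faller is injured
  p_inj <- min(1, params$p_nonfx_injury * rr$inj / rr$fall)
  fx_major <- q_fx * params$p_fx_major
  fx_minor <- q_fx * params$p_fx_minor
  inj_major <- (1 - q_fx) * p_inj * params$p_inj_major
  inj_minor <- (1 - q_fx) * (p_inj * params$p_inj_minor + (1 - p_inj))
  c(dead = pd * (fx_major + inj_major),
    fracture_major = fx_major * (1 - pd),
    fracture_minor = fx_minor,
    injury_major = inj_major * (1 - pd),
    injury_minor = inj_minor,
    at_risk_recurrent = 0)
}

#' Per-cycle transition matrix
#'
#' Builds the 7x7 row-stochastic matrix for one arm and cycle. The two at-risk
#' rows combine the per-cycle fall probability (annual first-fall or
#' recurrent-fall probability, times the fall relative risk in the exercise
#' arm while the effect lasts, converted by [annual_to_cycle_prob()]) with the
#' conditional outcome tree of [fall_outcome_distribution()]; non-fallers face
#' per-cycle background mortality and otherwise remain. Tunnel states exit to
#' the recurrent-risk state unless background mortality intervenes; death is
#' absorbing. Age advances by the cycle fraction each cycle; the fall-death
#' band uses exact fractional age and background mortality the completed year
#' of age.
#'
#' @inheritParams fall_outcome_distribution
#' @param cycle_index Zero-based cycle index.
#' @return 7x7 matrix with dimnames [health_states()].
#' @export
build_transition_matrix <- function(params, arm = c("control", "intervention"),
                                    cycle_index) {
  arm <- match.arg(arm)
  f <- params$cycle_months / 12
  n <- round(params$horizon_years * 12 / params$cycle_months)
  if (cycle_index < 0 || cycle_index >= n)
    stop("cycle_index must be in [0, ", n - 1, "]")
  years <- cycle_index * f
  age <- params$start_age + years
  rr <- .arm_rr(params, arm, years)
  q_bg <- annual_to_cycle_prob(
    params$background_mortality[[as.character(floor(age))]], f)
  outcome <- fall_outcome_distribution(params, arm, age, years)

  s <- health_states()
  M <- matrix(0, 7, 7, dimnames = list(s, s))
  for (row in 1:2) {
    p_ann <- if (row == 1) params$p_fall_year1 else params$p_fall_recurrent
    p_fall <- annual_to_cycle_prob(min(p_ann * rr$fall, 1), f)
    M[row, 3:6] <- p_fall * outcome[2:5]
    M[row, 7] <- p_fall * outcome[["dead"]] + (1 - p_fall) * q_bg
    M[row, 2] <- p_fall * outcome[["at_risk_recurrent"]] +
      (row == 2) * (1 - p_fall) * (1 - q_bg)
    M[row, 1] <- (row == 1) * (1 - p_fall) * (1 - q_bg)
  }
  for (row in 3:6) {
    M[row, 2] <- 1 - q_bg
    M[row, 7] <- q_bg
  }
  M[7, 7] <- 1
  M
}

# state utility vector for an arm
.state_utilities <- function(params, arm) {
  c(params$u_baseline,
    if (arm == "intervention") params$u_recurrent_exercise
    else params$u_recurrent_control,
    params$u_fx_major, params$u_fx_minor,
    params$u_inj_major, params$u_inj_minor,
    0)
}

# one-off treatment cost charged on entry into each state
.state_entry_costs <- function(params) {
  c(0, 0, params$c_fx_major, params$c_fx_minor,
    params$c_inj_major, params$c_inj_minor, 0)
}

#' Run the cohort model for one arm
#'
#' Propagates the full cohort (all mass starting in the pre-fall at-risk
#' state) through `horizon_years * 12 / cycle_months` cycles and accumulates
#' rewards:
#' * QALYs: state membership times state utility times the cycle length in
#'   years, half-cycle corrected (half weight on the initial and terminal
#'   occupancy rows) and discounted at `(1 + discount_annual)^(-t f)`.
#' * Event costs: the one-off treatment cost of each tunnel state, charged on
#'   entry in the entry cycle only, discounted by the entry cycle's factor,
#'   not half-cycle corrected.
#' * The intervention cost is charged once at time zero, undiscounted, in the
#'   intervention arm.
#'
#' @inheritParams fall_outcome_distribution
#' @param validate Re-check parameter invariants before running (default
#'   `TRUE`; the PSA loop validates once up front and skips per-draw checks).
#' @return An object of class `cohort_trace`: list with `arm`, `occupancy`
#'   ((n_cycles + 1) x 7 matrix), `cycle_costs` and `cycle_qalys` (discounted,
#'   indexed by cycle 0..n), `total_cost`, `total_qalys`,
#'   `undiscounted_life_years`, and the number of cycles `n_cycles`.
#' @export
run_cohort <- function(params, arm = c("control", "intervention"),
                       validate = TRUE) {
  arm <- match.arg(arm)
  if (validate) validate_parameters(params)
  f <- params$cycle_months / 12
  n <- round(params$horizon_years * 12 / params$cycle_months)

  occ <- matrix(0, n + 1, 7, dimnames = list(0:n, health_states()))
  occ[1, 1] <- 1
  for (t in seq_len(n))
    occ[t + 1, ] <- occ[t, ] %*% build_transition_matrix(params, arm, t - 1)

  disc <- (1 + params$discount_annual)^(-(0:n) * f)
  hc <- c(0.5, rep(1, n - 1), 0.5)
  u <- .state_utilities(params, arm)
  ec <- .state_entry_costs(params)

  cycle_qalys <- as.numeric(hc * disc * (occ %*% u) * f)
  # tunnel occupancy at cycle t equals entries during cycle t (states last one cycle)
  entry_costs <- as.numeric(disc * (occ %*% ec))
  entry_costs[1] <- 0
  cycle_costs <- entry_costs
  if (arm == "intervention") cycle_costs[1] <- cycle_costs[1] + params$c_intervention

  alive <- c(rep(1, 6), 0)
  structure(list(
    arm = arm,
    occupancy = occ,
    cycle_qalys = cycle_qalys,
    cycle_costs = cycle_costs,
    total_qalys = sum(cycle_qalys),
    total_cost = sum(cycle_costs),
    undiscounted_life_years = sum(hc * (occ %*% alive) * f),
    n_cycles = n,
    cycle_months = params$cycle_months,
    wtp = params$wtp
  ), class = "cohort_trace")
}

#' Export a cohort trace as a per-cycle tibble
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @return Tibble with cycle index, arm, the seven occupancy columns,
#'   discounted per-cycle cost and QALYs, and running totals.
#' @export
trace_table <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  occ <- tibble::as_tibble(as.data.frame(trace$occupancy))
  tibble::tibble(
    cycle = 0:trace$n_cycles,
    arm = trace$arm,
    occ,
    cost_disc = trace$cycle_costs,
    qaly_disc = trace$cycle_qalys,
    cum_cost = cumsum(trace$cycle_costs),
    cum_qalys = cumsum(trace$cycle_qalys)
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace [%s]: %d cycles of %g months\n",
              x$arm, x$n_cycles, x$cycle_months))
  cat(sprintf("  discounted cost  $%.0f\n  discounted QALYs %.4f\n",
              x$total_cost, x$total_qalys))
  cat(sprintf("  undiscounted life-years %.4f; surviving fraction %.4f\n",
              x$undiscounted_life_years,
              1 - x$occupancy[x$n_cycles + 1, 7]))
  invisible(x)
}
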