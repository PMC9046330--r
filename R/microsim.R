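## Individual-level Monte Carlo twin of the cohort engine. Large-n averages
## of realised discounted costs and QALYs converge to the cohort totals at
## the 1/sqrt(n) rate, which is the package's strongest end-to-end check: a
## discrepancy isolates reward-accumulation or trace bugs ("engine" mode,
## which reuses the engine's transition matrices) or probability-construction
## bugs ("independent" mode, which re-derives every per-cycle probability
## from the raw annual parameters with its own code path).

# independently re-derived per-cycle quantities for one arm and cycle:
# deliberately not calling build_transition_matrix / fall_outcome_distribution
.independent_cycle <- function(params, arm, cycle_index) {
  f <- params$cycle_months / 12
  years <- cycle_index * f
  age <- params$start_age + years
  on_effect <- arm == "intervention" && years < params$effect_years
  rr_fall <- if (on_effect) params$rr_fall_exercise else 1
  rr_fx <- if (on_effect) params$rr_fracture_exercise else 1
  rr_inj <- if (on_effect) params$rr_injury_exercise else 1
  pd <- if (age < 65) params$p_death_fall_60_64
        else if (age < 70) params$p_death_fall_65_69
        else params$p_death_fall_70_74
  list(
    p_fall_first = 1 - (1 - min(params$p_fall_year1 * rr_fall, 1))^f,
    p_fall_rec = 1 - (1 - min(params$p_fall_recurrent * rr_fall, 1))^f,
    q_fx = params$p_fracture * rr_fx / rr_fall,
    p_inj = min(1, params$p_nonfx_injury * rr_inj / rr_fall),
    p_death_major = pd,
    q_bg = 1 - (1 - params$background_mortality[[as.character(floor(age))]])^f
  )
}

#' Simulate individual trajectories
#'
#' Simulates `n` individuals through the identical stochastic process the
#' cohort engine integrates: everyone starts in the pre-fall at-risk state;
#' each cycle a fall may occur, fallers are routed through the fracture /
#' injury / death tree, tunnel states last one cycle, and background
#' mortality acts on everyone. Realised rewards use the same half-cycle
#' weighting, discounting and one-off entry costs as [run_cohort()], so the
#' cohort totals are the exact expectation of the per-person totals.
#'
#' @param params An `adt_params` parameter set.
#' @param arm `"control"` or `"intervention"`.
#' @param n Number of individuals.
#' @param seed Integer seed; runs are reproducible from `(params, arm, n,
#'   seed, mode)`.
#' @param mode `"engine"` samples transitions from the cohort engine's own
#'   per-cycle matrices; `"independent"` re-derives every probability from
#'   the raw annual parameters with separate code, giving a fully independent
#'   end-to-end check.
#' @return An object of class `microsim_result`: `mean_cost`, `se_cost`,
#'   `mean_qalys`, `se_qalys`, and `states`, the n x (n_cycles + 1) integer
#'   matrix of visited state indices (see [health_states()]).
#' @export
simulate_individuals <- function(params, arm = c("control", "intervention"),
                                 n, seed, mode = c("engine", "independent")) {
  arm <- match.arg(arm)
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  validate_parameters(params)
  f <- params$cycle_months / 12
  nc <- round(params$horizon_years * 12 / params$cycle_months)
  set.seed(.substream_seed(seed, paste("microsim", arm, mode)))

  states <- matrix(NA_integer_, n, nc + 1)
  states[, 1] <- 1L
  cur <- rep(1L, n)
  for (t in seq_len(nc)) {
    nxt <- cur
    if (mode == "engine") {
      M <- build_transition_matrix(params, arm, t - 1)
      for (s in 1:6) {
        idx <- which(cur == s)
        if (length(idx) > 0)
          nxt[idx] <- sample.int(7L, length(idx), replace = TRUE,
                                 prob = M[s, ])
      }
    } else {
      cy <- .independent_cycle(params, arm, t - 1)
      for (s in 1:2) {
        idx <- which(cur == s)
        if (length(idx) == 0) next
        k <- length(idx)
        p_fall <- if (s == 1) cy$p_fall_first else cy$p_fall_rec
        fell <- stats::runif(k) < p_fall
        # non-fallers: background mortality else remain
        stay <- idx[!fell]
        nxt[stay] <- ifelse(stats::runif(length(stay)) < cy$q_bg, 7L, s)
        # fallers: fracture? injury severity? death after a major event?
        fal <- idx[fell]
        kf <- length(fal)
        if (kf > 0) {
          is_fx <- stats::runif(kf) < cy$q_fx
          is_major <- ifelse(is_fx,
                             stats::runif(kf) < params$p_fx_major,
                             stats::runif(kf) < cy$p_inj * params$p_inj_major)
          dest <- ifelse(is_fx, ifelse(is_major, 3L, 4L),
                         ifelse(is_major, 5L, 6L))
          dies <- is_major & stats::runif(kf) < cy$p_death_major
          nxt[fal] <- ifelse(dies, 7L, dest)
        }
      }
      for (s in 3:6) {
        idx <- which(cur == s)
        if (length(idx) > 0)
          nxt[idx] <- ifelse(stats::runif(length(idx)) < cy$q_bg, 7L, 2L)
      }
    }
    cur <- nxt
    states[, t + 1] <- cur
  }

  u <- .state_utilities(params, arm)
  ec <- .state_entry_costs(params)
  disc <- (1 + params$discount_annual)^(-(0:nc) * f)
  hc <- c(0.5, rep(1, nc - 1), 0.5)
  qaly_w <- outer(rep(1, n), hc * disc * f)
  qalys <- rowSums(qaly_w * matrix(u[states], n, nc + 1))
  cost_w <- outer(rep(1, n), disc)
  cost_w[, 1] <- 0
  costs <- rowSums(cost_w * matrix(ec[states], n, nc + 1)) +
    (arm == "intervention") * params$c_intervention

  structure(list(
    arm = arm, mode = mode, n = n, seed = seed,
    mean_cost = mean(costs), se_cost = stats::sd(costs) / sqrt(n),
    mean_qalys = mean(qalys), se_qalys = stats::sd(qalys) / sqrt(n),
    states = states
  ), class = "microsim_result")
}

#' Long-format trajectory table
#'
#' @param sim A `microsim_result`.
#' @return Tibble with columns `person`, `cycle`, `state`.
#' @export
trajectory_table <- function(sim) {
  stopifnot(inherits(sim, "microsim_result"))
  nc <- ncol(sim$states) - 1
  tibble::tibble(
    person = rep(seq_len(sim$n), times = nc + 1),
    cycle = rep(0:nc, each = sim$n),
    state = health_states()[as.vector(sim$states)]
  )
}

#' Validate the cohort engine against the microsimulation
#'
#' Runs the microsimulation for both arms and compares its mean discounted
#' cost and QALYs with the cohort engine's totals via z-scores
#' `z = (microsim mean - cohort value) / SE`. Under a correct engine all |z|
#' stay below about 3 for large `n`.
#'
#' @param params An `adt_params` parameter set.
#' @param n Individuals per arm.
#' @param seed Integer seed.
#' @param mode Passed to [simulate_individuals()].
#' @return Tibble with one row per (arm, quantity): microsim mean, SE, cohort
#'   value and z-score.
#' @export
compare_to_cohort <- function(params, n, seed, mode = "engine") {
  rows <- lapply(c("control", "intervention"), function(arm) {
    sim <- simulate_individuals(params, arm, n, seed, mode)
    coh <- run_cohort(params, arm)
    tibble::tibble(
      arm = arm,
      quantity = c("cost", "qalys"),
      microsim = c(sim$mean_cost, sim$mean_qalys),
      se = c(sim$se_cost, sim$se_qalys),
      cohort = c(coh$total_cost, coh$total_qalys),
      z = (microsim - cohort) / se
    )
  })
  do.call(rbind, rows)
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("Microsimulation [%s, %s mode]: n = %d\n", x$arm, x$mode, x$n))
  cat(sprintf("  mean cost  $%.1f (SE %.1f)\n", x$mean_cost, x$se_cost))
  cat(sprintf("  mean QALYs %.4f (SE %.4f)\n", x$mean_qalys, x$se_qalys))
  invisible(x)
}
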