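## Probabilistic sensitivity analysis: distribution fitting, joint sampling,
## Monte Carlo propagation, NMB summaries and the acceptability curve.

# deterministic per-parameter seed so draws are invariant to the order in
# which parameters are listed; kept below 2^31 - 1
.substream_seed <- function(seed, name, round = 0L) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) * 7919 + h + 97 * round) %% 2147483647)
}

#' Fitted PSA sampling distributions
#'
#' Fits the sampling distribution of every uncertain parameter (family beta,
#' gamma or lognormal) from its registered mean and 95% CI, via
#' [fit_beta_from_ci()], [fit_gamma_from_ci()] and [fit_lognormal_from_ci()].
#' `complement` entries (the minor fracture/injury shares) are derived as one
#' minus their major counterpart rather than sampled, which preserves the
#' sum-to-one invariant; `fixed` entries are never sampled.
#'
#' @param params An `adt_params` parameter set.
#' @return Named list of fits, each `list(family, pars)`.
#' @export
psa_distributions <- function(params) {
  est <- params$estimates
  sampled <- est[!est$family %in% c("fixed", "complement"), ]
  fits <- lapply(seq_len(nrow(sampled)), function(i) {
    e <- sampled[i, ]
    pars <- switch(e$family,
      beta = fit_beta_from_ci(e$mean, e$ci_low, e$ci_high),
      gamma = fit_gamma_from_ci(e$mean, e$ci_low, e$ci_high),
      lognormal = fit_lognormal_from_ci(e$mean, e$ci_low, e$ci_high),
      stop("no sampling rule for family '", e$family, "'"))
    list(family = e$family, pars = pars)
  })
  stats::setNames(fits, sampled$name)
}

# n draws of every uncertain parameter; one substream per parameter
.draw_matrix <- function(fits, n, seed, round = 0L) {
  draws <- matrix(NA_real_, n, length(fits),
                  dimnames = list(NULL, names(fits)))
  for (nm in names(fits)) {
    f <- fits[[nm]]
    set.seed(.substream_seed(seed, nm, round))
    draws[, nm] <- switch(f$family,
      beta = stats::rbeta(n, f$pars[["alpha"]], f$pars[["beta"]]),
      gamma = stats::rgamma(n, shape = f$pars[["shape"]],
                            scale = f$pars[["scale"]]),
      lognormal = if (f$pars[["sigma"]] == 0) rep(exp(f$pars[["mu"]]), n)
        else stats::rlnorm(n, f$pars[["mu"]], f$pars[["sigma"]]))
  }
  draws
}

# rows whose sampled values break the conditional event-tree decomposition
# in the exercise arm (the control conditionals are probabilities already)
.infeasible_rows <- function(draws) {
  draws[, "p_fracture"] * draws[, "rr_fracture_exercise"] /
    draws[, "rr_fall_exercise"] > 1 |
  draws[, "p_nonfx_injury"] * draws[, "rr_injury_exercise"] /
    draws[, "rr_fall_exercise"] > 1
}

# write one draw row into a parameter set
.apply_draw <- function(params, draw) {
  for (nm in names(draw)) params[[nm]] <- draw[[nm]]
  params$p_fx_minor <- 1 - params$p_fx_major
  params$p_inj_minor <- 1 - params$p_inj_major
  params
}

#' Draw one joint parameter sample
#'
#' Single random draw of every uncertain parameter from its fitted
#' distribution; fixed fields (threshold, discounting, horizon, background
#' mortality) are untouched and the minor shares follow their sampled major
#' counterparts. Deterministic given `(seed, draw_index)` and invariant to
#' parameter ordering.
#'
#' @param params An `adt_params` parameter set.
#' @param seed Integer seed.
#' @param draw_index Which draw of the stream to return (default 1).
#' @return An `adt_params` with sampled values.
#' @export
sample_parameters <- function(params, seed, draw_index = 1L) {
  fits <- psa_distributions(params)
  draws <- .draw_matrix(fits, draw_index, seed)
  .apply_draw(params, draws[draw_index, ])
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws whose incremental net monetary benefit is
#' non-negative (ties count as cost-effective) at each willingness-to-pay
#' value of an ascending grid. At `wtp = 0` this reduces to the probability
#' that the intervention is cost saving.
#'
#' @param samples Tibble of PSA draws with columns `delta_cost` and
#'   `delta_qalys` (as in `psa_result$samples`).
#' @param wtp_grid Ascending numeric grid of thresholds (AUD/QALY); default 0
#'   to 100,000 in steps of 1,000.
#' @return Tibble with columns `wtp` and `probability`.
#' @export
compute_ceac <- function(samples, wtp_grid = seq(0, 100000, by = 1000)) {
  if (NROW(samples) == 0) stop("empty PSA sample set")
  if (is.unsorted(wtp_grid)) stop("wtp_grid must be ascending")
  prob <- vapply(wtp_grid, function(w)
    mean(w * samples$delta_qalys - samples$delta_cost >= 0), numeric(1))
  tibble::tibble(wtp = wtp_grid, probability = prob)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of joint parameter uncertainty: draws
#' `n_iterations` independent parameter sets from the fitted distributions,
#' runs both arms through the cohort engine for each, and summarises the
#' incremental results. Draws that break the event-tree decomposition (the
#' conditional fracture or injury probability exceeding one in the exercise
#' arm) are rejected and redrawn, with the count reported. The 95% CI on the
#' mean intervention NMB is the normal-approximation interval
#' `mean +/- 1.96 se` over draws. Fully reproducible from
#' `(params, n_iterations, seed)`.
#'
#' @param params An `adt_params` parameter set.
#' @param n_iterations Number of Monte Carlo draws (the published analysis
#'   used 10,000).
#' @param seed Integer seed.
#' @param wtp_grid Grid for the acceptability curve; see [compute_ceac()].
#' @return An object of class `psa_result`: `samples` tibble (one row per
#'   draw: increments and per-arm NMBs), `ceac` tibble, `mean_nmb_intervention`
#'   with `ci`, `prob_cost_effective`, `mean_inmb`, `n_iterations`, `seed`,
#'   `n_rejected`.
#' @export
run_psa <- function(params, n_iterations, seed,
                    wtp_grid = seq(0, 100000, by = 1000)) {
  stopifnot(n_iterations >= 1)
  validate_parameters(params)
  fits <- psa_distributions(params)
  draws <- .draw_matrix(fits, n_iterations, seed)
  n_rejected <- 0L
  round <- 0L
  repeat {
    bad <- which(.infeasible_rows(draws))
    if (length(bad) == 0) break
    round <- round + 1L
    if (round > 100L) stop("rejection sampling failed to converge")
    n_rejected <- n_rejected + length(bad)
    redraw <- .draw_matrix(fits, length(bad), seed, round)
    draws[bad, ] <- redraw
  }

  res <- matrix(NA_real_, n_iterations, 4,
                dimnames = list(NULL, c("delta_cost", "delta_qalys",
                                        "nmb_control", "nmb_intervention")))
  for (i in seq_len(n_iterations)) {
    p_i <- .apply_draw(params, draws[i, ])
    ctl <- run_cohort(p_i, "control", validate = FALSE)
    int <- run_cohort(p_i, "intervention", validate = FALSE)
    res[i, ] <- c(int$total_cost - ctl$total_cost,
                  int$total_qalys - ctl$total_qalys,
                  nmb(ctl$total_cost, ctl$total_qalys, params$wtp),
                  nmb(int$total_cost, int$total_qalys, params$wtp))
  }
  samples <- tibble::tibble(draw = seq_len(n_iterations),
                            tibble::as_tibble(as.data.frame(res)))
  inmb <- params$wtp * samples$delta_qalys - samples$delta_cost
  mean_nmb <- mean(samples$nmb_intervention)
  se_nmb <- stats::sd(samples$nmb_intervention) / sqrt(n_iterations)
  ceac <- compute_ceac(samples, wtp_grid)

  structure(list(
    samples = samples,
    ceac = ceac,
    mean_nmb_intervention = mean_nmb,
    ci_nmb_intervention = c(mean_nmb - 1.96 * se_nmb,
                            mean_nmb + 1.96 * se_nmb),
    mean_inmb = mean(inmb),
    sd_inmb = stats::sd(inmb),
    prob_cost_effective = mean(inmb >= 0),
    wtp = params$wtp,
    n_iterations = n_iterations,
    seed = seed,
    n_rejected = n_rejected
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d, %d draws rejected)\n",
              x$n_iterations, x$seed, x$n_rejected))
  cat(sprintf("  mean intervention NMB $%.0f (95%% CI %.0f-%.0f)\n",
              x$mean_nmb_intervention, x$ci_nmb_intervention[1],
              x$ci_nmb_intervention[2]))
  cat(sprintf("  mean iNMB $%.0f (sd %.0f)\n", x$mean_inmb, x$sd_inmb))
  cat(sprintf("  P(cost-effective at WTP $%s) = %.3f\n",
              format(x$wtp, big.mark = ","), x$prob_cost_effective))
  invisible(x)
}
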