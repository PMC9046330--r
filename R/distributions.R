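#' Fit a beta distribution from a published mean and 95% CI
#'
#' Method-of-moments fit used to turn a published point estimate with a 95%
#' confidence interval into a sampling distribution for probabilistic
#' sensitivity analysis. The standard error is recovered from the interval
#' width under a normal approximation, `se = (ci_high - ci_low) / 3.92`, and
#' the beta shape parameters follow from matching mean and variance:
#' `alpha + beta = mean (1 - mean) / se^2 - 1`, `alpha = mean (alpha + beta)`.
#'
#' @param mean Point estimate, strictly inside (0, 1).
#' @param ci_low,ci_high Lower and upper 95% confidence bounds.
#' @return Named numeric vector with elements `alpha` and `beta`.
#' @examples
#' fit_beta_from_ci(0.36, 0.29, 0.43)
#' @export
fit_beta_from_ci <- function(mean, ci_low, ci_high) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("beta fit requires a mean strictly inside (0, 1), got ", mean)
  if (ci_low >= ci_high)
    stop("ci_low must be smaller than ci_high")
  se <- (ci_high - ci_low) / 3.92
  if (se^2 >= mean * (1 - mean))
    stop("infeasible variance: se^2 = ", signif(se^2, 4),
         " >= mean(1-mean) = ", signif(mean * (1 - mean), 4),
         "; no beta distribution has these moments")
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Fit a gamma distribution from a published mean and 95% CI
#'
#' Method-of-moments fit for non-negative cost parameters:
#' `shape = mean^2 / se^2`, `scale = se^2 / mean` with
#' `se = (ci_high - ci_low) / 3.92`.
#'
#' @inheritParams fit_beta_from_ci
#' @param mean Point estimate, strictly positive.
#' @return Named numeric vector with elements `shape` and `scale`.
#' @examples
#' fit_gamma_from_ci(20724, 20082, 21366)
#' @export
fit_gamma_from_ci <- function(mean, ci_low, ci_high) {
  if (!is.finite(mean) || mean <= 0)
    stop("gamma fit requires a positive mean, got ", mean)
  if (ci_low >= ci_high)
    stop("ci_low must be smaller than ci_high")
  se <- (ci_high - ci_low) / 3.92
  c(shape = mean^2 / se^2, scale = se^2 / mean)
}

#' Fit a lognormal distribution from a published relative risk and 95% CI
#'
#' Relative risks from meta-analyses are estimated on the log scale, so the
#' printed value is treated as the median: `mu = log(rr)`,
#' `sigma = (log(ci_high) - log(ci_low)) / 3.92`. A degenerate interval
#' (`ci_low == ci_high == rr`) yields `sigma = 0`, a point mass.
#'
#' @param rr Published relative risk (the lognormal median).
#' @param ci_low,ci_high 95% confidence bounds, strictly positive.
#' @return Named numeric vector with elements `mu` and `sigma`.
#' @examples
#' fit_lognormal_from_ci(0.76, 0.70, 0.81)
#' @export
fit_lognormal_from_ci <- function(rr, ci_low, ci_high) {
  if (!is.finite(rr) || rr <= 0 || ci_low <= 0 || ci_high <= 0)
    stop("lognormal fit requires strictly positive rr and bounds")
  if (ci_low > rr || rr > ci_high)
    stop("need ci_low <= rr <= ci_high")
  c(mu = log(rr), sigma = (log(ci_high) - log(ci_low)) / 3.92)
}
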