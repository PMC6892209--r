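#' Analytic power of a two-sample MR analysis with a binary outcome
#'
#' Approximates the power of the IVW causal test at two-sided level `alpha`
#' given the outcome-study size, its case fraction K, the proportion of
#' exposure variance explained by the instruments (R-squared), and a
#' hypothesized causal odds ratio.
#'
#' The default `"risk_difference"` parameterization follows the analytic
#' calculator of Brion et al. (mRnd): the causal effect is attenuated to
#' the risk-difference scale, `b = K (OR / (1 + K (OR - 1)) - 1)`, the
#' estimator variance is `v = (K (1 - K) - b^2) / (N R2)`, and power is the
#' upper tail of a non-central chi-square,
#' `1 - pchisq(qchisq(1 - alpha, 1), 1, ncp = b^2 / v)`. The alternative
#' `"log_odds"` parameterization keeps the effect on the log-odds scale,
#' `ncp = N R2 K (1 - K) log(OR)^2`, which is exactly symmetric in
#' `OR <-> 1/OR`; the risk-difference form is only approximately so.
#'
#' @param n_outcome total outcome-study sample size.
#' @param case_fraction outcome case proportion K in (0, 1).
#' @param r2 proportion of exposure variance explained by the instruments,
#'   in (0, 1).
#' @param or hypothesized true causal odds ratio (> 0); may be a vector.
#' @param alpha two-sided significance level (default 0.05).
#' @param parameterization `"risk_difference"` (default) or `"log_odds"`.
#' @return Power as a proportion in \[0, 1\] (vectorized over `or`).
#' @export
mr_power_binary <- function(n_outcome, case_fraction, r2, or, alpha = 0.05,
                            parameterization = c("risk_difference", "log_odds")) {
  parameterization <- match.arg(parameterization)
  if (!is.finite(n_outcome) || n_outcome <= 0) stopf("n_outcome must be positive")
  if (case_fraction <= 0 || case_fraction >= 1) stopf("case_fraction must be in (0, 1)")
  if (r2 <= 0 || r2 >= 1) stopf("r2 must be in (0, 1)")
  if (any(or <= 0)) stopf("or must be positive")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  K <- case_fraction
  ncp <- switch(parameterization,
    risk_difference = {
      b <- K * (or / (1 + K * (or - 1)) - 1)
      v <- (K * (1 - K) - b^2) / (n_outcome * r2)
      b^2 / v
    },
    log_odds = n_outcome * r2 * K * (1 - K) * log(or)^2
  )
  1 - pchisq(qchisq(1 - alpha, 1), df = 1, ncp = ncp)
}

#' Simulation-based power oracle for the binary-outcome MR design
#'
#' Estimates the same power by Monte Carlo instead of the analytic
#' approximation: in each replicate, two-sample summary statistics are
#' drawn for `k` equally strong instruments that jointly explain `r2` of
#' the (unit-variance) exposure — exposure effects observed with sampling
#' noise from a study of `n_exposure` individuals, outcome effects centered
#' on the risk-difference causal effect with variance
#' `K(1-K)/n_outcome` per unit genotype variance — and the fixed-effects
#' IVW test ([mr_ivw()]) is run. Power is the rejection fraction.
#'
#' @inheritParams mr_power_binary
#' @param k number of instruments in the simulated design (default 10).
#' @param n_exposure exposure-study sample size used for the exposure-side
#'   sampling noise; `Inf` (default) matches the analytic formula's
#'   assumption of a precisely estimated exposure effect.
#' @param n_rep Monte Carlo replicates (default 2000).
#' @param seed RNG seed.
#' @return Estimated power (rejection proportion).
#' @export
mr_power_sim <- function(n_outcome, case_fraction, r2, or, alpha = 0.05,
                         k = 10, n_exposure = Inf, n_rep = 2000, seed = 1) {
  K <- case_fraction
  b <- K * (or / (1 + K * (or - 1)) - 1)     # risk-difference causal effect
  bx <- rep(sqrt(r2 / k), k)                 # unit-variance genotypes and exposure
  se_x <- if (is.finite(n_exposure)) rep(sqrt((1 - r2 / k) / n_exposure), k) else rep(1e-12, k)
  se_y <- rep(sqrt((K * (1 - K) - (b * bx[1])^2) / n_outcome), k)
  with_seed(seed, {
    rej <- vapply(seq_len(n_rep), function(i) {
      instr <- data.frame(
        snp = paste0("s", seq_len(k)),
        beta_exp = rnorm(k, bx, se_x), se_exp = se_x,
        beta_out = rnorm(k, b * bx, se_y), se_out = se_y,
        stringsAsFactors = FALSE
      )
      mr_ivw(instr, "fixed")$pvalue < alpha
    }, logical(1))
    mean(rej)
  })
}
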