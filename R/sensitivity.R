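#' Cochran's Q heterogeneity test over per-instrument ratios
#'
#' `Q = sum(w_j (theta_j - theta_fixed)^2)` with the IVW weights
#' `w_j = beta_exp_j^2 / se_out_j^2`; p-value from chi-square with k-1
#' degrees of freedom; `I2 = max(0, (Q - df)/Q)`.
#'
#' @param instruments harmonized instruments (k >= 2).
#' @return list `(Q, df, pvalue, I2, k)`.
#' @export
mr_cochran_q <- function(instruments) {
  k <- nrow(instruments)
  if (k < 2) stopf("Cochran's Q requires at least 2 instruments (got %d)", k)
  r <- wald_ratios(instruments)
  w <- 1 / r$se^2
  theta <- sum(w * r$theta) / sum(w)
  Q <- sum(w * (r$theta - theta)^2)
  df <- k - 1
  list(Q = Q, df = df, pvalue = pchisq(Q, df, lower.tail = FALSE),
       I2 = if (Q > 0) max(0, (Q - df) / Q) else 0, k = k)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate with each instrument omitted in turn and
#' flags omissions that move the point estimate across zero or change its
#' significance at `alpha`.
#'
#' @param instruments harmonized instruments (k >= 3).
#' @param effects IVW flavor passed to [mr_ivw()].
#' @param alpha significance level for the flag (default 0.05).
#' @return Data frame with one row per omitted SNP: `snp, k, theta, se,
#'   ci_low, ci_high, pvalue, flag_sign, flag_signif`.
#' @export
mr_leave_one_out <- function(instruments, effects = "fixed", alpha = 0.05) {
  k <- nrow(instruments)
  if (k < 3) stopf("leave-one-out requires at least 3 instruments (got %d)", k)
  full <- mr_ivw(instruments, effects)
  rows <- lapply(seq_len(k), function(j) {
    est <- mr_ivw(instruments[-j, , drop = FALSE], effects)
    data.frame(
      snp = instruments$snp[j], k = k - 1L, theta = est$theta, se = est$se,
      ci_low = est$ci_low, ci_high = est$ci_high, pvalue = est$pvalue,
      flag_sign = sign(est$theta) != sign(full$theta),
      flag_signif = (est$pvalue < alpha) != (full$pvalue < alpha),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Funnel-plot data with an asymmetry summary
#'
#' Per-instrument ratio estimates against their precision `1/se`, plus the
#' Egger-intercept p-value as the funnel-asymmetry summary.
#'
#' @param instruments harmonized instruments (k >= 3).
#' @return list with `data` (`snp, theta, precision`), `theta_ivw` (the
#'   fixed-effects estimate for the funnel's vertical line) and
#'   `asymmetry_p`.
#' @export
mr_funnel <- function(instruments) {
  k <- nrow(instruments)
  if (k < 3) stopf("funnel diagnostics require at least 3 instruments (got %d)", k)
  r <- wald_ratios(instruments)
  eg <- mr_egger(instruments)
  list(
    data = data.frame(snp = r$snp, theta = r$theta, precision = 1 / r$se,
                      stringsAsFactors = FALSE),
    theta_ivw = mr_ivw(instruments, "fixed")$theta,
    asymmetry_p = eg$pvalue[eg$method == "egger_intercept"]
  )
}

#' Regional correlation of exposure and outcome effect sizes
#'
#' Harmonizes the two studies, restricts to SNPs inside the (1-based,
#' inclusive) region, and reports the Pearson product-moment correlation of
#' the exposure and outcome effect sizes, with a Fisher-z confidence
#' interval and two-sided p-value.
#'
#' @param exposure,outcome validated summary-statistic data frames.
#' @param chrom chromosome label.
#' @param start,end region bounds in base pairs (inclusive).
#' @param conf_level confidence level (default 0.95).
#' @return list `(r, ci_low, ci_high, pvalue, n_snps)`.
#' @export
regional_effect_correlation <- function(exposure, outcome, chrom, start, end,
                                        conf_level = 0.95) {
  h <- harmonize_pair(exposure, outcome)$instruments
  inside <- !is.na(h$chr) & as.character(h$chr) == as.character(chrom) &
    !is.na(h$pos) & h$pos >= start & h$pos <= end
  h <- h[inside, , drop = FALSE]
  if (nrow(h) < 3)
    stopf("regional correlation requires >= 3 harmonized SNPs in %s:%s-%s (got %d)",
          chrom, format(start, scientific = FALSE),
          format(end, scientific = FALSE), nrow(h))
  ct <- cor.test(h$beta_exp, h$beta_out, method = "pearson",
                 conf.level = conf_level)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
       ci_high = ct$conf.int[2], pvalue = ct$p.value, n_snps = nrow(h))
}
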