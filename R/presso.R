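#' MR-PRESSO: pleiotropy residual sum and outlier analysis
#'
#' Resampling-based detection of horizontally pleiotropic instruments.
#'
#' With IVW weights `w_j = 1/se_out_j^2`, the observed global statistic is
#' the weighted residual sum of squares of the outcome effects about their
#' leave-one-out IVW predictions:
#' `RSS = sum(w_j (beta_out_j - theta_{-j} beta_exp_j)^2)`, where
#' `theta_{-j}` is the weighted through-origin slope fitted without
#' instrument j. Its null distribution is obtained by parametric
#' simulation: `beta_exp* ~ N(beta_exp, se_exp)` and
#' `beta_out* ~ N(theta_{-j} beta_exp_j, se_out)`, recomputing the same
#' statistic `n_sim` times; the global p-value is the fraction of simulated
#' RSS at or above the observed one. Each instrument's observed weighted
#' squared residual is compared to its own simulated distribution for the
#' per-SNP outlier test; outlier p-values are Bonferroni-adjusted across
#' the k instruments and instruments with adjusted p below `outlier_alpha`
#' are flagged. The distortion test compares the shift in the IVW estimate
#' caused by removing the flagged outliers against the distribution of
#' shifts from removing equally many instruments at random.
#'
#' @param instruments harmonized instruments (k >= 4).
#' @param n_sim number of parametric simulations (default 1000).
#' @param outlier_alpha significance level for flagging outliers on the
#'   Bonferroni-adjusted p-values (default 0.05).
#' @param seed RNG seed; the same seed gives bit-identical results and the
#'   caller's RNG state is left untouched.
#' @param effects IVW flavor used for the raw and outlier-corrected
#'   estimates.
#' @return list of class `mr_presso`: `global_rss`, `global_p`, `per_snp`
#'   (data frame `snp, rss, p_raw, p_adj`), `outliers` (snp ids),
#'   `distortion_p` (NA when no outlier is flagged), `theta_raw` and
#'   `theta_corrected` (`mr_estimate` rows; the corrected one is IVW on the
#'   instruments minus the flagged outliers), `n_sim`, `seed`.
#' @export
mr_presso <- function(instruments, n_sim = 1000, outlier_alpha = 0.05,
                      seed = 2019, effects = "fixed") {
  k <- nrow(instruments)
  if (k < 4)
    stopf("MR-PRESSO requires at least 4 instruments (got %d): the leave-one-out residual of every instrument must itself be estimable from >= 3 others", k)
  bx <- instruments$beta_exp
  by <- instruments$beta_out
  sx <- instruments$se_exp
  sy <- instruments$se_out
  w <- 1 / sy^2

  loo_slopes <- function(x, y) {
    sxy <- sum(w * x * y); sxx <- sum(w * x^2)
    (sxy - w * x * y) / (sxx - w * x^2)
  }
  th_loo <- loo_slopes(bx, by)
  res_obs <- w * (by - th_loo * bx)^2
  rss_obs <- sum(res_obs)

  sims <- with_seed(seed, {
    xs <- matrix(rnorm(k * n_sim, bx, sx), nrow = k)
    ys <- matrix(rnorm(k * n_sim, th_loo * bx, sy), nrow = k)
    sxy <- colSums(w * xs * ys)
    sxx <- colSums(w * xs^2)
    th <- (rep(sxy, each = k) - w * xs * ys) / (rep(sxx, each = k) - w * xs^2)
    res <- w * (ys - th * xs)^2          # k x n_sim weighted squared residuals
    list(rss = colSums(res), res = matrix(res, nrow = k))
  })
  global_p <- mean(sims$rss >= rss_obs)
  p_raw <- rowMeans(sims$res >= res_obs)
  p_adj <- pmin(1, p_raw * k)
  outliers <- instruments$snp[p_adj < outlier_alpha]

  theta_raw <- mr_ivw(instruments, effects)
  keep <- !(instruments$snp %in% outliers)
  theta_corrected <- if (sum(keep) >= 1) mr_ivw(instruments[keep, , drop = FALSE], effects) else NULL

  distortion_p <- NA_real_
  n_out <- length(outliers)
  if (n_out > 0 && sum(keep) >= 1) {
    d_obs <- abs(theta_corrected$theta - theta_raw$theta)
    wr <- bx^2 / sy^2               # fixed-effects IVW weights on the ratios
    tw <- wr * (by / bx)
    d_null <- with_seed(seed + 1, {
      vapply(seq_len(n_sim), function(i) {
        drop <- sample.int(k, n_out)
        est <- if (effects == "fixed")
          (sum(tw) - sum(tw[drop])) / (sum(wr) - sum(wr[drop]))
        else mr_ivw(instruments[-drop, , drop = FALSE], effects)$theta
        abs(est - theta_raw$theta)
      }, numeric(1))
    })
    distortion_p <- mean(d_null >= d_obs)
  }

  structure(list(
    global_rss = rss_obs, global_p = global_p,
    per_snp = data.frame(snp = instruments$snp, rss = res_obs,
                         p_raw = p_raw, p_adj = p_adj, stringsAsFactors = FALSE),
    outliers = outliers, distortion_p = distortion_p,
    theta_raw = theta_raw, theta_corrected = theta_corrected,
    n_sim = n_sim, seed = seed
  ), class = "mr_presso")
}
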