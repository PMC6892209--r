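#' Construct an MR estimate row
#'
#' Internal constructor shared by all estimators. The 95% confidence
#' interval and the two-sided p-value use a normal reference by default, or
#' Student's t with `df` degrees of freedom when `df` is finite (used by
#' MR-Egger).
#'
#' @param method method label.
#' @param theta causal effect on the log-odds scale.
#' @param se standard error of `theta`.
#' @param k number of instruments used.
#' @param df degrees of freedom for the reference distribution
#'   (`Inf` = normal).
#' @param conf_level confidence level (default 0.95).
#' @return One-row data frame of class `mr_estimate` with columns
#'   `method, k, theta, se, ci_low, ci_high, pvalue, or, or_ci_low,
#'   or_ci_high`.
#' @export
mr_estimate <- function(method, theta, se, k, df = Inf, conf_level = 0.95) {
  crit <- if (is.finite(df)) qt(1 - (1 - conf_level) / 2, df)
          else qnorm(1 - (1 - conf_level) / 2)
  z <- theta / se
  pvalue <- if (is.finite(df)) 2 * pt(-abs(z), df) else 2 * pnorm(-abs(z))
  ci_low <- theta - crit * se
  ci_high <- theta + crit * se
  structure(data.frame(
    method = method, k = as.integer(k), theta = theta, se = se,
    ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
    or = exp(theta), or_ci_low = exp(ci_low), or_ci_high = exp(ci_high),
    stringsAsFactors = FALSE
  ), class = c("mr_estimate", "data.frame"))
}

# per-instrument ratio estimates used by IVW / median / diagnostics
wald_ratios <- function(instruments, second_order = FALSE) {
  bx <- instruments$beta_exp; by <- instruments$beta_out
  sx <- instruments$se_exp; sy <- instruments$se_out
  if (any(bx == 0)) stopf("undefined Wald ratio: beta_exp = 0 for %s",
                          paste(instruments$snp[bx == 0], collapse = ", "))
  theta <- by / bx
  se <- if (second_order) sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4) else sy / abs(bx)
  data.frame(snp = instruments$snp, theta = theta, se = se,
             stringsAsFactors = FALSE)
}

#' Per-instrument Wald ratio estimates
#'
#' The ratio estimator `theta_j = beta_out / beta_exp` with first-order
#' standard error `se_out / |beta_exp|` (the weighting convention that makes
#' fixed-effects IVW an inverse-variance meta-analysis of the ratios). A
#' second-order delta option adds the `beta_out^2 se_exp^2 / beta_exp^4`
#' term.
#'
#' @param instruments harmonized instruments.
#' @param second_order use the second-order delta-method standard error.
#' @return `mr_estimate` data frame with one row per instrument (method
#'   `"wald"`); the `snp` id is carried in an extra column.
#' @export
mr_wald_ratio <- function(instruments, second_order = FALSE) {
  r <- wald_ratios(instruments, second_order)
  out <- do.call(rbind, lapply(seq_len(nrow(r)), function(j)
    mr_estimate("wald", r$theta[j], r$se[j], k = 1L)))
  out <- cbind(snp = r$snp, out)
  class(out) <- c("mr_estimate", "data.frame")
  out
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed effects: `theta = sum(w theta_j) / sum(w)` with
#' `w_j = beta_exp_j^2 / se_out_j^2` (equivalently, inverse-variance weights
#' on first-order Wald ratios), `se = 1/sqrt(sum(w))`. Multiplicative random
#' effects (`"random"`): the same point estimate with the standard error
#' inflated by `max(1, sqrt(Q/(k-1)))` where Q is Cochran's Q of the ratios,
#' so the random-effects interval is never narrower than the fixed one. An
#' additive DerSimonian-Laird flavor (`"dl"`) re-weights by
#' `1/(se_j^2 + tau2)`. A single instrument degenerates to the Wald ratio.
#'
#' @param instruments harmonized instruments (k >= 1).
#' @param effects `"fixed"` (default), `"random"` or `"dl"`.
#' @return One-row `mr_estimate` (method `ivw_fixed`, `ivw_random` or
#'   `ivw_dl`).
#' @export
mr_ivw <- function(instruments, effects = c("fixed", "random", "dl")) {
  effects <- match.arg(effects)
  k <- nrow(instruments)
  if (k == 0) stopf("no instruments supplied to mr_ivw")
  if (any(instruments$se_out <= 0)) stopf("se_out must be > 0 for every instrument")
  r <- wald_ratios(instruments)
  w <- 1 / r$se^2
  theta <- sum(w * r$theta) / sum(w)
  se <- sqrt(1 / sum(w))
  if (k == 1) return(mr_estimate(paste0("ivw_", effects), theta, se, k))
  if (effects == "random") {
    Q <- sum(w * (r$theta - theta)^2)
    se <- se * max(1, sqrt(Q / (k - 1)))
  } else if (effects == "dl") {
    Q <- sum(w * (r$theta - theta)^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    wd <- 1 / (r$se^2 + tau2)
    theta <- sum(wd * r$theta) / sum(wd)
    se <- sqrt(1 / sum(wd))
  }
  mr_estimate(paste0("ivw_", effects), theta, se, k)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with an
#' intercept, weights `1/se_out^2`, after orienting every instrument so that
#' `beta_exp >= 0` (the intercept is only identified up to this sign
#' convention). The slope is the causal estimate; the intercept estimates
#' the average directional pleiotropy and its test is the Egger pleiotropy
#' test. Standard errors follow the multiplicative random-effects
#' convention: the residual scale is floored at 1,
#' `se = se_wls * max(1, sqrt(RSS_w/(k-2)))`, with t (k-2 df) reference.
#'
#' @param instruments harmonized instruments (k >= 3).
#' @return Two-row `mr_estimate` (methods `egger_slope`, `egger_intercept`).
#' @export
mr_egger <- function(instruments) {
  k <- nrow(instruments)
  if (k < 3) stopf("MR-Egger requires at least 3 instruments (got %d)", k)
  flip <- sign(instruments$beta_exp)
  flip[flip == 0] <- 1
  bx <- instruments$beta_exp * flip
  by <- instruments$beta_out * flip
  w <- 1 / instruments$se_out^2
  if (length(unique(bx)) == 1)
    stopf("MR-Egger is not identified: all exposure effects are identical")
  fit <- lm(by ~ bx, weights = w)
  s <- suppressWarnings(summary(fit))  # zero-residual fits warn spuriously
  scale <- max(1, s$sigma) / s$sigma  # floor the residual scale at 1
  est <- coef(s)
  slope <- mr_estimate("egger_slope", est["bx", "Estimate"],
                       est["bx", "Std. Error"] * scale, k, df = k - 2)
  inter <- mr_estimate("egger_intercept", est["(Intercept)", "Estimate"],
                       est["(Intercept)", "Std. Error"] * scale, k, df = k - 2)
  out <- rbind(slope, inter)
  class(out) <- c("mr_estimate", "data.frame")
  out
}

# weighted median of ratios with linear interpolation over cumulative
# weights; the j-th order statistic sits at cumulative weight S_j - w_(j)/2
weighted_median_point <- function(theta, weight) {
  ord <- order(theta)
  th <- theta[ord]
  w <- weight[ord] / sum(weight)
  pos <- cumsum(w) - 0.5 * w
  if (pos[1] >= 0.5) return(th[1])
  if (pos[length(pos)] <= 0.5) return(th[length(th)])
  below <- max(which(pos < 0.5))
  th[below] + (th[below + 1] - th[below]) * (0.5 - pos[below]) / (pos[below + 1] - pos[below])
}

#' Weighted-median causal estimate
#'
#' The inverse-variance weighted median of the per-instrument ratios:
#' consistent when instruments carrying at least half of the weight are
#' valid. The point estimate interpolates linearly between the order
#' statistics bracketing cumulative weight 0.5 (the cumulative weight of
#' the j-th order statistic being `S_j - w_(j)/2`). The standard error comes
#' from a parametric bootstrap: each instrument's `(beta_exp, beta_out)` is
#' resampled from normal distributions with the stated standard errors, the
#' weighted median recomputed, and the standard deviation across replicates
#' taken.
#'
#' @param instruments harmonized instruments (k >= 3).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed making the bootstrap standard error reproducible
#'   (default 2019); the caller's RNG state is left untouched.
#' @return One-row `mr_estimate` (method `weighted_median`).
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = 2019) {
  k <- nrow(instruments)
  if (k < 3) stopf("weighted median requires at least 3 instruments (got %d)", k)
  r <- wald_ratios(instruments)
  w <- instruments$beta_exp^2 / instruments$se_out^2
  theta <- weighted_median_point(r$theta, w)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(k, instruments$beta_exp, instruments$se_exp)
      by <- rnorm(k, instruments$beta_out, instruments$se_out)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / instruments$se_out[ok]^2)
    }, numeric(1))
  })
  mr_estimate("weighted_median", theta, sd(boot), k)
}

#' Report an estimate on the odds-ratio scale with percent risk change
#'
#' Adds the exponentiated effect and the percent risk reduction
#' `(1 - OR) x 100`, with interval endpoints mapped monotonically (the
#' lower theta bound gives the lower OR bound and the upper reduction
#' bound).
#'
#' @param estimate an `mr_estimate` data frame.
#' @return The input with columns `risk_reduction_pct`,
#'   `risk_reduction_ci_low`, `risk_reduction_ci_high` appended.
#' @export
or_transform <- function(estimate) {
  estimate$risk_reduction_pct <- (1 - estimate$or) * 100
  estimate$risk_reduction_ci_low <- (1 - estimate$or_ci_high) * 100
  estimate$risk_reduction_ci_high <- (1 - estimate$or_ci_low) * 100
  estimate
}

#' Export estimates as a tidy table
#'
#' @param estimates an `mr_estimate` data frame (rows from several methods
#'   may be bound together).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  write.table(estimates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
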