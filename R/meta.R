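#' Random-effects meta-analysis of published odds ratios
#'
#' Pools study-level odds ratios on the log scale. Each study's log-OR
#' standard error is recovered from its symmetric 95% interval,
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.96)`. The between-study
#' variance uses the DerSimonian-Laird moment estimator
#' `tau2 = max(0, (Q - (m-1)) / (sum(w) - sum(w^2)/sum(w)))` with fixed
#' weights `w = 1/se^2`, and the pooled estimate is inverse-variance
#' weighted with weights `1/(se^2 + tau2)`. `method = "fixed"` forces
#' `tau2 = 0`; `method = "reml"` delegates the tau2 estimate to
#' `metafor::rma` (package metafor required).
#'
#' @param studies data frame with columns `or`, `ci_low`, `ci_high` (and
#'   optionally `label`); all must be positive with
#'   `ci_low <= or <= ci_high`.
#' @param method `"dl"` (default), `"reml"` or `"fixed"`.
#' @param conf_level confidence level of both the input intervals and the
#'   pooled interval (default 0.95).
#' @return list with `estimate` (one-row [mr_estimate()] on the log-OR /
#'   OR scale, method `meta_<method>`), `tau2`, `Q`, `df`, `p_q`, `I2`, `k`.
#' @export
dl_meta <- function(studies, method = c("dl", "reml", "fixed"),
                    conf_level = 0.95) {
  method <- match.arg(method)
  if (nrow(studies) < 1) stopf("dl_meta needs at least one study")
  or <- studies$or; lo <- studies$ci_low; hi <- studies$ci_high
  if (any(is.na(or) | is.na(lo) | is.na(hi)) || any(or <= 0 | lo <= 0 | hi <= 0))
    stopf("odds ratios and interval bounds must all be positive")
  if (any(lo > or | or > hi))
    stopf("each study needs ci_low <= or <= ci_high")
  z <- qnorm(1 - (1 - conf_level) / 2)
  y <- log(or)
  se <- (log(hi) - log(lo)) / (2 * z)
  m <- length(y)
  w <- 1 / se^2
  theta_f <- sum(w * y) / sum(w)
  Q <- sum(w * (y - theta_f)^2)
  df <- m - 1L
  tau2 <- switch(method,
    fixed = 0,
    dl = if (m > 1) max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w))) else 0,
    reml = {
      if (!requireNamespace("metafor", quietly = TRUE))
        stopf("method = 'reml' requires the metafor package")
      metafor::rma(yi = y, sei = se, method = "REML")$tau2
    })
  wr <- 1 / (se^2 + tau2)
  theta <- sum(wr * y) / sum(wr)
  se_pooled <- sqrt(1 / sum(wr))
  list(
    estimate = mr_estimate(paste0("meta_", method), theta, se_pooled, m,
                           conf_level = conf_level),
    tau2 = tau2, Q = Q, df = df,
    p_q = if (m > 1) pchisq(Q, df, lower.tail = FALSE) else NA_real_,
    I2 = if (m > 1 && Q > 0) max(0, (Q - df) / Q) else 0, k = m
  )
}

#' Observational studies of type 2 diabetes and ALS
#'
#' The 12 published observational effect sizes (odds/hazard ratios with 95%
#' intervals) of type 2 diabetes on amyotrophic lateral sclerosis shipped
#' with the package, one study from an East Asian population and 11 from
#' European-ancestry populations.
#'
#' @return Data frame `label, year, country, or, ci_low, ci_high,
#'   east_asian`.
#' @export
t2d_als_studies <- function() {
  path <- system.file("extdata", "t2d_als_observational.tsv", package = "mrcausal")
  read.delim(path, stringsAsFactors = FALSE)
}

#' GWAS sample sizes used in the two-sample MR design
#'
#' Cohort sizes (cases/controls or total) of the exposure and outcome GWAS
#' data sets behind the study design, shipped with the package.
#'
#' @return Data frame `trait, population, k_final, k_candidate, n_cases,
#'   n_controls, n_total, source`.
#' @export
gwas_sample_sizes <- function() {
  path <- system.file("extdata", "gwas_sample_sizes.tsv", package = "mrcausal")
  read.delim(path, stringsAsFactors = FALSE)
}
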