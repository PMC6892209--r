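#' @import ggplot2
NULL

#' Scatter plot of outcome against exposure effects with fitted MR lines
#'
#' Mirrors the standard two-sample MR scatter: per-instrument effects with
#' 95% error bars, plus the IVW line through the origin and the MR-Egger
#' fitted line.
#'
#' @param instruments harmonized instrument table (as exported by the
#'   pipeline).
#' @param estimates estimate table containing `ivw_fixed` (or
#'   `ivw_random`) and optionally `egger_slope` / `egger_intercept` rows.
#' @return A ggplot object.
#' @export
mr_scatter_plot <- function(instruments, estimates) {
  ivw <- estimates[estimates$method %in% c("ivw_fixed", "ivw_random"), ][1, ]
  p <- ggplot(instruments, aes(x = .data$beta_exp, y = .data$beta_out)) +
    geom_errorbar(aes(ymin = .data$beta_out - 1.96 * .data$se_out,
                      ymax = .data$beta_out + 1.96 * .data$se_out),
                  width = 0, colour = "grey60", linewidth = 0.3) +
    geom_errorbarh(aes(xmin = .data$beta_exp - 1.96 * .data$se_exp,
                       xmax = .data$beta_exp + 1.96 * .data$se_exp),
                   height = 0, colour = "grey60", linewidth = 0.3) +
    geom_point(size = 1.6) +
    geom_abline(intercept = 0, slope = ivw$theta, colour = "red") +
    labs(x = "SNP effect on exposure", y = "SNP effect on outcome") +
    theme_bw()
  eg <- estimates[estimates$method == "egger_slope", ]
  egi <- estimates[estimates$method == "egger_intercept", ]
  if (nrow(eg) == 1 && nrow(egi) == 1)
    p <- p + geom_abline(intercept = egi$theta, slope = eg$theta, colour = "blue")
  p
}

#' Funnel plot of per-instrument causal estimates
#'
#' @param funnel_data data frame `snp, theta, precision` (see
#'   [mr_funnel()]).
#' @param theta_ivw overall IVW estimate drawn as the vertical line.
#' @return A ggplot object.
#' @export
mr_funnel_plot <- function(funnel_data, theta_ivw) {
  ggplot(funnel_data, aes(x = .data$theta, y = .data$precision)) +
    geom_point(size = 1.6) +
    geom_vline(xintercept = theta_ivw, colour = "red", linetype = "dashed") +
    labs(x = "Per-instrument causal estimate", y = "Precision (1/SE)") +
    theme_bw()
}

#' Forest plot of per-instrument Wald ratios
#'
#' @param wald per-instrument estimate table (see [mr_wald_ratio()]).
#' @param overall optional one-row overall estimate appended at the bottom.
#' @return A ggplot object.
#' @export
mr_forest_plot <- function(wald, overall = NULL) {
  d <- data.frame(snp = wald$snp, theta = wald$theta,
                  lo = wald$ci_low, hi = wald$ci_high,
                  stringsAsFactors = FALSE)
  if (!is.null(overall))
    d <- rbind(d, data.frame(snp = "All (IVW)", theta = overall$theta,
                             lo = overall$ci_low, hi = overall$ci_high))
  d$snp <- factor(d$snp, levels = rev(d$snp))
  ggplot(d, aes(x = .data$theta, y = .data$snp)) +
    geom_vline(xintercept = 0, colour = "grey50", linetype = "dotted") +
    geom_errorbarh(aes(xmin = .data$lo, xmax = .data$hi), height = 0.2) +
    geom_point() +
    labs(x = "Causal estimate (log OR)", y = NULL) +
    theme_bw()
}

#' Leave-one-out plot
#'
#' @param loo leave-one-out table (see [mr_leave_one_out()]).
#' @param full_theta the all-instrument estimate drawn as a vertical line.
#' @return A ggplot object.
#' @export
mr_loo_plot <- function(loo, full_theta) {
  d <- loo
  d$snp <- factor(d$snp, levels = rev(d$snp))
  ggplot(d, aes(x = .data$theta, y = .data$snp)) +
    geom_vline(xintercept = full_theta, colour = "red", linetype = "dashed") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    geom_point() +
    labs(x = "IVW estimate omitting the SNP (log OR)", y = NULL) +
    theme_bw()
}
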