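#' Simulate two-sample GWAS summary statistics with known ground truth
#'
#' Generates exposure and outcome summary-statistic tables at the summary
#' level (normal sampling of effect estimates, not individual-level
#' genotypes), emulating the two-sample MR design: `k_instruments` true
#' instruments whose exposure effects jointly explain `pve_target` of the
#' exposure on the observed scale, plus `n_null_snps` background SNPs with
#' no effect, for exercising instrument selection.
#'
#' Per SNP j with allele frequency `f_j ~ U(maf_range)`, the true exposure
#' effect is `beta_X,j = sqrt(s_j / (2 f_j (1-f_j) c_X))` where the
#' variance-explained shares `s_j` are proportional to `U(0.5, 1.5)` draws
#' and sum exactly to `pve_target`: instrument strengths spread about
#' three-fold, none near zero, as for genome-wide-significant index SNPs.
#' The effect allele is the exposure-increasing allele (the orientation
#' under which directional pleiotropy has a well-defined sign); the true
#' outcome effect is `theta_true * beta_X,j + alpha_j` with the pleiotropic
#' effect `alpha_j` set by `pleiotropy_mode`:
#' `"none"` all zero; `"balanced"` `N(0, pleiotropy_sd)`; `"directional"`
#' `N(pleiotropy_mean, pleiotropy_sd)`; `"inside_violating"`
#' `pleiotropy_mean * beta_X,j + N(0, pleiotropy_sd)` (pleiotropy
#' correlated with instrument strength, breaking the InSIDE assumption).
#' Observed effects add normal noise with the logistic-score standard error
#' `se = 1 / sqrt(2 n f (1-f) c)` where the trait-scale constant `c` is
#' `K(1-K)` for a binary trait with case fraction K (1 for a quantitative
#' trait); p-values are two-sided Wald tests.
#'
#' Allele labels are assigned so that a fraction of SNPs are palindromic
#' (A/T or C/G) and fractions of the outcome rows are written with swapped
#' allele order (beta and frequency flipped accordingly) or on the opposite
#' strand, to exercise [harmonize_pair()]. No linkage disequilibrium is
#' simulated; positional clustering comes only from assigned coordinates.
#'
#' @param k_instruments number of true instruments (default 67, the study
#'   design's final European instrument count).
#' @param n_exposure,n_outcome study sample sizes (defaults 659,316 and
#'   80,610).
#' @param case_fraction_exposure,case_fraction_outcome case proportions for
#'   the binary exposure/outcome (`NULL` for a quantitative trait; defaults
#'   62,892/659,316 and 20,806/80,610).
#' @param theta_true causal effect on the log-odds scale (default
#'   `log(0.93)`).
#' @param pve_target total exposure variance explained by the instruments
#'   (default 0.0061).
#' @param maf_range allele-frequency interval (default c(0.05, 0.5)).
#' @param pleiotropy_mode one of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`.
#' @param pleiotropy_mean,pleiotropy_sd mean and sd of the pleiotropic
#'   effects (slope on `beta_X` for `"inside_violating"`).
#' @param n_null_snps background SNPs with zero true effect (default 0).
#' @param frac_palindromic fraction of SNPs given palindromic alleles
#'   (default 0.1).
#' @param frac_swapped fraction of outcome rows written with swapped
#'   effect/other alleles (default 0.2).
#' @param frac_strand_flipped fraction of non-palindromic outcome rows
#'   written on the opposite strand (default 0.1).
#' @param seed mandatory RNG seed; identical configurations and seeds give
#'   identical output.
#' @return list with `exposure` and `outcome` (validated canonical summary
#'   statistics) and `truth`, a data frame
#'   `(snp, beta_x_true, alpha, is_instrument, swapped, strand_flipped)`
#'   with attribute `theta_true`.
#' @export
simulate_two_sample <- function(k_instruments = 67,
                                n_exposure = 659316, n_outcome = 80610,
                                case_fraction_exposure = 62892 / 659316,
                                case_fraction_outcome = 20806 / 80610,
                                theta_true = log(0.93),
                                pve_target = 0.0061,
                                maf_range = c(0.05, 0.5),
                                pleiotropy_mode = c("none", "balanced",
                                                    "directional", "inside_violating"),
                                pleiotropy_mean = 0, pleiotropy_sd = 0,
                                n_null_snps = 0,
                                frac_palindromic = 0.1, frac_swapped = 0.2,
                                frac_strand_flipped = 0.1, seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed)) stopf("a seed is mandatory for reproducible simulation")
  stopifnot(k_instruments >= 1, n_null_snps >= 0,
            maf_range[1] > 0, maf_range[2] < 1, maf_range[1] <= maf_range[2])
  cx <- if (is.null(case_fraction_exposure)) 1 else {
    stopifnot(case_fraction_exposure > 0, case_fraction_exposure < 1)
    case_fraction_exposure * (1 - case_fraction_exposure)
  }
  cy <- if (is.null(case_fraction_outcome)) 1 else {
    stopifnot(case_fraction_outcome > 0, case_fraction_outcome < 1)
    case_fraction_outcome * (1 - case_fraction_outcome)
  }
  if (pve_target <= 0 || pve_target >= 1)
    stopf("pve_target must be in (0, 1)")
  # infeasibility guard: expected per-SNP effects must stay in a range where
  # the first-order variance decomposition holds
  if (pve_target / k_instruments > 0.5 * 2 * maf_range[1] * (1 - maf_range[1]) * cx)
    stopf("pve_target %g is infeasible for k = %d instruments on maf_range [%g, %g]",
          pve_target, k_instruments, maf_range[1], maf_range[2])

  m <- k_instruments + n_null_snps
  with_seed(seed, {
    f <- runif(m, maf_range[1], maf_range[2])
    is_instrument <- c(rep(TRUE, k_instruments), rep(FALSE, n_null_snps))

    # instrument strengths: per-SNP variance-explained shares vary ~3-fold
    # (mirroring the spread of F statistics among genome-wide-significant
    # index SNPs) and sum exactly to pve_target; no instrument is near-null.
    # The effect allele is the exposure-increasing allele, so directional
    # pleiotropy has a well-defined sign relative to instrument orientation.
    beta_x_true <- numeric(m)
    u <- runif(k_instruments, 0.5, 1.5)
    pve_share <- pve_target * u / sum(u)
    beta_x_true[is_instrument] <-
      sqrt(pve_share / (2 * f[is_instrument] * (1 - f[is_instrument]) * cx))
    alpha <- numeric(m)
    if (pleiotropy_mode == "balanced") {
      alpha[is_instrument] <- rnorm(k_instruments, 0, pleiotropy_sd)
    } else if (pleiotropy_mode == "directional") {
      alpha[is_instrument] <- rnorm(k_instruments, pleiotropy_mean, pleiotropy_sd)
    } else if (pleiotropy_mode == "inside_violating") {
      alpha[is_instrument] <- pleiotropy_mean * beta_x_true[is_instrument] +
        rnorm(k_instruments, 0, pleiotropy_sd)
    }
    beta_y_true <- theta_true * beta_x_true + alpha

    se_x <- 1 / sqrt(2 * n_exposure * f * (1 - f) * cx)
    se_y <- 1 / sqrt(2 * n_outcome * f * (1 - f) * cy)
    bx <- rnorm(m, beta_x_true, se_x)
    by <- rnorm(m, beta_y_true, se_y)
    px <- 2 * pnorm(-abs(bx / se_x))
    py <- 2 * pnorm(-abs(by / se_y))
    px <- pmax(px, .Machine$double.xmin)
    py <- pmax(py, .Machine$double.xmin)

    # coordinates: instruments on well-separated loci, null SNPs scattered
    chr <- as.character(rep_len(1:22, m))
    pos <- integer(m)
    pos[is_instrument] <- 1e6 + 3e6 * (cumsum(is_instrument)[is_instrument] %/% 22)
    pos[!is_instrument] <- as.integer(runif(sum(!is_instrument), 1e6, 2.4e8))

    pal <- runif(m) < frac_palindromic
    pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"), ncol = 2, byrow = TRUE)
    nonpal_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                             "G", "A", "C", "A", "G", "T", "C", "T"),
                           ncol = 2, byrow = TRUE)
    pick <- function(pairs, n) pairs[sample.int(nrow(pairs), n, replace = TRUE), , drop = FALSE]
    ea <- oa <- character(m)
    if (any(pal)) { pp <- pick(pal_pairs, sum(pal)); ea[pal] <- pp[, 1]; oa[pal] <- pp[, 2] }
    if (any(!pal)) { np <- pick(nonpal_pairs, sum(!pal)); ea[!pal] <- np[, 1]; oa[!pal] <- np[, 2] }

    snp <- sprintf("rs%06d", seq_len(m))
    eaf_x <- f
    eaf_y <- pmin(pmax(f + rnorm(m, 0, 0.005), 0.001), 0.999)

    exposure <- data.frame(
      snp = snp, chr = chr, pos = pos, ea = ea, oa = oa, eaf = eaf_x,
      beta = bx, se = se_x, p = px, n = n_exposure, stringsAsFactors = FALSE
    )

    swapped <- runif(m) < frac_swapped
    strand <- !pal & runif(m) < frac_strand_flipped
    ea_y <- ea; oa_y <- oa; by_out <- by; eaf_out <- eaf_y
    ea_y[swapped] <- oa[swapped]; oa_y[swapped] <- ea[swapped]
    by_out[swapped] <- -by_out[swapped]
    eaf_out[swapped] <- 1 - eaf_out[swapped]
    ea_y[strand] <- complement_allele(ea_y[strand])
    oa_y[strand] <- complement_allele(oa_y[strand])
    outcome <- data.frame(
      snp = snp, chr = chr, pos = pos, ea = ea_y, oa = oa_y, eaf = eaf_out,
      beta = by_out, se = se_y, p = py, n = n_outcome, stringsAsFactors = FALSE
    )

    truth <- data.frame(
      snp = snp, beta_x_true = beta_x_true, alpha = alpha,
      is_instrument = is_instrument, swapped = swapped,
      strand_flipped = strand, stringsAsFactors = FALSE
    )
    attr(truth, "theta_true") <- theta_true
    list(exposure = validate_sumstats(exposure),
         outcome = validate_sumstats(outcome),
         truth = truth)
  })
}

#' Simulate study-level odds ratios for meta-analysis
#'
#' Draws `m` studies whose true log-OR is normal around `true_logor` with
#' between-study variance `tau2`; each observed log-OR adds sampling noise
#' at a standard error drawn uniformly from `se_range`, and is reported as
#' an OR with a symmetric 95% interval.
#'
#' @param m number of studies.
#' @param true_logor mean true log odds ratio.
#' @param tau2 between-study variance (>= 0).
#' @param se_range interval the per-study standard errors are drawn from.
#' @param seed RNG seed.
#' @return Data frame `label, or, ci_low, ci_high` suitable for
#'   [dl_meta()].
#' @export
simulate_meta_studies <- function(m, true_logor, tau2, se_range = c(0.05, 0.3), seed) {
  stopifnot(m >= 1, tau2 >= 0)
  if (missing(seed)) stopf("a seed is mandatory for reproducible simulation")
  with_seed(seed, {
    se <- runif(m, se_range[1], se_range[2])
    y <- rnorm(m, true_logor, sqrt(tau2)) + rnorm(m, 0, se)
    z <- qnorm(0.975)
    data.frame(
      label = sprintf("study_%02d", seq_len(m)),
      or = exp(y), ci_low = exp(y - z * se), ci_high = exp(y + z * se),
      stringsAsFactors = FALSE
    )
  })
}
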