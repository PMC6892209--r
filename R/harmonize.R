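#' Harmonize exposure and outcome summary statistics
#'
#' Matches each SNP present in both studies and reorients the outcome
#' association onto the exposure's effect allele:
#'
#' * same orientation: outcome left unchanged;
#' * swapped alleles: outcome beta sign-flipped and `eaf_out` replaced by
#'   `1 - eaf_out`;
#' * strand flip (complementary alleles): resolved by complementing the
#'   outcome alleles, then applying the same/swapped rule;
#' * palindromic SNPs (A/T or C/G): alleles alone cannot resolve the strand.
#'   With `palindromic = "infer"` a palindromic SNP is retained only when
#'   both effect-allele frequencies are available and both lie outside
#'   `0.5 +/- palindromic_eaf_window`, in which case the orientation is the
#'   one that makes the frequencies consistent; otherwise it is dropped.
#'   With `palindromic = "drop"` every palindromic SNP is dropped;
#' * irreconcilable allele sets are dropped.
#'
#' Every SNP in the intersection appears exactly once in the harmonization
#' log, so `|intersection| = |retained| + |dropped|`.
#'
#' @param exposure,outcome validated summary-statistic data frames
#'   (see [read_sumstats()]); `snp` ids must be unique within each study.
#' @param palindromic_eaf_window half-width of the ambiguity window around
#'   frequency 0.5 used to resolve palindromic SNPs (default 0.08).
#' @param palindromic `"infer"` (default) to frequency-resolve palindromic
#'   SNPs, `"drop"` to discard them all.
#' @return A list with `instruments`, a data frame of harmonized records
#'   (`snp, chr, pos, ea, oa, beta_exp, se_exp, p_exp, eaf_exp, n_exp,
#'   beta_out, se_out, p_out, eaf_out, n_out`), and `log`, a data frame of
#'   `(snp, action, reason)` covering every shared SNP.
#' @export
harmonize_pair <- function(exposure, outcome, palindromic_eaf_window = 0.08,
                           palindromic = c("infer", "drop")) {
  palindromic <- match.arg(palindromic)
  for (nm in c("exposure", "outcome")) {
    x <- get(nm)
    dup <- unique(x$snp[duplicated(x$snp)])
    if (length(dup) > 0)
      stopf("duplicated snp id(s) in %s study: %s", nm,
            paste(head(dup, 5), collapse = ", "))
  }
  shared <- intersect(exposure$snp, outcome$snp)
  ex <- exposure[match(shared, exposure$snp), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp), , drop = FALSE]

  n <- length(shared)
  action <- character(n)
  reason <- rep("", n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  keep <- rep(TRUE, n)

  w <- palindromic_eaf_window
  for (i in seq_len(n)) {
    ea1 <- ex$ea[i]; oa1 <- ex$oa[i]
    ea2 <- ou$ea[i]; oa2 <- ou$oa[i]
    if (is_palindromic(ea1, oa1)) {
      same_set <- (ea2 == ea1 && oa2 == oa1) || (ea2 == oa1 && oa2 == ea1)
      if (!same_set) {
        keep[i] <- FALSE; action[i] <- "dropped"; reason[i] <- "irreconcilable alleles"
        next
      }
      if (palindromic == "drop") {
        keep[i] <- FALSE; action[i] <- "dropped"; reason[i] <- "palindromic"
        next
      }
      f1 <- ex$eaf[i]; f2 <- eaf_out[i]
      # align labels first, then let the frequencies decide the strand
      if (ea2 == oa1) f2 <- if (is.na(f2)) NA_real_ else 1 - f2
      ambiguous <- is.na(f1) || is.na(f2) ||
        abs(f1 - 0.5) <= w || abs(f2 - 0.5) <= w
      if (ambiguous) {
        keep[i] <- FALSE; action[i] <- "dropped"; reason[i] <- "palindromic_ambiguous"
        next
      }
      flip_labels <- ea2 == oa1
      flip_strand <- (f1 < 0.5) != (f2 < 0.5)
      flip <- xor(flip_labels, flip_strand)
      if (flip) {
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      }
      action[i] <- "palindromic_inferred"
      reason[i] <- if (flip) "orientation flipped by frequency" else "orientation kept by frequency"
    } else {
      c2 <- complement_allele(ea2); c2o <- complement_allele(oa2)
      if (ea2 == ea1 && oa2 == oa1) {
        action[i] <- "kept"; reason[i] <- "same orientation"
      } else if (ea2 == oa1 && oa2 == ea1) {
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
        action[i] <- "flipped"; reason[i] <- "effect/other alleles swapped"
      } else if (!is.na(c2) && !is.na(c2o) && c2 == ea1 && c2o == oa1) {
        action[i] <- "kept"; reason[i] <- "strand flip, same orientation"
      } else if (!is.na(c2) && !is.na(c2o) && c2 == oa1 && c2o == ea1) {
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
        action[i] <- "flipped"; reason[i] <- "strand flip, alleles swapped"
      } else {
        keep[i] <- FALSE; action[i] <- "dropped"; reason[i] <- "irreconcilable alleles"
      }
    }
  }

  instruments <- data.frame(
    snp = shared, chr = ex$chr, pos = ex$pos, ea = ex$ea, oa = ex$oa,
    beta_exp = ex$beta, se_exp = ex$se, p_exp = ex$p, eaf_exp = ex$eaf, n_exp = ex$n,
    beta_out = beta_out, se_out = ou$se, p_out = ou$p, eaf_out = eaf_out, n_out = ou$n,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(instruments) <- NULL
  log <- data.frame(snp = shared, action = action, reason = reason,
                    stringsAsFactors = FALSE)
  list(instruments = instruments, log = log)
}

#' Convert harmonized instruments back to per-study summary statistics
#'
#' Useful for re-harmonization checks and for the reverse-direction analysis.
#'
#' @param instruments harmonized data frame from [harmonize_pair()].
#' @param side `"exposure"` or `"outcome"`.
#' @return A canonical summary-statistic data frame.
#' @export
as_sumstats <- function(instruments, side = c("exposure", "outcome")) {
  side <- match.arg(side)
  sfx <- if (side == "exposure") "_exp" else "_out"
  validate_sumstats(data.frame(
    snp = instruments$snp, chr = instruments$chr, pos = instruments$pos,
    ea = instruments$ea, oa = instruments$oa,
    eaf = instruments[[paste0("eaf", sfx)]],
    beta = instruments[[paste0("beta", sfx)]],
    se = instruments[[paste0("se", sfx)]],
    p = instruments[[paste0("p", sfx)]],
    n = instruments[[paste0("n", sfx)]],
    stringsAsFactors = FALSE
  ))
}

#' Write a harmonization log
#'
#' @param log data frame `(snp, action, reason)` from [harmonize_pair()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_harmonization_log <- function(log, path) {
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
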