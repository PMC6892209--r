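#' Instrument-selection configuration
#'
#' Bundles the thresholds of the selection cascade: (A) exposure
#' genome-wide significance with distance pruning of index SNPs,
#' (B1) removal of instruments marginally associated with the outcome,
#' (B2) removal of instruments within a window of known outcome loci,
#' (C) removal of instruments on user-supplied exclusion lists.
#'
#' @param p_exposure exposure significance cutoff; SNPs are kept when
#'   `p < p_exposure` (strict, default `5e-8`).
#' @param prune_window_bp distance for index-SNP independence (default 1 Mb).
#' @param p_outcome outcome-association cutoff for filter B1; instruments
#'   with outcome `p < p_outcome` are removed (strict, default `1e-5`).
#' @param outcome_loci data frame with columns `chr`, `pos` of known
#'   outcome-associated loci for filter B2 (`NULL` disables the filter).
#' @param proximity_window_bp window for filter B2; an instrument within
#'   `<= proximity_window_bp` of a locus on the same chromosome is removed
#'   (inclusive, default 1 Mb).
#' @param exclusion_lists named list of character vectors of snp ids to
#'   remove in filter C; the list's name is recorded as the removal reason.
#' @param ld optional symmetric pairwise r-squared matrix (dimnames = snp
#'   ids) enabling LD-based clumping in place of pure distance pruning.
#' @param ld_r2 r-squared threshold for LD clumping (default 0.001).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(p_exposure = 5e-8, prune_window_bp = 1e6,
                             p_outcome = 1e-5, outcome_loci = NULL,
                             proximity_window_bp = 1e6,
                             exclusion_lists = list(), ld = NULL, ld_r2 = 0.001) {
  # p_exposure = 1 disables filter A; p_outcome = 0 disables filter B1
  stopifnot(p_exposure > 0, p_exposure <= 1, p_outcome >= 0, p_outcome <= 1,
            prune_window_bp >= 0, proximity_window_bp >= 0)
  structure(list(p_exposure = p_exposure, prune_window_bp = prune_window_bp,
                 p_outcome = p_outcome, outcome_loci = outcome_loci,
                 proximity_window_bp = proximity_window_bp,
                 exclusion_lists = exclusion_lists, ld = ld, ld_r2 = ld_r2),
            class = "selection_config")
}

removal_record <- function(snp, stage, reason) {
  snp <- as.character(snp)
  if (length(snp) == 0) stage <- reason <- character(0)
  data.frame(snp = snp, stage = stage, reason = reason,
             stringsAsFactors = FALSE)
}

#' Select independent index SNPs for the exposure
#'
#' Keeps SNPs with exposure p-value strictly below `p_threshold`, then
#' prunes to independent index SNPs greedily: survivors are visited in
#' ascending p-value order (ties broken by chromosome then position) and a
#' SNP is accepted only if no already-accepted SNP on the same chromosome
#' lies within `prune_window_bp` (inclusive). When a pairwise r-squared
#' matrix is supplied, a SNP is instead rejected when its r-squared with any
#' accepted SNP is `>= ld_r2` (distance is then ignored).
#'
#' @param records exposure summary statistics (canonical data frame); the
#'   p-value column may be `p` (raw records) or `p_exp` (harmonized).
#' @param p_threshold significance cutoff (strict `<`).
#' @param prune_window_bp pruning distance in base pairs.
#' @param ld,ld_r2 optional LD matrix and clumping threshold.
#' @return list with `selected` (the retained records, in the input order)
#'   and `removed` (data frame `snp, stage, reason`). An empty selection
#'   triggers a warning, not an error.
#' @export
select_index_snps <- function(records, p_threshold = 5e-8,
                              prune_window_bp = 1e6, ld = NULL, ld_r2 = 0.001) {
  pcol <- if ("p" %in% names(records)) "p" else "p_exp"
  p <- records[[pcol]]
  removed <- removal_record(character(), character(), character())

  # a threshold of 1 disables the filter (p <= 1 by invariant)
  sig <- !is.na(p) & (p < p_threshold | p_threshold >= 1)
  removed <- rbind(removed, removal_record(records$snp[!sig], "index_selection",
                                           sprintf("p >= %g", p_threshold)))
  surv <- records[sig, , drop = FALSE]

  if (nrow(surv) > 0 && (prune_window_bp > 0 || !is.null(ld))) {
    ord <- order(surv[[pcol]], surv$chr, surv$pos)
    accepted <- integer(0)
    pruned <- logical(nrow(surv))
    for (i in ord) {
      conflict <- FALSE
      if (!is.null(ld)) {
        for (j in accepted) {
          r2 <- ld[surv$snp[i], surv$snp[j]]
          if (!is.na(r2) && r2 >= ld_r2) { conflict <- TRUE; break }
        }
      } else {
        for (j in accepted) {
          if (!is.na(surv$chr[i]) && !is.na(surv$chr[j]) &&
              surv$chr[i] == surv$chr[j] &&
              abs(surv$pos[i] - surv$pos[j]) <= prune_window_bp) {
            conflict <- TRUE; break
          }
        }
      }
      if (conflict) pruned[i] <- TRUE else accepted <- c(accepted, i)
    }
    removed <- rbind(removed, removal_record(
      surv$snp[pruned], "pruning",
      if (is.null(ld)) sprintf("within %g bp of a better index SNP", prune_window_bp)
      else sprintf("r2 >= %g with a better index SNP", ld_r2)))
    surv <- surv[!pruned, , drop = FALSE]
  }

  if (nrow(surv) == 0) warnf("no index SNPs survive selection at p < %g", p_threshold)
  rownames(surv) <- NULL
  list(selected = surv, removed = removed)
}

#' Remove instruments marginally associated with the outcome (filter B1)
#'
#' @param instruments harmonized instruments.
#' @param p_threshold outcome p-value cutoff; removal requires
#'   `p_out < p_threshold` (strict).
#' @return list with `retained` and `removed` (audit rows).
#' @export
filter_outcome_pleiotropy <- function(instruments, p_threshold = 1e-5) {
  drop <- !is.na(instruments$p_out) & instruments$p_out < p_threshold
  list(retained = instruments[!drop, , drop = FALSE],
       removed = removal_record(instruments$snp[drop], "outcome_pleiotropy",
                                sprintf("outcome p < %g", p_threshold)))
}

#' Remove instruments near known outcome loci (filter B2)
#'
#' An instrument is removed iff some locus on the same chromosome satisfies
#' `|pos_instrument - pos_locus| <= window_bp` (inclusive boundary).
#'
#' @param instruments harmonized instruments with `chr`, `pos`.
#' @param outcome_loci data frame with columns `chr`, `pos`.
#' @param window_bp proximity window (default 1 Mb).
#' @return list with `retained` and `removed`.
#' @export
filter_proximity <- function(instruments, outcome_loci, window_bp = 1e6) {
  if (is.null(outcome_loci) || nrow(outcome_loci) == 0) {
    return(list(retained = instruments,
                removed = removal_record(character(), character(), character())))
  }
  if (any(is.na(outcome_loci$chr) | outcome_loci$chr == ""))
    stopf("outcome locus with unknown chromosome label")
  drop <- vapply(seq_len(nrow(instruments)), function(i) {
    same <- !is.na(instruments$chr[i]) &
      as.character(outcome_loci$chr) == as.character(instruments$chr[i])
    any(same & abs(outcome_loci$pos - instruments$pos[i]) <= window_bp)
  }, logical(1))
  list(retained = instruments[!drop, , drop = FALSE],
       removed = removal_record(instruments$snp[drop], "proximity",
                                sprintf("within %g bp of an outcome locus", window_bp)))
}

#' Remove instruments on a named exclusion list (filter C)
#'
#' @param instruments harmonized instruments.
#' @param excluded_ids character vector of snp ids to remove.
#' @param list_name label recorded as the removal reason.
#' @return list with `retained` and `removed`.
#' @export
filter_exclusion_list <- function(instruments, excluded_ids, list_name = "exclusion_list") {
  drop <- instruments$snp %in% excluded_ids
  list(retained = instruments[!drop, , drop = FALSE],
       removed = removal_record(instruments$snp[drop], "exclusion_list",
                                sprintf("on exclusion list '%s'", list_name)))
}

#' Run the full instrument-selection cascade
#'
#' Applies, in order: (A) exposure significance + distance pruning,
#' (B1) outcome-association filter, (B2) locus-proximity filter, (C) every
#' named exclusion list. Stage counts reconcile by construction:
#' each stage's input count equals its retained plus removed counts.
#'
#' @param instruments harmonized instruments (see [harmonize_pair()]).
#' @param config a [selection_config()].
#' @return list with `instruments` (final retained set), `audit` (data frame
#'   `snp, stage, reason`, one row per removal) and `counts` (per-stage
#'   data frame `stage, n_in, n_removed, n_out`).
#' @export
mr_select_instruments <- function(instruments, config = selection_config()) {
  audit <- removal_record(character(), character(), character())
  counts <- data.frame(stage = character(), n_in = integer(),
                       n_removed = integer(), n_out = integer(),
                       stringsAsFactors = FALSE)
  note <- function(stage, n_in, n_out) {
    counts <<- rbind(counts, data.frame(stage = stage, n_in = n_in,
                                        n_removed = n_in - n_out, n_out = n_out,
                                        stringsAsFactors = FALSE))
  }

  sel <- select_index_snps(instruments, config$p_exposure,
                           config$prune_window_bp, config$ld, config$ld_r2)
  audit <- rbind(audit, sel$removed)
  note("A_index_selection", nrow(instruments), nrow(sel$selected))
  cur <- sel$selected

  f1 <- filter_outcome_pleiotropy(cur, config$p_outcome)
  audit <- rbind(audit, f1$removed)
  note("B1_outcome_pleiotropy", nrow(cur), nrow(f1$retained))
  cur <- f1$retained

  f2 <- filter_proximity(cur, config$outcome_loci, config$proximity_window_bp)
  audit <- rbind(audit, f2$removed)
  note("B2_proximity", nrow(cur), nrow(f2$retained))
  cur <- f2$retained

  for (nm in names(config$exclusion_lists)) {
    f3 <- filter_exclusion_list(cur, config$exclusion_lists[[nm]], nm)
    audit <- rbind(audit, f3$removed)
    note(paste0("C_", nm), nrow(cur), nrow(f3$retained))
    cur <- f3$retained
  }
  rownames(audit) <- NULL
  list(instruments = cur, audit = audit, counts = counts)
}

#' Instrument-strength diagnostics (variance explained and F statistics)
#'
#' Per-SNP proportion of exposure variance explained on the observed scale,
#' `pve = 2 b^2 f (1-f) / (2 b^2 f (1-f) + 2 se^2 N f (1-f))` with `f` the
#' effect-allele frequency, and the one-instrument F statistic
#' `F = (N - 2) pve / (1 - pve)` (for small pve this is approximately
#' `b^2 / se^2`, available as `f_method = "ratio"`). The overall F across
#' the k instruments is `((N - k - 1) / k) * R2 / (1 - R2)` with `R2` the
#' summed per-SNP pve.
#'
#' @param instruments harmonized instruments (uses `beta_exp`, `se_exp`,
#'   `eaf_exp`, `n_exp`).
#' @param n_exposure scalar exposure sample size used where `n_exp` is
#'   missing.
#' @param f_method `"r2"` (default, exact one-instrument form) or
#'   `"ratio"` (`b^2/se^2` approximation).
#' @return list of class `strength_report`: `per_snp` (snp, pve, f),
#'   `mean_f`, `overall_f`, `total_pve`, `k`, `f_method`. SNPs lacking `eaf`
#'   or `n` get `NA` diagnostics and are excluded from totals with a
#'   warning.
#' @export
instrument_strength <- function(instruments, n_exposure = NULL,
                                f_method = c("r2", "ratio")) {
  f_method <- match.arg(f_method)
  b <- instruments$beta_exp
  se <- instruments$se_exp
  f <- instruments$eaf_exp
  n <- instruments$n_exp
  if (!is.null(n_exposure)) n[is.na(n)] <- n_exposure
  k <- nrow(instruments)

  num <- 2 * b^2 * f * (1 - f)
  den <- num + 2 * se^2 * n * f * (1 - f)
  pve <- ifelse(den > 0, num / den, 0)
  fstat <- switch(f_method,
                  r2 = (n - 2) * pve / (1 - pve),
                  ratio = b^2 / se^2)
  usable <- !is.na(pve) & !is.na(fstat)
  if (any(!usable))
    warnf("%d instrument(s) lack eaf or n; excluded from strength totals", sum(!usable))

  total_pve <- sum(pve[usable])
  n_bar <- mean(n[usable])
  overall_f <- if (sum(usable) > 0)
    ((n_bar - sum(usable) - 1) / sum(usable)) * total_pve / (1 - total_pve)
  else NA_real_
  structure(list(
    per_snp = data.frame(snp = instruments$snp, pve = pve, f = fstat,
                         stringsAsFactors = FALSE),
    mean_f = mean(fstat[usable]), overall_f = overall_f,
    total_pve = total_pve, k = k, n_used = sum(usable), f_method = f_method
  ), class = "strength_report")
}
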