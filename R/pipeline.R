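#' Configure an end-to-end MR study
#'
#' Bundles everything [run_mr_study()] needs: the two summary-statistic
#' inputs (file paths or in-memory data frames), the instrument-selection
#' configuration, estimator and sensitivity settings, the analysis
#' direction and the output directory. A configuration can also be read
#' from a YAML or JSON file with [read_study_config()].
#'
#' @param exposure,outcome file paths to summary-statistic tables, or
#'   canonical data frames.
#' @param exposure_column_map,outcome_column_map column maps passed to
#'   [read_sumstats()].
#' @param selection a [selection_config()].
#' @param direction `"forward"` or `"reverse"`; reverse swaps the
#'   exposure/outcome roles (instrument selection is then re-run on the new
#'   exposure).
#' @param effects IVW flavor reported alongside the fixed-effects estimate.
#' @param n_boot weighted-median bootstrap replicates.
#' @param presso_n_sim,presso_alpha MR-PRESSO simulation count and outlier
#'   level.
#' @param seed study-wide RNG seed (recorded in the report).
#' @param alpha study-wide significance level (default 0.05).
#' @param palindromic_eaf_window,palindromic harmonization settings (see
#'   [harmonize_pair()]).
#' @param out_dir output directory (`NULL` = no files written).
#' @param plots write scatter/funnel/forest/leave-one-out plots (requires a
#'   usable graphics device; default TRUE when `out_dir` is set).
#' @return list of class `mr_study_config`.
#' @export
mr_study_config <- function(exposure, outcome,
                            exposure_column_map = NULL, outcome_column_map = NULL,
                            selection = selection_config(),
                            direction = c("forward", "reverse"),
                            effects = "random", n_boot = 1000,
                            presso_n_sim = 1000, presso_alpha = 0.05,
                            seed = 2019, alpha = 0.05,
                            palindromic_eaf_window = 0.08,
                            palindromic = "infer",
                            out_dir = NULL, plots = !is.null(out_dir)) {
  direction <- match.arg(direction)
  structure(list(
    exposure = exposure, outcome = outcome,
    exposure_column_map = exposure_column_map,
    outcome_column_map = outcome_column_map,
    selection = selection, direction = direction, effects = effects,
    n_boot = n_boot, presso_n_sim = presso_n_sim, presso_alpha = presso_alpha,
    seed = seed, alpha = alpha,
    palindromic_eaf_window = palindromic_eaf_window, palindromic = palindromic,
    out_dir = out_dir, plots = plots
  ), class = "mr_study_config")
}

#' Read a study configuration from YAML or JSON
#'
#' File fields mirror the arguments of [mr_study_config()]; the `selection`
#' block mirrors [selection_config()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return list of class `mr_study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sel <- do.call(selection_config, cfg$selection %||% list())
  cfg$selection <- NULL
  do.call(mr_study_config, c(cfg, list(selection = sel)))
}

read_side <- function(x, column_map) {
  if (is.character(x) && length(x) == 1) read_sumstats(x, column_map)
  else validate_sumstats(x)
}

#' Run a complete two-sample MR study
#'
#' Executes the full workflow: read and validate both studies, harmonize
#' onto common effect alleles, run the instrument-selection cascade,
#' compute strength diagnostics, all causal estimators (fixed- and
#' random-effects IVW, MR-Egger, weighted median, per-instrument Wald
#' ratios) and all sensitivity analyses (Cochran's Q, leave-one-out,
#' MR-PRESSO, funnel data). An estimator whose minimum instrument count is
#' not met is skipped with an explicit notice and the run continues.
#'
#' When `out_dir` is set the bundle is exported: `results.json` (every
#' estimate and diagnostic, machine-readable and reproducible byte for byte
#' given the same configuration and seeds), `estimates.tsv`,
#' `instruments.tsv`, `audit.tsv`, `harmonization_log.tsv`, `loo.tsv`,
#' `presso.tsv`, plots (from the exported tables, so plotted and reported
#' numbers cannot diverge) and `run_log.txt` (package version, seeds,
#' configuration echo).
#'
#' @param config an [mr_study_config()].
#' @return list of class `mr_study_result` with elements `instruments`,
#'   `harmonization_log`, `audit`, `counts`, `strength`, `estimates`,
#'   `wald`, `q`, `loo`, `presso`, `funnel`, `notices`, `config`.
#' @export
run_mr_study <- function(config) {
  stopifnot(inherits(config, "mr_study_config"))
  exposure <- read_side(config$exposure, config$exposure_column_map)
  outcome <- read_side(config$outcome, config$outcome_column_map)
  if (config$direction == "reverse") {
    tmp <- exposure; exposure <- outcome; outcome <- tmp
  }

  notices <- character(0)
  notice <- function(msg) notices <<- c(notices, msg)

  # stage A runs on the exposure study (index-SNP discovery), the remaining
  # filters on the harmonized set
  sel <- select_index_snps(exposure, config$selection$p_exposure,
                           config$selection$prune_window_bp,
                           config$selection$ld, config$selection$ld_r2)
  harm <- harmonize_pair(sel$selected, outcome,
                         config$palindromic_eaf_window, config$palindromic)
  audit <- rbind(sel$removed,
                 removal_record(harm$log$snp[harm$log$action == "dropped"],
                                "harmonization",
                                harm$log$reason[harm$log$action == "dropped"]))
  unmatched <- setdiff(sel$selected$snp, harm$log$snp)
  audit <- rbind(audit, removal_record(unmatched, "harmonization",
                                       "absent from outcome study"))
  counts <- data.frame(
    stage = c("A_index_selection", "harmonization"),
    n_in = c(nrow(exposure), nrow(sel$selected)),
    n_removed = c(nrow(exposure) - nrow(sel$selected),
                  nrow(sel$selected) - nrow(harm$instruments)),
    n_out = c(nrow(sel$selected), nrow(harm$instruments)),
    stringsAsFactors = FALSE
  )
  instr <- harm$instruments
  note_stage <- function(stage, n_in, n_out) {
    counts <<- rbind(counts, data.frame(stage = stage, n_in = n_in,
                                        n_removed = n_in - n_out, n_out = n_out,
                                        stringsAsFactors = FALSE))
  }
  f1 <- filter_outcome_pleiotropy(instr, config$selection$p_outcome)
  audit <- rbind(audit, f1$removed)
  note_stage("B1_outcome_pleiotropy", nrow(instr), nrow(f1$retained))
  instr <- f1$retained
  f2 <- filter_proximity(instr, config$selection$outcome_loci,
                         config$selection$proximity_window_bp)
  audit <- rbind(audit, f2$removed)
  note_stage("B2_proximity", nrow(instr), nrow(f2$retained))
  instr <- f2$retained
  for (nm in names(config$selection$exclusion_lists)) {
    f3 <- filter_exclusion_list(instr, config$selection$exclusion_lists[[nm]], nm)
    audit <- rbind(audit, f3$removed)
    note_stage(paste0("C_", nm), nrow(instr), nrow(f3$retained))
    instr <- f3$retained
  }
  k <- nrow(instr)

  strength <- if (k >= 1) suppressWarnings(instrument_strength(instr)) else NULL

  estimates <- NULL
  add_est <- function(expr, label, k_min) {
    if (k < k_min) {
      notice(sprintf("%s skipped: %d instrument(s) < minimum %d", label, k, k_min))
      return(invisible(NULL))
    }
    est <- expr()
    estimates <<- if (is.null(estimates)) est else {
      out <- rbind(estimates, est)
      class(out) <- c("mr_estimate", "data.frame")
      out
    }
  }
  add_est(function() mr_ivw(instr, "fixed"), "ivw_fixed", 1)
  if (config$effects != "fixed")
    add_est(function() mr_ivw(instr, config$effects), paste0("ivw_", config$effects), 2)
  add_est(function() mr_egger(instr), "egger", 3)
  add_est(function() mr_weighted_median(instr, config$n_boot, config$seed),
          "weighted_median", 3)
  if (!is.null(estimates)) estimates <- or_transform(estimates)

  wald <- if (k >= 1) mr_wald_ratio(instr) else NULL
  q <- if (k >= 2) mr_cochran_q(instr) else { notice("cochran_q skipped: k < 2"); NULL }
  loo <- if (k >= 3) mr_leave_one_out(instr, if (config$effects == "fixed") "fixed" else "random",
                                      config$alpha)
         else { notice("leave_one_out skipped: k < 3"); NULL }
  presso <- if (k >= 4) mr_presso(instr, config$presso_n_sim, config$presso_alpha,
                                  config$seed)
            else { notice("mr_presso skipped: k < 4"); NULL }
  funnel <- if (k >= 3) mr_funnel(instr) else { notice("funnel skipped: k < 3"); NULL }

  result <- structure(list(
    instruments = instr, harmonization_log = harm$log, audit = audit,
    counts = counts, strength = strength, estimates = estimates, wald = wald,
    q = q, loo = loo, presso = presso, funnel = funnel,
    notices = notices, config = config
  ), class = "mr_study_result")

  if (!is.null(config$out_dir)) export_mr_study(result, config$out_dir)
  result
}

export_mr_study <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(out_dir, f)
  cfg <- result$config

  write.table(result$instruments, out("instruments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$audit, out("audit.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_harmonization_log(result$harmonization_log, out("harmonization_log.tsv"))
  if (!is.null(result$estimates)) write_estimates(result$estimates, out("estimates.tsv"))
  if (!is.null(result$loo))
    write.table(result$loo, out("loo.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$presso))
    write.table(result$presso$per_snp, out("presso.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  payload <- list(
    direction = cfg$direction, seed = cfg$seed, alpha = cfg$alpha,
    counts = result$counts,
    strength = if (!is.null(result$strength))
      result$strength[c("mean_f", "overall_f", "total_pve", "k", "f_method")] else NULL,
    estimates = result$estimates,
    heterogeneity = result$q,
    presso = if (!is.null(result$presso))
      result$presso[c("global_rss", "global_p", "outliers", "distortion_p")] else NULL,
    notices = result$notices
  )
  jsonlite::write_json(payload, out("results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  log_lines <- c(
    sprintf("mrcausal %s, R %s", as.character(packageVersion("mrcausal")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("direction=%s seed=%d alpha=%g effects=%s", cfg$direction, cfg$seed,
            cfg$alpha, cfg$effects),
    sprintf("selection: p_exposure=%g prune_window_bp=%g p_outcome=%g proximity_window_bp=%g",
            cfg$selection$p_exposure, cfg$selection$prune_window_bp,
            cfg$selection$p_outcome, cfg$selection$proximity_window_bp),
    sprintf("palindromic=%s window=%g", cfg$palindromic, cfg$palindromic_eaf_window),
    if (length(result$notices)) paste("notice:", result$notices) else character(0)
  )
  writeLines(log_lines, out("run_log.txt"))

  if (isTRUE(cfg$plots)) {
    dev_ok <- capabilities("png") || capabilities("cairo")
    if (!dev_ok) return(invisible(result))
    save_plot <- function(p, f) {
      tryCatch(suppressMessages(ggplot2::ggsave(out(f), p, width = 6, height = 5, dpi = 150)),
               error = function(e) invisible(NULL))
    }
    # plots are drawn from the exported tables, never from internal state
    instr_tab <- read.delim(out("instruments.tsv"), stringsAsFactors = FALSE)
    if (!is.null(result$estimates)) {
      est_tab <- read.delim(out("estimates.tsv"), stringsAsFactors = FALSE)
      save_plot(mr_scatter_plot(instr_tab, est_tab), "scatter.png")
      if (!is.null(result$wald))
        save_plot(mr_forest_plot(result$wald,
                                 est_tab[est_tab$method == "ivw_fixed", ]), "forest.png")
    }
    if (!is.null(result$funnel))
      save_plot(mr_funnel_plot(result$funnel$data, result$funnel$theta_ivw), "funnel.png")
    if (!is.null(result$loo)) {
      loo_tab <- read.delim(out("loo.tsv"), stringsAsFactors = FALSE)
      full <- result$estimates[result$estimates$method == "ivw_fixed", ]
      save_plot(mr_loo_plot(loo_tab, full$theta), "loo.png")
    }
  }
  invisible(result)
}
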