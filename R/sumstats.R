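#' Canonical summary-statistic columns
#'
#' The package's native dialect for GWAS summary-statistic tables is a
#' delimited text file (TSV by default) with one row per SNP and columns
#' `snp, chr, pos, ea, oa, eaf, beta, se, p, n`:
#' `snp` the variant identifier, `chr`/`pos` the 1-based genomic coordinate,
#' `ea`/`oa` the effect and other allele (upper-cased on ingest), `eaf` the
#' effect-allele frequency, `beta` the additive per-allele effect on the
#' trait (log-odds for binary traits), `se` its standard error, `p` the
#' association p-value and `n` the sample size. `chr`, `pos`, `eaf` and `n`
#' are optional.
#'
#' @format A character vector of canonical column names.
#' @export
sumstats_columns <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")

.required_columns <- c("snp", "ea", "oa", "beta", "se", "p")

empty_sumstats <- function() {
  data.frame(
    snp = character(), chr = character(), pos = numeric(),
    ea = character(), oa = character(), eaf = numeric(),
    beta = numeric(), se = numeric(), p = numeric(), n = numeric(),
    stringsAsFactors = FALSE
  )
}

#' Validate summary-statistic records
#'
#' Applies the row-level invariants of the canonical format: `se > 0`,
#' `p` in (0, 1], `eaf` in \[0, 1\] when present, `ea != oa`, finite `beta`.
#' Rows failing any invariant are removed and reported.
#'
#' @param x data frame with (at least) the required canonical columns.
#' @return The validated data frame, with a `rejections` attribute: a data
#'   frame of `(row, snp, reason)` for every rejected row.
#' @export
validate_sumstats <- function(x) {
  missing <- setdiff(.required_columns, names(x))
  if (length(missing) > 0)
    stopf("missing required column(s): %s", paste(missing, collapse = ", "))

  for (col in setdiff(sumstats_columns, names(x))) x[[col]] <- NA
  x <- x[, sumstats_columns]

  x$snp <- as.character(x$snp)
  x$chr <- as.character(x$chr)
  x$ea <- toupper(as.character(x$ea))
  x$oa <- toupper(as.character(x$oa))
  for (col in c("pos", "eaf", "beta", "se", "p", "n")) {
    v <- x[[col]]
    x[[col]] <- if (is.double(v)) v
      else if (is.numeric(v) || is.logical(v)) as.numeric(v)
      else suppressWarnings(as.numeric(as.character(v)))
  }

  reason <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reason[is.na(reason) & bad] <<- why
  }
  flag(is.na(x$snp) | x$snp == "", "missing snp id")
  flag(is.na(x$beta), "unparseable or missing beta")
  flag(is.na(x$se), "unparseable or missing se")
  flag(is.na(x$p), "unparseable or missing pvalue")
  flag(!is.na(x$se) & x$se <= 0, "se not > 0")
  flag(!is.na(x$p) & (x$p <= 0 | x$p > 1), "pvalue outside (0, 1]")
  flag(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "eaf outside [0, 1]")
  flag(is.na(x$ea) | is.na(x$oa) | x$ea == "" | x$oa == "", "missing allele")
  flag(x$ea == x$oa, "effect allele equals other allele")
  flag(!is.na(x$beta) & !is.finite(x$beta), "non-finite beta")

  bad <- !is.na(reason)
  rejections <- data.frame(
    row = which(bad), snp = x$snp[bad], reason = reason[bad],
    stringsAsFactors = FALSE
  )
  out <- x[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  out
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab- or comma-delimited text file with a header row, maps the
#' file's column names onto the canonical dialect (see [sumstats_columns]),
#' and validates every row. Rows violating the record invariants are
#' rejected (not a crash) and reported via the `rejections` attribute.
#'
#' @param path file path. `.csv` is read comma-delimited, anything else
#'   tab-delimited unless `delim` is given.
#' @param column_map named character vector mapping canonical names to the
#'   file's column names, e.g. `c(snp = "MarkerName", beta = "Effect")`.
#'   Canonical names absent from the map are looked up verbatim.
#' @param delim field delimiter override.
#' @return A validated data frame in canonical column order with a
#'   `rejections` attribute (see [validate_sumstats()]).
#' @export
read_sumstats <- function(path, column_map = NULL, delim = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = delim, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character", na.strings = c("NA", ""))
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), sumstats_columns)
    if (length(bad) > 0)
      stopf("unknown canonical column(s) in column_map: %s", paste(bad, collapse = ", "))
  }
  resolve <- function(canon) {
    src <- if (!is.null(column_map) && canon %in% names(column_map)) column_map[[canon]] else canon
    if (src %in% names(raw)) raw[[src]] else NULL
  }
  out <- list()
  for (canon in sumstats_columns) {
    v <- resolve(canon)
    if (is.null(v)) {
      if (canon %in% .required_columns) {
        src <- if (!is.null(column_map) && canon %in% names(column_map)) column_map[[canon]] else canon
        stopf("required column '%s' (mapped from '%s') not found in %s", canon, src, path)
      }
      v <- rep(NA_character_, nrow(raw))
    }
    out[[canon]] <- v
  }
  validate_sumstats(as.data.frame(out, stringsAsFactors = FALSE))
}

#' Write summary statistics in the canonical dialect
#'
#' Writes a tab-delimited file with the canonical header. Missing values are
#' written as empty fields and numeric values with 17 significant digits so
#' that `read_sumstats(write_sumstats(x))` reproduces `x` field for field.
#'
#' @param records validated summary-statistic data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  for (col in setdiff(sumstats_columns, names(records))) records[[col]] <- NA
  records <- records[, sumstats_columns]
  fmt <- records
  for (col in c("pos", "eaf", "beta", "se", "p", "n")) {
    v <- records[[col]]
    s <- ifelse(is.na(v), "", sprintf("%.17g", as.numeric(v)))
    fmt[[col]] <- s
  }
  ok <- tryCatch({
    write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) stopf("cannot write summary statistics to '%s': %s", path, conditionMessage(e)))
  invisible(path)
}
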