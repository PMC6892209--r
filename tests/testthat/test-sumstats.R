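test_that("a well-formed table parses to validated records with no rejections", {
  path <- write_tmp_sumstats(base_records())
  rec <- read_sumstats(path)
  expect_equal(nrow(rec), 3)
  expect_equal(nrow(attr(rec, "rejections")), 0)
  expect_equal(rec$snp, c("rs1", "rs2", "rs3"))
  expect_equal(rec$beta, c(0.1, -0.05, 0.02))
})

test_that("rows violating invariants are rejected with a reason, not a crash", {
  df <- base_records()
  df$se[2] <- 0                       # invariant boundary: se must be > 0
  df$p[3] <- 1.5
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_sumstats(path)
  rej <- attr(rec, "rejections")
  expect_equal(nrow(rec), 1)
  expect_equal(nrow(rej), 2)
  expect_true(any(grepl("se", rej$reason)))
  expect_true(any(grepl("pvalue", rej$reason)))
})

test_that("unparseable numeric fields reject the row only", {
  df <- base_records()
  df$beta <- as.character(df$beta)
  df$beta[1] <- "not_a_number"
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_sumstats(path)
  expect_equal(nrow(rec), 2)
  expect_equal(attr(rec, "rejections")$snp, "rs1")
})

test_that("a missing required column raises a configuration error naming it", {
  df <- base_records()
  df$se <- NULL
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), "se")
})

test_that("column maps resolve non-canonical headers and CSV is accepted", {
  df <- base_records()
  names(df) <- c("MarkerName", "CHR", "BP", "A1", "A2", "FRQ", "Effect", "StdErr", "P", "N")
  path <- tempfile(fileext = ".csv")
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  rec <- read_sumstats(path, column_map = c(
    snp = "MarkerName", chr = "CHR", pos = "BP", ea = "A1", oa = "A2",
    eaf = "FRQ", beta = "Effect", se = "StdErr", p = "P", n = "N"
  ))
  expect_equal(rec$snp, c("rs1", "rs2", "rs3"))
  expect_equal(rec$se, c(0.01, 0.02, 0.03))
})

test_that("lowercase alleles are upper-cased and give identical records", {
  up <- base_records()
  lo <- up
  lo$ea <- tolower(lo$ea); lo$oa <- tolower(lo$oa)
  p_up <- tempfile(fileext = ".tsv"); p_lo <- tempfile(fileext = ".tsv")
  write.table(up, p_up, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(lo, p_lo, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_sumstats(p_lo), read_sumstats(p_up))
})

test_that("writing then reading reproduces records field for field", {
  set.seed(11)
  df <- data.frame(
    snp = sprintf("rs%d", 1:5), chr = as.character(1:5),
    pos = as.integer(runif(5, 1, 1e8)),
    ea = c("A", "T", "G", "C", "A"), oa = c("G", "C", "A", "T", "C"),
    eaf = c(runif(4), NA), beta = rnorm(5), se = exp(rnorm(5)),
    p = runif(5), n = c(1e5, 2e5, NA, 1e5, 3e5), stringsAsFactors = FALSE
  )
  rec <- validate_sumstats(df)
  path <- tempfile(fileext = ".tsv")
  write_sumstats(rec, path)
  back <- read_sumstats(path)
  attr(back, "rejections") <- NULL
  attr(rec, "rejections") <- NULL
  expect_identical(back, rec)
  # missing eaf written as an empty field, read back as missing
  expect_true(is.na(back$eaf[5]))
  raw <- readLines(path)
  expect_match(raw[6], "\t\t", fixed = TRUE)
})

test_that("an empty collection writes a header-only file", {
  path <- tempfile(fileext = ".tsv")
  write_sumstats(validate_sumstats(base_records()[0, ]), path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_equal(strsplit(lines, "\t")[[1]], sumstats_columns)
})

test_that("harmonization applies the same/swap/strand rules", {
  ex <- validate_sumstats(data.frame(
    snp = c("s1", "s2", "s3", "s4"), chr = "1", pos = 1:4,
    ea = c("A", "A", "A", "A"), oa = c("G", "G", "G", "G"),
    eaf = 0.3, beta = 0.1, se = 0.01, p = 1e-9, n = NA
  ))
  ou <- validate_sumstats(data.frame(
    snp = c("s1", "s2", "s3", "s4"), chr = "1", pos = 1:4,
    ea = c("A", "G", "T", "C"), oa = c("G", "A", "C", "T"),
    eaf = c(0.3, 0.7, 0.3, 0.7), beta = c(-0.05, -0.05, -0.05, -0.05),
    se = 0.02, p = 0.01, n = NA
  ))
  h <- harmonize_pair(ex, ou)
  expect_equal(nrow(h$instruments), 4)
  # same orientation: unchanged
  expect_equal(h$instruments$beta_out[1], -0.05)
  # swapped alleles: sign flip, frequency complement
  expect_equal(h$instruments$beta_out[2], 0.05)
  expect_equal(h$instruments$eaf_out[2], 0.3)
  # strand flip, same orientation: unchanged
  expect_equal(h$instruments$beta_out[3], -0.05)
  # strand flip with swap: sign flip
  expect_equal(h$instruments$beta_out[4], 0.05)
})

test_that("palindromic SNPs follow the frequency-window policy", {
  ex <- validate_sumstats(data.frame(
    snp = c("amb", "inf_same", "inf_flip"), chr = "1", pos = 1:3,
    ea = "A", oa = "T", eaf = c(0.50, 0.20, 0.20),
    beta = 0.1, se = 0.01, p = 1e-9, n = NA
  ))
  ou <- validate_sumstats(data.frame(
    snp = c("amb", "inf_same", "inf_flip"), chr = "1", pos = 1:3,
    ea = "A", oa = "T", eaf = c(0.50, 0.22, 0.78),
    beta = -0.05, se = 0.02, p = 0.01, n = NA
  ))
  h <- harmonize_pair(ex, ou)
  expect_false("amb" %in% h$instruments$snp)
  expect_equal(h$log$reason[h$log$snp == "amb"], "palindromic_ambiguous")
  i_same <- h$instruments[h$instruments$snp == "inf_same", ]
  expect_equal(i_same$beta_out, -0.05)
  i_flip <- h$instruments[h$instruments$snp == "inf_flip", ]
  expect_equal(i_flip$beta_out, 0.05)
  expect_equal(i_flip$eaf_out, 0.22)
  # drop-all policy removes every palindromic SNP regardless of frequency
  h2 <- harmonize_pair(ex, ou, palindromic = "drop")
  expect_equal(nrow(h2$instruments), 0)
})

test_that("irreconcilable allele sets are dropped and logged", {
  ex <- validate_sumstats(data.frame(
    snp = "s1", chr = "1", pos = 1L, ea = "A", oa = "G",
    eaf = 0.3, beta = 0.1, se = 0.01, p = 1e-9, n = NA
  ))
  ou <- validate_sumstats(data.frame(
    snp = "s1", chr = "1", pos = 1L, ea = "A", oa = "C",
    eaf = 0.3, beta = 0.1, se = 0.01, p = 0.01, n = NA
  ))
  h <- harmonize_pair(ex, ou)
  expect_equal(nrow(h$instruments), 0)
  expect_equal(h$log$reason, "irreconcilable alleles")
})

test_that("duplicate snp ids are an error naming the duplicate", {
  ex <- validate_sumstats(base_records())
  dup <- validate_sumstats(rbind(base_records(), base_records()[1, ]))
  expect_error(harmonize_pair(dup, ex), "rs1")
  expect_error(harmonize_pair(ex, dup), "rs1")
})

test_that("harmonization is idempotent and conserves counts on simulated data", {
  sim <- simulate_two_sample(k_instruments = 40, n_null_snps = 60,
                             frac_palindromic = 0.25, seed = 301)
  h1 <- harmonize_pair(sim$exposure, sim$outcome)
  shared <- length(intersect(sim$exposure$snp, sim$outcome$snp))
  dropped <- sum(h1$log$action == "dropped")
  expect_equal(nrow(h1$log), shared)
  expect_equal(nrow(h1$instruments) + dropped, shared)
  expect_true(all(nzchar(h1$log$reason[h1$log$action == "dropped"])))

  # re-harmonizing the harmonized pair changes nothing
  h2 <- harmonize_pair(as_sumstats(h1$instruments, "exposure"),
                       as_sumstats(h1$instruments, "outcome"))
  expect_equal(h2$instruments[names(h1$instruments)], h1$instruments,
               ignore_attr = TRUE)
})

test_that("relabeling both studies' alleles leaves Wald ratios invariant", {
  sim <- simulate_two_sample(k_instruments = 30, seed = 302)
  h1 <- harmonize_pair(sim$exposure, sim$outcome)
  flip_labels <- function(x) {
    tmp <- x$ea; x$ea <- x$oa; x$oa <- tmp
    x$beta <- -x$beta
    x$eaf <- 1 - x$eaf
    x
  }
  h2 <- harmonize_pair(flip_labels(sim$exposure), flip_labels(sim$outcome))
  expect_setequal(h1$instruments$snp, h2$instruments$snp)
  m <- match(h1$instruments$snp, h2$instruments$snp)
  r1 <- h1$instruments$beta_out / h1$instruments$beta_exp
  r2 <- (h2$instruments$beta_out / h2$instruments$beta_exp)[m]
  expect_equal(r1, r2)
})
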