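test_that("index selection is strict at the significance boundary", {
  df <- make_instruments(beta_exp = c(0.1, 0.1), beta_out = c(0, 0),
                         chr = c("1", "2"), pos = c(1e6, 1e6),
                         p_exp = c(5e-8, 4.999e-8))
  sel <- select_index_snps(df, p_threshold = 5e-8)  # harmonized-style p_exp column
  expect_equal(sel$selected$snp, "rs002")   # p == 5e-8 exactly is excluded
  expect_equal(sel$removed$stage, "index_selection")
})

test_that("greedy distance pruning keeps the stronger of two nearby SNPs", {
  df <- data.frame(
    snp = c("a", "b"), chr = "3", pos = c(1e6, 1.5e6),
    p = c(1e-9, 1e-10), stringsAsFactors = FALSE
  )
  sel <- select_index_snps(df, prune_window_bp = 1e6)
  expect_equal(sel$selected$snp, "b")
  expect_equal(sel$removed$snp, "a")
  expect_equal(sel$removed$stage, "pruning")
})

test_that("pruned sets match a brute-force all-pairs oracle", {
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    df <- data.frame(
      snp = sprintf("v%02d", 1:10),
      chr = as.character(sample(1:3, 10, replace = TRUE)),
      pos = as.integer(runif(10, 1, 5e6)),
      p = 10^runif(10, -20, -8), stringsAsFactors = FALSE
    )
    sel <- select_index_snps(df, p_threshold = 5e-8, prune_window_bp = 1e6)
    expect_equal(sort(sel$selected$snp), prune_oracle(df, 1e6))
  }
})

test_that("an optional LD matrix drives r-squared clumping", {
  df <- data.frame(
    snp = c("a", "b", "c"), chr = c("1", "2", "3"), pos = c(1e6, 1e6, 1e6),
    p = c(1e-12, 1e-10, 1e-9), stringsAsFactors = FALSE
  )
  ld <- diag(3); dimnames(ld) <- list(df$snp, df$snp)
  ld["a", "b"] <- ld["b", "a"] <- 0.5    # b clumped into a despite distance
  sel <- select_index_snps(df, ld = ld, ld_r2 = 0.001)
  expect_equal(sel$selected$snp, c("a", "c"))
})

test_that("empty selections warn rather than error", {
  df <- data.frame(snp = "a", chr = "1", pos = 1L, p = 0.5, stringsAsFactors = FALSE)
  expect_warning(sel <- select_index_snps(df), "no index SNPs")
  expect_equal(nrow(sel$selected), 0)
})

test_that("the outcome-association filter is strict at its boundary", {
  instr <- make_instruments(beta_exp = rep(0.1, 3), beta_out = rep(0, 3),
                            p_out = c(2e-6, 1e-5, 0.5))
  f <- filter_outcome_pleiotropy(instr, 1e-5)
  expect_equal(f$removed$snp, "rs001")          # 2e-6 removed
  expect_true("rs002" %in% f$retained$snp)      # exactly 1e-5 retained
})

test_that("no instrument is removed when none is below the outcome threshold", {
  set.seed(9)
  instr <- make_instruments(beta_exp = runif(67, 0.02, 0.2),
                            beta_out = rnorm(67, 0, 0.01),
                            p_out = runif(67, 0.01, 1))
  f <- filter_outcome_pleiotropy(instr, 1e-5)
  expect_equal(nrow(f$removed), 0)
  expect_equal(nrow(f$retained), 67)
})

test_that("the proximity filter is inclusive at exactly the window", {
  instr <- make_instruments(beta_exp = c(0.1, 0.1), beta_out = c(0, 0),
                            chr = c("9", "10"), pos = c(1e6, 1e6))
  loci <- data.frame(chr = "9", pos = 2e6)
  f <- filter_proximity(instr, loci, window_bp = 1e6)
  expect_equal(f$removed$snp, "rs001")          # distance exactly 1 Mb: removed
  expect_equal(f$retained$snp, "rs002")         # same position, other chromosome
  expect_error(filter_proximity(instr, data.frame(chr = NA, pos = 1e6)),
               "chromosome")
})

test_that("proximity removals match an all-pairs distance oracle", {
  set.seed(5)
  instr <- make_instruments(beta_exp = runif(5, 0.05, 0.2), beta_out = rnorm(5, 0, 0.01),
                            chr = as.character(c(1, 1, 2, 2, 3)),
                            pos = as.integer(runif(5, 1, 1e7)))
  loci <- data.frame(chr = c("1", "2"), pos = c(4e6, 9e6))
  f <- filter_proximity(instr, loci, window_bp = 1e6)
  oracle <- instr$snp[sapply(seq_len(5), function(i) {
    any(loci$chr == instr$chr[i] & abs(loci$pos - instr$pos[i]) <= 1e6)
  })]
  expect_setequal(f$removed$snp, oracle)
})

test_that("exclusion lists are a named set difference", {
  set.seed(10)
  instr <- make_instruments(beta_exp = runif(67, 0.05, 0.2),
                            beta_out = rnorm(67, 0, 0.01))
  none <- filter_exclusion_list(instr, character(0), "empty")
  expect_equal(none$retained, instr)
  all_ids <- filter_exclusion_list(instr, instr$snp, "all")
  expect_equal(nrow(all_ids$retained), 0)
  lipid <- filter_exclusion_list(instr, instr$snp[1:17], "lipid")
  expect_equal(nrow(lipid$retained), 50)
  expect_true(all(grepl("lipid", lipid$removed$reason)))
})

test_that("instrument strength reproduces the one-instrument F formula", {
  # arithmetic oracle: pve = 2b^2f(1-f) / (2b^2f(1-f) + 2se^2 N f(1-f)),
  # F = (N-2) pve/(1-pve), computed independently here
  b <- 0.137; s <- 0.016; f <- 0.3; N <- 659316
  pve_oracle <- (2 * b^2 * f * (1 - f)) / (2 * b^2 * f * (1 - f) + 2 * s^2 * N * f * (1 - f))
  f_oracle <- (N - 2) * pve_oracle / (1 - pve_oracle)
  expect_equal(f_oracle, 73.31618, tolerance = 1e-6)

  instr <- make_instruments(beta_exp = b, beta_out = 0, se_exp = s,
                            eaf = f, n_exp = N)
  st <- instrument_strength(instr)
  expect_equal(st$per_snp$pve, pve_oracle)
  expect_equal(st$per_snp$f, f_oracle)
  expect_equal(st$per_snp$f, b^2 / s^2, tolerance = 1e-4)  # ratio approximation
  st2 <- instrument_strength(instr, f_method = "ratio")
  expect_equal(st2$per_snp$f, b^2 / s^2)
})

test_that("strength diagnostics degenerate and move correctly", {
  z <- make_instruments(beta_exp = 0, beta_out = 0, eaf = 0.3, n_exp = 1e5)
  st <- instrument_strength(z)
  expect_equal(st$per_snp$pve, 0)
  expect_equal(st$per_snp$f, 0)

  a <- instrument_strength(make_instruments(0.1, 0, se_exp = 0.01, eaf = 0.3, n_exp = 1e5))
  b <- instrument_strength(make_instruments(0.1, 0, se_exp = 0.02, eaf = 0.3, n_exp = 1e5))
  expect_lt(b$per_snp$pve, a$per_snp$pve)     # doubling se strictly decreases both
  expect_lt(b$per_snp$f, a$per_snp$f)

  miss <- make_instruments(beta_exp = c(0.1, 0.1), beta_out = c(0, 0),
                           n_exp = c(1e5, NA))
  expect_warning(stm <- instrument_strength(miss), "lack eaf or n")
  expect_true(is.na(stm$per_snp$f[2]))
  expect_equal(stm$n_used, 1)
})

test_that("the cascade is order-faithful and its counts reconcile", {
  sim <- simulate_two_sample(k_instruments = 40, n_null_snps = 200, seed = 77)
  h <- harmonize_pair(sim$exposure, sim$outcome)$instruments
  cfg <- selection_config(
    outcome_loci = data.frame(chr = h$chr[1], pos = h$pos[1]),
    exclusion_lists = list(lipid = h$snp[5:8])
  )
  sel <- mr_select_instruments(h, cfg)
  expect_equal(sel$counts$stage[1:3],
               c("A_index_selection", "B1_outcome_pleiotropy", "B2_proximity"))
  expect_equal(sel$counts$n_in[-1], sel$counts$n_out[-nrow(sel$counts)])
  expect_equal(sel$counts$n_removed, sel$counts$n_in - sel$counts$n_out)
  expect_equal(sum(sel$counts$n_removed), nrow(sel$audit))
  expect_equal(nrow(h) - nrow(sel$audit), nrow(sel$instruments))
  expect_false(any(sel$audit$snp %in% sel$instruments$snp))
})

test_that("each filter is monotone in its threshold", {
  sim <- simulate_two_sample(k_instruments = 50, n_null_snps = 100, seed = 78)
  h <- harmonize_pair(sim$exposure, sim$outcome)$instruments
  n_kept_p <- sapply(c(1e-10, 5e-8, 1e-5, 1e-2),
                     function(p) nrow(select_index_snps(h, p, 0)$selected))
  expect_true(all(diff(n_kept_p) >= 0))
  n_kept_b1 <- sapply(c(1e-8, 1e-5, 1e-2, 0.5),
                      function(p) nrow(filter_outcome_pleiotropy(h, p)$retained))
  expect_true(all(diff(n_kept_b1) <= 0))
  loci <- data.frame(chr = h$chr[1:3], pos = h$pos[1:3])
  n_kept_b2 <- sapply(c(0, 1e6, 1e7),
                      function(w) nrow(filter_proximity(h, loci, w)$retained))
  expect_true(all(diff(n_kept_b2) <= 0))
})

test_that("with all filters disabled the cascade is the identity", {
  sim <- simulate_two_sample(k_instruments = 30, n_null_snps = 50, seed = 79)
  h <- harmonize_pair(sim$exposure, sim$outcome)$instruments
  cfg <- selection_config(p_exposure = 1, prune_window_bp = 0, p_outcome = 0)
  sel <- mr_select_instruments(h, cfg)
  expect_equal(sel$instruments, h)
  expect_equal(nrow(sel$audit), 0)
})
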