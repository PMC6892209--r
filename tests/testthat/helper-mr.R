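# shared fixtures and independent oracles, all built in code

# minimal harmonized instrument table from explicit effect vectors
make_instruments <- function(beta_exp, beta_out, se_exp = NULL, se_out = NULL,
                             eaf = NULL, n_exp = NA, chr = NULL, pos = NULL,
                             p_exp = NULL, p_out = NULL) {
  k <- length(beta_exp)
  data.frame(
    snp = sprintf("rs%03d", seq_len(k)),
    chr = chr %||% rep("1", k),
    pos = pos %||% (seq_len(k) * 5e6),
    ea = rep("A", k), oa = rep("G", k),
    beta_exp = beta_exp,
    se_exp = se_exp %||% rep(0.01, k),
    p_exp = p_exp %||% rep(1e-10, k),
    eaf_exp = eaf %||% rep(0.3, k),
    n_exp = n_exp,
    beta_out = beta_out,
    se_out = se_out %||% rep(0.1, k),
    p_out = p_out %||% rep(0.5, k),
    eaf_out = eaf %||% rep(0.3, k),
    n_out = NA,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random harmonized instrument sets for property-style tests
random_instruments <- function(k, seed) {
  set.seed(seed)
  make_instruments(
    beta_exp = runif(k, 0.02, 0.2) * sample(c(-1, 1), k, replace = TRUE),
    beta_out = rnorm(k, 0, 0.05),
    se_exp = runif(k, 0.005, 0.02),
    se_out = runif(k, 0.01, 0.1)
  )
}

# weighted-least-squares oracle via explicit normal equations, with the
# multiplicative residual-scale floor used by MR-Egger
wls_oracle <- function(x, y, w, floor_scale = TRUE) {
  X <- cbind(1, x)
  W <- diag(w)
  xtwx_inv <- solve(t(X) %*% W %*% X)
  beta <- xtwx_inv %*% t(X) %*% W %*% y
  res <- y - X %*% beta
  k <- length(y)
  sigma2 <- sum(w * res^2) / (k - 2)
  scale2 <- if (floor_scale) max(1, sigma2) else sigma2
  se <- unname(sqrt(diag(xtwx_inv) * scale2))
  list(intercept = beta[1], slope = beta[2],
       se_intercept = se[1], se_slope = se[2])
}

# inverse-variance meta-analysis oracle over per-instrument estimates
iv_meta_oracle <- function(theta, se) {
  w <- 1 / se^2
  est <- sum(w * theta) / sum(w)
  list(theta = est, se = sqrt(1 / sum(w)))
}

# brute-force index-SNP pruning oracle: greedy over p-value order, checking
# every pairwise distance explicitly
prune_oracle <- function(df, window) {
  ord <- order(df$p, df$chr, df$pos)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (df$chr[i] == df$chr[j] && abs(df$pos[i] - df$pos[j]) <= window) ok <- FALSE
    }
    if (ok) kept <- c(kept, i)
  }
  sort(df$snp[kept])
}

write_tmp_sumstats <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  write_sumstats(validate_sumstats(df), path)
  path
}

base_records <- function() {
  data.frame(
    snp = c("rs1", "rs2", "rs3"),
    chr = c("1", "2", "3"), pos = c(1000L, 2000L, 3000L),
    ea = c("A", "T", "C"), oa = c("G", "C", "A"),
    eaf = c(0.2, 0.4, NA), beta = c(0.1, -0.05, 0.02),
    se = c(0.01, 0.02, 0.03), p = c(1e-10, 1e-3, 0.5),
    n = c(1000, 1000, NA), stringsAsFactors = FALSE
  )
}
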