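# internal helpers

if (getRversion() >= "2.15.1") utils::globalVariables(".data")

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# DNA complement for single-base alleles; multi-base (indel) alleles have no
# complement here and NA is returned
complement_allele <- function(x) {
  map <- c(A = "T", T = "A", C = "G", G = "C")
  out <- unname(map[x])
  out[is.na(out)] <- NA_character_
  out
}

is_palindromic <- function(ea, oa) {
  comp <- complement_allele(ea)
  !is.na(comp) & comp == oa
}
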