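# Internal helpers shared across modules.

# Deterministic per-subject seed derived from the cohort seed. Kept below
# 2^31 so it is always a valid R integer.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919 + 17) %%
               2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)
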