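# Internal helpers: seeded RNG substreams and argument checks.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number.", call. = FALSE)
  }
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic substream seed from a base seed and up to two indices.
# Arithmetic kept below 2^48 so doubles stay exact; result in [0, 2^31 - 2].
substream_seed <- function(seed, i, j = 0) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  h <- (h * 69621 + as.numeric(i)) %% m
  h <- (h * 69621 + as.numeric(j)) %% m
  h
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number.", name)
  }
  if (x < lower || x > upper) {
    stopf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x)
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) stopf("`%s` must be an integer, got %s.", name, x)
  as.integer(x)
}
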