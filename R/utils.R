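# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's RNG stream.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed from a parent seed and a few small
# integer tags. Kept strictly below 2^31 - 1; arithmetic in doubles is exact
# here (all terms < 2^53).
derive_seed <- function(seed, ...) {
  tags <- c(...)
  x <- (as.numeric(seed) %% 2147483647) * 48271
  for (t in tags) x <- (x + as.numeric(t) * 69621 + 1) %% 2147483647
  as.integer(x %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stop2 <- function(...) stop(..., call. = FALSE)
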