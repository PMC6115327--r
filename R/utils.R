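# Internal helpers shared across modules.

# Derive a child seed from a master seed and an index, keeping the result a
# valid 32-bit R integer. Used so that repetitions / replicates are
# reproducible from a single master seed yet mutually independent.
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.numeric(master)) %% m) * 48271 + 7919 * as.numeric(index)
  as.integer(s %% m) + 1L
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library functions never clobber user randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
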