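`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic derived seeds, kept inside 32-bit integer range.
seed_stream <- function(master, k) {
  as.integer((as.numeric(master) + 104729 * as.numeric(k)) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
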