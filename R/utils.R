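# Internal helpers shared across modules.

# Deterministic sub-seed derivation so replicate streams are independent of
# execution order. Arithmetic stays in double precision well below 2^53;
# result is a valid 32-bit seed.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- (master %% 2147483647) + 1
  for (i in seq_along(idx)) {
    s <- (s * 48271 + idx[i] * 10007 + i) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `expr` with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

upper_tri_values <- function(m) m[upper.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a
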