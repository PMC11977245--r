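# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic stream splitting: one user-facing seed fans out to per-item
# sub-seeds. Constants are coprime to 2^31 - 1; results stay in 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 11) %%
               2147483629)
}

clamp <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_lipdesq <- function(...) stop(..., call. = FALSE)

# Population (divide-by-N) standard deviation of a numeric vector.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
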