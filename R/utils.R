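# internal helpers shared across modules

# Deterministic per-condition seed derivation: mixes a base seed with one or
# more indices into a 31-bit integer, so protocol conditions get independent
# yet reproducible streams without consuming a global RNG sequence.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in idx) {
    # LCG-style mix; constants from Park-Miller / splitmix-like folding
    h <- (h * 48271 + as.numeric(k) * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)
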