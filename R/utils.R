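# Small shared helpers.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream label; keeps all
# randomness traceable to one top-level seed while decoupling stages.
# Result stays below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + 12345) %% 2147483629)
}

rms <- function(x) sqrt(mean(x^2))

# Shannon entropy (bits) of a probability vector.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
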