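# Run code under a fixed RNG seed, restoring the caller's RNG state.
# Every generator routes its randomness through this, so each is a pure
# function of (spec, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic 32-bit sub-seed from a master seed and a stage label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# counts of x in half-open windows [a_i, b_i), x sorted ascending
interval_counts <- function(x, a, b) {
  findInterval(b, x, left.open = TRUE) - findInterval(a, x, left.open = TRUE)
}
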