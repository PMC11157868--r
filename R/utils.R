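# Internal helpers shared across modules.

# Derive a stage-specific RNG seed from a master seed. Keeps every derived
# seed a valid 32-bit R integer so one master seed fans out deterministically
# to all stochastic stages (generator, auto-encoder init, GCN weights, walks,
# skip-gram, negative sampling, classifier).
derive_seed <- function(seed, salt) {
  stopifnot(is.character(salt), length(salt) == 1L)
  chars <- utf8ToInt(salt)
  s <- sum(chars * seq_along(chars))
  as.integer((as.double(seed) %% 2147483647 * 48271 + s * 69621) %% 2147483646) + 1L
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

check_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}
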