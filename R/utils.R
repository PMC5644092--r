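# Internal helpers.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Indices of a stratified (per-class) random subset of size frac * n_class.
stratified_pick <- function(y, frac) {
  unlist(lapply(split(seq_along(y), y), function(idx) {
    n <- max(1L, round(frac * length(idx)))
    sample(idx, n)
  }), use.names = FALSE)
}
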