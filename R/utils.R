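# Deterministically derive a sub-seed from a top-level seed and an index, so
# that run i is unaffected by how many other runs are requested. Kept below
# 2^31 - 1; arithmetic is exact in doubles.
derive_seed <- function(seed, i) {
  as.integer((abs(seed) %% 2147483647 + i * 2654435761) %% 2147483647)
}

# Run `expr` under `set.seed(seed)` without disturbing the caller's RNG
# stream; with seed = NULL the current stream is used as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
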