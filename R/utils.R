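# small shared helpers

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  force(expr)
}

# derive a reproducible child seed from a parent seed and an index,
# kept below 2^31 - 1
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629)
}

phred_from_p <- function(p) {
  ifelse(p <= 0, Inf, pmax(0, -10 * log10(p)))
}

`%||%` <- rlang::`%||%`
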