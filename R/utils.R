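# Run code with a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Round non-negative reals to integers preserving the (rounded) total:
# floor everything, then distribute the remaining units to the entries with
# the largest fractional parts.
largest_remainder_round <- function(x) {
  stopifnot(all(x >= 0))
  lo <- floor(x)
  need <- round(sum(x)) - sum(lo)
  if (need > 0) {
    idx <- order(x - lo, decreasing = TRUE)[seq_len(need)]
    lo[idx] <- lo[idx] + 1
  }
  as.integer(lo)
}
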