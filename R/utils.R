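# Small internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
withSeed <- function(seed, code) {
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

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit integer range.
childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + stream * 104729) %% 2147483647)
}

stopIfNot <- function(cond, msg, ...) {
  if (!cond) stop(sprintf(msg, ...), call. = FALSE)
}

# Resolve an axis name or index against a LabeledTensor, returning the index.
axisIndex <- function(tensor, axis) {
  nms <- axisNames(tensor)
  if (is.character(axis)) {
    idx <- match(axis, nms)
    stopIfNot(!is.na(idx), "unknown axis '%s' (axes: %s)", axis,
              paste(nms, collapse = ", "))
    return(idx)
  }
  stopIfNot(axis >= 1 && axis <= length(nms), "axis index %d out of range", axis)
  as.integer(axis)
}
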