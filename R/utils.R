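# Internal helpers shared across modules.

# Derive a child RNG seed from a master seed and a stream label. Each
# (module, purpose) pair draws from its own stream so that, e.g., toggling
# effect injection does not perturb the noise realizations. Plain integer
# hash kept below 2^31.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) h <- (h * 31 + ch) %% 2147480009
  # keep the combination in double precision until after the modulus so
  # the result always fits a 32-bit integer
  as.integer(((abs(as.numeric(seed)) %% 1000003) * 2099 + h) %% 2147480009)
}

# Evaluate expr with a local RNG state seeded from (seed, stream).
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub_seed(seed, stream))
  expr
}

# Standardized mean difference between two numeric vectors (pooled-sd
# denominator; 0 when both groups are constant and equal).
smd <- function(a, b) {
  sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
  if (!is.finite(sp) || sp == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) return(0)
    return(Inf)
  }
  (mean(a) - mean(b)) / sp
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}
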