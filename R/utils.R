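# Shared helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic operations in the package go
# through this so that a single pipeline seed gives bit-reproducible runs.
local_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# Derive a stream-specific child seed from a base seed, staying within the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

# Center-aligned bilinear resize of a numeric matrix or (H, W, C) array
# (compiled kernel; destination pixel centers sample source coordinates, so
# down-then-up round trips stay aligned).
resize_bilinear <- function(x, new_h, new_w) {
  if (is.matrix(x)) {
    matrix(cpp_resize_bilinear(x * 1, c(dim(x), 1L), as.integer(new_h),
                               as.integer(new_w)), new_h, new_w)
  } else {
    cpp_resize_bilinear(x * 1, as.integer(dim(x)), as.integer(new_h),
                        as.integer(new_w))
  }
}
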