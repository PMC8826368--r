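# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one parent seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Root-mean-square of a vector.
rms <- function(x) sqrt(mean(x^2))

# Collapse a logical vector into closed integer intervals [start, end].
mask_segments <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Dilate a logical mask by `k` samples on each side.
dilate_mask <- function(mask, k) {
  if (k <= 0 || !any(mask)) return(mask)
  n <- length(mask)
  out <- logical(n)
  seg <- mask_segments(mask)
  for (i in seq_len(nrow(seg))) {
    out[max(1L, seg[i, 1] - k):min(n, seg[i, 2] + k)] <- TRUE
  }
  out
}
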