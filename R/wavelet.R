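# Periodized orthonormal Daubechies-2 discrete wavelet transform, operating
# column-wise on matrices. Implemented in-package: the motion-correction step
# needs only this one filter bank, thresholded per decomposition level.

db2_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))  # scaling (lowpass)
  g <- c(h[4], -h[3], h[2], -h[1])                        # wavelet (highpass)
  list(h = h, g = g)
}

# One analysis step: X is (N x m), N even; returns approx and detail
# coefficient matrices of (N/2 x m), periodic boundary.
dwt_step <- function(X) {
  f <- db2_filters()
  N <- nrow(X)
  k <- seq_len(N / 2) - 1L
  idx <- function(i) ((2L * k + i) %% N) + 1L
  A <- f$h[1] * X[idx(0L), , drop = FALSE] +
    f$h[2] * X[idx(1L), , drop = FALSE] +
    f$h[3] * X[idx(2L), , drop = FALSE] +
    f$h[4] * X[idx(3L), , drop = FALSE]
  D <- f$g[1] * X[idx(0L), , drop = FALSE] +
    f$g[2] * X[idx(1L), , drop = FALSE] +
    f$g[3] * X[idx(2L), , drop = FALSE] +
    f$g[4] * X[idx(3L), , drop = FALSE]
  list(A = A, D = D)
}

# One synthesis step: inverse of dwt_step.
idwt_step <- function(A, D) {
  f <- db2_filters()
  N <- 2L * nrow(A)
  m <- ncol(A)
  Y <- matrix(0, N, m)
  k <- seq_len(N / 2) - 1L
  for (i in 0:3) {
    ii <- ((2L * k + i) %% N) + 1L
    Y[ii, ] <- Y[ii, ] + f$h[i + 1] * A + f$g[i + 1] * D
  }
  Y
}

# Full decomposition of an (N x m) matrix, N a power of two, down to an
# approximation of length >= 4. Returns list(approx, details = list by level,
# finest first).
dwt_full <- function(X) {
  details <- list()
  A <- X
  lev <- 0L
  while (nrow(A) >= 8) {
    st <- dwt_step(A)
    lev <- lev + 1L
    details[[lev]] <- st$D
    A <- st$A
  }
  list(approx = A, details = details)
}

idwt_full <- function(dec) {
  A <- dec$approx
  for (lev in rev(seq_along(dec$details))) {
    A <- idwt_step(A, dec$details[[lev]])
  }
  A
}

# Reflect-pad each column of X up to length `N`.
reflect_pad <- function(X, N) {
  n <- nrow(X)
  if (N == n) return(X)
  pad <- N - n
  idx <- c(seq_len(n), n - seq_len(pad))  # mirror without repeating the edge
  X[idx, , drop = FALSE]
}
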