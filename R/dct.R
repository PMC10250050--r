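# Type-II / type-III discrete cosine transforms via FFT (Makhoul's
# even-odd reordering), vectorised over matrix columns with mvfft().
# Used by the least-squares phase unwrapper, which needs the DCT basis
# that diagonalises the 5-point Laplacian under Neumann boundaries.

dct_cols <- function(m) {
  n <- nrow(m)
  v <- m[c(seq(1L, n, 2L), rev(seq(2L, n, 2L))), , drop = FALSE]
  V <- stats::mvfft(v)
  ph <- 2 * exp(-1i * pi * (seq_len(n) - 1) / (2 * n))
  Re(V * ph)
}

idct_cols <- function(X) {
  n <- nrow(X)
  ph <- exp(1i * pi * (seq_len(n) - 1) / (2 * n))
  Xr <- rbind(X[1L, , drop = FALSE] * 0, X[n:2L, , drop = FALSE])
  V <- 0.5 * ph * (X - 1i * Xr)
  v <- Re(stats::mvfft(V, inverse = TRUE)) / n
  out <- matrix(0, n, ncol(X))
  out[seq(1L, n, 2L), ] <- v[seq_len(ceiling(n / 2)), , drop = FALSE]
  out[seq(2L, n, 2L), ] <- v[n:(ceiling(n / 2) + 1L), , drop = FALSE]
  out
}

dct2 <- function(m) t(dct_cols(t(dct_cols(m))))
idct2 <- function(m) idct_cols(t(idct_cols(t(m))))
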