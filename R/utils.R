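# Internal numeric helpers shared across the imaging modules.

#' Wrap phase values into (-pi, pi]
#'
#' @param x numeric array of phase values (radians).
#' @return array of the same shape with every value wrapped to (-pi, pi].
#' @export
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # map the -pi boundary onto +pi so the range is the half-open (-pi, pi]
  w[w == -pi] <- pi
  w
}

# FFT frequency coordinates in cycles/sample for an n-point grid,
# in the native (unshifted) FFT ordering: 0, 1/n, ..., -1/n.
fft_freqs <- function(n) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq.int(-floor(n / 2), -1L))
  k / n
}

# Matrices of fx (varying along columns) and fy (varying along rows),
# cycles/px, FFT ordering. Row index = y, column index = x throughout.
freq_grids <- function(ny, nx) {
  fy <- fft_freqs(ny)
  fx <- fft_freqs(nx)
  list(fy = matrix(fy, ny, nx), fx = matrix(fx, ny, nx, byrow = TRUE))
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Circular shift of a matrix by (dy, dx) (positive = down/right).
circ_shift <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  dy <- ((dy %% ny) + ny) %% ny
  dx <- ((dx %% nx) + nx) %% nx
  if (dy > 0) m <- m[c((ny - dy + 1L):ny, 1L:(ny - dy)), , drop = FALSE]
  if (dx > 0) m <- m[, c((nx - dx + 1L):nx, 1L:(nx - dx)), drop = FALSE]
  m
}

# Gaussian smoothing by Fourier multiplication with periodic boundaries.
# sigma in pixels; sigma = 0 returns the input unchanged.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  g <- freq_grids(nrow(m), ncol(m))
  h <- exp(-2 * pi^2 * sigma^2 * (g$fx^2 + g$fy^2))
  out <- ifft2(fft2(m) * h)
  if (is.complex(m)) out else Re(out)
}

# 3x3 median filter (replicated borders) via a vectorised 9-input
# median network: pairwise min/max exchanges, no per-pixel loop.
median3x3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  p <- m[c(1L, 1L:ny, ny), c(1L, 1L:nx, nx)]
  v <- vector("list", 9L)
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    v[[k]] <- p[dy + seq_len(ny), dx + seq_len(nx)]
  }
  swap <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  # 25-exchange sorting network for 9 inputs; the median is slot 5.
  # Checked against a direct median() oracle in the tests.
  pairs <- list(c(1,4), c(2,8), c(3,6), c(5,9),
                c(1,8), c(3,5), c(4,9), c(6,7),
                c(1,3), c(2,4), c(5,6), c(8,9),
                c(2,5), c(4,7), c(6,8),
                c(1,2), c(3,5), c(4,6), c(7,9),
                c(3,4), c(5,6), c(7,8),
                c(2,3), c(4,5), c(6,7))
  for (pr in pairs) swap(pr[1], pr[2])
  v[[5]]
}

# round-half-up (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

# deterministic child seed derived from a parent seed and a stream tag,
# kept below 2^31
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
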