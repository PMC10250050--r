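# Brute-force oracles, independent of the package implementations.

# GLCM by explicit double loop over every in-mask pixel pair
glcm_brute <- function(values, mask, n_levels, offsets = list(c(0, 1))) {
  v <- values[mask]
  rng <- range(v)
  lev <- if (rng[1] == rng[2]) matrix(1L, nrow(values), ncol(values)) else
    matrix(pmin(n_levels, 1L + floor(
      (values - rng[1]) / (rng[2] - rng[1]) * n_levels)),
      nrow(values), ncol(values))
  P <- matrix(0, n_levels, n_levels)
  for (off in offsets) {
    for (y in seq_len(nrow(values))) for (x in seq_len(ncol(values))) {
      y2 <- y + off[1]; x2 <- x + off[2]
      if (y2 < 1 || y2 > nrow(values) || x2 < 1 || x2 > ncol(values)) next
      if (!mask[y, x] || !mask[y2, x2]) next
      P[lev[y, x], lev[y2, x2]] <- P[lev[y, x], lev[y2, x2]] + 1
    }
  }
  P <- P + t(P)
  P / sum(P)
}

# Kendall tau-b by O(n^2) concordance count with tie correction
kendall_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# one full Relief pass with k = 1, nearest hit/miss by exhaustive
# enumeration on min-max scaled features, Manhattan distance
relief_brute_k1 <- function(X, labels) {
  rng <- apply(X, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- rowSums(abs(sweep(Xs, 2, Xs[i, ])))
    d[i] <- Inf
    hits <- which(labels == labels[i]); hits <- hits[hits != i]
    miss <- which(labels != labels[i])
    h <- hits[which.min(d[hits])]
    m <- miss[which.min(d[miss])]
    w <- w + abs(Xs[m, ] - Xs[i, ]) - abs(Xs[h, ] - Xs[i, ])
  }
  w / n
}
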