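# Minimal CNN engine in vectorised base R. Activations for a batch are
# stored as a single matrix with one row per (sample, pixel) and one
# column per channel; row order is sample-major, then column-major
# within the spatial grid (row = (b-1)*H*W + (x-1)*H + y). All
# convolutions reduce to BLAS matrix products plus precomputed gather
# indices for the 3x3 neighbourhoods, so forward and backward passes
# contain no per-pixel R loops.

# cache of gather-index sets keyed by geometry
.nn_idx_cache <- new.env(parent = emptyenv())

# index sets for 3x3 windows with padding 1 and the given stride:
#  $core: rows of the padded layout holding the unpadded pixels
#  $win[[k]]: rows of the padded layout gathered for offset k
#             (k = 9 offsets, dx-major), aligned with the output layout
#  $ho, $wo: output spatial size
shift_indices <- function(H, W, B, stride) {
  key <- paste(H, W, B, stride, sep = "x")
  hit <- .nn_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  Ho <- (H - 1L) %/% stride + 1L
  Wo <- (W - 1L) %/% stride + 1L
  b_off_p <- (seq_len(B) - 1L) * Hp * Wp
  # core: padded rows of the original pixels
  yy <- rep(seq_len(H), times = W)
  xx <- rep(seq_len(W), each = H)
  core1 <- (xx + 1L - 1L) * Hp + (yy + 1L)
  core <- as.vector(outer(core1, b_off_p, `+`))
  # windows
  yo <- rep(seq_len(Ho), times = Wo)
  xo <- rep(seq_len(Wo), each = Ho)
  yi <- (yo - 1L) * stride + 1L
  xi <- (xo - 1L) * stride + 1L
  win <- vector("list", 9L)
  k <- 0L
  for (dx in -1L:1L) for (dy in -1L:1L) {
    k <- k + 1L
    w1 <- (xi + dx + 1L - 1L) * Hp + (yi + dy + 1L)
    win[[k]] <- as.vector(outer(w1, b_off_p, `+`))
  }
  out <- list(core = core, win = win, ho = Ho, wo = Wo,
              np = B * Hp * Wp)
  .nn_idx_cache[[key]] <- out
  out
}

nn_pad <- function(X, idx) {
  Xp <- matrix(0, idx$np, ncol(X))
  Xp[idx$core, ] <- X
  Xp
}

# ---- layer forward/backward -------------------------------------------------
# Each layer is a list(type, params = list of matrices, ...). forward()
# returns list(Y, cache); backward(dY, cache) returns list(dX, grads).

nn_act_fwd <- function(X, kind) {
  switch(kind,
    relu6 = pmin(pmax(X, 0), 6),
    hard_swish = X * pmin(pmax(X + 3, 0), 6) / 6,
    linear = X)
}

nn_act_bwd <- function(dY, X, kind) {
  switch(kind,
    relu6 = dY * (X > 0 & X < 6),
    hard_swish = dY * (pmin(pmax(X + 3, 0), 6) / 6 +
                         X * (X > -3 & X < 3) / 6),
    linear = dY)
}

# pointwise (1x1) convolution
add_bias <- function(Y, b) Y + rep(b, each = nrow(Y))

pw_fwd <- function(X, W, b) {
  Y <- X %*% W
  if (!is.null(b)) Y <- add_bias(Y, b)
  Y
}
pw_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# depthwise 3x3 convolution; W is 9 x C
dw_fwd <- function(X, W, b, geom, B, stride) {
  idx <- shift_indices(geom[1], geom[2], B, stride)
  Xp <- nn_pad(X, idx)
  C <- ncol(X)
  n_out <- length(idx$win[[1]])
  Y <- matrix(0, n_out, C)
  for (k in 1:9)
    Y <- Y + Xp[idx$win[[k]], , drop = FALSE] *
      rep(W[k, ], each = n_out)
  if (!is.null(b)) Y <- add_bias(Y, b)
  list(Y = Y, Xp = Xp, idx = idx)
}
dw_bwd <- function(dY, Xp, idx, W) {
  C <- ncol(dY)
  n_out <- nrow(dY)
  dXp <- matrix(0, nrow(Xp), C)
  dW <- matrix(0, 9, C)
  for (k in 1:9) {
    gk <- idx$win[[k]]
    dW[k, ] <- colSums(Xp[gk, , drop = FALSE] * dY)
    dXp[gk, ] <- dXp[gk, , drop = FALSE] + dY * rep(W[k, ], each = n_out)
  }
  list(dX = dXp[idx$core, , drop = FALSE], dW = dW, db = colSums(dY))
}

# full 3x3 convolution via patch matrix; W is (9*Cin) x Cout
full_fwd <- function(X, W, b, geom, B, stride) {
  idx <- shift_indices(geom[1], geom[2], B, stride)
  Xp <- nn_pad(X, idx)
  P <- do.call(cbind, lapply(1:9, function(k)
    Xp[idx$win[[k]], , drop = FALSE]))
  Y <- P %*% W
  if (!is.null(b)) Y <- add_bias(Y, b)
  list(Y = Y, P = P, idx = idx, cin = ncol(X))
}
full_bwd <- function(dY, P, idx, W, cin) {
  dP <- dY %*% t(W)
  dW <- crossprod(P, dY)
  dXp <- matrix(0, idx$np, cin)
  for (k in 1:9) {
    cols <- ((k - 1) * cin + 1):(k * cin)
    gk <- idx$win[[k]]
    dXp[gk, ] <- dXp[gk, , drop = FALSE] + dP[, cols, drop = FALSE]
  }
  list(dX = dXp[idx$core, , drop = FALSE], dW = dW, db = colSums(dY))
}

# 2x2 average pooling (even H, W); returns pooled matrix
avgpool2_fwd <- function(X, H, W, B) {
  grp <- avgpool2_groups(H, W, B)
  rowsum(X, grp, reorder = FALSE) / 4
}
avgpool2_bwd <- function(dY, H, W, B) {
  grp <- avgpool2_groups(H, W, B)
  dY[grp, , drop = FALSE] / 4
}

# group id per input row such that rowsum() emits output rows in the
# engine layout of the (H/2, W/2) grid
avgpool2_groups <- function(H, W, B) {
  key <- paste("pool", H, W, B, sep = "x")
  hit <- .nn_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  yy <- rep(seq_len(H), times = W)
  xx <- rep(seq_len(W), each = H)
  g1 <- ((xx - 1L) %/% 2L) * Ho + ((yy - 1L) %/% 2L) + 1L
  g <- as.vector(outer(g1, (seq_len(B) - 1L) * Ho * Wo, `+`))
  .nn_idx_cache[[key]] <- g
  g
}

# global average pooling to (B x C)
gap_fwd <- function(X, B) {
  hw <- nrow(X) / B
  rowsum(X, rep(seq_len(B), each = hw), reorder = FALSE) / hw
}
gap_bwd <- function(dY, B, hw) {
  dY[rep(seq_len(B), each = hw), , drop = FALSE] / hw
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# squeeze-and-excite gating; params W1 (C x Cr), b1, W2 (Cr x C), b2
se_fwd <- function(X, p, B) {
  hw <- nrow(X) / B
  s <- gap_fwd(X, B)
  z1 <- add_bias(s %*% p$W1, p$b1)
  a1 <- pmax(z1, 0)
  z2 <- add_bias(a1 %*% p$W2, p$b2)
  g <- sigmoid(z2)
  G <- g[rep(seq_len(B), each = hw), , drop = FALSE]
  list(Y = X * G, s = s, z1 = z1, a1 = a1, g = g, G = G, hw = hw)
}
se_bwd <- function(dY, X, p, cache, B) {
  hw <- cache$hw
  dG_full <- dY * X
  dg <- rowsum(dG_full, rep(seq_len(B), each = hw), reorder = FALSE)
  dz2 <- dg * cache$g * (1 - cache$g)
  dW2 <- crossprod(cache$a1, dz2); db2 <- colSums(dz2)
  da1 <- dz2 %*% t(p$W2)
  dz1 <- da1 * (cache$z1 > 0)
  dW1 <- crossprod(cache$s, dz1); db1 <- colSums(dz1)
  ds <- dz1 %*% t(p$W1)
  dX <- dY * cache$G + ds[rep(seq_len(B), each = hw), , drop = FALSE] / hw
  list(dX = dX, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# ---- initialisation ---------------------------------------------------------

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# softmax + cross-entropy; y is integer class index (1-based)
softmax_ce <- function(Z, y) {
  Zs <- Z - apply(Z, 1, max)
  E <- exp(Zs)
  P <- E / rowSums(E)
  n <- nrow(Z)
  loss <- -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(n), y)] <- dZ[cbind(seq_len(n), y)] - 1
  list(loss = loss, P = P, dZ = dZ / n)
}
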