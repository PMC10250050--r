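# Compact convolutional classifiers for phase crops, built from
# inverted-residual bottleneck blocks (pointwise expansion, 3x3
# depthwise, linear pointwise projection, shortcut when shapes match)
# or from plain residual basic blocks, with ReLU6 or hard-swish
# activations and an optional squeeze-and-excite gate. Trained from
# scratch with Adam and the cross-entropy loss on the pure-R engine in
# nn-engine.R.

#' CNN architecture specification
#'
#' @param block_type `"inverted_residual"` (MobileNet-style) or
#'   `"residual_basic"` (ResNet-style 3x3+3x3 blocks).
#' @param stages list of stages; each a list/vector with `channels`,
#'   `stride` (applied by the first block of the stage), `expansion`
#'   (inverted-residual only) and `repeats`.
#' @param activation `"relu6"` or `"hard_swish"`.
#' @param squeeze_excite add a squeeze-and-excite gate after the
#'   depthwise convolution of every inverted-residual block.
#' @param input_size input side in pixels (crops are downsampled to
#'   this size).
#' @param stem_channels channels of the stride-2 3x3 stem convolution.
#' @param stem_pool add a fixed 2x2 average pool after the stem
#'   (halves the resolution every learned block runs at; the phase
#'   blobs are smooth, so little discriminative detail is lost).
#' @param n_classes number of output classes.
#' @return object of class `dl_arch_spec`.
#' @export
arch_spec <- function(block_type = c("inverted_residual", "residual_basic"),
                      stages = list(
                        list(channels = 16, stride = 2, expansion = 4, repeats = 1),
                        list(channels = 32, stride = 2, expansion = 4, repeats = 1),
                        list(channels = 64, stride = 2, expansion = 4, repeats = 2)),
                      activation = c("relu6", "hard_swish"),
                      squeeze_excite = FALSE,
                      input_size = 96, stem_channels = 8,
                      stem_pool = TRUE, n_classes = 2) {
  block_type <- match.arg(block_type)
  activation <- match.arg(activation)
  stopifnot(input_size >= 16, input_size %% 8 == 0, n_classes >= 2)
  structure(list(block_type = block_type, stages = stages,
                 activation = activation,
                 squeeze_excite = isTRUE(squeeze_excite),
                 input_size = as.integer(input_size),
                 stem_channels = as.integer(stem_channels),
                 stem_pool = isTRUE(stem_pool),
                 n_classes = as.integer(n_classes)),
            class = "dl_arch_spec")
}

#' Parameter count of one inverted-residual block
#'
#' Closed form for the three convolutions (no biases, no
#' normalisation): `c_in * (c_in e) + 9 (c_in e) + (c_in e) * c_out`.
#'
#' @param c_in,c_out input/output channels.
#' @param expansion expansion factor.
#' @return integer parameter count.
#' @export
ir_block_param_count <- function(c_in, c_out, expansion) {
  ce <- c_in * expansion
  c_in * ce + 9 * ce + ce * c_out
}

#' Build a compact CNN
#'
#' Constructs the network for an [arch_spec()]: a stride-2 3x3 stem,
#' the configured stages, global average pooling and a fully connected
#' softmax head. Within a stage the first block applies the stage
#' stride; the remaining blocks use stride 1. A residual shortcut is
#' present exactly when a block has stride 1 and equal input/output
#' channel counts. Weights are He-initialised from the current RNG
#' state.
#'
#' @param arch a [dl_arch_spec()].
#' @return object of class `holocyte_cnn`: list with `arch`, `units`
#'   (layer geometry), `params` (named list of weight matrices) and
#'   `n_params`.
#' @export
build_cnn <- function(arch = arch_spec()) {
  stopifnot(inherits(arch, "dl_arch_spec"))
  units <- list()
  params <- list()
  H <- arch$input_size; C <- 1L
  add_p <- function(nm, m) params[[nm]] <<- m
  # stem
  u <- list(type = "stem", h = H, w = H, cin = C,
            cout = arch$stem_channels, stride = 2L)
  add_p("stem.W", he_init(9 * C, arch$stem_channels, 9 * C))
  add_p("stem.b", numeric(arch$stem_channels))
  units[[1]] <- u
  H <- (H - 1L) %/% 2L + 1L
  C <- arch$stem_channels
  if (isTRUE(arch$stem_pool)) {
    units[[2]] <- list(type = "pool", h = H, w = H, cin = C, cout = C)
    H <- H %/% 2L
  }
  ui <- 1L
  for (si in seq_along(arch$stages)) {
    st <- arch$stages[[si]]
    for (ri in seq_len(st$repeats)) {
      ui <- ui + 1L
      stride <- if (ri == 1) as.integer(st$stride) else 1L
      cout <- as.integer(st$channels)
      resid <- stride == 1L && C == cout
      nm <- sprintf("u%d", ui)
      if (arch$block_type == "inverted_residual") {
        ce <- C * (st$expansion %||% 4)
        u <- list(type = "ir", name = nm, h = H, w = H, cin = C,
                  cexp = ce, cout = cout, stride = stride,
                  residual = resid, se = arch$squeeze_excite)
        add_p(paste0(nm, ".Wexp"), he_init(C, ce, C))
        add_p(paste0(nm, ".bexp"), numeric(ce))
        add_p(paste0(nm, ".Wdw"), he_init(9, ce, 9))
        add_p(paste0(nm, ".bdw"), numeric(ce))
        if (arch$squeeze_excite) {
          cr <- max(4L, ce %/% 4L)
          add_p(paste0(nm, ".Wse1"), he_init(ce, cr, ce))
          add_p(paste0(nm, ".bse1"), numeric(cr))
          add_p(paste0(nm, ".Wse2"), he_init(cr, ce, cr))
          add_p(paste0(nm, ".bse2"), numeric(ce))
          u$cr <- cr
        }
        add_p(paste0(nm, ".Wproj"), he_init(ce, cout, ce))
        add_p(paste0(nm, ".bproj"), numeric(cout))
      } else {
        u <- list(type = "res", name = nm, h = H, w = H, cin = C,
                  cout = cout, stride = stride, residual = resid)
        add_p(paste0(nm, ".W1"), he_init(9 * C, cout, 9 * C))
        add_p(paste0(nm, ".b1"), numeric(cout))
        add_p(paste0(nm, ".W2"), he_init(9 * cout, cout, 9 * cout))
        add_p(paste0(nm, ".b2"), numeric(cout))
      }
      units[[length(units) + 1L]] <- u
      H <- (H - 1L) %/% stride + 1L
      C <- cout
    }
  }
  add_p("fc.W", he_init(C, arch$n_classes, C))
  add_p("fc.b", numeric(arch$n_classes))
  units[[length(units) + 1L]] <- list(type = "head", h = H, w = H,
                                      cin = C, cout = arch$n_classes)
  model <- structure(list(arch = arch, units = units, params = params),
                     class = "holocyte_cnn")
  model$n_params <- count_params(model)
  model
}

#' Parameter count of a built network
#'
#' @param model a `holocyte_cnn`.
#' @param include_bias count bias vectors too (default `FALSE`:
#'   kernels and fully connected weights only).
#' @return integer number of parameters.
#' @export
count_params <- function(model, include_bias = FALSE) {
  sum(vapply(names(model$params), function(nm) {
    p <- model$params[[nm]]
    if (!include_bias && grepl("\\.b", nm)) 0L else length(p)
  }, 0L))
}

#' @export
print.holocyte_cnn <- function(x, ...) {
  cat(sprintf("compact CNN (%s, %s%s): %d units, %d weight params (%d with biases)\n",
              x$arch$block_type, x$arch$activation,
              if (x$arch$squeeze_excite) " + SE" else "",
              length(x$units), count_params(x),
              count_params(x, include_bias = TRUE)))
  invisible(x)
}

# forward pass; X is (B*H*W) x 1 input matrix. Returns logits and,
# when train = TRUE, per-unit caches for the backward pass.
cnn_forward <- function(model, X, B, train = FALSE) {
  act <- model$arch$activation
  p <- model$params
  caches <- if (train) vector("list", length(model$units)) else NULL
  for (i in seq_along(model$units)) {
    u <- model$units[[i]]
    if (u$type == "stem") {
      fw <- full_fwd(X, p$stem.W, p$stem.b, c(u$h, u$w), B, u$stride)
      Z <- fw$Y
      Y <- nn_act_fwd(Z, act)
      if (train) caches[[i]] <- list(fw = fw, Z = Z, Xin = X)
      X <- Y
    } else if (u$type == "pool") {
      X <- avgpool2_fwd(X, u$h, u$w, B)
    } else if (u$type == "ir") {
      nm <- u$name
      Z1 <- pw_fwd(X, p[[paste0(nm, ".Wexp")]], p[[paste0(nm, ".bexp")]])
      A1 <- nn_act_fwd(Z1, act)
      dwc <- dw_fwd(A1, p[[paste0(nm, ".Wdw")]], p[[paste0(nm, ".bdw")]],
                    c(u$h, u$w), B, u$stride)
      A2 <- nn_act_fwd(dwc$Y, act)
      se_cache <- NULL
      if (u$se) {
        sp <- list(W1 = p[[paste0(nm, ".Wse1")]], b1 = p[[paste0(nm, ".bse1")]],
                   W2 = p[[paste0(nm, ".Wse2")]], b2 = p[[paste0(nm, ".bse2")]])
        se_cache <- se_fwd(A2, sp, B)
        A2se <- se_cache$Y
      } else A2se <- A2
      Y <- pw_fwd(A2se, p[[paste0(nm, ".Wproj")]], p[[paste0(nm, ".bproj")]])
      if (u$residual) Y <- Y + X
      if (train) caches[[i]] <- list(Xin = X, Z1 = Z1, A1 = A1, dwc = dwc,
                                     A2 = A2, se = se_cache, A2se = A2se)
      X <- Y
    } else if (u$type == "res") {
      nm <- u$name
      f1 <- full_fwd(X, p[[paste0(nm, ".W1")]], p[[paste0(nm, ".b1")]],
                     c(u$h, u$w), B, u$stride)
      A1 <- nn_act_fwd(f1$Y, act)
      ho <- f1$idx$ho; wo <- f1$idx$wo
      f2 <- full_fwd(A1, p[[paste0(nm, ".W2")]], p[[paste0(nm, ".b2")]],
                     c(ho, wo), B, 1L)
      Z2 <- f2$Y
      if (u$residual) Z2 <- Z2 + X
      Y <- nn_act_fwd(Z2, act)
      if (train) caches[[i]] <- list(Xin = X, f1 = f1, A1 = A1, f2 = f2,
                                     Z2 = Z2)
      X <- Y
    } else { # head
      G <- gap_fwd(X, B)
      logits <- pw_fwd(G, p$fc.W, p$fc.b)
      if (train) caches[[i]] <- list(Xin = X, G = G,
                                     hw = nrow(X) / B)
      X <- logits
    }
  }
  list(out = X, caches = caches)
}

# backward pass; returns named gradient list aligned with params
cnn_backward <- function(model, caches, dOut, B) {
  act <- model$arch$activation
  p <- model$params
  grads <- list()
  dX <- dOut
  for (i in rev(seq_along(model$units))) {
    u <- model$units[[i]]
    cc <- caches[[i]]
    if (u$type == "head") {
      grads$fc.W <- crossprod(cc$G, dX)
      grads$fc.b <- colSums(dX)
      dG <- dX %*% t(p$fc.W)
      dX <- gap_bwd(dG, B, cc$hw)
    } else if (u$type == "pool") {
      dX <- avgpool2_bwd(dX, u$h, u$w, B)
    } else if (u$type == "ir") {
      nm <- u$name
      dY <- dX
      bw <- pw_bwd(dY, cc$A2se, p[[paste0(nm, ".Wproj")]])
      grads[[paste0(nm, ".Wproj")]] <- bw$dW
      grads[[paste0(nm, ".bproj")]] <- bw$db
      dA2se <- bw$dX
      if (u$se) {
        sp <- list(W1 = p[[paste0(nm, ".Wse1")]], b1 = p[[paste0(nm, ".bse1")]],
                   W2 = p[[paste0(nm, ".Wse2")]], b2 = p[[paste0(nm, ".bse2")]])
        sb <- se_bwd(dA2se, cc$A2, sp, cc$se, B)
        grads[[paste0(nm, ".Wse1")]] <- sb$dW1
        grads[[paste0(nm, ".bse1")]] <- sb$db1
        grads[[paste0(nm, ".Wse2")]] <- sb$dW2
        grads[[paste0(nm, ".bse2")]] <- sb$db2
        dA2 <- sb$dX
      } else dA2 <- dA2se
      dZdw <- nn_act_bwd(dA2, cc$dwc$Y, act)
      db <- dw_bwd(dZdw, cc$dwc$Xp, cc$dwc$idx, p[[paste0(nm, ".Wdw")]])
      grads[[paste0(nm, ".Wdw")]] <- db$dW
      grads[[paste0(nm, ".bdw")]] <- db$db
      dA1 <- db$dX
      dZ1 <- nn_act_bwd(dA1, cc$Z1, act)
      bw1 <- pw_bwd(dZ1, cc$Xin, p[[paste0(nm, ".Wexp")]])
      grads[[paste0(nm, ".Wexp")]] <- bw1$dW
      grads[[paste0(nm, ".bexp")]] <- bw1$db
      dX <- bw1$dX
      if (u$residual) dX <- dX + dY
    } else if (u$type == "res") {
      nm <- u$name
      dZ2 <- nn_act_bwd(dX, cc$Z2, act)
      b2 <- full_bwd(dZ2, cc$f2$P, cc$f2$idx, p[[paste0(nm, ".W2")]],
                     ncol(cc$A1))
      grads[[paste0(nm, ".W2")]] <- b2$dW
      grads[[paste0(nm, ".b2")]] <- b2$db
      dA1 <- b2$dX
      dZ1 <- nn_act_bwd(dA1, cc$f1$Y, act)
      b1 <- full_bwd(dZ1, cc$f1$P, cc$f1$idx, p[[paste0(nm, ".W1")]],
                     u$cin)
      grads[[paste0(nm, ".W1")]] <- b1$dW
      grads[[paste0(nm, ".b1")]] <- b1$db
      dX <- b1$dX
      if (u$residual) dX <- dX + dZ2
    } else { # stem
      dZ <- nn_act_bwd(dX, cc$Z, act)
      bs <- full_bwd(dZ, cc$fw$P, cc$fw$idx, p$stem.W, u$cin)
      grads$stem.W <- bs$dW
      grads$stem.b <- bs$db
      dX <- bs$dX
    }
  }
  grads
}

# downsample a square crop to the network input size by block
# averaging (integer factors) or EBImage resize otherwise; phase stays
# in radians (order-one values, a fixed physical scale rather than a
# per-image standardisation)
prep_crop <- function(m, input_size) {
  n <- nrow(m)
  if (n != input_size) {
    if (n %% input_size == 0) {
      f <- n %/% input_size
      m <- rowsum(t(rowsum(m, rep(seq_len(input_size), each = f))),
                  rep(seq_len(input_size), each = f)) / f^2
      m <- t(m)
    } else {
      m <- EBImage::imageData(EBImage::resize(EBImage::Image(m),
                                              w = input_size,
                                              h = input_size))
    }
  }
  m
}

# stack crops into the engine's batch layout
crops_to_batch <- function(crops, input_size) {
  mats <- lapply(crops, function(cr) {
    m <- if (is.matrix(cr)) cr else cr$qpm
    prep_crop(m, input_size)
  })
  matrix(unlist(mats, use.names = FALSE), ncol = 1)
}

#' Class probabilities for a set of crops
#'
#' @param object a `holocyte_cnn`.
#' @param crops list of `cell_crop`s or square phase matrices.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return N x n_classes matrix of softmax probabilities.
#' @export
predict.holocyte_cnn <- function(object, crops, batch_size = 32, ...) {
  n <- length(crops)
  isz <- object$arch$input_size
  out <- matrix(0, n, object$arch$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch_size - 1L)
    X <- crops_to_batch(crops[i:j], isz)
    Z <- cnn_forward(object, X, j - i + 1L)$out
    E <- exp(Z - apply(Z, 1, max))
    out[i:j, ] <- E / rowSums(E)
    i <- j + 1L
  }
  out
}

#' Training protocol for the CNN
#'
#' @param folds cross-validation folds (default 5).
#' @param epochs training epochs per fold (default 10).
#' @param batch_size minibatch size (default 16).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param seed master seed.
#' @return object of class `train_config_dl`.
#' @export
train_config_dl <- function(folds = 5, epochs = 10, batch_size = 16,
                            learning_rate = 1e-4, seed = 1L) {
  stopifnot(folds >= 2, epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(folds = as.integer(folds), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config_dl")
}

# core optimisation loop on a fixed training set (labels as factor)
fit_cnn <- function(crops, y, arch, epochs, batch_size, learning_rate,
                    seed, steps = NULL) {
  y <- factor(y)
  yi <- as.integer(y)
  set.seed(seed)
  model <- build_cnn(arch)
  state <- adam_state(model$params)
  n <- length(crops)
  isz <- arch$input_size
  X_all <- lapply(crops, function(cr)
    prep_crop(if (is.matrix(cr)) cr else cr$qpm, isz))
  losses <- numeric(0)
  t <- 0L
  done <- FALSE
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    i <- 1L
    while (i <= n) {
      j <- min(n, i + batch_size - 1L)
      sel <- ord[i:j]
      B <- length(sel)
      X <- matrix(unlist(X_all[sel], use.names = FALSE), ncol = 1)
      fw <- cnn_forward(model, X, B, train = TRUE)
      sc <- softmax_ce(fw$out, yi[sel])
      grads <- cnn_backward(model, fw$caches, sc$dZ, B)
      t <- t + 1L
      up <- adam_update(model$params, grads, state, learning_rate, t)
      model$params <- up$params
      state <- up$state
      losses <- c(losses, sc$loss)
      if (!is.null(steps) && t >= steps) { done <- TRUE; break }
      i <- j + 1L
    }
    if (done) break
  }
  model$levels <- levels(y)
  model$loss_curve <- losses
  model
}

#' Train the CNN with stratified k-fold cross-validation
#'
#' Applies the full protocol: for each of `config$folds` folds a fresh
#' network is trained for `config$epochs` epochs (batch
#' `config$batch_size`, Adam, learning rate `config$learning_rate`,
#' cross-entropy loss) on the remaining folds and evaluated on the
#' held-out fold.
#'
#' @param crops list of `cell_crop`s or phase matrices.
#' @param labels class labels (both classes present).
#' @param arch a [dl_arch_spec()].
#' @param config a [train_config_dl()].
#' @return object of class `dl_cv_result`: list with `fold_models`,
#'   `fold_val_accuracy` (percent, length `folds`),
#'   `mean_val_accuracy`, `loss_curves` and the configs.
#' @export
train_dl <- function(crops, labels, arch = arch_spec(),
                     config = train_config_dl()) {
  y <- factor(as.character(labels))
  if (nlevels(y) < 2) stop("both classes must be present")
  if (length(crops) < config$folds) stop("fewer samples than folds")
  folds <- stratified_folds(y, config$folds,
                            seed = child_seed(config$seed, "dl-folds"))
  fold_models <- list()
  acc <- numeric(config$folds)
  curves <- list()
  for (f in seq_len(config$folds)) {
    tr <- which(folds != f); va <- which(folds == f)
    m <- fit_cnn(crops[tr], y[tr], arch, config$epochs,
                 config$batch_size, config$learning_rate,
                 seed = child_seed(config$seed, paste0("dl-fold", f)))
    P <- predict(m, crops[va])
    pred <- factor(m$levels[max.col(P)], levels = levels(y))
    acc[f] <- 100 * mean(pred == y[va])
    fold_models[[f]] <- m
    curves[[f]] <- m$loss_curve
  }
  structure(list(fold_models = fold_models, fold_val_accuracy = acc,
                 mean_val_accuracy = mean(acc), loss_curves = curves,
                 arch = arch, config = config, folds = folds),
            class = "dl_cv_result")
}

#' @export
print.dl_cv_result <- function(x, ...) {
  cat(sprintf("CNN %d-fold CV: val accuracy %s (mean %.1f%%)\n",
              x$config$folds,
              paste(sprintf("%.1f", x$fold_val_accuracy), collapse = "/"),
              x$mean_val_accuracy))
  invisible(x)
}

#' Evaluate a trained CNN on test crops
#'
#' @param model a `holocyte_cnn` with class levels (from [train_dl()]
#'   fold models or `fit_cnn`).
#' @param crops list of crops.
#' @param labels true class labels.
#' @return a `confusion_matrix`.
#' @export
evaluate_dl <- function(model, crops, labels) {
  stopifnot(inherits(model, "holocyte_cnn"))
  P <- predict(model, crops)
  lev <- model$levels %||% sort(unique(as.character(labels)))
  pred <- factor(lev[max.col(P)], levels = lev)
  truth <- factor(as.character(labels), levels = lev)
  confusion_matrix(truth, pred)
}
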