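# small deterministic crop set: two blob populations differing in
# peak phase, rendered directly as phase maps
toy_crops <- function(n_per_class = 8, size = 96, seed = 77) {
  set.seed(seed)
  crops <- list(); labels <- character()
  for (cl in c("OC", "MONO")) {
    peak <- if (cl == "OC") 2.3 else 1.3
    for (i in seq_len(n_per_class)) {
      sp <- phantom_spec(cl, radius_px = size / 3.5, peak_phase_rad = peak,
                         texture_amplitude_rad = 0.2)
      crops[[length(crops) + 1]] <-
        make_cell_phantom(sp, size, seed = sample.int(1e6, 1))
      labels <- c(labels, cl)
    }
  }
  list(crops = crops, labels = labels)
}

test_that("network outputs are softmax probabilities", {
  set.seed(1)
  model <- build_cnn(arch_spec(input_size = 24, stem_channels = 4,
                               stages = list(list(channels = 8, stride = 2,
                                                  expansion = 2,
                                                  repeats = 1))))
  X <- lapply(1:3, function(i) matrix(rnorm(24 * 24), 24, 24))
  P <- predict(model, X)
  expect_equal(dim(P), c(3, 2))
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-6)
  expect_true(all(P >= 0))
})

test_that("residual shortcuts exist exactly when shapes match", {
  arch <- arch_spec(input_size = 32, stem_channels = 4, stages = list(
    list(channels = 8, stride = 2, expansion = 2, repeats = 2),
    list(channels = 12, stride = 1, expansion = 2, repeats = 1)))
  model <- build_cnn(arch)
  ir <- Filter(function(u) u$type == "ir", model$units)
  expect_equal(vapply(ir, `[[`, TRUE, "residual"),
               c(FALSE,  # stride 2
                 TRUE,   # stride 1, 8 -> 8
                 FALSE)) # stride 1 but 8 -> 12
})

test_that("inverted-residual parameter count matches the closed form", {
  expect_equal(ir_block_param_count(16, 16, 6), 3936)
  # a built single-block model agrees: total minus stem and head
  arch <- arch_spec(input_size = 24, stem_channels = 16, stages = list(
    list(channels = 16, stride = 1, expansion = 6, repeats = 1)))
  model <- build_cnn(arch)
  stem_head <- 9 * 1 * 16 + 16 * 2
  expect_equal(count_params(model) - stem_head, 3936)
})

test_that("analytic gradients match finite differences", {
  set.seed(3)
  arch <- arch_spec(stages = list(list(channels = 6, stride = 2,
                                       expansion = 2, repeats = 2)),
                    input_size = 24, stem_channels = 4,
                    squeeze_excite = TRUE)
  model <- build_cnn(arch)
  # move the zero-initialised biases off the ReLU6 kinks first
  for (nm in names(model$params))
    if (grepl("\\.b", nm))
      model$params[[nm]] <- rnorm(length(model$params[[nm]]), sd = 0.05)
  B <- 2
  X <- matrix(rnorm(B * 24 * 24) * 0.5, ncol = 1)
  y <- c(1L, 2L)
  lossfun <- function(params) {
    m <- model; m$params <- params
    holocyte:::softmax_ce(holocyte:::cnn_forward(m, X, B)$out, y)$loss
  }
  fw <- holocyte:::cnn_forward(model, X, B, train = TRUE)
  sc <- holocyte:::softmax_ce(fw$out, y)
  gr <- holocyte:::cnn_backward(model, fw$caches, sc$dZ, B)
  eps <- 1e-6
  set.seed(4)
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (r in 1:2) {
      i <- sample(length(p), 1)
      pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]), 1e-6)
    }
  }
})

test_that("16 crops are memorised within 200 full-batch steps", {
  toy <- toy_crops(8)
  m <- holocyte:::fit_cnn(toy$crops, toy$labels, arch_spec(),
                          epochs = 1000, batch_size = 16,
                          learning_rate = 1e-3, seed = 5, steps = 200)
  P <- predict(m, toy$crops)
  pred <- m$levels[max.col(P)]
  expect_equal(mean(pred == toy$labels), 1)
})

test_that("five-fold training runs the exact protocol and is seeded", {
  toy <- toy_crops(10, size = 48, seed = 91)
  arch <- arch_spec(input_size = 48, stem_channels = 4, stages = list(
    list(channels = 8, stride = 2, expansion = 2, repeats = 1)))
  cfg <- train_config_dl(folds = 5, epochs = 2, batch_size = 4, seed = 9)
  res <- train_dl(toy$crops, toy$labels, arch, cfg)
  expect_length(res$fold_val_accuracy, 5)
  expect_length(res$fold_models, 5)
  # each fold runs exactly epochs * ceil(n_train / batch) steps
  n_train <- sum(res$folds != 1)
  expect_length(res$loss_curves[[1]], 2 * ceiling(n_train / 4))
  res2 <- train_dl(toy$crops, toy$labels, arch, cfg)
  expect_identical(res$loss_curves, res2$loss_curves)
  expect_error(train_dl(toy$crops[1:3], toy$labels[1:3], arch, cfg),
               "fewer samples|classes")
})

test_that("loss decreases over the first epochs on separable data", {
  toy <- toy_crops(12, size = 48, seed = 15)
  arch <- arch_spec(input_size = 48, stem_channels = 4, stages = list(
    list(channels = 8, stride = 2, expansion = 2, repeats = 1)))
  m <- holocyte:::fit_cnn(toy$crops, toy$labels, arch, epochs = 4,
                          batch_size = 8, learning_rate = 1e-3, seed = 2)
  per_epoch <- colMeans(matrix(m$loss_curve, ncol = 4))
  expect_lt(per_epoch[4], per_epoch[1])
})

test_that("evaluation returns a confusion matrix with perfect-oracle bounds", {
  toy <- toy_crops(6, size = 48, seed = 33)
  arch <- arch_spec(input_size = 48, stem_channels = 4, stages = list(
    list(channels = 8, stride = 2, expansion = 2, repeats = 1)))
  m <- holocyte:::fit_cnn(toy$crops, toy$labels, arch, epochs = 30,
                          batch_size = 12, learning_rate = 2e-3, seed = 6)
  cm <- evaluate_dl(m, toy$crops, toy$labels)
  expect_true(cm$accuracy >= 50 && cm$accuracy <= 100)
  expect_equal(sum(cm$counts), 12)
})

test_that("hard-swish and squeeze-excite variants build and train", {
  toy <- toy_crops(4, size = 24, seed = 44)
  arch <- arch_spec(activation = "hard_swish", squeeze_excite = TRUE,
                    input_size = 24, stem_channels = 4, stages = list(
                      list(channels = 8, stride = 2, expansion = 2,
                           repeats = 1)))
  m <- holocyte:::fit_cnn(toy$crops, toy$labels, arch, epochs = 2,
                          batch_size = 4, learning_rate = 1e-3, seed = 3)
  expect_length(m$loss_curve, 4)
  # ResNet-style variant
  archr <- arch_spec("residual_basic", input_size = 24, stem_channels = 4,
                     stages = list(list(channels = 8, stride = 2,
                                        repeats = 2)))
  mr <- holocyte:::fit_cnn(toy$crops, toy$labels, archr, epochs = 1,
                           batch_size = 4, learning_rate = 1e-3, seed = 3)
  expect_true(all(is.finite(mr$loss_curve)))
})
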