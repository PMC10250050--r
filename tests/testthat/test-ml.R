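make_toy_table <- function(n_a, n_b, sep = 3, seed = 1, frames = 1) {
  set.seed(seed)
  n <- n_a + n_b
  lab <- rep(c("OC", "MONO"), c(n_a, n_b))
  rows <- data.frame(
    cell_id = seq_len(n), frame_id = seq_len(n), class_label = lab,
    stringsAsFactors = FALSE)
  X <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, feature_names()))
  X[, "phase_mean"] <- X[, "phase_mean"] + sep * (lab == "OC")
  X[, "phase_max"] <- X[, "phase_max"] + sep * (lab == "OC")
  df <- cbind(rows, X)
  class(df) <- c("feature_table", "data.frame")
  df
}

test_that("holdout split size follows round-half-up of the fraction", {
  tb <- make_toy_table(2550, 401)
  sp <- holdout_split(tb, test_fraction = 0.027, group_by_cell = FALSE,
                      seed = 2)
  expect_length(sp$test, 80)  # round-half-up of 79.677
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(2951))
  # both classes on both sides
  expect_length(unique(tb$class_label[sp$test]), 2)
})

test_that("grouped splitting keeps all frames of a cell together", {
  set.seed(3)
  n_cell <- 60
  frames <- sample(1:4, n_cell, replace = TRUE)
  cell <- rep(seq_len(n_cell), frames)
  lab <- rep(rep(c("OC", "MONO"), c(48, 12)), frames)
  df <- data.frame(cell_id = cell, frame_id = seq_along(cell),
                   class_label = lab)
  X <- matrix(rnorm(length(cell) * 12), ncol = 12,
              dimnames = list(NULL, feature_names()))
  tb <- cbind(df, X); class(tb) <- c("feature_table", "data.frame")
  sp <- holdout_split(tb, test_fraction = 0.1, group_by_cell = TRUE,
                      seed = 5)
  expect_length(intersect(tb$cell_id[sp$train], tb$cell_id[sp$test]), 0)
})

test_that("cross-validation is stratified with balanced folds", {
  tb <- make_toy_table(80, 40, sep = 4, seed = 7)
  y <- factor(tb$class_label)
  folds <- holocyte:::stratified_folds(y, 10, seed = 1)
  sizes <- table(folds)
  expect_lte(max(sizes) - min(sizes), 1)
  per_class <- table(folds, y)
  expect_lte(max(per_class[, 1]) - min(per_class[, 1]), 1)
  expect_error(train_cv(make_toy_table(30, 5), "cubic_svm", k = 10),
               "smallest class")
})

test_that("a separable problem gives the cubic SVM 100% validation accuracy", {
  tb <- make_toy_table(60, 40, sep = 8, seed = 11)
  cv <- train_cv(tb, "cubic_svm", k = 10, seed = 1)
  expect_equal(cv$validation_accuracy, 100)
})

test_that("permuted labels collapse accuracy to the majority fraction", {
  accs <- sapply(1:20, function(s) {
    tb <- make_toy_table(70, 30, sep = 5, seed = 100 + s)
    set.seed(1000 + s)
    tb$class_label <- sample(tb$class_label)
    train_cv(tb, "linear_svm", k = 5, seed = s)$validation_accuracy
  })
  expect_lt(abs(mean(accs) - 70), 5)
})

test_that("confusion matrices have the stated arithmetic", {
  truth <- factor(rep(c("OC", "MONO"), c(30, 10)),
                  levels = c("MONO", "OC"))
  cm0 <- confusion_matrix(truth, truth)
  expect_equal(cm0$accuracy, 100)
  expect_equal(sum(cm0$counts) - sum(diag(cm0$counts)), 0)
  pred <- truth; pred[1] <- "OC"  # one MONO misclassified
  cm <- confusion_matrix(truth, pred)
  expect_equal(cm$accuracy, 100 * sum(diag(cm$counts)) / sum(cm$counts))
  expect_equal(unname(rowSums(cm$row_percent)), c(100, 100),
               tolerance = 1e-9)
})

test_that("evaluation rejects mismatched feature names", {
  tb <- make_toy_table(40, 20, sep = 6, seed = 13)
  cv <- train_cv(tb, "linear_svm", k = 5)
  X <- feature_matrix(tb)[, 1:6]
  expect_error(predict(cv$model, X), "mismatch")
})

test_that("the ablation grid has the full 4 x 8 x 2 structure", {
  tb <- make_toy_table(120, 40, sep = 4, seed = 17)
  sp <- holdout_split(tb, test_fraction = 0.15, group_by_cell = FALSE,
                      seed = 3)
  grid <- ablation_study(tb, sp, k = 5, seed = 1)
  expect_equal(dim(grid$validation), c(4, 8))
  expect_equal(dim(grid$test), c(4, 8))
  expect_identical(rownames(grid$validation),
                   c("all", "no_morphological", "no_texture", "no_QPI"))
  expect_true(all(is.finite(grid$validation)))
  expect_setequal(grid$configurations$all, grid$kept_features)
  # the class signal was put in the phase statistics: dropping the QPI
  # group must hurt on average
  expect_lt(mean(grid$validation["no_QPI", ]),
            mean(grid$validation["all", ]))
})
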