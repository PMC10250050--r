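# Classical classification of the 12-feature descriptor: stratified
# holdout split, eight reference models (three decision trees, linear
# and quadratic discriminants, polynomial SVMs of degree 1-3),
# stratified 10-fold cross-validation, confusion matrices, and the
# feature-group ablation grid.

#' The eight reference model names
#' @return character vector of model identifiers.
#' @export
ml_model_names <- function() {
  c("fine_tree", "medium_tree", "coarse_tree",
    "linear_discriminant", "quadratic_discriminant",
    "linear_svm", "quadratic_svm", "cubic_svm")
}

#' Model specification
#'
#' Hyperparameters mirror common preset semantics: decision trees with
#' a maximum of 100 / 20 / 4 splits (fine / medium / coarse), linear
#' and quadratic discriminant analysis, and polynomial-kernel SVMs of
#' degree 1 / 2 / 3 with standardised features, box constraint 1 and
#' `coef0 = 1`.
#'
#' @param name one of [ml_model_names()].
#' @param ... overrides stored alongside the defaults (`max_splits`,
#'   `degree`, `cost`).
#' @return object of class `ml_model_spec`.
#' @export
ml_model_spec <- function(name = ml_model_names(), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    fine_tree = list(max_splits = 100),
    medium_tree = list(max_splits = 20),
    coarse_tree = list(max_splits = 4),
    linear_discriminant = list(),
    quadratic_discriminant = list(),
    linear_svm = list(degree = 1, cost = 1),
    quadratic_svm = list(degree = 2, cost = 1),
    cubic_svm = list(degree = 3, cost = 1)
  )
  structure(utils::modifyList(c(list(name = name), defaults), list(...)),
            class = "ml_model_spec")
}

#' Stratified holdout split
#'
#' Splits a feature table into training and test sets. The test size
#' is `round(N * test_fraction)` (round-half-up). Stratification keeps
#' the class proportions and guarantees at least one test row per
#' class; with `group_by_cell` all frames of one cell fall on the same
#' side (the split is then computed over cells).
#'
#' @param table `feature_table` (needs `class_label`, and `cell_id`
#'   when grouping).
#' @param test_fraction fraction of rows held out (default 0.027).
#' @param stratified stratify by class (default `TRUE`).
#' @param group_by_cell keep all frames of a cell on one side (default
#'   `TRUE`).
#' @param seed integer seed.
#' @return object of class `split_spec`: list with integer `train` and
#'   `test` row indices and the call parameters.
#' @export
holdout_split <- function(table, test_fraction = 0.027, stratified = TRUE,
                          group_by_cell = TRUE, seed = 1L) {
  df <- as.data.frame(table)
  n <- nrow(df)
  stopifnot(n >= 2 / test_fraction)
  set.seed(seed)
  units <- if (group_by_cell) unique(df$cell_id) else seq_len(n)
  unit_label <- if (group_by_cell)
    df$class_label[match(units, df$cell_id)] else df$class_label
  n_test_units <- max(2L, round_half_up(length(units) * test_fraction))
  test_units <- integer()
  if (stratified) {
    cls <- unique(unit_label)
    quota <- length(units[unit_label %in% cls]) # == length(units)
    exact <- vapply(cls, function(cl)
      sum(unit_label == cl) / quota * n_test_units, 0)
    k <- pmax(1L, floor(exact))
    # largest-remainder allocation so the sizes sum to the target
    rem <- n_test_units - sum(k)
    if (rem > 0) {
      ord <- order(exact - floor(exact), decreasing = TRUE)
      k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
    }
    for (ci in seq_along(cls)) {
      u <- units[unit_label == cls[ci]]
      test_units <- c(test_units, sample(u, min(k[ci], length(u) - 1L)))
    }
  } else {
    test_units <- sample(units, n_test_units)
  }
  test <- if (group_by_cell) which(df$cell_id %in% test_units) else
    test_units
  train <- setdiff(seq_len(n), test)
  if (stratified &&
      (length(unique(df$class_label[train])) < 2 ||
       length(unique(df$class_label[test])) < 2))
    stop("a class is absent from one side of the stratified split")
  structure(list(train = train, test = sort(test),
                 test_fraction = test_fraction, stratified = stratified,
                 group_by_cell = group_by_cell, seed = seed),
            class = "split_spec")
}

# fit one model spec on features X (matrix) and factor labels y
fit_ml_model <- function(spec, X, y) {
  y <- factor(y)
  df <- data.frame(X, y = y, check.names = FALSE)
  fit <- switch(spec$name,
    fine_tree = , medium_tree = , coarse_tree = {
      depth <- max(1L, min(30L, ceiling(log2(spec$max_splits + 1))))
      rpart::rpart(y ~ ., df, method = "class",
                   control = rpart::rpart.control(
                     cp = 0, minsplit = 2, minbucket = 1,
                     maxdepth = depth, xval = 0,
                     maxcompete = 0, maxsurrogate = 0))
    },
    linear_discriminant = MASS::lda(y ~ ., df),
    quadratic_discriminant = MASS::qda(y ~ ., df),
    linear_svm = , quadratic_svm = , cubic_svm =
      e1071::svm(y ~ ., df, kernel = "polynomial", degree = spec$degree,
                 coef0 = 1, cost = spec$cost, scale = TRUE)
  )
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 features = colnames(X)),
            class = "holocyte_ml_fit")
}

#' @export
predict.holocyte_ml_fit <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else
    feature_matrix(newdata, object$features)
  if (!identical(colnames(X), object$features))
    stop("feature-name mismatch between model and data")
  df <- data.frame(X, check.names = FALSE)
  p <- switch(object$spec$name,
    fine_tree = , medium_tree = , coarse_tree = {
      cls <- predict(object$fit, df, type = "class")
      as.character(cls)
    },
    linear_discriminant = , quadratic_discriminant =
      as.character(predict(object$fit, df)$class),
    linear_svm = , quadratic_svm = , cubic_svm =
      as.character(predict(object$fit, df))
  )
  factor(p, levels = object$levels)
}

#' Train a model with stratified k-fold cross-validation
#'
#' Reports the cross-validated (validation) accuracy as the mean over
#' folds of the held-out-fold accuracy, then refits the model on all
#' training rows.
#'
#' @param table `feature_table` restricted to the training rows.
#' @param spec an [ml_model_spec()] (or model name).
#' @param features feature columns used.
#' @param k number of folds (default 10).
#' @param seed seed for the fold shuffle.
#' @return list with `model` (the refit on all rows), `validation_accuracy`
#'   (percent), and `fold_accuracies`.
#' @export
train_cv <- function(table, spec, features = feature_names(), k = 10,
                     seed = 1L) {
  if (is.character(spec)) spec <- ml_model_spec(spec)
  df <- as.data.frame(table)
  X <- feature_matrix(df, features)
  y <- factor(df$class_label)
  if (min(table(y)) < k)
    stop("k exceeds the smallest class count")
  folds <- stratified_folds(y, k, seed)
  acc <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    m <- fit_ml_model(spec, X[tr, , drop = FALSE], y[tr])
    mean(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
  }, 0)
  list(model = fit_ml_model(spec, X, y),
       validation_accuracy = 100 * mean(acc),
       fold_accuracies = 100 * acc)
}

# stratified fold assignment: within each class, shuffled indices are
# dealt round-robin so fold sizes differ by at most one
stratified_folds <- function(y, k, seed = 1L) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    i <- sample(which(y == cl))
    folds[i] <- rep_len(seq_len(k), length(i))
  }
  folds
}

#' Evaluate a fitted model on a test table
#'
#' @param model a fitted model from [train_cv()]`$model`.
#' @param table test `feature_table`.
#' @param features feature columns (default: those stored in the
#'   model).
#' @return a `confusion_matrix` object: 2x2 counts (true x predicted),
#'   row percentages and accuracy (percent).
#' @export
evaluate_model <- function(model, table, features = model$features) {
  df <- as.data.frame(table)
  pred <- predict(model, feature_matrix(df, features))
  truth <- factor(df$class_label, levels = model$levels)
  confusion_matrix(truth, pred)
}

#' Confusion matrix from true and predicted labels
#'
#' @param truth,pred factors with identical levels.
#' @return object of class `confusion_matrix`: list with `counts`,
#'   `row_percent` (each true-class row sums to 100) and `accuracy`
#'   (percent).
#' @export
confusion_matrix <- function(truth, pred) {
  counts <- table(truth = truth, predicted = pred)
  rp <- 100 * prop.table(counts + 0, 1)
  rp[is.nan(rp)] <- 0
  structure(list(counts = unclass(counts), row_percent = unclass(rp),
                 accuracy = 100 * sum(diag(counts)) / sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (accuracy %.1f%%)\n", x$accuracy))
  print(round(x$row_percent, 1))
  invisible(x)
}

#' Feature-group ablation study
#'
#' Trains every model on four feature configurations -- all features,
#' without the morphological group, without the texture group, without
#' the quantitative-phase (QPI) group -- and reports validation
#' (cross-validated) and test accuracy for each cell of the grid.
#' Correlation pruning is applied to the full training set before the
#' groups are formed.
#'
#' @param table full `feature_table`.
#' @param split a [holdout_split()] of the table.
#' @param models model names (default all eight).
#' @param config a [selection_config()] for the pruning step.
#' @param k folds for cross-validation.
#' @param seed seed for fold shuffles.
#' @param prune apply correlation pruning first (default `TRUE`).
#' @return object of class `ablation_grid`: list with `validation` and
#'   `test` (4 x length(models) accuracy matrices, percent),
#'   `kept_features`, `configurations` and per-cell confusion matrices
#'   in `confusions`.
#' @export
ablation_study <- function(table, split, models = ml_model_names(),
                           config = selection_config(), k = 10,
                           seed = 1L, prune = TRUE) {
  df <- as.data.frame(table)
  train_df <- df[split$train, , drop = FALSE]
  test_df <- df[split$test, , drop = FALSE]
  kept <- if (prune)
    prune_features(kendall_matrix(train_df), config)$kept
  else intersect(feature_names(), colnames(df))
  grp <- feature_groups()
  configs <- list(
    all = kept,
    no_morphological = setdiff(kept, grp$morphological),
    no_texture = setdiff(kept, grp$texture),
    no_QPI = setdiff(kept, grp$QPI)
  )
  val <- te <- matrix(NA_real_, length(configs), length(models),
                      dimnames = list(names(configs), models))
  confusions <- list()
  for (ci in names(configs)) {
    for (m in models) {
      cv <- train_cv(train_df, m, features = configs[[ci]], k = k,
                     seed = seed)
      cm <- evaluate_model(cv$model, test_df)
      val[ci, m] <- cv$validation_accuracy
      te[ci, m] <- cm$accuracy
      confusions[[paste(ci, m, sep = ".")]] <- cm
    }
  }
  structure(list(validation = val, test = te, kept_features = kept,
                 configurations = configs, confusions = confusions),
            class = "ablation_grid")
}

#' @export
print.ablation_grid <- function(x, digits = 1, ...) {
  cat("Ablation grid: validation accuracy (%)\n")
  print(round(x$validation, digits))
  cat("Ablation grid: test accuracy (%)\n")
  print(round(x$test, digits))
  invisible(x)
}
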