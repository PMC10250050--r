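# Feature analysis: Kendall tau-b correlation with significance,
# |tau|-threshold pruning of redundant features, Relief(F) ranking, and
# PCA / t-SNE embeddings for visual inspection of class clustering.

#' Feature-selection configuration
#'
#' @param corr_threshold absolute Kendall correlation above which a
#'   significant pair is considered redundant (default 0.9).
#' @param alpha significance level for the correlation p-values
#'   (default 0.05).
#' @param relief_k_neighbors number of nearest hits/misses aggregated
#'   by ReliefF (default 10; `1` recovers the original Relief).
#' @param relief_sample_size `"all"` or an integer number of instances
#'   to sample.
#' @param seed integer seed for the sampling in Relief and t-SNE.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(corr_threshold = 0.9, alpha = 0.05,
                             relief_k_neighbors = 10,
                             relief_sample_size = "all", seed = 1L) {
  stopifnot(corr_threshold > 0, corr_threshold <= 1,
            alpha > 0, alpha < 1, relief_k_neighbors >= 1)
  structure(list(corr_threshold = corr_threshold, alpha = alpha,
                 relief_k_neighbors = as.integer(relief_k_neighbors),
                 relief_sample_size = relief_sample_size,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Kendall tau-b correlation matrix with p-values
#'
#' Tie-corrected Kendall rank correlation for every feature pair, with
#' two-sided p-values (exact for small samples without ties, normal
#' approximation with tie correction otherwise, as provided by
#' [stats::cor.test()]). Constant columns yield `NA` entries and are
#' listed in the `flags`.
#'
#' @param table a `feature_table` or numeric matrix/data frame.
#' @param features columns to correlate (default: the 12 descriptor
#'   features present in the table).
#' @return object of class `correlation_report`: list with `tau` and
#'   `p_value` matrices, `flags` (constant columns), and the feature
#'   names.
#' @export
kendall_matrix <- function(table, features = NULL) {
  X <- if (is.matrix(table)) table else {
    if (is.null(features))
      features <- intersect(feature_names(), colnames(table))
    feature_matrix(table, features)
  }
  stopifnot(nrow(X) >= 3)
  p <- ncol(X)
  nms <- colnames(X) %||% paste0("f", seq_len(p))
  tau <- matrix(NA_real_, p, p, dimnames = list(nms, nms))
  pv <- matrix(NA_real_, p, p, dimnames = list(nms, nms))
  const <- apply(X, 2, function(v) length(unique(v)) == 1L)
  diag(tau) <- ifelse(const, NA, 1)
  diag(pv) <- ifelse(const, NA, 0)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (const[i] || const[j]) next
    ct <- suppressWarnings(
      stats::cor.test(X[, i], X[, j], method = "kendall"))
    tau[i, j] <- tau[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  structure(list(tau = tau, p_value = pv, features = nms,
                 flags = nms[const]),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Kendall correlation report over %d features\n",
              length(x$features)))
  if (length(x$flags))
    cat("  constant (flagged):", paste(x$flags, collapse = ", "), "\n")
  off <- abs(x$tau[upper.tri(x$tau)])
  cat(sprintf("  max |tau| off-diagonal: %.3f\n", max(off, na.rm = TRUE)))
  invisible(x)
}

#' Prune redundant features by correlation threshold
#'
#' Among feature pairs whose absolute Kendall tau exceeds
#' `corr_threshold` with p-value below `alpha`, the member with the
#' larger mean absolute correlation against all remaining features is
#' dropped, iteratively, until no violating pair remains. Ties are
#' broken toward the later feature in the canonical order, making the
#' procedure deterministic and idempotent.
#'
#' @param report a `correlation_report` from [kendall_matrix()].
#' @param config a [selection_config()].
#' @return list with `kept` and `dropped` character vectors, plus
#'   `pairs`: the significant high-correlation pairs found.
#' @export
prune_features <- function(report, config = selection_config()) {
  stopifnot(inherits(report, "correlation_report"))
  keep <- report$features
  tau <- abs(report$tau); pv <- report$p_value
  dropped <- character()
  pairs <- list()
  repeat {
    t2 <- tau[keep, keep, drop = FALSE]
    p2 <- pv[keep, keep, drop = FALSE]
    viol <- which(t2 > config$corr_threshold & p2 < config$alpha &
                    upper.tri(t2), arr.ind = TRUE)
    if (nrow(viol) == 0) break
    if (length(pairs) == 0)
      pairs <- lapply(seq_len(nrow(viol)), function(k)
        c(keep[viol[k, 1]], keep[viol[k, 2]]))
    # mean |tau| of each member against the other remaining features
    cand <- unique(c(keep[viol[, 1]], keep[viol[, 2]]))
    mt <- vapply(cand, function(f)
      mean(tau[f, setdiff(keep, f)], na.rm = TRUE), 0)
    worst <- cand[mt == max(mt)]
    worst <- worst[length(worst)]  # tie-break: later feature
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
  }
  list(kept = keep, dropped = dropped, pairs = pairs)
}

#' ReliefF feature ranking
#'
#' Feature weights rewarding features that agree across nearest
#' same-class neighbours (hits) and differ across nearest
#' opposite-class neighbours (misses). Features are min-max scaled
#' internally; distances are Manhattan. For every (sampled) instance
#' the `k` nearest hits and `k` nearest misses each contribute their
#' normalised per-feature difference, averaged over neighbours and
#' instances: `w[f] = mean(miss diff) - mean(hit diff)`. `k = 1`
#' recovers the original Relief algorithm.
#'
#' @param table `feature_table`, data frame or numeric matrix.
#' @param labels class labels (two classes present); taken from the
#'   table's `class_label` column when omitted.
#' @param config a [selection_config()].
#' @param features columns to rank.
#' @return object of class `relief_ranking`: data frame with columns
#'   `feature`, `weight`, sorted by decreasing weight.
#' @export
relief_rank <- function(table, labels = NULL,
                        config = selection_config(), features = NULL) {
  X <- if (is.matrix(table)) table else {
    if (is.null(features))
      features <- intersect(feature_names(), colnames(table))
    feature_matrix(table, features)
  }
  if (is.null(labels)) labels <- as.data.frame(table)$class_label
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("relief_rank needs two classes")
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  idx <- seq_len(n)
  if (!identical(config$relief_sample_size, "all")) {
    set.seed(config$seed)
    idx <- sample.int(n, min(n, config$relief_sample_size))
  }
  k <- config$relief_k_neighbors
  w <- numeric(p)
  D <- as.matrix(stats::dist(Xs, method = "manhattan"))
  for (i in idx) {
    same <- which(labels == labels[i]); same <- setdiff(same, i)
    diff_cl <- which(labels != labels[i])
    kh <- same[order(D[i, same])][seq_len(min(k, length(same)))]
    km <- diff_cl[order(D[i, diff_cl])][seq_len(min(k, length(diff_cl)))]
    hit <- colMeans(abs(Xs[kh, , drop = FALSE] -
                          matrix(Xs[i, ], length(kh), p, byrow = TRUE)))
    mis <- colMeans(abs(Xs[km, , drop = FALSE] -
                          matrix(Xs[i, ], length(km), p, byrow = TRUE)))
    w <- w + (mis - hit)
  }
  w <- w / length(idx)
  out <- data.frame(feature = colnames(X) %||% paste0("f", seq_len(p)),
                    weight = w, stringsAsFactors = FALSE)
  out <- out[order(-out$weight), ]
  rownames(out) <- NULL
  class(out) <- c("relief_ranking", "data.frame")
  out
}

#' Two-component PCA embedding
#'
#' Columns are standardised (z-score) before the rotation, since the
#' descriptor mixes incommensurate units.
#'
#' @param table `feature_table`, data frame or numeric matrix.
#' @param features columns to embed.
#' @return list with `coords` (N x 2 matrix), `explained_variance`
#'   (length-2 fractions), `rotation`, and `all_eigenvalues`.
#' @export
embed_pca <- function(table, features = NULL) {
  X <- if (is.matrix(table)) table else {
    if (is.null(features))
      features <- intersect(feature_names(), colnames(table))
    feature_matrix(table, features)
  }
  stopifnot(nrow(X) > 2)
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  list(coords = pc$x[, 1:2, drop = FALSE],
       explained_variance = ev[1:2] / sum(ev),
       rotation = pc$rotation[, 1:2, drop = FALSE],
       all_eigenvalues = ev)
}

#' Two-dimensional t-SNE embedding
#'
#' Seeded, deterministic Barnes-Hut t-SNE (via \pkg{Rtsne}) on the
#' standardised features.
#'
#' @param table `feature_table`, data frame or numeric matrix.
#' @param perplexity t-SNE perplexity; requires `N > 3 * perplexity`.
#' @param seed integer seed.
#' @param max_iter gradient-descent iterations.
#' @param features columns to embed.
#' @return N x 2 matrix of embedding coordinates.
#' @export
embed_tsne <- function(table, perplexity = 30, seed = 1L,
                       max_iter = 1000, features = NULL) {
  X <- if (is.matrix(table)) table else {
    if (is.null(features))
      features <- intersect(feature_names(), colnames(table))
    feature_matrix(table, features)
  }
  if (nrow(X) <= 3 * perplexity)
    stop("perplexity too large for the number of rows")
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  Xs <- scale(X[, keep, drop = FALSE])
  set.seed(seed)
  fit <- Rtsne::Rtsne(Xs, dims = 2, perplexity = perplexity,
                      max_iter = max_iter, check_duplicates = FALSE,
                      pca = TRUE, verbose = FALSE)
  fit$Y
}
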