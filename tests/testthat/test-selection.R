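test_that("Kendall matrix has the exact small-case values", {
  x <- c(1, 2, 3, 4, 5)
  M <- cbind(a = x, b = -x, c = c(1, 2, 2, 4, 5))
  rep <- kendall_matrix(M)
  expect_equal(rep$tau["a", "a"], 1)
  expect_equal(rep$tau["a", "b"], -1)
  expect_equal(rep$tau["a", "c"], kendall_brute(x, c(1, 2, 2, 4, 5)),
               tolerance = 1e-12)
  expect_true(isSymmetric(rep$tau))
})

test_that("Kendall matrix equals the O(n^2) concordance oracle", {
  set.seed(17)
  X <- matrix(rnorm(20 * 12), 20, 12)
  X[, 4] <- round(X[, 4])  # introduce ties
  rep <- kendall_matrix(X)
  for (i in c(1, 4, 7)) for (j in c(2, 4, 12)) {
    if (i == j) next
    expect_equal(rep$tau[i, j], kendall_brute(X[, i], X[, j]),
                 tolerance = 1e-12)
  }
})

test_that("constant columns are flagged, not fatal", {
  X <- cbind(a = rnorm(10), b = rep(1, 10))
  rep <- kendall_matrix(X)
  expect_true("b" %in% rep$flags)
  expect_true(is.na(rep$tau["a", "b"]))
})

test_that("pruning drops exactly one member of a redundant pair", {
  set.seed(21)
  base <- rnorm(60)
  X <- cbind(f1 = base + 0.01 * rnorm(60), f2 = base,
             f3 = rnorm(60), f4 = rnorm(60))
  rep <- kendall_matrix(X)
  pr <- prune_features(rep, selection_config())
  expect_length(pr$dropped, 1)
  expect_true(pr$dropped %in% c("f1", "f2"))
  expect_setequal(c(pr$kept, pr$dropped), colnames(X))

  # duplicated column: one copy dropped
  Xd <- cbind(u = base, v = base, w = rnorm(60))
  prd <- prune_features(kendall_matrix(Xd))
  expect_length(prd$dropped, 1)
  expect_true(prd$dropped %in% c("u", "v"))

  # everything below threshold: nothing dropped
  Xi <- matrix(rnorm(60 * 4), 60, 4,
               dimnames = list(NULL, paste0("g", 1:4)))
  pri <- prune_features(kendall_matrix(Xi))
  expect_length(pri$dropped, 0)
})

test_that("pruning is idempotent", {
  set.seed(22)
  base <- rnorm(50)
  X <- cbind(a = base, b = base + 0.005 * rnorm(50), c = -base,
             d = rnorm(50))
  rep1 <- kendall_matrix(X)
  pr1 <- prune_features(rep1)
  rep2 <- kendall_matrix(X[, pr1$kept, drop = FALSE])
  pr2 <- prune_features(rep2)
  expect_identical(sort(pr2$kept), sort(pr1$kept))
})

test_that("Relief ranks a separating feature above pure noise", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    n <- 40
    y <- rep(c("A", "B"), each = n / 2)
    X <- cbind(sep = ifelse(y == "A", 0, 1) + 0.05 * rnorm(n),
               noise = rnorm(n))
    w <- relief_rank(X, y, selection_config(relief_k_neighbors = 3))
    if (w$feature[1] == "sep") hits <- hits + 1
  }
  expect_equal(hits, 100)
})

test_that("identical feature columns get identical Relief weights", {
  set.seed(30)
  y <- rep(c("A", "B"), each = 10)
  v <- rnorm(20) + (y == "A")
  X <- cbind(p = v, q = v, r = rnorm(20))
  w <- relief_rank(X, y)
  expect_lt(abs(w$weight[w$feature == "p"] - w$weight[w$feature == "q"]),
            1e-12)
})

test_that("ReliefF with k = 1 equals a hand-executed Relief pass", {
  X <- matrix(c(0, 0,
                0.1, 0.2,
                1, 1,
                0.9, 0.8), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("x1", "x2")))
  y <- c("A", "A", "B", "B")
  w <- relief_rank(X, y, selection_config(relief_k_neighbors = 1))
  oracle <- relief_brute_k1(X, y)
  expect_equal(w$weight[match(colnames(X), w$feature)], unname(oracle),
               tolerance = 1e-12)
})

test_that("PCA embedding identities hold", {
  set.seed(41)
  t <- rnorm(30)
  line <- cbind(a = 2 * t, b = -t + 0)
  p <- embed_pca(line)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-9)
  X <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  p2 <- embed_pca(X)
  R <- p2$rotation
  expect_equal(unname(crossprod(R)), diag(2), tolerance = 1e-9)
  # reconstruction error from 2 PCs equals the discarded eigenvalue sum
  Z <- scale(X)
  approx2 <- p2$coords %*% t(R)
  err <- sum((Z - approx2)^2) / (nrow(X) - 1)
  expect_equal(err, sum(p2$all_eigenvalues[-(1:2)]), tolerance = 1e-8)
})

test_that("t-SNE is seeded, shaped, and separates separated clusters", {
  set.seed(50)
  X <- rbind(matrix(rnorm(40 * 3, 0, 0.3), 40, 3),
             matrix(rnorm(40 * 3, 8, 0.3), 40, 3))
  colnames(X) <- paste0("c", 1:3)
  e1 <- embed_tsne(X, perplexity = 20, seed = 4, max_iter = 500)
  e2 <- embed_tsne(X, perplexity = 20, seed = 4, max_iter = 500)
  expect_equal(dim(e1), c(80, 2))
  expect_identical(e1, e2)
  lab <- rep(1:2, each = 40)
  d <- as.matrix(dist(e1))
  sil <- sapply(1:80, function(i) {
    a <- mean(d[i, lab == lab[i] & seq_len(80) != i])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  })
  expect_gt(mean(sil), 0.5)
  expect_error(embed_tsne(X, perplexity = 50), "perplexity")
})
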