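test_that("morphological features match geometric closed forms", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  mo <- morph_features(sq)
  expect_equal(unname(mo["area_px"]), 100)
  # perimeter convention pinned: 4 (k - 1) for a k x k square
  expect_equal(unname(mo["perimeter_px"]), 36)
  expect_lt(unname(mo["eccentricity"]), 0.1)

  # rasterised disc: near-zero eccentricity
  d <- outer(1:80, 1:80, function(y, x) (y - 40)^2 + (x - 40)^2 <= 30^2)
  expect_lt(unname(morph_features(d)["eccentricity"]), 0.1)

  # 2:1 ellipse: eccentricity sqrt(1 - (b/a)^2) = 0.866
  e <- outer(1:120, 1:120,
             function(y, x) ((x - 60) / 40)^2 + ((y - 60) / 20)^2 <= 1)
  expect_equal(unname(morph_features(e)["eccentricity"]),
               sqrt(1 - 0.25), tolerance = 0.02)
  expect_error(morph_features(matrix(FALSE, 4, 4)), "empty")
})

test_that("GLCM matches enumeration on canonical patterns", {
  const <- matrix(1.5, 8, 8)
  P <- glcm(const, n_levels = 8)
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)

  cb <- outer(1:8, 1:8, function(y, x) (x + y) %% 2)
  P2 <- glcm(cb, n_levels = 2)
  expect_equal(P2[1, 2], 0.5)
  expect_equal(P2[2, 1], 0.5)
  expect_equal(P2[1, 1] + P2[2, 2], 0)
})

test_that("fast GLCM equals the brute-force pair enumeration exactly", {
  set.seed(31)
  for (rep in 1:5) {
    v <- matrix(rnorm(16 * 16), 16, 16)
    m <- matrix(runif(16 * 16) > 0.25, 16, 16)
    if (!any(m)) next
    offs <- list(c(0, 1), c(1, 0), c(1, 1))[[sample(3, 1)]]
    a <- glcm(v, m, n_levels = 6, offsets = list(offs))
    b <- glcm_brute(v, m, 6, offsets = list(offs))
    expect_equal(unname(a), unname(b), tolerance = 1e-12)
  }
})

test_that("texture statistics have their analytic values", {
  const <- matrix(2, 8, 8)
  P <- glcm(const)
  tx <- texture_features(P, rep(2, 64))
  expect_equal(unname(tx["homogeneity"]), 1)
  expect_equal(unname(tx["energy"]), 1)
  expect_equal(unname(tx["entropy"]), 0)
  expect_true(attr(tx, "zero_variance"))

  cb <- outer(1:8, 1:8, function(y, x) (x + y) %% 2)
  P2 <- glcm(cb, n_levels = 2)
  tx2 <- texture_features(P2, as.vector(cb))
  expect_equal(unname(tx2["energy"]), 0.5)
  expect_equal(unname(tx2["entropy"]), 1)
  expect_equal(unname(tx2["homogeneity"]), 0.5)

  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(unname(texture_features(P2, sym)["skewness"]), 0)
  # non-excess kurtosis: Gaussian sample near 3
  set.seed(5)
  g <- rnorm(20000)
  expect_equal(unname(texture_features(P2, g)["kurtosis"]), 3,
               tolerance = 0.15)
})

test_that("QPI statistics use in-mask pixels with population sd", {
  q <- matrix(0, 4, 4)
  q[1, 1:3] <- c(1, 2, 3)
  m <- matrix(FALSE, 4, 4); m[1, 1:3] <- TRUE
  f <- qpi_features(q, m)
  expect_equal(unname(f), c(3, 1, 2, sqrt(2 / 3)))
  # background pixels outside the mask are irrelevant
  q2 <- q; q2[4, 4] <- 99
  expect_equal(qpi_features(q2, m), f)
  cm <- matrix(TRUE, 2, 2)
  expect_equal(unname(qpi_features(matrix(1.3, 2, 2), cm)),
               c(1.3, 1.3, 1.3, 0))
})

test_that("the descriptor has exactly 12 deterministic finite values", {
  sp <- phantom_spec("OC", 28, 1.8, texture_amplitude_rad = 0.25)
  ph <- make_cell_phantom(sp, 128, seed = 9)
  crop <- list(qpm = ph, mask = attr(ph, "support"))
  v1 <- extract_features(crop)
  v2 <- extract_features(crop)
  expect_length(v1, 12)
  expect_identical(names(v1), feature_names())
  expect_identical(v1, v2)
  expect_true(all(is.finite(v1)))
})

test_that("features are invariant to translating the cell", {
  sp <- phantom_spec("OC", 25, 2, texture_amplitude_rad = 0.2,
                     orientation_rad = 0.6)
  a <- make_cell_phantom(sp, 160, center = c(70, 80), seed = 12)
  b <- make_cell_phantom(sp, 160, center = c(90, 60), seed = 12)
  fa <- extract_features(list(qpm = a, mask = attr(a, "support")))
  fb <- extract_features(list(qpm = b, mask = attr(b, "support")))
  expect_equal(fa, fb, tolerance = 1e-6)
})

test_that("90-degree rotation preserves mask and phase statistics", {
  sp <- phantom_spec("OC", 25, 2, aspect_ratio = 1.5,
                     texture_amplitude_rad = 0.2)
  a <- make_cell_phantom(sp, 128, seed = 3)
  rot <- t(a)[ncol(a):1, ]
  fa <- extract_features(list(qpm = a, mask = a > 0))
  fr <- extract_features(list(qpm = rot, mask = rot > 0))
  inv <- c("area_px", "eccentricity", "perimeter_px",
           "phase_max", "phase_min", "phase_mean", "phase_std")
  expect_equal(fa[inv], fr[inv], tolerance = 1e-6)
})

test_that("increasing peak phase raises phase_max and phase_mean", {
  peaks <- c(1, 1.5, 2, 2.5)
  vals <- sapply(peaks, function(p) {
    ph <- make_cell_phantom(phantom_spec("OC", 25, p), 96)
    extract_features(list(qpm = ph, mask = attr(ph, "support")))
  })
  expect_true(all(diff(vals["phase_max", ]) > 0))
  expect_true(all(diff(vals["phase_mean", ]) > 0))
})
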