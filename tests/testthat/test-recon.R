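test_that("apodization windows behave as specified", {
  h <- matrix(1, 32, 32)
  expect_equal(apodize(h, taper = 0), h)
  hann <- apodize(h, taper = 1)
  expect_true(all(abs(hann[1, ]) < 1e-12))
  expect_true(all(abs(hann[, 32]) < 1e-12))
  set.seed(1)
  r <- matrix(runif(32 * 32), 32, 32)
  expect_lte(sum(apodize(r, 0.3)^2), sum(r^2))
})

test_that("carrier location recovers the simulator ground truth", {
  sc <- noise_free_scene(frame = 128, aberr = FALSE)
  sc$carrier_cycles_per_px <- c(0.20, 0.10)
  holo <- synthesize_hologram(NULL, sc, size = 128)
  carrier <- locate_carrier(holo)
  expect_lt(abs(carrier["fx"] - 0.20), 1 / 128 + 1e-9)
  expect_lt(abs(carrier["fy"] - 0.10), 1 / 128 + 1e-9)
  # contract: always in the fx > 0 half-plane
  expect_true(carrier["fx"] > 0 || (carrier["fx"] == 0 && carrier["fy"] > 0))
  expect_error(locate_carrier(matrix(1, 64, 64)), "no carrier")
})

test_that("demodulation removes the carrier and residual tilt", {
  sc <- noise_free_scene(frame = 256, aberr = FALSE)
  holo <- synthesize_hologram(NULL, sc, size = 256)
  cf <- demodulate(apodize(holo, 0.2), locate_carrier(holo))
  ctr <- 65:192
  ph <- Arg(cf$field[ctr, ctr])
  expect_lt(stats::sd(ph), 0.01)
  # residual tilt below 0.01 rad/px via linear fit on the background
  yy <- row(ph); xx <- col(ph)
  fit <- stats::lm(as.vector(ph) ~ as.vector(yy) + as.vector(xx))
  expect_true(all(abs(stats::coef(fit)[2:3]) < 0.01))
})

test_that("angular-spectrum propagation has the exact free-space identities", {
  opt <- optics_config()
  set.seed(2)
  # band-limited random field
  f0 <- gaussian_test_field(96, opt)
  expect_equal(propagate(f0, 0)$field, f0$field)
  back <- propagate(propagate(f0, 23.7), -23.7)
  expect_lt(max(Mod(back$field - f0$field)), 1e-9)
  # energy conservation (Parseval, evanescent-free)
  e0 <- sum(Mod(f0$field)^2)
  e1 <- sum(Mod(propagate(f0, 31)$field)^2)
  expect_lt(abs(e1 - e0) / e0, 1e-9)
  # on-axis plane wave picks up exactly 2 pi z / lambda
  pw <- complex_field(matrix(1 + 0i, 64, 64), opt)
  z <- 5.3
  got <- Arg(propagate(pw, z)$field[10, 10])
  expect_equal(wrap_phase(got - 2 * pi * z / opt$wavelength_um), 0,
               tolerance = 1e-9)
})

test_that("the Tamura coefficient matches its closed forms", {
  expect_equal(tamura(matrix(3, 10, 10)), 0)
  half <- matrix(c(rep(1, 50), rep(3, 50)), 10, 10)
  expect_equal(tamura(half), sqrt(1 / 2), tolerance = 1e-12)
  set.seed(3)
  a <- matrix(runif(64, 1, 2), 8, 8)
  expect_equal(tamura(5 * a), tamura(a), tolerance = 1e-12)
  expect_error(tamura(matrix(0, 4, 4)), "positive")
})

test_that("autofocus recovers the defocus of a simulated cell", {
  opt <- optics_config()
  sc <- noise_free_scene(frame = 256)
  sp <- phantom_spec("OC", 30, 2, texture_amplitude_rad = 0.2)
  ph <- make_cell_phantom(sp, 256, seed = 5)
  for (zt in c(50, 0)) {
    pair <- render_pair(ph, sc, opt, z = zt)
    fo <- demodulate(apodize(pair$holo, 0.2), locate_carrier(pair$holo))
    fr <- demodulate(apodize(pair$ref, 0.2), locate_carrier(pair$holo))
    fc <- complex_field(fo$field * exp(-1i * Arg(fr$field)), opt)
    af <- autofocus(fc, -60, 60)
    expect_lt(abs(af$z_um + zt), 2)
    # the refined z stays inside the bracket of the coarse-scan minimum
    zmin <- af$curve$z_um[which.min(af$curve$tamura)]
    expect_lte(abs(af$z_um - zmin), 5)
  }
})

test_that("reference compensation removes shared aberrations exactly", {
  opt <- optics_config()
  sc <- noise_free_scene(frame = 128, aberr = TRUE)
  holo <- synthesize_hologram(matrix(0, 128, 128), sc)
  ref <- synthesize_hologram(NULL, sc, size = 128)
  fo <- demodulate(apodize(holo, 0.2), locate_carrier(holo))
  fr <- demodulate(apodize(ref, 0.2), locate_carrier(holo))
  w <- compensate(fo, fr)
  expect_true(all(w > -pi & w <= pi))
  ctr <- 33:96
  expect_lt(stats::sd(w[ctr, ctr]), 1e-6)
  expect_equal(max(abs(compensate(fo, fo))), 0)
  expect_error(compensate(fo, demodulate(apodize(holo[1:64, 1:64], 0.2),
                                         locate_carrier(holo))),
               "shape")
})

test_that("unwrapping is congruent and exact on residue-free maps", {
  # smooth map with < 2 pi total range: returned unchanged up to 2 pi k
  g1 <- outer(seq(-1, 1, length.out = 48), seq(-1, 1, length.out = 48),
              function(y, x) 2.5 * exp(-(x^2 + y^2)))
  u1 <- unwrap_phase(wrap_phase(g1))
  off <- round(mean(u1 - g1) / (2 * pi)) * 2 * pi
  expect_lt(max(abs(u1 - g1 - off)), 1e-9)
  # 6-rad bump needs real unwrapping
  g2 <- outer(seq(-1, 1, length.out = 64), seq(-1, 1, length.out = 64),
              function(y, x) 6 * exp(-2 * (x^2 + y^2)))
  w2 <- wrap_phase(g2)
  u2 <- unwrap_phase(w2)
  off2 <- round(mean(u2 - g2) / (2 * pi)) * 2 * pi
  expect_lt(max(abs(u2 - g2 - off2)), 1e-6)
  # congruence contract holds pixelwise
  expect_lt(max(abs(wrap_phase(u2) - w2)), 1e-9)
  expect_equal(attr(u2, "residue_density"), 0)
})

test_that("unwrapping flags noisy maps but still returns congruent output", {
  set.seed(4)
  noisy <- matrix(runif(32 * 32, -pi, pi), 32, 32)
  u <- unwrap_phase(noisy)
  expect_true(attr(u, "quality_flag"))
  expect_lt(max(abs(wrap_phase(u) - noisy)), 1e-9)
})

test_that("denoising preserves clean maps and reduces speckle", {
  sp <- phantom_spec("OC", 30, 2, texture_amplitude_rad = 0)
  clean <- make_cell_phantom(sp, 128)
  attr(clean, "support") <- NULL; attr(clean, "true_max") <- NULL
  out <- denoise_qpm(clean)
  expect_lt(max(abs(out - clean)), 0.01)
  set.seed(6)
  mask <- make_cell_phantom(sp, 128) > 0.1
  noisy <- clean + 0.08 * matrix(rnorm(128 * 128), 128, 128)
  dn <- denoise_qpm(noisy)
  expect_lt(stats::var(dn[!mask]), stats::var(noisy[!mask]))
  expect_lt(abs(mean(dn[mask]) - mean(noisy[mask])) /
              abs(mean(noisy[mask])), 0.01)
})

test_that("segmentation cuts a centred single-component crop", {
  sp <- phantom_spec("OC", 30, 2, texture_amplitude_rad = 0)
  ph <- make_cell_phantom(sp, 256, center = c(110, 150))
  crop <- segment_crop(ph, crop_size = 192)
  expect_equal(dim(crop$qpm), c(192, 192))
  lab <- EBImage::bwlabel(EBImage::Image(crop$mask * 1))
  expect_equal(max(lab), 1)
  idx <- which(crop$mask, arr.ind = TRUE)
  expect_lt(max(abs(colMeans(idx) - 96.5)), 1.6)
  # mask area tracks the true support within 10%
  expect_lt(abs(crop$area_px - sum(attr(ph, "support"))) /
              sum(attr(ph, "support")), 0.1)
  expect_error(segment_crop(matrix(0, 64, 64), 48), "empty frame")
})
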