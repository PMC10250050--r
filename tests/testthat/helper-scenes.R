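# Shared small scene configurations for reconstruction tests. All
# fixtures are generated in code; nothing is read from disk.

noise_free_scene <- function(frame = 256, counts = c(2, 1), seed = 11,
                             defocus = c(-35, 35), aberr = TRUE) {
  scene_config(
    frame_size_px = frame,
    defocus_range_um = defocus,
    speckle_contrast = 0, shot_noise_sigma = 0,
    aberration_coeffs = if (aberr)
      c(x = 0.6, y = -0.4, x2 = 0.8, y2 = 0.6, xy = 0.4) else NULL,
    class_counts = counts, frames_per_cell_range = c(1, 1),
    seed = seed)
}

# one clean hologram/reference pair from a given phantom
render_pair <- function(phase_map, scene, optics = optics_config(),
                        z = 0) {
  list(holo = synthesize_hologram(phase_map, scene, optics, z),
       ref = synthesize_hologram(NULL, scene, optics, 0,
                                 size = nrow(phase_map)))
}

# random band-limited complex field (no evanescent content at the
# default optics), for propagation identity tests
gaussian_test_field <- function(n, optics = optics_config(),
                                radius_cyc_px = 0.15) {
  S <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq.int(-floor(n / 2), -1L)) / n
  fx <- matrix(k, n, n, byrow = TRUE); fy <- matrix(k, n, n)
  S[fx^2 + fy^2 > radius_cyc_px^2] <- 0
  f <- stats::fft(S, inverse = TRUE) / n
  complex_field(f, optics, 0)
}

# quick feature table from phantom crops without the optics chain:
# phantom maps are treated as ideal reconstructions
phantom_feature_table <- function(n_per_class = c(30, 10), separation = 1,
                                  size = 128, seed = 5) {
  set.seed(seed)
  crops <- list(); labels <- character(); id <- 0
  for (cl in c("OC", "MONO")) {
    k <- if (cl == "OC") n_per_class[1] else n_per_class[2]
    specs <- sample_phantom_specs(k, cl, separation)
    for (sp in specs) {
      sp$radius_px <- min(sp$radius_px, size / 2 - 6)
      ph <- make_cell_phantom(sp, size = size)
      id <- id + 1
      crops[[id]] <- list(qpm = ph, mask = attr(ph, "support"),
                          cell_id = id, frame_id = id, label = cl)
    }
  }
  feature_table(crops)
}
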