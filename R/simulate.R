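# Physics-based synthetic off-axis hologram generator: renders phase
# phantoms into interference patterns with defocus, shared optical
# aberrations, correlated speckle and shot noise, plus a matching
# cell-free reference hologram, so the whole reconstruction and
# learning chain is testable without any external data.

#' Scene configuration for the hologram simulator
#'
#' @param frame_size_px even frame side in pixels.
#' @param carrier_cycles_per_px `c(fx, fy)` spatial carrier of the
#'   tilted reference beam, cycles/px; each component below Nyquist.
#' @param defocus_range_um `c(min, max)` interval from which each
#'   frame's true defocus is drawn, micrometres.
#' @param speckle_contrast contrast of the multiplicative complex
#'   speckle field, in `[0, 1)`.
#' @param speckle_correlation_px correlation length of the speckle.
#' @param shot_noise_sigma additive intensity noise, as a fraction of
#'   the mean intensity.
#' @param aberration_coeffs named numeric vector of low-order
#'   polynomial phase coefficients (radians) on coordinates normalised
#'   to `[-1, 1]`; recognised names: `x, y, x2, y2, xy`.
#' @param class_counts `c(OC, MONO)` number of cells per class.
#' @param frames_per_cell_range integer `c(min, max)` within `[1, 4]`:
#'   each cell is imaged on a random number of frames in this range.
#' @param separation class-separation knob in `[0, 1]` passed to
#'   [sample_phantom_specs()].
#' @param seed integer master seed for all randomness in the scene.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(frame_size_px = 512,
                         carrier_cycles_per_px = c(0.30, 0.30),
                         defocus_range_um = c(-60, 60),
                         speckle_contrast = 0.1,
                         speckle_correlation_px = 4,
                         shot_noise_sigma = 0.01,
                         aberration_coeffs = c(x = 0.6, y = -0.4,
                                               x2 = 0.8, y2 = 0.6,
                                               xy = 0.4),
                         class_counts = c(2550, 401),
                         frames_per_cell_range = c(1, 4),
                         separation = 1,
                         seed = 1L) {
  stopifnot(frame_size_px %% 2 == 0, frame_size_px >= 64)
  if (any(abs(carrier_cycles_per_px) >= 0.5) ||
      all(carrier_cycles_per_px == 0))
    stop("carrier components must satisfy 0 < |f| < 0.5 cycles/px")
  stopifnot(speckle_contrast >= 0, speckle_contrast < 1,
            shot_noise_sigma >= 0,
            length(class_counts) == 2, all(class_counts >= 1),
            all(frames_per_cell_range >= 1),
            all(frames_per_cell_range <= 4),
            frames_per_cell_range[1] <= frames_per_cell_range[2],
            separation >= 0, separation <= 1)
  structure(list(
    frame_size_px = as.integer(frame_size_px),
    carrier_cycles_per_px = carrier_cycles_per_px,
    defocus_range_um = defocus_range_um,
    speckle_contrast = speckle_contrast,
    speckle_correlation_px = speckle_correlation_px,
    shot_noise_sigma = shot_noise_sigma,
    aberration_coeffs = aberration_coeffs,
    class_counts = as.integer(class_counts),
    frames_per_cell_range = as.integer(frames_per_cell_range),
    separation = separation,
    seed = as.integer(seed)
  ), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "scene_config: %dpx frames, carrier (%.2f, %.2f) cyc/px, z in [%g, %g] um\n",
    x$frame_size_px, x$carrier_cycles_per_px[1], x$carrier_cycles_per_px[2],
    x$defocus_range_um[1], x$defocus_range_um[2]))
  cat(sprintf(
    "  counts OC/MONO = %d/%d (ratio %.2f), %d-%d frames/cell, speckle %.2f, shot %.3f, separation %.2f\n",
    x$class_counts[1], x$class_counts[2],
    x$class_counts[1] / x$class_counts[2],
    x$frames_per_cell_range[1], x$frames_per_cell_range[2],
    x$speckle_contrast, x$shot_noise_sigma, x$separation))
  invisible(x)
}

# polynomial aberration phase on [-1,1]^2 normalised coordinates
aberration_phase <- function(n, coeffs) {
  if (is.null(coeffs) || length(coeffs) == 0) return(matrix(0, n, n))
  t <- seq(-1, 1, length.out = n)
  x <- matrix(t, n, n, byrow = TRUE)
  y <- matrix(t, n, n)
  terms <- list(x = x, y = y, x2 = x^2, y2 = y^2, xy = x * y)
  out <- matrix(0, n, n)
  for (nm in names(coeffs))
    if (nm %in% names(terms)) out <- out + coeffs[[nm]] * terms[[nm]]
  out
}

# smoothed unit-variance complex Gaussian field
speckle_field <- function(n, correlation_px) {
  g <- complex(real = stats::rnorm(n * n), imaginary = stats::rnorm(n * n))
  g <- gauss_smooth(matrix(g, n, n), correlation_px / 2)
  g / sqrt(mean(Mod(g)^2))
}

#' Render one off-axis hologram
#'
#' Forms the object field `O = exp(i phase)`, propagates it by the true
#' defocus with the angular-spectrum method, applies the shared
#' aberration phase and (optionally) multiplicative correlated speckle,
#' interferes it with the tilted plane reference wave, and adds shot
#' noise to the recorded intensity:
#' `I = |O_z A s + R|^2 + noise`, clipped at zero.
#'
#' Randomness (speckle, shot noise) is drawn from the current RNG
#' state; seed the session or use [generate_dataset()] for reproducible
#' sets.
#'
#' @param phase_map real matrix of object phase (radians); use a zero
#'   matrix (or `NULL` with `size` given) for a cell-free reference
#'   hologram.
#' @param scene a [scene_config()].
#' @param optics an [optics_config()].
#' @param z_defocus_um true defocus distance of the object, um.
#' @param size frame size when `phase_map` is `NULL`.
#' @return real non-negative intensity matrix.
#' @export
synthesize_hologram <- function(phase_map, scene, optics = optics_config(),
                                z_defocus_um = 0, size = NULL) {
  if (is.null(phase_map)) {
    stopifnot(!is.null(size))
    phase_map <- matrix(0, size, size)
  }
  stopifnot(is.matrix(phase_map), inherits(scene, "scene_config"))
  n <- nrow(phase_map)
  stopifnot(ncol(phase_map) == n)
  if (any(abs(scene$carrier_cycles_per_px) >= 0.5))
    stop("carrier at or above Nyquist")
  obj <- exp(1i * phase_map)
  if (z_defocus_um != 0)
    obj <- propagate(complex_field(obj, optics, 0), z_defocus_um)$field
  obj <- obj * exp(1i * aberration_phase(n, scene$aberration_coeffs))
  if (scene$speckle_contrast > 0) {
    s <- speckle_field(n, scene$speckle_correlation_px)
    obj <- obj * (sqrt(1 - scene$speckle_contrast^2) +
                    scene$speckle_contrast * s)
  }
  fx <- scene$carrier_cycles_per_px[1]
  fy <- scene$carrier_cycles_per_px[2]
  xg <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  yg <- matrix(seq_len(n) - 1, n, n)
  # tilt sign chosen so the object-bearing (+1) order lies at +carrier
  ref <- exp(-2i * pi * (fx * xg + fy * yg))
  I <- Mod(obj + ref)^2
  if (scene$shot_noise_sigma > 0)
    I <- I + scene$shot_noise_sigma * mean(I) *
      matrix(stats::rnorm(n * n), n, n)
  pmax(I, 0)
}

#' Generate a ground-truthed synthetic hologram dataset
#'
#' Draws an unbalanced two-class population of cell phantoms, renders
#' 1-4 hologram frames per cell at random defocus (each frame has an
#' independent speckle and shot-noise realisation, a jittered cell
#' position, and the shared instrument aberration), renders one
#' cell-free reference hologram, and returns a manifest with the full
#' ground truth per frame. All randomness derives from `scene$seed`.
#'
#' With `render = FALSE` only the manifest (population draw, frame
#' multiplicities, true defocus values) is produced, which is useful
#' for planning and for dataset arithmetic.
#'
#' @param scene a [scene_config()].
#' @param optics an [optics_config()].
#' @param out_dir optional directory; when given, holograms, the
#'   reference and the manifest are written to disk (scaled float32
#'   TIFF + CSV + YAML scene sidecar, see [write_dataset()]).
#' @param render render the hologram frames (`TRUE`) or return the
#'   manifest only.
#' @return object of class `holo_dataset`: list with `manifest` (one
#'   row per frame: `cell_id`, `frame_id`, `class_label`,
#'   `true_defocus_um`, phantom ground truth, `file`), `holograms`
#'   (list of matrices, when rendered), `reference`, `phantoms` (list
#'   of ground-truth phase maps), `scene`, `optics`, `out_dir`.
#' @export
generate_dataset <- function(scene, optics = optics_config(),
                             out_dir = NULL, render = TRUE) {
  stopifnot(inherits(scene, "scene_config"))
  if (any(scene$class_counts < 1))
    stop("both classes need at least one cell")
  set.seed(scene$seed)
  n <- scene$frame_size_px
  specs <- c(
    sample_phantom_specs(scene$class_counts[1], "OC", scene$separation),
    sample_phantom_specs(scene$class_counts[2], "MONO", scene$separation)
  )
  labels <- rep(c("OC", "MONO"), scene$class_counts)
  ncell <- length(specs)
  fr <- scene$frames_per_cell_range
  nframes <- if (fr[1] == fr[2]) rep(fr[1], ncell) else
    sample(fr[1]:fr[2], ncell, replace = TRUE)

  rows <- list(); holograms <- list(); phantoms <- list()
  frame_no <- 0L
  for (ci in seq_len(ncell)) {
    sp <- specs[[ci]]
    for (k in seq_len(nframes[ci])) {
      frame_no <- frame_no + 1L
      z <- stats::runif(1, scene$defocus_range_um[1],
                        scene$defocus_range_um[2])
      jitter <- stats::runif(2, -0.08, 0.08) * n
      center <- c(n / 2 + jitter[1], n / 2 + jitter[2])
      rows[[frame_no]] <- data.frame(
        cell_id = ci, frame_id = frame_no, class_label = labels[ci],
        true_defocus_um = z,
        radius_px = sp$radius_px, peak_phase_rad = sp$peak_phase_rad,
        aspect_ratio = sp$aspect_ratio,
        texture_amplitude_rad = sp$texture_amplitude_rad,
        texture_correlation_px = sp$texture_correlation_px,
        orientation_rad = sp$orientation_rad,
        center_y = center[1], center_x = center[2],
        file = NA_character_, stringsAsFactors = FALSE
      )
      if (render) {
        ph <- make_cell_phantom(sp, size = n, center = center)
        rows[[frame_no]]$true_phase_max <- attr(ph, "true_max")
        phantoms[[frame_no]] <- ph
        holograms[[frame_no]] <- synthesize_hologram(ph, scene, optics, z)
      }
    }
  }
  reference <- if (render)
    synthesize_hologram(NULL, scene, optics, 0, size = n) else NULL
  manifest <- do.call(rbind, rows)
  ds <- structure(list(
    manifest = manifest,
    holograms = if (render) holograms else NULL,
    phantoms = if (render) phantoms else NULL,
    reference = reference,
    scene = scene, optics = optics, out_dir = out_dir
  ), class = "holo_dataset")
  if (!is.null(out_dir)) ds <- write_dataset(ds, out_dir)
  ds
}

#' @export
print.holo_dataset <- function(x, ...) {
  tab <- table(x$manifest$class_label[!duplicated(x$manifest$cell_id)])
  cat(sprintf(
    "holo_dataset: %d frames from %d cells (OC %d, MONO %d, ratio %.2f)%s\n",
    nrow(x$manifest), length(unique(x$manifest$cell_id)),
    tab[["OC"]], tab[["MONO"]], tab[["OC"]] / tab[["MONO"]],
    if (is.null(x$holograms)) " [manifest only]" else ""))
  invisible(x)
}

#' Write a rendered dataset to disk
#'
#' Holograms and the reference go to `holograms/` as single-channel
#' float32 TIFF. TIFF storage is clamped to `[0, 1]`, so each frame is
#' written as `(I - offset) / scale` with `offset`/`scale` recorded in
#' the manifest and undone by [read_hologram()]. The manifest is
#' written as CSV and the scene configuration as a YAML sidecar.
#'
#' @param ds a rendered `holo_dataset`.
#' @param out_dir output directory (created if needed).
#' @return the dataset with `manifest$file`, `tiff_offset`,
#'   `tiff_scale` filled in and `out_dir` set.
#' @export
write_dataset <- function(ds, out_dir) {
  stopifnot(inherits(ds, "holo_dataset"), !is.null(ds$holograms))
  hdir <- file.path(out_dir, "holograms")
  dir.create(hdir, recursive = TRUE, showWarnings = FALSE)
  ds$manifest$tiff_offset <- NA_real_
  ds$manifest$tiff_scale <- NA_real_
  for (i in seq_len(nrow(ds$manifest))) {
    f <- file.path(hdir, sprintf("frame_%05d.tif", ds$manifest$frame_id[i]))
    sc <- write_scaled_tiff(ds$holograms[[i]], f)
    ds$manifest$file[i] <- f
    ds$manifest$tiff_offset[i] <- sc[1]
    ds$manifest$tiff_scale[i] <- sc[2]
  }
  rf <- file.path(hdir, "reference.tif")
  rsc <- write_scaled_tiff(ds$reference, rf)
  utils::write.csv(ds$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  scene_l <- unclass(ds$scene)
  scene_l$reference_file <- rf
  scene_l$reference_offset <- rsc[1]
  scene_l$reference_scale <- rsc[2]
  yaml::write_yaml(scene_l, file.path(out_dir, "scene.yaml"))
  ds$out_dir <- out_dir
  ds
}

write_scaled_tiff <- function(m, path) {
  offset <- min(m)
  scale <- max(m) - offset
  if (scale == 0) scale <- 1
  tiff::writeTIFF((m - offset) / scale, path, bits.per.sample = 32L)
  c(offset, scale)
}

#' Read back a scaled float32 TIFF written by [write_dataset()]
#'
#' @param path TIFF path.
#' @param offset,scale scaling recorded in the manifest.
#' @return numeric matrix on the original scale.
#' @export
read_hologram <- function(path, offset = 0, scale = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m * scale + offset
}
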