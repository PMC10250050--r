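#' Specification of a single cell phase phantom
#'
#' A phantom is a smooth, compactly supported, non-negative phase bump:
#' a flat-topped ("super-Gaussian style") raised-cosine profile on an
#' ellipse, optionally carrying band-limited internal texture. It stands
#' in for the optical-path-delay signature of a single suspended cell.
#'
#' @param class_label `"OC"` (ovarian-cancer-like) or `"MONO"`
#'   (monocyte-like).
#' @param radius_px semi-major axis of the support ellipse, object-plane
#'   pixels (> 0).
#' @param peak_phase_rad peak phase delay at the cell centre, radians
#'   (>= 0).
#' @param aspect_ratio ratio of major to minor axis (>= 1).
#' @param texture_amplitude_rad standard deviation of the internal
#'   texture field at the cell centre, radians (>= 0).
#' @param texture_correlation_px correlation length of the texture,
#'   pixels (> 0).
#' @param orientation_rad in-plane rotation of the ellipse, radians.
#' @param flatness order of the radial profile; larger values give a
#'   flatter top and steeper rim.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(class_label = c("OC", "MONO"),
                         radius_px, peak_phase_rad,
                         aspect_ratio = 1,
                         texture_amplitude_rad = 0,
                         texture_correlation_px = 8,
                         orientation_rad = 0,
                         flatness = 4) {
  class_label <- match.arg(class_label)
  if (!is.numeric(radius_px) || length(radius_px) != 1 || radius_px <= 0)
    stop("radius_px must be a positive scalar")
  if (!is.numeric(peak_phase_rad) || peak_phase_rad < 0)
    stop("peak_phase_rad must be >= 0")
  if (aspect_ratio < 1) stop("aspect_ratio must be >= 1")
  if (texture_amplitude_rad < 0) stop("texture_amplitude_rad must be >= 0")
  if (texture_correlation_px <= 0) stop("texture_correlation_px must be > 0")
  structure(list(
    class_label = class_label,
    radius_px = radius_px,
    peak_phase_rad = peak_phase_rad,
    aspect_ratio = aspect_ratio,
    texture_amplitude_rad = texture_amplitude_rad,
    texture_correlation_px = texture_correlation_px,
    orientation_rad = orientation_rad,
    flatness = flatness
  ), class = "phantom_spec")
}

#' Render a cell phantom as a ground-truth phase map
#'
#' Evaluates the phantom profile on a `size x size` pixel grid centred
#' at `center` (default: grid centre). The radial profile is
#' `peak * cos(pi/2 * rho^flatness)^2` for elliptical radius `rho <= 1`
#' and exactly zero outside, so the support is contained in the
#' `radius_px` ellipse and the maximum equals `peak_phase_rad` at the
#' centroid. Texture is a smoothed Gaussian random field, unit variance
#' at the centre, scaled by `texture_amplitude_rad` and by the envelope
#' so it fades to zero at the rim; the result is clipped at zero so the
#' map is always non-negative.
#'
#' @param spec a [phantom_spec()].
#' @param size side length of the (square) output map in pixels.
#' @param center length-2 numeric `(y, x)` centre in pixels; defaults to
#'   the grid centre.
#' @param seed optional integer; when given, texture generation is
#'   seeded locally so identical calls are bit-identical.
#' @return `size x size` numeric matrix of phase values (radians), with
#'   attributes `support` (logical mask of the true support) and
#'   `true_max` (realised maximum).
#' @export
make_cell_phantom <- function(spec, size = 512, center = NULL, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), size >= 8)
  if (is.null(center)) center <- c((size + 1) / 2, (size + 1) / 2)
  y <- matrix(seq_len(size) - center[1], size, size)
  x <- matrix(seq_len(size) - center[2], size, size, byrow = TRUE)
  ct <- cos(spec$orientation_rad); st <- sin(spec$orientation_rad)
  u <- ct * x + st * y
  v <- -st * x + ct * y
  a <- spec$radius_px
  b <- spec$radius_px / spec$aspect_ratio
  rho2 <- (u / a)^2 + (v / b)^2
  inside <- rho2 < 1
  env <- matrix(0, size, size)
  rho <- sqrt(pmin(rho2, 1))
  env[inside] <- cos(pi / 2 * rho[inside]^spec$flatness)^2
  phase <- spec$peak_phase_rad * env

  if (spec$texture_amplitude_rad > 0 && spec$peak_phase_rad > 0) {
    # texture lives in cell-local coordinates: a fixed-size patch is
    # generated around the cell centre, so translating the cell inside
    # the frame translates its texture with it
    L <- 2L * ceiling(spec$radius_px) + 17L
    patch <- local({
      if (!is.null(seed)) {
        old <- if (exists(".Random.seed", .GlobalEnv))
          get(".Random.seed", .GlobalEnv) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
        set.seed(seed)
      }
      g <- gauss_smooth(matrix(stats::rnorm(L * L), L, L),
                        spec$texture_correlation_px / 2)
      g / stats::sd(g)
    })
    tex <- matrix(0, size, size)
    half <- (L - 1L) %/% 2L
    cy <- round(center[1]); cx <- round(center[2])
    ys <- (cy - half):(cy + half)
    xs <- (cx - half):(cx + half)
    ok_y <- ys >= 1 & ys <= size
    ok_x <- xs >= 1 & xs <= size
    tex[ys[ok_y], xs[ok_x]] <- patch[which(ok_y), which(ok_x)]
    phase <- phase + spec$texture_amplitude_rad * tex * env
    phase <- pmax(phase, 0)
  }
  attr(phase, "support") <- inside
  attr(phase, "true_max") <- max(phase)
  phase
}

#' Class-conditional phantom population model
#'
#' Draws phantom specifications for the two simulated populations. The
#' populations deliberately overlap in morphology (size, eccentricity)
#' and in texture; the scalar `separation` knob moves only the phase
#' statistics apart (peak phase delay), so that with `separation = 0`
#' the two class-conditional distributions are identical and with the
#' default strong separation the discriminative signal is concentrated
#' in the quantitative-phase features.
#'
#' Parameter values are nominal choices for ~4 um-radius suspended cells
#' sampled at 0.1 um/px; the real phase and size distributions of either
#' cell line are not publicly tabulated.
#'
#' @param n number of cells to draw.
#' @param class_label `"OC"` or `"MONO"`.
#' @param separation scalar in `[0, 1]`; 0 = identical classes,
#'   1 (default) = strong phase-statistic separation.
#' @return list of [phantom_spec()] objects, length `n`.
#' @export
sample_phantom_specs <- function(n, class_label = c("OC", "MONO"),
                                 separation = 1) {
  class_label <- match.arg(class_label)
  stopifnot(n >= 1, separation >= 0, separation <= 1)
  sgn <- if (class_label == "OC") 1 else -1
  radius <- pmin(pmax(stats::rnorm(n, 40, 5), 22), 58)
  aspect <- 1 + pmin(abs(stats::rnorm(n, 0, 0.22)), 0.7)
  peak <- pmax(stats::rnorm(n, 1.8 + sgn * 0.5 * separation, 0.15), 0.2)
  tex_amp <- pmin(pmax(stats::rnorm(n, 0.22, 0.04), 0), 0.4)
  orient <- stats::runif(n, 0, pi)
  lapply(seq_len(n), function(i) phantom_spec(
    class_label = class_label,
    radius_px = radius[i],
    peak_phase_rad = peak[i],
    aspect_ratio = aspect[i],
    texture_amplitude_rad = tex_amp[i],
    texture_correlation_px = 9,
    orientation_rad = orient[i]
  ))
}
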