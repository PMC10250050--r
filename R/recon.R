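# Quantitative phase-map reconstruction from off-axis holograms:
# apodization -> +1-order demodulation -> angular-spectrum refocusing
# with a Tamura-coefficient autofocus -> reference-hologram aberration
# compensation -> congruent least-squares unwrapping -> denoising ->
# segmentation and centred cropping.

#' Complex optical field
#'
#' Container for a demodulated complex wavefront: the complex-valued
#' array, the optics it was sampled with, and the cumulative numerical
#' defocus that has been applied to it.
#'
#' @param field complex matrix.
#' @param optics an [optics_config()].
#' @param z_um current defocus state in micrometres (object space).
#' @return object of class `complex_field`.
#' @export
complex_field <- function(field, optics, z_um = 0, validate = TRUE) {
  if (validate) {
    stopifnot(is.matrix(field), inherits(optics, "optics_config"))
    if (anyNA(field)) stop("complex field contains non-finite entries")
  }
  structure(list(field = field, optics = optics, z_um = z_um),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("complex_field %d x %d, z = %.2f um, pixel = %.4f um\n",
              nrow(x$field), ncol(x$field), x$z_um, x$optics$object_pixel_um))
  invisible(x)
}

#' Apodize a hologram
#'
#' Multiplies the frame by a separable 2-D Tukey (tapered-cosine)
#' window so the intensity falls off smoothly toward the borders,
#' suppressing edge diffraction in the Fourier spectrum. `taper = 0`
#' is the identity; `taper = 1` is a full Hann window.
#'
#' @param holo real intensity matrix.
#' @param taper fraction of each axis tapered (0..1).
#' @return windowed matrix of the same size.
#' @export
apodize <- function(holo, taper = 0.2) {
  stopifnot(is.matrix(holo), nrow(holo) > 0, taper >= 0, taper <= 1)
  holo * outer(tukey_window(nrow(holo), taper),
               tukey_window(ncol(holo), taper))
}

tukey_window <- function(n, taper) {
  if (taper <= 0) return(rep(1, n))
  t <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  lo <- t < taper / 2
  hi <- t > 1 - taper / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / taper - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / taper - 1)))
  w
}

#' Locate the +1 diffraction order in a hologram spectrum
#'
#' Finds the off-axis carrier frequency as the strongest spectral peak
#' outside a disk around DC, restricted to the half-plane `fx > 0`
#' (with `fx = 0, fy > 0` on the boundary) to break the +1/-1 conjugate
#' ambiguity. The frame is transformed as given; apodize it first
#' (as [reconstruct_qpm()] does) to sharpen the orders.
#'
#' @param holo real intensity matrix.
#' @param dc_radius radius (cycles/px) of the DC exclusion disk.
#' @param min_prominence required ratio between the peak magnitude and
#'   the median spectral magnitude of the search region.
#' @return named numeric `c(fx, fy)` in cycles/px.
#' @export
locate_carrier <- function(holo, dc_radius = 0.04, min_prominence = 5) {
  stopifnot(is.matrix(holo))
  S <- Mod(fft2(holo))
  g <- freq_grids(nrow(holo), ncol(holo))
  search <- (g$fx > 0 | (g$fx == 0 & g$fy > 0)) &
    (g$fx^2 + g$fy^2) > dc_radius^2
  vals <- S[search]
  if (max(vals) < min_prominence * stats::median(vals) ||
      max(vals) < 1e-9 * max(S))
    stop("no carrier: no off-axis peak with sufficient prominence")
  idx <- which(search)[which.max(vals)]
  c(fx = g$fx[idx], fy = g$fy[idx])
}

#' Demodulate the +1 order to baseband
#'
#' Translates the +1 diffraction order of the hologram spectrum to the
#' origin (integer-bin circular shift of the FFT), applies a circular
#' low-pass of radius `passband_radius` (cycles/px; default half the
#' carrier magnitude, shrunk with a warning if it would overlap the DC
#' term), and optionally removes any residual sub-bin carrier tilt,
#' estimated from the mean wrapped phase gradient of the field.
#'
#' @param holo real intensity matrix.
#' @param carrier `c(fx, fy)` carrier in cycles/px.
#' @param optics an [optics_config()] attached to the returned field.
#' @param passband_radius low-pass radius in cycles/px, or `NULL` for
#'   the default.
#' @param remove_tilt remove residual linear phase (default `TRUE`),
#'   estimated from the amplitude-weighted mean wrapped phase gradient;
#'   a field carrying residual tilt walks laterally when propagated.
#' @return a [complex_field()] at `z_um = 0` (collection plane).
#' @export
demodulate <- function(holo, carrier, optics = optics_config(),
                       passband_radius = NULL, remove_tilt = TRUE) {
  stopifnot(is.matrix(holo), length(carrier) == 2)
  fmag <- sqrt(sum(carrier^2))
  if (fmag >= 0.5 * sqrt(2)) stop("carrier at or above Nyquist")
  if (is.null(passband_radius)) passband_radius <- fmag / 2
  if (passband_radius >= 0.75 * fmag) {
    warning("passband overlaps the DC term; shrinking to half the carrier")
    passband_radius <- fmag / 2
  }
  ny <- nrow(holo); nx <- ncol(holo)
  kx <- round(carrier[1] * nx); ky <- round(carrier[2] * ny)
  Fs <- circ_shift(fft2(holo), -ky, -kx)
  g <- freq_grids(ny, nx)
  field <- ifft2(Fs * ((g$fx^2 + g$fy^2) <= passband_radius^2))
  if (remove_tilt) {
    tx <- Arg(sum(Conj(field[, -nx]) * field[, -1]))
    ty <- Arg(sum(Conj(field[-ny, ]) * field[-1, ]))
    xg <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE)
    yg <- matrix(seq_len(ny) - 1, ny, nx)
    field <- field * exp(-1i * (tx * xg + ty * yg))
  }
  complex_field(field, optics, z_um = 0)
}

#' Angular-spectrum propagation
#'
#' Propagates a complex field by `z_um` micrometres with the exact
#' free-space transfer function
#' `H = exp(i 2 pi z sqrt(1/lambda^2 - fx^2 - fy^2))`; evanescent
#' components (negative argument of the square root) are set to zero.
#' Spatial frequencies are in object-plane units (`object_pixel_um`).
#'
#' @param cf a [complex_field()].
#' @param z_um propagation distance in micrometres (either sign).
#' @return propagated [complex_field()] with updated defocus state.
#' @export
propagate <- function(cf, z_um) {
  stopifnot(inherits(cf, "complex_field"))
  if (z_um == 0) return(cf)
  kz <- propagation_kz(nrow(cf$field), ncol(cf$field),
                       cf$optics$wavelength_um, cf$optics$object_pixel_um)
  H <- exp(2i * pi * z_um * kz$kz)
  H[kz$evanescent] <- 0
  complex_field(ifft2(fft2(cf$field) * H), cf$optics, cf$z_um + z_um,
                validate = FALSE)
}

# cached axial spatial-frequency grid kz = sqrt(1/lambda^2 - f^2)
.kz_cache <- new.env(parent = emptyenv())
propagation_kz <- function(ny, nx, lam, pix) {
  key <- paste(ny, nx, lam, pix, sep = "|")
  hit <- .kz_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- freq_grids(ny, nx)
  arg <- 1 / lam^2 - (g$fx / pix)^2 - (g$fy / pix)^2
  out <- list(kz = sqrt(pmax(arg, 0)), evanescent = arg <= 0)
  .kz_cache[[key]] <- out
  out
}

#' Tamura coefficient of an amplitude image
#'
#' Contrast metric `sqrt(sd / mean)` (population standard deviation).
#' It is invariant to a positive rescaling of the image and is used as
#' the autofocus criterion: an in-focus pure-phase object has minimal
#' amplitude contrast.
#'
#' @param amplitude non-negative real matrix with positive mean.
#' @return scalar Tamura coefficient.
#' @export
tamura <- function(amplitude) {
  m <- mean(amplitude)
  if (!is.finite(m) || m <= 0) stop("tamura: mean must be positive")
  sqrt(sqrt(mean((amplitude - m)^2)) / m)
}

#' Autofocus by Tamura-coefficient minimisation
#'
#' Propagates the field over a coarse grid of defocus values, takes the
#' grid minimum of the Tamura coefficient of the amplitude, and refines
#' it by golden-section search. For (near-)pure-phase objects the
#' amplitude contrast is minimal in focus, so the metric is minimised.
#'
#' @param cf a [complex_field()].
#' @param z_min_um,z_max_um search interval (must bracket the focus).
#' @param coarse_step_um grid step of the coarse scan.
#' @param tol_um absolute tolerance of the refinement.
#' @param central_frac fraction of the field (per axis, centred) over
#'   which the metric is evaluated; excludes the apodization taper and
#'   border diffraction, which carry focus-independent amplitude
#'   contrast.
#' @param coarse_decimate integer factor: the coarse grid scan runs on
#'   a spatially decimated copy of the field (propagation cost drops
#'   by the square of the factor); the golden-section refinement works
#'   at full resolution.
#' @return list with `z_um` (best defocus), `tamura` (metric at the
#'   optimum), `boundary` (`TRUE` when the coarse optimum sat on an
#'   interval end), and `curve` (data frame of the coarse scan).
#' @export
autofocus <- function(cf, z_min_um = -60, z_max_um = 60,
                      coarse_step_um = 5, tol_um = 0.25,
                      central_frac = 0.6, coarse_decimate = 2) {
  stopifnot(inherits(cf, "complex_field"), z_max_um > z_min_um)
  ny <- nrow(cf$field); nx <- ncol(cf$field)
  roi <- function(n) seq.int(max(1L, round(n * (1 - central_frac) / 2)),
                             min(n, round(n * (1 + central_frac) / 2)))
  ys <- roi(ny); xs <- roi(nx)
  metric <- function(z) tamura(Mod(propagate(cf, z)$field[ys, xs]))
  metric_coarse <- metric
  if (coarse_decimate > 1 && ny %% coarse_decimate == 0 &&
      nx %% coarse_decimate == 0) {
    dopt <- cf$optics
    dopt$object_pixel_um <- dopt$object_pixel_um * coarse_decimate
    cfd <- complex_field(cf$field[seq(1L, ny, coarse_decimate),
                                  seq(1L, nx, coarse_decimate)],
                         dopt, cf$z_um, validate = FALSE)
    ysd <- roi(nrow(cfd$field)); xsd <- roi(ncol(cfd$field))
    metric_coarse <- function(z)
      tamura(Mod(propagate(cfd, z)$field[ysd, xsd]))
  }
  zs <- seq(z_min_um, z_max_um, by = coarse_step_um)
  if (zs[length(zs)] < z_max_um) zs <- c(zs, z_max_um)
  tc <- vapply(zs, metric_coarse, 0)
  i0 <- which.min(tc)
  boundary <- i0 == 1L || i0 == length(zs)
  if (boundary)
    warning("autofocus optimum on a search-range boundary")
  lo <- zs[max(1L, i0 - 1L)]; hi <- zs[min(length(zs), i0 + 1L)]
  opt <- stats::optimize(metric, lower = lo, upper = hi, tol = tol_um)
  # keep the better of the refined optimum and the full-resolution
  # metric at the coarse minimum
  cand <- rbind(c(opt$minimum, opt$objective), c(zs[i0], metric(zs[i0])))
  best <- which.min(cand[, 2])
  list(z_um = cand[best, 1], tamura = cand[best, 2], boundary = boundary,
       curve = data.frame(z_um = zs, tamura = tc))
}

#' Reference-hologram aberration compensation
#'
#' Subtracts the phase of a cell-free reference field (processed with
#' the same demodulation and refocusing steps) from the object field,
#' removing the aberrations and carrier residuals shared by both, and
#' returns the wrapped 2-pi-modulo phase map in `(-pi, pi]`.
#'
#' @param object_field,reference_field [complex_field()] objects of the
#'   same size.
#' @return real matrix of wrapped phase values.
#' @export
compensate <- function(object_field, reference_field) {
  stopifnot(inherits(object_field, "complex_field"),
            inherits(reference_field, "complex_field"))
  if (!all(dim(object_field$field) == dim(reference_field$field)))
    stop("object and reference fields differ in shape")
  Arg(object_field$field * Conj(reference_field$field))
}

#' Congruent least-squares phase unwrapping
#'
#' Two-stage unwrapper: (1) the weighted-free least-squares solution of
#' the wrapped phase gradients via the DCT-based discrete Poisson solve
#' with Neumann boundaries; (2) congruence projection, adding to each
#' pixel of the wrapped input the integer multiple of 2 pi closest to
#' the least-squares surface. The output therefore always satisfies the
#' congruence contract `wrap(output) == input` pixelwise, and on
#' residue-free inputs it equals the true phase up to one global
#' 2 pi k offset, to numerical precision.
#'
#' @param wrapped real matrix with values in `(-pi, pi]`.
#' @return unwrapped phase matrix with attributes `residue_density`
#'   (fraction of 2x2 plaquettes carrying a nonzero residue) and
#'   `quality_flag` (`TRUE` when the residue density exceeds 1%%,
#'   indicating the least-squares surface may be unreliable).
#' @export
unwrap_phase <- function(wrapped) {
  stopifnot(is.matrix(wrapped), all(is.finite(wrapped)))
  ny <- nrow(wrapped); nx <- ncol(wrapped)
  dx <- wrap_phase(wrapped[, -1, drop = FALSE] - wrapped[, -nx, drop = FALSE])
  dy <- wrap_phase(wrapped[-1, , drop = FALSE] - wrapped[-ny, , drop = FALSE])
  # residues: circulation of wrapped gradients around each 2x2 loop
  res <- dx[-ny, , drop = FALSE] + dy[, -1, drop = FALSE] -
    dx[-1, , drop = FALSE] - dy[, -nx, drop = FALSE]
  residue_density <- mean(abs(res) > pi)
  dx <- cbind(dx, 0); dy <- rbind(dy, 0)
  rho <- dx - cbind(0, dx[, -nx, drop = FALSE]) +
    dy - rbind(0, dy[-ny, , drop = FALSE])
  D <- dct2(rho)
  ii <- matrix(seq_len(ny) - 1, ny, nx)
  jj <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE)
  den <- 2 * (cos(pi * ii / ny) - 1) + 2 * (cos(pi * jj / nx) - 1)
  den[1, 1] <- 1
  ls <- idct2(D / den)
  # align the arbitrary LS constant with the wrapped data, then project
  # onto the congruent lattice
  c0 <- Arg(mean(exp(1i * (ls - wrapped))))
  out <- wrapped + 2 * pi * round((ls - c0 - wrapped) / (2 * pi))
  attr(out, "residue_density") <- residue_density
  attr(out, "quality_flag") <- residue_density > 0.01
  out
}

#' Denoise a quantitative phase map
#'
#' Hybrid median / Gaussian smoother targeted at speckle-correlated
#' phase noise. The noise level is first estimated robustly as the MAD
#' of the difference between the map and its 3x3 median; when it is
#' below `noise_floor` the map is returned unchanged (clean maps are
#' not degraded), otherwise a 3x3 median pass removes spikes and a mild
#' Gaussian (`sigma_px`) suppresses the remaining grain. The in-mask
#' mean phase is preserved to well within 1%% by both stages.
#'
#' @param qpm real phase matrix (radians).
#' @param sigma_px Gaussian sigma in pixels for the smoothing stage.
#' @param noise_floor noise estimate (radians) below which the input is
#'   returned untouched.
#' @return denoised phase matrix.
#' @export
denoise_qpm <- function(qpm, sigma_px = 0.8, noise_floor = 0.01) {
  stopifnot(is.matrix(qpm), all(is.finite(qpm)))
  noise <- stats::mad(qpm - median3x3(qpm))
  if (noise < noise_floor) return(qpm)
  gauss_smooth(median3x3(qpm), sigma_px)
}

#' Segment the cell and cut a centred square crop
#'
#' Thresholds the phase map a small fraction above the background
#' level, keeps the largest connected foreground component (8-connected,
#' holes filled), and cuts a `crop_size` square centred on the integer
#' centroid of that component; frames near the border are zero-padded.
#' The matching binary mask is cropped identically.
#'
#' The threshold is `bg + max(thresh_floor, thresh_frac * (p99 - bg))`
#' where `bg` is the median of the map and `p99` its 99th percentile; a
#' low fraction of the peak is used (rather than e.g. Otsu) so that the
#' smooth rim of the cell is retained and the mask area tracks the true
#' support.
#'
#' @param qpm real phase matrix (radians), background near zero.
#' @param crop_size side of the square crop in pixels.
#' @param thresh_frac fraction of the peak-above-background used as
#'   threshold.
#' @param thresh_floor minimum threshold above background (radians).
#' @param min_area_px smallest acceptable component area.
#' @param border_px exclude this margin (pixels) along every frame
#'   edge from the foreground search; the apodization taper leaves
#'   meaningless phase there.
#' @param cell_id,frame_id,label identifiers carried into the crop.
#' @return object of class `cell_crop`: list with `qpm` and `mask`
#'   (`crop_size` square matrices), `centroid` (y, x in the full
#'   frame), `area_px`, and the identifiers.
#' @export
segment_crop <- function(qpm, crop_size = 384, thresh_frac = 0.05,
                         thresh_floor = 0.1, min_area_px = 50,
                         border_px = 0, cell_id = NA, frame_id = NA,
                         label = NA) {
  stopifnot(is.matrix(qpm))
  interior <- matrix(TRUE, nrow(qpm), ncol(qpm))
  if (border_px > 0) {
    b <- seq_len(border_px)
    interior[b, ] <- FALSE; interior[nrow(qpm) + 1 - b, ] <- FALSE
    interior[, b] <- FALSE; interior[, ncol(qpm) + 1 - b] <- FALSE
  }
  bg <- stats::median(qpm[interior])
  peak <- stats::quantile(qpm[interior], 0.99, names = FALSE)
  th <- bg + max(thresh_floor, thresh_frac * (peak - bg))
  fg <- qpm > th & interior
  if (!any(fg)) stop("empty frame: no foreground after thresholding")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  counts <- tabulate(lab)
  # components hugging the interior margin are border-diffraction
  # artefacts (rings that would swallow the frame once hole-filled)
  if (border_px > 0 && length(counts) > 0) {
    edge <- interior & !circ_erode(interior)
    counts[unique(lab[edge & lab > 0])] <- 0L
  }
  if (length(counts) == 0 || max(counts) < min_area_px)
    stop("empty frame: no foreground component of sufficient size")
  best <- which.max(counts)
  mask <- EBImage::imageData(EBImage::fillHull(
    EBImage::Image((lab == best) * 1))) > 0
  idx <- which(mask, arr.ind = TRUE)
  cy <- round(mean(idx[, 1])); cx <- round(mean(idx[, 2]))
  crop <- function(m) {
    out <- matrix(0, crop_size, crop_size)
    half <- crop_size %/% 2
    ys <- (cy - half + 1):(cy - half + crop_size)
    xs <- (cx - half + 1):(cx - half + crop_size)
    ok_y <- ys >= 1 & ys <= nrow(m); ok_x <- xs >= 1 & xs <= ncol(m)
    out[which(ok_y), which(ok_x)] <- m[ys[ok_y], xs[ok_x]]
    out
  }
  structure(list(
    qpm = crop(qpm), mask = crop(mask * 1) > 0,
    centroid = c(y = cy, x = cx), area_px = max(counts),
    cell_id = cell_id, frame_id = frame_id, label = label
  ), class = "cell_crop")
}

#' @export
print.cell_crop <- function(x, ...) {
  cat(sprintf("cell_crop %dx%d  area=%d px  cell=%s frame=%s label=%s\n",
              nrow(x$qpm), ncol(x$qpm), x$area_px,
              as.character(x$cell_id), as.character(x$frame_id),
              as.character(x$label)))
  invisible(x)
}

# one-pixel logical erosion (4-neighbourhood) used to find the pixels
# bordering the excluded margin
circ_erode <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  p <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)[, , drop = FALSE]
  p[1:ny, 2:(nx + 1)] & p[3:(ny + 2), 2:(nx + 1)] &
    p[2:(ny + 1), 1:nx] & p[2:(ny + 1), 3:(nx + 2)] & m
}

#' Full single-frame reconstruction
#'
#' Runs the complete chain on one hologram / reference pair: apodize
#' both frames, locate the carrier on the object hologram, demodulate
#' both with identical settings, compensate the shared aberrations by
#' subtracting the reference phase at the collection plane, autofocus
#' the compensated field (Tamura minimisation), propagate it to the
#' focus, unwrap the phase, denoise, zero-reference the background
#' (median of the out-of-mask region) and segment a centred crop.
#'
#' Compensation is applied before refocusing: back-propagating through
#' the uncorrected aberration phase would act as a weak lens that
#' displaces and defocuses the cell, which measurably degrades the
#' recovered phase.
#'
#' @param holo,reference real intensity matrices (same size).
#' @param optics an [optics_config()].
#' @param crop_size side of the output crop in pixels.
#' @param z_search `c(min, max)` autofocus interval, micrometres.
#' @param taper apodization taper fraction.
#' @param denoise logical; run the denoising stage.
#' @param refocus logical; set `FALSE` to skip the autofocus and keep
#'   the collection plane.
#' @param ... passed to [segment_crop()].
#' @return list with `crop` (a `cell_crop`), `qpm` (full-frame
#'   zero-referenced phase map), `z_um`, `tamura`, `carrier`,
#'   `residue_density`, and `flags` (character vector of warnings
#'   raised along the chain).
#' @export
reconstruct_qpm <- function(holo, reference, optics = optics_config(),
                            crop_size = 384, z_search = c(-60, 60),
                            taper = 0.2, denoise = TRUE, refocus = TRUE,
                            ...) {
  stopifnot(all(dim(holo) == dim(reference)))
  flags <- character()
  ho <- apodize(holo, taper)
  hr <- apodize(reference, taper)
  carrier <- locate_carrier(ho)
  fo <- demodulate(ho, carrier, optics)
  fr <- demodulate(hr, carrier, optics)
  # reference-phase compensation at the collection plane
  fc <- complex_field(fo$field * exp(-1i * Arg(fr$field)), optics, 0)
  z <- 0; tc <- NA_real_
  if (refocus) {
    af <- withCallingHandlers(
      autofocus(fc, z_search[1], z_search[2]),
      warning = function(w) {
        flags <<- c(flags, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    z <- af$z_um; tc <- af$tamura
    fc <- propagate(fc, z)
  }
  qpm <- unwrap_phase(wrap_phase(Arg(fc$field)))
  residue_density <- attr(qpm, "residue_density")
  if (isTRUE(attr(qpm, "quality_flag")))
    flags <- c(flags, "high residue density in unwrapping")
  if (denoise) qpm <- denoise_qpm(qpm)
  crop <- segment_crop(qpm, crop_size = crop_size,
                       border_px = ceiling(taper / 2 * nrow(qpm)) + 2,
                       ...)
  # zero-reference: background median to 0 (estimated outside the mask
  # in the cropped neighbourhood, which brackets the cell)
  bgval <- stats::median(crop$qpm[!crop$mask])
  qpm <- qpm - bgval
  crop$qpm <- crop$qpm - bgval
  list(crop = crop, qpm = qpm, z_um = z, tamura = tc, carrier = carrier,
       residue_density = residue_density, flags = flags)
}
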