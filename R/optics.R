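#' Optical configuration of the holographic microscope
#'
#' Bundles the parameters of the off-axis digital holographic microscope
#' that both the hologram simulator and the reconstruction pipeline need:
#' illumination wavelength, objective numerical aperture, lateral
#' magnification and the camera pixel pitch. The object-plane sampling
#' step is derived as `camera_pixel_um / magnification`.
#'
#' Defaults correspond to a 488 nm laser, a 20x/0.50 objective used at a
#' measured lateral magnification of 55, and a camera with 5.5 um square
#' pixels, i.e. an object-plane pixel of 0.1 um.
#'
#' @param wavelength_um illumination wavelength in micrometres.
#' @param NA_ numerical aperture of the imaging objective (0 < NA <= 1).
#' @param magnification lateral magnification of the imaging system.
#' @param camera_pixel_um camera pixel pitch in micrometres.
#' @return An object of class `optics_config`: a list with the four
#'   parameters plus the derived `object_pixel_um`.
#' @examples
#' oc <- optics_config()
#' oc$object_pixel_um   # 0.1
#' lateral_resolution(oc)
#' @export
optics_config <- function(wavelength_um = 0.488, NA_ = 0.50,
                          magnification = 55, camera_pixel_um = 5.5) {
  stopifnot(wavelength_um > 0, NA_ > 0, NA_ <= 1,
            magnification > 0, camera_pixel_um > 0)
  structure(list(
    wavelength_um   = wavelength_um,
    NA_             = NA_,
    magnification   = magnification,
    camera_pixel_um = camera_pixel_um,
    object_pixel_um = camera_pixel_um / magnification
  ), class = "optics_config")
}

#' Theoretical lateral resolution of the system
#'
#' Coherent-imaging estimate `0.82 * wavelength / NA`, in micrometres in
#' the object space.
#'
#' @param optics an [optics_config()].
#' @return lateral resolution in micrometres.
#' @export
lateral_resolution <- function(optics) {
  stopifnot(inherits(optics, "optics_config"))
  0.82 * optics$wavelength_um / optics$NA_
}

#' @export
print.optics_config <- function(x, ...) {
  cat("Holographic microscope optics\n")
  cat(sprintf("  wavelength      : %.3f um\n", x$wavelength_um))
  cat(sprintf("  NA              : %.2f\n", x$NA_))
  cat(sprintf("  magnification   : %g\n", x$magnification))
  cat(sprintf("  camera pixel    : %.2f um\n", x$camera_pixel_um))
  cat(sprintf("  object pixel    : %.4f um\n", x$object_pixel_um))
  cat(sprintf("  lateral res.    : %.2f um (0.82 lambda/NA)\n",
              lateral_resolution(x)))
  invisible(x)
}
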