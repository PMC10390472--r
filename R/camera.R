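#' Camera model for single-molecule movies
#'
#' Describes the analog-to-digital conversion of an EMCCD/sCMOS camera as used
#' for STORM acquisition: physical pixel size in the sample plane, gain
#' (photoelectrons per A/D count), digitizer baseline, and Gaussian read
#' noise. The defaults are the acquisition constants of the imaging system the
#' package emulates (97 nm pixels, 0.46 e-/ADU, baseline 97 ADU).
#'
#' @param pixel_size_nm camera pixel size in the sample plane (nm).
#' @param photoelectrons_per_adu conversion gain: photoelectrons per A/D count.
#' @param baseline_adu digitizer offset added to every pixel (A/D counts).
#' @param read_noise_e Gaussian read noise, standard deviation in electrons.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(pixel_size_nm = 97,
                         photoelectrons_per_adu = 0.46,
                         baseline_adu = 97,
                         read_noise_e = 1) {
  stopifnot(pixel_size_nm > 0, photoelectrons_per_adu > 0,
            baseline_adu >= 0, read_noise_e >= 0)
  structure(list(pixel_size_nm = pixel_size_nm,
                 photoelectrons_per_adu = photoelectrons_per_adu,
                 baseline_adu = baseline_adu,
                 read_noise_e = read_noise_e),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(paste0("<camera_model> pixel %.4g nm, %.3g e-/ADU, ",
                     "baseline %.4g ADU, read noise %.3g e-\n"),
              x$pixel_size_nm, x$photoelectrons_per_adu,
              x$baseline_adu, x$read_noise_e))
  invisible(x)
}

#' Convert camera A/D counts to photons
#'
#' Inverts the camera model: `photons = max(0, ADU - baseline) * gain`.
#' Values below the baseline (possible because read noise dips below it) are
#' clamped to zero photons, since negative photon counts are unphysical.
#'
#' @param x a `pixel_image` (or plain numeric array) in A/D counts.
#' @param camera a [camera_model()].
#' @return the same container with intensities in photon units.
#' @export
adu_to_photons <- function(x, camera) {
  stopifnot(inherits(camera, "camera_model"))
  conv <- function(m) pmax(m - camera$baseline_adu, 0) * camera$photoelectrons_per_adu
  if (inherits(x, "pixel_image")) {
    x$data <- conv(x$data)
    x
  } else {
    conv(x)
  }
}
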