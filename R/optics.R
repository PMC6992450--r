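## Closed-form Gaussian-beam and instrument-geometry optics.

#' Widefield axial point spread function
#'
#' Axial extent of a widefield focal spot, 2 * lambda / NA^2. At 520 nm and
#' NA 0.1 this is 104 um.
#'
#' @param wavelength_nm wavelength (nm), > 0.
#' @param na numerical aperture, > 0.
#' @return Axial PSF length (um).
#' @examples
#' axialPsf(520, 0.1)   # 104
#' @export
axialPsf <- function(wavelength_nm, na) {
  stopifnot(wavelength_nm > 0)
  if (any(na <= 0)) stop("na must be positive (formula diverges at na = 0)")
  2 * (wavelength_nm / 1000) / na^2
}

#' Rayleigh range of a Gaussian beam
#'
#' z_R = pi * w0^2 / lambda. Exactly one of \code{na} or \code{waist_um} must
#' be given; from the numerical aperture the waist is taken as the
#' diffraction-limited w0 = 0.61 * lambda / NA (the radius of the Airy-scaled
#' focal spot). At 520 nm and NA 0.1 this gives w0 = 3.17 um and z_R =
#' 60.8 um. Note that quoting a spot by its diameter and halving it is a
#' different waist convention and yields a different range (a 15-um waist at
#' 520 nm gives 1.36 mm); both conventions are reachable through
#' \code{waist_um}, neither is silently preferred.
#'
#' @param wavelength_nm wavelength (nm).
#' @param na numerical aperture (exclusive with \code{waist_um}).
#' @param waist_um beam waist radius w0 (um).
#' @return Rayleigh range (um).
#' @examples
#' rayleighRange(520, na = 0.1)       # 60.8
#' rayleighRange(520, waist_um = 15)  # about 1.4 mm
#' @export
rayleighRange <- function(wavelength_nm, na = NULL, waist_um = NULL) {
  stopifnot(wavelength_nm > 0)
  if (is.null(na) == is.null(waist_um))
    stop("supply exactly one of na or waist_um")
  lam_um <- wavelength_nm / 1000
  w0 <- if (!is.null(na)) {
    if (any(na <= 0)) stop("na must be positive")
    0.61 * lam_um / na
  } else {
    if (any(waist_um <= 0)) stop("waist_um must be positive")
    waist_um
  }
  pi * w0^2 / lam_um
}

#' Laser speckle camera field of view
#'
#' Object-plane field of view of the speckle camera: n_pixels * pixel pitch /
#' magnification. The defaults (2048 px, 5.5-um pitch, 2x) give 5.63 mm.
#'
#' @param n_pixels sensor pixels along one side.
#' @param pixel_pitch_um sensor pixel pitch (um).
#' @param magnification optical magnification.
#' @return Field of view (mm).
#' @export
lsciFieldOfView <- function(n_pixels = 2048, pixel_pitch_um = 5.5,
                            magnification = 2) {
  stopifnot(n_pixels > 0, pixel_pitch_um > 0, magnification > 0)
  n_pixels * pixel_pitch_um / magnification / 1000
}

#' OCT angiogram pixel size
#'
#' Lateral pixel size of the angiogram raster: field size over pixel count.
#' The defaults (600 um over 400 px) give 1.5 um.
#'
#' @param field_um lateral field size (um).
#' @param n_pixels raster pixels across the field.
#' @return Pixel size (um).
#' @export
octPixelSize <- function(field_um = 600, n_pixels = 400) {
  stopifnot(field_um > 0, n_pixels > 0)
  field_um / n_pixels
}

#' Closed-form optics table for the photoactivation beam
#'
#' Summarizes the focal geometry for one or more numerical apertures at a
#' given wavelength: diffraction-limited waist radius and spot diameter,
#' axial PSF and Rayleigh range.
#'
#' @param wavelength_nm wavelength (nm), default the 520-nm activation line.
#' @param na numerical apertures; defaults compare the tight (0.1) and loose
#'   (0.02) focusing cases.
#' @return data.frame with one row per NA.
#' @export
opticsTable <- function(wavelength_nm = 520, na = c(0.1, 0.02)) {
  w0 <- 0.61 * (wavelength_nm / 1000) / na
  data.frame(wavelength_nm = wavelength_nm, na = na, waist_um = w0,
             spot_diameter_um = 2 * w0,
             axial_psf_um = axialPsf(wavelength_nm, na),
             rayleigh_um = rayleighRange_vec(wavelength_nm, na))
}

# vectorized-over-na helper (rayleighRange checks its single-argument
# contract; the table needs plain vector math)
rayleighRange_vec <- function(wavelength_nm, na) {
  lam_um <- wavelength_nm / 1000
  pi * (0.61 * lam_um / na)^2 / lam_um
}

#' Photoactivation beam specification
#'
#' @param wavelength_nm laser wavelength (nm), default 520.
#' @param na numerical aperture in (0, 1).
#' @param power_mw post-objective power (mW); protocol values are 0.6 (full)
#'   and 0.3 (half).
#' @param waist_um beam waist radius (um); defaults to the
#'   diffraction-limited 0.61 * lambda / NA.
#' @return A list of class "BeamSpec".
#' @export
beamSpec <- function(wavelength_nm = 520, na = 0.1, power_mw = 0.6,
                     waist_um = NULL) {
  stopifnot(wavelength_nm > 0, na > 0, na < 1, power_mw >= 0)
  if (is.null(waist_um)) waist_um <- 0.61 * (wavelength_nm / 1000) / na
  stopifnot(waist_um > 0)
  structure(list(wavelength_nm = wavelength_nm, na = na,
                 power_mw = power_mw, waist_um = waist_um),
            class = "BeamSpec")
}

#' Tissue optical properties
#'
#' Defaults are typical of murine cortex near 520 nm: absorption 0.37 mm^-1,
#' scattering 23 mm^-1, Henyey-Greenstein anisotropy 0.89, relative
#' refractive index 1.37. All configurable; no quantitative result in this
#' package hinges on the defaults.
#'
#' @param mu_a_mm absorption coefficient (mm^-1), >= 0.
#' @param mu_s_mm scattering coefficient (mm^-1), >= 0.
#' @param g scattering anisotropy in (-1, 1).
#' @param n_rel tissue/immersion relative refractive index.
#' @return A list of class "TissueOptics".
#' @export
tissueOptics <- function(mu_a_mm = 0.37, mu_s_mm = 23, g = 0.89,
                         n_rel = 1.37) {
  stopifnot(mu_a_mm >= 0, mu_s_mm >= 0, g > -1, g < 1, n_rel > 0)
  structure(list(mu_a_mm = mu_a_mm, mu_s_mm = mu_s_mm, g = g, n_rel = n_rel),
            class = "TissueOptics")
}
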