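## Forward hemodynamic model: synthetic multispectral reflectance movies.

#' Bundled hemoglobin molar extinction coefficients
#'
#' Approximate molar extinction coefficients of oxy- and deoxyhemoglobin at
#' the default LED wavelengths, in cm^-1 M^-1, of the magnitude found in the
#' standard compiled hemoglobin spectra. They are configuration inputs: every
#' inversion takes its table as an argument and no result in this package
#' depends on these specific values, only on forward/inverse consistency.
#'
#' @return data.frame with columns wavelength_nm, eps_hbo, eps_hbr.
#' @export
defaultExtinctionTable <- function() {
  data.frame(wavelength_nm = c(470, 530, 625),
             eps_hbo = c(33209, 39036, 740),
             eps_hbr = c(16156, 39437, 5960))
}

#' Bundled wavelength-dependent pathlengths
#'
#' Representative mean pathlengths (cm) of diffusely reflected light in
#' cortical tissue at the default LED wavelengths, of the magnitude obtained
#' from Monte Carlo estimates of photon migration; longer where absorption is
#' weak (red) and short in the green. Configuration inputs like the
#' extinction table.
#'
#' @return data.frame with columns wavelength_nm, L_cm.
#' @export
defaultPathlengthTable <- function() {
  data.frame(wavelength_nm = c(470, 530, 625),
             L_cm = c(0.050, 0.057, 0.300))
}

#' Canonical block-design hemoglobin response
#'
#' Single-trial time courses of dHbO and dHbR for a block design (baseline,
#' stimulus, recovery): zero during baseline, a 2-s linear rise to plateau
#' during the stimulus, and an exponential return (tau = 3 s) during
#' recovery. A functional activation raises HbO and lowers HbR, so the
#' default peaks are +10 uM and -3 uM.
#'
#' @param design c(baseline_s, stim_s, recovery_s).
#' @param rate_hz per-wavelength sampling rate.
#' @param peak_dhbo,peak_dhbr plateau concentration changes (molar).
#' @return List with vectors dHbO, dHbR (length sum(design) * rate_hz).
#' @export
blockResponseTimecourse <- function(design = c(5, 5, 20), rate_hz = 10,
                                    peak_dhbo = 10e-6, peak_dhbr = -3e-6) {
  stopifnot(length(design) == 3L, all(design > 0), rate_hz > 0)
  t <- seq(0, sum(design) - 1 / rate_hz, by = 1 / rate_hz)
  on <- design[1]; off <- design[1] + design[2]
  shape <- numeric(length(t))
  rise <- t >= on & t < off
  shape[rise] <- pmin(1, (t[rise] - on) / 2)
  rec <- t >= off
  shape[rec] <- exp(-(t[rec] - off) / 3)
  list(dHbO = peak_dhbo * shape, dHbR = peak_dhbr * shape)
}

#' Specification of the hemodynamic forward model
#'
#' Bundles everything the generator needs: single-trial concentration time
#' courses, a spatial response footprint, the LED wavelengths, the block
#' design and the noise level.
#'
#' @param dHbO_t,dHbR_t single-trial time courses (molar), equal length
#'   \code{sum(design[1:3]) * rate_hz}; defaults from
#'   \code{\link{blockResponseTimecourse}}.
#' @param spatial_kernel response footprint (unitless weights in [0, 1]); the
#'   default is a centered Gaussian blob on a 32 x 32 grid.
#' @param wavelengths LED center wavelengths (nm); exactly the set used for
#'   inversion.
#' @param design c(baseline_s, stim_s, recovery_s), default c(5, 5, 20).
#' @param n_trials number of trials, default 20.
#' @param stim_rate_hz stimulus pulse rate (Hz), metadata only.
#' @param rate_hz per-wavelength frame rate (Hz), default 10.
#' @param noise_sd relative intensity noise (fraction, multiplicative).
#' @return A list of class "HemoForwardSpec".
#' @export
hemoForwardSpec <- function(dHbO_t = NULL, dHbR_t = NULL,
                            spatial_kernel = NULL,
                            wavelengths = c(470, 530, 625),
                            design = c(5, 5, 20), n_trials = 20L,
                            stim_rate_hz = 3, rate_hz = 10, noise_sd = 0) {
  stopifnot(all(design > 0), n_trials >= 1L, rate_hz > 0, noise_sd >= 0)
  if (is.null(dHbO_t) || is.null(dHbR_t)) {
    tc <- blockResponseTimecourse(design, rate_hz)
    if (is.null(dHbO_t)) dHbO_t <- tc$dHbO
    if (is.null(dHbR_t)) dHbR_t <- tc$dHbR
  }
  nt <- round(sum(design) * rate_hz)
  if (length(dHbO_t) != nt || length(dHbR_t) != nt)
    stop("time courses must have length sum(design) * rate_hz = ", nt)
  if (is.null(spatial_kernel)) {
    g <- seq(-1, 1, length.out = 32)
    spatial_kernel <- outer(g, g, function(x, y) exp(-(x^2 + y^2) / 0.18))
  }
  structure(list(dHbO_t = dHbO_t, dHbR_t = dHbR_t,
                 spatial_kernel = spatial_kernel,
                 wavelengths = wavelengths, design = design,
                 n_trials = as.integer(n_trials),
                 stim_rate_hz = stim_rate_hz, rate_hz = rate_hz,
                 noise_sd = noise_sd),
            class = "HemoForwardSpec")
}

# Look up table rows for a set of wavelengths; error on any missing one.
.lookupWavelengths <- function(table, wavelengths, what) {
  i <- match(wavelengths, table$wavelength_nm)
  if (anyNA(i))
    stop(what, " table is missing wavelength(s): ",
         paste(wavelengths[is.na(i)], collapse = ", "), " nm")
  table[i, , drop = FALSE]
}

#' Generate a synthetic multispectral reflectance movie
#'
#' Applies the attenuation model I(lambda, t) = I0(lambda) *
#' exp(-dmu_a(lambda, t) * L(lambda)) pixel-wise, with dmu_a =
#' eps_HbO * dHbO + eps_HbR * dHbR scaled by the spatial kernel, tiled over
#' \code{n_trials} block-design trials. At zero noise the movie inverts back
#' to the generator's concentration time courses to numerical precision
#' (forward/inverse round trip). Multiplicative Gaussian intensity noise of
#' relative sd \code{noise_sd} is added when requested.
#'
#' @param spec A "HemoForwardSpec" from \code{\link{hemoForwardSpec}}.
#' @param extinction extinction table covering all spec wavelengths.
#' @param pathlength pathlength table covering all spec wavelengths.
#' @param I0 baseline intensity (camera counts) per wavelength (scalar or
#'   vector over wavelengths).
#' @param seed integer seed for the noise draw.
#' @return A \linkS4class{MultispectralStack} with trial triggers at the
#'   start of every trial.
#' @examples
#' sp <- hemoForwardSpec(n_trials = 2, spatial_kernel = diag(8))
#' mv <- genMultispectralMovie(sp)
#' @export
genMultispectralMovie <- function(spec, extinction = defaultExtinctionTable(),
                                  pathlength = defaultPathlengthTable(),
                                  I0 = 1000, seed = NULL) {
  stopifnot(inherits(spec, "HemoForwardSpec"))
  ext <- .lookupWavelengths(extinction, spec$wavelengths, "extinction")
  pl <- .lookupWavelengths(pathlength, spec$wavelengths, "pathlength")
  nl <- length(spec$wavelengths)
  I0 <- rep_len(I0, nl)

  hbo_t <- rep(spec$dHbO_t, spec$n_trials)
  hbr_t <- rep(spec$dHbR_t, spec$n_trials)
  nt <- length(hbo_t)
  kern <- as.matrix(spec$spatial_kernel)
  h <- nrow(kern); w <- ncol(kern)
  kv <- as.vector(kern)

  fr <- array(NA_real_, c(h, w, nl, nt))
  for (l in seq_len(nl)) {
    dmua_t <- ext$eps_hbo[l] * hbo_t + ext$eps_hbr[l] * hbr_t  # cm^-1, peak
    att <- outer(kv, dmua_t * pl$L_cm[l])                      # px x t
    fr[, , l, ] <- I0[l] * exp(-att)
  }
  if (spec$noise_sd > 0) {
    fr <- .withSeed(seed, {
      fr * (1 + stats::rnorm(length(fr), sd = spec$noise_sd))
    })
    fr[fr < 0] <- 0
  }
  trig <- (seq_len(spec$n_trials) - 1L) * sum(spec$design)
  MultispectralStack(fr, wavelengths = spec$wavelengths,
                     rate_hz = spec$rate_hz, trigger_s = trig)
}
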