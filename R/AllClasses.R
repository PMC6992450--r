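#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- FlowPhantom

#' FlowPhantom: latent flow state of a speckle phantom
#'
#' Per-pixel speckle decorrelation times together with a stylized pial-vessel
#' mask and region labels (0 = background/remote parenchyma, 1 = stroke core,
#' 2 = remote reference region). The observable of this latent state is the
#' spatial speckle contrast: a pixel with decorrelation time tau_c imaged with
#' exposure T shows contrast K(T/tau_c, beta) (see
#' \code{\link{speckleContrastTheory}}).
#'
#' @slot tauC numeric matrix of decorrelation times (seconds), strictly
#'   positive everywhere.
#' @slot vesselMask logical matrix flagging target-vessel pixels.
#' @slot regionLabels integer matrix of ROI labels on the same grid.
#' @slot beta speckle coherence factor in (0, 1]; 1 for an ideal system.
#'
#' @seealso \code{\link{makeStrokePhantom}}, \code{\link{genSpeckleStack}}
#' @export
setClass("FlowPhantom",
  representation(tauC = "matrix", vesselMask = "matrix",
                 regionLabels = "matrix", beta = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.numeric(object@tauC) || any(!is.finite(object@tauC)) ||
        any(object@tauC <= 0))
      msg <- c(msg, "tauC must be finite and strictly positive everywhere")
    if (!identical(dim(object@tauC), dim(object@vesselMask)) ||
        !identical(dim(object@tauC), dim(object@regionLabels)))
      msg <- c(msg, "tauC, vesselMask and regionLabels must share one grid shape")
    if (!is.logical(object@vesselMask))
      msg <- c(msg, "vesselMask must be logical")
    if (length(object@beta) != 1L || object@beta <= 0 || object@beta > 1)
      msg <- c(msg, "beta must be a single value in (0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a FlowPhantom
#'
#' @param tauC numeric matrix of per-pixel decorrelation times (seconds).
#' @param vesselMask logical matrix of target-vessel pixels (default none).
#' @param regionLabels integer matrix of ROI labels (default all 0).
#' @param beta coherence factor in (0, 1].
#' @return A \linkS4class{FlowPhantom}.
#' @export
FlowPhantom <- function(tauC, vesselMask = NULL, regionLabels = NULL, beta = 1) {
  tauC <- as.matrix(tauC)
  if (is.null(vesselMask))
    vesselMask <- matrix(FALSE, nrow(tauC), ncol(tauC))
  if (is.null(regionLabels))
    regionLabels <- matrix(0L, nrow(tauC), ncol(tauC))
  storage.mode(regionLabels) <- "integer"
  new("FlowPhantom", tauC = tauC, vesselMask = vesselMask,
      regionLabels = regionLabels, beta = beta)
}

#' @rdname accessors
#' @export
setMethod("tauC", "FlowPhantom", function(object) object@tauC)
#' @rdname accessors
#' @export
setMethod("coherenceBeta", "FlowPhantom", function(object) object@beta)
#' @rdname accessors
#' @export
setMethod("vesselMask", "FlowPhantom", function(object) object@vesselMask)
#' @rdname accessors
#' @export
setMethod("regionLabels", "FlowPhantom", function(object) object@regionLabels)

setMethod("show", "FlowPhantom", function(object) {
  cat("FlowPhantom:", nrow(object@tauC), "x", ncol(object@tauC), "pixels\n")
  cat("  tau_c range:", format(range(object@tauC), digits = 3), "s\n")
  cat("  vessel pixels:", sum(object@vesselMask),
      " | core pixels:", sum(object@regionLabels == 1L),
      " | beta:", object@beta, "\n")
})

## --------------------------------------------------------------- SpeckleStack

#' SpeckleStack: raw time-integrated speckle frames
#'
#' A time-ordered stack of raw speckle frames (camera counts) with acquisition
#' metadata. The default metadata mirror a typical awake-imaging configuration:
#' 5-ms exposure at 40 frames per second.
#'
#' @slot frames numeric 3-D array (rows x cols x time).
#' @slot exposureS camera exposure (seconds); must not exceed 1/fps.
#' @slot fps frame rate (Hz).
#' @slot pixelSizeUm effective object-plane pixel pitch (micrometres).
#'
#' @seealso \code{\link{genSpeckleStack}}, \code{\link{spatialContrast}}
#' @export
setClass("SpeckleStack",
  representation(frames = "array", exposureS = "numeric", fps = "numeric",
                 pixelSizeUm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@frames)) != 3L)
      msg <- c(msg, "frames must be a 3-D array (rows x cols x time)")
    if (object@exposureS <= 0) msg <- c(msg, "exposureS must be positive")
    if (object@fps <= 0) msg <- c(msg, "fps must be positive")
    if (object@exposureS > 1 / object@fps + 1e-12)
      msg <- c(msg, "exposureS exceeds the frame interval 1/fps")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SpeckleStack
#'
#' @param frames numeric 3-D array (rows x cols x time), camera counts.
#' @param exposure_s exposure time (s).
#' @param fps frame rate (Hz).
#' @param pixel_size_um object-plane pixel pitch (um); the default is the
#'   5.5-um camera pitch divided by 2x magnification.
#' @return A \linkS4class{SpeckleStack}.
#' @export
SpeckleStack <- function(frames, exposure_s = 0.005, fps = 40,
                         pixel_size_um = 5.5 / 2) {
  new("SpeckleStack", frames = frames, exposureS = exposure_s, fps = fps,
      pixelSizeUm = pixel_size_um)
}

#' @rdname accessors
#' @export
setMethod("frames", "SpeckleStack", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("exposureTime", "SpeckleStack", function(object) object@exposureS)
#' @rdname accessors
#' @export
setMethod("frameRate", "SpeckleStack", function(object) object@fps)
#' @rdname accessors
#' @export
setMethod("pixelSize", "SpeckleStack", function(object) object@pixelSizeUm)

setMethod("show", "SpeckleStack", function(object) {
  d <- dim(object@frames)
  cat("SpeckleStack:", d[1], "x", d[2], "pixels,", d[3], "frames\n")
  cat("  exposure:", object@exposureS * 1e3, "ms | fps:", object@fps,
      "| pixel:", object@pixelSizeUm, "um\n")
})

## ----------------------------------------------------- ContrastMap / BFIMap

#' ContrastMap: spatial speckle contrast
#'
#' Per-pixel spatial contrast K = sd/mean computed over a sliding square bin.
#'
#' @slot K numeric matrix (one frame) or 3-D array (one map per frame);
#'   NA where the window mean is non-positive or, under border = "mask",
#'   within window/2 pixels of the frame border.
#' @slot window odd window side length (7 by default).
#' @export
setClass("ContrastMap",
  representation(K = "array", window = "integer"),
  validity = function(object) {
    msg <- NULL
    if (any(object@K < 0, na.rm = TRUE)) msg <- c(msg, "K must be >= 0")
    if (object@window < 3L || object@window %% 2L == 0L)
      msg <- c(msg, "window must be odd and >= 3")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname accessors
#' @export
setMethod("contrastValues", "ContrastMap", function(object) object@K)
#' @rdname accessors
#' @export
setMethod("windowSize", "ContrastMap", function(object) object@window)

setMethod("show", "ContrastMap", function(object) {
  cat("ContrastMap:", paste(dim(object@K), collapse = " x "),
      "| window:", object@window, "x", object@window, "\n")
  cat("  K range:", format(range(object@K, na.rm = TRUE), digits = 4), "\n")
})

#' BFIMap: blood flow index
#'
#' Per-pixel blood flow index BFI = 1/K^2, a relative flow surrogate. Pixels
#' whose contrast falls below the contrast floor are masked (NA) rather than
#' allowed to blow up.
#'
#' @slot bfi numeric matrix or 3-D array of 1/K^2 values, NA where masked.
#' @slot kFloor contrast floor below which BFI is masked.
#' @export
setClass("BFIMap",
  representation(bfi = "array", kFloor = "numeric"))

#' @rdname accessors
#' @export
setMethod("bfiValues", "BFIMap", function(object) object@bfi)

setMethod("show", "BFIMap", function(object) {
  cat("BFIMap:", paste(dim(object@bfi), collapse = " x "),
      "| k_floor:", object@kFloor, "\n")
  cat("  BFI range:", format(range(object@bfi, na.rm = TRUE), digits = 4), "\n")
})

## --------------------------------------------------------- MultispectralStack

#' MultispectralStack: demultiplexed multispectral reflectance movie
#'
#' Reflectance frames acquired under sequential LED illumination, stored
#' demultiplexed per wavelength: a 4-D array (rows x cols x wavelength x time)
#' sampled at per_wavelength_rate_hz per channel. The declared wavelength order
#' is the interleave order of the raw acquisition.
#'
#' @slot frames numeric 4-D array (rows x cols x n_wavelengths x n_time).
#' @slot wavelengths LED center wavelengths (nm), in interleave order.
#' @slot rateHz per-wavelength frame rate (Hz), 10 by default.
#' @slot triggerS trial onset timestamps (seconds).
#' @export
setClass("MultispectralStack",
  representation(frames = "array", wavelengths = "numeric",
                 rateHz = "numeric", triggerS = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@frames)
    if (length(d) != 4L)
      msg <- c(msg, "frames must be 4-D (rows x cols x wavelength x time)")
    else if (d[3] != length(object@wavelengths))
      msg <- c(msg, "third dimension must match length(wavelengths)")
    if (object@rateHz <= 0) msg <- c(msg, "rateHz must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a MultispectralStack
#'
#' @param frames 4-D array (rows x cols x wavelength x time).
#' @param wavelengths LED center wavelengths (nm), default c(470, 530, 625).
#' @param rate_hz per-wavelength sampling rate (Hz).
#' @param trigger_s trial onset times (s).
#' @return A \linkS4class{MultispectralStack}.
#' @export
MultispectralStack <- function(frames, wavelengths = c(470, 530, 625),
                               rate_hz = 10, trigger_s = numeric()) {
  new("MultispectralStack", frames = frames, wavelengths = wavelengths,
      rateHz = rate_hz, triggerS = trigger_s)
}

#' @rdname accessors
#' @export
setMethod("frames", "MultispectralStack", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("wavelengths", "MultispectralStack", function(object) object@wavelengths)
#' @rdname accessors
#' @export
setMethod("sampleRate", "MultispectralStack", function(object) object@rateHz)
#' @rdname accessors
#' @export
setMethod("triggerTimes", "MultispectralStack", function(object) object@triggerS)

setMethod("show", "MultispectralStack", function(object) {
  d <- dim(object@frames)
  cat("MultispectralStack:", d[1], "x", d[2], "px,",
      d[3], "wavelengths (", paste(object@wavelengths, collapse = "/"),
      "nm ),", d[4], "samples at", object@rateHz, "Hz per wavelength\n")
  cat(" ", length(object@triggerS), "trial triggers\n")
})

## ---------------------------------------------------------- HemodynamicSeries

#' HemodynamicSeries: hemoglobin concentration-change time courses
#'
#' Per-pixel time courses of oxy- and deoxyhemoglobin concentration change
#' (molar) recovered from multispectral optical-density changes. Total
#' hemoglobin change is not stored: \code{hbt()} returns dHbO + dHbR by
#' construction, so the identity holds exactly.
#'
#' @slot dHbO numeric 3-D array (rows x cols x time), molar.
#' @slot dHbR numeric 3-D array (rows x cols x time), molar.
#' @slot rateHz sampling rate (Hz).
#' @export
setClass("HemodynamicSeries",
  representation(dHbO = "array", dHbR = "array", rateHz = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@dHbO), dim(object@dHbR)))
      "dHbO and dHbR must have identical dimensions" else TRUE
  })

#' @rdname accessors
#' @export
setMethod("hbo", "HemodynamicSeries", function(object) object@dHbO)
#' @rdname accessors
#' @export
setMethod("hbr", "HemodynamicSeries", function(object) object@dHbR)
#' @rdname accessors
#' @export
setMethod("hbt", "HemodynamicSeries", function(object) object@dHbO + object@dHbR)
#' @rdname accessors
#' @export
setMethod("sampleRate", "HemodynamicSeries", function(object) object@rateHz)

setMethod("show", "HemodynamicSeries", function(object) {
  d <- dim(object@dHbO)
  cat("HemodynamicSeries:", d[1], "x", d[2], "px,", d[3], "samples at",
      object@rateHz, "Hz\n")
  cat("  |dHbT| max:", format(max(abs(object@dHbO + object@dHbR), na.rm = TRUE),
                              digits = 3), "M\n")
})

## ----------------------------------------------------------------- FluenceGrid

#' FluenceGrid: Monte Carlo deposited-energy field
#'
#' Voxelized absorbed photon weight from Monte Carlo transport of the focused
#' photoactivation beam, normalized per launched photon. Weight is conserved:
#' sum(deposited) + escapedWeight = 1 per photon within the Russian-roulette
#' tolerance.
#'
#' @slot deposited non-negative 3-D array (x, y, z) of absorbed weight per
#'   voxel, per launched photon.
#' @slot voxelSizeUm isotropic voxel edge (um).
#' @slot nPhotons number of photons launched.
#' @slot escapedWeight total escaped weight per launched photon.
#' @slot seed RNG seed used for the run.
#' @slot beam,tissue parameter echoes (lists) of the beam and tissue specs.
#' @export
setClass("FluenceGrid",
  representation(deposited = "array", voxelSizeUm = "numeric",
                 nPhotons = "numeric", escapedWeight = "numeric",
                 seed = "numeric", beam = "list", tissue = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@deposited)) != 3L)
      msg <- c(msg, "deposited must be 3-D")
    if (any(object@deposited < 0)) msg <- c(msg, "deposited must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname accessors
#' @export
setMethod("deposited", "FluenceGrid", function(object) object@deposited)
#' @rdname accessors
#' @export
setMethod("voxelSize", "FluenceGrid", function(object) object@voxelSizeUm)
#' @rdname accessors
#' @export
setMethod("escapedWeight", "FluenceGrid", function(object) object@escapedWeight)
#' @rdname accessors
#' @export
setMethod("nPhotons", "FluenceGrid", function(object) object@nPhotons)

setMethod("show", "FluenceGrid", function(object) {
  d <- dim(object@deposited)
  cat("FluenceGrid:", paste(d, collapse = " x "), "voxels at",
      object@voxelSizeUm, "um |", object@nPhotons, "photons\n")
  cat("  absorbed:", format(sum(object@deposited), digits = 5),
      "| escaped:", format(object@escapedWeight, digits = 5),
      "(per photon)\n")
})

## ------------------------------------------------------------ AngiogramVolume

#' AngiogramVolume: OCT flow-contrast volume
#'
#' Motion-contrast volume built from repeated B-scans: flowing blood
#' decorrelates between repeats and appears bright, static tissue dark.
#'
#' @slot voxels non-negative 3-D array (x, y, z) of flow contrast.
#' @slot voxelSizeUm voxel size (x, y, z) in um; 1.5-um lateral by default.
#' @slot nRepeatsAveraged number of repeat-pair angiograms averaged.
#' @export
setClass("AngiogramVolume",
  representation(voxels = "array", voxelSizeUm = "numeric",
                 nRepeatsAveraged = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@voxels)) != 3L) msg <- c(msg, "voxels must be 3-D")
    if (any(object@voxels < 0)) msg <- c(msg, "voxels must be >= 0")
    if (length(object@voxelSizeUm) != 3L)
      msg <- c(msg, "voxelSizeUm must have length 3 (x, y, z)")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname accessors
#' @export
setMethod("angioVoxels", "AngiogramVolume", function(object) object@voxels)
#' @rdname accessors
#' @export
setMethod("voxelSize", "AngiogramVolume", function(object) object@voxelSizeUm)
#' @rdname accessors
#' @export
setMethod("nRepeatsAveraged", "AngiogramVolume",
          function(object) object@nRepeatsAveraged)

setMethod("show", "AngiogramVolume", function(object) {
  cat("AngiogramVolume:", paste(dim(object@voxels), collapse = " x "),
      "voxels at", paste(object@voxelSizeUm, collapse = " x "), "um\n")
  cat("  averaged over", object@nRepeatsAveraged, "repeat pairs\n")
})

## -------------------------------------------------------------- CapillaryMask

#' CapillaryMask: segmented flowing capillaries in a sub-surface slab
#'
#' Binary mask of flowing-capillary voxels inside a slab below the surface
#' vessels, with the lateral footprint of the large pial vessels excluded.
#' The mask is FALSE everywhere outside the slab by construction.
#'
#' @slot mask logical 3-D array, same shape as the source volume.
#' @slot slabUm c(z_top, z_bottom) of the slab (um below the surface).
#' @slot exclusion logical lateral (x, y) matrix of excluded surface-vessel
#'   footprint.
#' @slot voxelSizeUm voxel size (x, y, z) in um.
#' @slot density flowing fraction of included slab voxels.
#' @export
setClass("CapillaryMask",
  representation(mask = "array", slabUm = "numeric", exclusion = "matrix",
                 voxelSizeUm = "numeric", density = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
    if (length(object@slabUm) != 2L || diff(object@slabUm) <= 0)
      msg <- c(msg, "slabUm must be c(z_top, z_bottom) with z_bottom > z_top")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname accessors
#' @export
setMethod("maskArray", "CapillaryMask", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("slabRange", "CapillaryMask", function(object) object@slabUm)
#' @rdname accessors
#' @export
setMethod("capillaryDensity", "CapillaryMask", function(object) object@density)
#' @rdname accessors
#' @export
setMethod("exclusionMask", "CapillaryMask", function(object) object@exclusion)
#' @rdname accessors
#' @export
setMethod("voxelSize", "CapillaryMask", function(object) object@voxelSizeUm)

setMethod("show", "CapillaryMask", function(object) {
  cat("CapillaryMask: slab", object@slabUm[1], "-", object@slabUm[2], "um,",
      sum(object@mask), "flowing voxels\n")
  cat("  density:", format(object@density, digits = 4),
      "| excluded footprint:", sum(object@exclusion), "px\n")
})

## -------------------------------------------------------------- ProtocolTrace

#' ProtocolTrace: laser-state sequence of an illumination protocol
#'
#' Timestamped laser-state events emitted either by the feedback-guided
#' (optimized) occlusion controller or by the fixed-duration (nonoptimized)
#' protocol. States are FULL (0.6 mW post-objective), HALF (0.3 mW) and OFF.
#'
#' @slot events data.frame with columns t_s, state, power_mw; states change
#'   only at these timestamps.
#' @slot timeS sample clock of the input traces (s); empty for open-loop runs.
#' @slot vesselDrop percent BFI drop time course in the target-vessel ROI.
#' @slot regionDrop percent BFI drop time course in the supplied-region ROI.
#' @slot confirmed logical: both the vessel-drop and region-drop confirmation
#'   criteria were met (NA for open-loop runs).
#' @slot params parameter list of the guidance automaton.
#' @export
setClass("ProtocolTrace",
  representation(events = "data.frame", timeS = "numeric",
                 vesselDrop = "numeric", regionDrop = "numeric",
                 confirmed = "logical", params = "list"),
  validity = function(object) {
    msg <- NULL
    need <- c("t_s", "state", "power_mw")
    if (!all(need %in% names(object@events)))
      msg <- c(msg, "events needs columns t_s, state, power_mw")
    else {
      if (!all(object@events$state %in% c("FULL", "HALF", "OFF")))
        msg <- c(msg, "states must be FULL, HALF or OFF")
      if (!all(object@events$power_mw %in% c(0.6, 0.3, 0)))
        msg <- c(msg, "power values must be 0.6, 0.3 or 0 mW")
      if (is.unsorted(object@events$t_s))
        msg <- c(msg, "event timestamps must be non-decreasing")
    }
    if (is.null(msg)) TRUE else msg
  })

#' @rdname accessors
#' @export
setMethod("protocolEvents", "ProtocolTrace", function(object) object@events)
#' @rdname accessors
#' @export
setMethod("occlusionConfirmed", "ProtocolTrace", function(object) object@confirmed)

setMethod("show", "ProtocolTrace", function(object) {
  cat("ProtocolTrace:", nrow(object@events), "events\n")
  if (nrow(object@events))
    print(utils::head(object@events, 8))
  cat("  occlusion confirmed:", object@confirmed, "\n")
})
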