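#' Accessor generics
#'
#' Accessors for the container classes of the package. Each returns the
#' corresponding slot (or a quantity derived from it, as documented on the
#' class page) rather than requiring direct slot access.
#'
#' @param object A PhotoStroke container object.
#' @return The slot value; see the class documentation for details.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("exposureTime", function(object) standardGeneric("exposureTime"))

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("tauC", function(object) standardGeneric("tauC"))

#' @rdname accessors
#' @export
setGeneric("coherenceBeta", function(object) standardGeneric("coherenceBeta"))

#' @rdname accessors
#' @export
setGeneric("vesselMask", function(object) standardGeneric("vesselMask"))

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))

#' @rdname accessors
#' @export
setGeneric("contrastValues", function(object) standardGeneric("contrastValues"))

#' @rdname accessors
#' @export
setGeneric("windowSize", function(object) standardGeneric("windowSize"))

#' @rdname accessors
#' @export
setGeneric("bfiValues", function(object) standardGeneric("bfiValues"))

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("triggerTimes", function(object) standardGeneric("triggerTimes"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("hbo", function(object) standardGeneric("hbo"))

#' @rdname accessors
#' @export
setGeneric("hbr", function(object) standardGeneric("hbr"))

#' @rdname accessors
#' @export
setGeneric("hbt", function(object) standardGeneric("hbt"))

#' @rdname accessors
#' @export
setGeneric("deposited", function(object) standardGeneric("deposited"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("escapedWeight", function(object) standardGeneric("escapedWeight"))

#' @rdname accessors
#' @export
setGeneric("nPhotons", function(object) standardGeneric("nPhotons"))

#' @rdname accessors
#' @export
setGeneric("angioVoxels", function(object) standardGeneric("angioVoxels"))

#' @rdname accessors
#' @export
setGeneric("nRepeatsAveraged", function(object) standardGeneric("nRepeatsAveraged"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("slabRange", function(object) standardGeneric("slabRange"))

#' @rdname accessors
#' @export
setGeneric("capillaryDensity", function(object) standardGeneric("capillaryDensity"))

#' @rdname accessors
#' @export
setGeneric("exclusionMask", function(object) standardGeneric("exclusionMask"))

#' @rdname accessors
#' @export
setGeneric("protocolEvents", function(object) standardGeneric("protocolEvents"))

#' @rdname accessors
#' @export
setGeneric("occlusionConfirmed", function(object) standardGeneric("occlusionConfirmed"))

#' Spatial speckle contrast
#'
#' Compute the spatial speckle contrast K = sd/mean over a sliding square
#' window, per pixel (for a single frame) or per frame (for a stack).
#'
#' @param object A numeric matrix (one raw speckle frame, camera counts) or a
#'   \linkS4class{SpeckleStack}.
#' @param window Odd integer window side length; the default 7 gives the
#'   conventional 7x7 bin.
#' @param border Either "reflect" (symmetric padding so that K is defined at
#'   every pixel) or "mask" (pixels closer than window/2 to the border are NA).
#' @return A \linkS4class{ContrastMap} whose K slot is a matrix (frame input)
#'   or a 3-D array with one contrast map per frame (stack input).
#' @export
setGeneric("spatialContrast", function(object, window = 7L,
                                       border = c("reflect", "mask"))
  standardGeneric("spatialContrast"))
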