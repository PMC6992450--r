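## Plumbing: TIFF stacks with JSON sidecars, CSV tables.

# TIFF stores [0, 1] floats; the sidecar records the scale to invert.
.writeStackTiff <- function(arr, path, meta = list()) {
  d <- dim(arr)
  if (length(d) == 2L) arr <- array(arr, c(d, 1L))
  mn <- min(arr, na.rm = TRUE)
  mx <- max(arr, na.rm = TRUE)
  offset <- if (is.finite(mn)) mn else 0
  scale <- if (is.finite(mx) && mx > offset) mx - offset else 1
  pages <- lapply(seq_len(dim(arr)[3]), function(k) {
    m <- (arr[, , k] - offset) / scale
    m[!is.finite(m)] <- 0
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta$intensity_offset <- offset
  meta$intensity_scale <- scale
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.readStackTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  offset <- if (!is.null(meta$intensity_offset)) meta$intensity_offset else 0
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * scale + offset
  list(frames = arr, meta = meta)
}

#' Write / read a speckle stack as multi-page TIFF plus JSON sidecar
#'
#' The sidecar records exposure, frame rate, pixel pitch and the intensity
#' scale used to map counts into the TIFF's [0, 1] float range.
#'
#' @param stack A \linkS4class{SpeckleStack}.
#' @param path TIFF file path (the sidecar gets the same path + ".json").
#' @return \code{writeSpeckleStack}: the path, invisibly;
#'   \code{readSpeckleStack}: a \linkS4class{SpeckleStack}.
#' @export
writeSpeckleStack <- function(stack, path) {
  stopifnot(is(stack, "SpeckleStack"))
  .writeStackTiff(frames(stack), path,
                  list(kind = "speckle_stack",
                       exposure_s = exposureTime(stack),
                       fps = frameRate(stack),
                       pixel_size_um = pixelSize(stack),
                       n_frames = dim(frames(stack))[3]))
}

#' @rdname writeSpeckleStack
#' @param path TIFF file path written by \code{writeSpeckleStack}.
#' @export
readSpeckleStack <- function(path) {
  r <- .readStackTiff(path)
  SpeckleStack(r$frames, exposure_s = r$meta$exposure_s, fps = r$meta$fps,
               pixel_size_um = r$meta$pixel_size_um)
}

#' Write protocol events or ROI traces as CSV
#'
#' @param trace A \linkS4class{ProtocolTrace}.
#' @param path CSV output path.
#' @return The path, invisibly.
#' @export
writeProtocolTrace <- function(trace, path) {
  stopifnot(is(trace, "ProtocolTrace"))
  utils::write.csv(protocolEvents(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProtocolTrace
#' @param traces data.frame (t_s, roi, percent_baseline) from
#'   \code{\link{relativeCBF}}.
#' @export
writeRoiTraces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' Write / read paw-contact event logs as CSV
#'
#' @param log data.frame from \code{\link{genPawEvents}}.
#' @param path CSV path.
#' @return \code{writePawEvents}: the path, invisibly;
#'   \code{readPawEvents}: the event data.frame.
#' @export
writePawEvents <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePawEvents
#' @export
readPawEvents <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
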