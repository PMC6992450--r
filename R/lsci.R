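## Spatial speckle-contrast flowmetry: K, BFI, relative CBF.

# Contrast of a single frame. Reflect padding keeps K defined at every pixel;
# "mask" leaves an NA border of window/2 instead.
.contrastFrame <- function(frame, window, border) {
  stopifnot(is.numeric(frame), window %% 2L == 1L, window >= 3L)
  if (window > min(dim(frame)))
    stop("window (", window, ") larger than the frame")
  n <- window^2
  if (border == "reflect") {
    p <- .padReflect(frame, window %/% 2L)
    s1 <- .boxSum(p, window)
    s2 <- .boxSum(p^2, window)
    mu <- s1 / n
    v <- (s2 - s1^2 / n) / (n - 1)
    v[v < 0] <- 0
    K <- sqrt(v) / mu
    K[!is.finite(K) | mu <= 0] <- NA_real_
    K
  } else {
    s1 <- .boxSum(frame, window)
    s2 <- .boxSum(frame^2, window)
    mu <- s1 / n
    v <- (s2 - s1^2 / n) / (n - 1)
    v[v < 0] <- 0
    Kin <- sqrt(v) / mu
    Kin[!is.finite(Kin) | mu <= 0] <- NA_real_
    K <- matrix(NA_real_, nrow(frame), ncol(frame))
    r <- window %/% 2L
    K[(r + 1L):(nrow(frame) - r), (r + 1L):(ncol(frame) - r)] <- Kin
    K
  }
}

#' @rdname spatialContrast
#' @export
setMethod("spatialContrast", "matrix",
  function(object, window = 7L, border = c("reflect", "mask")) {
    border <- match.arg(border)
    K <- .contrastFrame(object, as.integer(window), border)
    new("ContrastMap", K = K, window = as.integer(window))
  })

#' @rdname spatialContrast
#' @export
setMethod("spatialContrast", "SpeckleStack",
  function(object, window = 7L, border = c("reflect", "mask")) {
    border <- match.arg(border)
    fr <- frames(object)
    d <- dim(fr)
    K <- array(NA_real_, d)
    for (t in seq_len(d[3]))
      K[, , t] <- .contrastFrame(fr[, , t], as.integer(window), border)
    new("ContrastMap", K = K, window = as.integer(window))
  })

#' Blood flow index from speckle contrast
#'
#' BFI = 1/K^2, the conventional relative flow surrogate: in the exposure >>
#' tau_c regime 1/K^2 is proportional to the inverse decorrelation time and
#' hence to scatterer speed. Contrast values below \code{k_floor} are masked
#' (NA) so that noise- or saturation-flattened pixels do not explode.
#'
#' @param cmap A \linkS4class{ContrastMap}.
#' @param k_floor positive contrast floor; pixels with K < k_floor are NA.
#' @return A \linkS4class{BFIMap} with the same dimensions as the input.
#' @examples
#' cm <- spatialContrast(matrix(rexp(64^2), 64))
#' bfi <- bloodFlowIndex(cm)
#' @export
bloodFlowIndex <- function(cmap, k_floor = 1e-3) {
  stopifnot(is(cmap, "ContrastMap"), k_floor > 0)
  K <- contrastValues(cmap)
  b <- 1 / K^2
  b[is.na(K) | K < k_floor] <- NA_real_
  new("BFIMap", bfi = b, kFloor = k_floor)
}

#' Relative cerebral blood flow from a speckle stack
#'
#' Converts a raw speckle stack to per-frame BFI maps, normalizes by the mean
#' baseline BFI and expresses flow as percent of baseline, with per-ROI mean
#' time courses. ROI traces are smoothed with a centered sliding mean
#' (1 s by default); frames inside declared gap intervals (e.g. animal
#' repositioning) are explicit NAs, never interpolated.
#'
#' @param stack A \linkS4class{SpeckleStack}.
#' @param baseline_frames integer indices of the baseline frames; must be
#'   non-empty and precede the earliest analysis frame they are compared to.
#' @param rois named list of logical masks (frame-shaped).
#' @param window contrast window (odd, default 7).
#' @param k_floor contrast floor for BFI masking.
#' @param smooth_s width of the centered sliding mean applied to the ROI
#'   traces (seconds); 0 disables smoothing.
#' @param gaps optional list of c(start_s, end_s) intervals marked missing.
#' @return List with \code{percent_map} (mean percent-of-baseline map over
#'   all frames), \code{traces} (data.frame t_s, roi, percent_baseline) and
#'   \code{baseline_bfi} (the baseline mean BFI map).
#' @examples
#' ph <- makeStrokePhantom(c(64, 64))
#' st <- genSpeckleStack(ph, n_frames = 8, seed = 1)
#' r <- relativeCBF(st, 1:4, list(vessel = vesselMask(ph)))
#' @export
relativeCBF <- function(stack, baseline_frames, rois, window = 7L,
                        k_floor = 1e-3, smooth_s = 1, gaps = NULL) {
  stopifnot(is(stack, "SpeckleStack"), is.list(rois), length(rois) >= 1L)
  fr <- frames(stack)
  nt <- dim(fr)[3]
  baseline_frames <- as.integer(baseline_frames)
  if (length(baseline_frames) == 0L || any(baseline_frames < 1L) ||
      any(baseline_frames > nt))
    stop("empty or out-of-range baseline window")
  if (is.null(names(rois)) || any(!nzchar(names(rois))))
    names(rois) <- paste0("roi", seq_along(rois))
  for (m in rois)
    if (!identical(dim(m), dim(fr)[1:2]))
      stop("ROI mask shape does not match the frames")

  b <- bfiValues(bloodFlowIndex(spatialContrast(stack, window = window),
                                k_floor = k_floor))
  base_map <- apply(b[, , baseline_frames, drop = FALSE], c(1, 2), mean,
                    na.rm = TRUE)
  pct <- 100 * sweep(b, c(1, 2), base_map, "/")
  t_s <- (seq_len(nt) - 1L) / frameRate(stack)

  in_gap <- rep(FALSE, nt)
  for (g in gaps)
    in_gap <- in_gap | (t_s >= g[1] & t_s <= g[2])

  k <- max(1L, round(smooth_s * frameRate(stack)))
  traces <- do.call(rbind, lapply(names(rois), function(nm) {
    m <- rois[[nm]]
    tr <- vapply(seq_len(nt), function(t) mean(pct[, , t][m], na.rm = TRUE),
                 numeric(1))
    if (k > 1L) {
      sm <- stats::filter(tr, rep(1 / k, k), sides = 2)
      tr <- ifelse(is.na(sm), tr, as.numeric(sm))  # keep ends unsmoothed
    }
    tr[in_gap] <- NA_real_
    data.frame(t_s = t_s, roi = nm, percent_baseline = tr,
               stringsAsFactors = FALSE)
  }))
  pct_map <- apply(pct, c(1, 2), mean, na.rm = TRUE)
  list(percent_map = pct_map, traces = traces, baseline_bfi = base_map)
}
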