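## Modified Beer-Lambert analysis: dOD -> dmu_a -> dHbO/dHbR -> dHbT.

# Per-trial sample index ranges from trigger times.
.trialRanges <- function(nt, trigger_s, rate_hz) {
  if (!length(trigger_s)) trigger_s <- 0
  start <- round(trigger_s * rate_hz) + 1L
  end <- c(start[-1L] - 1L, nt)
  keep <- start <= nt
  data.frame(start = start[keep], end = pmin(end[keep], nt))
}

#' Change in optical density
#'
#' Computes dOD(lambda, t) = -ln(I / I0) per pixel and wavelength, with the
#' baseline intensity I0 taken as the per-trial mean of the first
#' \code{baseline_s} seconds of each trial (so slow drifts between trials do
#' not leak into the response). Non-positive intensities are masked (NA) with
#' a warning.
#'
#' @param stack A \linkS4class{MultispectralStack}.
#' @param baseline_s baseline duration at the start of every trial (s).
#' @return Numeric 4-D array of dOD, same shape as \code{frames(stack)}.
#' @export
deltaOD <- function(stack, baseline_s = 5) {
  stopifnot(is(stack, "MultispectralStack"), baseline_s > 0)
  fr <- frames(stack)
  d <- dim(fr)
  bad <- fr <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive intensities masked")
    fr[bad] <- NA_real_
  }
  tr <- .trialRanges(d[4], triggerTimes(stack), sampleRate(stack))
  nb <- max(1L, round(baseline_s * sampleRate(stack)))
  dod <- array(NA_real_, d)
  for (k in seq_len(nrow(tr))) {
    idx <- tr$start[k]:tr$end[k]
    bidx <- idx[seq_len(min(nb, length(idx)))]
    i0 <- apply(fr[, , , bidx, drop = FALSE], 1:3, mean, na.rm = TRUE)
    dod[, , , idx] <- -log(sweep(fr[, , , idx, drop = FALSE], 1:3, i0, "/"))
  }
  dod
}

#' Absorption-coefficient change from optical density
#'
#' Inverts the attenuation model I = I0 exp(-dmu_a L): dmu_a(lambda, t) =
#' dOD(lambda, t) / L(lambda), element-wise per wavelength.
#'
#' @param dod 4-D dOD array (rows x cols x wavelength x time).
#' @param pathlength table with columns wavelength_nm, L_cm covering
#'   \code{wavelengths}.
#' @param wavelengths the stack's wavelengths (nm), in the dOD wavelength
#'   order.
#' @return 4-D array of dmu_a (cm^-1), same shape.
#' @export
invertMua <- function(dod, pathlength, wavelengths) {
  stopifnot(length(dim(dod)) == 4L, dim(dod)[3] == length(wavelengths))
  pl <- .lookupWavelengths(pathlength, wavelengths, "pathlength")
  if (any(pl$L_cm <= 0)) stop("pathlengths must be positive")
  mua <- dod
  for (l in seq_along(wavelengths))
    mua[, , l, ] <- dod[, , l, ] / pl$L_cm[l]
  mua
}

#' Hemoglobin concentration changes from absorption changes
#'
#' Solves, per pixel and time point, the overdetermined linear system
#' dmu_a(lambda) = eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR across the
#' stack wavelengths by ordinary least squares (three equations, two
#' unknowns for the default LED set). The extinction matrix must have at
#' least two wavelengths and be well conditioned.
#'
#' @param mua 4-D dmu_a array (rows x cols x wavelength x time), cm^-1.
#' @param extinction table with columns wavelength_nm, eps_hbo, eps_hbr.
#' @param wavelengths the wavelengths (nm) along dim 3 of \code{mua}.
#' @param rate_hz sampling rate recorded in the result.
#' @param max_condition reject if the extinction matrix condition number
#'   exceeds this.
#' @return A \linkS4class{HemodynamicSeries}.
#' @export
solveHemoglobin <- function(mua, extinction, wavelengths, rate_hz = 10,
                            max_condition = 1e6) {
  stopifnot(length(dim(mua)) == 4L)
  if (length(wavelengths) < 2L)
    stop("at least two wavelengths are required (system underdetermined)")
  ext <- .lookupWavelengths(extinction, wavelengths, "extinction")
  E <- cbind(ext$eps_hbo, ext$eps_hbr)
  sv <- svd(E)$d
  cond <- sv[1] / sv[length(sv)]
  if (!is.finite(cond) || cond > max_condition)
    stop("extinction matrix ill-conditioned (condition number ",
         format(cond, digits = 4), ")")
  d <- dim(mua)
  M <- matrix(aperm(mua, c(3L, 1L, 2L, 4L)), nrow = d[3])
  P <- solve(crossprod(E), t(E))      # 2 x n_lambda pseudoinverse
  coef <- P %*% M                      # 2 x (px * t)
  new("HemodynamicSeries",
      dHbO = array(coef[1L, ], c(d[1], d[2], d[4])),
      dHbR = array(coef[2L, ], c(d[1], d[2], d[4])),
      rateHz = rate_hz)
}

#' Block-design trial averaging and stimulus response map
#'
#' Aligns a hemodynamic series on the trial design, averages across complete
#' trials and returns the trial-mean series together with the stimulus-period
#' response map: the time-mean of dHbT over the stimulus window, the map used
#' to locate the responding cortical territory. A truncated final trial is
#' dropped with a warning.
#'
#' @param series A \linkS4class{HemodynamicSeries}.
#' @param design c(baseline_s, stim_s, recovery_s), default c(5, 5, 20).
#' @param trigger_s trial onsets (s); defaults to contiguous tiling from 0.
#' @return List with \code{trial} (trial-mean \linkS4class{HemodynamicSeries}),
#'   \code{response_map} (matrix of stimulus-window dHbT), and
#'   \code{n_trials_used}.
#' @export
blockAverage <- function(series, design = c(5, 5, 20), trigger_s = NULL) {
  stopifnot(is(series, "HemodynamicSeries"), length(design) == 3L,
            all(design > 0))
  rate <- sampleRate(series)
  nt <- dim(hbo(series))[3]
  len <- round(sum(design) * rate)
  if (is.null(trigger_s))
    trigger_s <- seq(0, by = sum(design),
                     length.out = max(1L, nt %/% len))
  start <- round(trigger_s * rate) + 1L
  complete <- start + len - 1L <= nt
  if (!all(complete))
    warning(sum(!complete), " truncated trial(s) dropped")
  start <- start[complete]
  if (!length(start)) stop("no complete trial in the series")

  acc <- function(a) {
    out <- array(0, c(dim(a)[1:2], len))
    for (s in start) out <- out + a[, , s:(s + len - 1L)]
    out / length(start)
  }
  trial <- new("HemodynamicSeries", dHbO = acc(hbo(series)),
               dHbR = acc(hbr(series)), rateHz = rate)
  stim_idx <- (round(design[1] * rate) + 1L):round((design[1] + design[2]) * rate)
  response <- apply(hbt(trial)[, , stim_idx, drop = FALSE], c(1, 2), mean)
  list(trial = trial, response_map = response,
       n_trials_used = length(start))
}

#' Candidate responding region from a stimulus response map
#'
#' Thresholds the response map at a fraction of its maximum and returns the
#' connected region(s) above threshold, flagging the largest component as
#' the candidate target territory. Choosing the vessel that supplies it
#' remains an operator decision.
#'
#' @param map numeric response-map matrix.
#' @param threshold_fraction fraction of the map maximum in (0, 1).
#' @return List with \code{mask} (all pixels above threshold),
#'   \code{largest} (largest connected component), \code{labels}
#'   (component labels) and \code{localized} (FALSE when the mask covers the
#'   entire field).
#' @export
responseROI <- function(map, threshold_fraction = 0.5) {
  stopifnot(is.matrix(map), threshold_fraction > 0, threshold_fraction < 1)
  mx <- max(map, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("empty response map")
  mask <- !is.na(map) & map >= threshold_fraction * mx
  labels <- .labelArray(mask)
  sizes <- tabulate(labels[labels > 0L])
  largest <- labels == which.max(sizes)
  localized <- !all(mask)
  if (!localized)
    warning("response map is non-localized: the whole field is above threshold")
  list(mask = mask, largest = largest, labels = labels, localized = localized)
}
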