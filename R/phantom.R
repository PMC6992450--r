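#' Stylized stroke phantom for speckle simulation
#'
#' Builds a \linkS4class{FlowPhantom} with three disjoint regions on a
#' rectangular grid: a vertical target-vessel band through the middle of the
#' field, a stroke-core block on one side (the territory supplied by the
#' vessel), and a remote reference block on the other. The baseline
#' decorrelation time is uniform; occlusion is emulated by multiplying tau_c
#' inside the vessel and core regions, since slower scatterers decorrelate
#' more slowly.
#'
#' The default baseline tau_c of 20 us against a 5-ms exposure puts the
#' simulation deep in the exposure >> tau_c regime where 1/K^2 is proportional
#' to 1/tau_c; a five-fold vessel tau increase then produces the ~80% BFI drop
#' used to confirm an occlusion, and a 2.5-fold core increase the ~60% drop of
#' the stroke core.
#'
#' @param shape c(rows, cols) of the grid; both >= 32.
#' @param tau_baseline_s uniform baseline decorrelation time (s).
#' @param vessel_tau_factor multiplier applied to tau_c in the vessel band.
#' @param core_tau_factor multiplier applied to tau_c in the core block.
#' @param beta speckle coherence factor.
#' @return A \linkS4class{FlowPhantom}; region labels are 1 for the core,
#'   2 for the remote block, 0 elsewhere, with the vessel flagged in
#'   \code{vesselMask()}.
#' @examples
#' ph <- makeStrokePhantom(c(64, 64), vessel_tau_factor = 5)
#' table(regionLabels(ph))
#' @export
makeStrokePhantom <- function(shape = c(256L, 256L), tau_baseline_s = 20e-6,
                              vessel_tau_factor = 1, core_tau_factor = 1,
                              beta = 1) {
  stopifnot(length(shape) == 2L, all(shape >= 32L),
            tau_baseline_s > 0, vessel_tau_factor > 0, core_tau_factor > 0)
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  core_cols <- seq_len(max(1L, round(0.375 * w)))
  v_start <- round(0.453 * w)
  vessel_cols <- v_start:min(w, v_start + round(0.1875 * w) - 1L)
  remote_cols <- (round(0.703 * w)):w

  vessel <- matrix(FALSE, h, w); vessel[, vessel_cols] <- TRUE
  labels <- matrix(0L, h, w)
  labels[, core_cols] <- 1L
  labels[, remote_cols] <- 2L

  tau <- matrix(tau_baseline_s, h, w)
  tau[vessel] <- tau_baseline_s * vessel_tau_factor
  tau[labels == 1L] <- tau_baseline_s * core_tau_factor
  FlowPhantom(tau, vesselMask = vessel, regionLabels = labels, beta = beta)
}
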