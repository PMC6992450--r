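#' Theoretical speckle contrast of time-integrated dynamic speckle
#'
#' Closed-form spatial speckle contrast of a fully developed dynamic speckle
#' pattern integrated over a camera exposure, for an exponentially
#' decorrelating field (the standard time-integrated model underlying the
#' 1/K^2 blood flow index):
#' \deqn{K(x) = \sqrt{\beta \, \frac{e^{-2x} - 1 + 2x}{2x^2}}, \qquad
#'       x = T/\tau_c,}
#' where T is the exposure, tau_c the speckle decorrelation time, and beta the
#' coherence factor of the detection system. For x -> 0 (static scatterers)
#' K -> sqrt(beta); for x >> 1 (fast flow) K^2 -> beta/x, so the blood flow
#' index 1/K^2 grows linearly with 1/tau_c, which is what makes BFI a relative
#' flow surrogate.
#'
#' A series expansion is used below x = 1e-4 to avoid cancellation.
#'
#' @param x exposure-to-decorrelation-time ratio T/tau_c, >= 0 (vectorized).
#' @param beta coherence factor in (0, 1].
#' @return Speckle contrast K, same shape as \code{x}.
#' @examples
#' speckleContrastTheory(0)        # 1: fully developed static speckle
#' speckleContrastTheory(250)      # 5-ms exposure over tau_c = 20 us
#' @export
speckleContrastTheory <- function(x, beta = 1) {
  stopifnot(all(x >= 0), length(beta) == 1L, beta > 0, beta <= 1)
  small <- x < 1e-4
  k2 <- x
  k2[small] <- beta * (1 - 2 * x[small] / 3 + x[small]^2 / 3)
  xl <- x[!small]
  k2[!small] <- beta * (exp(-2 * xl) - 1 + 2 * xl) / (2 * xl^2)
  sqrt(k2)
}

#' Theoretical blood-flow-index drop between two decorrelation times
#'
#' Percent decrease of the blood flow index 1/K^2 when the decorrelation time
#' changes from \code{tau_baseline} to \code{tau_post} at fixed exposure:
#' the closed-form oracle against which the simulated speckle pipeline is
#' checked. An occlusion slows the scatterers, lengthens tau_c, raises K and
#' lowers BFI, so a tau increase yields a positive drop.
#'
#' @param tau_baseline_s baseline decorrelation time (s).
#' @param tau_post_s post-event decorrelation time (s).
#' @param exposure_s camera exposure (s).
#' @param beta coherence factor.
#' @return Percent BFI decrease, 100 * (1 - BFI_post / BFI_baseline).
#' @examples
#' bfiDropTheory(20e-6, 100e-6)  # five-fold tau increase: about 80 percent
#' @export
bfiDropTheory <- function(tau_baseline_s, tau_post_s, exposure_s = 0.005,
                          beta = 1) {
  k0 <- speckleContrastTheory(exposure_s / tau_baseline_s, beta)
  k1 <- speckleContrastTheory(exposure_s / tau_post_s, beta)
  100 * (1 - k0^2 / k1^2)
}
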