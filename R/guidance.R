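## Illumination-guidance state machine for feedback-guided photothrombosis.

#' Parameters of the occlusion-guidance automaton
#'
#' Defaults encode the protocol-confirmation levels: an occlusion is declared
#' when the target-vessel BFI has dropped by at least 80 percentage points
#' from baseline, confirmed when additionally the supplied region has dropped
#' by more than 50 points; on occlusion the laser halves its power (0.3 mW
#' post-objective) for 2 min and then turns off; from OFF the laser re-arms
#' to full power when the vessel drop falls back below \code{rearm_drop_pct}
#' (flow recovered above 50% of baseline). All criteria must hold
#' continuously for \code{persistence_s} seconds before a state change, an
#' explicit debounce standing in for an operator's real-time judgment.
#'
#' @param occlusion_drop_pct vessel BFI drop (percent points) declaring
#'   occlusion.
#' @param region_drop_pct region drop (percent points) required, together
#'   with the vessel criterion, to confirm the occlusion.
#' @param persistence_s seconds a criterion must hold continuously.
#' @param half_power_hold_s duration of the half-power state (s).
#' @param rearm_drop_pct vessel drop below which a turned-off laser re-arms.
#' @param full_power_mw,half_power_mw post-objective powers (mW).
#' @return A named parameter list for \code{\link{occlusionGuidance}}.
#' @export
guidanceParams <- function(occlusion_drop_pct = 80, region_drop_pct = 50,
                           persistence_s = 5, half_power_hold_s = 120,
                           rearm_drop_pct = 50, full_power_mw = 0.6,
                           half_power_mw = 0.3) {
  list(occlusion_drop_pct = occlusion_drop_pct,
       region_drop_pct = region_drop_pct,
       persistence_s = persistence_s,
       half_power_hold_s = half_power_hold_s,
       rearm_drop_pct = rearm_drop_pct,
       full_power_mw = full_power_mw,
       half_power_mw = half_power_mw)
}

# First sample index at which `cond` has held continuously for >= hold_s
# seconds ending at that sample, scanning from `from`; NA if never.
.sustainedAt <- function(cond, t_s, hold_s, from) {
  onset <- NA_real_
  for (i in from:length(cond)) {
    if (isTRUE(cond[i])) {
      if (is.na(onset)) onset <- t_s[i]
      if (t_s[i] - onset >= hold_s) return(i)
    } else {
      onset <- NA_real_
    }
  }
  NA_integer_
}

#' Feedback-guided illumination controller (optimized protocol)
#'
#' Deterministic walk of the optimized-protocol state machine over
#' percent-of-baseline BFI traces sampled on a common clock. The laser starts
#' FULL; once the vessel drop criterion has held for the persistence window
#' the laser goes to HALF for exactly \code{half_power_hold_s} seconds, then
#' OFF. From OFF, a sustained recanalization (vessel drop below the re-arm
#' threshold) turns the laser FULL again, and the cycle can repeat. The
#' returned trace also carries an occlusion-confirmed flag that requires the
#' vessel and region criteria to hold simultaneously for the persistence
#' window.
#'
#' @param vessel_trace target-vessel BFI as percent of baseline (100 =
#'   baseline).
#' @param region_trace supplied-region BFI, percent of baseline; same length.
#' @param time_s sample times (s), strictly increasing, common to both
#'   traces.
#' @param params parameter list from \code{\link{guidanceParams}}.
#' @return A \linkS4class{ProtocolTrace}.
#' @examples
#' t_s <- 0:299
#' v <- ifelse(t_s < 60, 100, 15)
#' occlusionGuidance(v, v, t_s)
#' @export
occlusionGuidance <- function(vessel_trace, region_trace, time_s,
                              params = guidanceParams()) {
  n <- length(time_s)
  if (length(vessel_trace) != n || length(region_trace) != n)
    stop("vessel_trace, region_trace and time_s must share one clock")
  if (n < 2L || is.unsorted(time_s, strictly = TRUE))
    stop("time_s must be strictly increasing with >= 2 samples")
  p <- params
  vdrop <- 100 - vessel_trace
  rdrop <- 100 - region_trace

  occl <- !is.na(vdrop) & vdrop >= p$occlusion_drop_pct
  recan <- !is.na(vdrop) & vdrop < p$rearm_drop_pct

  ev <- data.frame(t_s = time_s[1], state = "FULL",
                   power_mw = p$full_power_mw, stringsAsFactors = FALSE)
  state <- "FULL"
  i <- 1L
  while (i <= n) {
    if (state == "FULL") {
      j <- .sustainedAt(occl, time_s, p$persistence_s, i)
      if (is.na(j)) break
      ev <- rbind(ev, data.frame(t_s = time_s[j], state = "HALF",
                                 power_mw = p$half_power_mw))
      state <- "HALF"
      half_until <- time_s[j] + p$half_power_hold_s
      i <- j + 1L
    } else if (state == "HALF") {
      j <- which(time_s >= half_until & seq_len(n) >= i)[1]
      if (is.na(j)) break
      ev <- rbind(ev, data.frame(t_s = time_s[j], state = "OFF",
                                 power_mw = 0))
      state <- "OFF"
      i <- j + 1L
    } else { # OFF
      j <- .sustainedAt(recan, time_s, p$persistence_s, i)
      if (is.na(j)) break
      ev <- rbind(ev, data.frame(t_s = time_s[j], state = "FULL",
                                 power_mw = p$full_power_mw))
      state <- "FULL"
      i <- j + 1L
    }
  }

  both <- occl & !is.na(rdrop) & rdrop > p$region_drop_pct
  confirmed <- !is.na(.sustainedAt(both, time_s, p$persistence_s, 1L))

  new("ProtocolTrace", events = ev, timeS = time_s, vesselDrop = vdrop,
      regionDrop = rdrop, confirmed = confirmed, params = p)
}

#' Fixed-duration illumination (nonoptimized protocol)
#'
#' Open-loop control: the laser is FULL for \code{duration_s} seconds (15 min
#' by default) and then OFF, independent of any feedback.
#'
#' @param duration_s illumination duration (s), > 0; a zero duration is
#'   accepted but produces an empty illumination flagged with a warning.
#' @return A \linkS4class{ProtocolTrace} with two events (or one OFF event
#'   for a zero duration); the confirmation flag is NA since no traces are
#'   observed.
#' @export
nonoptimizedProtocol <- function(duration_s = 900) {
  stopifnot(duration_s >= 0)
  if (duration_s == 0) {
    warning("zero illumination duration: empty protocol")
    ev <- data.frame(t_s = 0, state = "OFF", power_mw = 0,
                     stringsAsFactors = FALSE)
  } else {
    ev <- data.frame(t_s = c(0, duration_s), state = c("FULL", "OFF"),
                     power_mw = c(0.6, 0), stringsAsFactors = FALSE)
  }
  new("ProtocolTrace", events = ev, timeS = numeric(), vesselDrop = numeric(),
      regionDrop = numeric(), confirmed = NA, params = list(
        duration_s = duration_s))
}

#' Total time at full power in a protocol trace
#'
#' Sums the durations of FULL intervals; for a trace whose last event is not
#' OFF the final interval is closed at \code{end_s} (or left out if NULL).
#'
#' @param trace A \linkS4class{ProtocolTrace}.
#' @param end_s end of observation (s); defaults to the last trace sample,
#'   or the last event time for open-loop traces.
#' @return Seconds at full power.
#' @export
fullPowerTime <- function(trace, end_s = NULL) {
  ev <- protocolEvents(trace)
  if (is.null(end_s))
    end_s <- if (length(trace@timeS)) max(trace@timeS) else max(ev$t_s)
  tt <- c(ev$t_s, end_s)
  sum((tt[-1] - tt[-length(tt)])[ev$state == "FULL"])
}
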