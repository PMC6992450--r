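## Synthetic cylinder-test paw-contact event streams.

#' Timepoint schedule of the longitudinal cylinder test
#'
#' Baseline plus the post-stroke testing schedule: 4 h, 1 day, 3 days and
#' weekly out to 4 weeks.
#' @return Character vector of timepoint labels in temporal order.
#' @export
behaviorSchedule <- function() {
  c("baseline", "4h", "1d", "3d", "1w", "2w", "3w", "4w")
}

#' Specification of a synthetic cylinder-test session series
#'
#' @param n_rears_per_session rears observed per session.
#' @param p_contra_baseline probability that a rear's first wall contact uses
#'   the contralateral (to-be-impaired) forelimb at baseline.
#' @param p_contra_by_timepoint named numeric vector of probabilities for the
#'   post-stroke timepoints (names from \code{\link{behaviorSchedule}});
#'   defaults to the baseline probability everywhere (no deficit).
#' @param subject_id subject label.
#' @param seed integer seed.
#' @return A list of class "BehaviorSpec".
#' @export
behaviorSpec <- function(n_rears_per_session = 30L, p_contra_baseline = 0.5,
                         p_contra_by_timepoint = NULL, subject_id = "m1",
                         seed = 1L) {
  sched <- setdiff(behaviorSchedule(), "baseline")
  if (is.null(p_contra_by_timepoint))
    p_contra_by_timepoint <- stats::setNames(
      rep(p_contra_baseline, length(sched)), sched)
  stopifnot(n_rears_per_session >= 0L,
            p_contra_baseline >= 0, p_contra_baseline <= 1,
            all(p_contra_by_timepoint >= 0), all(p_contra_by_timepoint <= 1),
            all(names(p_contra_by_timepoint) %in% sched))
  structure(list(n_rears_per_session = as.integer(n_rears_per_session),
                 p_contra_baseline = p_contra_baseline,
                 p_contra_by_timepoint = p_contra_by_timepoint,
                 subject_id = subject_id, seed = seed),
            class = "BehaviorSpec")
}

#' Generate a synthetic paw-contact event log
#'
#' One row per rear, with the paw of first wall contact drawn Bernoulli with
#' the declared per-timepoint contralateral-use probability. A zero rear
#' count yields an empty (zero-row) log that downstream scoring must flag,
#' not crash on.
#'
#' @param spec A "BehaviorSpec".
#' @return data.frame with columns subject, timepoint, rear_index, paw
#'   (levels contra/ipsi).
#' @export
genPawEvents <- function(spec) {
  stopifnot(inherits(spec, "BehaviorSpec"))
  tps <- c(baseline = spec$p_contra_baseline, spec$p_contra_by_timepoint)
  n <- spec$n_rears_per_session
  .withSeed(spec$seed, {
    rows <- lapply(names(tps), function(tp) {
      if (n == 0L) return(NULL)
      data.frame(subject = spec$subject_id, timepoint = tp,
                 rear_index = seq_len(n),
                 paw = ifelse(stats::runif(n) < tps[[tp]], "contra", "ipsi"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(subject = character(), timepoint = character(),
                        rear_index = integer(), paw = character(),
                        stringsAsFactors = FALSE)
    out
  })
}
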