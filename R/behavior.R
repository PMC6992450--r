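## Cylinder-test forelimb-asymmetry scoring and longitudinal statistics.

#' Score cylinder-test sessions into an asymmetry table
#'
#' Counts contralateral and ipsilateral first wall contacts per subject and
#' timepoint, forms the contralateral-use fraction n_contra / (n_contra +
#' n_ipsi), and expresses each post-stroke timepoint as the percent change
#' from the subject's own baseline fraction:
#' 100 * (f_t - f_baseline) / f_baseline. Working on the fraction rather
#' than raw counts makes the score invariant to session length, and the
#' change-from-baseline normalization compensates for innate paw preference.
#' Reduced contralateral use after stroke therefore yields a negative
#' percent change.
#'
#' Timepoints with zero rears give NA counts flagged in \code{flag}; a zero
#' baseline contralateral use leaves the percent change undefined (NA,
#' flagged).
#'
#' @param log data.frame with columns subject, timepoint, paw
#'   ("contra"/"ipsi"), e.g. from \code{\link{genPawEvents}}; every subject
#'   must have a baseline timepoint (or an empty log is returned flagged).
#' @param schedule timepoint ordering, default \code{\link{behaviorSchedule}}.
#' @return data.frame with subject, timepoint, n_contra, n_ipsi, n_rears,
#'   contra_fraction, percent_change, flag.
#' @export
scoreSession <- function(log, schedule = behaviorSchedule()) {
  stopifnot(is.data.frame(log),
            all(c("subject", "timepoint", "paw") %in% names(log)))
  if (nrow(log) == 0L) {
    warning("empty event log: nothing to score")
    return(data.frame(subject = character(), timepoint = character(),
                      n_contra = integer(), n_ipsi = integer(),
                      n_rears = integer(), contra_fraction = numeric(),
                      percent_change = numeric(), flag = character()))
  }
  if (!all(log$paw %in% c("contra", "ipsi")))
    stop("paw must be 'contra' or 'ipsi'")
  bad_tp <- setdiff(unique(log$timepoint), schedule)
  if (length(bad_tp))
    stop("timepoint(s) outside the declared schedule: ",
         paste(bad_tp, collapse = ", "))

  out <- list()
  for (sub in unique(log$subject)) {
    sl <- log[log$subject == sub, ]
    if (!"baseline" %in% sl$timepoint)
      stop("subject ", sub, " has no baseline timepoint")
    rows <- lapply(intersect(schedule, unique(sl$timepoint)), function(tp) {
      p <- sl$paw[sl$timepoint == tp]
      nc <- sum(p == "contra"); ni <- sum(p == "ipsi")
      data.frame(subject = sub, timepoint = tp, n_contra = nc, n_ipsi = ni,
                 n_rears = nc + ni,
                 contra_fraction = if (nc + ni > 0) nc / (nc + ni) else NA_real_,
                 percent_change = NA_real_, flag = "",
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    f0 <- tab$contra_fraction[tab$timepoint == "baseline"]
    for (i in seq_len(nrow(tab))) {
      if (tab$n_rears[i] == 0L) {
        tab$flag[i] <- "no_rears"
      } else if (tab$timepoint[i] == "baseline") {
        tab$percent_change[i] <- 0
      } else if (is.na(f0) || f0 == 0) {
        tab$flag[i] <- "zero_baseline_contra"
      } else {
        tab$percent_change[i] <- 100 * (tab$contra_fraction[i] - f0) / f0
      }
    }
    out[[sub]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Longitudinal paired tests of contralateral forelimb use
#'
#' Paired t-test of the contralateral-use fraction at each post-stroke
#' timepoint against the same subjects' baseline, flagged at \code{alpha}.
#' Subjects missing either member of a pair are dropped with a warning; at
#' least two complete pairs are required per timepoint. No multiplicity
#' correction is applied by default (per-timepoint tests are reported as
#' such); \code{adjust = "bonferroni"} is available.
#'
#' @param table asymmetry table from \code{\link{scoreSession}}.
#' @param alpha significance level.
#' @param adjust p-adjustment method passed to \code{\link[stats]{p.adjust}}
#'   ("none" by default).
#' @return data.frame with timepoint, n_pairs, mean_baseline, mean_t,
#'   mean_diff, t, df, p, p_adj, significant.
#' @export
longitudinalTests <- function(table, alpha = 0.05, adjust = "none") {
  stopifnot(is.data.frame(table),
            all(c("subject", "timepoint", "contra_fraction") %in% names(table)))
  base <- table[table$timepoint == "baseline" & !is.na(table$contra_fraction), ]
  tps <- setdiff(unique(table$timepoint), "baseline")
  rows <- list()
  for (tp in tps) {
    cur <- table[table$timepoint == tp & !is.na(table$contra_fraction), ]
    subs <- intersect(base$subject, cur$subject)
    dropped <- setdiff(union(base$subject, cur$subject), subs)
    if (length(dropped))
      warning("timepoint ", tp, ": unpaired subject(s) dropped: ",
              paste(dropped, collapse = ", "))
    if (length(subs) < 2L)
      stop("timepoint ", tp, ": fewer than 2 paired subjects")
    b <- base$contra_fraction[match(subs, base$subject)]
    x <- cur$contra_fraction[match(subs, cur$subject)]
    if (stats::sd(x - b) == 0) {
      # degenerate paired differences: t.test would error on zero variance
      tt <- list(statistic = if (all(x == b)) 0 else sign(mean(x - b)) * Inf,
                 parameter = length(subs) - 1,
                 p.value = if (all(x == b)) 1 else 0)
    } else {
      tt <- stats::t.test(x, b, paired = TRUE)
    }
    rows[[tp]] <- data.frame(timepoint = tp, n_pairs = length(subs),
                             mean_baseline = mean(b), mean_t = mean(x),
                             mean_diff = mean(x - b),
                             t = unname(tt$statistic),
                             df = unname(tt$parameter), p = tt$p.value,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_adj <- stats::p.adjust(res$p, method = adjust)
  res$significant <- res$p_adj < alpha
  res
}
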