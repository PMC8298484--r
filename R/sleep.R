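## Sleep behaviour summaries from pre-scored nightly episodes: duration,
## quality, timing and regularity aggregates, the rule-based delayed sleep
## phase (DSP) classification, and the six-item MEQ sum score.

## clock hours of POSIXct or pass-through numeric hours
.asClockHours <- function(x) {
  if (inherits(x, "POSIXct") || inherits(x, "POSIXlt")) clockHours(x)
  else as.numeric(x)
}

checkEpisodes <- function(episodes) {
  need <- c("subject_id", "night", "bedtime", "onset", "offset", "waso_min")
  miss <- setdiff(need, names(episodes))
  if (length(miss))
    stop("sleep episodes lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dur <- as.numeric(difftime(episodes$offset, episodes$onset, units = "hours"))
  sol <- as.numeric(difftime(episodes$onset, episodes$bedtime, units = "hours"))
  bad <- dur <= 0 | sol < 0 | episodes$waso_min < 0 | dur > 16
  if (any(bad)) {
    warning(sum(bad), " episode(s) with invalid durations rejected")
    episodes <- episodes[!bad, , drop = FALSE]
  }
  episodes
}

#' Summarize one subject's sleep episodes
#'
#' Per-night quantities -- assumed sleep (offset minus onset), sleep onset
#' latency (onset minus bedtime), midpoint (onset plus half the sleep period)
#' -- aggregated over nights. Clock-time means and SDs are computed on an
#' unwrapped scale anchored at 18:00 (sleep onsets in this population never
#' cluster near 18:00, so ordinary moments are safe there) and mapped back to
#' clock time.
#'
#' @param episodes `data.frame` with columns `subject_id`, `night`,
#'   `bedtime`, `onset`, `offset` (POSIXct) and `waso_min`, for one subject;
#'   needs >= 3 valid nights.
#' @param anchor clock hour anchoring the unwrapped scale.
#' @return one-row `data.frame`: `subject_id`, `n_nights`, `assumed_sleep_h`,
#'   `waso_min`, `sol_h`, `onset_mean_h`, `midpoint_mean_h`, `offset_mean_h`
#'   (clock hours), `sd_onset_min`, `sd_midpoint_min`, `insufficient`.
#' @export
summarizeSleep <- function(episodes, anchor = 18) {
  episodes <- checkEpisodes(episodes)
  sid <- unique(episodes$subject_id)
  if (length(sid) != 1L)
    stop("summarizeSleep expects episodes of a single subject", call. = FALSE)
  n <- nrow(episodes)
  insufficient <- n < 3L
  if (insufficient) warning("fewer than 3 nights: summary flagged insufficient")

  assumed <- as.numeric(difftime(episodes$offset, episodes$onset, units = "hours"))
  sol <- as.numeric(difftime(episodes$onset, episodes$bedtime, units = "hours"))
  onsetU <- hoursSinceAnchor(.asClockHours(episodes$onset), anchor)
  offsetU <- hoursSinceAnchor(.asClockHours(episodes$offset), anchor)
  midU <- onsetU + assumed / 2

  sdOrZero <- function(x) if (length(x) > 1) stats::sd(x) else 0
  data.frame(
    subject_id = sid, n_nights = n,
    assumed_sleep_h = mean(assumed),
    waso_min = mean(episodes$waso_min),
    sol_h = mean(sol),
    onset_mean_h = anchorToClock(mean(onsetU), anchor),
    midpoint_mean_h = anchorToClock(mean(midU), anchor),
    offset_mean_h = anchorToClock(mean(offsetU), anchor),
    sd_onset_min = sdOrZero(onsetU) * 60,
    sd_midpoint_min = sdOrZero(midU) * 60,
    insufficient = insufficient,
    stringsAsFactors = FALSE)
}

#' Summarize sleep for every subject of a cohort
#'
#' @param episodes multi-subject episode `data.frame`.
#' @param anchor clock hour anchoring the unwrapped scale.
#' @return `data.frame`, one row per subject.
#' @export
summarizeSleepCohort <- function(episodes, anchor = 18) {
  rows <- lapply(split(episodes, episodes$subject_id), summarizeSleep,
                 anchor = anchor)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rule-based delayed sleep phase classification
#'
#' A subject is DSP when they go to sleep after `lateThreshold` (default
#' 01:00, strictly) at least `perWeek` times per week: with `n` observed
#' nights the weekly rate is `(late count / n) * 7`, normalizing for the
#' 8-10-day windows with dropouts. Nights with a missing onset are excluded
#' from both numerator and denominator.
#'
#' @param episodes episode `data.frame` for one subject (>= 3 nights).
#' @param lateThreshold clock hour after which an onset counts as late.
#' @param perWeek required late nights per week.
#' @param use `"onset"` (default; actigraphy-scored falling asleep) or
#'   `"bedtime"`.
#' @param anchor clock hour anchoring the unwrapped scale.
#' @return logical DSP flag.
#' @export
classifyDsp <- function(episodes, lateThreshold = 1, perWeek = 3,
                        use = c("onset", "bedtime"), anchor = 18) {
  use <- match.arg(use)
  episodes <- checkEpisodes(episodes)
  h <- .asClockHours(episodes[[use]])
  h <- h[!is.na(h)]
  if (length(h) < 3L) stop("need at least 3 nights with a recorded ", use,
                           call. = FALSE)
  late <- hoursSinceAnchor(h, anchor) > hoursSinceAnchor(lateThreshold, anchor)
  (sum(late) / length(late)) * 7 >= perWeek
}

#' Score the 6-item MEQ short form
#'
#' Simple sum of the six responses (items 4, 7, 9, 15, 17 and 19 of the full
#' questionnaire); higher scores indicate a more morning-oriented circadian
#' preference. Responses are validated against the per-item legal ranges of
#' the scoring table; a missing or out-of-range item makes the score
#' undefined (no prorating).
#'
#' @param items named numeric vector or one-row `data.frame` with the six
#'   item responses.
#' @param table scoring table (see [meqScoringTable()]).
#' @return integer sum score, or `NA` with a warning when undefined.
#' @export
scoreMeq <- function(items, table = meqScoringTable()) {
  if (is.data.frame(items)) items <- unlist(items[1, table$item])
  vals <- suppressWarnings(as.numeric(items[table$item]))
  if (anyNA(vals)) {
    warning("missing MEQ item(s): score undefined")
    return(NA_integer_)
  }
  if (any(vals < table$min | vals > table$max)) {
    warning("MEQ item out of legal range: score undefined")
    return(NA_integer_)
  }
  as.integer(sum(vals))
}

#' Sleep, DSP and MEQ battery for a whole cohort
#'
#' @param sleep multi-subject episode `data.frame`.
#' @param meq `data.frame` with `subject_id` and the six item columns.
#' @param ... passed to [classifyDsp()].
#' @return `data.frame`: per-subject sleep summary plus `dsp` and `meq_sum`.
#' @export
sleepBattery <- function(sleep, meq = NULL, ...) {
  summ <- summarizeSleepCohort(sleep)
  summ$dsp <- vapply(split(sleep, sleep$subject_id), classifyDsp,
                     logical(1), ...)[summ$subject_id]
  if (!is.null(meq)) {
    scores <- vapply(seq_len(nrow(meq)), function(i)
      scoreMeq(meq[i, , drop = FALSE]), integer(1))
    summ$meq_sum <- scores[match(summ$subject_id, meq$subject_id)]
  }
  summ
}
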