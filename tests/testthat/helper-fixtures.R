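## Shared fixtures: all inputs are built in code at test time.

## noise spec with every distortion switched off
zeroNoise <- function() {
  noiseSpec(sigma = 0, ar = 0, transientMagnitude = 0, transientDuration = 0,
            missingFraction = 0, quantizationStep = 0)
}

## a single archetype with convenient round numbers
toyArchetype <- function(mesor = 34, amplitude = 2, period = 24,
                         acrophase_clock = 2.5, dsp_prob = 0.5,
                         n_subjects = 1L) {
  archetypeSpec("toy", mesor, amplitude, period, acrophase_clock, dsp_prob,
                sleep_onset_mean = 0.5, sleep_onset_sd = 60,
                meq_mean = 13, meq_sd = 4, n_subjects = n_subjects)
}

## no between-subject parameter dispersion
noSubjectSd <- function() list(mesor = 0, amplitude = 0, period = 0)

## a RawRecording built directly (independent of generateSeries) from a
## start clock time and a function of absolute hours since day-0 midnight
makeRecording <- function(startClock, nMinutes, fn,
                          subjectId = "T001", day0 = "2016-11-01") {
  start <- as.POSIXct(paste(day0, "00:00:00"), tz = "UTC") + startClock * 3600
  tMin <- seq_len(nMinutes) - 1L
  hAbs <- startClock + tMin / 60
  structure(list(subjectId = subjectId, startTime = start,
                 time = start + tMin * 60, temp = fn(hAbs), truth = NULL),
            class = "RawRecording")
}

## minimal sleep-episode table from onset clock hours (relative to midnight;
## negative = evening before); durations/latencies fixed unless overridden
makeEpisodes <- function(onset_h, subjectId = "T001", sol_h = 1 / 3,
                         dur_h = 8, waso = 40, day0 = "2016-11-01") {
  n <- length(onset_h)
  midnight <- as.POSIXct(paste(day0, "00:00:00"), tz = "UTC") +
    seq_len(n) * 86400
  onset <- midnight + onset_h * 3600
  data.frame(subject_id = subjectId, night = seq_len(n),
             bedtime = onset - sol_h * 3600, onset = onset,
             offset = onset + dur_h * 3600, waso_min = waso,
             stringsAsFactors = FALSE)
}

## circular distance between two clock hours (period 24)
clockDist <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}
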