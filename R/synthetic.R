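## Synthetic free-living cohort generator. Emulates minute-resolution wrist
## temperature loggers (one sample per minute over three days, start jittered
## between 15:00 and 22:00, 0.0625 degC quantization), pre-scored nightly sleep
## episodes, six-item morningness-eveningness responses and demographics, with
## cluster-structured cosinor parameters so the whole downstream pipeline is
## testable without any data download.

#' Archetype specification for one simulated cluster
#'
#' An archetype is the generative parameter set of one cluster: cosinor
#' parameters of the temperature rhythm, the delayed-sleep-phase probability,
#' sleep-onset distribution, the morningness-eveningness (MEQ) sum-score
#' distribution, and the cluster size.
#'
#' @param label cluster name.
#' @param mesor rhythm-adjusted mean, degC.
#' @param amplitude half peak-to-trough extent, degC (> 0).
#' @param period cycle length in hours, in `[20, 30]`.
#' @param acrophase_clock clock hour (hours after midnight) of the expected
#'   temperature peak.
#' @param dsp_prob probability of delayed sleep phase in `[0, 1]`.
#' @param sleep_onset_mean mean sleep onset as clock hours relative to
#'   midnight (negative = before midnight).
#' @param sleep_onset_sd SD of sleep onset in minutes.
#' @param meq_mean,meq_sd mean and SD of the 6-item MEQ sum score.
#' @param n_subjects number of subjects (>= 1).
#' @return a one-row `data.frame` of class validated archetype fields.
#' @export
archetypeSpec <- function(label, mesor, amplitude, period, acrophase_clock,
                          dsp_prob, sleep_onset_mean, sleep_onset_sd,
                          meq_mean, meq_sd, n_subjects) {
  a <- data.frame(label = as.character(label), mesor = mesor,
                  amplitude = amplitude, period = period,
                  acrophase_clock = acrophase_clock, dsp_prob = dsp_prob,
                  sleep_onset_mean = sleep_onset_mean,
                  sleep_onset_sd = sleep_onset_sd, meq_mean = meq_mean,
                  meq_sd = meq_sd, n_subjects = as.integer(n_subjects),
                  stringsAsFactors = FALSE)
  validateArchetypes(a)
  a
}

validateArchetypes <- function(a) {
  need <- c("label", "mesor", "amplitude", "period", "acrophase_clock",
            "dsp_prob", "sleep_onset_mean", "sleep_onset_sd", "meq_mean",
            "meq_sd", "n_subjects")
  miss <- setdiff(need, names(a))
  if (length(miss))
    stop("archetype table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(a$amplitude <= 0)) stop("archetype amplitude must be > 0", call. = FALSE)
  if (any(a$period < 20 | a$period > 30))
    stop("archetype period must lie in [20, 30] h", call. = FALSE)
  if (any(a$dsp_prob < 0 | a$dsp_prob > 1))
    stop("dsp_prob must lie in [0, 1]", call. = FALSE)
  if (any(a$n_subjects < 1)) stop("n_subjects must be >= 1", call. = FALSE)
  invisible(a)
}

#' Default three-cluster archetype table
#'
#' The versioned fixture shipped with the package: three clusters whose mesor
#' (34.29 / 33.46 / 32.80 degC), amplitude (1.02 / 1.38 / 2.09 degC), period
#' (25.75 / 25.76 / 25.33 h), observed acrophase (02:40 / 02:34 / 02:02),
#' DSP probabilities (0.46 / 0.68 / 0.37), sleep-onset timing and MEQ score
#' distributions, and sizes (100 / 130 / 51) follow the reported cluster
#' characteristics of the free-living adolescent cohort this package models.
#'
#' @return `data.frame` with one row per archetype.
#' @export
defaultArchetypes <- function() {
  path <- system.file("extdata", "archetypes.csv", package = "CircaTemp")
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  a$n_subjects <- as.integer(a$n_subjects)
  validateArchetypes(a)
  a
}

#' Noise specification for the temperature generator
#'
#' @param sigma AR(1) innovation SD in degC (>= 0).
#' @param ar AR(1) coefficient in `[0, 1)`; skin temperature noise is strongly
#'   autocorrelated, hence the high default.
#' @param transientMagnitude size of the additive warm-up transient at
#'   recording start, degC (device equilibrating to skin temperature).
#' @param transientDuration transient length in minutes.
#' @param missingFraction fraction of samples masked in contiguous runs
#'   (re-attachment gaps), must be < 0.5.
#' @param quantizationStep logger resolution in degC (0 disables quantization;
#'   default is the 0.0625 degC resolution of DS1922L-class loggers).
#' @return list of class `"NoiseSpec"`.
#' @export
noiseSpec <- function(sigma = 0.4, ar = 0.9, transientMagnitude = 1.5,
                      transientDuration = 120, missingFraction = 0.05,
                      quantizationStep = 0.0625) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (ar < 0 || ar >= 1) stop("ar must lie in [0, 1)", call. = FALSE)
  if (missingFraction < 0 || missingFraction >= 0.5)
    stop("missingFraction must lie in [0, 0.5)", call. = FALSE)
  if (quantizationStep < 0) stop("quantizationStep must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, ar = ar,
                 transientMagnitude = transientMagnitude,
                 transientDuration = transientDuration,
                 missingFraction = missingFraction,
                 quantizationStep = quantizationStep),
            class = "NoiseSpec")
}

## closed-form cosinor signal at absolute clock hours hAbs (hours since
## midnight of day 0, may exceed 24). The peak reference is anchored so that
## the two cycles inside the harmonized 48-h window (noon day 1 to noon day 3)
## peak at clock times peakClock -/+ (period - 24)/2: with a non-24-h period
## the peak drifts across days, and this choice makes the circular mean of
## the in-window peaks equal the specified acrophase clock time.
cosinorSignal <- function(hAbs, mesor, amplitude, period, peakClock) {
  peakRef <- 48 + peakClock - (period - 24) / 2
  mesor + amplitude * cos(2 * pi * (hAbs - peakRef) / period)
}

#' Generate one raw temperature recording
#'
#' Simulates a 72-h, 1-min resolution wrist temperature recording: a
#' single-component cosinor signal plus AR(1) noise, an additive warm-up
#' transient over the first `transientDuration` minutes, logger quantization,
#' and contiguous missing runs. The recording start is jittered uniformly
#' between 15:00 and 22:00. Per-subject cosinor parameters are drawn around
#' the archetype values: mesor ~ N(spec, 0.15), amplitude ~ N(spec, 0.15)
#' truncated above 0.2 degC, period ~ N(spec, 0.4 h).
#'
#' @param archetype one-row archetype `data.frame` (see [archetypeSpec()]).
#' @param noise a [noiseSpec()].
#' @param seed integer seed (required; the series is bit-reproducible).
#' @param subjectId identifier stored in the recording.
#' @param startDate `Date` (or string) of day 0.
#' @param nMinutes number of samples (default 4320 = 72 h).
#' @param subjectSd named list of between-subject SDs for `mesor`, `amplitude`
#'   and `period` (set all to 0 to generate exactly at the archetype values).
#' @return list of class `"RawRecording"` with elements `subjectId`,
#'   `startTime` (POSIXct), `time` (POSIXct vector), `temp` (numeric with `NA`
#'   for masked samples), and `truth` (realized generative parameters).
#' @export
generateSeries <- function(archetype, noise = noiseSpec(), seed,
                           subjectId = "S001", startDate = "2016-11-01",
                           nMinutes = 4320,
                           subjectSd = list(mesor = 0.15, amplitude = 0.15,
                                            period = 0.4)) {
  validateArchetypes(archetype)
  stopifnot(nrow(archetype) == 1L)
  if (!inherits(noise, "NoiseSpec")) stop("noise must be a noiseSpec()", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  seed <- checkSeed(seed)
  nMinutes <- as.integer(nMinutes)
  if (is.na(nMinutes) || nMinutes <= 0)
    stop("nMinutes must be a positive integer", call. = FALSE)

  set.seed(seed)
  m <- stats::rnorm(1, archetype$mesor, subjectSd$mesor)
  a <- stats::rnorm(1, archetype$amplitude, subjectSd$amplitude)
  while (subjectSd$amplitude > 0 && a <= 0.2)
    a <- stats::rnorm(1, archetype$amplitude, subjectSd$amplitude)
  tau <- stats::rnorm(1, archetype$period, subjectSd$period)

  startOffsetMin <- floor(stats::runif(1, 0, 7 * 60))   # 15:00 .. 21:59
  day0 <- as.POSIXct(paste(as.character(startDate), "15:00:00"), tz = "UTC")
  startTime <- day0 + startOffsetMin * 60
  tMin <- seq_len(nMinutes) - 1L
  hAbs <- 15 + startOffsetMin / 60 + tMin / 60

  temp <- cosinorSignal(hAbs, m, a, tau, archetype$acrophase_clock)

  if (noise$sigma > 0) {
    innov <- stats::rnorm(nMinutes, 0, noise$sigma)
    e0 <- stats::rnorm(1, 0, noise$sigma / sqrt(1 - noise$ar^2))
    e <- as.numeric(stats::filter(innov, noise$ar, method = "recursive",
                                  init = e0))
    temp <- temp + e
  }
  if (noise$transientMagnitude > 0 && noise$transientDuration > 0) {
    idx <- which(tMin < noise$transientDuration)
    temp[idx] <- temp[idx] -
      noise$transientMagnitude * (1 - tMin[idx] / noise$transientDuration)
  }
  if (noise$quantizationStep > 0)
    temp <- round(temp / noise$quantizationStep) * noise$quantizationStep

  mask <- rep(FALSE, nMinutes)
  target <- round(noise$missingFraction * nMinutes)
  guard <- 0L
  while (sum(mask) < target && guard < 10000L) {
    len <- sample(10:45, 1)
    st <- sample.int(max(nMinutes - len, 1L), 1)
    mask[st:min(st + len - 1L, nMinutes)] <- TRUE
    guard <- guard + 1L
  }
  if (sum(mask) > target) {
    extra <- which(mask)[seq.int(target + 1L, sum(mask))]
    mask[extra] <- FALSE
  }
  temp[mask] <- NA_real_

  structure(list(
    subjectId = as.character(subjectId),
    startTime = startTime,
    time = startTime + tMin * 60,
    temp = temp,
    truth = list(label = archetype$label, mesor = m, amplitude = a,
                 period = tau, acrophase_clock = archetype$acrophase_clock)
  ), class = "RawRecording")
}

## default per-item legal ranges of MEQ items 4, 7, 9, 15, 17 and 19; the
## response scales are configuration, not code (item 17 has five options)
#' Default scoring table for the 6-item MEQ short form
#' @return `data.frame` with columns `item`, `min`, `max`.
#' @export
meqScoringTable <- function() {
  data.frame(item = c("item4", "item7", "item9", "item15", "item17", "item19"),
             min = c(1L, 1L, 1L, 1L, 1L, 1L),
             max = c(4L, 4L, 4L, 4L, 5L, 4L),
             stringsAsFactors = FALSE)
}

## draw six item responses whose sum is close to a N(mean, sd) draw clipped to
## the legal range: start each item at its minimum and spread the remainder
## uniformly over items with free capacity
drawMeqItems <- function(meanScore, sdScore, table = meqScoringTable()) {
  lo <- sum(table$min); hi <- sum(table$max)
  target <- round(min(max(stats::rnorm(1, meanScore, sdScore), lo), hi))
  items <- table$min
  cap <- table$max - table$min
  extra <- target - lo
  while (extra > 0) {
    free <- which(cap > 0)
    pick <- if (length(free) == 1L) free else sample(free, 1)
    items[pick] <- items[pick] + 1L
    cap[pick] <- cap[pick] - 1L
    extra <- extra - 1L
  }
  stats::setNames(as.integer(items), table$item)
}

## nightly sleep episodes for one subject; onsets are drawn around the
## archetype mean and then minimally shifted so that a DSP-labelled subject
## has >= 4 of 8 onsets after 01:00 and a non-DSP subject has <= 2 (makes the
## rule-based classifier recover labels exactly at zero noise)
drawSleepEpisodes <- function(subjectId, archetype, dsp, nNights = 8L,
                              startDate = "2016-11-01") {
  onset_h <- stats::rnorm(nNights, archetype$sleep_onset_mean,
                          archetype$sleep_onset_sd / 60)
  late <- onset_h > 1
  nLateMin <- ceiling(4L * nNights / 8)   # >= 4 of 8 late for DSP
  nLateMax <- floor(2L * nNights / 8)     # <= 2 of 8 late for non-DSP
  if (dsp && sum(late) < nLateMin) {
    ## shift the latest non-late nights past 01:00
    cand <- which(!late)
    fix <- cand[order(onset_h[cand], decreasing = TRUE)][
      seq_len(nLateMin - sum(late))]
    onset_h[fix] <- 1 + abs(stats::rnorm(length(fix), 0.75, 0.5)) + 1 / 60
  } else if (!dsp && sum(late) > nLateMax) {
    ## pull the earliest late nights back before 01:00
    cand <- which(late)
    fix <- cand[order(onset_h[cand])][seq_len(sum(late) - nLateMax)]
    onset_h[fix] <- 1 - abs(stats::rnorm(length(fix), 0.5, 0.3))
  }
  sol_h <- pmax(stats::rnorm(nNights, 20 / 60, 8 / 60), 0)
  dur_h <- stats::rnorm(nNights, 8, 40 / 60)
  waso <- pmax(stats::rnorm(nNights, 55, 15), 0)

  midnight <- as.POSIXct(paste(as.character(startDate), "00:00:00"), tz = "UTC") +
    seq_len(nNights) * 86400
  onset <- midnight + onset_h * 3600
  data.frame(subject_id = subjectId, night = seq_len(nNights),
             bedtime = onset - sol_h * 3600, onset = onset,
             offset = onset + dur_h * 3600, waso_min = waso,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort bundle
#'
#' Draws every subject of every archetype: raw temperature recordings (via
#' [generateSeries()]), a Bernoulli DSP label at the archetype's `dsp_prob`,
#' eight nightly sleep episodes consistent with that label, six MEQ item
#' responses whose sum follows the archetype's score distribution, and
#' demographics (sex ~ Bernoulli(0.3 male), age ~ N(16.9, 0.7) years,
#' BMI ~ N(21.7, 3)).
#'
#' @param archetypes archetype table (default [defaultArchetypes()]).
#' @param noise a [noiseSpec()].
#' @param seed integer master seed; all per-subject streams are derived from it.
#' @param startDate `Date` (or string) of day 0.
#' @param subjectSd between-subject SDs passed to [generateSeries()].
#' @return list of class `"CohortBundle"`: `recordings` (list of
#'   `RawRecording`), `sleep`, `meq`, `demographics`, `truth` (`data.frame`s),
#'   and `seed`.
#' @export
generateCohort <- function(archetypes = defaultArchetypes(),
                           noise = noiseSpec(), seed,
                           startDate = "2016-11-01",
                           subjectSd = list(mesor = 0.15, amplitude = 0.15,
                                            period = 0.4)) {
  validateArchetypes(archetypes)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  seed <- checkSeed(seed)
  n <- sum(archetypes$n_subjects)
  seeds <- matrix(deriveSeeds(seed, 2L * n), ncol = 2L)

  ids <- sprintf("S%04d", seq_len(n))
  labels <- rep(archetypes$label, archetypes$n_subjects)
  rowIdx <- rep(seq_len(nrow(archetypes)), archetypes$n_subjects)

  recordings <- vector("list", n)
  sleep <- vector("list", n)
  meqRows <- vector("list", n)
  demo <- vector("list", n)
  truth <- vector("list", n)

  for (i in seq_len(n)) {
    arch <- archetypes[rowIdx[i], , drop = FALSE]
    rec <- generateSeries(arch, noise, seed = seeds[i, 1L], subjectId = ids[i],
                          startDate = startDate, subjectSd = subjectSd)
    recordings[[i]] <- rec

    set.seed(seeds[i, 2L])
    dsp <- stats::runif(1) < arch$dsp_prob
    sleep[[i]] <- drawSleepEpisodes(ids[i], arch, dsp, startDate = startDate)
    items <- drawMeqItems(arch$meq_mean, arch$meq_sd)
    meqRows[[i]] <- data.frame(subject_id = ids[i], t(items),
                               stringsAsFactors = FALSE)
    demo[[i]] <- data.frame(
      subject_id = ids[i],
      sex = if (stats::runif(1) < 0.3) "M" else "F",
      age = stats::rnorm(1, 16.9, 0.7),
      bmi = stats::rnorm(1, 21.7, 3),
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      subject_id = ids[i], label = arch$label, dsp = dsp,
      mesor = rec$truth$mesor, amplitude = rec$truth$amplitude,
      period = rec$truth$period, acrophase_clock = rec$truth$acrophase_clock,
      stringsAsFactors = FALSE)
  }

  structure(list(
    recordings = stats::setNames(recordings, ids),
    sleep = do.call(rbind, sleep),
    meq = do.call(rbind, meqRows),
    demographics = do.call(rbind, demo),
    truth = do.call(rbind, truth),
    seed = seed
  ), class = "CohortBundle")
}

#' Write a cohort bundle as plain-text CSV inputs
#'
#' Writes `temperature.csv` (long format: subject_id, timestamp, temp_c),
#' `sleep.csv`, `meq.csv`, `demographics.csv` and `truth.csv` into `dir`.
#'
#' @param bundle a `CohortBundle` from [generateCohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
writeCohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "CohortBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  long <- data.table::rbindlist(lapply(bundle$recordings, function(r)
    data.table::data.table(subject_id = r$subjectId, timestamp = fmt(r$time),
                           temp_c = r$temp)))
  paths <- file.path(dir, c("temperature.csv", "sleep.csv", "meq.csv",
                            "demographics.csv", "truth.csv"))
  data.table::fwrite(long, paths[1])
  sl <- bundle$sleep
  for (cc in c("bedtime", "onset", "offset")) sl[[cc]] <- fmt(sl[[cc]])
  data.table::fwrite(sl, paths[2])
  data.table::fwrite(bundle$meq, paths[3])
  data.table::fwrite(bundle$demographics, paths[4])
  data.table::fwrite(bundle$truth, paths[5])
  invisible(paths)
}

#' Read a cohort's recordings back from temperature CSV
#'
#' Inverse of the temperature part of [writeCohort()]: returns a list of
#' `RawRecording`-shaped objects (without generative truth).
#'
#' @param path path to a long-format temperature CSV
#'   (`subject_id,timestamp,temp_c`).
#' @return named list of `RawRecording` objects.
#' @export
readTemperatureCsv <- function(path) {
  dt <- data.table::fread(path)
  need <- c("subject_id", "timestamp", "temp_c")
  if (!all(need %in% names(dt)))
    stop("temperature CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  split <- split(dt, dt$subject_id)
  lapply(split, function(d) {
    tt <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    o <- order(tt)
    structure(list(subjectId = as.character(d$subject_id[1]),
                   startTime = tt[o][1], time = tt[o],
                   temp = as.numeric(d$temp_c)[o], truth = NULL),
              class = "RawRecording")
  })
}
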