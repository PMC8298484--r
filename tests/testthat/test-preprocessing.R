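test_that("harmonization windows start at the first noon and keep 2880 samples", {
  lin <- function(h) 30 + 0.0001 * h
  ## start 18:00 day 0, 72 h: window = noon day 1 .. noon day 3
  ts <- harmonizeStart(makeRecording(18, 4320, lin))
  expect_s4_class(ts, "TemperatureSeries")
  expect_length(seriesValues(ts), 2880L)
  expect_equal(attr(ts, "nDroppedHead"), 18 * 60)  # 18:00 -> 12:00 next day
  expect_equal(seriesValues(ts)[1], lin(36), tolerance = 1e-12)

  ## start exactly noon: zero samples dropped at the head
  ts2 <- harmonizeStart(makeRecording(12, 4320, lin))
  expect_equal(attr(ts2, "nDroppedHead"), 0L)
  expect_equal(seriesValues(ts2)[1], lin(12), tolerance = 1e-12)

  ## start 21:59, 72 h: tail discard count is 599
  ts3 <- harmonizeStart(makeRecording(21 + 59 / 60, 4320, lin))
  expect_equal(attr(ts3, "nDroppedHead"), 841L)
  expect_equal(attr(ts3, "nDroppedTail"), 599L)
})

test_that("harmonization rejects too-short or out-of-window recordings", {
  lin <- function(h) 30 + 0.0001 * h
  expect_error(harmonizeStart(makeRecording(18, 3000, lin)), "unusable")
  expect_error(harmonizeStart(makeRecording(9, 4320, lin)), "12:00")
})

test_that("harmonization is idempotent on an already-harmonized series", {
  rec <- generateSeries(toyArchetype(), zeroNoise(), seed = 2,
                        subjectSd = noSubjectSd())
  ts <- harmonizeStart(rec)
  ## re-wrap the harmonized series as a recording starting exactly at noon
  again <- structure(list(
    subjectId = "T001",
    startTime = as.POSIXct("2016-11-02 12:00:00", tz = "UTC"),
    time = as.POSIXct("2016-11-02 12:00:00", tz = "UTC") + (0:2879) * 60,
    temp = seriesValues(ts), truth = NULL), class = "RawRecording")
  expect_equal(seriesValues(harmonizeStart(again)), seriesValues(ts))
})

test_that("imputation is a fixed point on complete data and never alters observed cells", {
  set.seed(71)
  x <- matrix(rnorm(200), 20, 10)
  expect_identical(imputeMissing(x, ncp = 2)[, ], x[, ])

  xm <- x
  holes <- cbind(sample(20, 15, TRUE), sample(10, 15, TRUE))
  xm[holes] <- NA
  out <- imputeMissing(xm, ncp = 2)
  obs <- !is.na(xm)
  expect_identical(out[obs], xm[obs])
})

test_that("rank-1 matrices are recovered nearly exactly from 5% deletions", {
  set.seed(72)
  u <- runif(40, 1, 2); v <- runif(60, 1, 2)
  x <- outer(u, v)
  xm <- x
  del <- sample(length(x), round(0.05 * length(x)))
  xm[del] <- NA
  out <- imputeMissing(xm, ncp = 1)
  expect_lt(max(abs(out - x)), 1e-4)
})

test_that("a single hole in two perfectly correlated columns is the regression prediction", {
  set.seed(73)
  y1 <- rnorm(30)
  y2 <- 2 + 3 * y1
  x <- cbind(y1, y2)
  x[7, 2] <- NA
  out <- imputeMissing(x, ncp = 1)
  expect_lt(abs(out[7, 2] - (2 + 3 * y1[7])), 1e-3)
  expect_error(imputeMissing(cbind(y1, NA)), "observed")
})

test_that("imputation error decreases with the deletion fraction on average", {
  set.seed(74)
  base <- outer(runif(40, 1, 2), runif(60, 1, 2)) +
    matrix(rnorm(2400, 0, 0.02), 40)
  err <- vapply(c(0.02, 0.1, 0.3), function(f) {
    es <- vapply(1:5, function(r) {
      xm <- base
      xm[sample(length(base), round(f * length(base)))] <- NA
      mean(abs(imputeMissing(xm, ncp = 1) - base)[is.na(xm)])
    }, numeric(1))
    mean(es)
  }, numeric(1))
  expect_true(all(diff(err) > 0))
})

test_that("loess reproduces linear and constant inputs and commutes with shifts", {
  x <- seq_len(2880)
  lin <- 30 + 0.001 * x
  expect_equal(loessSmooth(lin), lin, tolerance = 1e-8)
  expect_equal(loessSmooth(rep(33, 2880)), rep(33, 2880), tolerance = 1e-10)
  set.seed(75)
  y <- 33 + cos(2 * pi * x / 1440) + rnorm(2880, 0, 0.3)
  expect_equal(loessSmooth(y + 5), loessSmooth(y) + 5, tolerance = 1e-8)
  expect_error(loessSmooth(c(NA, y[-1])), "impute")
  expect_error(loessSmooth(y, span = 1e-4), "span")
})

test_that("loess smoothing reduces RMSE against the generating curve", {
  x <- seq_len(2880)
  truth <- 33.5 + 1.4 * cos(2 * pi * ((x - 1) / 60) / 25.75)
  wins <- vapply(1:100, function(s) {
    set.seed(700 + s)
    y <- truth + rnorm(2880, 0, 0.4)
    sm <- loessSmooth(y)
    sqrt(mean((sm - truth)^2)) < sqrt(mean((y - truth)^2))
  }, logical(1))
  expect_gte(sum(wins), 99L)
})

test_that("spline smoothing agrees with loess and reproduces simple inputs", {
  x <- seq_len(2880)
  expect_equal(splineSmooth(rep(31, 2880)), rep(31, 2880), tolerance = 1e-6)
  lin <- 30 + 0.001 * x
  expect_equal(splineSmooth(lin), lin, tolerance = 1e-6)
  set.seed(76)
  y <- 33.5 + 1.4 * cos(2 * pi * ((x - 1) / 60) / 25.75) + rnorm(2880, 0, 0.4)
  expect_gt(cor(splineSmooth(y), loessSmooth(y)), 0.99)
})

test_that("smoothing preserves the grid", {
  set.seed(77)
  y <- 33 + rnorm(2880, 0, 0.2)
  expect_length(loessSmooth(y), 2880L)
  expect_length(splineSmooth(y), 2880L)
})

test_that("sensitivity filter flags smoother-dependent fits with reasons", {
  fits <- data.frame(subject_id = c("a", "b", "c"),
                     period_h = c(25, 25, 24.5),
                     amplitude = c(1.0, 1.0, 2.0))
  expect_equal(sum(sensitivityFilter(fits, fits)$excluded), 0L)

  alt <- fits
  alt$period_h[2] <- 28        # 3 h discrepancy -> period
  alt$amplitude[3] <- 1.0      # 50% relative discrepancy -> amplitude
  out <- sensitivityFilter(fits, alt)
  expect_equal(out$excluded, c(FALSE, TRUE, TRUE))
  expect_equal(out$reason, c("", "period", "amplitude"))

  expect_error(sensitivityFilter(fits, fits[1:2, ]), "subjects")
})

test_that("cohort harmonize/impute pipeline yields a complete 2880 x n assay", {
  arch <- toyArchetype(n_subjects = 4L)
  b <- generateCohort(arch, noiseSpec(sigma = 0.1, ar = 0.5,
                                      transientMagnitude = 1,
                                      transientDuration = 60,
                                      missingFraction = 0.08,
                                      quantizationStep = 0.0625), seed = 81)
  co <- harmonizeCohort(b)
  expect_s4_class(co, "TemperatureCohort")
  expect_equal(dim(temperatureMatrix(co)), c(2880L, 4L))
  expect_gt(sum(is.na(temperatureMatrix(co))), 0)
  co2 <- imputeCohort(co, ncp = 2)
  expect_false(anyNA(temperatureMatrix(co2)))
  ## observed cells untouched
  m0 <- temperatureMatrix(co); m2 <- temperatureMatrix(co2)
  expect_identical(m2[!is.na(m0)], m0[!is.na(m0)])
  ## per-subject interpolation fallback also completes the assay
  co3 <- imputeCohort(co, perSubject = TRUE)
  expect_false(anyNA(temperatureMatrix(co3)))
})

test_that("default-noise cohorts lose fewer than 15% of subjects to the sensitivity filter", {
  arch <- defaultArchetypes()
  arch$n_subjects <- c(14L, 14L, 14L)
  b <- generateCohort(arch, noiseSpec(), seed = 82)
  co <- smoothCohort(imputeCohort(harmonizeCohort(b)), "loess")
  fitsL <- fitCosinorCohort(co, assay = "smoothed")
  coS <- smoothCohort(co, "spline")
  fitsS <- fitCosinorCohort(coS, assay = "smoothed")
  out <- sensitivityFilter(fitsL, fitsS)
  expect_lt(mean(out$excluded), 0.15)
})
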