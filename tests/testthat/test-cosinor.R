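minuteGrid <- function(n = 2880) (seq_len(n) - 1) / 60

test_that("fixed-period fits recover exact cosinor curves to machine precision", {
  t <- minuteGrid()
  y <- 34 + 2 * cos(2 * pi * t / 24)
  f <- fitFixedPeriod(y, tau = 24)
  expect_equal(f@mesor, 34, tolerance = 1e-9)
  expect_equal(f@amplitude, 2, tolerance = 1e-9)
  expect_equal(f@acrophase, 0, tolerance = 1e-9)
  expect_lt(f@rss, 1e-12)
  expect_equal(f@amplitude, sqrt(f@beta^2 + f@gamma^2), tolerance = 1e-12)
})

test_that("constant series give zero amplitude and an undefined period", {
  y <- rep(33, 2880)
  f <- fitFixedPeriod(y, tau = 24)
  expect_equal(f@mesor, 33)
  expect_equal(f@amplitude, 0, tolerance = 1e-9)
  expect_lt(f@rss, 1e-15)
  g <- estimatePeriod(y)
  expect_true(is.na(g@period))
  expect_equal(g@amplitude, 0)
})

test_that("singular designs and bad inputs are rejected", {
  t <- minuteGrid(240)  # 4-h window
  y <- 33 + 0.5 * cos(2 * pi * t / 24)
  expect_error(fitFixedPeriod(y, tau = 5000, tHours = t), "singular")
  expect_error(fitFixedPeriod(c(NA, y[-1]), tau = 24), "impute")
  expect_error(fitFixedPeriod(y[1:2], tau = 24), "3 samples")
  expect_error(estimatePeriod(y, tauRange = c(30, 20), tHours = t), "tauRange")
})

test_that("fixed-period fits agree with a brute-force (M, A, phi) grid search", {
  t <- minuteGrid()
  set.seed(101)
  y <- 33.5 + 1.3 * cos(2 * pi * t / 24 + 0.7) + rnorm(2880, 0, 0.3)
  f <- fitFixedPeriod(y, tau = 24)
  ## oracle: profile phi on a fine grid; M, A by linear LS given phi
  phis <- seq(-pi, pi, length.out = 2001)
  best <- list(rss = Inf)
  for (p in phis) {
    cc <- cos(2 * pi * t / 24 + p)
    co <- stats::coef(stats::lm.fit(cbind(1, cc), y))
    r <- sum((y - co[1] - co[2] * cc)^2)
    if (co[2] >= 0 && r < best$rss) best <- list(rss = r, M = co[1], A = co[2])
  }
  expect_lt(abs(f@mesor - best$M), 0.01)
  expect_lt(abs(f@amplitude - best$A), 0.01)
  expect_lte(f@rss, best$rss + 1e-6)
})

test_that("period estimation recovers noiseless periods exactly and never at a boundary", {
  t <- minuteGrid()
  y25 <- 33 + 1.5 * cos(2 * pi * t / 25)
  f25 <- estimatePeriod(y25)
  expect_lt(abs(f25@period - 25), 0.1 / 60)
  y24 <- 33 + 1.5 * cos(2 * pi * t / 24)
  f24 <- estimatePeriod(y24)
  expect_lt(abs(f24@period - 24), 0.1 / 60)
  expect_gt(f24@period, 20); expect_lt(f24@period, 30)
})

test_that("mean estimated period across noisy series is close to the generating value", {
  arch <- toyArchetype(mesor = 33.46, amplitude = 1.38, period = 25.75)
  nz <- noiseSpec(sigma = 0.4 * sqrt(1 - 0.81), ar = 0.9,
                  transientMagnitude = 0, missingFraction = 0,
                  quantizationStep = 0)
  taus <- vapply(1:40, function(s) {
    rec <- generateSeries(arch, nz, seed = 9000 + s, subjectSd = noSubjectSd())
    estimatePeriod(seriesValues(harmonizeStart(rec)))@period
  }, numeric(1))
  expect_lt(abs(mean(taus) - 25.75), 0.15)
})

test_that("profiled-period rss is never worse than the 24-h fixed fit", {
  t <- minuteGrid()
  set.seed(102)
  for (s in 1:5) {
    y <- 33 + 1.2 * cos(2 * pi * t / runif(1, 23, 27) + runif(1, -pi, pi)) +
      rnorm(2880, 0, 0.3)
    expect_lte(estimatePeriod(y)@rss, fitFixedPeriod(y, 24)@rss + 1e-9)
  }
})

test_that("quadrant-corrected acrophase matches its defining equations in all quadrants", {
  expect_equal(correctedAcrophase(1, 0), 0)
  expect_equal(correctedAcrophase(0, 1), -pi / 2)
  expect_equal(correctedAcrophase(0, -1), pi / 2)
  expect_equal(correctedAcrophase(-1, 0), pi)
  expect_true(is.na(correctedAcrophase(0, 0)))
  set.seed(103)
  for (i in 1:200) {
    b <- rnorm(1); g <- rnorm(1)
    phi <- correctedAcrophase(b, g)
    A <- sqrt(b^2 + g^2)
    expect_equal(A * cos(phi), b, tolerance = 1e-9)
    expect_equal(-A * sin(phi), g, tolerance = 1e-9)
    expect_true(phi > -pi && phi <= pi)
  }
})

test_that("acrophase peak times match brute-force argmax of the curve within 2 s", {
  set.seed(104)
  tau <- 24
  tGrid <- seq(0, tau, by = 1 / 3600)  # 1-s grid in hours
  for (i in 1:1000) {
    b <- rnorm(1); g <- rnorm(1)
    if (b == 0 && g == 0) next
    phi <- correctedAcrophase(b, g)
    tStar <- (-phi * tau / (2 * pi)) %% tau
    curve <- b * cos(2 * pi * tGrid / tau) + g * sin(2 * pi * tGrid / tau)
    tBrute <- tGrid[which.max(curve)] %% tau
    d <- abs(tStar - tBrute); d <- min(d, tau - d)
    expect_lt(d, 2 / 3600 + 1e-9)
  }
})

test_that("model extrema map to clock time with the noon window start", {
  t <- minuteGrid()
  f <- fitFixedPeriod(34 + cos(2 * pi * t / 24), tau = 24)
  ext <- extremaClockTimes(f)
  expect_equal(clockDist(ext[["acrophase_clock"]], 12), 0, tolerance = 1e-6)
  expect_equal(clockDist(ext[["bathyphase_clock"]], 0), 0, tolerance = 1e-6)
  f2 <- fitFixedPeriod(34 + cos(2 * pi * t / 24 - pi), tau = 24)
  ext2 <- extremaClockTimes(f2)
  expect_equal(clockDist(ext2[["acrophase_clock"]], 0), 0, tolerance = 1e-6)
  ## zero-amplitude: undefined
  expect_true(all(is.na(extremaClockTimes(fitFixedPeriod(rep(33, 100), 24,
                                                         tHours = minuteGrid(100))))))
})

test_that("clock extrema agree with brute-force extrema of the reconstructed curve", {
  set.seed(105)
  for (i in 1:25) {
    M <- runif(1, 32, 35); A <- runif(1, 0.5, 2)
    tau <- runif(1, 22, 28); phi <- runif(1, -pi, pi - 1e-6)
    t <- minuteGrid()
    y <- M + A * cos(2 * pi * t / tau + phi)
    f <- fitFixedPeriod(y, tau = tau)
    ext <- extremaClockTimes(f)
    tFine <- seq(0, tau, by = 1 / 120)
    curve <- M + A * cos(2 * pi * tFine / tau + phi)
    acroBrute <- (12 + tFine[which.max(curve)]) %% 24
    bathyBrute <- (12 + tFine[which.min(curve)]) %% 24
    expect_lt(clockDist(ext[["acrophase_clock"]], acroBrute), 1 / 60 + 1e-9)
    expect_lt(clockDist(ext[["bathyphase_clock"]], bathyBrute), 1 / 60 + 1e-9)
  }
})

test_that("observed extrema use per-cycle circular means with wrap handling", {
  t <- minuteGrid()
  ## pure 24-h cosine peaking 02:30: clock peak = 2.5 -> t = 14.5 h after noon
  y <- 33 + cos(2 * pi * (t - 14.5) / 24)
  obs <- observedExtrema(y)
  expect_equal(clockDist(obs$acrophase_clock, 2.5), 0, tolerance = 1e-2)

  ## two cycles with peaks 02:00 and 03:00 -> circular mean 02:30
  mk <- function(peakClock) {
    tt <- minuteGrid(1440)
    33 + cos(2 * pi * (tt - ((peakClock - 12) %% 24)) / 24)
  }
  y2 <- c(mk(2), mk(3))
  obs2 <- observedExtrema(y2)
  expect_equal(clockDist(obs2$acrophase_clock, 2.5), 0, tolerance = 0.02)

  ## peaks 23:30 and 00:30 -> 00:00, not 12:00
  y3 <- c(mk(23.5), mk(0.5))
  obs3 <- observedExtrema(y3)
  expect_equal(clockDist(obs3$acrophase_clock, 0), 0, tolerance = 0.02)

  ## constant cycles are skipped; all-constant is undefined
  y4 <- c(rep(33, 1440), mk(2))
  expect_equal(clockDist(observedExtrema(y4)$acrophase_clock, 2), 0,
               tolerance = 0.02)
  expect_true(is.na(observedExtrema(rep(33, 2880))$acrophase_clock))
  expect_error(observedExtrema(rep(33, 1000)), "cycles")
})

test_that("fits round-trip: refitting the reconstructed curve returns identical parameters", {
  t <- minuteGrid()
  set.seed(106)
  y <- 33.2 + 1.1 * cos(2 * pi * t / 25.3 + 1.9) + rnorm(2880, 0, 0.2)
  f <- estimatePeriod(y)
  recon <- f@mesor + f@amplitude * cos(2 * pi * t / f@period + f@acrophase)
  f2 <- fitFixedPeriod(recon, tau = f@period)
  expect_equal(f2@mesor, f@mesor, tolerance = 1e-9)
  expect_equal(f2@amplitude, f@amplitude, tolerance = 1e-9)
  expect_equal(f2@acrophase, f@acrophase, tolerance = 1e-9)
})

test_that("cohort-level fitting returns the full parameter table", {
  arch <- toyArchetype(n_subjects = 3L)
  b <- generateCohort(arch, zeroNoise(), seed = 107, subjectSd = noSubjectSd())
  co <- smoothCohort(imputeCohort(harmonizeCohort(b)), "loess")
  tab <- fitCosinorCohort(co)
  expect_equal(nrow(tab), 3L)
  expect_named(tab, c("subject_id", "mesor", "amplitude", "period_h",
                      "acrophase_rad", "acro_clock_h", "bathy_clock_h",
                      "obs_acro_clock_h", "obs_bathy_clock_h", "rss"))
  expect_true(all(abs(tab$mesor - 34) < 0.05))
})
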