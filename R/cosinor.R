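## Single-component cosinor rhythmometry:
##   Y(t) = M + A cos(2 pi t / tau + phi) + e(t)
## fitted per subject by linearized least squares (beta, gamma parametrization)
## with the period profiled out by a 1-D search, full-quadrant acrophase
## resolution, and model-based and observed extrema in clock time.

## least-squares fit of Y = M + beta cos(w t) + gamma sin(w t) at fixed tau;
## t in hours, w = 2 pi / tau
.cosinorLS <- function(y, t, tau) {
  w <- 2 * pi / tau
  cc <- cos(w * t); ss <- sin(w * t)
  X <- cbind(1, cc, ss)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12)
    stop("singular cosinor design: period too long for the window",
         call. = FALSE)
  coef <- unname(drop(solve(XtX, crossprod(X, y))))
  res <- y - drop(X %*% coef)
  list(coef = coef, rss = sum(res^2))
}

#' Quadrant-corrected acrophase from linearized coefficients
#'
#' Resolves the acrophase angle `phi` such that `beta = A cos(phi)` and
#' `gamma = -A sin(phi)` over all four quadrants via an explicit sign-case
#' table (equivalent to a full-range two-argument arctangent), so the fitted
#' peak lands at `t* = (-phi tau / (2 pi)) mod tau` regardless of quadrant.
#'
#' @param beta,gamma linearized cosinor coefficients (degC).
#' @return `phi` in radians, in `(-pi, pi]`; `NA` when `beta = gamma = 0`
#'   (amplitude zero, phase undefined).
#' @export
correctedAcrophase <- function(beta, gamma) {
  if (is.na(beta) || is.na(gamma)) return(NA_real_)
  if (beta == 0 && gamma == 0) return(NA_real_)
  if (beta == 0) return(if (gamma < 0) pi / 2 else -pi / 2)
  base <- atan(-gamma / beta)
  if (beta > 0) return(base)
  if (gamma < 0) base + pi else if (gamma > 0) base - pi else pi
}

## CosinorFit assembly shared by the fitting entry points
.makeFit <- function(y, t, tau, subjectId, t0Clock = 12) {
  ls <- .cosinorLS(y, t, tau)
  m <- ls$coef[1]; beta <- ls$coef[2]; gamma <- ls$coef[3]
  a <- sqrt(beta^2 + gamma^2)
  if (a < 1e-8 * max(1, abs(m))) {  # numerically zero: phase undefined
    beta <- 0; gamma <- 0; a <- 0
  }
  phi <- correctedAcrophase(beta, gamma)
  fit <- new("CosinorFit", subjectId = as.character(subjectId), mesor = m,
             amplitude = a, acrophase = if (is.na(phi)) NA_real_ else phi,
             period = tau, beta = beta, gamma = gamma, rss = ls$rss)
  clocks <- extremaClockTimes(fit, t0Clock = t0Clock)
  fit@acroClock <- clocks[["acrophase_clock"]]
  fit@bathyClock <- clocks[["bathyphase_clock"]]
  fit
}

#' Fit the cosinor model at a fixed period
#'
#' @param values numeric series (degC) or [TemperatureSeries-class]; no `NA`.
#' @param tau period in hours (> 0).
#' @param tHours time grid in hours since window start; defaults to the
#'   1-min grid `(0, 1/60, 2/60, ...)`.
#' @param subjectId identifier stored in the fit.
#' @param t0Clock clock hour of the window start (12 after harmonization).
#' @return a [CosinorFit-class].
#' @export
fitFixedPeriod <- function(values, tau, tHours = NULL, subjectId = NA,
                           t0Clock = 12) {
  if (is(values, "TemperatureSeries")) {
    if (is.na(subjectId)) subjectId <- subjectId(values)
    values <- seriesValues(values)
  }
  if (anyNA(values)) stop("series contains missing values; impute first",
                          call. = FALSE)
  if (length(values) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (is.null(tHours)) tHours <- (seq_along(values) - 1) / 60
  .makeFit(values, tHours, tau, subjectId, t0Clock)
}

#' Estimate the best-fitting period by iterative cosinor fitting
#'
#' Minimizes the residual sum of squares over the period: a coarse grid at
#' 6-min steps across `tauRange`, then golden-section refinement of the
#' bracketing interval down to `resolutionMin`. Returns the full cosinor fit
#' at the optimum. A series whose RSS profile is flat to machine precision
#' (constant input) gets an undefined period and amplitude 0.
#'
#' @inheritParams fitFixedPeriod
#' @param tauRange search bounds in hours (default `c(20, 30)`, bracketing
#'   the near-24-h rhythms this device records).
#' @param resolutionMin period resolution in minutes (>= 1/60).
#' @return a [CosinorFit-class].
#' @export
estimatePeriod <- function(values, tauRange = c(20, 30), resolutionMin = 0.1,
                           tHours = NULL, subjectId = NA, t0Clock = 12) {
  if (is(values, "TemperatureSeries")) {
    if (is.na(subjectId)) subjectId <- subjectId(values)
    values <- seriesValues(values)
  }
  if (anyNA(values)) stop("series contains missing values; impute first",
                          call. = FALSE)
  if (is.null(tHours)) tHours <- (seq_along(values) - 1) / 60
  if (resolutionMin < 1 / 60) stop("resolution must be >= 1 second", call. = FALSE)
  winH <- diff(range(tHours))
  if (tauRange[1] <= 0 || tauRange[2] <= tauRange[1] || tauRange[2] > 2 * winH)
    stop("tauRange must be increasing, positive and within the window",
         call. = FALSE)

  grid <- seq(tauRange[1], tauRange[2], by = 0.1)
  rssGrid <- vapply(grid, function(tau) .cosinorLS(values, tHours, tau)$rss,
                    numeric(1))
  if (diff(range(rssGrid)) <= 1e-12 * (abs(mean(rssGrid)) + 1e-12)) {
    ## flat profile: constant series, period undefined
    m <- mean(values)
    fit <- new("CosinorFit", subjectId = as.character(subjectId), mesor = m,
               amplitude = 0, acrophase = NA_real_, period = NA_real_,
               beta = 0, gamma = 0, rss = sum((values - m)^2))
    return(fit)
  }
  i <- which.min(rssGrid)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]

  ## golden-section refinement of the bracket
  gr <- (sqrt(5) - 1) / 2
  tolH <- resolutionMin / 60
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- .cosinorLS(values, tHours, x1)$rss
  f2 <- .cosinorLS(values, tHours, x2)$rss
  while ((b - a) > tolH) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a)
      f1 <- .cosinorLS(values, tHours, x1)$rss
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a)
      f2 <- .cosinorLS(values, tHours, x2)$rss
    }
  }
  tauHat <- (a + b) / 2
  ## keep the grid optimum if refinement did not improve on it
  if (.cosinorLS(values, tHours, tauHat)$rss > rssGrid[i]) tauHat <- grid[i]
  .makeFit(values, tHours, tauHat, subjectId, t0Clock)
}

#' Model-based extrema in clock time
#'
#' First peak and trough of the fitted curve after the window start, mapped to
#' wall-clock time via the window's start clock hour. The model trough sits
#' exactly `tau / 2` after the peak.
#'
#' @param fit a [CosinorFit-class] with `amplitude > 0`.
#' @param t0Clock clock hour of the window start.
#' @return named numeric `c(acrophase_clock, bathyphase_clock)` in hours;
#'   `NA` for an undefined (zero-amplitude) fit.
#' @export
extremaClockTimes <- function(fit, t0Clock = 12) {
  if (is.na(fit@period) || is.na(fit@acrophase) || fit@amplitude <= 0)
    return(c(acrophase_clock = NA_real_, bathyphase_clock = NA_real_))
  tau <- fit@period
  tStar <- (-fit@acrophase * tau / (2 * pi)) %% tau
  tTrough <- (tStar + tau / 2) %% tau
  c(acrophase_clock = (t0Clock + tStar) %% 24,
    bathyphase_clock = (t0Clock + tTrough) %% 24)
}

#' Observed extrema on smoothed data
#'
#' Splits the smoothed series into consecutive 24-h cycles from the window
#' start, takes each cycle's argmax/argmin in clock time, and summarizes with
#' the circular mean over cycles (period 24 h), so peaks straddling midnight
#' average correctly. Constant cycles are skipped.
#'
#' @param values smoothed numeric vector covering >= 2 full 24-h cycles, or a
#'   [TemperatureSeries-class].
#' @param t0Clock clock hour of the first sample.
#' @return list with `acrophase_clock`, `bathyphase_clock` (circular-mean
#'   clock hours, `NA` if every cycle is constant) and `per_cycle`
#'   (`data.frame` of per-cycle times).
#' @export
observedExtrema <- function(values, t0Clock = 12) {
  if (is(values, "TemperatureSeries")) values <- seriesValues(values)
  n <- length(values)
  if (n < 2 * 1440L) stop("need at least two full 24-h cycles", call. = FALSE)
  nCycles <- n %/% 1440L
  acro <- bathy <- rep(NA_real_, nCycles)
  for (cyc in seq_len(nCycles)) {
    idx <- ((cyc - 1L) * 1440L + 1L):(cyc * 1440L)
    seg <- values[idx]
    if (diff(range(seg)) < 1e-12) next
    acro[cyc] <- (t0Clock + (idx[which.max(seg)] - 1) / 60) %% 24
    bathy[cyc] <- (t0Clock + (idx[which.min(seg)] - 1) / 60) %% 24
  }
  list(acrophase_clock = circularMeanClock(acro),
       bathyphase_clock = circularMeanClock(bathy),
       per_cycle = data.frame(cycle = seq_len(nCycles), acrophase = acro,
                              bathyphase = bathy))
}

#' Fit the cosinor battery across a cohort
#'
#' Runs [estimatePeriod()] per subject on the requested assay and appends the
#' observed (smoothed-data) extrema, yielding the per-subject parameter table
#' used by clustering and association analyses.
#'
#' @param cohort a [TemperatureCohort-class] (imputed; smoothed if
#'   `assay = "smoothed"`).
#' @param assay `"smoothed"` (default, falling back to `"temperature"` when no
#'   smoothed assay exists) or `"temperature"`.
#' @param tauRange,resolutionMin passed to [estimatePeriod()].
#' @return `data.frame`: `subject_id`, `mesor`, `amplitude`, `period_h`,
#'   `acrophase_rad`, `acro_clock_h`, `bathy_clock_h`, `obs_acro_clock_h`,
#'   `obs_bathy_clock_h`, `rss`.
#' @export
fitCosinorCohort <- function(cohort, assay = "smoothed",
                             tauRange = c(20, 30), resolutionMin = 0.1) {
  if (assay == "smoothed" && is.null(smoothedMatrix(cohort)))
    assay <- "temperature"
  m <- SummarizedExperiment::assay(cohort, assay)
  rows <- lapply(colnames(m), function(id) {
    y <- m[, id]
    fit <- estimatePeriod(y, tauRange = tauRange,
                          resolutionMin = resolutionMin, subjectId = id)
    obs <- observedExtrema(y)
    data.frame(subject_id = id, mesor = fit@mesor, amplitude = fit@amplitude,
               period_h = fit@period, acrophase_rad = fit@acrophase,
               acro_clock_h = fit@acroClock, bathy_clock_h = fit@bathyClock,
               obs_acro_clock_h = obs$acrophase_clock,
               obs_bathy_clock_h = obs$bathyphase_clock, rss = fit@rss,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
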