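## Preprocessing: start-time harmonization to a canonical 48-h noon window,
## cross-subject low-rank imputation, loess / smoothing-spline smoothing, and
## the smoother-sensitivity exclusion rule.

#' Harmonize a raw recording to the canonical 48-h noon window
#'
#' All records are set to start from 12 noon: samples before the first noon
#' strictly after recording start are dropped (a record starting exactly at
#' noon keeps its first sample), and exactly the next 48 h (2880 one-minute
#' samples) are returned. This removes the warm-up fluctuation of the first
#' hours and gives every subject an equal-length vector. Samples absent from
#' the recording are flagged missing, never silently filled.
#'
#' @param raw a `RawRecording` (from [generateSeries()] or
#'   [readTemperatureCsv()]); must start between 12:00 and 23:59 and cover the
#'   full 48-h window.
#' @return a [TemperatureSeries-class]; attributes `nDroppedHead` and
#'   `nDroppedTail` count discarded samples.
#' @export
harmonizeStart <- function(raw) {
  stopifnot(inherits(raw, "RawRecording"))
  start <- raw$startTime
  n <- length(raw$temp)
  if (n < 1L) stop("empty recording", call. = FALSE)
  startClock <- clockHours(start)
  if (startClock < 12)
    stop("recording must start between 12:00 and 23:59", call. = FALSE)
  ## first noon strictly after start; keep the start itself if exactly noon
  day <- as.POSIXct(format(start, "%Y-%m-%d"), tz = "UTC")
  noon0 <- day + 12 * 3600
  w0 <- if (abs(as.numeric(difftime(start, noon0, units = "secs"))) < 1)
    start else noon0 + 86400
  offset <- round(as.numeric(difftime(w0, start, units = "mins")))
  idx <- offset + seq_len(2880L)
  if (max(idx) > n + 0L && (n - offset) < 2880L)
    stop("recording too short to cover 48 h from the first noon; ",
         "subject flagged unusable", call. = FALSE)
  values <- raw$temp[idx]
  ts <- TemperatureSeries(raw$subjectId, values, is.na(values), t0Hour = 12)
  attr(ts, "nDroppedHead") <- offset
  attr(ts, "nDroppedTail") <- n - (offset + 2880L)
  ts
}

#' Harmonize a whole cohort into a TemperatureCohort
#'
#' Applies [harmonizeStart()] per subject; subjects whose recording cannot
#' cover the 48-h window are dropped and reported.
#'
#' @param recordings list of `RawRecording`s, or a `CohortBundle`.
#' @param subjectData optional per-subject `data.frame` keyed by `subject_id`
#'   merged into `colData` (a `CohortBundle`'s truth table is used
#'   automatically).
#' @return a [TemperatureCohort-class]; unusable subjects are listed in
#'   `metadata(x)$unusable`.
#' @export
harmonizeCohort <- function(recordings, subjectData = NULL) {
  if (inherits(recordings, "CohortBundle")) {
    if (is.null(subjectData)) subjectData <- recordings$truth
    recordings <- recordings$recordings
  }
  out <- lapply(recordings, function(r)
    tryCatch(harmonizeStart(r), error = function(e) e))
  bad <- vapply(out, inherits, logical(1), "error")
  series <- out[!bad]
  mat <- vapply(series, seriesValues, numeric(2880))
  colnames(mat) <- vapply(series, subjectId, character(1))
  cd <- NULL
  if (!is.null(subjectData)) {
    m <- subjectData[match(colnames(mat), subjectData$subject_id), , drop = FALSE]
    rownames(m) <- colnames(mat)
    cd <- S4Vectors::DataFrame(m)
  }
  TemperatureCohort(mat, subjectData = cd,
                    metadata = list(unusable = names(out)[bad]))
}

#' Regularized iterative principal-components imputation
#'
#' Completes a subjects x timepoints matrix by iterating: center columns,
#' truncate the SVD at rank `ncp` with singular values shrunk by the mean
#' residual variance, refill only the missing cells, until the largest change
#' on the missing cells is below `tol`. Observed cells are never altered; the
#' shrinkage prevents the overfitting of a plain truncated SVD on sparse
#' patterns.
#'
#' @param x numeric matrix with `NA`s; every column needs >= 1 observed value.
#' @param ncp number of components (>= 1).
#' @param tol convergence tolerance on the imputed cells.
#' @param maxIter iteration cap; non-convergence returns the last iterate with
#'   attribute `converged = FALSE` and a warning.
#' @return completed matrix; attributes `converged` and `iterations`.
#' @export
imputeMissing <- function(x, ncp = 2, tol = 1e-6, maxIter = 1000) {
  x <- as.matrix(x)
  if (ncp < 1) stop("ncp must be >= 1", call. = FALSE)
  miss <- is.na(x)
  if (!any(miss)) {
    attr(x, "converged") <- TRUE; attr(x, "iterations") <- 0L
    return(x)
  }
  if (any(colSums(!miss) == 0))
    stop("every column needs at least one observed value", call. = FALSE)
  mu0 <- colMeans(x, na.rm = TRUE)
  x[miss] <- matrix(mu0, nrow(x), ncol(x), byrow = TRUE)[miss]

  n <- nrow(x); p <- ncol(x)
  ncp <- min(ncp, n - 1L, p - 1L)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    ## SVD via the smaller Gram matrix (n << p for cohort use)
    if (n <= p) {
      eg <- eigen(tcrossprod(xc), symmetric = TRUE)
      d2 <- pmax(eg$values, 0)
      d <- sqrt(d2)
      keep <- seq_len(ncp)
      u <- eg$vectors[, keep, drop = FALSE]
      v <- crossprod(xc, u) %*% diag(1 / pmax(d[keep], 1e-300), ncp)
    } else {
      eg <- eigen(crossprod(xc), symmetric = TRUE)
      d2 <- pmax(eg$values, 0)
      d <- sqrt(d2)
      keep <- seq_len(ncp)
      v <- eg$vectors[, keep, drop = FALSE]
      u <- xc %*% v %*% diag(1 / pmax(d[keep], 1e-300), ncp)
    }
    sig2 <- if (length(d2) > ncp) mean(d2[-seq_len(ncp)]) else 0
    dShrunk <- pmax((d2[keep] - sig2) / pmax(d[keep], 1e-300), 0)
    fit <- sweep(u %*% (dShrunk * t(v)), 2, mu, `+`)
    delta <- max(abs(fit[miss] - x[miss]))
    x[miss] <- fit[miss]
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("imputation did not converge in ", maxIter, " iterations")
  attr(x, "converged") <- converged
  attr(x, "iterations") <- it
  x
}

#' Impute a TemperatureCohort
#'
#' Cross-subject variant of [imputeMissing()]: operates on the subjects x
#' timepoints matrix so each subject borrows the cohort's dominant rhythm
#' shapes. Set `perSubject = TRUE` for within-subject linear interpolation
#' only (no cross-subject borrowing).
#'
#' @param cohort a [TemperatureCohort-class].
#' @param ncp components for the low-rank scheme.
#' @param perSubject fall back to per-subject linear interpolation.
#' @return the cohort with a complete `temperature` assay; the pre-imputation
#'   mask is kept in `metadata(x)$missingMask`.
#' @export
imputeCohort <- function(cohort, ncp = 2, perSubject = FALSE) {
  m <- temperatureMatrix(cohort)
  mask <- is.na(m)
  if (perSubject) {
    filled <- apply(m, 2, function(y) {
      if (!anyNA(y)) return(y)
      idx <- seq_along(y)
      stats::approx(idx[!is.na(y)], y[!is.na(y)], xout = idx, rule = 2)$y
    })
  } else {
    filled <- t(imputeMissing(t(m), ncp = ncp))
  }
  SummarizedExperiment::assay(cohort, "temperature") <- filled
  S4Vectors::metadata(cohort)$missingMask <- mask
  cohort
}

#' Loess smoothing of a temperature series
#'
#' Local quadratic regression with tricube weights over a `span` fraction of
#' the 2880-point grid, evaluated at every grid point (default span 0.3).
#'
#' @param values numeric vector (imputed; no `NA`) or a
#'   [TemperatureSeries-class].
#' @param span fraction of points in each local fit, in `(0, 1]`.
#' @return numeric smoothed vector on the same grid.
#' @export
loessSmooth <- function(values, span = 0.3) {
  if (is(values, "TemperatureSeries")) values <- seriesValues(values)
  if (anyNA(values)) stop("impute before smoothing", call. = FALSE)
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]", call. = FALSE)
  n <- length(values)
  if (span * n < 4)
    stop("span too small: local quadratic design is singular", call. = FALSE)
  x <- seq_len(n)
  fit <- stats::loess(values ~ x, span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "interpolate"))
  as.numeric(stats::predict(fit, newdata = data.frame(x = x)))
}

#' Penalized smoothing-spline smoothing
#'
#' Cubic smoothing spline with the penalty chosen by generalized
#' cross-validation; the sensitivity companion to [loessSmooth()]. When GCV
#' degenerates toward an interpolating fit (noiseless input), the fit falls
#' back to a fixed 30 effective degrees of freedom with a warning.
#'
#' @param values numeric vector (imputed) or a [TemperatureSeries-class].
#' @return numeric smoothed vector on the same grid.
#' @export
splineSmooth <- function(values) {
  if (is(values, "TemperatureSeries")) values <- seriesValues(values)
  if (anyNA(values)) stop("impute before smoothing", call. = FALSE)
  n <- length(values)
  x <- seq_len(n)
  fit <- tryCatch(stats::smooth.spline(x, values, cv = FALSE),
                  error = function(e) NULL)
  if (is.null(fit) || fit$df > 0.9 * fit$n) {
    warning("GCV degenerate; falling back to df = 30")
    fit <- stats::smooth.spline(x, values, df = 30)
  }
  as.numeric(stats::predict(fit, x)$y)
}

#' Smooth every subject of a cohort
#'
#' @param cohort an imputed [TemperatureCohort-class].
#' @param method `"loess"` or `"spline"`.
#' @param span loess span.
#' @return the cohort with a `"smoothed"` assay added.
#' @export
smoothCohort <- function(cohort, method = c("loess", "spline"), span = 0.3) {
  method <- match.arg(method)
  m <- temperatureMatrix(cohort)
  sm <- apply(m, 2, function(y)
    if (method == "loess") loessSmooth(y, span) else splineSmooth(y))
  SummarizedExperiment::assays(cohort)$smoothed <- sm
  S4Vectors::metadata(cohort)$smoothing <- list(method = method, span = span)
  cohort
}

#' Smoother-sensitivity exclusion
#'
#' Flags subjects whose cosinor parameters depend strongly on the smoothing
#' method: a subject is excluded when the loess-based and spline-based period
#' estimates differ by more than `tauThreshold` hours, or when the relative
#' amplitude discrepancy exceeds `ampThreshold`.
#'
#' @param fitsLoess,fitsSpline `data.frame`s of per-subject cosinor parameters
#'   (columns `subject_id`, `period_h`, `amplitude`) fitted on loess- and
#'   spline-smoothed series; must cover the same subjects.
#' @param tauThreshold period discrepancy threshold, hours.
#' @param ampThreshold relative amplitude discrepancy threshold.
#' @return `data.frame` with `subject_id`, `excluded`, `reason`
#'   (`""`, `"period"`, `"amplitude"` or `"period+amplitude"`).
#' @export
sensitivityFilter <- function(fitsLoess, fitsSpline, tauThreshold = 2,
                              ampThreshold = 0.25) {
  if (!setequal(fitsLoess$subject_id, fitsSpline$subject_id))
    stop("fit lists cover different subjects", call. = FALSE)
  s <- fitsSpline[match(fitsLoess$subject_id, fitsSpline$subject_id), ]
  dTau <- abs(fitsLoess$period_h - s$period_h)
  relA <- abs(fitsLoess$amplitude - s$amplitude) /
    pmax(fitsLoess$amplitude, s$amplitude)
  badTau <- !is.na(dTau) & dTau > tauThreshold
  badAmp <- !is.na(relA) & relA > ampThreshold
  reason <- rep("", nrow(fitsLoess))
  reason[badTau] <- "period"
  reason[badAmp] <- paste0(ifelse(badTau[badAmp], "period+", ""), "amplitude")
  data.frame(subject_id = fitsLoess$subject_id,
             excluded = badTau | badAmp, reason = reason,
             stringsAsFactors = FALSE)
}
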