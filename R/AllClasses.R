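#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

## ---------------------------------------------------------------------------
## TemperatureSeries: one subject's harmonized 48-h minute grid
## ---------------------------------------------------------------------------

#' TemperatureSeries: a harmonized single-subject temperature vector
#'
#' One subject's wrist temperature on the canonical minute grid: 48 h starting
#' at the first noon after recording start (2880 samples). `values` may contain
#' `NA` before imputation; `missingMask` records which samples were absent from
#' the raw recording.
#'
#' @slot subjectId character subject identifier.
#' @slot values numeric length-2880 temperature vector (degrees C).
#' @slot missingMask logical length-2880 pre-imputation missingness flags.
#' @slot t0Hour numeric clock hour of the first sample (12 after harmonization).
#' @exportClass TemperatureSeries
setClass("TemperatureSeries",
  representation(subjectId = "character", values = "numeric",
                 missingMask = "logical", t0Hour = "numeric"),
  prototype(t0Hour = 12)
)

setValidity("TemperatureSeries", function(object) {
  msg <- NULL
  if (length(object@values) != 2880L)
    msg <- c(msg, "values must have length 2880 (48 h at 1-min resolution)")
  if (length(object@missingMask) != length(object@values))
    msg <- c(msg, "missingMask must match values in length")
  v <- object@values[!is.na(object@values)]
  if (length(v) && (min(v) < 20 || max(v) > 42))
    msg <- c(msg, "temperatures outside physiological bounds [20, 42] degC")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TemperatureSeries
#' @param subjectId subject identifier.
#' @param values numeric length-2880 vector, `NA` for missing samples.
#' @param missingMask logical mask; defaults to `is.na(values)`.
#' @param t0Hour clock hour of the first sample.
#' @return a [TemperatureSeries-class] object.
#' @export
TemperatureSeries <- function(subjectId, values, missingMask = is.na(values),
                              t0Hour = 12) {
  new("TemperatureSeries", subjectId = as.character(subjectId),
      values = as.numeric(values), missingMask = as.logical(missingMask),
      t0Hour = t0Hour)
}

#' @describeIn TemperatureSeries-class values accessor
#' @param x,object a `TemperatureSeries`.
#' @export
seriesValues <- function(x) x@values

#' @describeIn TemperatureSeries-class missingness accessor
#' @export
missingMask <- function(x) x@missingMask

#' @describeIn TemperatureSeries-class subject identifier accessor
#' @export
subjectId <- function(x) x@subjectId

setMethod("show", "TemperatureSeries", function(object) {
  cat("TemperatureSeries for subject", object@subjectId, "\n")
  cat(sprintf("  %d samples from %s, %.1f%% missing pre-imputation\n",
              length(object@values), formatClock(object@t0Hour),
              100 * mean(object@missingMask)))
})

## ---------------------------------------------------------------------------
## TemperatureCohort: SummarizedExperiment of timepoints x subjects
## ---------------------------------------------------------------------------

#' TemperatureCohort: a harmonized cohort of temperature series
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the aligned
#' cohort: the `"temperature"` assay is a 2880 x n matrix (rows = minutes from
#' the first noon, columns = subjects), an optional `"smoothed"` assay holds a
#' smoothed version, and `colData` carries per-subject metadata (demographics,
#' truth labels for simulated cohorts, cosinor parameters once fitted).
#'
#' @exportClass TemperatureCohort
setClass("TemperatureCohort", contains = "SummarizedExperiment")

setValidity("TemperatureCohort", function(object) {
  msg <- NULL
  if (!"temperature" %in% names(SummarizedExperiment::assays(object)))
    msg <- c(msg, "a 'temperature' assay is required")
  else {
    m <- SummarizedExperiment::assay(object, "temperature")
    if (nrow(m) != 2880L)
      msg <- c(msg, "temperature assay must have 2880 rows (48 h at 1-min)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a TemperatureCohort
#'
#' @param temperature 2880 x n numeric matrix (degC), `NA` for missing samples.
#' @param subjectData `data.frame`/`DataFrame` of per-subject covariates
#'   (one row per column of `temperature`).
#' @param smoothed optional matrix of the same shape (smoothed values).
#' @param metadata list stored in the object metadata (seeds, specs).
#' @return a [TemperatureCohort-class] object.
#' @export
TemperatureCohort <- function(temperature, subjectData = NULL, smoothed = NULL,
                              metadata = list()) {
  assays <- list(temperature = temperature)
  if (!is.null(smoothed)) assays$smoothed <- smoothed
  if (is.null(subjectData))
    subjectData <- S4Vectors::DataFrame(row.names = colnames(temperature))
  rd <- S4Vectors::DataFrame(
    minute = seq_len(nrow(temperature)) - 1L,
    clock_hour = (12 + (seq_len(nrow(temperature)) - 1L) / 60) %% 24
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, colData = subjectData, rowData = rd, metadata = metadata)
  new("TemperatureCohort", se)
}

#' Temperature matrix accessor
#' @param x a `TemperatureCohort`.
#' @return 2880 x n numeric matrix.
#' @export
temperatureMatrix <- function(x) SummarizedExperiment::assay(x, "temperature")

#' Smoothed matrix accessor
#' @param x a `TemperatureCohort`.
#' @return 2880 x n numeric matrix, or `NULL` if no smoothed assay exists.
#' @export
smoothedMatrix <- function(x) {
  if ("smoothed" %in% names(SummarizedExperiment::assays(x)))
    SummarizedExperiment::assay(x, "smoothed") else NULL
}

setMethod("show", "TemperatureCohort", function(object) {
  cat("TemperatureCohort:", ncol(object), "subjects x", nrow(object),
      "minute samples\n")
  cat("  assays:", paste(names(SummarizedExperiment::assays(object)),
                         collapse = ", "), "\n")
  nmiss <- sum(is.na(SummarizedExperiment::assay(object, "temperature")))
  cat(sprintf("  missing temperature cells: %d (%.2f%%)\n", nmiss,
              100 * nmiss / prod(dim(object))))
  cd <- names(SummarizedExperiment::colData(object))
  if (length(cd)) cat("  colData:", paste(cd, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## CosinorFit
## ---------------------------------------------------------------------------

#' CosinorFit: a fitted single-component cosinor model
#'
#' Parameters of `Y(t) = M + A cos(2 pi t / tau + phi) + e(t)` for one series:
#' mesor `M` (rhythm-adjusted mean), amplitude `A` (half the peak-to-trough
#' extent), acrophase angle `phi` in radians, period `tau` in hours, plus the
#' linearized coefficients `beta = A cos(phi)`, `gamma = -A sin(phi)` and the
#' residual sum of squares. Clock-time slots give the first model peak/trough
#' after the window start mapped to wall-clock time.
#'
#' @slot subjectId character identifier.
#' @slot mesor,amplitude numeric, degrees C.
#' @slot acrophase numeric radians in `(-pi, pi]`.
#' @slot period numeric hours (`NA` when the period is undefined).
#' @slot beta,gamma numeric linearized coefficients.
#' @slot rss numeric residual sum of squares.
#' @slot acroClock,bathyClock numeric clock hours of model peak/trough.
#' @exportClass CosinorFit
setClass("CosinorFit",
  representation(subjectId = "character", mesor = "numeric",
                 amplitude = "numeric", acrophase = "numeric",
                 period = "numeric", beta = "numeric", gamma = "numeric",
                 rss = "numeric", acroClock = "numeric", bathyClock = "numeric"),
  prototype(subjectId = NA_character_, acroClock = NA_real_,
            bathyClock = NA_real_)
)

setValidity("CosinorFit", function(object) {
  msg <- NULL
  if (!is.na(object@amplitude) && object@amplitude < 0)
    msg <- c(msg, "amplitude must be >= 0")
  if (!is.na(object@amplitude) && !is.na(object@beta) &&
      abs(object@amplitude - sqrt(object@beta^2 + object@gamma^2)) > 1e-9)
    msg <- c(msg, "amplitude must equal sqrt(beta^2 + gamma^2)")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CosinorFit", function(object) {
  cat("CosinorFit", if (!is.na(object@subjectId)) object@subjectId else "", "\n")
  cat(sprintf("  mesor %.3f degC  amplitude %.3f degC  period %s h\n",
              object@mesor, object@amplitude,
              ifelse(is.na(object@period), "NA", sprintf("%.3f", object@period))))
  cat(sprintf("  acrophase %.4f rad  peak %s  trough %s  rss %.4g\n",
              object@acrophase, formatClock(object@acroClock),
              formatClock(object@bathyClock), object@rss))
})

#' @describeIn CosinorFit-class mesor accessor
#' @param x a `CosinorFit`.
#' @export
mesor <- function(x) x@mesor

#' @describeIn CosinorFit-class amplitude accessor
#' @export
amplitude <- function(x) x@amplitude

#' @describeIn CosinorFit-class acrophase (radians) accessor
#' @export
acrophase <- function(x) x@acrophase

#' @describeIn CosinorFit-class period (hours) accessor
#' @export
period <- function(x) x@period

## ---------------------------------------------------------------------------
## ClusterSolution
## ---------------------------------------------------------------------------

#' ClusterSolution: a k-medoids partition of the cohort
#'
#' @slot k integer number of clusters.
#' @slot labels integer per-subject assignment (named by subject id), numbered
#'   so cluster 1 has the highest mean ordering statistic (mesor by default).
#' @slot medoidIds character identifiers of the k medoid subjects.
#' @slot totalCost numeric sum of within-cluster distances to medoids.
#' @slot seed integer RNG seed used for restarts.
#' @exportClass ClusterSolution
setClass("ClusterSolution",
  representation(k = "integer", labels = "integer", medoidIds = "character",
                 totalCost = "numeric", seed = "integer")
)

setValidity("ClusterSolution", function(object) {
  msg <- NULL
  if (length(object@medoidIds) != object@k)
    msg <- c(msg, "need exactly k medoids")
  if (length(unique(object@labels)) != object@k)
    msg <- c(msg, "labels must use exactly k clusters")
  for (m in object@medoidIds) {
    if (!m %in% names(object@labels))
      msg <- c(msg, paste("medoid", m, "not among labelled subjects"))
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ClusterSolution-class labels accessor
#' @param x a `ClusterSolution`.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn ClusterSolution-class medoid identifiers accessor
#' @export
medoidIds <- function(x) x@medoidIds

#' @describeIn ClusterSolution-class total cost accessor
#' @export
totalCost <- function(x) x@totalCost

setMethod("show", "ClusterSolution", function(object) {
  cat("ClusterSolution: k =", object@k, "\n")
  cat("  sizes:", paste(table(object@labels), collapse = ", "), "\n")
  cat("  medoids:", paste(object@medoidIds, collapse = ", "), "\n")
  cat(sprintf("  total cost %.4f (seed %d)\n", object@totalCost, object@seed))
})
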