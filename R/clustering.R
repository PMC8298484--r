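## Rhythm clustering: discrete Fourier features, k-medoids (PAM) with
## mesor-ordered labels, cluster validity indices, and the eigenvalue-based
## RMSEA/eBIC dimensionality diagnostics.

#' Discrete Fourier features of temperature series
#'
#' Reduces each 2880-sample series to its DC term plus the first `H` harmonic
#' coefficients of the discrete Fourier transform, as (real, imaginary) pairs
#' -- the dimension reduction used before k-medoids clustering. Under the
#' normalized convention (default) coefficients are divided by the series
#' length, so the DC term equals the series mean and harmonic magnitudes are
#' half the corresponding sinusoid amplitudes.
#'
#' @param x 2880 x n matrix (columns = subjects), a numeric vector, or a
#'   [TemperatureCohort-class] (smoothed assay preferred).
#' @param H number of harmonics to retain (default 24: periods >= 2 h over
#'   the 48-h window).
#' @param normalized divide coefficients by the series length.
#' @param dropDC drop the DC term for shape-only clustering (mesor
#'   differences then no longer separate clusters).
#' @param magnitudesOnly return `|X_h|` instead of (Re, Im) pairs.
#' @return n x (2H + 1) feature matrix (n x (H + 1) with `magnitudesOnly`),
#'   rows named by subject.
#' @export
dftFeatures <- function(x, H = 24, normalized = TRUE, dropDC = FALSE,
                        magnitudesOnly = FALSE) {
  if (is(x, "TemperatureCohort")) {
    m <- smoothedMatrix(x)
    if (is.null(m)) m <- temperatureMatrix(x)
    x <- m
  }
  if (is.vector(x)) x <- matrix(x, ncol = 1, dimnames = list(NULL, "S1"))
  if (anyNA(x)) stop("series contain missing values; impute first", call. = FALSE)
  n <- nrow(x)
  if (H < 1 || H > floor((n - 1) / 2))
    stop("H must lie in [1, ", floor((n - 1) / 2), "]", call. = FALSE)
  feats <- t(apply(x, 2, function(y) {
    X <- stats::fft(y)
    if (normalized) X <- X / n
    dc <- Re(X[1])
    harm <- X[2:(H + 1)]
    if (magnitudesOnly) c(dc = dc, stats::setNames(Mod(harm), paste0("mag", 1:H)))
    else c(dc = dc, rbind(Re(harm), Im(harm)))
  }))
  if (!magnitudesOnly)
    colnames(feats) <- c("dc", paste0(rep(c("re", "im"), H),
                                      rep(1:H, each = 2)))
  if (dropDC) feats <- feats[, -1, drop = FALSE]
  feats
}

#' k-medoids (PAM) clustering of feature vectors
#'
#' Partitioning Around Medoids (BUILD initialization then SWAP passes to a
#' local optimum) on Euclidean distances, restarted over permuted input
#' orders with the best total cost kept. Clusters are renumbered so cluster 1
#' has the highest mean of `orderBy` (default: the DC Fourier term, i.e. the
#' mesor), matching the convention that cluster 1 is the warmest.
#'
#' @param features n x p numeric matrix, rows named by subject.
#' @param k number of clusters, `2 <= k < n`.
#' @param seed integer seed for the restarts.
#' @param restarts number of permuted-order restarts.
#' @param orderBy numeric vector (length n) whose decreasing cluster means
#'   define the label order; defaults to the first feature column.
#' @return a [ClusterSolution-class].
#' @export
pamCluster <- function(features, k, seed = 1, restarts = 10, orderBy = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 2 || k >= n) stop("need 2 <= k < n", call. = FALSE)
  if (nrow(unique(features)) <= k)
    stop("fewer than k + 1 distinct feature rows", call. = FALSE)
  if (is.null(rownames(features))) rownames(features) <- sprintf("S%04d", 1:n)
  if (is.null(orderBy)) orderBy <- features[, 1]
  seed <- checkSeed(seed)
  perms <- deriveSeeds(seed, restarts)

  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(perms[r])
    ord <- sample.int(n)
    fit <- cluster::pam(features[ord, , drop = FALSE], k = k,
                        metric = "euclidean", do.swap = TRUE,
                        keep.diss = FALSE, keep.data = FALSE)
    cost <- fit$objective[["swap"]] * n
    if (is.null(best) || cost < best$cost - 1e-12)
      best <- list(cost = cost, labels = fit$clustering[order(ord)],
                   medoids = rownames(features)[ord][fit$id.med])
  }
  labels <- best$labels
  names(labels) <- rownames(features)

  ## renumber so cluster means of orderBy are strictly decreasing
  mu <- tapply(orderBy, labels, mean)
  newOrder <- order(mu, decreasing = TRUE)
  relabel <- integer(k); relabel[as.integer(names(mu))[newOrder]] <- seq_len(k)
  labels <- stats::setNames(relabel[labels], names(labels))
  medoids <- best$medoids[order(relabel[labels[best$medoids]])]

  new("ClusterSolution", k = as.integer(k), labels = labels,
      medoidIds = medoids, totalCost = best$cost, seed = seed)
}

#' Mean silhouette width
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` averaged over subjects;
#' singleton clusters contribute 0.
#'
#' @param d a `dist` object or distance matrix.
#' @param labels integer cluster assignment.
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouetteIndex <- function(d, labels) {
  if (length(unique(labels)) < 2) stop("need k >= 2", call. = FALSE)
  sil <- cluster::silhouette(as.integer(labels), stats::as.dist(d))
  mean(sil[, "sil_width"])
}

#' Dunn index
#'
#' Minimum between-cluster point-pair distance divided by the maximum
#' within-cluster diameter. A zero-diameter partition is guarded at 1e12.
#'
#' @inheritParams silhouetteIndex
#' @return nonnegative index (larger = better separated).
#' @export
dunnIndex <- function(d, labels) {
  if (length(unique(labels)) < 2) stop("need k >= 2", call. = FALSE)
  dm <- as.matrix(stats::as.dist(d))
  labels <- as.integer(labels)
  same <- outer(labels, labels, `==`)
  diag(same) <- NA
  maxIntra <- max(dm[same & !is.na(same)], 0)
  minInter <- min(dm[!same & !is.na(same)])
  if (maxIntra == 0) return(1e12)
  minInter / maxIntra
}

#' Davies-Bouldin index
#'
#' Mean over clusters of `max_{j != i} (S_i + S_j) / M_ij`, with `S` the mean
#' distance to the cluster centroid and `M` the centroid separation
#' (smaller = better). Coincident centroids are guarded.
#'
#' @param features n x p feature matrix.
#' @param labels integer cluster assignment.
#' @return nonnegative index.
#' @export
daviesBouldinIndex <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("need k >= 2", call. = FALSE)
  cent <- do.call(rbind, lapply(ks, function(g)
    colMeans(features[labels == g, , drop = FALSE])))
  S <- vapply(seq_along(ks), function(gi) {
    pts <- features[labels == ks[gi], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[gi, ])^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(cent))
  R <- vapply(seq_along(ks), function(i) {
    max(vapply(setdiff(seq_along(ks), i), function(j)
      (S[i] + S[j]) / max(M[i, j], 1e-12), numeric(1)))
  }, numeric(1))
  mean(R)
}

#' Eigenvalue-based dimensionality fit indices (RMSEA/eBIC analogues)
#'
#' A reconstruction of PCA-based fit assessment: the feature covariance is
#' eigen-decomposed (features first reduced to at most `nPCs` principal
#' components), and for each candidate `k` a Bartlett-style equality test on
#' the `p - k` trailing eigenvalues gives
#' `chi2 = c * ((p - k) log(mean(lambda)) - sum(log(lambda)))` with the
#' small-sample factor `c = n - 1 - (2 (p - k) + 5) / 6` and
#' `df = (p - k + 2)(p - k - 1) / 2`. From these,
#' `RMSEA = sqrt(max(0, (chi2 / df - 1) / (n - 1)))` and
#' `eBIC = chi2 - df log(n)`. This construction is a documented analogue,
#' not a reproduction of any specific software's internals.
#'
#' @param features n x p feature matrix.
#' @param kRange candidate component counts.
#' @param nPCs cap on the working dimensionality (default 10).
#' @return `data.frame` with columns `k`, `chi2`, `df`, `rmsea_like`,
#'   `ebic_like` (`NA` rows where `k >= p - 1`).
#' @export
dimensionFitIndices <- function(features, kRange = 0:6, nPCs = 10) {
  features <- as.matrix(features)
  n <- nrow(features)
  p <- min(ncol(features), nPCs)
  lambda <- eigen(stats::cov(features), symmetric = TRUE,
                  only.values = TRUE)$values[seq_len(p)]
  out <- lapply(kRange, function(k) {
    if (k >= p - 1)
      return(data.frame(k = k, chi2 = NA_real_, df = NA_real_,
                        rmsea_like = NA_real_, ebic_like = NA_real_))
    tail <- lambda[(k + 1):p]
    df <- (p - k + 2) * (p - k - 1) / 2
    tol <- 1e-12 * max(lambda[1], 1)
    if (all(tail <= tol)) {
      ## data of exact rank <= k: perfect fit, guarded logs
      return(data.frame(k = k, chi2 = 0, df = df, rmsea_like = 0,
                        ebic_like = -df * log(n)))
    }
    tail <- pmax(tail, tol)   # zero eigenvalues in a heterogeneous tail
    cc <- n - 1 - (2 * (p - k) + 5) / 6
    chi2 <- cc * ((p - k) * log(mean(tail)) - sum(log(tail)))
    rmsea <- sqrt(max(0, (chi2 / df - 1) / (n - 1)))
    data.frame(k = k, chi2 = chi2, df = df, rmsea_like = rmsea,
               ebic_like = chi2 - df * log(n))
  })
  do.call(rbind, out)
}

#' Validity report over a range of cluster counts
#'
#' Runs [pamCluster()] for each `k` and tabulates Davies-Bouldin, Dunn and
#' silhouette indices together with the [dimensionFitIndices()] analogues.
#'
#' @param features n x p feature matrix.
#' @param kRange candidate cluster counts (each >= 2).
#' @param seed seed forwarded to [pamCluster()].
#' @param orderBy label-ordering statistic forwarded to [pamCluster()].
#' @return list with `table` (per-k `data.frame`) and `solutions`
#'   (list of [ClusterSolution-class] keyed by `k`).
#' @export
validityReport <- function(features, kRange = 2:6, seed = 1, orderBy = NULL) {
  features <- as.matrix(features)
  d <- stats::dist(features)
  fitIdx <- dimensionFitIndices(features, kRange = kRange)
  sols <- list()
  rows <- lapply(kRange, function(k) {
    sol <- pamCluster(features, k, seed = seed, orderBy = orderBy)
    sols[[as.character(k)]] <<- sol
    lab <- clusterLabels(sol)
    data.frame(k = k,
               db = daviesBouldinIndex(features, lab),
               dunn = dunnIndex(d, lab),
               silhouette = silhouetteIndex(d, lab))
  })
  tab <- do.call(rbind, rows)
  tab <- merge(tab, fitIdx[, c("k", "rmsea_like", "ebic_like")],
               by = "k", all.x = TRUE)
  list(table = tab, solutions = sols)
}

#' Recommend a cluster count from a validity table
#'
#' Per-index votes -- max silhouette, max Dunn, min Davies-Bouldin, the first
#' `k` with RMSEA-like < 0.05, min eBIC-like -- plus a majority consensus.
#' Disagreement is surfaced, never collapsed; ties break toward smaller `k`.
#'
#' @param table per-k `data.frame` as produced by [validityReport()]
#'   (columns `k`, `db`, `dunn`, `silhouette`, optionally `rmsea_like`,
#'   `ebic_like`).
#' @return list with `votes` (named integer vector) and `consensus`.
#' @export
selectK <- function(table) {
  if (is.list(table) && !is.data.frame(table)) table <- table$table
  if (is.null(table) || nrow(table) < 2)
    stop("need a validity table covering >= 2 candidate k", call. = FALSE)
  votes <- c(
    db = table$k[which.min(table$db)],
    dunn = table$k[which.max(table$dunn)],
    silhouette = table$k[which.max(table$silhouette)]
  )
  if ("rmsea_like" %in% names(table) && any(!is.na(table$rmsea_like))) {
    ok <- which(!is.na(table$rmsea_like) & table$rmsea_like < 0.05)
    if (length(ok)) votes["rmsea"] <- table$k[min(ok)]
  }
  if ("ebic_like" %in% names(table) && any(!is.na(table$ebic_like)))
    votes["ebic"] <- table$k[which.min(table$ebic_like)]
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(votes = votes, consensus = min(winners))
}
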