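## Exact (O(n^2)) t-distributed stochastic neighbour embedding, used as a
## cluster-stability diagnostic for cohort-sized inputs (a few hundred
## subjects), plus the ARI-based stability check against a re-clustering of
## the embedding.

## per-point conditional probabilities at the requested perplexity via binary
## search on the Gaussian precision
.tsneP <- function(D2, perplexity, tol = 1e-5, maxIter = 50) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betaMin <- -Inf; betaMax <- Inf
    Di <- D2[i, -i]
    for (it in seq_len(maxIter)) {
      Pi <- exp(-Di * beta)
      sumPi <- sum(Pi)
      if (sumPi < 1e-300) sumPi <- 1e-300
      H <- log(sumPi) + beta * sum(Di * Pi) / sumPi
      diffH <- H - logU
      if (abs(diffH) < tol) break
      if (diffH > 0) {
        betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else {
        betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sumPi
  }
  P
}

#' t-SNE embedding of feature vectors
#'
#' Exact t-SNE with early exaggeration and momentum gradient descent;
#' deterministic for a fixed seed.
#'
#' @param features n x p numeric matrix.
#' @param perplexity effective neighbour count; requires `n >= 3 * perplexity`.
#' @param seed integer seed for the random initialization.
#' @param maxIter gradient-descent iterations.
#' @return n x 2 embedding matrix (rows named as `features`).
#' @export
tsneEmbed <- function(features, perplexity = 30, seed = 1, maxIter = 500) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3 * perplexity)
    stop("perplexity too large: need n >= 3 * perplexity", call. = FALSE)
  seed <- checkSeed(seed)
  D2 <- as.matrix(stats::dist(features))^2
  P <- .tsneP(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)           # momentum buffer
  gains <- matrix(1, n, 2)
  eta <- 100
  for (it in seq_len(maxIter)) {
    exag <- if (it <= 100) 4 else 1
    mom <- if (it <= 250) 0.5 else 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (exag * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    gains <- pmax(ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8), 0.01)
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rownames(Y) <- rownames(features)
  Y
}

#' t-SNE cluster-stability diagnostic
#'
#' Embeds the features in 2-D, re-clusters the embedding by k-medoids at the
#' same `k` as the provided labels, and reports the adjusted Rand index
#' between the two partitions: near 1 means the cluster structure survives
#' the nonlinear embedding.
#'
#' @param features n x p numeric matrix.
#' @param labels integer cluster assignment to check.
#' @param perplexity,seed,maxIter passed to [tsneEmbed()].
#' @return list with `embedding` (n x 2), `ari`, and `labelsEmbedding`.
#' @export
tsneStability <- function(features, labels, perplexity = 30, seed = 1,
                          maxIter = 500) {
  Y <- tsneEmbed(features, perplexity = perplexity, seed = seed,
                 maxIter = maxIter)
  k <- length(unique(labels))
  sol <- pamCluster(Y, k = k, seed = seed, orderBy = NULL)
  lab2 <- clusterLabels(sol)
  list(embedding = Y,
       ari = mclust::adjustedRandIndex(as.integer(labels), lab2),
       labelsEmbedding = lab2)
}
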