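## Network diagnostics: Gaussian-kernel similarity graph on Fourier-feature
## distances, force-directed layout, and Newman modularity of a candidate
## partition. Positioned as a stability diagnostic, not as the clustering.

#' Similarity-network diagnostics of a cluster solution
#'
#' Builds a weighted graph on the subjects with Gaussian-kernel edge weights
#' `w = exp(-d^2 / (2 sigma^2))` (`sigma` = median pairwise distance),
#' sparsified to each node's `nNeighbors` nearest neighbours (symmetrized by
#' union), lays it out with the Fruchterman-Reingold algorithm under a fixed
#' seed, and evaluates the Newman modularity of the provided labels on this
#' graph. High modularity means the partition aligns with the distance
#' structure.
#'
#' @param features n x p numeric feature matrix (n >= 3).
#' @param labels integer cluster assignment.
#' @param nNeighbors neighbours kept per node.
#' @param seed integer seed for the layout.
#' @param layoutIter Fruchterman-Reingold iterations.
#' @return list with `graph` (igraph), `layout` (n x 2), `modularity`, and
#'   `connected` (logical; a disconnected graph is flagged, modularity is
#'   still computed).
#' @export
networkDiagnostics <- function(features, labels, nNeighbors = 10, seed = 1,
                               layoutIter = 500) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  seed <- checkSeed(seed)
  dm <- as.matrix(stats::dist(features))
  sigma <- stats::median(dm[upper.tri(dm)])
  if (sigma <= 0) sigma <- 1
  W <- exp(-dm^2 / (2 * sigma^2))
  diag(W) <- 0

  ## keep each node's nNeighbors strongest edges, symmetrized by union
  keep <- matrix(FALSE, n, n)
  kk <- min(nNeighbors, n - 1L)
  for (i in seq_len(n)) {
    nb <- order(dm[i, ], decreasing = FALSE)
    nb <- setdiff(nb, i)[seq_len(kk)]
    keep[i, nb] <- TRUE
  }
  keep <- keep | t(keep)
  W[!keep] <- 0

  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  lay <- igraph::layout_with_fr(g, niter = layoutIter,
                                weights = igraph::E(g)$weight)
  mod <- igraph::modularity(g, membership = as.integer(labels),
                            weights = igraph::E(g)$weight)
  list(graph = g, layout = lay, modularity = mod,
       connected = igraph::is_connected(g))
}
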