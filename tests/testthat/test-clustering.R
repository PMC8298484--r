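## small deterministic feature sets used across blocks
twoClouds1d <- function() {
  f <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), "x"))
  list(features = f, labels = c(1L, 1L, 2L, 2L))
}

test_that("Fourier features satisfy orthogonality, Parseval and mean-shift behaviour", {
  n <- 2880
  tIdx <- 0:(n - 1)
  ## constant series: DC only (normalized convention: DC = the constant)
  fc <- dftFeatures(rep(33, n), H = 5)
  expect_equal(unname(fc[1, "dc"]), 33, tolerance = 1e-9)
  expect_true(all(abs(fc[1, -1]) < 1e-9))

  ## pure second harmonic: only harmonic 2 nonzero
  y2 <- cos(2 * pi * 2 * tIdx / n)
  f2 <- dftFeatures(y2, H = 5)
  nz <- which(abs(f2[1, ]) > 1e-9)
  expect_setequal(colnames(f2)[nz], "re2")
  expect_equal(unname(f2[1, "re2"]), 0.5, tolerance = 1e-9)

  ## Parseval: retained + discarded coefficient energy equals series energy
  set.seed(201)
  y <- rnorm(n)
  X <- fft(y) / n
  H <- 24
  fAll <- dftFeatures(y, H = H)
  ## retained energy from the feature pairs (x2 for the conjugate half)
  retained <- fAll[1, "dc"]^2 + 2 * sum(fAll[1, -1]^2)
  discarded <- sum(Mod(X[(H + 2):(n - H)])^2)
  energy <- mean(y^2)
  expect_equal(retained + discarded, energy, tolerance = 1e-6)

  ## mean shift alters only the DC term
  fShift <- dftFeatures(y + 2, H = H)
  expect_equal(unname(fShift[1, "dc"] - fAll[1, "dc"]), 2, tolerance = 1e-9)
  expect_equal(fShift[1, -1], fAll[1, -1], tolerance = 1e-9)

  expect_equal(ncol(fAll), 2L * H + 1L)
  expect_equal(ncol(dftFeatures(y, H = 3, magnitudesOnly = TRUE)), 4L)
  expect_error(dftFeatures(c(NA, y[-1])), "impute")
  expect_error(dftFeatures(y, H = 2000), "H must")
})

test_that("PAM recovers well-separated clouds exactly and orders labels by mesor", {
  set.seed(202)
  f <- rbind(matrix(rnorm(60, 0, 0.05), 30, 2),
             matrix(rnorm(40, 30, 0.05), 20, 2))
  rownames(f) <- sprintf("s%02d", 1:50)
  truth <- rep(c(2L, 1L), c(30, 20))  # cloud at 30 has the higher "mesor"
  sol <- pamCluster(f, 2, seed = 1, orderBy = f[, 1])
  expect_equal(mclust::adjustedRandIndex(truth, clusterLabels(sol)), 1)
  ## ordering convention: cluster 1 mean orderBy above cluster 2
  mu <- tapply(f[, 1], clusterLabels(sol), mean)
  expect_true(all(diff(mu) < 0))
  expect_true(all(medoidIds(sol) %in% rownames(f)))
})

test_that("PAM total cost equals the exhaustive optimum on small instances", {
  set.seed(203)
  for (r in 1:5) {
    f <- matrix(rnorm(16), 8, 2)
    rownames(f) <- letters[1:8]
    sol <- pamCluster(f, 2, seed = r)
    dm <- as.matrix(dist(f))
    ## brute force over all C(8,2) medoid pairs
    best <- Inf
    for (i in 1:7) for (j in (i + 1):8)
      best <- min(best, sum(pmin(dm[, i], dm[, j])))
    expect_equal(totalCost(sol), best, tolerance = 1e-9)
  }
})

test_that("PAM solutions are locally optimal under single-medoid swaps", {
  set.seed(204)
  f <- matrix(rnorm(60), 30, 2)
  rownames(f) <- sprintf("s%02d", 1:30)
  sol <- pamCluster(f, 3, seed = 9)
  dm <- as.matrix(dist(f))
  med <- match(medoidIds(sol), rownames(f))
  cost <- function(m) sum(apply(dm[, m, drop = FALSE], 1, min))
  expect_equal(cost(med), totalCost(sol), tolerance = 1e-9)
  for (mi in seq_along(med)) for (cand in setdiff(1:30, med)) {
    alt <- med; alt[mi] <- cand
    expect_gte(cost(alt), totalCost(sol) - 1e-9)
  }
})

test_that("PAM rejects degenerate inputs", {
  f <- matrix(rep(c(0, 1), each = 4), ncol = 1)
  expect_error(pamCluster(f, 3, seed = 1), "distinct")
  expect_error(pamCluster(matrix(rnorm(10), 5), 5, seed = 1), "k < n")
})

test_that("validity indices match hand-computed values on the {0,1}/{10,11} instance", {
  tc <- twoClouds1d()
  d <- dist(tc$features)
  expect_equal(silhouetteIndex(d, tc$labels), 0.8997, tolerance = 1e-4)
  expect_equal(dunnIndex(d, tc$labels), 9)
  expect_equal(daviesBouldinIndex(tc$features, tc$labels), 0.1, tolerance = 1e-9)
})

test_that("validity indices behave in limits and under invariances", {
  ## coincident clusters: no separation
  set.seed(205)
  pts <- matrix(rnorm(40), 20, 2)
  f <- rbind(pts, pts)
  lab <- rep(1:2, each = 20)
  expect_lte(silhouetteIndex(dist(f), lab), 0)
  expect_equal(dunnIndex(dist(f), lab), 0)

  ## extreme separation: silhouette -> 1, DB -> 0
  f2 <- rbind(matrix(rnorm(20, 0, 1e-3), 10, 2),
              matrix(rnorm(20, 1e4, 1e-3), 10, 2))
  lab2 <- rep(1:2, each = 10)
  expect_gt(silhouetteIndex(dist(f2), lab2), 0.999)
  expect_lt(daviesBouldinIndex(f2, lab2), 1e-3)

  ## Dunn is scale invariant; DB unchanged by duplicating every point
  tc <- twoClouds1d()
  expect_equal(dunnIndex(dist(tc$features * 37), tc$labels),
               dunnIndex(dist(tc$features), tc$labels))
  fDup <- rbind(tc$features, tc$features)
  expect_equal(daviesBouldinIndex(fDup, c(tc$labels, tc$labels)),
               daviesBouldinIndex(tc$features, tc$labels), tolerance = 1e-12)

  ## all indices invariant to adding a constant to every feature
  set.seed(206)
  f3 <- matrix(rnorm(60), 30, 2)
  lab3 <- rep(1:3, each = 10)
  expect_equal(silhouetteIndex(dist(f3 + 5), lab3),
               silhouetteIndex(dist(f3), lab3))
  expect_equal(dunnIndex(dist(f3 + 5), lab3), dunnIndex(dist(f3), lab3))
  expect_equal(daviesBouldinIndex(f3 + 5, lab3),
               daviesBouldinIndex(f3, lab3), tolerance = 1e-9)
})

test_that("dimension fit indices detect exact low rank and calibrate on spherical nulls", {
  ## exact rank-2 data: RMSEA-like 0 at k = 2
  set.seed(207)
  X <- matrix(rnorm(200 * 2), 200, 2) %*% matrix(rnorm(12), 2, 6)
  fi <- dimensionFitIndices(X, kRange = 0:3)
  expect_equal(fi$rmsea_like[fi$k == 2], 0)
  expect_gt(fi$rmsea_like[fi$k == 0], 0.05)

  ## spherical Gaussian, k = 0, n = 500, p = 5: RMSEA-like < 0.05 in >= 90%
  hits <- vapply(1:20, function(s) {
    set.seed(210 + s)
    dimensionFitIndices(matrix(rnorm(500 * 5), 500, 5),
                        kRange = 0)$rmsea_like[1] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 18L)

  ## k >= p - 1 rows are reported missing
  expect_true(is.na(dimensionFitIndices(X[, 1:3], kRange = 2)$rmsea_like))
})

test_that("RMSEA-like separates under- from adequately-dimensioned solutions", {
  ## three dominant components over an isotropic residual: the index stays
  ## above the 0.05 acceptance level while components are missing and falls
  ## below it once all three are absorbed
  set.seed(208)
  for (r in 1:5) {
    scores <- matrix(rnorm(400 * 3), 400, 3)
    load <- matrix(rnorm(3 * 8, sd = 3), 3, 8)
    X <- scores %*% load + matrix(rnorm(400 * 8), 400, 8)
    v <- dimensionFitIndices(X, kRange = 0:4)$rmsea_like
    expect_true(all(v[1:3] > 0.05))
    expect_true(all(v[4:5] < 0.05))
  }
})

test_that("selectK surfaces per-index votes and breaks ties toward smaller k", {
  tab <- data.frame(k = 2:4,
                    db = c(0.5, 0.8, 0.9),          # min at 2
                    dunn = c(1.0, 2.0, 1.5),        # max at 3
                    silhouette = c(0.5, 0.7, 0.6))  # max at 3
  out <- selectK(tab)
  expect_equal(unname(out$votes[c("db", "dunn", "silhouette")]), c(2, 3, 3))
  expect_equal(out$consensus, 3)

  tabAgree <- data.frame(k = 2:4, db = c(0.9, 0.2, 0.8),
                         dunn = c(1, 5, 2), silhouette = c(0.3, 0.8, 0.4))
  expect_equal(selectK(tabAgree)$consensus, 3)

  ## 2-2 tie between k = 2 and k = 3 resolves to 2
  tabTie <- data.frame(k = 2:3, db = c(0.2, 0.5), dunn = c(3, 1),
                       silhouette = c(0.4, 0.9), rmsea_like = c(0.2, 0.01))
  expect_equal(selectK(tabTie)$consensus, 2)
  expect_error(selectK(tab[1, ]), ">= 2")
})

test_that("the dft -> PAM stack recovers archetype structure at low noise", {
  arch <- defaultArchetypes()
  arch$n_subjects <- c(15L, 20L, 8L)
  nz <- noiseSpec(sigma = 0.1 * sqrt(1 - 0.81), ar = 0.9,
                  transientMagnitude = 1.5, missingFraction = 0.02,
                  quantizationStep = 0.0625)
  b <- generateCohort(arch, nz, seed = 209)
  co <- smoothCohort(imputeCohort(harmonizeCohort(b)), "loess")
  feats <- dftFeatures(co, H = 24)
  sol <- pamCluster(feats, 3, seed = 1)
  truth <- b$truth$label[match(rownames(feats), b$truth$subject_id)]
  expect_equal(mclust::adjustedRandIndex(truth, clusterLabels(sol)), 1)
  ## label convention: cluster 1 = highest mesor archetype
  expect_true(all(clusterLabels(sol)[truth == "cluster1"] == 1L))
  expect_true(all(clusterLabels(sol)[truth == "cluster3"] == 3L))
})

test_that("t-SNE stability: separation preserved, permuted labels score zero, seeds reproduce", {
  set.seed(211)
  f <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 20), 20, 2),
             matrix(rnorm(40, -20), 20, 2))
  rownames(f) <- sprintf("s%02d", 1:60)
  lab <- rep(1:3, each = 20)
  st <- tsneStability(f, lab, perplexity = 6, seed = 4, maxIter = 300)
  expect_equal(st$ari, 1)
  set.seed(212)
  stPerm <- tsneStability(f, sample(lab), perplexity = 6, seed = 4,
                          maxIter = 300)
  expect_lt(abs(stPerm$ari), 0.2)
  Y1 <- tsneEmbed(f, perplexity = 6, seed = 4, maxIter = 150)
  Y2 <- tsneEmbed(f, perplexity = 6, seed = 4, maxIter = 150)
  expect_identical(Y1, Y2)
  expect_error(tsneEmbed(f, perplexity = 30), "perplexity")
})

test_that("network diagnostics: symmetric weights, block modularity, null labels", {
  ## 3 equidistant points: all edge weights equal
  tri <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), 3, 2, byrow = TRUE)
  nd <- networkDiagnostics(tri, labels = c(1, 1, 2), nNeighbors = 2, seed = 1)
  w <- igraph::E(nd$graph)$weight
  expect_equal(max(w) - min(w), 0, tolerance = 1e-12)

  set.seed(213)
  f <- rbind(matrix(rnorm(80, 0, 0.5), 40, 2), matrix(rnorm(80, 8, 0.5), 40, 2))
  lab <- rep(1:2, each = 40)
  nd2 <- networkDiagnostics(f, lab, seed = 2)
  expect_gt(nd2$modularity, 0.3)
  set.seed(214)
  nd3 <- networkDiagnostics(f, sample(lab), seed = 2)
  expect_lt(abs(nd3$modularity), 0.15)
  expect_error(networkDiagnostics(f[1:2, ], lab[1:2]), "3 subjects")
})
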