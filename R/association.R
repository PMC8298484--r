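## Association machinery: bias-corrected percentile bootstrap CIs, bootstrap
## omnibus and pairwise cluster comparisons for continuous and binary
## outcomes, logistic models with per-SD odds ratios, and Benjamini-Hochberg
## FDR over the omnibus family.

#' Bias-corrected percentile bootstrap confidence interval
#'
#' BC (not BCa: no acceleration term) interval: with
#' `z0 = qnorm(P(stat* < stat))` (ties at the point estimate counted half),
#' the endpoints are the bootstrap percentiles at `pnorm(2 z0 -+ z_{a/2})`.
#' Reduces to the plain percentile interval when the bootstrap distribution
#' is median-unbiased.
#'
#' @param x numeric sample (n >= 3).
#' @param statistic function of a numeric vector (default `mean`).
#' @param B resample count (>= 100).
#' @param seed integer seed; results are bit-reproducible.
#' @param conf confidence level.
#' @return list of class `"BootstrapCI"`: `estimate`, `lower`, `upper`, `B`,
#'   `seed`, `degenerate` (statistic constant across resamples).
#' @export
bootstrapCi <- function(x, statistic = mean, B = 1000, seed = 1, conf = 0.95) {
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (B < 100) stop("need B >= 100", call. = FALSE)
  seed <- checkSeed(seed)
  est <- statistic(x)
  set.seed(seed)
  n <- length(x)
  stats <- vapply(seq_len(B), function(b) statistic(x[sample.int(n, n,
    replace = TRUE)]), numeric(1))
  degenerate <- stats::sd(stats) == 0
  if (degenerate) {
    ci <- c(est, est)
  } else {
    prop <- (sum(stats < est) + 0.5 * sum(stats == est)) / B
    prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
    z0 <- stats::qnorm(prop)
    za <- stats::qnorm((1 + conf) / 2)
    probs <- stats::pnorm(c(2 * z0 - za, 2 * z0 + za))
    ci <- unname(stats::quantile(stats, probs))
  }
  structure(list(estimate = est, lower = ci[1], upper = ci[2], B = B,
                 seed = seed, conf = conf, degenerate = degenerate),
            class = "BootstrapCI")
}

## one-way ANOVA F statistic from a response and group factor
.fstat <- function(y, g) {
  n <- length(y); k <- nlevels(g)
  m <- mean(y)
  mg <- tapply(y, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng * (mg - m)^2)
  ssw <- sum((y - mg[g])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

## vectorized null-imposed bootstrap of the F statistic: groups are centered
## (imposing the null) and resampled within group
.bootF <- function(y, g, B) {
  g <- droplevels(g)
  k <- nlevels(g); n <- length(y)
  yc <- y - tapply(y, g, mean)[g]
  groups <- split(yc, g)
  ng <- lengths(groups)
  gm <- matrix(0, B, k)   # resampled group means
  rs2 <- matrix(0, B, k)  # resampled group sums of squares
  for (j in seq_len(k)) {
    M <- matrix(sample(groups[[j]], B * ng[j], replace = TRUE), nrow = B)
    gm[, j] <- rowMeans(M)
    rs2[, j] <- rowSums(M^2)
  }
  overall <- as.vector(gm %*% ng) / n
  ssb <- as.vector((gm - overall)^2 %*% ng)
  ssw <- as.vector((rs2 - sweep(gm^2, 2, ng, `*`)) %*% rep(1, k))
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Compare a continuous outcome across clusters
#'
#' Per-cluster means with bias-corrected bootstrap CIs, an omnibus bootstrap
#' p-value for any between-cluster difference (the one-way F statistic under
#' null-imposed within-group resampling), and pairwise mean contrasts with
#' their own bootstrap p-values and BC CIs.
#'
#' @param y numeric outcome per subject.
#' @param g cluster labels (coerced to factor); each cluster needs n >= 3.
#' @param Bci resamples for the BC CIs.
#' @param Bp resamples for the bootstrap p-values.
#' @param seed integer seed.
#' @param outcome label stored in the output.
#' @return list of class `"GroupComparison"`: `groups` (`data.frame` of
#'   cluster, n, estimate, lower, upper), `omnibus_p`, `pairwise`
#'   (`data.frame`), `outcome`.
#' @export
groupCompareContinuous <- function(y, g, Bci = 1000, Bp = 500, seed = 1,
                                   outcome = "outcome") {
  g <- droplevels(as.factor(g))
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need k >= 2 groups", call. = FALSE)
  if (any(tabulate(g) < 3)) stop("every group needs n >= 3", call. = FALSE)
  seed <- checkSeed(seed)
  seeds <- deriveSeeds(seed, nlevels(g) + 1L + choose(nlevels(g), 2) * 2L)

  groups <- do.call(rbind, lapply(seq_len(nlevels(g)), function(j) {
    yy <- y[g == levels(g)[j]]
    ci <- bootstrapCi(yy, mean, B = Bci, seed = seeds[j])
    data.frame(cluster = levels(g)[j], n = length(yy), estimate = ci$estimate,
               lower = ci$lower, upper = ci$upper, stringsAsFactors = FALSE)
  }))

  fObs <- .fstat(y, g)
  set.seed(seeds[nlevels(g) + 1L])
  fBoot <- .bootF(y, g, Bp)
  omnibus <- (1 + sum(fBoot >= fObs)) / (Bp + 1)

  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  sIdx <- nlevels(g) + 1L
  pw <- do.call(rbind, lapply(seq_along(pairs), function(pi) {
    a <- pairs[[pi]][1]; b <- pairs[[pi]][2]
    sub <- g %in% c(a, b)
    ys <- y[sub]; gs <- droplevels(g[sub])
    fO <- .fstat(ys, gs)
    set.seed(seeds[sIdx + 2L * pi - 1L])
    fB <- .bootF(ys, gs, Bp)
    pv <- (1 + sum(fB >= fO)) / (Bp + 1)
    ## BC CI of the mean difference under joint (non-null) resampling
    ya <- y[g == a]; yb <- y[g == b]
    diffStat <- function(idx) mean(ya[idx$ia]) - mean(yb[idx$ib])
    set.seed(seeds[sIdx + 2L * pi])
    dBoot <- vapply(seq_len(Bci), function(bb)
      mean(sample(ya, length(ya), replace = TRUE)) -
        mean(sample(yb, length(yb), replace = TRUE)), numeric(1))
    est <- mean(ya) - mean(yb)
    if (stats::sd(dBoot) == 0) {
      lo <- hi <- est
    } else {
      prop <- (sum(dBoot < est) + 0.5 * sum(dBoot == est)) / Bci
      prop <- min(max(prop, 1 / (2 * Bci)), 1 - 1 / (2 * Bci))
      z0 <- stats::qnorm(prop); za <- stats::qnorm(0.975)
      qq <- unname(stats::quantile(dBoot, stats::pnorm(c(2 * z0 - za, 2 * z0 + za))))
      lo <- qq[1]; hi <- qq[2]
    }
    data.frame(cluster_a = a, cluster_b = b, estimate = est, lower = lo,
               upper = hi, p = pv, stringsAsFactors = FALSE)
  }))

  structure(list(outcome = outcome, groups = groups, omnibus_p = omnibus,
                 pairwise = pw, seed = seed, Bci = Bci, Bp = Bp),
            class = "GroupComparison")
}

#' Logistic models of a binary outcome with bootstrap ORs
#'
#' Maximum-likelihood logistic fit with odds ratios and bias-corrected
#' bootstrap CIs; continuous predictors are standardized so their ORs are per
#' SD. An omnibus p-value for a designated predictor block is computed from
#' the likelihood-ratio statistic under label permutation. Complete
#' separation is detected and reported as non-estimable rather than silently
#' diverging.
#'
#' @param outcome logical/0-1 vector (both classes required).
#' @param predictors `data.frame` of predictors; factors expand to indicator
#'   columns, numeric columns are standardized when `standardize = TRUE`.
#' @param testVars columns of `predictors` whose joint effect the omnibus
#'   LRT p-value targets (default: all).
#' @param B resamples for the BC CIs (0 skips CIs).
#' @param Bp permutations for the omnibus p (0 skips it).
#' @param seed integer seed.
#' @param standardize standardize numeric predictors (per-SD ORs).
#' @return list of class `"LogisticReport"`: `coefficients` (`data.frame`
#'   with `term`, `or`, `lower`, `upper`), `omnibus_p`, `separation`,
#'   `converged`, `model` (the `glm`).
#' @export
logisticOutcome <- function(outcome, predictors, testVars = NULL, B = 1000,
                            Bp = 500, seed = 1, standardize = TRUE) {
  y <- as.integer(outcome)
  if (length(unique(y[!is.na(y)])) < 2)
    stop("outcome needs both classes", call. = FALSE)
  predictors <- as.data.frame(predictors)
  seed <- checkSeed(seed)
  if (standardize) {
    for (cc in names(predictors)) {
      if (is.numeric(predictors[[cc]]) && length(unique(predictors[[cc]])) > 2) {
        s <- stats::sd(predictors[[cc]], na.rm = TRUE)
        if (s > 0) predictors[[cc]] <-
            (predictors[[cc]] - mean(predictors[[cc]], na.rm = TRUE)) / s
      }
    }
  }
  dat <- cbind(.y = y, predictors)
  ok <- stats::complete.cases(dat)
  dat <- dat[ok, , drop = FALSE]

  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  separation <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
  co <- stats::coef(fit)[-1]
  res <- data.frame(term = names(co), or = exp(co), lower = NA_real_,
                    upper = NA_real_, stringsAsFactors = FALSE)

  if (B > 0 && !separation) {
    set.seed(seed)
    n <- nrow(dat)
    boots <- matrix(NA_real_, B, length(co))
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      fb <- tryCatch(suppressWarnings(stats::glm(.y ~ ., data = dat[idx, ],
        family = stats::binomial())), error = function(e) NULL)
      if (!is.null(fb) && fb$converged) {
        cb <- stats::coef(fb)[-1]
        boots[b, seq_along(cb)] <- cb[res$term]
      }
    }
    za <- stats::qnorm(0.975)
    for (j in seq_along(co)) {
      bj <- boots[, j]; bj <- bj[is.finite(bj)]
      if (length(bj) < 50 || stats::sd(bj) == 0) next
      prop <- (sum(bj < co[j]) + 0.5 * sum(bj == co[j])) / length(bj)
      prop <- min(max(prop, 1 / (2 * length(bj))), 1 - 1 / (2 * length(bj)))
      z0 <- stats::qnorm(prop)
      qq <- unname(stats::quantile(bj, stats::pnorm(c(2 * z0 - za, 2 * z0 + za))))
      res$lower[j] <- exp(qq[1]); res$upper[j] <- exp(qq[2])
    }
  }

  omnibus <- NA_real_
  if (Bp > 0 && !separation) {
    if (is.null(testVars)) testVars <- names(predictors)
    nullVars <- setdiff(names(predictors), testVars)
    nullForm <- if (length(nullVars))
      stats::as.formula(paste(".y ~", paste(nullVars, collapse = "+")))
    else stats::as.formula(".y ~ 1")
    fit0 <- suppressWarnings(stats::glm(nullForm, data = dat,
                                        family = stats::binomial()))
    lrObs <- fit0$deviance - fit$deviance
    set.seed(seed + 1L)
    lrPerm <- vapply(seq_len(Bp), function(b) {
      datp <- dat
      datp$.y <- dat$.y[sample.int(nrow(dat))]
      f1 <- suppressWarnings(stats::glm(.y ~ ., data = datp,
                                        family = stats::binomial()))
      f0 <- suppressWarnings(stats::glm(nullForm, data = datp,
                                        family = stats::binomial()))
      f0$deviance - f1$deviance
    }, numeric(1))
    omnibus <- (1 + sum(lrPerm >= lrObs)) / (Bp + 1)
  }

  structure(list(coefficients = res, omnibus_p = omnibus,
                 separation = separation, converged = fit$converged,
                 model = fit, seed = seed),
            class = "LogisticReport")
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values in cumulative-minimum form; order-preserving and
#' never below the raw p-values.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
fdrCorrect <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Compare a binary outcome across clusters
#'
#' Per-cluster probabilities with BC bootstrap CIs and a permutation-LRT
#' omnibus p-value from a cluster-indicator logistic model.
#'
#' @param y logical/0-1 outcome.
#' @param g cluster labels.
#' @param Bci,Bp,seed as in [groupCompareContinuous()].
#' @param outcome label stored in the output.
#' @return a `"GroupComparison"` list (pairwise contrasts on the probability
#'   scale).
#' @export
groupCompareBinary <- function(y, g, Bci = 1000, Bp = 500, seed = 1,
                               outcome = "outcome") {
  g <- droplevels(as.factor(g))
  y <- as.integer(y)
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  seed <- checkSeed(seed)
  seeds <- deriveSeeds(seed, nlevels(g) + 1L + choose(nlevels(g), 2))

  groups <- do.call(rbind, lapply(seq_len(nlevels(g)), function(j) {
    yy <- y[g == levels(g)[j]]
    ci <- bootstrapCi(yy, mean, B = Bci, seed = seeds[j])
    data.frame(cluster = levels(g)[j], n = length(yy), estimate = ci$estimate,
               lower = ci$lower, upper = ci$upper, stringsAsFactors = FALSE)
  }))

  lr <- logisticOutcome(y, data.frame(cluster = g), B = 0, Bp = Bp,
                        seed = seeds[nlevels(g) + 1L])
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(seq_along(pairs), function(pi) {
    a <- pairs[[pi]][1]; b <- pairs[[pi]][2]
    sub <- g %in% c(a, b)
    lr2 <- logisticOutcome(y[sub], data.frame(cluster = droplevels(g[sub])),
                           B = 0, Bp = Bp,
                           seed = seeds[nlevels(g) + 1L + pi])
    data.frame(cluster_a = a, cluster_b = b,
               estimate = mean(y[g == a]) - mean(y[g == b]),
               lower = NA_real_, upper = NA_real_, p = lr2$omnibus_p,
               stringsAsFactors = FALSE)
  }))
  structure(list(outcome = outcome, groups = groups, omnibus_p = lr$omnibus_p,
                 pairwise = pw, seed = seed, Bci = Bci, Bp = Bp),
            class = "GroupComparison")
}

#' Assemble the full association battery over one cohort
#'
#' Runs the standard analysis battery: demographics by cluster, cosinor
#' parameters and observed timings by cluster, sleep variables by cluster,
#' MEQ by cluster, the DSP-by-cluster comparison, and the three DSP logistic
#' model forms (clusters only, cosinor parameters only, clusters plus
#' cosinor). One global Benjamini-Hochberg family covers all omnibus
#' p-values; pairwise p-values are corrected within their own family.
#' Clock-time outcomes are analysed on the 18:00-anchored scale.
#'
#' @param cohortTable per-subject `data.frame` with columns `cluster` plus
#'   any of: `sex`, `age`, `bmi`, `mesor`, `amplitude`, `period_h`,
#'   `acro_clock_h`, `bathy_clock_h`, `obs_acro_clock_h`,
#'   `obs_bathy_clock_h`, `assumed_sleep_h`, `waso_min`, `sol_h`,
#'   `onset_mean_h`, `midpoint_mean_h`, `offset_mean_h`, `sd_onset_min`,
#'   `sd_midpoint_min`, `meq_sum`, `dsp`. Absent columns are skipped with a
#'   warning.
#' @param Bci,Bp,seed bootstrap controls.
#' @return list of class `"AssociationReport"`: `table` (one row per omnibus
#'   test: outcome, p, p_fdr), `comparisons` (named list of
#'   `GroupComparison`), `pairwise` (long `data.frame` with `p_fdr` within
#'   the pairwise family), `dspModels` (list of `LogisticReport`).
#' @export
buildReport <- function(cohortTable, Bci = 1000, Bp = 500, seed = 1) {
  stopifnot("cluster" %in% names(cohortTable))
  seed <- checkSeed(seed)
  g <- as.factor(cohortTable$cluster)

  clockVars <- c("acro_clock_h", "bathy_clock_h", "obs_acro_clock_h",
                 "obs_bathy_clock_h", "onset_mean_h", "midpoint_mean_h",
                 "offset_mean_h")
  contVars <- c("age", "bmi", "period_h", "mesor", "amplitude", clockVars,
                "assumed_sleep_h", "waso_min", "sol_h", "sd_onset_min",
                "sd_midpoint_min", "meq_sum")
  binVars <- c("sex", "dsp")

  comparisons <- list()
  seeds <- deriveSeeds(seed, length(contVars) + length(binVars) + 4L)
  si <- 0L
  for (v in contVars) {
    si <- si + 1L
    if (!v %in% names(cohortTable)) next
    y <- cohortTable[[v]]
    if (v %in% clockVars) y <- hoursSinceAnchor(y, 18)
    comparisons[[v]] <- tryCatch(
      groupCompareContinuous(y, g, Bci = Bci, Bp = Bp, seed = seeds[si],
                             outcome = v),
      error = function(e) { warning("skipping ", v, ": ", conditionMessage(e)); NULL })
  }
  for (v in binVars) {
    si <- si + 1L
    if (!v %in% names(cohortTable)) next
    y <- cohortTable[[v]]
    if (v == "sex") y <- cohortTable[[v]] == "M"
    comparisons[[v]] <- tryCatch(
      groupCompareBinary(y, g, Bci = Bci, Bp = Bp, seed = seeds[si],
                         outcome = v),
      error = function(e) { warning("skipping ", v, ": ", conditionMessage(e)); NULL })
  }
  comparisons <- Filter(Negate(is.null), comparisons)

  ## DSP logistic model forms
  dspModels <- list()
  cosVars <- intersect(c("mesor", "amplitude", "period_h", "acro_clock_h"),
                       names(cohortTable))
  if ("dsp" %in% names(cohortTable)) {
    dspModels$clusters <- logisticOutcome(
      cohortTable$dsp, data.frame(cluster = g), B = 0, Bp = Bp,
      seed = seeds[si + 1L])
    if (length(cosVars) >= 2) {
      cos <- cohortTable[, cosVars, drop = FALSE]
      if ("acro_clock_h" %in% names(cos))
        cos$acro_clock_h <- hoursSinceAnchor(cos$acro_clock_h, 18)
      dspModels$cosinor <- logisticOutcome(cohortTable$dsp, cos, B = 0,
                                           Bp = Bp, seed = seeds[si + 2L])
      dspModels$clustersAdjusted <- logisticOutcome(
        cohortTable$dsp, cbind(data.frame(cluster = g), cos),
        testVars = "cluster", B = 0, Bp = Bp, seed = seeds[si + 3L])
    }
  }

  tab <- data.frame(outcome = names(comparisons),
                    p = vapply(comparisons, `[[`, numeric(1), "omnibus_p"),
                    stringsAsFactors = FALSE)
  tab$p_fdr <- fdrCorrect(tab$p)

  pw <- do.call(rbind, lapply(names(comparisons), function(v) {
    p <- comparisons[[v]]$pairwise
    if (is.null(p)) return(NULL)
    cbind(outcome = v, p, stringsAsFactors = FALSE)
  }))
  if (!is.null(pw)) pw$p_fdr <- fdrCorrect(pw$p)

  structure(list(table = tab, comparisons = comparisons, pairwise = pw,
                 dspModels = dspModels, seed = seed, Bci = Bci, Bp = Bp),
            class = "AssociationReport")
}
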