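# CircaTemp

Data-driven profiling of circadian temperature rhythms from free-living,
minute-resolution wrist skin temperature recordings.

Wearable thermologgers (iButton-class devices, 0.0625 °C resolution, one
sample per minute over about three days) make it possible to measure the
circadian rhythm of skin temperature outside the laboratory. `CircaTemp`
implements a complete analysis pipeline for such cohorts, aimed at sleep and
circadian researchers who want to characterize *physiological* rhythm
profiles without committing to a parametric model up front:

1. **Synthetic cohort generation** — cluster-structured cosinor parameters,
   AR(1) sensor noise, attachment warm-up transients, re-attachment gaps,
   logger quantization, start-time jitter (15:00–22:00), plus matched
   nightly sleep episodes, six-item morningness–eveningness (MEQ) responses
   and demographics. Every downstream stage is testable with no data
   download.
2. **Preprocessing** — harmonization of all records to a common 48-h window
   starting at the first noon after attachment (2880 samples), regularized
   iterative principal-components imputation of missing stretches, loess
   smoothing (span 0.3) with a smoothing-spline sensitivity companion and an
   exclusion rule for smoother-dependent fits.
3. **Cosinor rhythmometry** — per subject, the single-component model

   *Y(t) = M + A·cos(2πt/τ + φ) + e(t)*

   with mesor *M* (rhythm-adjusted mean), amplitude *A* (half the
   peak-to-trough extent), acrophase *φ*, and period *τ* profiled out by an
   iterative 1-D search over 20–30 h; quadrant-resolved acrophase and model
   and observed (smoothed-data) peak/nadir times in clock time.
4. **Rhythm clustering** — discrete Fourier features (DC + 24 harmonics),
   k-medoids (PAM) with mesor-ordered labels, silhouette / Dunn /
   Davies–Bouldin validity indices, eigenvalue-based RMSEA/eBIC analogues,
   and t-SNE + similarity-network (Fruchterman–Reingold, Newman modularity)
   stability diagnostics.
5. **Sleep behaviour** — assumed sleep, WASO, sleep-onset latency, onset /
   midpoint / offset clock means, onset and midpoint regularity SDs, the
   rule-based delayed-sleep-phase (DSP) classification (onset after 01:00 at
   least three times per week) and the 6-item MEQ sum score.
6. **Association inference** — bias-corrected percentile bootstrap CIs,
   null-imposed bootstrap omnibus and pairwise tests, logistic models with
   per-SD odds ratios, and one global Benjamini–Hochberg FDR family over all
   omnibus tests.

## Worked example

Simulate a scaled cohort from the shipped three-archetype fixture, fit the
cosinor battery, cluster the Fourier features, and run the association
report:

```r
library(CircaTemp)

arch <- defaultArchetypes()
arch$n_subjects <- c(30L, 39L, 15L)
bundle <- generateCohort(arch, noiseSpec(), seed = 1)

cohort <- smoothCohort(imputeCohort(harmonizeCohort(bundle), ncp = 2),
                       "loess", span = 0.3)
cohort
#> TemperatureCohort: 84 subjects x 2880 minute samples
#>   assays: temperature, smoothed
#>   missing temperature cells: 0 (0.00%)
#>   colData: subject_id, label, dsp, mesor, amplitude, period, acrophase_clock

fits <- fitCosinorCohort(cohort)
lab <- bundle$truth$label[match(fits$subject_id, bundle$truth$subject_id)]
aggregate(cbind(mesor, amplitude, period_h) ~ lab,
          data = cbind(fits, lab), FUN = function(x) round(mean(x), 2))
#>        lab mesor amplitude period_h
#> 1 cluster1 34.29      1.06    25.73
#> 2 cluster2 33.46      1.39    25.80
#> 3 cluster3 32.75      2.12    25.39
```

The recovered per-cluster means sit on the generative archetypes: cluster 1
is the warmest (mesor 34.29 °C) and flattest (amplitude ~1 °C), cluster 3
the coolest with the largest swing (~2.1 °C), all periods near 25–26 h.
Clustering the Fourier features recovers the generative partition exactly:

```r
feats <- dftFeatures(cohort, H = 24)
sol <- pamCluster(feats, k = 3, seed = 1, orderBy = fits$mesor)
sol
#> ClusterSolution: k = 3
#>   sizes: 30, 39, 15
#>   medoids: S0046, S0029, S0077
#>   total cost 20.0392 (seed 1)
mclust::adjustedRandIndex(lab, clusterLabels(sol))
#> [1] 1

sl <- sleepBattery(bundle$sleep, bundle$meq)
tab <- cbind(fits, cluster = clusterLabels(sol)[fits$subject_id],
             sl[match(fits$subject_id, sl$subject_id), -1])
rep <- buildReport(tab, Bci = 1000, Bp = 500, seed = 2)
rep$comparisons$dsp$groups
#>   cluster  n estimate lower upper
#> 1       1 30     0.50 0.333  0.67
#> 2       2 39     0.72 0.564  0.85
#> 3       3 15     0.27 0.067  0.47
```

The DSP probability peaks in cluster 2 (72%, BC bootstrap 95% CI 56–85%)
and is lowest in the high-amplitude cluster 3 (27%), with the omnibus
DSP-by-cluster test FDR-significant (`rep$table`); mesor, amplitude and
sleep-onset timing differ between clusters at FDR < 0.01 while MEQ does not
at this scale.

A full configured run — every stage artifact as CSV plus a seeded
`manifest.json` — is one call:

```r
runPipeline(defaultConfig(seed = 1), "runs/demo")
```

(or `Rscript inst/scripts/run_pipeline.R --seed 1 --out runs/demo`).

## Layout

- `R/` — implementation (S4 classes `TemperatureCohort`, `TemperatureSeries`,
  `CosinorFit`, `ClusterSolution`; camelCase exported functions per stage).
- `inst/extdata/archetypes.csv` — the versioned three-cluster fixture.
- `vignettes/circadian-temperature-profiling.Rmd` — the methods vignette:
  model, parameters, generator assumptions, numerical choices, limitations.
- `tests/testthat/` — unit, property and acceptance suites.

CSV schemas (one example row each):

| file | columns | example |
|---|---|---|
| `temperature.csv` | subject_id, timestamp, temp_c | `S0001,2016-11-01T16:24:00,33.6875` |
| `sleep.csv` | subject_id, night, bedtime, onset, offset, waso_min | `S0001,1,2016-11-02T00:05:00,2016-11-02T00:25:00,2016-11-02T08:21:00,52.1` |
| `meq.csv` | subject_id, item4…item19 | `S0001,3,2,4,1,5,2` |
| `cosinor_params.csv` | subject_id, mesor, amplitude, period_h, acrophase_rad, …, acro_clock, bathy_clock | `S0001,34.28,1.05,25.71,1.85,…,01:49,14:41` |
| `clusters.csv` | subject_id, cluster | `S0001,1` |
| `validity.csv` | k, db, dunn, silhouette, rmsea_like, ebic_like | `3,0.52,0.31,0.61,0.04,-120.2` |
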