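---
title: "Profiling circadian temperature rhythms: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling circadian temperature rhythms: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CircaTemp)
```

`CircaTemp` analyses minute-resolution wrist skin temperature from
free-living cohorts: it fits per-subject cosinor rhythms, clusters subjects
by the shape of their whole temperature time series, and relates the
resulting profiles to actigraphy-style sleep behaviour, delayed sleep phase
(DSP) status and circadian preference. This vignette is the package's own
account of the science: the models, every tunable that matters, what the
synthetic cohorts do and do not emulate, and the numerical decisions that a
reader of results produced with this package should know about.

## The measurement model

A wrist-worn thermologger records temperature once per minute for about
three days, attached between 15:00 and 22:00. Three artefacts dominate such
recordings and are modelled explicitly by the generator and handled by the
pipeline:

* a **warm-up transient** in the first 1–2 hours while the device
  equilibrates against the skin;
* **re-attachment gaps** — contiguous runs of missing samples when the
  device is taken off;
* **quantization** to the logger's 0.0625 °C resolution (accuracy is far
  coarser, ±0.5 °C, which motivates treating the noise floor generously).

Skin temperature noise is strongly autocorrelated minute to minute
(movement, posture, microclimate), so the generator uses AR(1) noise rather
than i.i.d. draws: `noiseSpec()` defaults to an innovation SD of 0.4 °C with
autoregressive coefficient 0.9. Neither value is measured from a specific
device; they are chosen to make the smoothing and sensitivity-filtering
stages do real work while leaving the rhythm clearly recoverable, which is
the regime wrist loggers actually operate in.

## Harmonization: the canonical 48-h noon window

All records are aligned to start at the **first noon strictly after
recording start** (a record starting exactly at noon keeps its first
sample), and exactly 48 h = 2880 one-minute samples are retained. "12 p.m."
is read as *noon* throughout: starting the window at noon discards the
evening attachment transient, which is the point of the harmonization. A
3-day recording started between 15:00 and 22:00 always contains this
window, so every subject contributes an equal-length vector with no padding.
Samples the recording did not cover are flagged missing, and a recording
too short to cover the window flags the subject unusable rather than being
silently truncated.

## Imputation

Missing runs are completed with a regularized iterative
principal-components scheme on the subjects × timepoints matrix
(`imputeMissing()`, default `ncp = 2` components): initialize missing cells
with column means, then iterate {center, rank-`ncp` truncated decomposition
with each retained singular value shrunk by the mean discarded
eigen-energy, refill only the missing cells} until the largest change is
below 1e-6 (cap 1000 iterations; non-convergence returns the last iterate
with a warning). Observed cells are never altered. Operating across
subjects lets a subject's gap borrow the cohort's dominant diurnal shapes;
a per-subject linear interpolation fallback (`perSubject = TRUE`) exists
for isolated use. Whether imputation should precede or follow
harmonization is genuinely open; the package harmonizes first (the dropped
head would otherwise dominate the missingness pattern) and documents the
choice here.

## Smoothing and the sensitivity filter

The working series for cosinor fitting and clustering is loess-smoothed
(`span = 0.3`, local quadratic, tricube weights — the conventional defaults
of that smoother; only the span is a scientific choice, trading ultradian
detail against stability of the fitted extrema). As a sensitivity
companion, a penalized cubic smoothing spline with GCV-chosen penalty
(`splineSmooth()`) re-smooths every series; when GCV collapses toward an
interpolating fit on effectively noiseless input, the fit falls back to 30
effective degrees of freedom with a warning.

Subjects whose cosinor parameters depend strongly on the smoother are
excluded: by default when the two period estimates differ by more than 2 h
or the relative amplitude discrepancy exceeds 25%. These thresholds are
package choices, not measured constants — they are exposed in the
configuration (`sensitivity`) precisely because reasonable analysts could
set them differently. At default generator noise they exclude well under
15% of simulated subjects, comparable to the ~10% exclusion typical of real
cohorts of this kind.

## Cosinor rhythmometry

The single-component cosinor model is

$$Y(t) = M + A\cos(2\pi t/\tau + \phi) + e(t)$$

with mesor $M$ (rhythm-adjusted mean, °C), amplitude $A$ (half the
peak-to-trough extent of the fitted curve, °C), acrophase $\phi$ (radians)
and period $\tau$ (hours). The fit is linearized —
$Y = M + \beta\cos(2\pi t/\tau) + \gamma\sin(2\pi t/\tau)$ with
$A = \sqrt{\beta^2 + \gamma^2}$ — and $\tau$ is profiled out by a 1-D
search: a coarse 6-min grid over 20–30 h followed by golden-section
refinement to 6 s. This reaches the same optimum as joint 4-parameter
nonlinear least squares without its convergence fragility. The 20–30 h
bounds bracket the near-24-h rhythms this instrument records in free-living
data (cohort means around 25.3–25.8 h); they are configurable
(`tauRange`).

The acrophase is resolved over all four quadrants with an explicit
sign-case table equivalent to a full-range two-argument arctangent, so
$\beta = A\cos\phi$, $\gamma = -A\sin\phi$ holds everywhere and the model
peak lands at $t^* = (-\phi\tau/2\pi) \bmod \tau$. The convention fixes
$\phi \in (-\pi, \pi]$; clock-time exports use the first model extremum
after the window start (noon), and the model nadir is reported exactly
$\tau/2$ after the peak.

**Observed extrema** are computed independently of the model: the smoothed
series is split into consecutive 24-h cycles, each cycle contributes its
argmax/argmin as a clock time, and cycles are summarized by the circular
mean (period 24 h) so peaks straddling midnight average correctly. Model
and observed timings differ in real data — the package deliberately keeps
both as first-class outputs, because the discrepancy is itself informative
about non-sinusoidal rhythm shapes. With a non-24-h period the extrema
drift across days; a constant cycle is skipped, and an all-constant series
has undefined timing.

Degenerate inputs: a constant series has amplitude 0, undefined phase and
an undefined period (the RSS profile is flat); a fitted amplitude below
1e-8 of the mesor scale is treated as numerically zero rather than
producing a meaningless phase from rounding noise.

## Fourier features and k-medoids clustering

Rather than reducing each subject to the cosinor parameters, the clustering
embeds the entire series shape: each 2880-sample smoothed series is reduced
to its DC term plus the first `H = 24` harmonics of the discrete Fourier
transform as (real, imaginary) pairs — 49 features spanning periods of 2 h
and longer over the 48-h window. The truncation is configurable; 24
harmonics keep everything at ultradian scales a 0.3-span loess survives.
Under the normalized convention the DC term equals the series mean, so
Euclidean feature distance includes mesor separation — a real cluster
separator in this domain. A `dropDC` flag gives shape-only clustering, and
a `magnitudesOnly` flag discards phase, for analysts who read "Euclidean
distances between Fourier parameters" either way.

Partitioning Around Medoids (BUILD + SWAP to local optimality, via the
`cluster` package) is restarted over 10 permuted input orders with the best
total cost kept and the seed recorded. Labels are renumbered so cluster 1
has the highest mean mesor — a reporting convention, not a model choice.

**Validity battery.** Per candidate $k$: Davies–Bouldin (min better), Dunn
and mean silhouette (max better), plus two dimensionality diagnostics
reconstructed as eigenvalue statistics: a Bartlett-style equality test on
the $p-k$ trailing eigenvalues of the feature covariance (features first
reduced to 10 principal components), converted to an RMSEA-like index
$\sqrt{\max(0, (\chi^2/df - 1)/(n-1))}$ with the usual 0.05 acceptance
level, and an eBIC-like index $\chi^2 - df\log n$. These two are documented
analogues — the field reports indices under these names without a canonical
formula for this setting — and are flagged as such wherever they appear.
One property worth knowing: the RMSEA analogue is *not* globally monotone
in $k$; it is high while dominant components remain unabsorbed and drops
below 0.05 once the residual spectrum is near-isotropic, which is the
behaviour the tests pin down. `selectK()` surfaces every index's vote and a
majority consensus with ties broken toward smaller $k$ — disagreement
between indices is the expected situation, never collapsed silently.

**Stability diagnostics, not clusterers.** An exact t-SNE embedding
(perplexity-calibrated Gaussian affinities, early exaggeration 4, momentum
descent, fixed seed) is re-clustered at the same $k$ and compared by
adjusted Rand index; and a Gaussian-kernel 10-nearest-neighbour similarity
graph (bandwidth = median pairwise distance) is laid out with
Fruchterman–Reingold and scored by the Newman modularity of the candidate
partition. Both answer "does the partition survive a different view of the
same distances?" — they are diagnostics of the PAM solution, not
alternative clusterings.

## Sleep behaviour, DSP and MEQ

Per night: assumed sleep = offset − onset; sleep-onset latency = onset −
bedtime; midpoint = onset + assumed/2; WASO is carried per night in
minutes. Clock-time means and regularity SDs are computed on an unwrapped
scale anchored at 18:00 — adolescent sleep onsets never cluster near 18:00,
so ordinary moments are safe there; this anchor is the single place where
clock arithmetic could break, which is why it is a documented parameter
rather than a constant. At least 3 nights are required; episodes with
negative durations are rejected with a warning.

DSP is classified by rule: sleep onset strictly after 01:00 on at least 3
nights per week, normalized by observed nights
($(\text{late}/n)\times 7 \ge 3$) because real windows are 8–10 days with
dropouts. Onset (actigraphy-scored falling asleep) is the default event; a
`bedtime` mode exists because "going to sleep" is genuinely ambiguous. The
MEQ short form sums six items (4, 7, 9, 15, 17, 19; higher = more
morning-oriented); the per-item legal ranges live in a scoring table
(`meqScoringTable()`), not in code, since response scales are a
questionnaire convention.

## Bootstrap inference and FDR

Confidence intervals are bias-corrected (BC) percentile bootstrap intervals
— no acceleration term — with `B = 1000` resamples; ties at the point
estimate count half toward the bias correction, and a degenerate resampling
distribution collapses the interval to the point with a flag. Omnibus
p-values for cluster comparisons use **null-imposed resampling**: groups
are centered (imposing the null) and resampled within group, and the
one-way F statistic's tail probability is estimated with `B = 500` and the
add-one correction $(1 + \#\{F^* \ge F\})/(B+1)$. For logistic models the
omnibus p-value is a permutation tail of the likelihood-ratio statistic.
The two resample counts (1000 for CIs, 500 for p-values) are both exposed
and recorded in output metadata. Complete separation in logistic fits is
detected and reported as non-estimable instead of silently diverging;
continuous predictors are standardized so odds ratios are per SD.

The FDR family is *all omnibus tests of one pipeline run*, corrected
together by Benjamini–Hochberg; pairwise contrasts form their own family.
Whether post-hoc tests belong in the global family is ambiguous in
practice; keeping them separate is the more conservative reading for the
omnibus conclusions and is the package default.

## What the synthetic cohorts emulate — and what they do not

The shipped archetype fixture (`defaultArchetypes()`) encodes three
profiles with mesors 34.29/33.46/32.80 °C, amplitudes 1.02/1.38/2.09 °C,
periods 25.75/25.76/25.33 h, observed acrophases 02:40/02:34/02:02, DSP
probabilities 0.46/0.68/0.37, cluster-specific sleep-onset distributions
and MEQ score distributions, and sizes 100/130/51. Within-cluster
dispersions (mesor and amplitude SD 0.15 °C, period SD 0.4 h) are package
choices calibrated so bootstrap CI widths are comparable to what cohorts of
this size report — no published subject-level dispersions exist to copy.
The generator anchors each subject's peak so that the two cycles inside the
harmonized window straddle the archetype acrophase symmetrically; with a
non-24-h period the peak necessarily drifts ~1.75 h/day, and this choice
makes the *circular-mean observed acrophase* the quantity the archetype
specifies. A DSP-labelled subject is guaranteed ≥ 4 of 8 late onsets and a
non-DSP subject ≤ 2, so the rule-based classifier recovers generative
labels exactly at zero noise — by construction, not as an empirical
finding.

Passing tests on these cohorts therefore demonstrate *parameter and
structure recovery under the stated noise model*, not performance on real
recordings. The generator deliberately omits: raw tri-axial accelerometry,
light exposure and its feedback on the rhythm, ultradian and menstrual
components, posture/exercise artefacts beyond the AR(1) term, and any
dependence of sleep behaviour on the temperature series beyond the shared
cluster membership. Real-data discrepancies between cosinor and observed
timing, and real DSP–temperature coupling, are richer than this.

## Problem sizes and numerical conventions

The test and acceptance suites run the recovery studies at 200 series per
archetype, the full 281-subject cohort for structure recovery, 500
simulations for null-calibration and 1000 for BC coverage — sizes chosen so
each study estimates its target within the tolerances it asserts
(Monte-Carlo SEs of ~0.01 °C for parameter means, KS resolution ~0.07 for
uniformity) while the whole suite stays comfortably interactive. Clock
times are serialized as `hh:mm` strings in reports and decimal hours in
machine-readable CSVs, avoiding the float-vs-clock ambiguity that haunts
published tables. All timestamps are UTC; the package attaches no DST
semantics to recordings.

## Known limitations

* The RMSEA/eBIC analogues are reconstructions; their absolute values
  should not be compared against software using different definitions, only
  their per-$k$ profile within one analysis.
* The exact t-SNE is $O(n^2)$ per iteration — fine for hundreds of
  subjects, not for tens of thousands.
* The imputation shrinkage schedule is a simplified variant of regularized
  iterative PCA; with very high missingness (> 30–40%) its rank-`ncp`
  assumption becomes load-bearing.
* Period estimates from 48-h windows have wide sampling variability by
  nature (two cycles); between-cluster period differences of ~0.5 h are not
  resolvable at cohort sizes in the hundreds, and the package makes no
  claim otherwise.
* DSP classification is behavioural (timing rule), not clinical.
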