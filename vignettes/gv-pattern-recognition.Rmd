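---
title: "Glycemic variability pattern recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycemic variability pattern recognition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continuous glucose monitoring (CGM) devices sample interstitial glucose
roughly every 15 minutes for weeks at a time. Classical summaries of these
traces — mean glucose, SD, the coefficient of variation (COV = SD/mean), and
time in range (TIR, the share of readings between consensus breakpoints at
3, 3.9, 10 and 13.9 mmol/L) — are order-free: shuffling the readings leaves
them unchanged, so they cannot say *how* a patient's glucose fluctuates,
only how much. gvpatterns implements an order-aware alternative: it mines a
cohort's traces for a small dictionary of recurring fluctuation shapes
("patterns"), summarises each patient by the fraction of their time spent in
each pattern, and groups patients into glycemic-variability profiles from
those compositions.

## The procedure

1. **Canonicalisation** (`read_cgm_csv`, `dedup_minute_median`). Values are
   converted to mmol/L (÷ 18.016 from mg/dL); timestamps are truncated to
   the calendar minute and duplicate readings within a minute are replaced
   by their median. Truncation rather than rounding keeps "within the same
   minute" a pure bucketing rule; the median also quietly resolves
   daylight-saving duplicates.
2. **Windowing** (`extract_windows`, `density_filter`). Each trace is cut
   into overlapping windows of fixed duration (default 150 min, 50%
   overlap), anchored at the patient's first sample. Windows are half-open
   `[start, start + duration)` so a boundary sample belongs to exactly one
   window at 0% overlap. Windows averaging fewer than 4 measurements per
   hour are discarded — at nominal 15-minute sampling this keeps only
   complete windows, which is why moderate sensor dropout removes a large
   share of windows. Samples are *not* resampled onto a regular grid:
   dynamic time warping tolerates uneven spacing, and interpolation would
   invent data inside sensor gaps. A linear-interpolation resampler
   (`resample_windows`) exists for sensitivity analyses only.
3. **The DTW distance** (`dtw_distance`). The dissimilarity between two
   windows is the classical dynamic-programming alignment cost: over all
   monotone warping paths, the minimal sum of local costs, with L1 local
   cost and the symmetric unit-weight step (diagonal, vertical and
   horizontal moves each pay the local cost once). Two deliberate defaults:
   *no input normalization* — the patterns must distinguish a steady
   normoglycemic window from a steady severely hyperglycemic one, which
   z-normalization would erase — and *no path-length normalization*, the raw
   cost being the simplest contract (a normalized variant is exported
   separately). An optional Sakoe-Chiba band bounds `|i - j|` for speed on
   long sequences; it is off everywhere results are reported.
4. **Pattern extraction** (`cluster_windows`). k-medoids (PAM) on the
   pairwise DTW matrix: deterministic farthest-point seeding from the seed,
   best-improvement swaps until convergence (cap 100 iterations), best of 5
   restarts by total within-cluster distance. Medoids rather than
   barycenters because a medoid is an actual observed window — the natural
   "median curve" to show a clinician — and because averaging under warping
   (DBA) adds machinery without changing the statistic of interest.
   Patterns are relabeled so mean medoid glucose increases with the label:
   pattern 1 is always the lowest-glucose shape.
5. **Hyperparameter selection** (`grid_search`, `elbow_select_k`). Duration
   and overlap are searched over {120, 150, 180} min × {0, 25, 50, 75}%.
   Each configuration is scored by four internal validity indices computed
   on the distance matrix — silhouette, a medoid-based Calinski-Harabasz,
   COP, and the modified Davies-Bouldin (DB*) — and configurations are
   ranked per index and aggregated by mean rank (ties: shorter duration,
   then lower overlap). Rank aggregation is an explicit policy choice: the
   four indices live on incomparable scales, and ranks are the least
   committal way to combine them. The number of patterns k is chosen over
   3..8 by the sharpest bend of the total within-distance curve, formalised
   as the maximal discrete second difference `W(k-1) - 2W(k) + W(k+1)`
   (interior k only, ties to smaller k). A visual "evaluate the graph" rule
   is not testable; the second difference is its deterministic counterpart,
   and a flat curve returns the smallest interior k with a warning.
6. **Patient summaries** (`time_in_patterns`, `glycemic_summary`,
   `target_fulfillment`, `pattern_occurrence_by_hour`). Time in patterns is
   the percentage composition of a patient's kept windows over the k
   patterns. TIR uses measurement weighting (each sample counts once);
   band edges are fixed as ≤3 | (3, 3.9] | (3.9, 10] | (10, 13.9) | ≥13.9 so
   the extreme bands are closed, matching how the extreme rows of clinical
   tables are labelled. SD uses the n−1 denominator. Consensus targets are
   strict inequalities: TIR(3.9–10] > 70%, COV < 0.36, HbA1c < 58 mmol/mol.
   The diurnal table assigns each window its midpoint clock hour.
7. **Patient profiling** (`hcluster_patients`, `cut_by_largest_gap`,
   `compare_clusters`). Compositions are compared with a distance suited to
   percentage data — Hellinger by default,
   `(1/√2)·||√(p/100) − √(q/100)||₂`, bounded in [0, 1] and defined at zero
   shares; Bray-Curtis, Aitchison (multiplicative zero replacement,
   δ = half the smallest positive share) and Euclidean are selectable
   because the literature's "percentage-data distance" is underdetermined
   and conclusions should be checked against this choice. Complete-linkage
   agglomeration (monotone merge heights) is cut where the gap between
   successive merge heights is largest, within 2–10 clusters, ties to fewer
   clusters. Clusters are then compared variable by variable: one-way ANOVA
   for numeric variables, Pearson chi-square without continuity correction
   for categorical ones, missing values omitted per variable, significance
   flagged at p < 0.05 with no multiplicity correction (by design — the
   output mirrors a univariate clinical characteristics table).
   `group_compare` reuses the same machinery for tertile splits of any
   numeric covariate (e.g. days of CGM use).

## The synthetic cohort generator

No public CGM cohort ships with the package, so every stage is validated
against `generate_cohort`, which states a world explicitly:

* six archetypal 15-minute-resolution templates spanning the fluctuation
  regimes seen in T1DM — steady 3–6; slight rise 6→8; decline 11→6; rise
  11→16; concave 14–19; peak-and-decline 19–28 — with strictly increasing
  means (the shapes are this package's own constructions, not fitted
  centroids);
* per patient, a template mixture drawn from a Dirichlet centred on one of
  four canonical profile archetypes (A: mixed with substantial
  hyperglycemia; B: dominated by severe hyperglycemia; C: in-target but
  variable; D: well controlled), with total concentration 60 — chosen once
  so the simulated within-profile spread (≈4–6 percentage points per
  component) is realistic for within-profile heterogeneity;
* wear time tiled by contiguous 150-minute template segments, with
  overnight (2–6 AM) draws favouring the low steady template (×4) and
  segments containing 9 AM / 1 PM / 7 PM favouring the rising templates
  (×3);
* i.i.d. Gaussian sensor noise (SD 0.5 mmol/L), clipping to [1, 30] mmol/L,
  and 5% random dropout; 15-minute sampling; everything reproducible from
  one seed.

What a green test establishes: the pipeline recovers structure *of this
kind* — well-separated template shapes, Dirichlet-mixed compositions,
diurnal placement. What it does not establish: performance on real sensor
error (autocorrelated, drifting), on gradual physiological transitions
between states, or on patterns whose separation is weaker than the
templates'. The generator is a correctness instrument, not a physiological
simulator — there is no meal/insulin kinetics model behind it.

Ground truth at window granularity needs care: with 50% overlap, half the
windows straddle a segment boundary. A window's truth label is the template
covering a strict majority of its samples and is `NA` for exact 50/50
straddles, which have no single true label. Recovery invariants are
therefore asserted where truth is well defined; the strictest version
(noiseless generation, windows aligned with segments at 0% overlap) must —
and does — recover labels perfectly, because every window is then an exact
template copy.

## Numerical choices and edge cases

* mg/dL ↔ mmol/L uses 18.016 (glucose molar mass 180.16 g/mol).
* Window strides may be fractional (150 min at 25% overlap gives 112.5 min):
  window bounds are real-valued instants compared against minute-resolution
  timestamps, so nothing forces integrality. Only non-positive strides are
  rejected.
* Trailing windows extending past the last sample are not emitted by
  default (`emit_partial = TRUE` opts in); a span shorter than one duration
  still yields its single covering window so short traces are not silently
  dropped.
* Percentile envelopes use linear-interpolation (type 7) quantiles on a
  common 15-minute offset grid, each window contributing its nearest-offset
  sample.
* Silhouette of a singleton is 0; validity-index denominators that vanish
  (coincident medoids, zero separation) yield `NaN` with a warning rather
  than an arbitrary number.
* PAM with k equal to the window count returns the trivial zero-cost
  solution; all-identical windows with k ≥ 2 raise a degenerate-data error
  naming the condition.
* Assignment ties go to the lowest pattern label; grid-search rank ties to
  the shorter duration, then lower overlap; elbow ties to smaller k;
  merge-gap ties to fewer clusters. Every tie rule is deterministic so
  reruns are byte-identical.

## Known limitations

* The percentage-data distance is the main faithfulness risk: the
  profiling stage's cluster count and memberships depend on it, which is
  why it is a first-class argument rather than a constant.
* The largest-merge-gap rule inherits a general weakness of gap statistics
  on hierarchies with one extreme group: when one profile (here the
  severe-hyperglycemia archetype) is far from a chain of closer profiles,
  the dominant gap sits at the final merge and the rule returns 2 clusters
  even when a finer planted structure is perfectly recoverable at a deeper
  cut — on the four-archetype synthetic world, `cutree(tree, 4)` matches
  the planted profiles essentially perfectly while the gap rule stops at 2.
  Users who expect a particular granularity should inspect the dendrogram
  and the returned height sequence rather than trusting any single cut
  rule.
* DTW is not a metric (no triangle inequality); the k-medoids and validity
  indices only require a symmetric dissimilarity, but no indexing
  accelerations that assume metricity are used or provided.
* No lower-bounding (LB_Keogh) pruning and no multivariate DTW; sequences
  at 15-minute resolution are short enough that the exact quadratic DP is
  cheap.
* HbA1c and other clinical covariates arrive as a prepared CSV; the package
  deliberately contains no clinical-records parsing.
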