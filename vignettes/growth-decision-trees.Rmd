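---
title: "From plate-reader kinetics to growth decision trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From plate-reader kinetics to growth decision trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rktree connects defined culture-media composition to two growth phenotypes
measured in 96-well plate-reader kinetics: the exponential growth rate
`r` (h^-1) and the saturated density `K` (OD600 units). It has four
working parts — growth-parameter extraction, ion-feature construction,
CART regression-tree learning, and a decision readout that classifies
chemicals as trade-off or uniform — plus a synthetic plate simulator with
planted decision structure that makes the whole chain testable without an
instrument. This vignette explains the models and the choices behind
them.

## Growth-parameter extraction

A raw well trace is an OD600 time series containing the optical
background of plate and medium, a lag phase, an exponential phase, and a
plateau. Extraction proceeds in fixed stages:

1. **Background subtraction.** The mean of the medium-only wells at each
   timepoint is subtracted from every sample well. Corrected values may
   be slightly negative; they are only floored when logs are taken.
2. **Saturated density.** `K` is the mean of three consecutive reads
   containing the maximum (centered on it; anchored at the boundary with
   an `edge_max` flag when the maximum is the first or last read). The
   three-read mean suppresses single-read noise at the plateau.
3. **Exponential window.** The window is the contiguous run of reads that
   ends just before the curve reaches `f_high * K` (default 0.9) and
   starts after the last crossing of the noise floor (default 0.01 OD)
   before that sustained rise. Anchoring the start at the *last* floor
   crossing excludes isolated lag-phase spikes. Two guards handle
   degenerate inputs: a curve that never clears the floor, or that holds
   a level near its maximum for fewer than two consecutive reads (a
   single-read transient is an artifact, not growth), is called
   `zero_growth` with `r = 0`; a window shorter than
   `min_window_points` (default 4) falls back to the longest rising run
   above the floor, flagged `too_few_slopes`.
4. **Log slopes.** Slopes of `ln OD` per hour inside the window. The
   default is the numerical-gradient convention — central differences at
   interior reads, one-sided at the two window edges — which averages
   read noise over two sampling intervals; plain forward differences are
   available via `extraction_config(slope_method = "forward")`. At an OD
   of 0.02 and a read noise of 0.005, a single 30-min forward difference
   has a slope standard deviation near 0.7 h^-1, which is why the choice
   of difference scheme matters far more than it first appears.
5. **Outlier removal.** Slopes outside the closed Tukey box-plot fences
   `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (quartiles by linear interpolation of
   order statistics, `stats::quantile` type 7) are discarded. A
   `below_q1` compatibility rule that discards only slopes below the
   first quartile is provided; the symmetric default also catches
   downward spikes. Positions are preserved.
6. **Rate.** `r` is the mean of the maximal surviving slope and its
   nearest surviving neighbours in time order (one on each side, fewer at
   a boundary), floored at zero. On an exact exponential every slope
   equals the rate, so `r` is recovered to floating-point accuracy at any
   uniform sampling interval.

**Dataset refinement.** A curve still rising at the end of the run is
unreliable: its `K` is censored and its window is truncated. The
incompleteness proxy used here is a mean log-slope above
`plateau_slope_tol` (default 0.02 h^-1) over the final `plateau_window`
(default 5) reads, applied only to curves whose `K` exceeds twice the
noise floor — in a flat well the final-window "slope" is pure read noise.
Zero-growth curves are deliberately retained: `r = 0` under a media
combination is information, and the zero-growth tree leaves need those
rows. In a very-low-`K` well the plateau test can fire on noise; this is
accepted as realistic attrition and every removal is logged.

Known limitation: because the window bounds are absolute OD levels, the
estimate of `r` is exactly scale-invariant only on pure exponentials; on
a saturating curve, rescaling all ODs shifts the window start by a read
or two and moves `r` by a few percent. `K` scales exactly.

## Ion features

The ten media compounds dissolve into 13 tracked components (glucose,
NH4, K, PO4, Mg, thiamine, Fe, Na, leucine, histidine, SO4, Cl, H);
`expand_to_ions()` is the linear stoichiometric map (one (NH4)2SO4 gives
two NH4 and one SO4; hydrate water contributes nothing). Concentrations
are log10-transformed because the designs vary them over orders of
magnitude; zeros are floored one decade below the column's smallest
positive value, recorded as `zero_floor`.

Column order is a deliberate choice: primary nutrients first,
counter-ions that are *sums* over several compounds (SO4, Cl, H) last.
Tree learning breaks exactly tied splits toward the lower column index,
and on a gridded design a counter-ion column can separate the very same
combinations as its source ion; the ordering attributes such splits to
the primary ion rather than to sulfate arithmetic. Correlated pairs that
are not exact ties (the classic compound-sourced NH4/SO4 confounding)
remain visible
in `feature_correlations()` and in split-stability reports.

## CART regression trees

`fit_tree()` is greedy binary recursive partitioning: at each node every
feature is scanned, candidate thresholds are arithmetic midpoints between
consecutive sorted distinct values, and the split minimizing the summed
within-child squared error is taken; `<=` goes left. On log10 features a
midpoint threshold back-transforms to the geometric mean of two adjacent
tested concentrations — which is how boundaries such as 63.2 mM
(= sqrt(20 x 200)) arise. Ties are broken deterministically (lower column
index, then lower threshold) so that split-stability reports measure
resampling variability, not arbitrary ordering. Splitting stops at
`max_depth`, below `2 * min_leaf` rows, or when no split reduces the
error.

Model selection follows the cross-validation plateau: `kfold_mse()`
partitions rows into k random near-equal folds (seeded; no
stratification) and `select_depth()` returns the smallest depth at which
moving one step deeper changes the mean CV mse by at most `tol` (default
0.001 on the squared target scale; the choice of an absolute tolerance
makes "the mse stopped changing" concrete). `split_stability()` refits
the tree on every training fold and reports, per node position
(`root`, `root.L`, ...), how often each feature occupies it — confounded
features alternate at a position, which is the fingerprint of
compound-sourced ion pairs.

`fit_tree()`'s own `min_leaf` default is 5, appropriate for small
instances; `run_pipeline()` fits plate-scale trees with `min_leaf = 20`
so that each leaf represents a media class with replicate support
(several combinations times replicates), matching the occupancy of
published growth decision trees and keeping best-leaf identification out
of single-leaf noise.

## Decision readout

`best_worst_paths()` traces the leaves with maximal and minimal mean
target (ties: larger leaf, then leftmost). `optimal_intervals()`
intersects a path's constraints per component into one concentration
interval, back-transformed to mM; a side the path leaves unconstrained is
filled from the design's tested range, since nothing outside the tested
range is evidenced. `classify_mechanism()` compares the rate-optimal and
density-optimal intervals per component: overlapping interiors mean the
chemical serves both objectives in the same range (*uniform*); disjoint
interiors — including intervals that touch only at a shared boundary —
mean a *trade-off*; components constrained in only one tree are
*unshared*. Intervals are taken from the single best path of each tree;
alternative high-target leaves are visible in the tree itself but are not
merged into the interval.

Two conventional statistics complete the readout. `spearman_rk()` gives
the rank correlation between `r` and `K` at curve or combination level
(average ranks for ties, p from the t approximation on n - 2 df; no
multiplicity correction anywhere in the package).
`regression_baseline()` is ordinary least squares of the growth parameter
on the 13 features — the analysis the trees are contrasted with. On
gridded designs it is rank-deficient by construction (constant phosphate,
exactly collinear counter-ions); by default this is an error naming the
collinear columns, and `drop_aliased = TRUE` drops them with a record. A
window-shaped effect (good at intermediate concentration, bad at both
extremes) has little linear signal, which is precisely why the tree finds
deciders the regression misses.

## The synthetic study

`rk_scenario()` defines the default study conditions: 225 combinations
sampled without replacement from a 324-cell log-grid factorial over six
varied compounds — glucose {2, 20, 200}, (NH4)2SO4 {10, 100, 200} (so NH4
spans 20–400 mM), MgSO4 {5, 100}, FeSO4 {0.001, 0.1, 10}, NaCl
{1, 10, 100}, thiamine·HCl {0.0015, 0.015} mM — over a fixed M63-like
base (phosphate buffer locked at the 5:3 ratio), five replicate wells per
combination distributed over 96-well plates with four medium-only wells
each, reads every 0.5 h for 48 h, additive Gaussian read noise of
0.005 OD, and a 5% rate for each artifact class. Grid levels were placed
so adjacent-level geometric means land on round decision boundaries
(63.2, 282.8, 22.4 mM).

The planted response (`rk_ground_truth()`) is a product of
piecewise-constant window rules on the ion profile:

* rate: `r* = 0.8 * g_NH4 * g_Mg * g_glc` with the NH4 optimum at
  (63.2, 282.8] mM (low NH4 gives factor 0.7, excess NH4 gives zero
  growth), the Mg optimum at (0.1, 22.4] mM (depletion below 0.1 mM
  gives zero growth; excess, factor 0.75), and glucose preferring
  <= 63.2 mM (factor 0.65 above);
* density: `K* = 1.2 * h_NH4 * h_Fe * h_Mg * h_glc * h_thi * h_Na` with
  the NH4 optimum *below* 63.2 mM (factor 0.55 in the rate-optimal
  window), iron toxic above 1 mM (0.8), the Mg optimum *above* 22.4 mM
  (0.7 below), the same glucose preference (0.65), and mild yield costs
  of thiamine limitation (0.85) and 100 mM salt (0.85);
* a well that cannot grow has `K* = 0` — a non-growing culture shows no
  density, so the excess-ammonium third of the design is zero in both
  responses.

So NH4 and Mg are planted trade-off chemicals, glucose a uniform one, and
iron a density-only decider. Replicates vary biologically: each well's
`(r*, K*)` are multiplied by lognormal factors with a coefficient of
variation of 0.18 whose logs correlate at -0.85 — a fast-growing
replicate tends to saturate lower, the resource-allocation trade-off
acting at the well level. This replicate structure is what makes
combination means sharper than individual curves (the per-combination
rank correlation of `r` and `K` exceeds the per-curve one), as replicate
averaging does in real landscape data. The per-well realized truth is
emitted (`well_truth`) so extraction accuracy can be scored against what
each well actually grew at, separately from biological scatter.

Artifacts mirror instrument pathology: a +0.1–0.3 OD spike at a single
lag-phase or exponential-phase read, or "truncation" — the well is
shifted late so it is still rising when the run ends, which is exactly
the downstream incomplete signature. (A literal shortening of one well is
impossible in a rectangular plate export; the late-onset implementation
preserves the shared time base.) All injections are logged.

Design notes, recorded because the design was genuinely open:

* The greedy root of the rate tree lands on the *zero-growth* boundary at
  282.8 mM NH4, one grid boundary above 63.2 mM, and the 63.2 mM cut
  appears at depth 2. This is forced: for any rule with a hard zero
  branch, the split isolating that branch reduces more variance than any
  interior split of the same factor. The same argument puts the density
  root on an NH4 cut rather than iron: with `K* = 0` wherever `r* = 0`,
  ammonium's zero branch dominates the density variance under a uniform
  factorial, and iron decides *within* the growing branch.
* The Mg grid has two levels rather than three with a depletion level:
  a second one-third-weight zero branch would tie the NH4-vs-Mg root
  split exactly (both reductions equal `(a+b)/2 * E[other]` with
  `E[self] = (a+b)/3`), making root recovery a coin flip rather than a
  property of the method. The 0.1 mM depletion boundary remains in the
  rule and is exercised off-grid.
* Penalty factors are shallow (0.55–0.8) because the rate estimator's
  accuracy degrades on slow, low-plateau wells; the chosen values keep
  the slowest planted wells within the regime where a 30-min-interval,
  0.005-OD-noise trace still supports slope estimation, while leaving
  every decision boundary's contrast greedy-dominant at depth 4.

What passing tests on this generator do **not** show about real data:
logistic growth with additive i.i.d. read noise has no plate-position or
evaporation effects, no diauxie or death phase, no correlated drift; the
design is an exact grid, so confounded counter-ions produce exact split
ties that real, irregular concentration sets would not; and the planted
response is exactly piecewise-constant on the grid, which flatters tree
learning relative to smooth dose responses.

## Reproducibility and sizes

Every stochastic step — design subsampling, lags, biological factors,
read noise, artifact draws, CV folds, stability resampling — derives from
explicit integer seeds, and reports serialize to byte-identical JSON
under a fixed seed. The shipped analyses run at the default study size
(1125 wells of 97 reads; trees on ~1050 refined curves), which a single
CPU handles in seconds per stage; multi-seed properties (mechanism calls
across 20 seeds, rank-correlation ordering across 10) are sized to keep
the full suite in single-digit minutes.
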