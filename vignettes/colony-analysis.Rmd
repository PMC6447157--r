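---
title: "Quantifying heterogeneity in colony-forming-unit assays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heterogeneity in colony-forming-unit assays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonytrack)
```

## The problem

Colony-forming-unit (CFU) assays plate bone-marrow stromal cells (BMSCs) at
very low density (tens of cells per cm²) and count the colonies that form
over one to two weeks, on the assumption that each colony is the clonal
progeny of one stem-like founder. Time-lapse imaging at 15-minute intervals
shows that this assumption fails in interesting, quantifiable ways: many
apparent colonies have several founders, colonies accumulate senescent
(permanently non-dividing) cells within days, sibling cells divide asynchronously,
and cell spread area shrinks systematically with each generation.

`colonytrack` implements the full analysis layer for such experiments:
lineage reconstruction from tracking output, per-frame and per-cell
morphology, colony geometry, fate/proliferation/asynchrony classification,
and a filtered rank-correlation / PCA statistical screen. Because raw
time-lapse data at this scale runs to terabytes per experiment, the package
pairs the analysis with an agent-based simulator whose defaults are
calibrated to published summary statistics, so every stage can be exercised
end to end with ground truth available.

## The tracking exchange format and lineage reconstruction

The canonical interchange object is the *object-number matrix*: one row per
frame, one column per unique cell, entries equal to the cell's per-frame
segmentation label and 0 where the cell does not exist. Its structural
grammar encodes the biology: a column's support must be one contiguous
block, and when a column ends mid-experiment (a division), exactly two new
columns must begin at the next frame (the daughters).

`validate_matrix()` checks exactly these two rules and reports *all*
findings (`gap`, `merge`, `orphan`, optionally `late_sibling`), because
real tracking output is corrected iteratively. `build_forest()` turns a
clean matrix into a lineage forest with parent, twin, generation, and
birth/division frames. Two conventions are worth stating:

* **Lifetime convention.** A cell spanning frames $b$ to $e$ has lifetime
  $(e - b + 1)\,\Delta t$, counting both endpoint frames. At 15-minute
  frames, 96 frames equal one day. Lifetimes are only defined for cells
  that divide *and* whose birth was observed — founders (generation 1) and
  non-dividers carry `NA`, and every downstream statistic respects that
  mask.
* **Simultaneous divisions.** When two or more columns end at the same
  frame, daughters are attributed by minimizing the summed distance between
  parent end-centroids and daughter start-centroids (exact enumeration up
  to four coincident divisions, greedy beyond). Without centroids this
  situation is an error rather than a guess.
* **Migrating-in cells.** Columns that begin mid-experiment at a frame with
  no coincident division are roots of their own (generation 1, undefined
  lifetime): cells that infiltrated the field, tracked but never conflated
  with the resident progeny.

## The synthetic colony model

`simulate_colony()` is an agent-based generative model. Its defaults *are*
the study conditions the analysis is designed for; they were fixed once,
against published summary statistics, and the tests treat them as frozen.

* **Lifetimes.** Dividing-cell lifetimes are truncated-normal
  (mean 0.83 d, SD 0.27 d, truncated at one frame). The distribution
  family is a modelling choice — only the first two moments are
  constrained by data — and is isolated in one sampler so it can be
  swapped. First-generation cells draw from the same family centered at
  1.0 d: freshly plated cells show an extended first cycle, so founders
  divide about a day after plating.
* **Senescence.** Each daughter is independently senescent with
  probability 0.08. Senescent cells never divide and keep growing linearly
  (1050 µm²/d). The probability was calibrated so that the mean per-colony
  fraction of Day-4 cells with no division by Day 7 is ≈16% *computed the
  way the observational statistic is computed*: an unweighted mean over
  experiments that actually form a colony (≥50 cells by Day 7). The
  unweighted per-colony mean is sensitive to small colonies (one early
  senescent daughter in a four-cell progeny is a 25% fraction), which is
  why the calibration uses the same inclusion rule as the assay.
* **Area dynamics.** Cells grow linearly (2400 µm²/d while proliferative);
  at division the parent's area is multiplied by a shrink factor (0.85)
  and split between the daughters, so birth area contracts geometrically
  toward an equilibrium — the generation–area trend the statistics module
  measures. Founders attach at 3800 µm².
* **Migration.** A persistent random walk (AR(1) velocity, persistence
  0.6, per-axis step SD 12 µm/frame) reflected at the field borders;
  daughters are placed one cell radius apart along a uniformly random
  axis. Step size and persistence were calibrated jointly with the area
  parameters so that Day-7 colonies match the published geometry
  (confluency ≈12.7%, circle-equivalent diameter ≈1.9 mm).
* **Media exchange.** Feeding events (frame 374, then twice weekly)
  multiply the SD of subsequent lifetime and birth-area draws by
  `(1 + 0.2)` per exchange. The observational record ties behavioural
  deviations to feeding times but quantifies no effect size, so the
  magnitude is an explicitly free parameter.
* **No death, no field exit.** The tracked data contain neither, so the
  model omits both; cell count therefore equals founders plus completed
  divisions at every frame, which the tests assert as a conservation law.

What the simulator does *not* emulate: phase-contrast photometry and
segmentation artifacts, contact inhibition or any cell–cell interaction,
nutrient fields, and real migration statistics beyond a persistent walk.
Passing recovery tests on this generator shows the *pipeline* is correct
and the calibration self-consistent — not that the generator is a faithful
model of BMSC biology.

## Rendering and measurement

`render_labels()` draws each living cell as a rotated filled ellipse
(aspect ratio 2 by default) of its current area at 0.6467 µm/px (15 px =
9.7 µm); overlapping pixels go to the nearer centroid and every cell keeps
at least one pixel. Coordinates are 0-based, origin top-left, x = column.

`measure_frame()` computes the standard region-property set. Numerical
choices that matter:

* Perimeter uses the four-direction Cauchy–Crofton estimator, which is
  close to unbiased on smooth shapes (a digital disk of radius 20 px gets a
  form factor of 0.97; a naive boundary-pixel count would overshoot 1.25).
* Second moments carry the 1/12 per-pixel variance term, so a single pixel
  has finite axis lengths and eccentricity stays strictly below 1.
* Solidity divides by the convex hull of the pixel *squares*, not pixel
  centres, so a filled rectangle scores exactly 1.
* Neighbor distances are clear gaps between edges (adjacent pixels are 0
  apart); the contact rule is an edge clearance of 15 px (9.7 µm).

Colony-level metrics (`colony_hull_metrics()`) measure the convex hull of
all member pixels, the occupied area, their ratio (confluency), and the
circle-equivalent diameter $2\sqrt{A_{hull}/\pi}$ — the standard way to
report colony size from a hull area. When only centroids are available the
hull is computed over centroids and flagged, since that slightly
underestimates the pixel-true footprint. Day-7 geometry in the acceptance
suite is measured on images rendered at 4× the native pixel size
(≈2.6 µm/px); the hull metrics are insensitive to this decimation at
millimetre colony scales, and it keeps a 30-colony run in seconds.

## Classification rules

All categorical calls follow the operational definitions of the assay:

* **Fate:** a cell alive at the Day-4 reference frame (374) is
  *proliferative* if it divides by the Day-7 horizon (672), *senescent* if
  tracked through the horizon without dividing. Tracks that end before the
  horizon without division are *censored* — a generalization the original
  visual workflow did not need — and are excluded from senescent
  fractions.
* **Proliferative class of a progeny:** fewer than 8 cells at Day 4 (under
  three population doublings) is *slow*, more than 16 (over four
  doublings) is *fast*, 8–16 inclusive is *moderate*.
* **Twin asynchrony:** sibling lifetimes differing by strictly more than
  one dataset-wide SD of dividing-cell lifetime (auto-computed, or 0.27 d
  as the published value); pairs with undefined lifetimes are excluded.
* **Colony origin:** single- vs multi-cell-derived by the number of
  original (first-frame) roots with living descendants among the members;
  late-joining roots set an `infiltrated` flag without changing the count.
* **Colony predicate:** at least 50 cells.
* **Isolation score 1–5:** when the nearest foreign cell first became
  visible under the staged field-of-view schedule (1.7×1.3 mm from Day 0,
  2.6×2.1 mm from Day 2, 3.5×2.6 mm from Day 6).

## The statistical layer

`spearman_rs()` computes the tie-corrected (midrank) Spearman coefficient.
The p-value uses the t approximation for $n \ge 10$ and the exact
permutation distribution (all $n!$ orderings, two-sided) for $n \le 9$ —
small progenies are common, and the exact distribution removes any
dependence on an asymptotic approximation precisely where it is worst. The
cutoff at 10 keeps the permutation matrix ($9! \times 9$) trivially cheap
and memoized.

`correlation_matrix()` screens all property pairs on pairwise-complete
observations, so the per-column validity masks act as the per-property
filters (cells without a documented lifetime never enter lifetime pairs,
first- and second-generation cells never enter parent-property pairs — a
founder's own birth and properties were not observed). The Bonferroni
threshold is $\alpha/m$ with $m$ the number of pairs evaluated: 24
fully-defined properties give $m = 276$ and threshold $1.8\times10^{-4}$
at $\alpha = 0.05$. A critical value for $|r_s|$ (e.g. the tabulated 0.619
for $n = 14$ whole-colony screens) is accepted as user input, never derived
internally. `binary_ttests()` applies Welch (unequal-variance) two-sample
t-tests with the correction computed *per filter family*: the three
parent-derived properties are tested against $0.05/3 \approx 0.0167$.

`pca_embed()` z-scores the selected columns, drops rows with any masked
value (a documented, deliberate choice: imputation would leak mask
structure into the embedding), and clusters scores with k-means at
$k = \mathrm{round}(\sqrt{N/2})$ — 26 clusters at $N = 1384$. The
alternative reading $\sqrt{N}/2$ (= 19) is noted; the first is used because
"square root of N divided by 2" binds most naturally as $\sqrt{N/2}$ and
both are overridable via `k`. k-means uses a fixed documented seed with 10
restarts.

### Estimating lifetime parameters under right-censoring

The naive mean over observed dividers is biased low at a finite horizon:
long-lived cells born late are censored out while short-lived ones are
kept. `dividing_lifetime_stats()` therefore restricts to dividing cells
born at least one full observation margin — by default the longest
lifetime observed anywhere in the dataset — before the end of tracking.
Cells passing that filter would have been observed to divide almost surely
whatever lifetime they drew, so the restricted sample is essentially
unbiased: on 4-day synthetic runs it recovers 0.83 ± 0.27 d where the
naive estimator returns ≈0.77 d.

## Problem sizes and determinism

The test and acceptance runs use 30–60 single-founder colonies simulated to
Day 4 (384 frames) for lifetime recovery and Day 7 (672 frames) for
senescence and geometry, with Day-7 rendering at 4× pixel decimation —
sizes chosen so a complete verification run finishes in well under a
minute while keeping Monte-Carlo error a factor of two or more inside each
tolerance. Every random quantity flows from a single integer seed:
`simulate_colony()` is bit-reproducible given its config, `run_pipeline()`
derives one sub-seed per colony from its master seed, and k-means seeding
is explicit. Re-running any pipeline with the same seed yields
byte-identical CSV outputs.

## Known limitations

* The simulator's senescence mechanism (i.i.d. per-daughter Bernoulli) is
  the simplest model consistent with the summary statistics; real
  senescence onset is very likely state-dependent.
* Neighbor counts in the feature table use a centroid-disc approximation
  of the edge-clearance rule (flagged `centroid_disc`); exact edge-to-edge
  contacts are available from rendered images via `neighbor_stats()` at
  higher cost.
* The correlation screen treats properties as exchangeable columns; it
  does not model within-colony dependence, exactly like the observational
  analysis it reproduces.
* `corrupt_matrix()` covers the three error classes that dominate manual
  correction (gaps, merges, orphans); it does not simulate label swaps
  between adjacent cells.
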