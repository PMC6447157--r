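# colonytrack

Single-cell lineage tracking and heterogeneity analysis for
colony-forming-unit (CFU) assays imaged by time-lapse microscopy.

## What it is for

CFU assays plate bone-marrow stromal cells (BMSCs) sparsely
(~30 cells/cm²) and score the colonies that form, assuming each colony is
the clonal, homogeneous progeny of a single stem-like cell. Time-lapse
imaging at 15-minute intervals lets you test that assumption cell by cell —
and it fails often: colonies form from multiple founders, accumulate
senescent cells within days, divide asynchronously, and shrink in spread
area with each generation. `colonytrack` is the analysis toolbox for such
experiments, aimed at groups doing quantitative live-cell imaging of
stem/progenitor cultures.

The core objects and operations:

* **Object-number matrix** — the tracking exchange format: rows = frames,
  columns = unique cells, entries = per-frame segmentation labels (0 =
  absent). `validate_matrix()` surfaces every tracking error (gaps,
  merges, orphans); `build_forest()` reconstructs the lineage forest
  (parent, twin, generation, birth/division frames), attributing
  simultaneous divisions by centroid proximity.
* **Lifetimes.** A cell spanning frames *b..e* has lifetime
  (e − b + 1)·Δt; undefined for founders and non-dividers.
  `dividing_lifetime_stats()` estimates the lifetime distribution while
  correcting for right-censoring at the end of tracking.
* **Measurement.** `measure_frame()` (area, centroid, Crofton perimeter,
  axes, eccentricity, solidity, extent, form factor 4πA/P², compactness),
  `neighbor_stats()` (edge-clearance contacts, 15 px = 9.7 µm rule),
  `colony_hull_metrics()` (convex-hull area, confluency = occupied/hull,
  approximate diameter 2·√(A/π)), `mitotic_event_map()`.
* **Classification.** `classify_fate()` (senescent = alive at Day 4, no
  division by Day 7), `classify_progeny()` (slow < 8 cells at Day 4 <
  moderate ≤ 16 < fast, i.e. three vs four population doublings),
  `classify_asynchrony()` (twin lifetimes differing by more than one SD),
  `classify_origin()` (single- vs multi-cell-derived), `is_colony()`
  (≥50 cells), `isolation_score()` (staged field-of-view schedule).
* **Statistics.** `spearman_rs()` (midrank Spearman; exact permutation p
  for n ≤ 9), `correlation_matrix()` (filtered all-pairs screen with
  Bonferroni threshold α/m — e.g. 0.05/276 = 1.8×10⁻⁴), `binary_ttests()`
  (Welch tests with per-filter correction), `generation_area_trend()`,
  `generation_dispersion()`, `pca_embed()` (z-scored PCA + k-means with
  k = round(√(N/2))).
* **Simulator.** `simulate_colony()` — an agent-based generator of
  synthetic experiments (stochastic truncated-normal lifetimes
  0.83 ± 0.27 d, ~1 d founder lag, per-daughter senescence, heritable
  shrinking areas, persistent migration, media-exchange perturbations)
  with ground-truth lineages, plus `render_labels()` /
  `export_tracking_matrix()` / `corrupt_matrix()` to produce the exact
  input modalities the analysis consumes.

File formats: object matrices and feature tables as CSV, lineage forests
as JSON, label stacks as multi-page 16-bit TIFF, configs as YAML. A thin
CLI lives at `inst/scripts/colonytrack-pipeline.R`.

## Worked example

Simulate one colony to Day 7, rebuild its lineage from the exported
tracking matrix, and run the classifiers and colony metrics:

```r
library(colonytrack)

cfg <- simulation_config(n_frames = 672, rng_seed = 42)  # Day 7
exp <- simulate_colony(cfg)
m   <- export_tracking_matrix(exp)
f   <- build_forest(m)
f
#> <lineage_forest> 267 cells, 1 root(s), 133 division(s)

dividing_lifetime_stats(f)[c("mean_d", "sd_d", "n")]
#> $mean_d
#> [1] 0.8638699
#> $sd_d
#> [1] 0.3064633
#> $n
#> [1] 73

table(classify_fate(f, reference_frame = 374, horizon_frame = 672)$fate)
#> proliferative     senescent
#>            11             2

classify_progeny(progeny_counts(f, 374))
#>   founder_id n_cells_at_day4    class
#> 1          1              13 moderate

img <- render_labels(exp, 672, pixel_size_um = 4 * cfg$pixel_size_um)
colony_hull_metrics(img)
#> <colony_metrics> hull 2.19 mm^2, confluency 13.2%, diameter 1.67 mm (pixels)

generation_area_trend(build_feature_table(f, exp$tracks))
#>   founder_id        r_s      p_value n_cells degenerate
#> 1          1 -0.6864411 1.539783e-38     267      FALSE
```

Reading the numbers: this colony grew from one founder to 267 tracked
cells (133 divisions). The censoring-aware lifetime estimate over the 73
dividing cells with a full observation window is 0.86 ± 0.31 d. Of the 13
cells present at the Day-4 frame, 2 never divided by Day 7 (senescent);
with 13 cells at Day 4 the progeny is a *moderate* proliferator. At Day 7
the colony occupies 13.2% of its 2.19 mm² convex hull (circle-equivalent
diameter 1.67 mm), and spread area falls significantly with generation
(Spearman r_s = −0.68).

`run_pipeline(pipeline_config(...))` chains all of the above over many
simulated colonies and writes every artifact (matrices, forests, feature
table, correlation and trend reports) to an output directory,
byte-identically for a fixed seed.

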