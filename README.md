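# subpopdyn

Subpopulation dynamics of transcription-factor activation from imaging
flow cytometry.

## What this package is for

Transcription factor EB (TFEB) controls lysosomal biogenesis and
autophagy. mTOR phosphorylates TFEB and keeps it cytoplasmic; mTOR
inhibition (Torin1, nutrient deprivation) lets it accumulate in the
nucleus. In single-cell imaging cytometry this response is strongly
heterogeneous: at any time only a fraction of cells is activated, and
population means hide the structure. `subpopdyn` is for cell biologists
and image-cytometry analysts who want to describe such a response as a
**mixture of activity phenotypes** — Inactive, Medium, Active, ordered
by nuclear TFEB — and follow the phenotype fractions over time and
treatment.

The analysis core is:

* **Per-cell features** from multichannel images. Compartment masks
  (cell, nucleus = 70%-intensity threshold of the DNA stain, cytoplasm
  = cell ∖ nucleus) give background-subtracted intensities *I*, areas
  *A* (µm²), concentrations *I/A*, the nuclear percentage
  100·*I*<sub>nuc</sub>/*I*<sub>cell</sub>, the pixel-mean
  nuclear/cytoplasmic ratio on eroded masks (the clustering feature),
  and the radial *Max Contour Position* of the LAMP1 signal
  (0 = perinuclear, 1 = peripheral).
* **Density-normalized clustering.** Features are transformed with
  asinh(x/5); each cell's local density is the neighbor count within a
  kernel radius; cells are kept with probability min(1, TD/density) so
  rare phenotypes survive downsampling; k-means (k-means++, 10
  restarts) runs on the retained cells and every event is assigned to
  its nearest centroid.
* **Criteria-driven model selection** over feature sets and cluster
  numbers: subpopulation dynamics must be reproducible across
  replicates (mean across-replicate SD of fractions ≤ 0.10), cluster
  pairs must not co-move (Pearson r < 0.9 across concatenated
  treatment time courses), and adjacent clusters must differ in the
  ranking feature (Wilcoxon on 1000-cell subsamples, p ≤ 0.001).
* **Classification-model transfer**: the selected model is frozen and
  applied to new conditions without refitting, yielding per-condition
  phenotype fractions, region annotations (activation waves), and an
  exact decomposition of the mean response into fraction-weighted
  cluster means.

A synthetic-data module generates feature tables (and, optionally,
rendered cell images) with the documented mixture structure — baseline
45/46/9% Inactive/Medium/Active, pooled r ≈ 0.53 between ratio and
TFEB concentration, pooled r ≈ −0.25 between lysosome position and
ratio, treatment-specific weight trajectories — so the entire pipeline
runs and is tested without any instrument data.

## Worked example

```r
library(subpopdyn)

cfg    <- default_synthetic_config(profile = "fast", seed = 1)
train  <- generate_timecourse(cfg, treatments = c("FM", "Torin1"))
merged <- merge_experiments(list(train), seed = 1)
params <- cluster_params(max_pooled = 20000, target_remaining = 8000,
                         seed = 1)

search <- search_models(
  merged,
  feature_combos = list("mean_pixel_nuc_cyto",
                        c("mean_pixel_nuc_cyto", "concentration_cell")),
  k_values = c(2L, 3L, 4L), params = params)
search$candidates[, c("features", "k", "c1_pass", "c2_pass", "pass",
                      "selected")]
```

```
                                features k c1_pass c2_pass  pass selected
1                    mean_pixel_nuc_cyto 2    TRUE    TRUE  TRUE    FALSE
2 mean_pixel_nuc_cyto+concentration_cell 2    TRUE    TRUE  TRUE    FALSE
3                    mean_pixel_nuc_cyto 3    TRUE    TRUE  TRUE     TRUE
4 mean_pixel_nuc_cyto+concentration_cell 3    TRUE   FALSE FALSE    FALSE
5                    mean_pixel_nuc_cyto 4    TRUE   FALSE FALSE    FALSE
6 mean_pixel_nuc_cyto+concentration_cell 4    TRUE   FALSE FALSE    FALSE
```

The ratio-only, three-cluster model is selected: four clusters split a
real phenotype into redundant twins (criterion 2 fails), and among sound
models the fewest-features, finest-resolution candidate wins. Applying
the frozen model to all treatments:

```r
model <- search$model
full  <- generate_timecourse(cfg)
tc    <- compute_timecourse(classify_events(model, full), full,
                            labels = model$label_map)
avg <- aggregate(fraction ~ treatment + time_h + label,
                 as.data.frame(tc), mean)
round(xtabs(fraction ~ time_h + label,
            avg[avg$treatment == "Torin1", ]), 3)
```

```
      label
time_h Active Inactive Medium
   0    0.101    0.469  0.430
   0.5  0.355    0.217  0.428
   1    0.470    0.100  0.431
   1.5  0.577    0.035  0.388
   3    0.435    0.164  0.401
   5    0.220    0.334  0.446
   15   0.080    0.472  0.448
```

Under mTOR inhibition the Active fraction rises from ~10% to ~58% at
1.5 h and relaxes back to ~8% by 15 h — activation is transient and
only ever captures part of the population. The nutrient-deprivation
time course shows the two-wave pattern:

```r
annotate_regions(tc, "ND")
```

```
  region t_start t_end direction
1     R1       0     1      rise
2     R2       1     5      fall
3     R3       5    15      rise
```

`predict_mean_from_subpops()` verifies that fraction-weighted cluster
means reproduce the population mean ratio exactly (per-condition mode,
residual ≤ 1e−9), i.e. the three phenotypes fully account for the mean
response.

A thin command-line wrapper over these functions is installed at
`inst/cli/subpopdyn-cli.R` (subcommands: `simulate`, `extract`,
`cluster`, `classify`, `timecourse`, `search`, `report`, `run-all`).

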