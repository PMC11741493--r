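# synthsweep

Sensitivity analysis of MRI auto-contouring across synthetic contrast
weightings.

Quantitative MRI fits voxelwise T1, T2 and proton-density (PD) maps from a
single acquisition; from those maps, a contrast-weighted image at *any*
repetition time (TR) and echo time (TE) can be synthesized in software.
`synthsweep` uses this to answer a question radiotherapy physicists and
auto-contouring developers face when deploying a segmentation model trained
at one contrast: **how sensitive are the model's contours to the acquisition
parameters of the input image?**

The package:

* synthesizes spin-echo contrast-weighted images
  `S = g·B1·PD·(1 − e^(−TR/T1))·e^(−TE/T2)` from quantitative maps
  (inversion recovery available as an extension);
* fuses multiple rater contours into a consensus ground truth with the
  STAPLE expectation-maximization algorithm, estimating each rater's
  sensitivity/specificity along the way;
* scores any plug-in segmenter with the Dice similarity coefficient (DSC)
  and the 95th-percentile Hausdorff distance (HD95, in mm, spacing-aware)
  at every point of a TR×TE grid — by default 18 TR × 16 TE values
  partitioned into T1-/T2-/PD-weighted contrast regions (216 evaluated
  points, 72 per region; the mixed region is excluded);
* aggregates per structure × region (mean/median/min/max) and reports the
  fraction of grid points at which the segmenter performs at least as well
  as human interobserver variability (IOV), using per-structure DSC and
  HD95 cutoffs;
* ships a digital head-and-neck phantom (bilateral parotid-like and
  submandibular-like structures, map noise, simulated raters, optional B1
  bias field) plus a calibrated reference segmenter, so the entire pipeline
  runs with no external data.

Volumes are read and written as NIfTI-1 (via RNifti), results as tidy CSV;
a YAML config drives full runs.

## Worked example

The `run_demo()` pipeline builds the phantom, simulates three raters per
structure, fuses them with STAPLE, calibrates the reference segmenter at
the anchor acquisition (TR = 1535 ms, TE = 212 ms), sweeps all 216 grid
points, and aggregates:

```r
library(synthsweep)
out <- run_demo(seed = 1, output_dir = "results")

out$staple_results$parotid_l
#> <staple_result> 3 raters, 7 iterations (converged)
#>   sensitivity: 0.9798 1.0000 0.9039
#>   specificity: 0.9997 0.9577 1.0000

subset(out$summary, structure == "parotid_l",
       select = c(region, n, dsc_mean, dsc_min, dsc_max,
                  hd95_mean, n_hd95_undefined))
#>   region  n dsc_mean dsc_min dsc_max hd95_mean n_hd95_undefined
#>      PDW 72    0.191   0.000   0.830     11.15                5
#>      T1W 72    0.830   0.830   0.830      4.00                0
#>      T2W 72    0.293   0.132   0.875      6.48                0

subset(out$exceedance, region == "ALL")
#>          structure region   n dsc_exceedance hd95_exceedance
#>          parotid_l    ALL 216          0.380           0.449
#>          parotid_r    ALL 216          0.157           0.139
#>    submandibular_l    ALL 216          0.245           0.269
#>    submandibular_r    ALL 216          0.000           0.176
```

Reading the left-parotid summary: STAPLE estimated the three simulated
raters' per-voxel sensitivity (0.98/1.00/0.90) and specificity against the
hidden truth it inferred. Across the sweep, the PD-weighted region is worst
(mean DSC 0.19 with 5 of 72 grid points failing outright — HD95 undefined
because the prediction was empty or disjoint), which is expected: the
phantom's glands and muscle background have nearly equal proton density, so
PD-weighted images carry almost no contrast for an intensity-based
segmenter to use. The best single points sit near the anchor contrast the
segmenter was calibrated on (DSC up to 0.88 in the T2-weighted region), and
performance decays with distance from it — the acquisition-parameter
sensitivity the sweep is designed to expose. The exceedance table gives the
fraction of all 216 points at which the segmenter was at least as good as
human IOV (DSC ≥ cutoff; HD95 ≤ cutoff).

`results/` additionally contains the per-point records
(`sweep_records.csv`, one row per structure × grid point with TR/TE deltas
from the anchor), region summaries, the exceedance table, rater
performance, DSC/HD95 heatmaps and a provenance record.

The pieces compose individually — e.g. scoring one mask pair:

```r
dice(a, b)                       # 0..1
hd95(a, b, spacing = c(0.5, 0.5, 5))  # mm
```

or sweeping your own segmenter: any function
`(image, spacing) -> integer label volume` can be passed to `run_sweep()`
(validate it first with `check_segmenter()`).

A thin command-line wrapper with `demo`, `phantom`, `staple`, `metrics` and
`sweep` subcommands is installed at `inst/cli/synthsweep`.

See `vignettes/methods.Rmd` for the model, conventions (HD95 percentile
pooling, STAPLE crop rule, degenerate-case definitions) and the phantom's
design and limitations.

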