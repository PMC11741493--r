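---
title: "Contrast-sweep sensitivity analysis for MRI auto-contouring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast-sweep sensitivity analysis for MRI auto-contouring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthsweep)
```

## The problem

Deep-learning auto-contouring models for radiotherapy are trained on images
with one particular contrast weighting — a fixed repetition time (TR) and
echo time (TE). Quantitative MRI changes the economics of testing that
dependence: once voxelwise T1, T2 and proton-density (PD) maps have been
fitted from a single acquisition, a contrast-weighted image at *any* TR/TE
can be synthesized in software, so a segmenter can be evaluated across
hundreds of acquisition-parameter combinations without rescanning the
patient. `synthsweep` implements that sensitivity analysis end to end:
contrast synthesis, consensus ground truth from multiple raters, agreement
metrics in physical units, and per-region aggregation against
interobserver-variability (IOV) thresholds.

## Signal model

The synthesizer uses the saturation-recovery spin-echo model,

$$S(\mathbf{x}) = g \, B_1(\mathbf{x}) \, PD(\mathbf{x})
  \left(1 - e^{-TR/T_1(\mathbf{x})}\right) e^{-TE/T_2(\mathbf{x})},$$

with gain $g$ and an optional multiplicative transmit-field volume $B_1$.
Commercial synthetic-MR engines use proprietary variants of this equation
(possible slice-profile and echo-train corrections are not public), so the
model here should be read as the canonical approximation that preserves the
TR/TE contrast behaviour the sweep probes — which is the quantity under
study — rather than as a replica of any vendor pipeline. Assumptions worth
stating explicitly:

* **Background** is marked by $PD = 0$ or $T_1 = 0$ and synthesizes to
  exactly 0 at every TR/TE.
* **$B_1$ is purely multiplicative.** Real transmit inhomogeneity perturbs
  the flip angle and hence enters the signal nonlinearly; the multiplicative
  model is sufficient to reproduce the lateral-asymmetry failure mode that
  inconsistent head-and-neck coil placement produces, which is what the
  phantom needs it for.
* **$T_2 > T_1$ voxels are warned about, not rejected** — noisy fitted maps
  can violate physical plausibility and should not crash an analysis.
* Inversion recovery ($S \propto |1 - 2e^{-TI/T_1} + e^{-TR/T_1}|\,
  e^{-TE/T_2}$) is provided as an extension; the sweep itself only uses
  spin-echo synthesis.

Output images are floating point. A 12-bit quantization step is available
for realism but off by default, because segmenter preprocessing re-normalizes
intensities anyway.

## Sweep grid and contrast regions

The default grid is TR $\in \{100, 200, \dots, 1000, 1500, \dots, 5000\}$ ms
(18 values) by TE $\in \{5, 10, \dots, 40, 60, 80, \dots, 200\}$ ms
(16 values), partitioned by

| Region | TR | TE |
|--------|-----|-----|
| T1-weighted | < 1000 ms | ≤ 40 ms |
| T2-weighted | ≥ 1000 ms | > 40 ms |
| PD-weighted | ≥ 1000 ms | ≤ 40 ms |
| mixed | < 1000 ms | > 40 ms |

The mixed region has limited clinical use and is excluded by default,
leaving 216 evaluated grid points, 72 per used region. Deltas are reported
relative to an anchor acquisition — the grid's stand-in for the segmentation
model's training contrast — defaulting to TR = 1535 ms, TE = 212 ms.
Enumeration places no TE < TR constraint (the excluded mixed region may
contain infeasible combinations such as TR = 100/TE = 200); any point that
would actually be synthesized is checked against TE < TR and rejected by
name.

## Consensus ground truth: STAPLE

Ground truth is fused from $R$ rater masks by simultaneous truth and
performance level estimation. With rater votes $D_{ij}$, prior $\pi$,
sensitivity $p_j$ and specificity $q_j$, the E-step computes the voxelwise
posterior

$$W_i = \frac{a_i}{a_i + b_i}, \qquad
  a_i = \pi \prod_j p_j^{D_{ij}}(1-p_j)^{1-D_{ij}}, \qquad
  b_i = (1-\pi) \prod_j (1-q_j)^{D_{ij}} q_j^{1-D_{ij}},$$

and the M-step re-estimates
$p_j = \sum_{i:D_{ij}=1} W_i / \sum_i W_i$ and
$q_j = \sum_{i:D_{ij}=0} (1-W_i) / \sum_i (1-W_i)$.

Numerical and convention choices:

* **Prior**: scalar, defaulting to the mean rater foreground fraction;
  overridable per voxel.
* **Initialization** $p_j = q_j = 0.99999$, avoiding the degenerate 0.5
  saddle.
* **Convergence**: absolute change of $\overline{p} + \overline{q}$ below
  `tol` (default 1e-7), `max_iter` 100. The E-step runs in log space.
* **Crop rule**: computation is restricted to the bounding box of the union
  of rater masks dilated by 5 voxels; outside voxels are background with
  $W = 0$. The specificity estimate depends directly on how much background
  enters the computation, so fixing this rule is what makes results
  reproducible across mask paddings.
* **Threshold** 0.5; a posterior exactly at the threshold counts as
  foreground.

On simulated raters with known performance (10,000-voxel domain, three
raters, sensitivities 0.95/0.90/0.85, specificities 0.99/0.98/0.97) the
estimates recover the generating values to about $\pm 0.004$ averaged over
20 draws — well inside the ±0.05 band the test suite asserts.

One property worth knowing: with an even prior and *fixed equal* $p = q$
across raters, the posterior is an unweighted vote and thresholding gives
exactly the voxelwise majority. After EM convergence the per-rater weights
differ, so the consensus is a *weighted* majority and may legitimately
disagree with the plain vote — that re-weighting is the point of STAPLE.

## Agreement metrics

**DSC** is $2|A \cap B| / (|A| + |B|)$, with two documented degenerate
conventions: both masks empty gives 1.0, exactly one empty gives 0.0.

**HD95** is computed on surface voxels — mask voxels with at least one
face-adjacent (6-connectivity) background neighbour — using Euclidean
distances between voxel centers scaled by the physical spacing. Both
directed nearest-neighbour distance multisets are pooled and the 95th
percentile taken with linear interpolation between order statistics. The
pooled convention is symmetric by construction and is the default in
contouring-QA practice; the max-of-directed-percentiles variant is available
behind `directed_max = TRUE`. No sub-voxel mesh is extracted: voxel-center
distances are reproducible and checkable against an exhaustive all-pairs
oracle, which the test suite does to 1e-9 mm.

An empty mask makes HD95 undefined. That raises a typed condition which the
sweep layer converts to a failure sentinel (DSC 0, HD95 undefined) rather
than aborting — a sweep must tolerate total segmentation failures, which
genuinely occur at unfavourable contrasts. Undefined values are excluded
from HD95 statistics and counted separately.

## IOV thresholding

Per-structure cutoffs mark the level of human interobserver agreement:
DSC 0.83 / 0.84 / 0.75 / 0.78 and HD95 4.9 / 5.1 / 3.1 / 3.1 mm for left
parotid / right parotid / left submandibular / right submandibular.
"Exceeding IOV" is implemented as *performing at least as well as* a human:
DSC at or above the cutoff, HD95 defined and at or below the cutoff (both
inclusive). Fractions are reported per structure overall and within each
contrast region.

## The digital phantom

The phantom makes the pipeline runnable and testable with no patient data:
a head ellipsoid of muscle-like tissue with a fat-like rim, containing
bilateral parotid-like and submandibular-like ellipsoids, mirror-symmetric
about the mid-sagittal plane. Tissue parameters are literature-plausible
3T values (parotid T1 ≈ 1100/T2 ≈ 120 ms, submandibular 1300/100 ms,
muscle 1400/40 ms, fat 400/130 ms) — phantom defaults, not measurements.
Proton density is deliberately nearly equal across glands and muscle
(82/81 vs 80 a.u.), a deliberate design choice: it makes PD-weighted
contrast collapse, so the phantom exhibits the clinically observed failure
mode (worst performance in the PD-weighted region) through a physical
mechanism rather than a tuned constant.

Gaussian noise (s.d. 30/5/2 map units on T1/T2/PD) is added inside the head
only; labels are never noisy. Simulated raters perturb the true boundary by
a signed distance offset drawn from N(0, 2 mm) plus a smooth Gaussian jitter
field (s.d. half the offset scale), then keep the largest connected
component. The 2 mm default is a realistic glandular contouring
disagreement relative to the ~5 mm IOV HD95 cutoffs; note that offsets well
below the voxel spacing cannot flip any voxel, so sub-voxel perturbations
reproduce the truth exactly. The signed distance is defined symmetrically
(inside voxels: −distance to nearest background center; outside: +distance
to nearest foreground center) so a zero offset reproduces the mask exactly.

The default realization is a 64 × 64 × 16 grid at 2 × 2 × 5 mm spacing
(128 × 128 × 80 mm field of view): structures have realistic millimetre
sizes and a full 216-point sweep over four structures completes in well
under a minute on one CPU, which keeps multi-seed analyses cheap. The
slice spacing of 5 mm is a center-to-center distance (4 mm slices with a
1 mm gap) — the quantity surface metrics need. A finer
240 × 240 × 16 / 0.5 × 0.5 × 5 mm geometry is the `phantom_spec()`
signature default for users who want in-plane resolution at acquisition
scale.

What the phantom does **not** emulate: anatomical shape detail, partial
volume at tissue interfaces, spatially correlated map-fitting error,
motion, and any pathology. Passing tests on the phantom therefore
demonstrate correctness of the *method* — synthesis, fusion, metrics,
aggregation — not clinical performance of any segmenter.

## The reference segmenter

The plug-in contract is a function `(image, spacing) -> integer label
volume`, checked at registration on a smoke volume (shape preservation,
declared labels only, determinism). The packaged reference segmenter is
deliberately simple: preprocess the image (clip to the 0.25/99.75
percentiles, z-score with population s.d., linear map of the post-clip
range onto [−1, 1] — scaling bounds computed after clipping), then keep
voxels inside a per-structure intensity window ([P5, P95] of the
structure's preprocessed intensities at the anchor acquisition),
intersect with an ellipsoidal spatial prior (true-mask centroid, extents
inflated 20%), and take the largest connected component.

Because the windows are calibrated on the anchor image's normalized
intensities, the segmenter depends on absolute contrast and degrades away
from the anchor — by design. It is a test harness that makes the sweep
exhibit acquisition-parameter sensitivity, not a model of any clinical
network; its absolute DSC values carry no clinical meaning.

## Problem sizes and runtime choices

The packaged analyses use: the 64 × 64 × 16 phantom; 216-point sweeps over
4 structures (864 records per run); STAPLE recovery at 10,000 voxels
averaged over 20 draws; metric-oracle checks on 30 random mask pairs across
three shapes. A full phantom pipeline (phantom → 3 raters × 4 structures →
STAPLE → calibration → sweep → aggregation) runs in roughly 20 seconds on a
single core, so the five-seed sensitivity analysis in the test suite
completes in about two minutes.

## Reproducibility

All randomness flows from one global seed through named substreams
(phantom, per-structure raters, B1), so every stage is independently
reproducible and `run_demo()` writes a provenance record (config echo,
seed, package version) sufficient to regenerate its outputs byte for byte.
CSV is the canonical output format; heatmaps are derived artifacts.

## Known limitations

* The synthesis equation is the canonical model, not a vendor replica;
  absolute intensities will differ from commercial synthetic images even at
  matched TR/TE.
* HD95 is voxel-center based; against mesh-based implementations expect
  differences up to about half a voxel diagonal.
* STAPLE results depend on the documented crop rule and prior; other
  implementations may differ near the boundary by a voxel layer.
* The exceedance denominators are the 216 evaluated grid points; analyses
  that include the mixed region will scale them accordingly.
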