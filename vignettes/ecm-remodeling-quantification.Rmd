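---
title: "Quantifying tumor-cell-induced ECM remodeling in 3D image stacks"
author: "ecmscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-cell-induced ECM remodeling in 3D image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmscore)
```

## The measurement problem

Ovarian tumor cells cultured inside a fluorescently pre-labeled,
fibroblast-derived 3D extracellular matrix (ECM) remodel that matrix in two
opposite ways: *degraders* proteolytically remove labeled matrix beneath and
around their clusters, while *accumulators/contractors* pull matrix fibers
toward the cluster and pile new material on top of it. Both phenotypes are
visible in confocal z-stacks of the cultures (nuclei, immunostained
fibronectin, and a bulk "total matrix protein" (TMP) label recorded as
separate channels, planes every 0.5 µm).

`ecmscore` turns those stacks into numbers:

1. **Layer partition.** The stack is split into *top*, *middle* and *bottom*
   layers from the per-plane fibronectin coverage curve: the top starts at
   the first plane (scanning downward from the free surface) on which at
   least 20% of the field is stain-positive, plus one plane below; the
   bottom is the first plane on which staining covers the entire field, plus
   one plane above; the middle is the one (odd span) or two (even span)
   halfway planes.
2. **Regions.** The nuclei channel's full-stack maximum projection is
   segmented into a *cell-containing* region (cell clumps, enclosed by the
   convex hull of each clump plus a margin — an automated stand-in for
   manual tracing, which remains available via polygon input) and an
   adjacent *cell-devoid* region, separated by a buffer ring.
3. **Score.** For every layer and matrix channel, the maximum-intensity
   projection over the layer's planes is binned at 90 on the 0–225
   pseudo-color scale, and the score is
   \[
   S \;=\; 100 \times
   \frac{A_{\ge 90}^{cell} / A_{<90}^{cell}}
        {A_{\ge 90}^{devoid} / A_{<90}^{devoid}},
   \]
   the high/low intensity *area ratio* in the cell region as a percentage of
   the same ratio in the devoid region. \(S = 100\) means the cells changed
   nothing; \(S < 100\) indicates degradation, \(S > 100\) accumulation.
4. **Classification and statistics.** The top layer — where both phenotypes
   express most strongly — decides the phenotype call, with a calibrated
   neutral band around 100. Inhibitor conditions are compared against
   untreated controls by one-way ANOVA on log-transformed scores, with
   Benjamini–Hochberg control of the false discovery rate at 0.05 and a
   significance flag at p ≤ 0.01.

## Thresholds and units

All intensity thresholds live on a closed 0–225 pseudo-color scale;
`rescale_to_225()` maps raw data onto it by an order-preserving affine
transform. The *fixed-range* mode (one `(lo, hi)` shared by every stack of
an experiment, conventionally the untreated day-0 control's range) is the
default because the score is only comparable across conditions when all
stacks share a scale; per-stack global min–max is available for isolated
stacks. A constant-intensity channel rescales to 0, not 225 — the
conservative choice that cannot fabricate high-intensity area.

Two different cutoffs play different roles:

* the **high-intensity bin** is `[90, 225]`, closed at 90 (a pixel at
  exactly 90 is high);
* the **stain-positive (detection) threshold** used for the coverage curve
  and layer partition defaults to **30**.

Keeping the detection threshold below the scoring bin is deliberate. The
bottom layer is *defined* as the depth at which staining covers ≥ 99.5% of
the field; if "stain-positive" meant "≥ 90", a rule-satisfying bottom plane
would by construction contain almost no low-bin pixels, both area ratios
would be dominated by the ±0.5 smoothing guard, and the bottom-layer score
would collapse to the ratio of region sizes. A detection threshold of 30
records where matrix is *present*, while the 90/225 bin records where it is
*bright*, and the bottom layer keeps a genuine low-intensity area. An
Otsu-derived detection threshold can be substituted via the
`positive_threshold` arguments.

Other numerical conventions:

* *Full coverage* is operationalized as ≥ 0.995 (`full_coverage`), since
  real, noisy fields never reach exactly 1.0.
* If no plane reaches full coverage — expected for heavily degraded
  matrices, the very phenotype of interest — the deepest plane achieving
  the maximum coverage serves as the bottom, flagged `bottom_fallback`,
  rather than aborting.
* In thin stacks the top/middle/bottom plane sets may overlap; they are
  reported as-is, never silently merged.
* The ±0.5 smoothing guard on the bin counts is off by default and
  auto-enabled (with a flag in the output) only when a bin is empty; the
  division-by-zero case is otherwise an error.
* Region masks: the buffer ring between the cell and devoid regions
  defaults to 10 µm so halo signal at clump borders does not contaminate
  the control region. Cell and devoid regions are not area-matched; the
  area-ratio statistic is size-invariant (a property the tests verify by
  pixel-replication upsampling).

## The phenotype call

`classify_phenotype()` uses the mean top-layer score: below \(100-\delta\)
is a degrader, above \(100+\delta\) an accumulator, otherwise neutral. The
neutral margin δ is not a biological constant — the original comparison was
made by eye — so it is calibrated: δ = 3 × the between-field standard
deviation of the top-layer statistic under the null (no-remodeling)
simulation at default parameters, which gives the package default δ = 45
(null SD ≈ 15 over a 24-seed calibration run). Any δ up to ~70 separates
the two reference phenotypes' reported top-layer fibronectin anchors (28
vs. 244); the calibrated value is far inside that.

## The synthetic study conditions

No real image data accompany the method, so the package ships a generator,
`simulate_matrix_stack()`, whose *defaults are the study conditions* used
throughout the tests:

* **Geometry** — 256 × 256 px fields at 0.5 µm/px (a 128 µm field), 12
  planes at 0.5 µm; desk-scale while leaving several planes per layer.
* **Matrix texture** — random line-segment fibers with Gaussian
  cross-section (σ 0.9–1.4 px), peak intensity N(150, 15), lengths 6–15% of
  the field side, placed uniformly over a border-padded domain so the
  texture is stationary across the field (no dim border band that would
  bias the devoid region). Fibers are added until each plane reaches its
  target stain-positive coverage. Fine fibers were chosen over long,
  thick ones so that the cell region contains many independent texture
  units; this keeps the between-field variance of the null score small
  (SD ≈ 10–17 per layer/channel) without changing its meaning.
* **Depth profile** — per-plane coverage tapers from 2% at the topmost
  plane through a 20% crossing about a third of the way down to full-field
  coverage at the bottom; planes at ≥ 99% coverage are rendered as a dense
  "carpet" N(110, 25), so the bottom layer keeps both high- and low-bin
  area. The two matrix channels share fiber geometry (biologically the TMP
  label includes fibronectin); TMP is 5% brighter.
* **Cells** — 4 clusters of radius 36 px (18 µm), each with 12 elliptical
  nuclei (σ 6 × 4 px) rendered on a mid-depth reference plane band. The
  union of cluster disks is the ground-truth cell footprint.
* **Remodeling** — applied inside the footprint with a depth weight that is
  1 at the matrix surface plane (the 20% coverage crossing) and decays as
  the fourth power of relative depth to 0.01 at the bottom: remodeling
  concentrates where cells meet the free matrix surface and barely reaches
  the dense bottom, which is what produces the observed "largest change in
  the top layer" signature. Degraders multiply intensities by
  `effect_size` (default 0.3) at the surface; accumulators by
  `effect_size` (default 3), additionally depositing 25% of the moved
  signal as *new, additive* matrix over the footprint on the two surface
  planes (apical build-up on top of the cells) and withdrawing half of the
  moved signal (`conservation_fraction = 0.5`) proportionally from a 15 µm
  annulus around the footprint — contraction moves matrix rather than
  creating it, but compaction along z means lateral withdrawal need not
  balance exactly; with `conservation_fraction = 1` the channel total is
  preserved to machine precision, a property the tests pin down.
* **Noise** — additive Gaussian (σ = 4), truncated at 0, drawn fresh per
  timepoint.
* **Time courses** — the same seed-fixed field imaged at days 0/7/10 with
  effect scaling 0/0.6/1.0 (non-decreasing by contract), day 0 always
  unremodeled.

Everything is deterministic given `seed`.

### What the generator does and does not emulate

It reproduces the *features the score consumes*: a fiber-textured matrix
with a depth-coverage profile, nuclei-marked cell footprints, and the two
remodeling transforms with realistic spatial structure (surface
concentration, annular pulling, apical deposition). It does **not** model
optics (PSF, attenuation with depth, bleed-through), fibrillogenesis or
fiber mechanics, cell motility or division, or 3D nuclei placement across
planes. Passing tests therefore demonstrate that the *pipeline measures
what it claims to measure* on data with known ground truth — not that any
particular biological effect size will be recovered from real microscopes,
and the generator's effect sizes (0.3 / 3) are calibration choices
validated by direction and separability, not by matching any reported
percentage.

## Statistics

Scores are log-transformed before ANOVA because between-group variances of
percent scores are strongly unequal; the natural log is used (the base does
not affect F or p). The one-way F is the classical equal-variance statistic
(`oneway.test(var.equal = TRUE)`); a Welch option exists behind a flag but
is off by default. Each inhibitor condition is compared against the
untreated control per layer, and the Benjamini–Hochberg step-up adjustment
is applied across the whole family of condition × layer comparisons of the
experiment — the family definition is configurable (`family = "layer"`
adjusts per layer) because the original control of "multiple comparisons"
does not pin the family down. Flags: `significant` at raw p ≤ 0.01,
`fdr_pass` at adjusted p ≤ 0.05. No post-hoc pairwise tests among
inhibitors are performed; comparisons are only against the control.

## Problem sizes used by the validation suite

The test suite and `scripts/acceptance.R` run entirely on simulated fields:
null calibration over 20 default-scale fields; phenotype separation over
12–20 fields per phenotype; dose–response sweeps over 4 factor levels × 3–4
seeds; brute-force oracle equivalence on 100 random 64 × 64 (× 8)
instances; Monte-Carlo calibration of the p ≤ 0.01 rule over 1000 null
replicates and power over 200 replicates at a 3-SD shift with n = 8. Unit
tests use a reduced 96 × 96 × 8 fixture of the same generator. These sizes
were chosen so the whole suite completes in minutes on a single core while
keeping every estimate's Monte-Carlo error well inside the asserted bands.

## Known limitations

* The layer rules assume a monotone-enough coverage curve; stacks whose
  coverage never reaches 20% are rejected as "no matrix".
* The automated segmentation expects clustered nuclei; sparse single-cell
  fields produce small blobs that may fall below `min_blob_area` (the
  manual-polygon path covers such fields).
* Scores are computed on 2D per-layer projections, as the method defines
  them; no voxel-wise 3D region growing or per-cell invasion depth is
  attempted.
* Only TIFF input is supported; proprietary microscope formats must be
  exported first.
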