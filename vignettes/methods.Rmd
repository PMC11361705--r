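---
title: "Models and methods behind proxiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind proxiquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`proxiquant` quantifies a contrast between two ways of imaging the same
tagged protein: fluorophore-conjugated streptavidin binding the biotin
marks left by a TurboID fusion, versus an anti-tag antibody. Streptavidin
(~60 kDa) penetrates dense, phase-separated compartments; IgG (~150 kDa,
plus a secondary) often cannot. This vignette explains the models, the
defaults, and what the synthetic data can and cannot show.

## The synthetic scene model

Images are generated, not downloaded, so every stage has ground truth.

A scene is a 3D voxel grid — by default 48 z-slices spaced 140 nm, 256×256
pixels of 65 nm (a 6.5 µm camera pixel behind a 100× objective) — holding
two kinds of emitters:

* **Granules**: spheres with either uniform interior label density
  (*volume* mode, the streptavidin-like stain) or density confined to a
  peripheral shell `[r(1−f), r]` (*shell* mode, the antibody-like stain;
  `f` is the `shell_fraction`, and `f = 1` is exactly volume mode).
  Rasterization samples 3×3×3 sub-voxel points per voxel so that partial
  volumes at the sphere edge are graded, not binary; the diameter analyses
  need that sub-pixel fidelity.
* **Pore punctae**: point emitters placed evenly on the mid-plane rim
  circle of a nucleus, deposited by trilinear interpolation, with
  per-channel amplitude scaling (the ground-truth accessibility of the
  tagged protein).

The optical model is a separable anisotropic Gaussian PSF (defaults
σ\_xy = 90 nm, σ\_z = 300 nm — typical widefield values for a 1.4-NA
objective at green emission). A full vectorial PSF would change profile
tails, not the half-maximum geometry these analyses consume. Noise follows
the standard camera model, applied after blurring: Poisson shot noise on
the expected photon count, then additive Gaussian read noise, clamped at
zero. Each channel draws from its own stream derived from the scene seed
and the channel's *position*, so renaming channels permutes the stack and
changes nothing else, and re-rendering a scene is bit-identical.

`simulate_granule_experiment()` renders per-cell crops (32 z × 96 × 96 px)
rather than full frames: the analysis is local to one granule, and
full-frame rendering only adds runtime. Its defaults define the simulated
study: 3 replicates × 25 cells; granule radius log-normal around 600 nm
(CV 0.15) — the "larger granules" a starved cell shows, and large enough
that the shell's two rim peaks survive PSF blurring; shell fraction 0.25;
amplitudes chosen so shot noise is visible but not dominant; replicate-level
amplitude jitter (10%) emulating staining batches. No value in the paper
constrains granule size or staining amplitude, so these are realism
choices, fixed once, and exposed as arguments.

What the generator does **not** emulate: granule ellipticity and clustering,
cytoplasmic autofluorescence texture, chromatic registration error, depth-
dependent PSF aberration, and the partial antibody penetration real
granules may allow. Passing tests therefore demonstrate that the
*quantification* is correct and unbiased on data matching its assumptions —
not that real granules have quotient 1.2.

## Diameter at 50% fluorescence

A sum-slices projection preserves total intensity, and for a uniform ball
of radius `r` the projected line profile through the center is proportional
to `√(r² − x²)`; its width at half maximum is `√3·r`. This closed form is
the anchor for the whole sizing pipeline: rendered, projected and profiled
spheres must reproduce it as sampling becomes dense (tests check radii
325–975 nm within 1% on a 4× finer lateral grid; at the native 65 nm pixel
pitch, linear interpolation across a steep, curved profile biases the
crossing inward by up to ~2%, which is why the pipeline is also checked
against a 10×-supersampled numerical oracle with a half-pixel tolerance).

Conventions, each a deliberate choice:

* **Baseline**: mean of the lowest decile of profile samples; the 50% level
  is halfway between baseline and global maximum. This makes the measure
  robust to diffuse cytoplasmic background and reduces to plain
  half-maximum when the baseline is ~0. `baseline = "zero"` gives the
  plain convention.
* **Outermost crossings**: the diameter spans the first upward and last
  downward crossing of the level, each linearly interpolated. A
  double-peaked (peripherally stained) profile thus returns its *outer*
  width — which is what "wider" means for a shell stain.
* **Segment placement**: granules are detected on the streptavidin channel
  (Otsu threshold, connected components, intensity-weighted centroids,
  ordered by integrated intensity — taking the first emulates choosing
  "one of the larger granules"), and one segment (default angle 0°,
  3-pixel averaging width) is reused for *both* channels, as one would
  draw a single line in ImageJ. Keeping the detection channel fixed while
  exchanging the stain roles makes the swapped quotients exact
  reciprocals, mirroring a fluorophore-swap control.
* **Quotients are averaged per granule** (not formed from mean diameters),
  and summaries are emitted both pooled across granules and across
  replicate means, since either convention is defensible for a
  "mean ± SD" statement.

Peak counting uses topographic prominence after a 3-sample moving average,
with threshold 0.3 of the baseline-to-max range. Smoothing is skipped for
profiles shorter than three windows, where it would erase genuine
structure; among equal-height summits the leftmost absorbs the shared
prominence, so a shallow dip is one peak, a deep one two.

## Maximum-signal statistics

Brightness comparisons take each cell's maximum (sum-projection, within an
optional mask), then fold change = ratio of group means and an unpaired
two-tailed Student's t-test (equal variance; Welch behind a flag — the
equal-variance flavour is the named default because that is the test the
workflow standardly reports). The simulated analogue scales a cell's whole
stain — punctae *and* background — by the true factor, as a staining-
efficiency difference would, so the per-cell maxima scale by that factor up
to shot noise.

## Accessibility score

The score divides background-subtracted antibody signal by
background-subtracted streptavidin signal inside the streptavidin-defined
mask: medians throughout (robust to hot pixels and puncta variability), a
2-px erosion between mask and background (threshold-edge pixels inform
neither region), an `ε = 1e−6` denominator guard, and aggregation by median
over at least 10 cells. The construction makes the score invariant to
global intensity rescaling and monotone in true antibody amplitude; both
are tested against ground truth. Increment edges (default 0, 0.1, 0.5, 1.0,
half-open upward) are presentation configuration, not biology.

## LFQ enrichment

The proteomics chain mirrors the standard label-free proximity-labelling
workflow: keep protein groups with ≥1 valid value in the bait group; log2;
impute each sample column's missing cells from
`N(μ − 1.8σ, (0.3σ)²)` of that column's observed values (the usual
constants for this imputation; per-column because the detection limit is a
property of the run); equal-variance Student's t-test against the untagged
control triplicate; report the *t-test difference* (mean bait − mean
control, log2). Duplicate bait groups run on df = 3. No multiple-testing
correction gates the increments — the map colours effect sizes, not
FDR-thresholded hits — but a Benjamini–Hochberg column is emitted.
Imputation streams are seeded per column name, so results are independent
of column order and byte-reproducible.

The LFQ simulator draws per-protein base log2 intensities N(25, 2), within-
group replicate noise SD 0.4, and drops cells with logistic probability
decreasing in intensity (midpoint 22, slope 1 — about 10–15% missing
overall, concentrated in the low tail, emulating a detection limit).
Recovery tests require stratum-mean bias < 0.3 log2 units for true effects
0, 2 and 5, and nominal type-I error under the global null. The component
map ships with a trypanosome nuclear-pore parts list; entries whose gene
IDs are not published are keyed by protein name (the file is labelled
synthetic for that reason).

## Numerical and degenerate-input choices

* Gaussian blur kernels truncate at 4σ and renormalize; flux conservation
  is tested to 0.5% for interior emitters.
* A level never crossed on both sides of the maximum yields a QC flag
  (`"unbounded"`), never a diameter; flagged channels make the quotient
  undefined rather than silently dropping out.
* Zero pooled variance in a t-test: p = 1 when the difference is 0
  (indistinguishable groups), flagged `"degenerate variance"` otherwise.
* Flat reference channels, empty masks, and all-background images raise
  errors or flags — degenerate inputs never produce scores.
* Scores/differences exactly on a bin edge go to the upper half-open
  interval.

## Problem sizes

Tests and the acceptance script run desk-scale versions of the study
designs: 3×25 granule cells (the design's own size), 60+60 cells for the
fold-change comparison (the design's own size), 600–2000 simulated protein
groups, 10,000 imputation draws, and 4×4 radius-by-PSF grids for the oracle
comparison. These sizes make all Monte-Carlo tolerances comfortable while
keeping a full run in minutes on one CPU.

## Known limitations

* Diameters are 2D (projected); no volumetric fitting, deconvolution, or
  drift correction.
* The granule detector is a surrogate for manual selection; heavily
  overlapping granules will merge into one component.
* The accessibility score compares *relative* amplitudes; absolute epitope
  densities are not identifiable from two-channel ratios.
* The Gaussian PSF and spherical emitters are idealizations; quantitative
  claims about real images should rest on the method's behaviour near the
  tested regime, not outside it.
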