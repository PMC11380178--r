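---
title: "Quantifying myogenic differentiation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myogenic differentiation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoquant)
```

## The assay and its indices

Differentiating myoblast cultures are stained for DNA (DAPI) and sarcomeric
myosin heavy chain (the MF20 antibody), and the progress of myogenesis is
read out by counting nuclei inside and outside MF20-positive cells. With
$N$ the total nucleus count and $n_k$ the number of nuclei in MF20⁺ object
$k$:

$$\mathrm{MDI} = \frac{\sum_k n_k}{N}, \qquad
  \mathrm{MFI} = \frac{\sum_{k : n_k \ge m} n_k}{N},$$

with $m$ = `mfi_min_nuclei` (default 2). MDI measures commitment to
differentiation (expression of myosin heavy chain regardless of fusion);
MFI measures fusion into multinucleated syncytia. Neither index has a
universally fixed denominator in the literature; this package uses all
nuclei in both, which bounds $0 \le \mathrm{MFI} \le \mathrm{MDI} \le 1$
and makes the two indices directly comparable. Because conventions differ,
the per-myotube nucleus-count histogram (with the mononucleated bin
reported as a reference) is always emitted alongside the scalars, so any
alternative convention can be recomputed from the saved tables.

## The segmentation chains

Both channels are first smoothed with a Gaussian of $\sigma$ =
`blur_sigma_px` (default 1 px) and binarized by Otsu's method. The nuclear
mask then goes through a distance-transform watershed to separate touching
nuclei, and a size filter. The myotube mask goes through the classical
consolidation chain — despeckle (3×3 median), 4× dilate, close, fill
holes, 3× erode — then watershed and a minimum-area filter. The dilation /
erosion counts are deliberately asymmetric (net one-pass growth): the
chain's purpose is to consolidate ragged, partially stained myotube
interiors into solid regions of interest, and the extra pass guarantees
each ROI covers its generating structure (asserted ≥ 99% on noise-free
synthetic capsules). No boundary-restoring correction is applied.

Operator semantics are pinned exactly and oracle-tested:

* **Otsu**: 256 equal-width bins over the observed range; the threshold
  maximizes between-class variance, ties broken toward the smallest cut;
  foreground is *strictly above* the threshold. A constant image yields an
  empty mask with a degenerate flag rather than an error.
* **Morphology**: 3×3 square structuring element, one pass per iteration.
  Pixels beyond the raster count as background for dilation and foreground
  for erosion, which makes erosion the exact dual of dilation on a
  1-px-padded domain.
* **Hole filling**: background components not 4-connected to the border
  become foreground (8-connectivity for foreground, 4 for background — the
  standard complementary pair).
* **Particle analysis**: connected components under 4- or 8-connectivity,
  size-filtered, relabeled contiguously in raster order.

### Watershed details

The splitter computes the exact Euclidean distance transform (pixels
beyond the raster count as background, so border-clipped objects are not
assigned inflated interior distances), takes regional maxima of the
distance map as seeds, and floods downhill from the seeds with a priority
queue; pixels where two basins meet become 1-px background lines, so split
objects are disconnected in the label map.

Two numerical refinements matter in practice:

1. **Maxima consolidation.** The discrete distance map of an elongated or
   border-grazing object carries a sub-pixel ripple along its ridge, which
   fragments the naive maxima set. Seeds are therefore taken from the
   *h-maxima* of the distance map (grayscale reconstruction of
   $d - h$ under $d$, merge depth $h$ = 1 px), followed by an exact
   regional-maxima extraction (a second reconstruction, $\varepsilon$ =
   0.005, below the smallest spacing of distinct EDT values in the working
   range). Maxima separated by dips shallower than 1 px merge; genuine
   necks between touching nuclei (dips of several pixels) do not.
2. **Component-aware seed suppression.** Seeds closer than
   `min_seed_separation` are suppressed keeping the deeper one, but only
   within the same connected component — a seed can never be suppressed by
   a seed of a different object, so every object retains at least one
   label. Sensible separations are the expected object radius (nuclei,
   default 8 px) and roughly the object width (myotubes, default 50 px).

This is an emulation of the reference desktop tool's
ultimate-eroded-points watershed, not a bit-exact port; line placement may
differ by a pixel.

### Guard against signal-free channels

Otsu's method always returns *some* cut, so thresholding a channel that
contains only noise would mark about half the pixels and percolate into
large spurious components. The segmentation wrappers therefore check the
threshold's *effectiveness* — the maximized between-class variance divided
by the total variance. Pure Gaussian noise yields about 0.64; real stained
channels in this regime exceed 0.95. Below
`min_threshold_effectiveness` (default 0.75) the channel is treated as
empty. The guard sits in `segment_nuclei()` / `segment_myotubes()`, not in
`otsu_threshold()` itself, whose contract stays minimal.

## Counting and statistics

Each accepted nucleus is assigned by the **rounded-centroid rule**: its
myotube id is the ROI label under the pixel nearest its centroid (0 if
background). Every nucleus is counted exactly once, making the
conservation identity $N_{in} + N_{out} = N$ exact by construction; it is
asserted on every pipeline run. Pixel-overlap majority voting was the
alternative; centroid membership was chosen because it matches counting
nuclei "within" regions, cannot double-count, and is insensitive to the
net dilation bias of the ROI chain.

Between-condition comparison of per-image indices uses the two-sided
unpaired Student t test with pooled variance (`stats::t.test`,
`var.equal = TRUE`), the historical default of the graphing software used
for such assays; a degenerate branch returns $t = 0, p = 1$ when both
groups are constant and equal. The qPCR utility implements
$\mathrm{fold} = 2^{-\Delta\Delta C_T}$ against a housekeeping reference
(e.g. 18S).

## The synthetic-data generator

`generate_image()` renders, on a dark background: elliptical nuclei
(equivalent-circle radius $\mathcal{N}(8, 1)$ px, eccentricity up to 0.6,
intensity 20000), capsule-shaped myotube footprints (40 × 400 px,
intensity 15000), a Gaussian PSF ($\sigma$ = 1 px), a flat background
(1000) plus additive Gaussian noise (SD 100), clipped to 16-bit. Defaults
describe a 512 × 512 field with 150 nuclei, six myotubes, half the nuclei
inside, and 10% of nuclei as co-oriented touching pairs with ≤ 1 px
boundary gaps — the latter specifically so the watershed stage is
genuinely exercised rather than vacuously passed.

Placement is rejection sampling with a budget of 1000 retries per object
and up to 10 whole-stage restarts, after which the generator fails with an
error naming the violated constraint — bounded runtime, explicit failure.
Myotube axes keep a 12 px mutual clearance so ROIs remain separable after
the net-dilation chain; outside-nucleus centers keep a 6 px clearance from
footprints so the ROI growth cannot capture them. In crowded fields
(combined footprint clearance above 70% of the canvas) tube orientations
are drawn semi-aligned, as dense differentiating cultures are. When the
intended inside count `round(target_mdi * n_nuclei)` is placeable, the
realized ground-truth MDI equals it exactly; the realized value is always
recorded. An explicit `multinucleation_profile` fixes per-tube intended
counts instead of `target_mdi` (touching pairs are then placed outside, to
keep the per-tube counts exact without a pair-packing subproblem).

The acceptance sweeps span target MDI 0.1–0.9; along that sweep the scene
scales the myotube footprint moderately with the differentiation level
(width 40 + 12·target px, length 400 + 80·target px), emulating
hypertrophic growth and keeping 150 nuclei placeable at the dense end.

**What passing does and does not show.** The simulator emulates the
geometry and photometry that the operator chain actually consumes:
two-channel composition, blur, noise, touching nuclei, elongated
partially overlapping-free footprints, border clipping. It does not
emulate sarcomeric texture, branched or crossing myotubes, uneven
illumination, stitching seams, Poisson shot noise, or out-of-focus debris.
Recovery results on synthetic scenes therefore validate the *logic* of the
chain (segmentation, splitting, counting, indices) — they do not certify
performance on real micrographs, which is exactly why the QC overlay
(composite with outlines and burned-in counts) exists for manual
validation.

## Conventions and degenerate inputs

* Matrices are indexed 1-based (row, column), R's native convention;
  areas in px², centroids are arithmetic means of pixel coordinates.
* Label maps are integer matrices, 0 = background, labels contiguous
  1..K in raster order of first occurrence; every label is 8-connected.
* Zero nuclei ⇒ MDI = MFI = 0 with a `degenerate` flag, not an error;
  empty masks flow through every operator; `sigma = 0` blur and
  `iterations = 0` morphology are identities.
* Equal (config, seed) reproduce byte-identical images, ground truth,
  tables and overlays; the generator restores the caller's RNG state.
* TIFF I/O: channel-first multi-page 16-bit by default; channel-last
  single-page TIFFs are auto-detected (the axis of length ≤ 4 is taken as
  channels). Physical pixel size is carried as optional metadata only —
  all processing is in pixel units.

## Test problem sizes

The suite validates operators on 32×32–64×64 random masks against
per-pixel oracles (100 and 50 cases), watershed splitting on 50 generated
touching pairs, nucleus detection on ten 512×512 scenes of 150 nuclei
(recall ≥ 95%, spurious ≤ 5%), index recovery on twenty scenes across
target MDI 0.1–0.9 (mean absolute error ≤ 0.05 for both indices), and
effect detection on five-vs-five scenes at target MDI 0.3 vs 0.6. The
same computations, reseeded from the command line, are what
`scripts/acceptance.R` reports.

## Known limitations

* The watershed is an emulation, not a bit-exact port of the desktop
  tool's variant; heavily branched syncytia may split differently.
* Myotube ROIs inherit the chain's net one-pass growth; absolute ROI
  areas are biased slightly upward by design and should not be compared
  across parameter sets.
* The original workflow's particle-size and circularity limits are not
  published; the defaults here (nucleus ≥ 40 px², myotube ≥ 500 px² at
  512×512 scale) are config-exposed and echoed into every output.
* Whether the original analysis thresholded the myotube channel by Otsu
  is not recorded; this package reuses Otsu for both channels (one
  mechanism, fewer knobs) and reports it in the parameter echo.
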