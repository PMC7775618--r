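---
title: "Shape analysis of streamline bundles: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape analysis of streamline bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tractshape)
```

## The problem

Diffusion-MRI tractography represents a white-matter pathway as a *bundle*:
a set of streamlines, each an ordered polyline of 3D coordinates
$\{v_i(t)\,|\,t = 1\ldots m_i\}$ in scanner millimetre space. Conventional
tract analysis reduces a bundle to tissue microstructure averages;
`tractshape` instead quantifies the *morphology* of the bundle — how long,
wide, curved, and irregular it is, and how large its cortical termination
fields are. The package computes a canonical set of 15 descriptors per
bundle, provides the two cleaning stages that such descriptors need
(atlas-style track recognition and topology-informed pruning), and includes
the reliability and asymmetry statistics used to judge whether a descriptor
is trustworthy in test-retest data.

## The descriptor model

Streamline-space descriptors are averages over tracks:

* **length** $= \frac{1}{n}\sum_i \sum_t \lVert v_i(t) - v_i(t+1)\rVert_2$ —
  mean polyline arc length (mm);
* **span** $= \frac{1}{n}\sum_i \lVert v_i(1) - v_i(m_i)\rVert_2$ — mean
  endpoint-to-endpoint distance (mm);
* **curl** $=$ length / span, in $[1, \infty)$: 1 for a straight bundle,
  $\pi/2$ for a semicircle, $a / (2\sin(a/2))$ for an arc of angle $a$.

Volume and area descriptors come from a voxelized representation. Each
track is resampled so consecutive points are closer than the effective grid
spacing, coordinates are multiplied by a scale factor (default 2) relative
to the source voxel grid, rounded to the nearest integer, and deduplicated
into the voxel set $T = \{V_i\,|\,i = 1\ldots N\}$. The doubled resolution
halves the spacing, so one voxel carries $(\text{voxel size}/2)^3 =
0.125\,\mathrm{mm^3}$ on a 1 mm grid. Then:

* **volume** $= N \times$ per-voxel volume;
* **diameter** $= 2\sqrt{\text{volume}/(\pi\,\text{length})}$ — the
  cylinder-model diameter;
* **elongation** $=$ length / diameter;
* **surface area** $= N_s \times \text{spacing}^2$, where $N_s$ counts
  voxels with at least one zero-valued face neighbour (the end caps are part
  of this surface);
* **irregularity** $=$ surface area $/ (\pi \times \text{diameter} \times
  \text{length})$ — the ratio of the measured surface to the lateral surface
  of the model cylinder. An ideal continuous cylinder with caps gives
  $1 + D/2L$; convoluted or fragmented surfaces give more.

End-surface descriptors operate on the two voxelized termination fields
$E_1, E_2$:

* **end-surface area** $= N_e \times \text{spacing}^2$;
* **radius** $= 1.5 \times$ mean voxel distance to the centroid — for a
  uniform distribution on a disk the mean distance to the centre is $2/3$
  of the radius, so the factor 1.5 inverts the disk model;
* **end-surface irregularity** $= \pi\,\text{radius}^2 / \text{area}$ — 1
  for a disk, larger for any protrusion, intrusion, or split termination
  field.

The **trunk volume** is the voxelized volume of the sub-bundle whose
endpoints fall in the largest connected component of each end surface,
discarding streamlines that terminate on detached termination islands.

```{r}
b <- make_cylinder(length_mm = 50, diameter_mm = 8,
                   n_streamlines = round(3 * pi * 64), seed = 1)
round(t(compute_profile(b)[, shape_descriptor_names()]), 3)
```

## Endpoint clustering

Track point order is arbitrary (a streamline may be stored in either
direction), so the endpoint fields are recovered by a constrained
two-cluster iteration: initialize with every first point in cluster 1 and
every last point in cluster 2; recompute the two cluster means; for each
track choose whichever of the two admissible endpoint-to-cluster pairings
has the smaller summed distance to the means; repeat until no endpoint
moves. The constraint — exactly one endpoint per track in each cluster —
holds at every iteration. Ties keep the current pairing, which makes the
iteration stable. One degenerate case needs special handling: when the two
cluster means coincide exactly (possible for perfectly symmetric toy
inputs), every pairing ties and distances carry no information, so the
implementation orients each track along the axis of largest endpoint
variance instead. $E_1$ is defined as the cluster with the larger mean
coordinate along the axis of largest inter-mean separation; axis ties
resolve z, then y, then x, matching the superior/posterior labelling
convention.

Clustering runs in millimetre space; the converged clusters are voxelized
with the same ×2 scale as the bundle so all areas share one spacing
convention.

## Cleaning stages

**Recognition.** Each candidate streamline is labelled by its nearest
reference trajectory under the symmetric Hausdorff distance (max of the two
directed nearest-point maxima over the discrete point sets), and dropped if
that shortest distance exceeds 16 mm. Because the discrete Hausdorff
distance depends on point density, candidates and references are first
resampled to a common 1 mm maximum step. Equidistant references resolve to
the alphabetically first label, so results do not depend on reference
ordering.

**Topology-informed pruning.** Pathways form bundles or sheets, so a
streamline threading a voxel supported by (almost) no other streamline is
likely spurious. Each of up to 20 iterations recomputes the voxel-wise
streamline density (distinct streamlines per voxel, on the scaled grid) and
removes every streamline touching a voxel with count at or below the
low-density threshold (default 1). Iteration stops early at a fixed point,
and a pass that would empty the bundle is not taken: by default the last
non-empty bundle is returned with a warning, mirroring what one must do for
very thin bundles. The low-density cutoff is a parameter because
"low-density" has no canonical value; count ≤ 1 is the minimal reading.

## Reliability and asymmetry statistics

Test-retest reliability per bundle-descriptor cell uses the one-way random,
single-measures intraclass correlation
$\mathrm{ICC}(1,1) = (MS_B - MS_W)/(MS_B + (k-1)MS_W)$ with $k = 2$
sessions. Cells are categorized good (ICC ≥ 0.75), moderate (0.5 ≤ ICC <
0.75), or poor (ICC < 0.5); the median ICC per descriptor across bundles
summarizes overall performance. Negative estimates are reported as
computed. Left-right asymmetry uses a two-sided paired t-test with the
conventional star map (*** < 0.001, ** < 0.01, * < 0.05), the percentage
difference $100(a-b)/a$ with $a$ the dominant (larger-mean) side, and
Cohen's d. The paired form $\bar d / s_d$ is the default denominator since
it matches paired-t reporting; a pooled-SD form is available
(`d_form = "pooled"`). No multiple-testing correction is applied by
default, matching raw-star reporting. Between-subject variation is the
absolute deviation from the median divided by the median, summarized by its
quartiles.

## The synthetic generator, and what passing tests do not show

`make_cylinder()` and `make_arc()` produce bundles whose descriptors have
closed forms (attached as the `ground_truth` attribute), and
`make_retest_pair()` produces jittered/dropped test-retest copies with a
controllable reliability structure. Transverse positions are sampled
uniformly over a disk by square-root inversion, the same uniform-disk model
that calibrates the radius estimate. The generators emulate the geometry of
real bundles — straight and C-shaped cores, disk-like termination fields,
isolated stray streamlines — but not their anatomy: no branching or fanning
terminations, no crossing-fibre ambiguity, no tracking-algorithm bias, no
registration error. Tests passing on these phantoms validate the
descriptor arithmetic and the cleaning logic, not the anatomical accuracy
of any tracking pipeline.

## Numerical choices

* **Rounding** is half-away-from-zero to the nearest integer (standard
  voxel binning); ceiling would bias every coordinate by +0.5 voxel.
* **Sampling density.** Voxel-count metrics carry two opposing
  discretization biases: rounding dilates the cross-section by about half a
  voxel (inflating volume by roughly $2h/D$ at saturation, $h$ = 0.5 mm
  spacing), while finite streamline counts leave unsampled interior cells
  (deflating it by about $e^{-\lambda}$ at $\lambda$ streamlines per
  transverse cell). Synthetic validation bundles use $\lambda = 3$
  ($n = 3\pi D^2$ streamlines), where the two biases roughly cancel: there
  volume lands within 10% and diameter within 5% of truth across lengths
  50–100 mm and diameters 5–15 mm. Surface area is far more hole-sensitive
  — a single interior hole adds up to six spurious surface faces — so
  surface-area validation saturates the cross-section ($\lambda = 10$)
  instead, where only the staircase bias (about −10%) remains.
* **Connectivity defaults.** Surface voxels use 6-connectivity (face
  neighbours, the morphological surface definition); connected components
  use 26-connectivity because one-voxel-thick end-surface sheets often
  connect only diagonally. Both are arguments.
* **Degenerate inputs.** Closed loops (span < 0.1 mm) are refused rather
  than emitting infinite curl; zero-length streamlines contribute 0 to
  length with a warning; a pruning pass that would empty a bundle is never
  taken; ICC on zero total variance and deviations about a zero median are
  errors, not NaNs.
* **Determinism.** All generators take seeds and restore the caller's RNG
  state; recognition and component ordering have explicit tie-breaks, so
  pipeline reruns are byte-identical.

Validation problem sizes (chosen to make the discretization regimes above
explicit while keeping examples quick): cylinders of length 50–100 mm and
diameter 5–15 mm at $n = 3\pi D^2$ streamlines, a saturated
$\lambda = 10$ cylinder for surface area, 14-bundle cohorts at 150–200
streamlines per bundle, and 20-subject retest cohorts for the reliability
layer.

## Known limitations

* Voxel-count surface area systematically deviates from the true surface of
  smooth shapes (staircase effect), and volumes of thin bundles ($D
  \lesssim 2h$) are dominated by the dilation bias; at saturation the
  volume of a $D = 5$ mm cylinder overshoots by about 20%. Descriptor
  *comparisons* across bundles measured at the same resolution are
  unaffected, but absolute values inherit these biases. A triangulated
  surface would remove the staircase effect and is a natural extension.
* The discrete Hausdorff distance is computed on resampled polylines; very
  coarse reference trajectories should be resampled (the default does so at
  1 mm).
* Whole-track removal is the only pruning action; partial-track trimming is
  out of scope.
* Recognition assumes candidates and references are already co-registered;
  no warping is performed.
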