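---
title: "Methods: single-neuron reconstruction and branch repair in neurostitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-neuron reconstruction and branch repair in neurostitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurostitch)
```

## The problem

Golgi impregnation labels a sparse random subset of neurons at very high
contrast, in both optical block-face imaging (here: 8- or 16-bit stacks at
anisotropic spacing, typically 1 × 1 × 2.5 μm) and synchrotron micro-CT
(0.65 μm isotropic). Three failure modes dominate reconstruction from such
material: *staining gaps* that interrupt neurite branches (either in the
middle of a branch or by leaving a whole terminal branch undetected),
*non-specific labelling* of blood vessels and glia that entangles the
segmentation, and *punctate artefacts*. `neurostitch` implements a
semi-automated pipeline around these failure modes: automatic thresholding
and component analysis do the bulk of the work, while a human supplies
exactly the judgements that are genuinely ambiguous — one soma seed per
neuron, one marker per interrupted branch terminal, and optional eraser
regions.

All geometry is computed in physical micrometres from the voxel spacing
`(dz, dy, dx)`; grids are indexed `(z, y, x)` with 1-based indices, and
physical coordinates are voxel centers with voxel `(1, 1, 1)` at the
origin. SWC files use the standard seven columns with `x y z` in μm.

## Stage 1: background denoising

A single global threshold `T` separates signal from tissue background
(`threshold_volume()`); bright-foreground is the default polarity since
the processed signal is brighter than background in both supported
modalities, with an invert option for dark-foreground data. Raising `T`
under keep-above polarity can only shrink the mask, which
`evaluate_thresholds()` exploits to report objective proxies (foreground
fraction, component count, largest component volume) over a candidate
sweep — e.g. 160/190/220/250 for fluorescence-type contrast or 20/40/60/80
for micro-CT-type. The function deliberately does **not** auto-select `T`:
the trade-off between removing background and eroding fine structure is a
visual judgement, and the shipped presets (`T = 220` fluorescence-mode,
`T = 40` micro-CT-mode) encode the values that balance it for the two
supported contrast regimes. 16-bit input is first reduced to 8 bits
(`convert_to_8bit()`), by default with global min–max scaling; a
fixed-window mode exists for reproducible conversion across stacks, and a
constant (zero-contrast) volume maps to all-zero by convention.

## Stage 2: single-neuron extraction

`label_components()` labels the thresholded mask under 26-connectivity by
default (foreground 26 / background 6 is the standard digital-topology
pairing, and 26 preserves thin diagonal neurites at coarse z-sampling).
`filter_small_components()` removes components whose *physical* volume
(voxel count × voxel volume) is strictly below `min_volume`, default
1000 μm³ — stated in μm³ so the same rule applies across voxel sizes
(400 voxels at 2.5 μm³/voxel, but 3642 voxels at 0.65³ μm³/voxel).
`select_neuron()` keeps the component nearest the soma seed; the seed
snaps to foreground within 5 μm by default, because manual clicks rarely
land on the medial axis but should never jump to a different neuron.
`apply_edits()` clears eraser spheres/boxes (for vessels that touch the
neuron and survive everything else); it can only remove voxels.

## Stage 3: marker-guided branch repair

The tracing cost at a voxel with intensity $I$ is

$$c(v) = \exp\!\left[\lambda\,\bigl(1 - I(v)/I_{\max}\bigr)^{\gamma}\right],
\qquad \lambda = 10,\ \gamma = 2,$$

so cost spans $[1, e^{\lambda}]$: bright voxels are nearly free and dark
background is ~$e^{10}$ per μm. This exponential intensity weighting with
Dijkstra shortest paths is the de-facto standard in neurite tracing; we
adopt it because the underlying interactive tool the workflow replaces
does not document its algorithm. Edge weights on the 26-neighbor graph are
the physical step length times the mean endpoint cost; ties break toward
the lexicographically smaller `(z, y, x)` voxel, so traces are exactly
reproducible. Traces abort when the accumulated cost exceeds
$e^{\lambda} \cdot 10 \cdot d_{\text{straight}}$ — a deliberately loose cap
that only stops runaway searches across pure background; a capped trace is
reported with its best frontier voxel and the remaining repairs proceed.

`repair_neuron()` traces from each marked terminal **through the raw
volume** (not the thresholded mask) to the nearest voxel of the current
soma-connected mask. Tracing through raw data is the central design
choice: the faint sub-threshold staining inside a gap is exactly the
signal that should guide the bridge. The trace starts at the marker's own
voxel — for a mid-branch interruption that voxel is bright and the
geodesic rides the detached fragment; for an undetected terminal branch
the marker sits in background and the geodesic reconstructs the missing
terminal stretch — so both discontinuity classes are handled by the same
operation, and the marked terminus always ends up inside the repaired
tube. Each path is rasterized as a tube of locally estimated radii
(minimum one voxel, so consecutive spheres stay 26-connected), and the
mask is then re-labelled against the thresholded foreground so that any
fragment the tube touches is absorbed; later terminals can therefore
attach to fragments reconnected earlier. Terminals are processed in file
order.

## Skeletonization

`skeletonize_to_swc()` converts a voxel mask to an SWC tree by the
distance-tree/path-pruning construction familiar from shortest-path
neurite tracers:

1. a geodesic spanning tree over the mask from the soma voxel, with the
   intensity cost divided by the chamfer distance-to-boundary — this
   *canalization* makes geodesics through a thick tube merge on its medial
   axis instead of running parallel surface lines (without it, a tube of
   radius 2 yields several same-cost paths and phantom bifurcations at the
   root);
2. candidate tips = geodesic-distance local maxima (plateaus broken
   lexicographically), paths extracted from tips in decreasing distance
   order;
3. spur pruning: a terminal chain is removed if it is shorter than
   `prune_um` (default 3 μm, suppressing voxelization burrs at 1–2.5 μm
   sampling without deleting real twigs), if its tip lies inside the
   estimated soma ball (surface bumps of the soma are not neurites), or if
   every chain node lies within the local tube radius of its nearest
   remaining skeleton node — the coverage rule that removes tube-surface
   artefacts while keeping genuine branches, which escape their
   neighbor's radius. The local radius used here tolerates a fraction of
   sub-threshold voxels inside the ball (90% occupancy), because single
   noise dropouts inside genuine structure would otherwise collapse the
   estimate;
4. each surviving branch polyline is lightly smoothed (moving average,
   window 5 voxel-chain nodes, endpoints fixed) to suppress digital
   zigzag, then resampled at ≤ 2 μm arc spacing; radii come from
   `estimate_radii()` (largest ball with all voxel centers at/above `T`,
   floored at half the minimum spacing, capped at 10 μm — the strict
   all-voxels rule is kept here because SWC radii should be conservative).
   The root is typed soma (1), everything else basal dendrite (3) until
   `retype_subtree()` is applied, since no reliable automatic
   axon/dendrite classifier exists for this material.

A degenerate blob (no elongated structure) collapses to a near-empty tree
rather than erroring.

## Morphometry

A *branch* is a maximal path between consecutive critical nodes (root,
bifurcations/multifurcations, tips); for a degree-1 root with $b$ binary
bifurcations this gives $2b + 1$ branches. The convention is declared in
the outputs because published branch counts rarely state theirs. Lengths
are sums of Euclidean parent–child distances in μm (the root contributes
no edge); per-type lengths attribute each edge to the child's structure
type, so branch lengths, type lengths and total length are exactly
conserved. Sholl profiles count sign changes of
(distance-to-center − r) along branch polylines resampled at ≤ 1 μm —
sampling instead of quadratic root-finding, with the error bounded by an
analytic segment–sphere oracle in the test suite. Points exactly on a
sphere count with the outgoing step; a crossing landing exactly on a
bifurcation node is the one measure-zero case the convention cannot
attribute. Default radii run in 10 μm steps from 10 μm to the farthest
tip, a step consistent with published profiles that never state theirs.
`compare_morphometry()` reports percent change rounded to the nearest
integer and fold change to one decimal — the rounding that reproduces
every published raw/revised figure from its printed inputs; a zero raw
value makes percent change undefined and the fold is reported alone.

## The phantom generator

`make_phantom()` emulates the study conditions so every stage is testable
without deposited raw data. Defaults (fluorescence mode): 56 × 224 × 224
voxels at (2.5, 1, 1) μm; a self-avoiding random binary tree with 5
bifurcations grown from a central 6 μm soma ball (segment lengths
25–45 μm, bifurcation half-angles 20–60°, gentle 4°/5 μm direction
jitter, radii tapering from 2 μm to a 1.5 μm floor — the thinnest tube
resolvable at 2.5 μm z-sampling); neurite mean 240 over background 120
with Gaussian noise sd 10, so the preset threshold 220 separates them
(~2% of neurite voxels fall below threshold, the realistic salt-noise the
robust radius estimates must survive). Micro-CT mode switches to 0.65 μm
isotropic, neurite 60 / background 20 / noise 5 under threshold 40.
Centerline self-avoidance (7 μm separation) matters for oracle validity:
crossing branches make ground-truth branch counts unrecoverable in
principle, and crossing disambiguation is explicitly out of scope.

Corruption erases tube segments back to noisy background along sampled
arc intervals — interior intervals produce mid-branch interruptions,
intervals abutting a tip produce undetected terminal branches. Gaps are
carved as capsules *clipped to the interval* (a voxel is erased only if it
is nearer the gap interval than the intact remainder of the branch), so
the erased arc length equals the bookkept gap length; intervals keep 5 μm
clear of critical nodes (15 μm on the proximal stem, so the soma fragment
always survives the volume filter). The gap model is rate-based (2 gaps
per 100 μm, lengths 5–10 μm) or, for controlled experiments, a target
total gap fraction. Distractors are placed disjoint from the neurite tube
with bounded retries: vessels are random-walk tubes rendered at neurite
intensity (they must survive thresholding and be removed only by
connectivity or edits), glia are ellipsoidal blobs each under 1000 μm³
(they survive thresholding but fall to the volume filter), puncta are 1–3
voxel bright spots. Truth output: the tree, the gap table, the distractor
mask, and markers — the soma seed plus one branch terminal per
ground-truth tip distal to any gap. Each stage seeds the RNG from
`spec$seed` plus a fixed offset, so phantoms are bit-reproducible and the
stages remain individually reproducible.

What the phantom does *not* emulate: optics/CT physics (PSF anisotropy,
ring artefacts, reconstruction streaks), multi-neuron forests with
designed crossings, spines, and intensity inhomogeneity along branches.
Passing the recovery tests therefore demonstrates the pipeline's
correctness on its own failure model, not performance on arbitrary real
tissue.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on the
default 56 × 224 × 224 phantom (≈ 2.8 M voxels, ≈ 400 μm of cable, six
marked termini), which exercises every stage in a few seconds; oracle
equivalence uses exhaustive reference implementations on volumes up to
12³ (components) and 6³ (Dijkstra, 60–100 random trials) and 50 random
trees (Sholl). Under the default conditions with 15% of the cable erased,
the raw-stage reconstruction recovers only ~5–15% of the true length
(every gap detaches everything distal to it), while the repaired
reconstruction recovers ≥ 95%, reconnects all marked termini into one
component, and gap-free phantoms give exact branch counts and total
length within ±5%.

Degenerate inputs are handled deterministically: zero-contrast 16-bit
volumes map to all-zero 8-bit; empty eraser sets and `min_volume = 0` are
identities; a trace whose start equals its goal is an error; exact
distance ties (marker attachment, path relaxation, tip plateaus) resolve
lexicographically by `(z, y, x)`.

## Known limitations

* Branch repair is marker-driven; there is no automatic gap detection.
* The geodesic bridge has no curvature or orientation prior, so in very
  low contrast a bridge may cut a corner relative to the true curved path;
  the recovered length is then a slight underestimate.
* Revised reconstructions can split branches at repair-tube junctions,
  inflating the branch count relative to ground truth (lengths are
  unaffected); the branch-count fidelity claims therefore apply to
  gap-free structures.
* Radius estimates are quantized at half the minimum voxel spacing and
  capped at 10 μm; somata larger than the cap are under-reported in the
  SWC radius column.
* Axon/dendrite typing is manual (`retype_subtree()`).
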