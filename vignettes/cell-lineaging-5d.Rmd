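---
title: "Tracking and lineaging proliferating cells in 5-D: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and lineaging proliferating cells in 5-D: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrack)
```

clonetrack quantifies clones of motile, proliferating cells — the motivating
case is neural stem cells imaged live together with vasculature in brain
tissue — from 5-D (x, y, z, t, channel) confocal time-lapse data. This
vignette explains the models behind each stage, the parameters that matter,
the numerical choices that were genuinely open, and what the synthetic-data
tests do and do not demonstrate about real data.

## Data model

A movie is a `volume5d`: an array ordered (t, channel, z, y, x) with a
physical calibration (`voxel_spacing`, micrometres per voxel, typically
anisotropic: z steps of 1 um against an xy pitch of ~0.8 um) and per-channel
roles (`cell`, `vessel`). All distances in the package are physical: voxel
index (z, y, x) maps to ((x-1)·dx, (y-1)·dy, (z-1)·dz) um through one
conversion point, `voxel_coords_um()`. Indices are 1-based, the native R
convention; serialized JSON records `index_base` explicitly so other tools
cannot misread it.

Files are multi-page TIFF plus a JSON sidecar (spacing, frame interval,
channel roles, shape, tile stage positions). Integer-valued stacks within
16-bit range — what microscopes emit — round-trip bit-exactly; float data is
stored as scaled 32-bit float and round-trips to single precision. That is a
deliberate trade: the one storage mode the instrument produces is lossless,
and nothing downstream manufactures sub-single-precision intensities.

## Background noise removal

The two channels get different noise models because their foregrounds
differ.

**Cell channel.** The observed image is modelled as signal plus a slowly
varying background plus high-frequency shot noise. The background is a
separable Gaussian low-pass of the image; the `background_neighborhood`
window (voxels per axis, default 100, useful range about 75–250) maps to the
Gaussian as sigma = window/6 with the kernel truncated at three sigma — the
conventional window-to-sigma correspondence, chosen because the window, not
sigma, is what a user reasons about. Subtracting it preserves compact bright
somata while removing illumination gradients; negatives are clamped to zero
because intensity is physical; a 3×3×3 median then removes isolated shot
voxels. Borders are reflected for all filters so no energy is invented or
lost at the edges. One honest limitation: the operator is not idempotent to
within a few percent — clamping zero-mean noise at zero leaves a small
positive baseline that a second pass re-estimates as background. Measured on
simulated frames a second application changes the output by ~13–14% of the
first-pass change; the test suite asserts that contraction rather than a
stricter bound the operator cannot meet.

**Vessel channel.** Vessel foreground fills large image regions, so local
background estimation would eat the signal. Instead an iterative
Markov-random-field-style smoother is used: each sweep recomputes the
minimum occupied-intensity gap `delta` of the current histogram and moves
every voxel by exactly ±delta toward its 6-neighbour mean (voxels within
delta/2 do not move). The stopping rule compares the mean squared difference
from the original image to a global noise-variance estimate: smoothing stops
once the image has changed as much as the noise model predicts. The variance
estimate convolves the image with the 6-neighbour Laplacian (center −6) and
divides the interior response variance by 42, the kernel's sum of squared
coefficients, which makes it unbiased for i.i.d. noise while smooth
structure contributes almost nothing. Two numerical guards: a sweep cap
(default 500) and a fixed-point stop when no voxel wants to move. On a
finite field the reachable mean squared difference fluctuates around the
variance estimate (both are ~the sample variance of the noise), so the
stopping inequality is met only up to sampling slack; the tests allow 10%.
`delta` is recomputed from the current histogram each sweep, reading
"current" literally; with integer data this keeps voxels on the integer
lattice.

## Montage registration

Large static specimens are imaged as a checkerboard of overlapping 3-D
tiles. Three assumptions make registration purely translational: tiles are
captured at right angles on a single time point, the specimen deforms only
along gravity (z), and there is a single subsection along z. Stage positions
recorded at capture predict which tiles can be adjacent (neighbours along
exactly one of x, y; an axis counts as partial below 80% of the full extent
so that stage jitter cannot disqualify a true neighbour; corner-only
contacts are excluded).

Each adjacent pair is registered in two stages around the stage-predicted
offset: first an exhaustive (x, y) search on the z maximum-intensity
projections, then a z refinement on the full 3-D overlap, both scored by
normalized covariance — mean-subtracted, variance-normalized, hence
invariant to per-tile gain and offset. The default search half-width is 20
voxels (the stage is rarely off by more); candidates with fewer than 32
overlapping voxels are skipped because covariance on tiny overlaps is
unstable. The per-pair scores feed a maximum spanning tree (Kruskal, ties
broken by the lexicographic tile-id pair for determinism); the lowest tile
id is held stationary and every other tile's global delta accumulates along
its tree path. Fusion places every channel of a tile with that one delta and
resolves overlaps by voxel-wise maximum — the simplest order-independent
rule. Two open points were resolved as: the (x, y) stage uses the full
overlap covariance of the MIPs (not a windowed subset), and the covariance
normalization uses the population (1/N) convention, which cancels in the
argmax anyway.

Registration presumes the structural channel has unique features spanning
every overlap strip — vasculature is the canonical example. The synthetic
master generator therefore scales its tube count with field area and bends
each tube (quadratic Bezier polylines): a straight tube parallel to an
overlap strip pins no offset along its own axis, a degeneracy real branching
vessels do not exhibit.

## Segmentation

Per frame and channel: Otsu threshold (256-bin between-class-variance
maximization, applied globally per frame — "adaptive" across frames, not
tiles), then morphological closing with a ball whose radius is given in
micrometres and converted per axis to voxels (default 1 um), so holes are
filled isotropically in physical space. Erosion treats outside-image voxels
as foreground, which guarantees closing never removes input foreground.
Connected components use 26-connectivity, standard for 3-D somata.
Components with physical volume strictly below `min_volume_um3` (default 19
cubic micrometres, below the smallest expected soma; cell-type dependent)
are discarded — strictly below, so a component exactly at the threshold
survives. Detections are ordered by each component's first scan-order voxel,
making segmentation fully deterministic.

Each detection carries a convex hull mesh (vertex and facet lists in
micrometres) built by an incremental hull on the per-column z-extreme voxel
centers (interior column voxels cannot be vertices, which cuts the point
count several-fold). Collinear or coplanar voxel sets — one-voxel-thick
detections — fall back to a flagged bounding-box mesh rather than failing
the pipeline. The vessel mask becomes an exact anisotropy-aware Euclidean
distance map (separable lower-envelope transform), zero on foreground, used
for all niche distances.

## Tracking

Tracking is windowed multitemporal association. The link cost between
detections combines the connected-component distance — the minimum pairwise
distance between foreground voxel centers in micrometres, zero for
overlapping masks — with a normalized size difference
|‖a‖−‖b‖| / max(‖a‖, ‖b‖) that keeps sizes homogeneous along a track. An
extension of track τ by the consecutive-frame sequence ρ costs

  (W / |ρ|) · Σᵢ d(ρᵢ₋₁, ρᵢ) · (1 + λ·s(ρᵢ₋₁, ρᵢ))

with ρ₀ the track's last detection, W the window (default 4 frames), λ the
size weight (default 1), and |ρ| the achieved extension length (paths run to
the window unless they dead-end). The multiplicative W/|ρ| term penalizes
short extensions, which would otherwise be cheap by having fewer terms. Any
single link longer than `max_link_distance` (default 30 um — cells move
~1 um/frame at 20-minute sampling, so this is generous) makes the extension
infeasible, which also bounds the combinatorics of the exhaustive windowed
search.

Per frame transition, the minimum extension cost through each next-frame
detection defines the edge costs; an edge that is simultaneously its row and
column minimum (ties to the lower id) is a matching edge and extends its
track. Unmatched detections seed new tracks; unmatched tracks stay live for
up to `occlusion_gap` frames (default 1) with their last detection standing
in as ρ₀ — gap frames contribute no cost terms — then close. Every detection
ends up in exactly one track.

## Lineaging

A track born after the first frame is assigned the parent that was cheapest
to divide from: the argmin, over tracks with a detection in the frame before
birth, of the stored single-link cost to the newborn's first detection.
Single-link (not full windowed path) was chosen because a division is a
frame-adjacent event at 20-minute sampling; for the same reason a candidate
must have a detection exactly one frame before the birth. If every candidate
is infeasible the newborn is a root.

Because the tracker extends the dividing cell straight into one daughter,
the forest builder cuts the parent track at the division: the tail becomes a
second daughter track, the parent ends one frame before both daughters are
born, and the division frame is the parent's end. This yields the canonical
two-daughter division topology and makes recovered trees directly comparable
to ground truth. A third concurrent daughter raises a validation flag, not
an error. The largest tree (most track nodes; ties to earliest root birth,
then lowest id) is the default presentation target.

Niche quantification reads, per frame, the minimum of the vessel distance
map over the detection's voxel set — a surface-to-vessel distance that is
zero on contact. The cleavage plane of a division is the perpendicular
bisector of the daughters' first-frame centroids (plane through the
midpoint, unit normal along the centroid difference); given a distance map
it also reports the angle between that normal and the direction to the
nearest vessel voxel, folded into [0, 90] degrees. The bisector definition
was chosen over a parent-elongation-axis definition because it is defined
exactly when a division exists and degrades never.

## Validation and correction

`split_detection` fits an n-component full-covariance Gaussian mixture to a
detection's voxel coordinates and partitions voxels by maximum posterior;
full covariances favour the ellipsoidal shapes of somata where k-means would
favour spheres. The voxel union is conserved exactly; undersized parts warn
but are kept — the user's intent wins. `delete_detection` removes a
detection and lets the rerun decide whether occlusion rules bridge the gap.

A split propagates forward through the original track's assignments as long
as the tracked successor still looks like the same merge. Three gates, each
necessary: the successor's volume must exceed 75% of the parts' combined
volume; it must be the minimal-cost successor of at least two of the parts;
and it must itself be multimodal — an n-component mixture must beat a single
component on BIC. The third gate is what stops a false split of a true
single cell immediately (its volume trivially passes the first gate and both
halves nominate it under the second); heavily overlapped merges may fail it
too, in which case propagation stops conservatively and the user edits the
next frame. Auto-split seeds derive from the user's seed plus the frame
offset, so the whole cascade is reproducible. After the edit, tracking and
lineaging rerun over the full movie: at desk scale a full rerun is cheap,
deterministic, and trivially equivalent to a windowed rerun, so the simpler
rule was kept.

## The synthetic-data generator

The simulator defines the study conditions for every test. Its defaults
mirror the acquisition geometry the pipeline targets: 25 z-planes at 1 um,
0.8 um xy pitch, 20-minute frames, movies of 64×64×25 voxels and 20 frames
at test scale. Cells are solid ellipsoids (semi-axes 2.5–4 um, smallest axis
along z) with a one-voxel Gaussian edge falloff so thresholding sees a
realistic boundary; intensities are quantized to integers and clamped at
zero like detector output. Noise is a smooth cosine background field
(amplitude 20, ~40 um scale), Gaussian read noise (sd 8), and salt impulses
(probability 10⁻³, amplitude 200). Motion is a random walk capped at 1 um
per frame, which keeps consecutive ground-truth masks overlapping well above
the 50% bound that underwrites error-free tracking; distinct cells steer
apart below 10 um so identities stay well-posed, and daughters are placed
jointly at division along the direction that best preserves separation after
clamping to the volume bounds. Vessels are two static tubes.

What passing these tests shows: the association, division and edit machinery
is exact under its stated premises (correct segmentation, ≥50% overlap,
separated cells). What it does not show: robustness to touching cells,
photobleaching, point-spread blur, segmentation errors other than the
modelled post-mitotic merges, or anatomy-specific vessel geometry — none of
which the generator emulates.

## Problem sizes and determinism

The shipped test suite uses 10 movies of 64×64×25×20 voxels for the
tracking guarantee, 2×2 and 3×3 montages cut from a 256×256×25 master
(15% overlap, ≤4 voxel stage jitter, search window 8 which covers the
worst-case relative jitter of 8), 32³ fields for the noise estimator, and
8³-and-below grids for exhaustive oracle comparisons — sizes chosen so a
desk machine reproduces everything in about a minute. Every stochastic
element is seeded; rerunning a pipeline with the same configuration and seed
produces byte-identical serialized results, which the suite asserts by
hashing.
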