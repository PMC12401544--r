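---
title: "Point-assignment neurite reconstruction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-assignment neurite reconstruction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pointneurite)
```

## Overview

`pointneurite` reconstructs neurite skeletons by assigning foreground points
to neurites instead of tracing paths through the image. The pipeline has
five stages, each exposed as ordinary functions so every intermediate state
can be inspected:

1. **Foreground extraction** — voxels of a distance-field segmentation with
   value above 0.5 become points; intensities are `round(255 * field)` and a
   point survives only above the intensity floor ε₀ = 128.
2. **Constrained Gaussian mixture** — EM over the points with two
   constraints applied after every M-step, so clusters stay *columnar*
   (elongated sections of a single neurite).
3. **MVCE characterization** — each cluster is summarized by its
   minimum-volume covering ellipsoid; the long-axis endpoints become link
   terminals.
4. **0–1 assignment linking** — one exact linear assignment over all
   terminals decides every connection simultaneously.
5. **MIFT revision** — trees are re-rooted, merged, and split under a
   smoothness prior.

## Foreground and seeding

Cluster seeds are chosen from the *density median outward*: points are
sorted by local density (neighbor count within 3 voxels) and visited
starting at the median, alternating below/above. A visited point becomes a
seed unless it lies within the exclusion radius (5 voxels) of an existing
seed. Starting at the median avoids seeding at crossing centers (highest
density, ambiguous ownership) and at neurite edges (lowest density).

```{r seeds}
sp <- phantom_spec(shape = c(64, 64, 64), n_neurites = 2,
                   n_parallel_pairs = 1, parallel_gap = 2, rng_seed = 1)
ph <- generate_phantom(sp)
field <- make_distance_field_labels(ph$skeleton, sp$shape)
fg <- extract_foreground_points(field)
sel <- select_seeds(fg$points, compute_density(fg$points, 3), 5)
sel$K
```

## Constrained GMM

EM starts at the seeds with identity covariances. After every M-step:

- a component whose center rounds onto a voxel with intensity below ε₀ is
  replaced by two daughters displaced half a standard deviation along its
  principal axis (bridging across gaps is forbidden);
- a component with `det(Σ) > ε₁ = (3 · neurite_diameter)³ = 5832` is
  rescaled by the cube root so the determinant equals ε₁ (components must
  not grow past a neurite section).

After convergence, points are hard-assigned, clusters are split into
26-connected components, and centers are recursively split until each sits
on foreground. A consolidation pass then merges abutting clusters whose
union is still a clean column (rms distance to the principal line
≤ 2.2 voxels) — sections of one tube merge, parallel tubes and crossing
regions never pass the columnarity test.

```{r gmm}
cls <- fit_constrained_gmm(fg$points, fg$intensity, sel$seeds)
cls <- merge_lateral_duplicates(cls, fg$points)
length(cls)
range(vapply(cls, function(cl) det(cl$sigma), numeric(1)))
```

## MVCE characterization

Each cluster's covering ellipsoid is found by a primal–dual barrier/Newton
method; large clusters use an exact active-set wrapper (solve on directional
extremes, add covering violators, rescale over all points). If the solved
center falls outside the member hull — a bent cluster — the cluster is split
by a local two-component mixture and characterized recursively. Degenerate
(collinear) clusters get thin ellipsoids with the extreme members as axis
endpoints. The test suite checks the solver against an independent
Khachiyan implementation to 1% in volume.

## Linking by 0–1 assignment

Every ellipsoid contributes two terminals. The cost of joining terminal
`i0` of ellipsoid `i` to terminal `j0` of ellipsoid `j` is

```
gap / (0.5 * (theta / 3 + 1.001))^4
```

where `gap` is the terminal distance and `theta` in [-3, 3] adds three
direction cosines: each ellipsoid pointing at the other's terminal
(rewarded twice) and the axes anti-aligned end-to-end (rewarded once). The
full matrix is 4n × 4n with constant auxiliary blocks at 100, letting any
terminal opt out; 100 is also the link rejection threshold. The assignment
is solved exactly (Jonker–Volgenant), so all links are decided jointly — a
crossing cannot steal a terminal that a smoother continuation needs.

## MIFT revision

The *information flow* of a tree is the sum over branch nodes of the cosine
of the vertex angle between the directions toward the head and toward the
left child (directions averaged over a 5-node window). Smooth chains score
-1 per interior node; sharp turns score up to +1. For each tree the package
evaluates the flow at every candidate root with O(1) re-rooting transitions
and keeps the minimizing root — an exact minimization, verified in tests
against exhaustive enumeration.

```{r mift}
rec <- reconstruct(field)
prof <- information_flow_profile(rec$trees[[1]], window = 5)
which.min(prof)
```

Revision rounds then merge trees whose roots face another tree's terminal
within the merge radius, heal small terminal gaps, split any link turning
sharper than 120°, and absorb redundant debris, repeating to a fixed point.

## Block fusion

Per-block forests are fused pairwise along x, then y, then z. Terminal
nodes within 5 voxels of the shared face are matched by a second exact
assignment with cost `d * (2 - |cos|)` and auxiliary value 20; joined trees
are re-minimized and the MIFT merge radius grows over levels (8, 12, 16).

## Evaluation

`evaluate_reconstruction()` resamples ground-truth polylines to 1-voxel
spacing, assigns each reconstructed tree to the neurite with which it
shares the most matched points (tolerance 4 voxels), pools the trees per
neuron, and averages per-neuron precision/recall/f1 weighted by
ground-truth point counts.

```{r eval}
ev <- evaluate_reconstruction(rec$trees, ph$skeleton)
ev$weighted
```

Note one consequence of this pooling: the metric is insensitive to
*fragmentation* — a neurite split into several trees that are all assigned
back to it scores the same as a single connected tree. This is why the
MIFT on/off fusion ablation in the acceptance suite can tie: MIFT's merges
and re-rootings improve connectivity and topology, which this point-overlap
metric does not see unless a merge or split changes tree-to-neuron purity.

SNR of simulated volumes follows the masked definition: foreground = voxels
of the densified true skeleton, background = voxels outside its 3-voxel
spherical expansion, `SNR = 10 log10(mean_fg / sd_bg)` dB. The phantom
generator calibrates additive truncated-Gaussian background noise to a
target SNR and the round trip is exact to within 0.5 dB.

## Practical notes

- `reconstruct()` expects a (possibly blockwise) distance-field
  segmentation, as produced by the package's `make_distance_field_labels()`
  or an external network. Feeding a raw noisy volume through the 0.5
  threshold works but degrades precision — denoising/segmentation is
  deliberately out of scope.
- All tunables live in `pn_config()`; the defaults reproduce every number
  in this vignette.
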