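---
title: "Identifying venous voxels from resting-state connectivity graphs"
author: "veingraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying venous voxels from resting-state connectivity graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

BOLD fMRI measures blood oxygenation, not neuronal firing. Signal changes
in medium and large draining veins can appear far downstream of the neural
site that caused them, so voxels dominated by macrovascular signal violate
the assumption that a voxel's BOLD time course reflects local activity.
Identifying such voxels from the EPI data themselves — without extra
acquisitions such as susceptibility-weighted imaging (SWI) — lets analysts
flag or exclude them.

The observation this package exploits is that venous voxels exhibit very
strong positive *and negative* low-frequency correlations with many other
voxels of the macrovasculature, whereas parenchymal voxels of resting-state
networks correlate with one another far more weakly in unsmoothed data. A
voxelwise correlation graph binarized at a sufficiently high absolute
threshold therefore contains almost exclusively vein-to-vein edges, and its
large communities trace the venous tree.

## The procedure

Given a 4D BOLD series and a brain mask on the same voxel grid,
`veinclust()` performs:

1. **Temporal band-pass, 0.01–0.2 Hz.** A 4th-order Butterworth band-pass
   applied forward–backward (zero phase) to every voxel time course. The
   band excludes scanner drift and DC below 0.01 Hz and cardiorespiratory
   fluctuations above 0.2 Hz, so surviving correlations are genuinely
   low-frequency.
2. **Voxelwise correlation graph.** Pearson correlations between all pairs
   of in-mask voxels, computed tile-by-tile so the dense N×N matrix is
   never materialized (N is routinely 10^5 in real data; the result is
   independent of the tile size). Every in-mask voxel is a node; pairs with
   |r| at or above the binarization threshold become edges weighted by the
   signed coefficient. The graph is simple by construction.
3. **Sparsity-driven threshold selection.** The threshold is the largest
   value t in the descending grid 1.00, 0.99, … whose graph satisfies
   S = log E / log K < 4, with E the edge count and K = 2E/N the average
   degree. Graphs with E = 0 or K ≤ 1 are treated as *not* satisfying the
   criterion: a near-empty graph would otherwise trivially select t = 1.0
   on pure noise, contradicting the thresholds this criterion is meant to
   produce (roughly 0.6–0.95 on real data). Because all candidate edge
   counts are accumulated in a single pass over the tiled correlations, the
   scan costs one sweep regardless of how many steps it visits.
4. **Fast-greedy modularity clustering.** Agglomerative community
   detection in the style of Newman's fast-greedy algorithm: starting from
   singletons, repeatedly merge the connected pair of communities with the
   largest modularity gain, and cut the merge sequence at maximum Q.
   Modularity is the standard weighted form
   Q = Σ_c (e_c/m − (d_c/2m)²).
5. **Pooling.** All communities with ≥ 50 voxels (inclusive) are pooled
   into one venous-voxel mask. On sparse graphs the algorithm can return
   whole connected components as communities; for the purpose of pooling
   large coherent voxel sets this is acceptable.
6. **Validation utilities.** Overlap of the pooled mask with a reference
   vein mask; the "brain edge" (in-brain voxels removed by eroding the
   brain mask with a 5×5×5 box kernel — superficial veins sit there);
   Welch comparison of temporal SDs inside vs. outside the mask; and seed
   correlation maps for visual inspection.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `low_hz`, `high_hz` | 0.01, 0.2 Hz | pass-band of the temporal filter |
| `s_max` | 4 | sparsity bound on S = logE/logK |
| `start`, `step` | 1.0, 0.01 | threshold scan grid |
| `min_cluster_size` | 50 voxels | inclusive pooling threshold |
| `kernel_width` | 5 voxels | brain-edge erosion kernel |
| `tile_size` | 512 columns | memory/speed trade-off only; no effect on results |

## Numerical choices

* **Filter realization.** Zero-phase filtering uses odd-reflection end
  padding with steady-state initial conditions. A single forward–backward
  sweep leaves a direction-dependent edge transient (narrow-band filters
  settle slowly), so the sweep is run in both time orders and averaged;
  the antisymmetric part of the transient cancels, a symmetric pulse maps
  to an exactly symmetric output, and the steady-state gain remains
  |H(f)|². The design is validated in the tests against the filter's
  analytic frequency response and, for the recursion core, against an
  independent IIR implementation.
* **Inclusive thresholding.** "Above the threshold" is implemented as
  |r| ≥ t. With a 0.01-quantized scan the boundary is otherwise arbitrary,
  and inclusivity makes the identical-columns case (r = 1.0 at t = 1.0)
  well-defined. Correlations are clamped to [−1, 1], and values within
  1e-12 of ±1 are snapped, so numerically perfect pairs survive t = 1.0.
* **Edge weights for clustering.** Thresholding is on |r| and both signs
  are kept on the stored edges, but modularity with negative weights is
  ill-defined for the greedy merge rule, so the optimizer consumes |r|.
  Sign-flipped venous branches (draining geometry can invert the BOLD
  polarity) therefore cluster together with the rest of the tree.
* **Determinism.** Ties in the merge gain are broken toward the
  lexicographically smallest community-id pair, and ties in the maximum-Q
  cut toward fewer communities. Zero-variance voxels form no edges, remain
  isolated singletons, and can never enter the pooled mask. The whole
  pipeline is deterministic given its inputs.
* **Erosion at volume borders.** Out-of-bounds neighbours count as
  background, so the brain edge includes voxels at the volume boundary.
  The erosion is computed with separable running box sums and is verified
  against a brute-force neighbourhood oracle.
* **Grid discipline.** Series and masks must share shape and affine (max
  abs difference ≤ 1e-4); the pipeline refuses mismatched grids rather
  than resampling, since all comparisons are defined in EPI space. A
  missing repetition time in a NIfTI header is an error rather than a
  guess, because the TR drives the filter design.

## The synthetic phantom

No benchmark dataset with voxel-level venous ground truth exists at desk
scale, so `generate_phantom()` builds one embodying exactly the structure
the method assumes:

* an ellipsoidal "brain" of ~4900 voxels in a 32×32×16 grid
  (1.7×1.7×4 mm voxels), scanned for 600 volumes at TR = 0.333 s;
* three contiguous 100-voxel vein branches grown as self-avoiding
  axis-aligned random walks (tubular, like real veins, without a vascular
  model), all sharing **one** band-limited (0.01–0.2 Hz) signal, one branch
  sign-flipped;
* two 150-voxel network regions, each with its own shared band-limited
  signal at a moderate correlation level;
* independent Gaussian background noise elsewhere, zero outside the brain.

Pairwise correlation targets are set through the noise-to-signal variance
ratio: a voxel carrying unit-variance shared signal plus independent noise
of variance ε² correlates with a same-signal voxel at ρ = 1/(1 + ε²), so
ε² = 1/ρ − 1. Defaults are ρ = 0.9 within veins and ρ = 0.4 within
networks, mirroring the field observation that adjacent venous voxels
correlate above typical binarization thresholds while parenchymal
network correlations stay well below them. Vein voxels are rescaled to
1.8× the background temporal SD, with mild lognormal per-voxel SD jitter
(sdlog 0.2) so the vein and background SD distributions overlap — on real
data the SD boundary is not clear-cut, which is precisely why a
one-dimensional SD threshold is insufficient.

One consequence of the sparsity criterion shaped the brain size: with a
300-voxel vein system the complete within-vein graph has E = C(300,2) =
44850 edges, and S = logE/log(2E/N) < 4 then requires N ≲ 6100 in-mask
voxels. Within that bound the scan halts while the graph is still almost
purely venous; far above it the scan would be forced deep enough that
diffuse network correlations enter the graph. The default ellipsoid
(~4900 voxels) sits inside this regime, which is the regime the method
targets on real data as well — there, vein systems are proportionally
larger (the identified masks span ~6–18% of the brain).

The generator consumes a single seeded RNG stream in a documented order
(vein geometry, network geometry, shared signals, noise, SD jitter), so a
fixed spec reproduces bit-identical data.

**What the phantom does not model:** hemodynamic response shapes, motion
and scanner drift, spatial autocorrelation of the noise, partial-volume
effects, multi-subject variability, and the continuum of vessel calibers.
Recovery results on the phantom therefore demonstrate the algorithm's
correctness under its own assumptions, not its sensitivity or specificity
on real MRI data, which in the source literature is assessed against
SWI-derived vein masks.

## Problem sizes used in the tests

Module-level tests run on a 16×16×10 phantom (240 volumes, two 60-voxel
branches, one 40-voxel network; ~440 in-mask voxels), where a full
pipeline run takes about a second. End-to-end and recovery checks use the
default phantom above (~4900 nodes, ~3.4×10^4 edges at the selected
threshold), chosen so that the complete analysis — filtering, a full
tiled correlation sweep, the scan, clustering, pooling and validation —
exercises every stage at a size where exhaustive oracles (brute-force
correlation loops, per-threshold rescans, exhaustive partition
enumeration up to 10 nodes) remain feasible alongside it.

## Known limitations

* The fast-greedy optimizer is the referenced method's standard
  agglomerative scheme; alternative community algorithms (Louvain,
  Infomap, spectral) are deliberately out of scope.
* Inputs must already be skull-stripped, motion-corrected and on a single
  grid; no registration, resampling or SWI segmentation is provided.
* On graphs whose largest communities are whole connected components the
  modularity cut is degenerate but harmless for pooling (see above).
* The per-subject report covers one subject per run; cohort summaries are
  a matter of aggregating report files.
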