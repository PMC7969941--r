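---
title: "Seed-based probabilistic liver segmentation: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based probabilistic liver segmentation: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(liverseg)
```

## The problem and the modelling idea

Liver CT segmentation is hard for reasons that have little to do with noise:
adjacent organs (heart, kidney, stomach wall) absorb X-rays almost identically
to liver parenchyma, the organ's interior is inhomogeneous, and its complex
but singly connected 3D shape appears as several disconnected regions on
individual axial slices. `liverseg` implements a semi-automatic pipeline that
asks the user for exactly one voxel inside the liver and builds everything
else from the image itself — no training data, no statistical shape model.

The chain is: display windowing → seed-patch tissue model → per-voxel
probability map → relaxation labeling → per-slice graph cut (in parallel with
an Otsu binarization of the map) → bottleneck detection with an
adjacent-contour constraint. Each stage is exported on its own
(`apply_window()`, `local_stats()`, `fit_mnd()`, `probability_map()`,
`rl_refine()`, `min_cut_segment()`, `polish_volume()`), so the pipeline can be
dissected, and `segment_liver()` runs it end to end.

## The tissue model

CT intensities are calibrated (HU), so a normal model over low-order
statistics is defensible. The classification feature of a pixel is not its
intensity but the pair

$$\mathbf{f}(p) = (\mu_p, \sigma_p),$$

the mean and standard deviation of windowed intensities over the pixel's
11 × 11 neighbourhood (mirror-padded at slice borders; the standard deviation
uses the population divisor). Averaging over a window suppresses imaging
noise — which is why no denoising pre-processing is needed — and the local
standard deviation separates homogeneous parenchyma from textured or
boundary-crossing regions.

The subject-specific model is a bivariate normal fitted to the features of
the 11 × 11 patch around the seed: the patch's per-pixel features are the
sample, their sample mean is $\bar{\mathbf{f}}$ and their sample covariance
(plus a 10⁻⁶ ridge) is $\Sigma$. The ridge keeps a perfectly homogeneous
patch — common in noise-free synthetic data — invertible rather than fatal.
A voxel's liver probability is its model density normalised by the density at
$\bar{\mathbf{f}}$, which places the map in [0, 1] with
$P(\text{background}) = 1 - P$; the normalisation leaves the graph-cut
argmin unchanged (it shifts both log-costs by the same constant).

Features are computed on *windowed* intensities (W = 150, L = 80 HU, the
standard liver display preset, values kept as reals in [0, 255]): a model
built on raw HU would either depend on per-site display calibration or have
to span the full HU range, noise included. One documented consequence is
that the probability map is invariant to a constant HU shift only while both
the shifted and unshifted intensities stay inside the window's linear range
(tested in `test-mnd-model.R`).

## Relaxation labeling

The map is refined by five synchronous updates

$$P^{t+1}_p(\lambda) \propto P^{t}_p(\lambda)\,\bigl(1 + S_p(\lambda)\bigr),$$

where the support $S_p(\lambda)$ is the weighted sum of the same class's
probabilities over the eight in-plane neighbours (identity compatibility),
with inverse-Euclidean-distance weights normalised to sum to one (axial :
diagonal = √2 : 1). Five iterations is a deliberate stop well short of
convergence: enough to remove isolated misclassified pixels and consolidate
dispersed regions, few enough not to round off genuine boundary detail. The
update is strictly 2D — extending the neighbourhood through slices would
couple it to the (much coarser, anisotropic) z axis. Unanimous
neighbourhoods are absorbing and the uniform map is a fixed point, both of
which are tested as invariants.

## Graph cut

Each slice is labelled by exactly minimising

$$E(\mathcal{L}) = \alpha \sum_p R(C_p) +
  (1-\alpha) \sum_{p \sim q,\ C_p \neq C_q} B(p, q),$$

with $R(c) = -\ln P(p \mid c)$ (probabilities clamped at 10⁻¹⁰ so certain
pixels stay finite), the boundary affinity
$B = \exp\!\bigl(-(I_p-I_q)^2/2\sigma^2\bigr)/\mathrm{dist}(p,q)$ over
8-connected pairs (dist ∈ {1, √2} pixels), and α = 0.5. The boundary sum is
charged only across label disagreements (Potts convention) — without the
disagreement indicator the term would be constant and the energy degenerate.
All boundary weights are non-negative, so the energy is submodular and the
s-t min-cut solution is the global minimum.

Two numerical choices are ours. The noise scale σ is estimated from the
slice as 1.4826 × the median absolute axial neighbour difference (a robust
estimator consistent for Gaussian noise), floored at 1 to avoid division
blow-up on constant slices. And the solver is a compiled Dinic max-flow
(`src/mincut.cpp`): generic max-flow routines without vision-style
heuristics can be orders of magnitude slower on these grid instances, whose
binary region costs create a large source-saturated plateau. The solver
sits behind `solve_min_cut()` (costs in, labels out), so the exhaustive
enumeration oracle can replace it; the test suite verifies the labeling
attains the brute-force minimum on dozens of random 2 × 2 and 3 × 3
instances and beats the trivial baselines (all-0, all-1, thresholding) on
larger ones.

## Post-processing: propose with bottlenecks, decide with neighbours

Residual over-segmentation appears as nodal lobes attached to the liver
outline where tissue separation is fuzzy. Per slice, contours of both
segmentation routes (graph-cut labels; Otsu-binarized probability map) are
simplified to key points (Douglas–Peucker, 2 px tolerance, anchored at the
farthest-apart hull vertices so the result does not depend on the starting
vertex). A pair of key points is a *bottleneck* when the Euclidean gap
divided by the shorter connecting arc-length falls below 0.60 **and** both
exterior angles (360° minus interior; notches < 180°, convex corners > 180°)
are below 150°. The angle gate is what protects salient convex anatomy — a
pair across an elongated lobe can easily have a low cost, but its apexes are
convex and are never candidates (`test-postprocess.R` constructs exactly
this configuration).

Crucially, a detected bottleneck only *proposes* a removal. Cutting the
contour along the chord detaches the smaller lobe (pixel-count areas;
equal-area ties discard the lobe with smaller centroid x, then y) as a
separate candidate contour. The decision is then made by the
adjacent-contour constraint: sweeping outward from the anchor slice (largest
single contour; ties toward lower z), every candidate piece is kept iff its
best overlap ratio $S = |c \cap c'| / \min(|c|, |c'|)$ against the previous
accepted slice reaches $T_c = 0.8 - 0.05\,(d_z - 1)$, or it is the larger
member of its best pair. A genuine lobe — well supported by the neighbouring
slice — is re-attached; a spurious one is not. On the anchor slice itself no
neighbour evidence exists and detached lobes are dropped outright. We apply
bottleneck cutting to the contours of *both* routes before fusing: the routes
carry the same spurious lobes, and a lobe cut from one route but fused back
in from the other would undo the cleanup. The final mask is the union of
retained filled contours, so post-processing can only remove foreground,
never invent it (a tested invariant). If a slice loses every contour, the
sweep keeps the last non-empty slice as reference rather than re-anchoring.

The thicker the slices, the more shapes legitimately change between
neighbours, hence the 0.05 per-mm relaxation of $T_c$. The per-candidate
matching uses the *best* reference pairing rather than quantifying over all
pairs: a universal quantifier would delete large valid contours merely
because some small spurious contour overlaps them poorly.

## Evaluation metrics

`evaluate_masks()` implements the five-metric battery: volumetric overlap
error, signed relative volume difference $100(|A|-|B|)/|B|$, and the
average / RMS / maximum symmetric surface distances over 6-neighbour-exposed
surface voxel centres in physical mm, computed with an exact anisotropic
Euclidean distance transform (`src/edt.cpp`) so whole-volume surfaces cost
linear time. Scores follow $\max(100 - 25\,e/\bar e,\ 0)$ — 100 at zero
error, 75 at the reference error $\bar e$, 0 at four times it — with the
magnitude used for the signed RVD. The reference errors are deliberately
*not* defaulted: they are an external calibration (average human rater
errors on a given dataset), and hard-coding any particular value would bake
a dataset into the package. Metrics are always reported raw alongside any
scores.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds the study conditions the pipeline targets, at a
scale a desktop test suite can afford:

* a lobed liver (union of three overlapping ellipsoids), singly 26-connected
  in 3D but appearing as ≥ 2 regions on some slices;
* an adjacent organ of overlapping intensity (default 100 HU vs liver
  110 HU) joined by a thin neck, to exercise bottleneck removal;
* smooth sinusoidal intensity inhomogeneity (amplitude 10 HU), Gaussian
  noise (sd 12 HU), background at −20 HU — all inside the W150/L80 window;
* geometry and noise on separate sub-seeds, so ground truth never depends on
  the noise draw.

The default grid is 48 × 320 × 320 at 0.7 × 0.7 × 2.0 mm. Both in-plane and
z scales were chosen to respect, at reduced size, two properties of the
clinical data the method was designed for. First, the 11-px feature window
cannot support the outermost ≈ 5 px of boundary (any window straddling the
boundary yields a feature far from the model), so recovery quality is
governed by the liver's diameter *in pixels*; clinical livers span roughly
200–300 px on 512² slices, and the phantom liver spans ≈ 190–220 px. Second,
the adjacent-contour constraint assumes shapes change little between
neighbouring slices; at 2 mm spacing that requires lobes of clinically
plausible z-extent (the phantom liver spans 72 mm in z — lobes much flatter
than that genuinely violate the assumption and get their z-tips clipped, a
behaviour we reproduced and document rather than hide).

What the phantom does **not** emulate: real parenchymal texture, lesions,
vessels (other than the optional synthetic tube), respiratory artefacts,
partial-volume effects, and anatomy beyond one adjacent organ. Passing the
phantom tests therefore demonstrates the machinery — model fitting, exact
optimisation, anatomical cleanup — under controlled conditions, not clinical
accuracy.

Two phantom-derived checks anchor the end-to-end suite: the noise-free clean
phantom is recovered with Dice ≥ 0.90 (the residual deficit is precisely the
window-support erosion, visible as a negative RVD with zero false-positive
volume), and an adjacent organ — whether 10 HU away (excluded by the model)
or at identical intensity joined by a wide neck (cut at the neck and removed
by the constraint) — contributes at most 10 % of its volume to the output.
The vessel-extraction mode (probability map + relaxation + Otsu, no graph
cut, no anatomical constraints) is validated on a synthetic bright tube of
36 px radius: the same ≈ 5 px erosion bounds the recoverable radius, which is
why a thin-vessel phantom is not a meaningful target for this feature set.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `window`, `level` | 150, 80 | HU | liver display window; fixed across subjects |
| `patch` | 11 | px | feature window and seed patch side (odd) |
| `rl_iters` | 5 | — | relaxation updates (deliberately short of convergence) |
| `alpha` | 0.5 | — | region vs boundary balance of the energy |
| `tb` | 0.60 | — | bottleneck cost threshold (gap / shorter arc) |
| `angle_max` | 150 | degrees | exterior-angle gate for bottleneck candidates |
| `approx_tol` | 2.0 | px | polygon simplification tolerance |
| `tc_base`, `tc_slope` | 0.8, 0.05 | —, per mm | contour-constraint threshold $0.8 - 0.05(d_z-1)$ |
| `ridge` | 10⁻⁶ | — | covariance regulariser |
| eps clamp | 10⁻¹⁰ | — | floor inside the log region costs |

`alpha` and `angle_max` are the two genuinely empirical knobs;
`sweep_parameters()` re-runs the pipeline over a grid of both and scores
against a reference for exactly this exploration.

## Degenerate inputs and tie-breaks

Constant seed patches warn and fall back to the pure-ridge covariance;
constant slices floor the σ estimate at 1 and produce an empty Otsu mask
with a warning; probabilities of exactly 0/1 are clamped inside logs;
anchor-slice ties break toward lower z; equal-area bottleneck lobes discard
the smaller-centroid lobe; contours with fewer than four vertices skip
bottleneck analysis; an empty reference slice leaves the current slice
unconstrained (with a warning); single-slice volumes receive bottleneck
cleanup only. Otsu's threshold maximises 256-bin between-class variance and
takes the first bin on a flat plateau — the resulting *mask* is what is
compared against the exhaustive-sweep oracle.

## Problem sizes used in validation

The test suite runs the full pipeline on the default 48 × 320 × 320 phantom
(three configurations: clean, necked, identical-intensity organ) and uses
12 × 96 × 96 phantoms for determinism, sweep and I/O properties; graph-cut
exactness is checked by exhaustive enumeration on 2 × 2 and 3 × 3 instances,
and metric equivalence against O(n²) brute-force oracles on ≤ 20³ masks.
These sizes were chosen so the entire suite completes in a few minutes on a
single CPU while still exercising every stage at realistic relative scales.

## Known limitations

* **Single-patch model.** One seed patch cannot capture strong intensity
  inhomogeneity: liver regions whose local mean drifts more than a few HU
  from the seed neighbourhood lose probability mass. Multi-seed model
  building is the natural extension and is deliberately out of scope.
* **Boundary erosion.** The 11-px feature window bounds achievable boundary
  accuracy to ≈ 5 px per slice edge; thin structures (vessels ≲ 25 px
  diameter) cannot be recovered by the vessel mode.
* **2D context.** Relaxation and graph cut are per-slice; cross-slice
  consistency is enforced only by the contour constraint, which assumes
  gentle inter-slice shape change and will clip structures that violate it.
* **Healthy-liver focus.** The anatomical constraints encode a normal liver;
  boundary lesions of background-like intensity defeat them by design.
* **Persistent neighbours.** A disjoint organ that overlaps itself
  consistently across many slices passes the adjacent-contour constraint;
  only attached (bottlenecked) or slice-transient over-segments are removed.
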