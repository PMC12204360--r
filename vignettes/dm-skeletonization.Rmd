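---
title: "Persistence-guided discrete Morse skeletonization of axon images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistence-guided discrete Morse skeletonization of axon images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmskel)
```

## The problem

Tracer injections label the axons of many neurons at once. In 2D microscopy
sections these axons appear as thin, bright, curvilinear structures with
Y-junctions, variable label intensity, and short stretches where the signal
almost vanishes. Classical skeletonization (binarize, then thin to a medial
axis) breaks exactly where the biology is most interesting: at faint
segments and gaps, where a hard threshold removes the evidence before the
skeleton is formed.

`dmskel` instead treats the likelihood image as a scalar landscape
$\rho : K \to \mathbb{R}$ on the grid cubical complex and extracts its
*mountain ridges*: the 1-unstable manifold formed by gradient paths that
connect local maxima through their intervening saddles. Because a ridge is
a global object, it passes *through* a low-intensity gap as long as the two
bright sides are joined by a saddle of sufficient height — this is the core
advantage over thinning, and the package's evaluation module quantifies it.

## The skeletonization model

**Filtration.** The superlevel sets $\{\rho \ge t\}$ are filtered as $t$
decreases. Connected components are born at local maxima and die when two
components merge at an edge; the merging edge is the discrete saddle. With
the upper-star convention used here, an edge enters the filtration at the
minimum of its endpoint values, so the saddle of a ridge between two peaks
is the lowest point of that ridge. The pairing (maximum, saddle) is computed
by a union-find sweep with the elder rule: the component whose maximum is
lower dies. Its persistence, birth value minus death value, scores the
importance of the ridge feature.

**Determinism.** Equal values are totally ordered by (value, linear pixel
index), with the lower index treated as older. Every downstream operation —
the ascent forest, plateau drainage, saddle retention, fragment walks —
derives its tie-breaks from this one order, so identical inputs always give
byte-identical outputs.

**The graph.** `extract_morse_graph(field, delta, floor)` retains each
merging saddle whose persistence is at least `delta` and whose edge value is
at least `floor`, together with the two ascending V-paths from the saddle's
endpoints to their maxima, traced along the steepest-ascent forest
(`steepest_ascent_forest()`).

**Plateaus.** Discrete images have ties, and a constant-height ridge is a
perfectly legitimate input. A flat connected region is treated as one
(degenerate) critical set: a maximal plateau drains deterministically to a
single root, and when a V-path reaches a flat summit — or when a summit is
essential (it never dies) — the summit's entire internal drainage tree is
included in the graph. On tie-free fields this addition is empty and the
construction reduces to the textbook saddles-plus-V-paths output; on a
noiseless constant ridge it returns exactly the ridge polyline, which is
what the tests assert.

**Simplification.** The persistence threshold is deliberately run *low*:
its job is to define the graph, not to denoise it. Noise suppression is the
role of the third stage, following the mask → maximal spanning forest →
haircut order:

1. `otsu_mask()` binarizes the (smoothed) likelihood at the threshold
   maximizing between-class variance over a 256-bin histogram, and
   `mask_graph()` removes graph nodes in low-likelihood background.
2. `max_spanning_forest()` keeps, per connected component, the spanning
   tree of maximal total edge weight, with an edge weighted by the mean of
   its endpoint densities — cycles are broken at their weakest link.
3. `haircut()` prunes every branch-to-endpoint path of at most
   `max_len_px` edges (default 10) whose axial step sequence changes
   direction at most once. These short, nearly straight "hairs" are the
   signature of a ridge wandering to a nearby noise maximum; genuinely
   tortuous short branches are retained by the direction-change rule. The
   pass is applied once, on the spurs present in the input forest, not
   iterated to a fixpoint — iterating would progressively eat real terminal
   branches.

`extract_fragments()` then decomposes the simplified graph into maximal
paths between critical points (branch points, degree $> 2$; endpoints,
degree 1), with pure cycles emitted as closed fragments anchored at their
minimum-index node, and `to_vector_document()` writes the polylines as
GeoJSON LineStrings in planar micrometer coordinates.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `smooth_sigma` | 1 | px | Gaussian pre-smoothing of the likelihood |
| `delta` | — (choose per dataset) | likelihood | persistence threshold; keep low, let masking denoise |
| `floor` | 0 | likelihood | minimum retained saddle height in unmasked use |
| `haircut_len_px` | 10 | px | maximal pruned spur length |
| optical thickness | 2.5 (whole-slide), 3 (two-photon) | µm | slab each 2D image represents |
| section spacing | 40 (whole-slide), 50 (two-photon) | µm | distance between imaged sections |
| analysis voxel | 100 | µm | grid for projection densities and surprise |
| `Dr` | 5 (whole-slide), 3 (two-photon) | px | evaluation matching radius |

`sweep_delta()` reports retained-saddle and graph-size curves over a grid
of thresholds to guide the choice of `delta`. On the bundled phantom at its
default noise level, `delta = 0` with Otsu masking is the recommended
setting: the within-ridge intensity fluctuations are of the same order as
the background noise, so any threshold high enough to kill noise saddles
also severs real ridges, and the mask/forest/haircut stages are the right
tools for the residual clutter.

## Density summarization

`rasterize_density()` converts fragments to an areal line density: each
unit segment contributes its physical length, divided by the pixel area, to
the pixel containing its midpoint (midpoints on pixel borders go to the
lower index — a deterministic tie rule). This makes total length exactly
conserved: summing density times pixel area recovers the fragment lengths
to machine precision, which the tests assert at $10^{-9}$ relative.

Dividing by the effective optical thickness (`to_volumetric()`) yields
length per volume. Imaged sections are spaced more widely than the optical
slab, so `interpolate_sections()` inserts
$\mathrm{round}(\mathrm{spacing}/\mathrm{thickness}) - 1$ intermediate
planes by linear interpolation along the section axis — 15 planes for 40 µm
spacing at 2.5 µm thickness. The last imaged slab is extended by the same
number of replicated planes so every section stands for a full spacing of
tissue; with identical slabs the interpolation then multiplies the total
integrated length by exactly spacing/thickness, the stated multiplication-
factor property. For the two-photon geometry (50/3) the ratio is not an
integer; `round()` is applied and the nearest plane count (16, i.e. ~15
intermediates) is used.

Fragment vertices can be pushed through an externally supplied dense
displacement lookup (`displacement_transform()`, nearest or bilinear) with
connectivity untouched; estimating such transforms is out of scope here.
`integrate_compartments()` sums density × voxel volume per label and
reports lengths in meters with their log10, and `voxelize_swc()` rasterizes
single-neuron morphologies by subdividing each segment into quarter-voxel
pieces accumulated at their midpoints, conserving cable length exactly.

## The surprise index

For a tracer-injection density $p$ and a single neuron's normalized
voxel-wise length distribution $q$ on the same voxel grid, the surprise is
the relative entropy in bits:

$$S = \sum_{i\,:\,q_i > 0} q_i \log_2 \frac{q_i}{p_i},$$

with $0 \log 0 = 0$ by continuity. $S = 0$ iff $q = p$ on the union
support ("a typical neuron"); for $p$ uniform over $n$ voxels a point-mass
$q$ scores $\log_2 n$; the most surprising neuron concentrates on the
weakest projection voxel and scores $-\log_2 \min_i p_i$. Base 2 is used
throughout so the limiting cases come out in round bits; where the
literature mixes natural-log and log2 forms of the maximum, the log2 form
is the one consistent with the definition above.

Single neurons are traced in different brains than the tracer, so $q$ can
occupy voxels where the estimated $p$ is zero. `fill_support()`
interpolates $p$ into exactly those voxels by inverse-distance-weighted
$k$-nearest-neighbor averaging over the positive voxels (defaults $k = 6$,
the 3D face-neighbor count, power 1) and renormalizes so $p$ remains a
distribution; renormalization is required for $S$ to be a true divergence
and perturbs small fills only marginally. `surprise_report()` summarizes a
set of scores as a histogram plus Pearson and Spearman correlations between
$\log_{10}$ total length and $S$ (both are reported because the choice is
not canonical).

## Evaluation

`match_pixels(pred, gt, Dr)` matches predicted to ground-truth skeleton
pixels one-to-one within Euclidean radius `Dr`, greedily in increasing
distance with index tie-breaks, so a ground-truth pixel contributes only
once. The counting clauses are applied literally: TP = matched predictions;
FP = predictions neither matched nor lying on a ground-truth pixel; FN =
ground-truth pixels neither matched nor lying on a prediction. Precision,
recall, F1 and IoU = TP/(TP+FP+FN) follow. Greedy matching is the
documented algorithm; the tests compare it against an optimal bipartite
assignment and show it is maximal (never leaves a matchable pair unmatched)
and at least half-optimal, attaining the optimum on thin skeleton-like
inputs while falling short on dense random blobs.

The baseline for comparison is `thin_skeleton()`, a Zhang–Suen two-subpass
morphological thinning applied to the Otsu-binarized image — the classic
medial-axis-style route that cannot see below its threshold.

## The phantom generator

`generate_phantom()` draws correlated random walks (default 3 trees on a
192×192 px grid at 1 µm/px, step 2 px, turn at most 15° per step,
stochastic Y-branching) and rasterizes the centerlines as minimal
4-connected digital curves: the ground-truth skeleton. The image renders
each centerline with a unit-peak Gaussian cross-section (σ = 1 px),
rescaled so a straight line's interior reads its branch intensity (drawn
from U(0.8, 1)) and its ends stay above half of it; gap runs (8% of
centerline pixels, up to 3 px long) are attenuated to 10% of the branch
intensity — faint, not absent, as real label gaps are; clipped Gaussian
background noise (σ = 0.05) is added. Branches whose raster is shorter
than 12 px are discarded: a true branch at or below the haircut scale is
indistinguishable from a hair by construction, so keeping them would only
measure that ambiguity. All randomness comes from one seed and the
caller's RNG state is restored.

What the phantom does *not* emulate: anisotropic point-spread functions,
intensity falloff with depth, autofluorescent blobs and vasculature,
section-boundary artifacts, and densely labeled injection-site cores.
Passing the recovery tests therefore shows the pipeline is correct and
robust at realistic signal-to-noise with gaps and junctions; it does not
certify performance on whole-brain data with those artifacts.

## Numerical and design choices

- **Superlevel vs. sublevel.** Ridges of bright structures mean superlevel
  filtration of $\rho$ (equivalently sublevel of $-\rho$); the sign
  convention is fixed here once and used everywhere.
- **4-connectivity.** The cubical 1-skeleton has axial edges only; no
  2-cells are needed because only 0-dimensional persistence and the
  1-unstable manifold are used. Every output edge is an axial grid edge.
- **Gaussian smoothing** uses separable convolution with reflect padding,
  which preserves constants and invents no values at borders; the kernel is
  truncated at 4σ and renormalized.
- **Spanning-forest weights** (mean endpoint density) are the natural
  companion of the ridge semantics: the tree keeps the highest-likelihood
  connectivity.
- **Direction changes** in the haircut are inequalities of consecutive
  axial unit steps — the simplest reading, stated so it can be revised.
- **Terminology.** The literature alternates between "1-unstable" and
  "1-stable" manifolds for the saddle-to-maximum structure; this package
  computes ascending paths from saddles to maxima and calls them V-paths
  throughout.
- **Units.** Internally densities are µm/µm² (areal) and µm/µm³
  (volumetric); compartment tables report meters. Mixed-unit display forms
  occasionally seen in print are avoided.
- **Problem sizes.** The test suite exercises exhaustive oracles at 8×8
  (boundary-matrix persistence, spanning-forest enumeration) and the full
  pipeline at 96–192 px tiles, sizes at which every oracle is feasible
  exactly and a complete run takes seconds.

## Known limitations

- Single image per invocation; an overlap-and-merge tiling mode for very
  large slides is not implemented.
- The haircut is one pass by design; heavily fragmented inputs may retain
  compound spurs (a hair on a hair).
- Greedy evaluation matching can undercount TP relative to an optimal
  assignment on thick, blob-like inputs; for 1-px-wide skeletons the two
  coincide in practice (and the tests show where they do not).
- Persistence is computed single-process; whole-brain-scale distributed
  computation is out of scope.
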