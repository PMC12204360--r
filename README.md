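# dmskel

Persistence-guided discrete Morse skeletonization of neuronal process
images, with biologically meaningful summarization and evaluation.

## What it does, and for whom

Tracer injections label many axons at once; in 2D microscopy sections they
appear as thin bright curves with junctions, intensity variation, and
faint gaps. Anyone who needs *centerlines* from such images — to measure
axon length per brain compartment, to build volumetric projection
densities, or to compare single-neuron reconstructions against bulk tracer
data — faces the weakness of classical skeletonization: binarize-then-thin
breaks at every faint stretch.

`dmskel` treats the likelihood image as a density field ρ on the grid
cubical complex and extracts the **1-unstable manifold**: the ridge
network formed by gradient paths connecting local maxima through their
saddles. Features are scored by 0-dimensional **persistence** (birth minus
death of superlevel-set components under the elder rule), so ridges of low
importance can be filtered while true ridges bridge *through* low-density
gaps. The raw Morse graph is then masked (Otsu), reduced to maximal
spanning forests, pruned of short straight spurs (*haircut*), and
decomposed into polyline fragments with recorded lengths:

    smooth -> extract_morse_graph -> mask -> max_spanning_forest
           -> haircut -> extract_fragments -> GeoJSON

Around the core the package provides:

- **Density summarization** — exact-conservation rasterization of fragment
  length to areal density (µm/µm²), optical-thickness division to
  volumetric density (µm/µm³), section interpolation
  (`round(spacing/thickness) − 1` intermediate planes, e.g. 40/2.5 → 15),
  application of supplied displacement-field coordinate transforms, and
  per-compartment length totals in meters.
- **Surprise index** — the Kullback–Leibler divergence in bits,
  `S = Σ q_i log2(q_i / p_i)`, of a single neuron's normalized voxel-wise
  length distribution q from a tracer-injection density p, with
  weighted-nearest-neighbor support filling so S stays finite.
- **Evaluation** — distance-tolerant one-to-one pixel matching within a
  radius Dr (each ground-truth pixel used once), giving precision, recall,
  F1 and IoU; plus a Zhang–Suen thinning baseline.
- **Phantom generator** — synthetic axon-like likelihood images with known
  centerlines (Gaussian profiles, branch-intensity variation, faint gaps,
  background noise), so the whole pipeline is testable without any data
  download.

## Worked example

```r
library(dmskel)

ph <- generate_phantom(phantom_spec(seed = 0))   # image + known centerline
sk <- dm_skeletonize(ph$field, delta = 0)        # low persistence threshold;
print(sk)                                        # masking does the denoising
#> dm_skeleton
#>   grid: 192 x 192 px (1 um/px)
#>   fragments: 34, total length 188 um
#>   critical points: 15 branch, 22 end

evaluate_skeleton(skeleton_mask(sk), ph$gt_skeleton, Dr = 3)
#>    TP FP FN precision    recall        f1       iou
#> 1 180 11 10 0.9424084 0.9473684 0.9448819 0.8955224

# the thinning baseline on the same image cannot cross the faint gaps
bl <- evaluate_skeleton(thin_skeleton(otsu_mask(ph$field)),
                        ph$gt_skeleton, Dr = 3)
round(bl$f1, 3)
#> [1] 0.801

# fragment length is conserved exactly through density rasterization
ar <- rasterize_density(sk$fragments, dim(ph$field$values), 1)
c(sum(fragment_lengths(sk$fragments)), integrated_length(ar))
#> [1] 188 188
```

The skeleton recovers ~95% of the known centerline (F1 0.945 at a 3 px
matching radius) and beats the binarize-then-thin baseline by ~0.14 F1 on
the same image, because the Morse ridges pass through the low-intensity
gaps that the threshold removes. Rasterized density sums back to the exact
fragment length — the conservation property the summarization stage is
built on.

A command-line interface wrapping the same functions ships in
`inst/cli/dmskel.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/dmskel.R", package="dmskel"))')
Rscript $CLI phantom --seed 0 --shape 192,192 --out-img img.tif --out-gt gt.png
Rscript $CLI skeletonize --input img.tif --delta 0 --out frags.geojson
Rscript $CLI evaluate --pred pred.png --gt gt.png --dr 3
```

## Layout

- `R/` — implementation: Morse core (persistence, ascent forest, graph
  extraction), skeleton post-processing, density summarization, surprise,
  evaluation, phantom generator, pipeline driver and IO.
- `tests/testthat/` — unit, property and acceptance tests, including
  brute-force oracles (boundary-matrix persistence reduction, exhaustive
  Otsu search, spanning-forest enumeration, per-voxel integration loops).
- `vignettes/dm-skeletonization.Rmd` — the methods vignette: model,
  parameters, numerical choices, generator realism, limitations.
- `inst/cli/dmskel.R` — command-line interface.
- `scripts/acceptance.R` — headline-quantity recomputation.
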