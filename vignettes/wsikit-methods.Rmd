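---
title: "Models and methods in wsikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in wsikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the models, conventions and numerical decisions
behind `wsikit`: what each subsystem assumes, which parameters matter and
why their defaults are what they are, what the synthetic fixtures do and do
not emulate, and where the design was genuinely open and a choice had to be
made.

## Coordinates, units and reads

Every location and region in the package lives in one reference frame: the
baseline (level 0) pixel grid, origin at the top-left, half-open integer
intervals. A resolution request (`resolution(value, units)`) is the second
half of every read: `mpp` targets a physical sampling resolution in
microns-per-pixel (scale = slide mpp / requested mpp, per axis, so
anisotropic scans are handled throughout), `power` an apparent
magnification, `level` a stored pyramid level, `baseline` a plain scale
fraction. A single frame plus an explicit request removes the per-level
coordinate ambiguity that multi-resolution formats otherwise invite.

Reads pick the stored level with the largest downsample `d` satisfying
`d <= 1/scale` — the smallest sufficient higher-resolution copy — and
resample the residual factor. A lower-resolution copy is never upsampled to
serve a sharper request; requests beyond the baseline resolution are served
from level 0 with a warning. Resampling is exact area averaging on the way
down (each output pixel is the mean of the source interval it covers,
implemented as separable row-stochastic weight matrices), Catmull-Rom cubic
convolution on the way up, and nearest neighbour whenever the raster is a
label image, so masks and class maps never acquire invented values.
Out-of-slide area is filled by constant padding (default 0), mirror
reflection, or refused (`pad_mode = "none"`).

`read_rect` fixes the output size — the field of view grows as the request
coarsens — while `read_bounds` fixes the field of view and lets the output
size scale. Both share one region-read core, which is why the two modes
agree pixel-wise when asked for the same field of view at the same scale.

Virtual readers (`as_virtual`) carry a donor slide's metadata and serve
reads by sampling a flat raster directly at output-pixel centres (bilinear
for intensity data, nearest for labels). Direct sampling avoids the double
rounding of a crop-then-resize path, which matters for small derived
rasters such as masks. The raster must match the donor's aspect within 1%
per axis, with a ±1 px allowance because small thumbnail dimensions are
themselves rounded.

## Tissue masking

Masking runs on a thumbnail (default: 32 µm/px when the slide is
calibrated, 1/32 of baseline otherwise — coarse enough to be instant,
fine enough for patch filtering). The luminosity channel is the minimum
over R, G and B: tissue is darker than glass in at least one channel
whatever the stain hue, which makes the statistic robust to
eosin-dominated or hematoxylin-dominated fields. Otsu's threshold then
maximises the between-class variance over the 256-bin histogram
(equivalently minimises intra-class variance; the implementation uses
cumulative moments and is tested against an exhaustive 255-split oracle;
ties take the smallest threshold). The darker class is tissue.

Morphology afterwards: closing with a square kernel, removal of tissue
components below `min_region_px`, filling of enclosed background holes
below `min_hole_px`. A hole is a background component that does not touch
the image border — without that restriction a blank slide would be
"filled" into all-tissue. The kernel side defaults to
`round(objective_power / mask_downsample * 2)` with floor 1, and both area
thresholds default to its square; all three are configurable. The order
(close, then remove regions, then fill holes) is a documented choice, not
a claim about any reference implementation.

A blank slide yields a degenerate single-bin histogram; the masker returns
an all-background mask with a warning rather than erroring, because blank
margins are a normal occurrence in batch runs.

## Patch extraction

Patch size and stride are specified in the output (requested-resolution)
frame and converted to baseline pixels once, with round-half-away-from-zero,
so grids cannot accumulate rounding drift. Grid counts follow the closed
forms `floor((L - p) / s) + 1` (discard-partial; 0 when the patch exceeds
the slide) and `ceiling(L / s)` (pad) per axis, verified against a walk-the-
anchors enumerator. Mask filtering measures the tissue fraction on the mask
raster at its native resolution with fractional-cell coverage weights;
out-of-slide area counts as non-tissue, and the default acceptance
threshold is 0.5. Point-centred patches anchor at
`point - patch_extent / 2` and rely on constant padding at slide edges so
the output size stays homogeneous. The iterator is a closure that performs
one `read_rect` per request — nothing is materialised ahead of demand.

## Stain model

The physical model is Beer–Lambert attenuation with a white point fixed at
255: `OD = -log10(max(I, 1) / 255)`, and a two-stain decomposition
`OD = C M` with unit rows of `M` ordered Hematoxylin first. The H row is
identified as the one with the larger blue-channel component (H absorbs
red/blue more than eosin does), with the red component as a deterministic
tie-break.

**Macenko.** High-density pixels (OD norm above `od_min = 0.15`) are
projected onto their top two singular directions; the stain vectors are
the directions at the 1st and 99th percentile of the projected angle. The
method assumes that some pixels are (nearly) pure in each stain — the
angular extremes. Rank deficiency is declared when the second singular
value falls below 2% of the first; that threshold sits well above the
off-plane energy that 8-bit quantisation injects (~0.2%) and well below
the second component of any genuine two-stain image.

**Dictionary learning.** A 2-atom nonnegative sparse dictionary is fitted
to the same high-density pixels by exact alternating minimisation of
`sum(|OD - C D|^2) + lambda * sum(C)`, `C >= 0`, atom rows in the unit
ball: the codes solve a two-variable nonnegative lasso in closed form
(interior KKT solution compared against the two single-atom boundary
solutions), the atoms solve per-channel two-variable NNLS, and atoms are
projected onto the unit ball after each sweep. Initialisation is
deterministic (means of the top and bottom deciles of the blue/green OD
ratio), pixels are subsampled to at most 5000 under the seed, and
convergence is declared when atoms move less than `5e-5` or the objective
stalls (relative change below `1e-8`), within 3000 alternations — the
slowest fixture converges in about 1200. The sparsity default is `0.001`:
the penalty must stay one to two orders of magnitude below the typical
per-pixel OD scale (~0.5), because a large penalty makes it optimal to
pull both atoms inside the data cone — trading a little residual on the
near-pure pixels for a large saving in code mass — and the recovered
vectors then stop being stains. With the small penalty the fit term
dominates, the optimum must cover the OD cone, and recovery on exact
Beer–Lambert fixtures is row-cosine ≥ 0.99.

**Concentrations.** Plain per-pixel ordinary least squares
`C = OD M' (M M')^{-1}` with negatives clipped to zero. Clipping (rather
than a constrained solve) is a deliberate speed choice; on non-degenerate
pixels the unconstrained solution is already nonnegative, so the two
differ only where noise pushes a tiny concentration below zero.

**Normalization.** Reinhard transfers per-channel mean and standard
deviation in LAB (via `grDevices::convertColor`); it is an exact fixed
point on its own target. Matrix-based normalization estimates the source
matrix and concentrations, rescales each stain by the ratio of target to
source 99th-percentile concentrations (a robust proxy for maximum stain
content), and reconstructs with the target matrix.

**Augmentation.** Per stain, `C' = alpha * C + beta` with
`alpha ~ U(1 ± sigma_alpha)`, `beta ~ U(±sigma_beta)` (defaults 0.2),
clipped at zero and reconstructed with the source matrix, deterministic
under the seed. Background pixels (OD norm below `od_min`) are exempted
from the additive shift so glass is never tinted. Images with too little
tissue to decompose pass through unchanged with a warning, since erroring
inside an augmentation pipeline would abort training.

## Inference engine

Models plug in through a contract: a task kind, input geometry and
resolution, and a pure batched inference function. Purity (same batch,
same output) is what makes results provably independent of batch size.
Patch classification runs grid → mask filter → lazy iteration → batched
inference; records go to a JSON-lines file (human-diffable,
streaming-friendly, byte-reproducible) and the merged map places each
patch's probabilities at its grid cell — one map pixel per stride step.
When strides overlap, footprints are *not* blended; the map is a grid of
per-anchor results, and this is documented behaviour.

Tiled per-pixel inference averages probability contributions where tiles
overlap and takes the argmax after averaging. Per-pixel models declare a
receptive-field `margin`; output pixels within the margin of a tile edge
are emitted as `NA` and excluded from the average. With
`overlap >= 2 * margin` every interior pixel keeps at least one
full-receptive-field contribution, which makes tiled inference *exactly*
equal whole-image inference on interiors for translation-equivariant
models — an equality the tests assert at 1e-6 — rather than approximately
equal under edge contamination.

Instance merging follows the overlapping-tile contract: instances touching
a tile's inner boundary (an edge not shared with the slide boundary) are
dropped — with overlap at least the largest instance diameter, each such
instance lies strictly inside a neighbouring tile — survivors are shifted
into the slide frame, and centroid duplicates within 1 px are removed.
Slide-level pooling is the usual multiple-instance max or mean over the
chosen class probability.

The shipped reference models (mean-intensity classifier, k×k box-filter
segmenter, colour-histogram featurizer) are not toys for show: they are
the test oracles' counterparts, chosen because their whole-image behaviour
is computable independently of the engine.

## Annotation store

Both backends implement one mapping surface (insert/get/delete/keys/
length; inserting an existing key overwrites). The database backend is a
single-file SQLite schema: an `annotations` table (key, geometry type,
properties as JSON text, WKB blob, centroid, and exact float64 bounds)
plus an R-Tree virtual table of bounding boxes and a key↔rowid bridge.
SQLite's R-Tree stores 32-bit floats widened to contain the true box, so
it is strictly a superset prefilter; window queries re-check candidates
against the float64 bounds in the main table, which is what makes the
indexed path return byte-identical key sets to a linear scan. Points store
no WKB at all — their coordinates live in the index row and centroid
columns and reconstruct exactly.

Geometry is OGC WKB (little-endian; point, line string, single-ring
polygon; closed rings double as linear rings), optionally wrapped in a
zlib (RFC 1950) deflate stream; round trips are vertex-exact because
coordinates are written as IEEE-754 doubles, and JSON documents use
17-significant-digit output for the same reason.

The predicate language is an R expression over `props` validated against a
whitelist (literals, comparisons, boolean connectives, arithmetic,
`%in%`, subscript/`$` access, `abs`/`min`/`max`/`length`/`is.null`)
*before* any evaluation; everything else is rejected outright — never
partially evaluated. Translatable predicates compile to SQLite
`json_extract` comparisons and run inside the database; anything else
falls back silently to interpreted filtering. The two paths returning
identical sets is a tested contract, including the convention that a
missing property never matches (SQL `NULL` comparisons and R's
`isTRUE(logical(0))` agree on this).

## Graph construction

Patches cluster under the blended distance
`D = lambda * d_xy / s_xy + (1 - lambda) * d_feat / s_feat`, each term
scaled by its population median so pixels and feature units are
commensurable, with average-linkage agglomeration cut at a height. This
operationalisation — median scaling, average linkage, default
`lambda = 0.5`, default cut at half the median blended distance — is this
package's own; at the endpoints it provably reduces to pure-spatial or
pure-feature clustering, and the cut height is monotone in cluster count.
Node centroids and features are member means. Edges default to Delaunay
triangulation of the centroids pruned at a centroid distance (default 4×
the median neighbour distance), with a symmetric k-NN rule as the
alternative; fewer than three (or degenerate) nodes fall back to pruned
complete linkage. Graph documents serialize to JSON at full floating-point
precision and round-trip bit-exactly.

## Zoomify tiles and overlays

Tier `t` of the pyramid has dimensions `ceiling(baseline / 2^(K-1-t))`
with `K = max(1, ceil(log2(max_dim / tile_size)) + 1)`, so the smallest
tier fits one tile and each tier doubles. Tiles are numbered tier-major
from the smallest tier, row-major within a tier, 256 per `TileGroup`
directory; edge tiles are cropped, not padded (the viewer convention), and
JPEG quality defaults to 85%. Overlays blend
`(1 - alpha) * base + alpha * colour` on covered cells only, so
unprocessed regions remain untouched; annotation overlays rasterize
polygons by even-odd scanline filling.

## Synthetic fixtures: what they do and do not show

The fixture slides are near-white backgrounds (Gaussian noise, sd 2 gray
levels) with elliptical tissue blobs whose colour follows the exact
Beer–Lambert model under smooth random concentration fields (coarse
uniform grids upsampled bicubically), written as tiled multi-page TIFFs
with resolution tags and a JSON sidecar of the exact layout. Pyramids are
built by repeated 2× area averaging, which makes level arithmetic exact.
Stained test images come with their exact generating matrix and
concentration fields; pixels that quantise to intensity ≤ 1 are flagged
saturated, because their optical density is clipped and no estimator can
recover them.

Because the generative model is exact, these fixtures give sharp oracles:
recovery failures are implementation errors, not model mismatch. The flip
side is equally important: the fixtures do not emulate scanner compression
artefacts, misaligned pyramid levels, pen marks, tissue folds, vendor
metadata dialects, or stains beyond an idealised H&E pair. Passing tests
therefore demonstrate the *machinery* — unit conversion, level selection,
resampling, estimation, indexing — not robustness to real-slide artefacts.
Test problem sizes (e.g. 1024×768 fixture slides, 128×96 stained images,
10,000-annotation stores, 200 randomized read requests) were chosen as the
smallest sizes at which the contracts are non-trivially exercised.

## Known limitations

* TIFF, PNG and JPEG only; no vendor-specific formats (JP2, DICOM,
  OME-TIFF, CZI) and no fluorescence channels.
* The in-package TIFF writer emits deflate or uncompressed tiles only.
* Pyramid levels are assumed registered; no inter-level alignment
  tolerance is modelled.
* Readers hold stored levels in memory, which is appropriate for fixtures
  and visual fields; a chunked backend would be needed for multi-gigapixel
  production slides.
* The annotation store has no concurrent multi-writer contract and no
  coordinate reference systems (slide pixels only).
* The dictionary stain estimator assumes exactly two stains.
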