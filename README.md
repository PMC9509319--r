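# wsikit

Whole-slide images (WSIs) are multi-gigapixel scans of glass pathology
slides, stored as multi-resolution pyramids with physical calibration
metadata (microns-per-pixel, objective power). Every computational-pathology
pipeline repeats the same plumbing around its model: read calibrated
regions, mask the glass background, cut the tissue into patches, correct
stain variation, run a patch-level model and merge the results back into
slide coordinates, store millions of output geometries, and serve the
results to a viewer. `wsikit` implements that plumbing as one coherent R
toolkit, for image-analysis researchers and bioinformaticians who build or
reproduce WSI pipelines:

* **Reading** — one reader interface over pyramidal TIFFs, PNG/JPEG visual
  fields and in-memory arrays. Every read is phrased in the baseline pixel
  frame plus a resolution request (`mpp`, `power`, pyramid `level`, or a
  plain `baseline` scale). `read_rect()` fixes the output size while the
  field of view varies; `read_bounds()` fixes the field of view while the
  output size varies. Reads resample from the best stored pyramid level
  (area averaging down, cubic convolution up, nearest neighbour for
  labels). `as_virtual()` wraps any derived raster (mask, prediction map)
  so it answers reads in the donor slide's coordinates.
* **Tissue masking** — Otsu's threshold (the 8-bit split minimising
  intra-class intensity variance) on a min-over-RGB luminosity thumbnail,
  plus morphological clean-up, returned as a virtual reader.
* **Patch extraction** — grid or point-centred patch coordinates with
  overlap, edge policies and tissue-fraction filtering; a lazy iterator
  reads patches on demand.
* **Stain tools** — Beer–Lambert optical density `OD = -log10(I/255)`
  decomposed as `OD = C M` with `M` the 2×3 unit-row stain matrix
  (Hematoxylin, Eosin) and `C >= 0` the pixel concentrations. `M` is
  estimated by Macenko's angle-percentile method or 2-atom nonnegative
  sparse dictionary learning; `C` by ordinary least squares with clipping.
  Normalizers: Reinhard (LAB mean/sd transfer) and matrix-based
  (99th-percentile concentration rescaling onto a target matrix).
  `stain_augment()` perturbs per-stain concentrations
  `C' = alpha C + beta` for training-time augmentation.
* **Inference engine** — any model enters through a small contract (task,
  input geometry, a pure batched `infer_batch`). The engine handles grids,
  masking, batching, JSON-lines record files, merged prediction maps,
  overlap-averaged tiled segmentation, per-patch feature tables, a generic
  overlapping-tile instance-merging rule, and max/mean slide-level pooling.
  Reference models (mean-intensity classifier, box-filter segmenter,
  colour-histogram featurizer) ship with the package, so the whole engine
  is testable without a deep-learning runtime.
* **Annotation store** — geometry + JSON-like properties behind a mapping
  interface, with an in-memory backend and a persistent SQLite backend
  (R-Tree bounding-box index, WKB geometry optionally zlib-compressed,
  points stored index-only). Queries: bounding box, exact polygon
  intersection, and a restricted predicate language over properties that
  compiles to SQL `json_extract` when translatable. GeoJSON / ndjson /
  table / mapping round trips.
* **Graphs** — hybrid location+feature agglomerative clustering of patches
  into tissue-region nodes with Delaunay or k-NN edges, for downstream
  graph learning.
* **Visualization** — Zoomify tile pyramids (`TileGroup*/z-x-y.jpg` +
  `ImageProperties.xml`) and alpha-blended overlays of maps or annotations.
* **Fixtures** — synthetic pyramidal slides (tiled TIFF with resolution
  tags and a JSON ground-truth sidecar) and Beer–Lambert stained images
  with exact concentration ground truth, so everything above is testable
  with no external data.

## Worked example

```r
library(wsikit)

# synthesize a calibrated pyramidal slide with two tissue blobs
spec <- slide_spec(1024, 768, n_levels = 3, mpp = 0.5,
                   objective_power = 40, seed = 7)
fx <- make_pyramid_slide(spec, "slide.tiff")
reader <- open_reader("slide.tiff", objective_power = 40)
reader$meta
#> <wsi_meta 1024 x 768 px, 3 level(s)>
#>   downsamples: 1, 2, 4
#>   mpp: 0.5, 0.5
#>   power: 40

# a 224x224 patch at 1.0 mpp (half the scan resolution)
patch <- read_rect(reader, c(100, 100), c(224, 224), resolution(1, "mpp"))
dim(patch)
#> [1] 224 224   3

# tissue mask, then classify 128 px patches with the reference model
mask <- make_mask(reader, res = resolution(16, "mpp"))
grid <- patch_grid_spec(c(128, 128))
res <- predict_wsi(model_mean_intensity(threshold = 220), reader, grid,
                   mask = mask)
nrow(res$coords)                      # patches kept by the tissue filter
#> [1] 14
pool_slide(res$records, rule = "mean") # slide-level mean tissue probability
#> [1] 0.8867277
```

The slide score is the mean over kept patches of the model's "tissue"
probability; with the mean-intensity reference model on this fixture the
14 tissue patches are all confidently dark, so the pooled score is near 1.

A command-line wrapper is installed as `exec/wsikit`:

```sh
wsikit fixtures make-slide --seed 7 --out s.tiff
wsikit tissue-mask s.tiff --out mask.png
wsikit tiles s.tiff --out zoomify/
```

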