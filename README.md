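# vegmorph

Connected attribute morphology for vegetation segmentation and crop/weed
classification in precision agriculture imagery.

Robotic weeding and selective spraying need a vision pipeline that (i)
separates vegetation from soil on an NDVI image and (ii) classifies each
plant region as crop or weed. Global thresholding (Otsu, RATS) handles
step (i) poorly under uneven lighting, textured soil or sparse vegetation,
and needs component labelling and noise clean-up before a region
classifier can run. `vegmorph` instead performs the whole pipeline on one
data structure, the **max-tree** (the hierarchy of connected components of
all upper level sets of the image), so every decision is local and the
segmentation emits described, labelled regions directly:

1. **Markers** — regional maxima (tree leaves) are ranked by grey-range
   *extinction values*; maxima with extinction < 10 grey levels are
   discarded as noise.
2. **Segmentation** — along each marker's branch, the growth factor over a
   span of Δ grey levels, `G(R_k) = (A(R_{k-Δ}) − A(R_k)) / A(R_k)`,
   spikes where a contrasted region merges into the background; the
   selected candidate is adjusted towards slightly larger, repeated
   (stable) regions, filtered by a minimal area `T`, and deduplicated by
   canonical node identity.
3. **Features** — each region is described by five incrementally computed
   attributes: solidity, eccentricity, moment-based circularity
   `A²/(2π(μ₂₀+μ₀₂+A/6))`, non-compactness `2π((μ₂₀+μ₀₂)/A² + 1/(6A))`
   (Hu's first invariant with the discrete correction), and grey range.
4. **Classification** — a two-class SVM over a fixed kernel grid with
   image-level 10-fold cross-validation, mixed-class duplication, exact
   class balancing, and confidence-based rejection
   (`p_crop = 1 − p_weed`).

Otsu and RATS baselines, pixel precision/recall/F1, interpolated PR
curves, and a deterministic synthetic-field generator (crop rosettes,
thin weed blades, textured noisy soil, per-pixel ground truth and
crop/weed/mixed region labels) are included.

## Worked example

```r
library(vegmorph)

field <- generate_field(field_spec(seed = 42))   # 512x512 synthetic NDVI
field$table
#>   region class area
#> 1      1  weed  633
#> 2      2  crop  605
#> 3      3  weed  809
#> ...

tree <- max_tree(field$image)
tree
#> max-tree: 6968 nodes (6084 leaves), 512 x 512 image, 4-connectivity

markers <- select_markers(extinction_values(tree), 10)
nrow(markers)          # 519 of 6084 maxima survive the contrast filter

seg <- segment_tree(tree, seg_params(t_area = 50))
seg$regions
#>   node level area   growth marker
#> 1   11    85  633 413.1295      1
#> 2   12    85  605 432.2959      2
#> ...                                 (8 regions, one per plant)

pixel_metrics(segmentation_mask(seg), field$truth)
#> TP=4687 FP=0 FN=0  precision=1.0000 recall=1.0000 F1=1.0000

round(region_features(seg$tree, seg$regions$node), 3)
#>   node solidity eccentricity circularity non_compactness grey_range
#> 1   11    0.877        0.994       0.211           4.729         45
#> 2   12    0.762        0.129       0.896           1.117         45
#> ...
```

The 6084 regional maxima of the noisy field collapse to 519 markers after
extinction filtering and to exactly one region per plant after stability
selection; the pixel F1 against the generator's ground truth is 1.0 here.
In the feature table the thin weed blades are immediately visible
(eccentricity ≈ 0.99, non-compactness 4.7–6.8) against the compact crop
rosettes (eccentricity ≈ 0.13, non-compactness ≈ 1.2); `cross_validate()`
runs the full image-level 10-fold protocol over such tables. From RGBN
input, `compute_ndvi()` and `quantize_ndvi()` produce the 8-bit NDVI
image first; `otsu_threshold()` / `rats_threshold()` give the global
baselines.

A command-line front end wrapping these functions is installed at
`inst/cli/vegmorph.R` with subcommands `segment`, `classify`, `synth` and
`eval`, YAML configuration and per-parameter flags (`--delta`, `--T`,
`--eta`, ...).

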