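# elemap

Post-processing of quantitative **LA-ICP-MS element maps** of small
biological specimens — prototypically laser-ablated whole zebrafish embryos
— for analysts who want to move beyond eyeballing color-coded intensity
images.  `elemap` links each ablation pixel to the **morphological
compartment** it belongs to (fish contour, yolk, eyes, notochord, ...),
segments the elemental image with clustering, and turns the result into
comparable, quantitative tables.

## What it computes

Given a per-pixel intensity table (columns `element1, element2, …, X, Y`;
cps and µm) and a set of annotated feature contours detected on a reference
microscope image, the workflow is:

1. **Registration.** The annotation frame (image pixels, v-axis down) is
   mapped onto the laser stage frame by an affine transform
   `(x, y)ᵀ = A (u, v)ᵀ + t`, estimated by least squares from landmark
   pairs, or by a rectangle-to-bounding-box fallback.
2. **ROI rasterization.** Each transformed contour becomes a pixel mask via
   a pixel-centre, even-odd point-in-polygon test with a half-open boundary
   rule (a centre exactly on an edge counts for the lower/left edge only,
   so adjacent compartments never double-claim a pixel).  Polyline features
   such as the notochord are buffered to one beam diameter.  Derived
   compartments are mask algebra, e.g. *fish body = fish contour − yolk*.
3. **Segmentation.** Feature matrices built from element channels (and
   optionally the coordinates), z-scored by default, are clustered with one
   of six algorithms: k-means (k-means++ seeding, best of 10 restarts),
   mean shift, affinity propagation, spectral clustering, DBSCAN and
   HDBSCAN.  Density-based noise pixels keep the label −1 as a first-class
   cluster.  `elbow_k()` picks k at the maximum discrete second difference
   of the within-cluster sum of squares.
4. **Cross-tabulation.** Cluster × ROI heatmap layers: overlap as a
   percentage of the ablation area, per-element mean intensity, and — after
   linear calibration `I = a·c + b` with 3.3σ/10σ detection limits —
   summed analyte amount in ng.  Zero-overlap cells stay empty rather than
   zero.
5. **Reproducibility.** Replicate heatmaps (labels canonicalized by mean
   reference intensity) are compared by Spearman rank correlation with
   mid-rank ties, pairwise-complete over non-empty cells.

A deterministic synthetic-embryo generator (`synth_scene()`,
`render_scene()`) produces annotation polygons, noisy element maps and
ground-truth region labels, so the whole pipeline is testable offline.

## Worked example

```r
library(elemap)

# simulate a 96-hpf-embryo-like specimen rasterized at the 35 um beam pitch
ds <- render_scene(synth_scene(seed = 1))
ds$grid
#> <pixel_grid> 3000 pixels, 5 elements (12C, 31P, 39K, 79Br, 127I)
#>   x: [17.5, 3482.5] um   y: [17.5, 1032.5] um   pitch: 35 x 35 um

# map the annotated features onto the laser stage frame and build ROI masks
ann  <- transform_annotations(ds$annotations, ds$scene$annotation_affine)
rois <- build_roi_set(ann, ds$grid,
                      derived = list(fish_body = list(op = "difference",
                                                      a = "body", b = "yolk")))

# segment the carbon channel; inspect the elbow curve, then cluster at k = 4
fm <- build_features(ds$grid, feature_spec("12C"))
round(elbow_k(fm, 1, 8, seed = 1)$inertia)
#> [1] 3000 1272  360   43   32   23   16   11
cl <- canonical_relabel(
  cluster_pixels(fm, "kmeans", list(n_clusters = 4), seed = 1),
  ds$grid, "12C")
round(cluster_area_pct(cl), 1)
#>    0    1    2    3
#> 53.2 39.3  5.7  1.8

# cross-tabulate clusters against body compartments
hm <- build_heatmap(cl, rois, ds$grid, elements = "12C")
round(hm$layers$count_pct[, c("body", "yolk", "eye_left", "total")], 1)
#>   body yolk eye_left total
#> 0  0.0  0.0        0  53.2
#> 1 39.3  0.0        0  39.3
#> 2  5.7  5.7        0   5.7
#> 3  1.8  0.0        1   1.8
signif(hm$layers[["mean_intensity:12C"]][, c("fish_body", "yolk")], 3)
#>   fish_body   yolk
#> 0        NA     NA
#> 1    121000     NA
#> 2        NA 291000
#> 3    703000     NA
```

Cluster 0 is the bare support (53 % of the ablation area, no carbon),
cluster 1 the fish body, cluster 2 the carbon-rich yolk and cluster 3 the
eyes — the densest tissue with the highest mean ¹²C signal (7.0 × 10⁵
cps).  Empty cells (`NA`) mark cluster–compartment pairs that share no
pixel.

Replicate agreement, after canonicalizing both label sets by mean ¹²C
intensity:

```r
compare_heatmaps(hm, hm2, "mean_intensity:12C")  # hm2: same analysis, seed 2
#> <correlation_result> rho = 0.9600, p = 1.07e-09 (t), n = 17 (15 dropped)
```

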