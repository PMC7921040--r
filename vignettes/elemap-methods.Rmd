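---
title: "Methods: segmentation and compartment analysis of LA-ICP-MS element maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation and compartment analysis of LA-ICP-MS element maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elemap)
```

`elemap` post-processes quantitative laser-ablation ICP-MS images of small
biological specimens.  Its premise is that an elemental image only becomes
interpretable when each ablation pixel is tied to the morphological
compartment it samples: the same bromine signal means something different
in the notochord than in the yolk.  This vignette describes the models and
conventions behind each stage, the tunable parameters, and what the
accompanying synthetic phantom does and does not demonstrate.

## Data model

An ablation image is a `pixel_grid`: an ordered list of laser spots with
stage coordinates in micrometres and one intensity (counts per second) per
measured element.  Inputs are assumed **baseline-corrected** upstream, so
negative intensities are legal and are carried as-is.  Missing values stay
`NA` end to end: downstream statistics exclude them pixel-wise, clustering
excludes the affected pixels and reports them as `"excluded"`, and nothing
is ever imputed — fabricating signal in a quantitative map is worse than
losing a pixel.

Annotated morphology arrives as named contours or polylines in the
coordinate frame of a reference microscope image, with the raster
convention u rightward, v downward, origin at the top-left corner.  The
native JSON dialect is deliberately minimal and versioned; an import
mapping for FishInspector-style files is provided behind a dialect flag
but has not been validated against real exports, whose schema is not
public.

## Registration

The annotation frame is related to the stage frame by a 2-D affine
transform.  The primary path estimates the six parameters by ordinary
least squares from landmark pairs; three non-collinear landmarks
interpolate exactly, more landmarks average out clicking error, and the
RMS residual is reported.  A residual above one pixel pitch triggers a
warning rather than an error, because overlay quality is ultimately the
analyst's call.  When no landmarks exist, a fallback maps the image
rectangle onto the grid's bounding box with an axis-aligned scale and
translation (optionally flipping the vertical axis, since image rows point
down while stage y typically points up).  Both paths are recorded in the
run report, as they can differ materially.  Nonlinear warping is out of
scope: at a 35 µm pitch, residual chromatic or perspective distortion of
the reference image is far below one pixel.

## ROI rasterization

A pixel belongs to a compartment iff its centre lies inside the transformed
polygon under the even-odd rule.  Membership is all-or-nothing: pixels are
ablation spots of fixed diameter, and partial-coverage weighting would
suggest sub-spot information the measurement does not have.  Boundary
centres follow a **half-open rule** — a centre exactly on an edge counts as
inside for its lower/left edges only — so two compartments sharing an edge
partition the boundary pixels deterministically instead of double-counting
them.

Line features (the notochord) carry no width of their own; they are
buffered to a stadium with rounded caps and joins.  The default half-width
is one beam diameter (35 µm), surfaced in every run report, because the
annotation line marks the structure's axis while the ablated track it
dominates is at least one spot wide.  The arc discretization keeps the
buffered area within about half a percent of the exact stadium; strongly
self-intersecting polylines are not supported.

Derived compartments are boolean mask algebra, restricted to difference
and union — enough to express the one derived region the workflow needs
(fish body = fish contour − yolk) without inventing a constraint language.
The implicit ROI `total` (all pixels, the "ablation area") is always
appended; it is the denominator of every percentage.

## Segmentation

Feature matrices combine element channels and optionally the stage
coordinates.  The default scaling is a per-column z-score (population
convention): intensities are of order 10⁴–10⁶ cps while coordinates are of
order 10²–10³ µm, so any unscaled mix is dominated by whichever unit is
numerically larger.  `scaling = "none"` is provided for parity with
workflows that cluster raw cps plus coordinates — there, the intensity
channel effectively decides the partition and the coordinates only break
ties.  This choice matters and is easy to get wrong, which is why it is
explicit rather than buried.

A caveat the package's own tests document: on nested anatomy (a body
containing yolk and eyes, surrounded by support), *z-scored* coordinates
are actively harmful to compartment recovery.  Once all columns have unit
variance, splitting the image spatially reduces the k-means objective more
than separating intensity levels does, so the optimum quarters the image
instead of tracing the anatomy.  Intensity-only features (or unscaled
features, where cps dominate) recover the planted compartments of the
synthetic phantom essentially perfectly; z-scored intensity-plus-xy does
not, and this is a property of the k-means objective, not of the
implementation.  Analysts wanting spatial regularization should cluster on
intensity and inspect spatial coherence afterwards.

Six algorithms are exposed with their standard knobs.  k-means uses
k-means++ seeding with ten restarts driven by seed-derived substreams,
keeping runs bit-reproducible and the inertia curve monotone for the elbow
rule; Lloyd iterations are delegated to `stats::kmeans`.  Spectral
clustering wraps `kernlab::specc`.  Mean shift (flat kernel, bandwidth
estimated from the 30 %-quantile nearest-neighbour distance when not
given), affinity propagation (median-similarity preference, damping 0.5),
DBSCAN and HDBSCAN are implemented in-package on dense distance matrices,
which is adequate for images of a few thousand pixels; the DBSCAN and
HDBSCAN implementations reproduce scikit-learn's partitions on shared
fixtures in the test suite.  Density-based noise (label −1) is a
first-class cluster everywhere downstream, since "no dense neighbourhood"
is itself biologically interpretable (outliers, one-off spots).

`elbow_k()` runs k-means over a k range and picks the argmax of the
discrete second difference of the within-cluster sum of squares over
interior k — a stated, deterministic curvature rule.  The full curve is
returned because the rule is a suggestion: on a strongly imbalanced 1-D
intensity distribution the maximum-curvature point can sit below the
number of anatomically distinct levels (the README example shows exactly
this), and the analyst should override it with domain knowledge.

Cluster indices are arbitrary, so before replicates are compared,
`canonical_relabel()` renumbers clusters by ascending mean intensity of a
reference element (ties: larger cluster first, then original label).  The
renumbering is invariant under any permutation of the input labels.

## Cross-tabulation and quantification

Heatmap layers share fixed conventions: rows are cluster labels ascending
with −1 first; columns are ROIs in declared order; the denominator of all
percentages is the number of clustered pixels (noise included, excluded
pixels not).  A cluster–ROI pair with no shared pixel is an **empty** cell,
not a zero: zero-filling would fabricate agreement between replicates that
differ precisely in which cells are populated.  Empty cells are dropped
pairwise from correlations, with the dropped count reported.  Per-ROI
mean intensities are computed over clustered pixels, and the package
documents this choice since "per-ROI" could also be read as
all-pixels-in-ROI.

Intensity converts to amount through an unweighted ordinary-least-squares
line fitted to spiked standards; `r_squared`, the residual standard
deviation `sqrt(SSE/(n-2))`, and detection/quantification limits via the
3.3σ/10σ residual rule are reported.  Back-calculated negative amounts
are floored at zero — pixels cannot carry negative mass — but amounts
quantified upstream and merely imported are passed through untouched,
flagged when negative, out of respect for the upstream processing chain.
The cps→ng conversion requires a user-declared `pixel_factor` (ng per
concentration unit per pixel): the ablated mass per spot depends on tissue
and instrument and cannot be inferred from the table.  Weighted fits,
drift correction and internal-standard normalization are out of scope.

Per-ROI descriptive statistics (sum, mean, sd, median, variance, min, max)
use the sample (n−1) convention; single-pixel ROIs report `NA` dispersion
rather than a misleading zero.

## Replicate comparison

Reproducibility between individuals is quantified by Spearman's rank
correlation over matched heatmap cells: Pearson correlation of mid-ranks,
with the two-sided t approximation `t = ρ√((n−2)/(1−ρ²))` on n−2 degrees
of freedom for the p-value (a seeded permutation p-value is available for
small n).  `ρ = ±1` reports the smallest representable double rather than
an exact zero.  Rank correlation is the right instrument here because
replicate ablations share ordering, not scale: tissue thickness and plasma
conditions rescale intensities monotonically between runs.

## The synthetic phantom

`synth_scene()` emulates a laterally mounted ~3.5 mm × 1 mm embryo at the
35 µm beam pitch (100 × 30 = 3000 pixels): an elliptical body containing a
yolk ellipse, two eye circles, a notochord polyline and a swim bladder,
annotated in a synthetic 1000 × 300 px "microscope" frame related to the
stage by a known affine (scale 3.5, vertical flip) so registration is
exercised nontrivially.  Intensity is driven by four regions with
precedence eye > yolk > body > background; notochord and bladder are
annotation-only.  The default carbon levels (0, 1.2 × 10⁵, 2.9 × 10⁵,
7.0 × 10⁵ cps) sit in the range of real whole-embryo carbon signals and
are spaced several noise interquartile ranges apart, so the planted
partition is unambiguous.  Noise is multiplicative log-normal (σ = 0.1 by
default) — detector flicker at high count rates is closer to
multiplicative than additive — with optional Poisson resampling for
low-count realism.  Everything is deterministic given the seed, and the
bundle manifest regenerates the dataset bit-identically.

What the phantom does **not** emulate: laser plume washout (no smearing
along the scan axis), intensity drift, partial-pixel ablation at
compartment borders, inter-individual shape variation beyond the noise
seed, or annotation error (the truth labels derive from the same polygons
as the annotations).  Passing tests therefore demonstrate correctness of
the computational chain, not robustness to imperfect annotations or
instrument artefacts.

## Numerical choices and problem sizes

Coordinate columns are recognized case-insensitively by `/^x/` and `/^y/`
among trailing columns (overridable), delimiters are auto-detected among
tab/comma/semicolon, and a comma decimal mark is supported for
locale-variant exports.  Round trips through the text writer preserve
values to 17 significant digits.  The HDF5 reader covers a documented
four-dataset subset (intensity matrix, labels, x, y) rather than any
proprietary vendor schema.  Configuration files are YAML, the R
ecosystem's standard for structured run configs.  Affine inversion
refuses |det| < 1e−12; zero-area polygons rasterize to empty masks with a
warning; constant feature columns z-score to zeros with a warning.

The test and acceptance workloads use the phantom at its native 3000
pixels, 50 random cross-tab instances of up to 500 pixels, 100 random
polygons for the rasterization oracle, and 200 Monte-Carlo calibration
fits — sizes chosen so the full suite exercises every code path in well
under a minute per property while keeping estimates stable across seeds.

## Known limitations

* The six algorithms run on dense distance matrices (except k-means and
  spectral); beyond ~10⁴ pixels, memory grows quadratically.
* The FishInspector import dialect is best-effort and unvalidated.
* Heatmap comparison requires identical cluster counts between replicates;
  when algorithms return different k, only the shared canonicalized
  structure can be compared, and the package refuses rather than guesses.
* The elbow rule is a heuristic; its curve should be inspected, not
  trusted blindly, on imbalanced intensity distributions.
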