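---
title: "Canopy-cover segmentation and quality control with ccpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy-cover segmentation and quality control with ccpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccpipe)
```

## The problem

Field phenotyping platforms image crop plots from above, every day, under
natural light. Canopy cover — the plant-pixel fraction of a plot image — is
one of the most informative early-season traits, but extracting it from
tens of thousands of images requires segmentation that copes with two very
different illumination regimes: *low light-contrast* (LLC) scenes, where an
even sky leaves all detail visible, and *high light-contrast* (HLC) scenes,
where direct sun saturates highlights and casts deep shadows. A threshold
that separates plant from soil on an LLC image routinely fails on an HLC
image of the same plot.

`ccpipe` structures the analysis as three steps — image conversion,
segmentation, post-processing/quality control — with the illumination
regime classified per image so that segmentation can be routed to a model
trained for that regime.

## Image conversion

Channels are treated symbolically: the first channel is "R" whether it
carries red or, as with NIR-converted cameras common in vegetation
monitoring, near-infrared. Vegetation indices are computed on `[0, 1]`
floats: ExR `1.4R − G`, ExB `1.4B − G`, NDI2 `(R − B)/(R + B)` and NDI3
`(R + G − 2B)/(R + G + 2B)`. Pixels where an NDI denominator vanishes
(black pixels) are assigned 0, the background-neutral value, rather than
NaN.

The product indices multiply an NDI plane element-wise with a colour plane
that carries complementary information: HSV *V* (brightness) or Lab *a*
(green–red opponency). *V* is already in `[0, 1]` and is used as-is. The
*a* plane is signed with an image-dependent range, and no convention
exists for combining it multiplicatively; we min-max rescale *a* to
`[0, 1]` per image, which preserves the sign structure of the NDI factor
and keeps thresholds comparable across images. A constant *a* plane (only
possible for synthetic or grayscale input) rescales to all 0.5 with a
warning. Lab conversion assumes sRGB primaries and the D65 white point —
the conventional choice when the camera profile is unknown.

The supervised feature space is fixed and ordered: `R, G, B, H, S, V, L,
a, b, NDI3V` (`PIXEL_FEATURES`). Models record this order and verify it at
prediction time, so tables and models are portable.

## Automated thresholding

**μRow.** Row crops make the segmentation problem one-dimensional:
averaging a vegetation-index image over the axis parallel to the crop rows
gives a profile with one bump per row. The profile is smoothed with a
cubic smoothing spline (`spar = 0.3` by default; chosen so that synthetic
scenes with 6–12 rows yield exactly one detected peak per row at typical
row spacings), peaks are detected subject to a minimum spacing
(`min_row_spacing_px`, default 8 px) and a prominence floor of 10% of the
smoothed profile's range (suppressing noise bumps), and the threshold is
the arithmetic mean of the smoothed profile values at the peaks. We use
the smoothed values, not the raw ones — peaks are defined on the smoothed
curve. Troughs are detected and reported for diagnostics but do not enter
the threshold.

With `row_axis = "auto"` both orientations are profiled. The along-row
axis shows many regularly spaced prominent peaks; the cross axis typically
shows only a few accidental bumps. Selecting purely on the regularity
(coefficient of variation) of inter-peak spacing proved fragile — three or
four accidental peaks can be accidentally regular — so the axis with more
detected peaks wins, with the lower spacing-CV as tie-break.

An image without row structure (bare soil shortly after germination, or a
numerically flat profile) raises a classed `ccpipe_no_rows` error. The
batch pipeline catches it and, by default, falls back to Otsu for that
image.

**Otsu.** Values are histogrammed into 256 equal-width bins over
`[min, max]`; the returned threshold is the bin edge maximising the
between-class variance, the lowest edge in case of ties (a deterministic
convention). The implementation is closed-form via cumulative sums; the
test suite checks it against an exhaustive search written as an
independent loop.

Foreground is `vi > t`, strictly; the boundary value is background. This
makes the all-background limit reachable with `t = max(vi)`.

## Illumination classification

Each channel is quantized to 8-bit levels and histogrammed into 256 bins;
the three blocks are normalized to frequencies (so image size cancels) and
concatenated into a 768-vector. An RBF-kernel SVM (`e1071`) separates LLC
(class 1) from HLC (class 2). Two notes:

- The histogram blocks sum to 1, so entries are small and squared
  distances between feature vectors are tiny; a textbook `gamma = 1/768`
  leaves the kernel saturated near 1 and the classifier useless. The
  default scales gamma by the overall feature variance,
  `gamma = 1/(768 · var)`, the standard variance-scaled heuristic. Cost
  is 1; both are configurable.
- The class coding follows the histogram-figure convention 1 = LLC,
  2 = HLC. Conflicting codings exist in the field; `route_scenario()` is
  the single place where the coding is interpreted (1 → M_LLC, 2 → M_HLC).

Models persist with a format-version header and refuse to load mismatched
versions.

## Supervised pixel segmentation and scenario routing

The decision tree (`rpart`) is depth-limited (default 10) with a small
complexity penalty — unlimited depth would memorize the training pixels.
The SVM uses a linear kernel by default: per-pixel prediction over full
frames must stay tractable, and on the 10-feature space the linear
decision surface already separates plant from soil well; an RBF kernel is
available through the arguments. Tables larger than the training budget
(`max_pixels`, default 500,000) are reduced by stratified per-class
subsampling under the caller's seed.

Scenario models M_LLC and M_HLC are trained on scenes of their own regime;
M_ALC pools both training sets. At run time the illumination class routes
each image to its scenario model, falling back to M_ALC (with a warning)
when the scenario model is absent. On synthetic benchmarks the
scenario-matched model is at least as accurate as the mismatched one on
its own regime — the motivating property for routing — and the test suite
asserts exactly that, reporting M_ALC alongside without an inequality (it
is expected to sit between).

The unsupervised alternative clusters the per-pixel Lab (a, b) pairs with
k-means, k = 3 (nominally plant, and two background materials such as dry
and wet soil), 10 restarts under a fixed seed, and labels the cluster with
the highest mean NDI3 as plant; ties break toward the larger cluster.
Fewer than three distinct (a, b) values is a degenerate-clustering error.

## Post-processing and canopy cover

Masks are cleaned by a 5×5 median filter followed by removal of connected
components smaller than `min_object_px`, in that order (the filter first
consolidates speckle into removable fragments). For binary data the median
is exactly a majority vote, implemented with an integral image under
reflect padding. Components use 8-connectivity by default so diagonal leaf
segments stay connected. The size floor is strict: a 399-px object is
removed, a 400-px object kept.

The 400-px default is meant for multi-megapixel plot images. The synthetic
scenes used throughout the tests are ~10⁴ px, so pipeline runs on them use
`min_object_px = 10` — the same salt-and-pepper intent at that frame size.
Test problem sizes follow the same logic: scenes of 64×96 to 120×180 px,
series of 4–6 plots over 6 dates, training tables of ~10⁴ pixels, 20 test
scenes per scenario for the model comparison.

Canopy cover is the plant fraction over the frame or a rectangular ROI;
records carry the pixel counts, the illumination class and the method for
provenance.

## Quality metrics

`evaluate_segmentation()` computes, over plant pixels, Qseg (intersection
over union), Sr (recall) and Es (false-plant relative to reference-plant),
with integer counts and division last. Degenerate cases: both masks empty
gives Qseg 1 (vacuous agreement); an all-background reference makes the
Sr/Es denominators undefined, so they return NA with a classed warning
while Qseg is still reported. Qseg ≤ Sr always, since the union contains
the reference.

## Time-series quality control

CC records are arranged plot-by-date (duplicate plot/date pairs are a data
error; absent combinations are missing). Pearson correlation (the
conventional *r*; Spearman available) is computed per date pair over
pairwise-complete plots, requiring at least 3 complete pairs. A date is
flagged when its correlation with *both* chronological neighbours (its
single neighbour, at the series ends) falls below `r_min = 0.5`. Requiring
both neighbours distinguishes one bad imaging day from a genuine growth
change, which affects a period rather than a date; 0.5 sits well below the
near-unity correlations of consecutive healthy dates while still catching
a date whose segmentation collapsed. Both the statistic and the threshold
are configurable.

## The synthetic generator — what it does and does not emulate

`generate_field_image()` places jittered circular leaf blobs along
equally spaced vertical crop rows until the plant fraction reaches the
target (±0.02), then colours plant (0.75, 0.55, 0.15) and soil
(0.45, 0.40, 0.35) with Gaussian pixel noise (sd 0.03). The first-channel
plant brightness emulates an NIR-modified camera, where vegetation is the
brightest material. LLC scenes have uniform illumination; HLC scenes apply
a multiplicative field of bright patches (gain 2.5, clipped at 1.0, with
at least 5% of pixels saturated — the defining HLC property) and shadow
patches (gain 0.25). The truth mask is frozen *before* illumination, so
saturation creates genuine difficulty without corrupting the ground truth.
`generate_series()` drives per-plot logistic growth curves
`cc(t) = cc_max / (1 + exp(-rate (t - t0)))` across dates, each date with
its own scenario. All randomness flows through one seed per call; global
RNG state is saved and restored.

What passing tests on these scenes show: the pipeline's operations are
correct, deterministic and internally consistent, and the scenario-routing
logic helps exactly when illumination differs. What they do not show:
performance on real canopies — real wheat has overlapping leaf layers,
specular soil, mixed pixels at leaf edges, dirt on leaves and continuous
illumination gradients, none of which the blob model reproduces. Absolute
accuracy numbers on synthetic scenes therefore do not transfer to field
images; the relative orderings (HLC harder than LLC, matched models no
worse than mismatched ones) are the transferable content.

## Numerical choices and degenerate inputs

- Zero NDI denominators → 0; constant index image → Otsu error (no
  separable classes); numerically flat μRow profile (range < 1e-8) → no
  rows.
- Otsu ties → lowest threshold; k-means plant-cluster tie → larger
  cluster.
- Median window must be odd; even sizes are a parameter error, not a
  silent round.
- Masks are strictly 0/1 integers end to end; quality-metric counts are
  exact integers before the final division.
- Float-TIFF export of index planes min-max rescales to `[0, 1]`, since
  the writer's behaviour outside that range is undefined.
- A failed image in a batch is logged and skipped; the run fails only if
  every image fails.

## Known limitations

- The μRow method assumes straight rows aligned with a frame axis; curved
  or diagonal rows would need a rotation search it does not attempt.
- The illumination classifier knows exactly two regimes; scenes that are
  neither (fog, dusk, wet soil glare) are forced into one of them.
- Supervised models do not transfer across camera spectral configurations:
  a model trained with NIR-as-R expects that channel layout at prediction.
- Multiband (multi-threshold) segmentation and local/adaptive thresholds
  are out of scope, as are shape-based features and growth-curve smoothing
  of flagged dates.
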