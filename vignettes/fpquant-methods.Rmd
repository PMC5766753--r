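---
title: "Methods: automated fungiform papillae quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated fungiform papillae quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpquant)
```

## The problem

Fungiform papillae (FP) are the pink, mushroom-shaped structures on the
anterior tongue that house taste buds; their number and spatial density are
widely used as an anatomical proxy for taste function.  Manual counting —
typically inside a small dyed circle near the tongue tip — is slow,
subjective, and samples only a tiny region.  `fpquant` implements an
automated alternative that works on ordinary colour photographs of the
unstained anterior 2 cm of a protruded tongue: it detects every papilla in
the crop, measures it, and maps its position, then provides the agreement
statistics needed to validate the automated counts against a reference
method.

## Colour model and segmentation

The segmentation is supervised nearest-neighbour colour classification.
Three tissue classes tile the tongue: *fungiform papillae* (pink,
elevated), *filiform papillae* (whitish, threadlike), and *tongue base*
(the light-pink tissue between papillae).  A fourth *background* class
absorbs everything that is not tongue; real crops always contain some.

For each class the user supplies one or more training regions of interest
(rectangles, polygons, or masks).  Pixels are converted from 8-bit sRGB to
CIELAB under the D65 reference white using the standard closed-form chain
(inverse sRGB companding, the sRGB-to-XYZ matrix, then the CIE cube-root
compression).  CIELAB is close to perceptually uniform, so the Euclidean
distance

$$ d(p, m) = \sqrt{(L_p - L_m)^2 + (a_p - a_m)^2 + (b_p - b_m)^2} $$

between a pixel $p$ and a class marker $m$ approximates perceived colour
difference.  The marker of a class is the unweighted mean CIELAB colour
over all pooled ROI pixels of that class; every pixel then receives the
class of its nearest marker.  Ties are broken deterministically in the
fixed order fungiform, filiform, base, background so results are identical
across platforms.  A configuration switch (`channels = "ab"`) drops the
lightness channel for stronger illumination invariance; the full 3-D
distance is the default because lightness carries most of the
papilla/filiform contrast.

Papilla colour shade varies across the tongue, so a single global
codebook can leave some areas poorly resolved.  `reanalyze_region()`
re-classifies a rectangular sub-region with markers learned from ROIs
local to it and merges the result with the original classification
outside the rectangle at pixel level.  Components that straddle the
rectangle edge are re-extracted from the merged map, so no papilla is
double-counted.  Pixels labelled background keep that label: re-analysis
refines tissue assignment, never the analysis support.

## Papilla extraction and measurement

Individual papillae are connected components of the fungiform class.
Labelling is run-based with union-find and supports 4- and
8-connectivity; 8-connectivity is the default because blob edges fragment
less.  Components smaller than `min_area_mm2` (default 0.01 mm², an
equivalent diameter of roughly 0.11 mm) are discarded as colour noise —
small enough to keep the smallest plausible papilla.  No morphological
opening or closing is applied by default, and merged papillae are *not*
split automatically (regional re-analysis is the intended remedy); shape
or roundness scoring is out of scope.

Each retained papilla is measured by pixel area, physical area
($A_{px} \cdot s^2$ for calibration $s$ in mm/px), centroid (unweighted
mean of pixel coordinates), ordered outer contour, and the
circular-equivalent diameter

$$ d_{eq} = 2 \sqrt{A / \pi}, $$

which assumes papillae are circular.  Whole-tongue density is the total
retained fungiform area divided by the whole tongue area (the union of
the three tissue classes).  The numerator deliberately uses the
*filtered* papillae so density and count describe the same structures;
the unfiltered alternative differs only by the area of sub-threshold
specks.

## Analysis geometry

All spatial mapping runs off the tongue mask and the calibration:

* **Tip**: the most protruded mask row (image bottom by default,
  configurable).
* **Midline**: the vertical line through the tongue-mask centroid column,
  kept as a continuous coordinate.  A centroid exactly on the midline
  counts as left.
* **Bands**: distance from the tip is measured along image rows;
  Band 1 is $[0, 10)$ mm, Band 2 $[10, 20)$ mm (half-open, so a centroid
  at exactly 10 mm is in Band 2).  Papillae beyond 20 mm are flagged and
  excluded from counts.
* **Grids**: within each (side, band), the span from the midline to that
  band's lateral mask extreme is divided into 4 equal-width vertical
  strips, numbered outward from the midline: strips 1–4 in Band 1 and
  5–8 in Band 2 give grids L1–L8 and R1–R8.  The strip construction is
  one consistent reading of the published 16-grid layout and is isolated
  behind the geometry interface so an alternative could be substituted.
* **Counting circle**: a 6-mm circle placed wholly inside the tongue on
  the left side, right edge tangent to the midline, as close to the tip
  as possible; membership is by centroid (boundary-inclusive), matching
  manual ring-counting practice and keeping counts additive.

Pixel coordinates are 1-based with x = column and y = row, R's native
convention.  Band distance is measured along rows, not along the curved
tongue surface; for the anterior 2 cm of a protruded tongue the
difference is small, but it is a modelling choice to be aware of.

Conservation invariants — side, band, and grid counts each summing to the
total — are asserted on every summary.

## The synthetic tongue model

Because no real annotated tongue images ship with the package, every
stage is validated against a seeded generator with exact ground truth.
The generator emulates the statistical structure the method assumes:

| parameter | default | rationale |
|---|---|---|
| calibration | 0.05 mm/px | consumer-camera close-up scale |
| tongue outline | superellipse, exponent 3, half-width 24 mm | blunt, tongue-like anterior outline (~48 mm wide) |
| image | 1000 × 480 px | anterior ~23 mm crop, tip at bottom |
| papillae | 204 | population mean automated count (148 Band 1 + 56 Band 2) |
| Band-1 fraction | 0.7 | observed anterior gradient (148/204) |
| papilla radius | U(0.2, 0.5) mm | plausible FP sizes; free parameters |
| filiform texture | 30% coverage, 3-px blobs | thresholded blurred noise |
| illumination | ±8% linear multiplicative drift | mild uncorrected lighting |
| noise | Gaussian, σ in RGB units | sensor noise |

Placement is Poisson-disk-style rejection sampling, stratified by band:
a candidate centre is accepted only if its disk lies wholly inside the
mask with 1-px clearance, keeps a 3-px free gap to every accepted disk
(so components never touch under 8-connectivity), and keeps 2 px clear of
every band/grid/midline boundary so planted centres and detected
centroids bin identically.  An unplaceable request raises a capacity
error reporting how many were placed.

Papilla disks are rendered **hard-edged** by default (a pixel belongs to
the disk iff its centre is within the radius).  This is a deliberate
design choice: it makes the ground-truth class map an *exact* description
of the noiseless image, so exact-recovery properties (counts equal truth,
density equal to machine precision) are well defined.  With anti-aliased
edges (available via `antialias = TRUE`) a blended edge pixel has no
unambiguous true class, because the nearest-marker decision boundary in
CIELAB does not fall exactly at 50% coverage.

Class colours (base pink, filiform whitish, papilla darker pink, dark
background) were chosen with pairwise CIELAB separations of roughly 25
units or more.  The ±8% illumination drift shifts colours by at most a
few CIELAB units, well below half the smallest class separation, so at
zero noise the nearest-marker classifier is guaranteed to reproduce the
true class map exactly — the end-to-end exact-recovery tests exercise the
pipeline, not a lucky colour draw.

What the generator does **not** emulate: real papilla shape variation and
interconnection, specular glare, depth-of-field blur, tongue coating and
staining, pose variation, or camera colour processing.  Passing the
synthetic suite therefore demonstrates algorithmic correctness (the
pipeline measures exactly what is planted, degrades gracefully with
noise), not clinical performance on photographs; the latter requires the
agreement statistics below against a manual reference.

## Validation statistics

The method-comparison machinery is implemented at formula level:

* **Bland-Altman**: for paired measurements $x, y$, the mean difference
  $\bar d$, its sample SD, and limits of agreement
  $\bar d \pm 1.96\, s_d$; plus a one-sample t-test of zero mean
  difference, the conventional reading of a "Bland-Altman test" with a
  p-value.
* **ICC, two-way random, absolute agreement**, from the two-way ANOVA
  mean squares ($MS_R$ subjects, $MS_C$ raters, $MS_E$ error):
  $$ ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + k(MS_C - MS_E)/n},
     \qquad
     ICC(2,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}. $$
  Both single and average measures are returned; reliability judgements
  of a mean over $k$ raters or replicate images refer to the average-
  measures form.
* **Spearman correlation**: Pearson correlation of mid-ranks (ties get
  average ranks), p-value from the t approximation on $n-2$ df, which is
  adequate at the study scale of dozens of subjects.  An exact
  permutation p-value is available for $n \le 8$, where enumeration is
  instant; beyond that the approximation is preferred over a 10!-sized
  enumeration.
* **Forward stepwise regression** of the total count on band/grid
  counts: at each step the candidate with the largest $R^2$ increase
  enters if its partial-F p-value is below `p_enter` (default 0.05);
  selection stops when none qualifies.  No removal step is performed, and
  exactly collinear candidates tie-break by column order with a message.
  An $R^2$ within $10^{-12}$ of the total sum of squares terminates
  selection (the response is already fitted exactly).

Each statistic is unit-tested against an independent oracle: `aov()`
variance components for the ICC, `cor.test()` and mid-rank Pearson for
Spearman, exhaustive single-predictor search for the first stepwise
entry, and closed forms for Bland-Altman.

## Numerical and design choices

* sRGB→CIELAB uses the exact published constants; `grDevices::convertColor`
  differs from the standard chain by up to ~0.3 CIELAB units and serves
  as an approximate cross-check only.
* Classification ties, component ordering (top-most then left-most first
  pixel), and strip binning are all deterministic, so a fixed
  configuration reproduces bit-identical outputs.
* The acceptance experiments use 20 noiseless and 20 noisy tongues at
  the default conditions and 30 tongues with planted totals drawn
  uniformly from 53–396, the observed range of total FP counts.  At the
  top of that range, default-sized papillae physically cannot pack into
  the first centimetre of a real-size anterior tongue, so the
  high-count experiment plants smaller papillae (radius U(0.15, 0.30) mm)
  — the physically consistent reading that crowded tongues bear smaller
  papillae.
* JPEG input is not supported (no reader dependency); PNG and TIFF are.

## Limitations

* The equivalent diameter assumes circular papillae and ignores shape
  and roundness; diameters of irregular or merged papillae are biased.
* Merged papillae are counted as one component unless resolved by
  regional re-analysis.
* No automatic tongue detection, white-balance or colour-constancy
  correction, pose normalisation, or support for dye-stained images.
* The 16-grid layout is one geometric reading of the published
  partition; absolute per-grid counts depend on it, though the
  conservation and symmetry properties do not.
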