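# fpquant

Automated detection, quantification and spatial mapping of **fungiform
papillae** (FP) on colour photographs of the anterior 2 cm of an unstained
human tongue.

Fungiform papillae are the pink, mushroom-shaped structures on the anterior
tongue that house taste buds; their count and density are a standard
anatomical proxy for taste function.  Manual counting inside a small dyed
circle is slow and subjective and samples only a fraction of the tongue.
`fpquant` automates the measurement on ordinary unstained photographs:

* **Colour segmentation** — tissue classes (*fungiform papillae*,
  *filiform papillae*, *tongue base*, plus *background*) are learned as
  mean CIELAB colours from user-drawn training ROIs; every pixel is
  assigned to the class of its nearest marker by Euclidean distance in
  L\*a\*b\* (D65).  Rectangular sub-regions can be re-analysed with local
  markers where papilla shade differs across the tongue.
* **Papilla quantification** — papillae are connected components of the
  fungiform class, each measured by area, centroid, boundary and the
  circular-equivalent diameter *d* = 2√(A/π); whole-tongue density is the
  FP area over the total tongue area.
* **Spatial mapping** — the tongue is split at the midline into left and
  right, into two 1-cm bands from the tip, and into 16 grids L1–L8/R1–R8
  (4 equal-width strips per side per band, numbered outward from the
  midline), with the conventional 6-mm counting circle placed against the
  midline as close to the tip as possible.
* **Synthetic ground truth** — a seeded generator renders tongue images
  with known papilla positions, a Band-1/Band-2 density gradient,
  filiform texture, illumination drift and sensor noise, so the entire
  pipeline is testable without patient data.
* **Method-agreement statistics** — Bland-Altman limits of agreement,
  two-way random absolute-agreement ICC (single and average measures),
  Spearman correlation, and forward stepwise regression of total count on
  regional counts.

## Worked example

Generate a synthetic tongue at the default study conditions (204 papillae,
70% in the first centimetre), learn markers from the ground-truth patches,
and run the full pipeline:

```r
library(fpquant)

syn <- generate_tongue(synth_params(seed = 42))
mk  <- markers_from_truth(syn$image, syn$truth)
q   <- fp_quantify(syn$image, mm_per_px = 0.05, markers = mk)
q
#> <fp_quant> 204 papillae on 24.0 x 50.0 mm of tongue
#>   Band 1: 143   Band 2: 61   Left: 107   Right: 97
#>   density 0.0790, mean equivalent diameter 0.674 mm, circle count 13
```

The summary row reports the total count, the per-band counts (143 of the
204 papillae sit in the first centimetre — the planted anterior
gradient), the count inside the 6-mm circle near the tip (13), and the FP
density (7.9% of the tongue surface).  Every value matches the planted
truth exactly at zero noise:

```r
truth_counts(syn$truth)[, c("total", "band1", "band2")]
#>   total band1 band2
#> 1   204   143    61
```

Per-papilla measurements are a tidy tibble:

```r
tidy(q)
#> # A tibble: 204 x 9
#>      id  x_px  y_px area_px area_mm2 equiv_diameter_mm side   band grid
#>   <int> <dbl> <dbl>   <int>    <dbl>             <dbl> <chr> <int> <chr>
#> 1     1  367.  75.8     257    0.643             0.904 L         2 L6
#> 2     2  584.  75.4     144    0.36              0.677 R         2 R5
#> ...
```

`autoplot(q)` draws the class map with papilla boundaries, midline, band
edges and the counting circle; `plot_grid_counts(q)` shows the L1–L8/R1–R8
distribution.  Agreement between measurement arms (e.g. automated vs
reference counts per subject) is assessed with `fp_validate()`,
`bland_altman()`, `icc_twoway_random()`, `spearman_cor()` and
`stepwise_forward()`.

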