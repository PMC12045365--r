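# peristroma

Spatial statistics for digital pathology: does tumor-cell proliferation
under therapy concentrate in the **peristromal niche**?

Stroma can shelter adjacent tumor cells from targeted therapy through
ECM contacts and short-range paracrine factors. In a segmented histology
cross-section this predicts that proliferation-marker-positive (e.g.
BrdU+) tumor cells lie closer to stroma than the tumor-cell population as
a whole. `peristroma` quantifies that bias per sample and tests it at the
group level.

## The statistic at the core

For a section with tumor-cell centroids, stroma raster and marker labels
(K positives among N cells):

* d_i — exact Euclidean distance (µm) from each tumor cell to the
  nearest stroma pixel;
* the observed positive-cell distance ECDF, median and mean, and the
  two-sample Kolmogorov–Smirnov D of positives vs the null reference;
* the **digital avatar** null: marker labels redistributed uniformly
  among the tumor cells with positions, stroma and K fixed. The expected
  positive ECDF under this null is exactly the all-cell ECDF (closed
  form); the null *distribution* of any statistic comes from R explicit
  avatar draws, giving an add-one empirical p-value
  p = (1 + #{null ≤ observed}) / (R + 1) for the left tail;
* Δ_median and Δ_mean = observed − expected null; negative values mean
  proliferating cells concentrate near stroma;
* group level: a two-tailed paired t-test of observed vs predicted within
  a treatment group (one-sample t on the per-tumor deltas) and the
  interaction term of a two-way ANOVA (host model × condition, with a
  tumor-level error stratum) for comparisons between two host models.

Inputs are segmentation-platform exports: a cell table (CSV with
configurable columns), stroma geometry (GeoJSON/WKT polygons or PNG/TIFF
masks) and an optional necrosis-exclusion mask. A synthetic-tissue
generator with a known distance-dependent labeling bias (length scale λ;
λ = ∞ reproduces the null exactly) provides ground truth for validation.

## Worked example

```r
library(peristroma)

cfg <- synthetic_config(width = 512, height = 512, pixel_size = 2,
                        n_cells = 20000, positive_fraction = 0.1,
                        bias_length = 15, seed = 1)
ds <- generate_dataset(cfg)
ds$sample
#> <tissue_sample 'synthetic'> 20000 tumor cells (2000 marker+), 512x512 grid @ 2 um/px, stroma 13.0%

bias <- sample_bias(ds$sample, R = 999, seed = 2)
round(as.data.frame(bias)[, c("obs_median", "null_median", "delta_median",
                              "ks_d", "p_left")], 4)
#>   obs_median null_median delta_median  ks_d p_left
#> 1     8.4853     59.9333      -51.448 0.603  0.001
```

The marker-positive cells have a median stroma distance of 8.5 µm against
an expected 59.9 µm if proliferation were spatially random — a proximity
bias of −51.4 µm with KS D = 0.60, and no avatar among 999 produced a
median that small (p = 0.001, the smallest value the add-one estimator
can return at R = 999). The labeling bias was simulated at λ = 15 µm, so
this is the expected answer. `plot_ecdf_overlay(cell_distances(ds$sample))`
draws the observed-vs-null ECDF comparison; `run_compare()` produces
ladder plots and group tests across samples.

A shell interface wraps the same functions:

```sh
Rscript exec/peristroma simulate --out bundle --seed 4 --n-cells 20000 --bias-length-um 15
Rscript exec/peristroma analyze  --bundle bundle --permutations 999 --seed 5
Rscript exec/peristroma compare  --summaries a/summary.json,b/summary.json --out cmp
```

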