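---
title: "Quantifying peristromal proliferation bias with digital-avatar nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peristromal proliferation bias with digital-avatar nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the pipeline answers

Stroma can shelter tumor cells from targeted therapy: cells in the
peristromal niche — within the reach of juxtacrine ECM contacts and
short-range paracrine factors — keep proliferating while cells far from
stroma arrest. In a segmented histology cross-section this shows up as a
spatial asymmetry: proliferation-marker-positive (e.g. BrdU+) tumor cells
sit closer to stroma than the tumor-cell population as a whole.

Testing this directly against other tumors is confounded: therapy changes
the tumor/stroma ratio itself, so the distance distributions of two
sections are not comparable. The pipeline therefore compares each sample
to its own *digital avatar* null: a copy of the section that keeps every
tumor-cell position and the full stroma geometry, but redistributes the
marker labels uniformly at random among the tumor cells, preserving the
positive fraction. Any distance statistic of the observed positives can
then be referred to its sample-specific null distribution.

## Model and statistics

For a section with tumor-cell centroids $c_1,\dots,c_N$, stroma raster
$S$, and marker labels $m_i \in \{0,1\}$ with $K=\sum_i m_i$ positives:

* **Distance profile.** $d_i$ is the exact Euclidean distance from the
  pixel containing $c_i$ to the nearest stroma pixel, in microns.
  Distances are pixel-center to pixel-center on the rasterized geometry,
  so the discretization error is bounded by pixel\_size$/\sqrt2$; cells
  whose pixel is stroma get $d_i=0$.
* **Observed statistics.** The ECDF of $\{d_i : m_i = 1\}$, its median
  and mean, and the two-sample Kolmogorov–Smirnov statistic $D$ of the
  positives against the null reference. $D$ is the effect size of record:
  at $10^4$–$10^5$ cells the asymptotic KS p-value underflows and carries
  no information.
* **Avatar null.** Under the null the positive subset is a uniformly
  random size-$K$ subset of $\{1..N\}$. Two consequences are used:
  (i) the *expected* positive ECDF equals the all-cell ECDF exactly, at
  every threshold — so "predicted" medians/means are taken from the
  all-cell distances in closed form, with no sampling noise; (ii) the
  *distribution* of any null statistic is estimated from $R$ explicit
  avatar draws, giving the add-one empirical p-value
  $p = (1 + \#\{\text{null} \le \text{obs}\})/(R+1)$ for the left tail
  (proximity bias = smaller distances).
* **Bias summary.** $\Delta_{\text{median}}$ and $\Delta_{\text{mean}}$,
  observed minus expected-null; negative values mean positives
  concentrate near stroma.
* **Group inference.** Within a treatment group the observed-vs-predicted
  comparison is paired within tumor, so the two-tailed paired t-test is
  computed as a one-sample t-test of the per-tumor deltas against zero.
  Across two host models the comparison is the interaction term of a
  two-way ANOVA (model × condition, condition ∈ {observed, predicted}).

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `pixel_size` | µm/px | 2 | converts raster distances to microns; must match the segmentation export |
| `R` (`null_ensemble`) | replicates | 1000 | p-value resolution 1/(R+1); predicted values use the closed form, so R only affects p |
| `exclude_necrotic_stroma` | flag | `TRUE` | necrotic tissue is excluded from all analyses; by default necrotic stroma pixels are also removed as distance targets |
| `positive_fraction` (generator) | — | 0.1 | plausible proliferating fraction under therapy; not calibrated to a published per-tumor value |
| `bias_length` λ (generator) | µm | ∞ | length scale of the labeling bias; ∞ = unbiased (a draw from the avatar null) |
| `target_stroma_fraction` (generator) | — | 0.15 | minority stroma area in strand form, as in ECM-rich xenograft sections |

## What the synthetic generator emulates — and what it does not

`generate_dataset()` emulates the *output* of an AI segmentation platform,
not the image: strand-like stroma (thickened correlated random walks,
grown until the realized area fraction is within ±20% of target),
tumor-cell centroids uniform outside stroma and necrosis with continuous
(jittered) coordinates, an optional single elliptical necrotic region,
and marker labels drawn without replacement with weights
$w_i = e^{-d_i/\lambda}$ so that exactly $K=\operatorname{round}(fN)$
cells are positive. The weighted draw is realized with exponential race
keys in log space (equivalent to successive draws proportional to
remaining weights), so small weights never underflow and $\lambda=\infty$
reduces *exactly* to a uniform size-$K$ subset — one avatar draw. This
embedding is what makes the calibration tests meaningful.

The generator does **not** emulate: cell-density gradients, clustered or
excluded point patterns (real centroids have a hard-core radius),
segmentation errors near boundaries, multiple necrotic foci, or any
appearance-level features. Passing tests therefore demonstrate that the
*inference machinery* is exact and calibrated under a known null and
sensitive to a known bias — not that any particular tissue is unbiased.

Default generator geometry is a 1536×1536 grid at 2 µm/px (~3×3 mm
section) with 80,000 cells, about one centroid per 10 µm — the scale of a
whole tumor cross-section. The test suite and the acceptance script run
the same structure scaled to 160–192 px grids with 1,000–2,000 cells and
25–500 replicate samples, which keeps the full suite to a few minutes;
one capacity check runs the full 400,000-cell configuration.

## Numerical and convention choices

* **Coordinates.** Origin top-left, x rightward, y downward; pixel
  (row i, col j) covers $[j-1,j)\times[i-1,i)$ with center
  $(j-\tfrac12, i-\tfrac12)$. The far borders $x=W$, $y=H$ belong to the
  last pixel.
* **Distance transform.** Exact Euclidean (via `EBImage::distmap`), and
  the test suite enforces exactness against brute-force minimization over
  all stroma pixels — a chamfer approximation would fail it.
* **Median.** Midpoint of the two central order statistics for even n.
* **KS.** $D$ is evaluated on the pooled support with ties merged; the
  p-value uses the asymptotic Kolmogorov distribution at effective size
  $n_an_b/(n_a+n_b)$.
* **Rasterization.** Pixel centers under the even-odd rule; a center
  exactly on a ring edge counts as inside. Self-intersecting rings are
  refused rather than repaired.
* **Seeding.** Every stochastic operation takes an explicit seed and
  leaves the caller's RNG untouched. Ensemble replicate r derives its
  seed from (seed, r), so replicate streams do not depend on R and
  ensembles are extensible.
* **Ties in empirical p.** "As or more extreme" for the left tail is
  `null <= observed`; with pixel-discretized distances ties do occur and
  this choice is conservative.

## Design choices where the design was open

* **Predicted values: closed form, not a single shuffle.** A single
  random redistribution is an unbiased but noisy null reference; the
  all-cell ECDF/median/mean is its exact expectation (and the large-R
  limit). Both are available — `make_avatar()` gives single draws — but
  summaries and group tests use the closed form for stability.
* **Cells on stroma pixels are kept** with distance 0. Segmentation
  classes are exclusive in principle, but rasterization coarsens
  boundaries; dropping such cells would bias against the very signal
  being measured.
* **Necrotic stroma is not a distance target** by default (the exclusion
  is read as removing that tissue from the analysis entirely); the
  opposite convention is one flag away (`exclude_necrotic_stroma =
  FALSE`) since upstream conventions vary.
* **Interaction test stratum.** Observed and predicted values are paired
  within tumor and strongly correlated through its geometry. A plain
  fixed-effects two-way ANOVA on the long table pools that between-tumor
  variability into its residual and becomes markedly conservative, so
  `interaction_test()` defaults to the repeated-measures form with a
  tumor-level error stratum — algebraically a comparison of per-tumor
  deltas between models, calibrated at its nominal level. The
  fixed-effects form is kept behind `paired = FALSE`.
* **Exact-count marker assignment.** Per-cell Bernoulli labeling would
  make K random; sampling without replacement keeps K exact, matching the
  avatar null's fixed-fraction structure.
* **No multiplicity correction across the median and mean endpoints**;
  they are reported separately as two views of the same contrast.

## A minimal run

```r
library(peristroma)

cfg <- synthetic_config(width = 512, height = 512, pixel_size = 2,
                        n_cells = 20000, positive_fraction = 0.1,
                        bias_length = 15, seed = 1)
ds <- generate_dataset(cfg)
bias <- sample_bias(ds$sample, R = 999, seed = 2)
bias[, c("delta_median", "ks_d", "p_left")]
plot_ecdf_overlay(cell_distances(ds$sample))
```

## Known limitations

* Distances are raster distances to stroma *pixels*, not to polygon
  boundaries; at coarse pixel sizes the discretization error
  (≤ pixel\_size/√2) matters for cells hugging the boundary.
* The avatar null is fully exchangeable among tumor cells; it does not
  condition on local cell density, so confounders that correlate both
  with position and with marker status (e.g. hypoxia gradients away from
  vessels) are attributed to "stroma proximity".
* The asymptotic KS p-value is anti-conservative for heavily tied small
  samples; at the intended scale (10³–10⁵ cells) this is immaterial and
  $D$ itself is the reported quantity.
* Group tests treat tumors as independent replicates; repeated sections
  from one tumor should be merged or averaged upstream.
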