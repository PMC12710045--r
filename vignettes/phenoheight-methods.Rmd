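---
title: "Models and methods behind phenoheight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenoheight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phenoheight` reimplements, as testable R code, the analysis chain of a
UAV-based plant-height phenotyping campaign: surface modelling from sensor
returns, per-plot height extraction, regression calibration against manual
measurements, trajectory clustering, and a kinship-corrected association
scan. This vignette documents the models, the default parameters and their
rationale, and the places where the design was genuinely open.

## The synthetic field trial

All validation rests on a generator whose outputs carry their ground truth.

**Field geometry.** Plots of 4.5 m × 5.0 m (the standard footprint of the
variety trials this pipeline targets) on a rectangular grid with 0.5 m
bare-soil alleys and a half-alley margin. Accession *i* occupies plot *i*.

**Terrain.** A band-limited sum of six random-phase sinusoids with
wavelengths of 0.8–2.5 field lengths, scaled so the surface stays within
±`relief_amplitude` (default 0.15 m) of zero. Levelled production fields
have gentle grades; long wavelengths keep local slopes near or below the
~2 % typical of graded fields, which matters because the ground classifier
fits local planes. With `relief_amplitude = 0` the field is exactly flat,
which the noiseless-limit tests exploit.

**Growth.** Each accession follows a 3-parameter logistic
$h(t) = A / (1 + e^{-r(t - t_{mid})})$ sampled at five acquisition days
(0, 7, 14, 20, 27 — a rapid-growth window between squaring and manual
topping). The literature on such campaigns shows sigmoidal
increase-then-plateau height curves without committing to a parametric
family; the logistic is the simplest monotone S-curve with interpretable
asymptote/rate/midpoint. Accessions belong to `n_clusters` growth habits
whose mean rate (and, secondarily, mean asymptote) increase with cluster
index. The `separation` knob is defined in units of the within-cluster
rate standard deviation (0.012 d⁻¹), so `separation = 0` makes clusters
exchangeable and `separation ≥ 4` makes them well separated. Within-cluster
nuisance spread is deliberately modest (asymptote sd 0.02 m, midpoint sd
0.4 d) so that `separation` is the operative recoverability parameter, and
each trajectory additionally carries independent per-time-point
fluctuation (sd 0.025 m) — the biological and extraction-epoch variation
real trajectories show — passed through a running maximum so heights stay
non-decreasing before topping. That fluctuation term matters for the gap
statistic (below): it keeps within-cluster scatter from collapsing onto a
one-dimensional curve manifold.

**Sensor model.** Returns are placed uniformly at `point_density`
(default 100 m⁻², of the order of a low-altitude LiDAR flight), with
vertical Gaussian noise (`noise_sd`, default 0.02 m), a fraction
`outlier_rate` of gross ±5 m outliers to exercise denoising, and a canopy
modelled as a height plateau covering `canopy_cover` (default 0.3) of each
plot — sufficient for plot-level percentile semantics, since the target
quantity is the height of the stem tops, not individual-plant structure.
The RGB branch produces a single surface raster mixing soil cells (terrain)
and canopy cells (terrain + height): no bare-ground flight exists in the
emulated protocol, which is exactly why the percentile extractor must be
datum-free.

**Genetics.** Dosages in {0, 1, 2} with ancestral minor-allele frequencies
uniform on `maf_range`, Balding–Nichols drift between `n_subpop`
subpopulations at differentiation `fst_like`, and missing calls at random.
Phenotypes decompose as causal + polygenic + residual, rescaled so the
realised accession-level heritability equals `h2` exactly and the causal
share of genetic variance equals `1 - polygenic_share`. When structure is
present, a fraction `structure_share` (default 0.5) of the polygenic
variance is aligned with subpopulation membership: this is the classic
confounder that inflates a naive scan and that the kinship correction must
absorb; without it, the alignment of a purely random polygenic draw with
structure varies wildly between seeds and the "naive scan inflates" control
becomes a coin flip. The default panel is 419 accessions — the panel size
of the motivating campaigns — by a few thousand SNPs, a desk-scale stand-in
for millions of markers.

## Surface models

* **Voxel resampling** (default 0.03 m) keeps the return closest to each
  voxel centroid; output is a subset of the input.
* **Denoising** is statistical outlier removal: drop points whose mean
  distance to their `k = 8` nearest neighbours exceeds the global mean by
  `3` standard deviations. These defaults are the common defaults of
  point-cloud toolchains; the upstream acquisition software does not
  document its own.
* **Ground classification** seeds with per-cell minima on a coarse 0.5 m
  grid, flags cells whose minimum sits more than `veg_thresh = 0.2` m above
  the windowed minimum as vegetated, fits a plane to the remaining minima
  in a 7×7-cell window, and labels a point ground when it lies within
  `slope_tol = 0.08` m of that plane. This is the standard open equivalent
  (progressive-morphological in spirit) of the proprietary classifier used
  by commercial LiDAR suites. The window half-width (1.5 m) must out-span
  half a canopy patch; the defaults assume `canopy_cover ≤ ~0.4`.
  `slope_tol` trades ground recall against rejecting short early-season
  canopies (~0.15 m); 0.08 m ≈ 4 noise standard deviations keeps recall
  high at `noise_sd = 0.02` while staying below the earliest canopy.
* **DSM** is the per-cell maximum of returns (empty cells are nodata);
  **DTM** is Delaunay (TIN) linear interpolation of ground points with
  nearest-neighbour fill outside the hull, via the `interp` package. Dense
  clouds are first thinned to the per-cell lowest ground return on a grid
  sized to keep ≤ 20 000 triangulation points: on smooth terrain the extra
  points buy no accuracy and the triangulation is memory-hungry.
* **CHM = DSM − DTM**, negative values clamped to zero (negative canopy
  height is physically meaningless), nodata propagating from either
  operand. The default raster cell is 0.05 m: commercial products advertise
  0.01 m, but 0.05 m keeps a 60-plot raster in tens of megabytes with no
  measurable height-recovery penalty at plot level.

## Plot extraction

Masks are plot rectangles inset by `shrink` per side (demarcation is
repeated per acquisition in real campaigns as canopies grow; the inset may
differ per time point). Cells belong to a mask when their centre falls
inside the polygon.

The RGB extractor returns
`max(percentile(v, 95..98)) − min(percentile(v, 1..2))`: the low band
stands in for the ground, the high band for the stem tops. By percentile
monotonicity this equals p98 − p1; the interval grid is evaluated anyway
and the identity is asserted in tests, keeping the field protocol's
phrasing as the API. Percentiles use linear interpolation between order
statistics (type 7) — dialects differ, so this is stated. Because only
within-mask differences enter, the result is invariant to the absolute
elevation datum. The LiDAR extractor aggregates in-mask CHM values; the
default p95 is robust to residual outliers while tracking the canopy top
(max and mean-top-decile are options; the manual reference value averages
a dozen stem tops per plot, which p95 of a plateau canopy approximates
well). Both extractors require ≥ 20 in-mask cells and record failures as
`NA`, never zero.

## Calibration

Fifteen regression families map extracted to measured heights. Polynomials
(degree 1–3) and the classic ML set are fitted through the installed
ecosystem (randomForest, ranger extra-trees, rpart, FNN, MASS::rlm Huber,
closed-form ridge) where an implementation exists; least-angle regression,
orthogonal matching pursuit, Bayesian ridge (evidence iteration) and
AdaBoost.R2 are implemented in-package, and the two gradient-boosting
families are xgboost presets (loss-guided/leaf-wise vs depth-wise), since
matching specific vendor libraries is not the point of the comparison. All
stochastic families are deterministic given a seed.

The train/test protocol mirrors the field design: 24 plots measured at all
five times form the pooled 120-pair training set (whether real campaigns
pool across times or fit per time is ambiguous; pooling is the default and
a per-time option exists), the whole panel measured at times 4 and 5 forms
the test set, training plots excluded. Families are ranked by training R²
with RMSE as tie-break — the selection criterion the protocol prescribes.
Note that nested polynomials make "poly-k beats poly-(k−1) on training R²"
automatic; the interesting check, asserted in the acceptance suite, is that
the quadratic's coefficients recover an injected quadratic distortion
within their 95 % confidence intervals.

The metric suite is R² = 1 − Σ(Zmᵢ−Zpᵢ)²/Σ(Zmᵢ−Z̄m)², MAE, MSE,
RMSE = √MSE, RMSLE = √(mean(log(1+Zp) − log(1+Zm))²) and
MAPE = mean(|Zm−Zp|/|Zm|). R² with zero-variance measurements is reported
as `NA` (undefined), not 0.

## Trajectory clustering

K-means uses Lloyd iterations with k-means++ seeding, best of `n_init = 10`
restarts by within-cluster sum of squares, on raw heights in metres — the
five time points share units and absolute height is part of the growth
habit, so no z-scoring (a config option flags this choice). Missing cells
are mean-imputed per time point.

The cluster count comes from the Tibshirani gap statistic,
`Gap(k) = E*[log W_k] − log W_k`, with `B = 50` uniform reference sets
drawn in the box aligned with the data's principal components (Tibshirani's
method "b"). Growth trajectories are strongly correlated across time
points; a raw feature-wise box is almost entirely empty of realistic curves
and makes the gap curve rise monotonically. The chosen k is the global
maximiser, matching the "largest gap" reading of the reference protocol;
under the generator's conditions (5 clusters, separation ≥ 4, n = 419) the
curve has a genuine interior maximum at k = 5. The elbow curve (largest
second difference of log-WCSS; the log scale keeps the always-huge first
drop of a spread-out panel from masking the elbow) is reported as a
diagnostic, with the gap as the authoritative selector.

Cluster recovery is always scored by adjusted Rand index — labels are
arbitrary under permutation.

## Association

**BLUE.** Accession estimates from the two-way fixed-effects least-squares
model (accession + replicate), predictions averaged over replicate levels.
Balanced designs give accession means exactly; single-record accessions
pass through. The generator supports both the single-plot and the
three-replicate design, since field protocols use either.

**QC.** SNPs kept when MAF > 0.05 (computed on non-missing calls) and
missing fraction < 0.10 — both strict inequalities, as in the PLINK-style
rule the protocol quotes.

**Kinship.** Identity-by-state similarity,
`K = 1 − mean|gᵢ − gⱼ|/2`, after per-SNP mean imputation — the default
relatedness matrix of EMMAX-style pipelines (VanRaden is a config
alternative left out of scope here).

**Scan.** The EMMAX approximation: variance components (σ²g, σ²e) are
estimated once under the null by REML on the eigenbasis of S K S (S the
projection off the null fixed effects), profiling the likelihood over the
variance ratio on a log grid refined by golden-section optimisation
(tolerance 1e-8); the phenotype, covariates and dosages are rotated into
the kinship eigenbasis, whitened with the fitted weights, and each SNP gets
a generalized-least-squares Wald t-test. With K = I this reduces exactly to
per-SNP OLS, which the tests use as an oracle. Missing dosages are
mean-imputed for kinship and scan; for haplotype grouping they are
excluded, never imputed. Covariates (e.g. structure PCs) are optional and
off by default — the reference protocol does not state any.

**Significance and peaks.** The flat threshold −log₁₀ p ≥ 5 (inclusive).
The protocol labels 10⁻⁵ "Bonferroni-corrected" while using it as a flat
control threshold; the flat threshold is implemented. Significant SNPs
merge into a peak while gaps stay below 500 kb (reported peak spans in
comparable studies are 0.13–0.7 Mb; configurable), peaks from different
time points replicate when their intervals intersect, and genes overlap a
peak by ≥ 1 bp on 1-based inclusive GFF3 coordinates (BED exports convert
to 0-based half-open).

**Haplotypes.** Accessions homozygous at both of two chosen SNPs are
partitioned by joint genotype; the two most frequent joint genotypes form
the haplotype groups (≥ 3 accessions each required) and group means are
compared per time point with Welch's t-test.

## Problem sizes and what the tests do (and do not) show

The package validates itself at desk scale: a 60-plot field for the
point-cloud branch (five acquisitions, ~165 000 returns each), 419
accessions for clustering and association, 800–2 000 SNPs per scan, 10–50
simulation replicates per property, and a 12-plot configuration for the
end-to-end determinism check. These sizes were chosen so the full suite
runs in minutes on a laptop while keeping every statistical check
well-powered; all of them scale with configuration values, not code.

Passing on synthetic fields demonstrates that the algorithms are
implemented correctly and behave as the theory predicts under the
generator's assumptions: plateau canopies, Gaussian sensor noise, uniform
return density, logistic growth, additive genetics. It does not certify
performance on real fields, where canopies are heterogeneous and gappy,
occlusion and multi-path produce structured (not Gaussian) errors,
demarcation masks are hand-drawn, growth deviates from any parametric
curve, and linkage disequilibrium gives association peaks their width. In
the integrated default pipeline the planted major QTL deliberately
dominates the height variance so that a 60-accession demo can recover it;
as a side effect the trajectory clusters blur there — cluster-count
recovery is demonstrated under the dedicated growth-truth conditions, where
genetics and cluster structure are not competing for the same variance.

## Known limitations

No SfM/photogrammetry internals (surface rasters are generated, not
reconstructed from images); no multi-return waveform physics; no LD in the
genotype generator, so peak widths come from the merge window rather than
from linkage; no multi-locus or Bayesian association models; no LAS binary
I/O (XYZ text with gzip stands in); rasters travel as ESRI ASCII grid
text rather than GeoTIFF.
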