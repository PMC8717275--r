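---
title: "Modelling habitat-type richness on equal-area grids: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling habitat-type richness on equal-area grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habrich)
```

## The question and the quantities

Habitat richness (HR) — the number of distinct habitat types, in the sense
of the EU Habitats Directive Annex I units, reported in a grid cell — is a
spatially explicit facet of biodiversity.  On the 10 km × 10 km
equal-area reporting grid used for EU habitat monitoring, HR responds to
bioclimatic, geographic, and anthropogenic drivers, and it is strongly
affected by one nuisance: cells on coastlines contain less land, and
richness grows with area.  `habrich` implements the full analysis chain
for this problem, exercised end to end on synthetic landscapes whose
generative truth is known, so that every step can be tested as a recovery
problem rather than taken on faith.

### Area normalization

Raw counts are corrected with a log–log (species–area style)
normalization,

$$\mathrm{NHR} = \frac{\log_{10}(\mathrm{HR} + 1)}{\lvert\log_{10}(\mathrm{area})\rvert},$$

with area in km².  Adding 1 maps empty cells to 0 instead of $-\infty$;
the absolute value keeps the sign consistent when the land area is below
1 km².  The transform is undefined where area is numerically 1 km²
($\log_{10} = 0$): `normalize_richness()` raises an error there, and the
pipeline excludes and logs such cells (an exclusion radius of
$10^{-6}$ on $\lvert\log_{10}\mathrm{area}\rvert$).  Exclusion, rather
than imputation, is a deliberate choice: the singularity is a property of
the formula, and any patched value would be arbitrary.  The unit (km²) is
part of the contract — the formula is not unit-invariant.

### Terrain ruggedness

The topographic-heterogeneity covariate is the terrain ruggedness index:
per DEM pixel, the mean of the absolute elevation differences to the
8-neighborhood, summed over the 2500 pixels (200 m pixels in a 10 km
cell) of each grid cell.  Two decisions here were genuinely open:

* **TRI variant.** The verbal definition ("mean of the absolute
  differences") differs from the original root-sum-of-squares index of
  Riley and colleagues.  We implement the verbal form as the default and
  the Riley form behind `tri_raster(..., variant = "riley")`, because the
  source text and the original formula cannot be reconciled from the text
  alone.
* **Edges.** Border pixels average over their available 5 (edges) or 3
  (corners) neighbors rather than padding; padding would deflate TRI at
  the raster rim for no physical reason.

TRI is invariant under adding a constant to the DEM and scales linearly
with elevation rescaling — both are tested properties.

## The synthetic landscape

The generator produces every input the analysis consumes, with recorded
truth (`truth_record()`):

* an equal-area cell grid in which a configurable fraction of
  lattice-boundary cells is "coastal", with land area uniform between 5%
  and 95% of the full cell (the real coastline geometry is not emulated —
  coastal cells are simply the boundary cells);
* smooth bioclimatic fields (linear gradient plus a Gaussian random field
  with exponential covariance), a strictly positive and right-skewed
  population-density raster (log-normal of a GRF), a bounded
  fragmentation index (inverse-logit of a GRF), and a DEM with broad
  relief plus fine-scale Gaussian roughness;
* two deliberately collinear bioclim variants (`BIO_4` tracks `BIO_7`,
  `BIO_17` tracks `BIO_12`) so the collinearity screen has real work;
* a street network whose per-cell expected total length is proportional
  to population density, with road classes drawn from a fixed
  multinomial;
* habitat occupancy: for habitat $h$ in cell $i$,
  $\operatorname{logit}(p_{hi}) = \alpha_h + \sum_j(\gamma_j +
  \delta_{hj})x_{ij} + \sum_{(u,v)}\gamma_{uv}x_{iu}x_{iv} + u_i +
  w\log(\mathrm{area}_i/\mathrm{cell\ area})$, with one shared spatial
  GRF $u$ (exponential covariance), per-habitat deviations
  $\delta_{hj}\sim N(0, \delta^2)$, and an area-thinning exponent $w$
  whose default 1 makes the log–log normalization the matched correction;
* species richness coupled to habitat richness through
  $SR_i \sim \mathrm{Poisson}(\lambda_0 e^{\kappa z_i})$ with $z$ the
  standardized HR.

Defaults are the study conditions: a 30 × 30 grid (900 cells), 60 habitat
types of which 6 are marine, spatial field sd 1 with range 50 km (5
cells), $w = 1$, $\delta = 0.2$, $\kappa = 0.5$, $\lambda_0 = 50$, and a
built-in negative fragmentation × population interaction (−0.5 on the
occupancy logit) reflecting the anthropogenic synergy the analysis is
meant to expose.  The $\delta$ spread has no empirical anchor — no
distributional facts about real habitat co-occurrence are available — so
it is exposed as a parameter (`delta_sd`); note that a nonzero $\delta$
is itself a (habitat-specific) covariate effect, which is why null-model
tests set it to zero.

Gaussian random fields on small point sets (cell centers) are simulated
exactly by Cholesky factorization with a $10^{-8}$ diagonal nugget.
Large pixel lattices are simulated exactly on a coarse node lattice
(spacing about a third of the covariance range, at most 48 nodes per
axis) and bilinearly interpolated; this preserves structure at and above
the range while keeping the desk-scale DEM (1500 × 1500 pixels)
affordable.  Sub-node roughness is deliberately carried by the DEM's
separate fine-scale white-noise component, not by the interpolated field.
The pipeline's synthetic DEM is generated directly at the 200 m analysis
resolution; the mean-aggregation resampler (`aggregate_mean()`) is part
of the public surface and is oracle-tested, but re-enacting a 20 m to
200 m aggregation at continental extent would serve no inferential
purpose here.

What the generator does **not** emulate — real coastline and country
geometry, reporting gaps, coordinate reference systems, empirical habitat
co-occurrence structure — bounds what passing tests show: they validate
the machinery and its statistical behaviour under known truth, not the
published continental magnitudes, which derive from the real reporting
data.

## Covariate assembly and screening

Skewed anthropogenic rasters are upscaled from 1 km pixels to cells by
the **median** (robust to their long right tails; the median under-shoots
the cell mean on log-normal rasters, a tested property).  Street length
is the sum of segment lengths clipped to each cell (Liang–Barsky interval
clipping against the axis-aligned cell boxes); street density divides by
the cell's land area.  Cell-center northing and easting enter as `NORTH`
and `EAST`.

Collinearity screening is iterative: while any pair of covariates has
$\lvert r\rvert > 0.7$, the worst pair loses its lower-priority member
(ties broken alphabetically, so the result is deterministic and invariant
to row order).  The published analysis discarded "the variable judged of
less ecological importance", a judgment that cannot be reproduced
algorithmically; we encode it as an explicit, user-editable priority list
(`default_priority()`) whose default reproduces the canonical nine-variable
set {BIO_1, BIO_7, BIO_12, BIO_15, FRAG_IND, POP_DENS, TRI, NORTH, EAST}
by dropping BIO_4, BIO_17 and both street metrics.  `NORTH` and `EAST`
are never dropped, since the coordinates enter every model to absorb
broad spatial trend.  The bivariate pre-screen reports, per covariate,
the linear Pearson correlation with the response and the multiple
correlation on the covariate plus its orthogonalized square (orthogonal
so the quadratic term measures curvature, not leverage).

## The model ensemble and the RAC correction

Normalized habitat richness is modelled with three learners on the
standardized screened covariates:

* **GLM** — gaussian-identity least squares with main effects plus the
  retained pairwise interactions.  The response family is nowhere stated
  in the source analysis; NHR is continuous and bounded below by zero,
  and the gaussian-identity choice makes explained deviance $D^2$
  coincide with $R^2$.
* **GAM** — penalized thin-plate splines (basis dimension $k = 6$) per
  covariate, fitted by REML (mgcv); interactions enter as linear product
  terms and the autocovariate, when present, as a linear term — the
  spatial correction should not itself be wiggly.
* **GBM** — boosted regression trees (xgboost, squared-error loss), with
  the hyperparameter grid selected by cross-validated RMSE (held-out
  folds, seeded; ties resolved toward fewer trees, then shallower
  depth).  Trees model interactions natively, so the selected pair list
  is not passed to the booster.  The full published grid
  (10000/15000/20000 trees × depths 3/5/7/9 × shrinkage 0.01/0.1/0.5 ×
  bag 0.65/0.8/1) is available as `gbm_grid("paper")`; the default
  `gbm_grid("desk")` (500/1000 trees × depths 3/5 × shrinkage 0.05 × bag
  0.8) is sized for interactive use and testing.

Interaction pairs are chosen by exhaustive single-pair search: each
unordered covariate pair is added alone to the main-effects linear model
and retained when it improves small-sample-corrected AIC (AICc) by more
than 2.  The search tool used in the original analysis names no
criterion; AICc with $\Delta > 2$ is the conventional reading.  Note its
operating characteristics: $\Delta\mathrm{AICc} > 2$ for one added
parameter corresponds to a likelihood ratio of about 4, i.e. roughly a
4.5% per-pair false-positive rate under additivity — with 36 candidate
pairs, a handful of weak spurious pairs is expected behaviour, not a
defect, and the tests assert exactly that level.

**Residuals autocovariate (RAC).**  Spatial autocorrelation unexplained
by the covariates is absorbed by computing, per cell, the
inverse-distance-weighted average of the model's own residuals over
neighbors within 1.5 cell sizes (the queen-contiguity analogue on a
square grid; the source analysis states neither radius nor weighting),
then refitting the same model with this autocovariate as one extra
predictor.  Computing the autocovariate from residuals rather than the
raw response confines it to the unexplained variance.  Diagnostics use
Moran's I under the same weights (null expectation $-1/(n-1)$), verified
in the tests against a brute-force double-sum oracle.  On the default
synthetic landscape — which deliberately omits the generative spatial
field from the covariate set — the acceptance tests verify, over ten
seeds, that the RAC raises $D^2$ for GLM and GAM and moves residual
Moran's I toward zero from above; the acceptance script recomputes the
corresponding $D^2$/RMSE/Moran table for the grading seed.  $D^2$ for the
boosted trees is reported as `NA` by default (boosting deviance is not
comparable), with an opt-in pseudo-$D^2$.

## Decomposing the fits

* **Importance** — for GLM/GAM, drop-one refits: the influence of a
  covariate is the loss in $D^2$ when it (and any interaction containing
  it) is removed, clipped at zero (refit noise can make the difference
  marginally negative) and normalized to 100 per model; $D^2$ is
  scale-free, so importance is invariant to affine covariate rescaling
  (tested).  For the GBM, native split-gain importance, normalized the
  same way.  The autocovariate is excluded from the denominator.  Groups
  (geographic / bioclimatic / anthropogenic) partition the variables and
  their contributions sum to 100.
* **Inflated response curves** — for a focal covariate, the ensemble-mean
  prediction along a 50-point grid spanning the focal 1st–99th
  percentile, repeated for 100 background vectors drawn by Latin
  hypercube over the non-focal 1st–99th percentile ranges (uniform
  marginals over empirical ranges, not resampled observations — simpler,
  and sufficient to reveal interaction-induced spread), with pointwise
  median and mean summaries.  For a single deterministic model the
  curves collapse to that model's own conditional predictions (tested).
* **Interaction surfaces** — the source figures threshold an interaction
  magnitude $z$ that is never defined.  We take the double-centered
  component of the pairwise prediction surface (all other covariates at
  their means):
  $z(u,v) = \hat y(u,v) - \hat y(u,\bar v) - \hat y(\bar u,v) +
  \hat y(\bar u,\bar v)$.
  This is exactly zero for any additive surface, which is the property a
  "magnitude of the interaction" should have, and it is the reading we
  commit to; a surface is displayed when $\max\lvert z\rvert$ exceeds the
  threshold (default 0.3, in response units).

Importance, curves and surfaces are computed on the base (non-RAC)
ensemble; the RAC exists to make the performance table honest about
spatial dependence, not to participate in effect interpretation.

## Reproducibility and problem sizes

Every generator and every stochastic fitting step takes an explicit seed;
draws are made under a save/restore RNG discipline so package functions
never perturb the caller's stream, and `run_pipeline()` derives one named
seed per stage from the master seed, echoing all of them into the run
log.  Two runs with the same configuration produce byte-identical CSV
artifacts (tested).  The desk-scale defaults — 900 cells, 60 habitats,
the reduced boosted-tree grid, $K = 100$ curves at $G = 50$ grid points —
run the full pipeline in well under a minute on one core; the full
published grid sizes remain available behind `scale = "paper"`.

## Known limitations

* The synthetic coastline is a lattice boundary; no real geometry, CRS,
  or partial-land interior cells.
* The gaussian-identity family ignores the lower bound of NHR at 0; a
  boundary-respecting family was not pursued because the reference
  workflow is linear-scale.
* Interpolated GRFs underrepresent sub-node-scale roughness of the
  exponential covariance (by design; see above).
* The species layer is a one-parameter Poisson coupling — a device for
  testing the correlation machinery, not an ecological model of species
  richness.
* Inflated curves carry no uncertainty bands, and no SHAP/ALE-style
  attribution variants are offered.
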