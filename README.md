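# habrich

Drivers of habitat-type richness on equal-area monitoring grids.

## The problem

EU member states report the distribution of protected habitat types
(Habitats Directive Annex I units) on a standard 10 km × 10 km grid.
The number of distinct habitat types per cell — **habitat richness (HR)**
— is a spatially explicit biodiversity measure in its own right and a
practical proxy for species richness.  Analysing its drivers raises four
methodological problems that this package solves as one tested pipeline,
for macroecologists and biodiversity-informatics practitioners:

1. **Unequal land area.** Coastal cells hold less land, and richness
   grows with area.  Counts are corrected by a log–log species–area style
   normalization:

   `NHR = log10(HR + 1) / |log10(area)|`, area in km².

2. **Covariate construction.** A terrain ruggedness index (TRI: per-pixel
   mean absolute elevation difference to the 8-neighborhood, summed over
   the 2500 × 200 m pixels of each cell), median-upscaled skewed
   anthropogenic rasters, street length/density clipped to cells, and
   cell coordinates; followed by an iterative Pearson |r| > 0.7
   collinearity screen with an explicit keep-priority list.

3. **Spatial dependence.** A three-model ensemble — gaussian GLM,
   penalized-spline GAM (mgcv), boosted regression trees (xgboost) with a
   grid search by cross-validated RMSE — each refitted with a
   **residuals autocovariate (RAC)**: the inverse-distance-weighted
   average of the model's own residuals within 1.5 cell sizes, added as
   one extra predictor.  Explained deviance D², RMSE, and residual
   Moran's I are reported with and without the RAC.

4. **Interpretation.** Drop-one D² (GLM/GAM) and split-gain (GBM)
   variable importance, grouped into geographic / bioclimatic /
   anthropogenic contributions; inflated response curves (100
   Latin-hypercube background draws per focal variable, averaged across
   the models); and interaction surfaces whose magnitude
   `z(u,v) = ŷ(u,v) − ŷ(u,v̄) − ŷ(ū,v) + ŷ(ū,v̄)` is zero for additive
   models and thresholded (default |z| > 0.3) for display.

Because the real reporting data are not bundled, the package ships a
first-class synthetic-landscape generator (`gen_grid()`, `gen_fields()`,
`gen_streets()`, `gen_occupancy()`, `gen_species()`) with recorded
generative truth, so every stage is validated by parameter-recovery tests
rather than fixtures.

## Worked example

```r
library(habrich)

# Eq.-style normalization: 9 habitats in a full 100 km^2 cell
normalize_richness(9, 100)
#> [1] 0.5

# full desk-scale pipeline on a 30 x 30 synthetic landscape
report <- run_pipeline(pipeline_config(seed = 1))
print(report)
#> <pipeline_report> 900 cells, 60 habitats
#> HR in [0, 52]; r(HR, SR) = 0.923
#>          model rac    D2    RMSE  moran_i
#> 1          GLM  no 0.526 0.12890  0.36091
#> 2 GLM with RAC yes 0.709 0.10105 -0.12834
#> 3          GAM  no 0.586 0.12056  0.31531
#> 4 GAM with RAC yes 0.715 0.09997 -0.12273
#> 5          GBM  no    NA 0.00316 -0.00967
#> 6 GBM with RAC yes    NA 0.00268 -0.00521
```

Reading the table: the base GLM explains 53% of the deviance and leaves
strong positive residual spatial autocorrelation (Moran's I = 0.36,
against a null expectation of −1/899 ≈ 0) because the landscape's
generative spatial field is not among the covariates.  Adding the
residuals autocovariate raises D² to 0.71 and pulls residual Moran's I
to near zero, the signature of a successful spatial correction.  GBM D²
is reported as `NA` (boosting deviance is not comparable; see
`goodness(..., include_gbm_d2 = TRUE)`).  `report$importance`,
`report$groups`, `report$curves` and `report$surfaces` hold the
variable-importance tables, the inflated response curves, and the
thresholded interaction surfaces; with the default truth, the geographic
group (NORTH, EAST, TRI) carries the largest cumulative influence and the
built-in fragmentation × population interaction surfaces with the
expected sign pattern (fragmentation helps at low population density,
harms at high).

A thin command-line wrapper is included:

```sh
Rscript inst/cli/habrich.R --seed 1 --outdir habrich-run --scale desk
```

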