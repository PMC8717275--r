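test_that("gen_grid places coastal cells on the boundary with reduced area", {
  spec <- grid_spec(5, 5)
  full <- gen_grid(spec, coastal_fraction = 0)
  expect_equal(nrow(full), 25)
  expect_true(all(full$land_area == 100))

  coast <- gen_grid(spec, coastal_fraction = 1, seed = 7)
  boundary <- coast$row %in% c(1, 5) | coast$col %in% c(1, 5)
  expect_equal(sum(boundary), 16)
  expect_true(all(coast$land_area[boundary] < 100))
  expect_true(all(coast$land_area[boundary] > 0.05 * 100))
  expect_true(all(coast$land_area[!boundary] == 100))

  expect_identical(coast, gen_grid(spec, coastal_fraction = 1, seed = 7))
  expect_error(gen_grid(spec, coastal_fraction = 1.2), "proportion")
  expect_false(identical(coast, gen_grid(spec, 1, seed = 8)))
})

test_that("gen_grid does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- rnorm(1)
  set.seed(99)
  invisible(gen_grid(grid_spec(4, 4), 0.5, seed = 3))
  expect_identical(rnorm(1), a)
})

test_that("gen_fields produces the advertised field families", {
  spec <- grid_spec(5, 5)
  cfg <- list(
    POP = list(type = "lognormal-grf", meanlog = 3, sdlog = 1.2,
               range = 30, pixel_size = 1),
    FLAT = list(type = "gradient+grf", mean = 4, slope_north = 0,
                slope_east = 0, sd = 0, range = 30, pixel_size = 10),
    FRAG = list(type = "logit-grf", mean_logit = -1, sd = 1.5, range = 30,
                pixel_size = 1)
  )
  f <- gen_fields(spec, cfg, seed = 3)
  x <- as.vector(f$POP$values)
  expect_true(all(x > 0))
  skew <- mean(((x - mean(x)) / sd(x))^3)
  expect_gt(skew, 1)
  expect_true(all(f$FLAT$values == 4))
  expect_true(all(f$FRAG$values > 0 & f$FRAG$values < 1))
  expect_identical(f, gen_fields(spec, cfg, seed = 3))
  expect_error(gen_fields(spec, list(X = list(type = "nope")), 1),
               "unknown field type")
})

test_that("fine-scale DEM noise strictly increases per-cell TRI sums", {
  spec <- grid_spec(5, 5)
  cells <- gen_grid(spec, 0)
  mk <- function(fine_sd) {
    gen_fields(spec, list(DEM = list(type = "dem", mean = 500,
                                     coarse_sd = 100, coarse_range = 50,
                                     fine_sd = fine_sd, pixel_size = 0.5)),
               seed = 9)$DEM
  }
  smooth <- tri_per_cell(tri_raster(mk(0)), cells)
  rough <- tri_per_cell(tri_raster(mk(50)), cells)
  expect_true(all(rough > smooth))
})

test_that("street totals are proportional to the density field", {
  spec <- grid_spec(4, 4)
  cells <- gen_grid(spec, 0)
  flat <- function(val) raster_field(matrix(val, 40, 40), 1)

  empty <- gen_streets(cells, flat(0), seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(street_metrics(empty, cells)$STREET_LENGTH == 0))

  s1 <- gen_streets(cells, flat(10), seed = 5)
  expect_identical(s1, gen_streets(cells, flat(10), seed = 5))

  tot <- function(d, seed) {
    net <- gen_streets(cells, flat(d), seed = seed)
    sum(sqrt((net$x1 - net$x0)^2 + (net$y1 - net$y0)^2))
  }
  t1 <- mean(vapply(1:100, function(s) tot(10, s), numeric(1)))
  t2 <- mean(vapply(1:100, function(s) tot(20, s), numeric(1)))
  expect_lt(abs(t2 / t1 - 2), 0.2)
  expect_true(all(s1$road_class %in%
                    c("highway", "primary", "secondary", "tertiary",
                      "local")))
})

test_that("null occupancy truth yields no covariate correlation", {
  cells <- gen_grid(grid_spec(30, 30), 0)
  covs <- make_iid_covariates(900, 42)
  rmat <- sapply(1:3, function(s) {
    truth <- truth_record(gamma = setNames(rep(0, 9), names(covs)),
                          gamma_int = NULL, spatial_sd = 0, delta_sd = 0,
                          area_exponent = 0, seed = s)
    hr <- compute_richness(filter_marine(gen_occupancy(cells, covs,
                                                       truth)))
    vapply(covs, function(x) cor(hr, x), numeric(1))
  })
  # each single r has null sd 1/sqrt(900); per-covariate means across the
  # three seeds must sit well inside 0.1, single draws inside the
  # 99.9% null envelope
  expect_true(all(abs(rowMeans(rmat)) < 0.1))
  expect_true(all(abs(rmat) < 3.5 / sqrt(900)))
})

test_that("a strong TRI effect on occupancy shows up in richness", {
  cells <- gen_grid(grid_spec(30, 30), 0)
  covs <- make_iid_covariates(900, 7)
  truth <- truth_record(gamma = c(TRI = 1), gamma_int = NULL,
                        spatial_sd = 0.5, area_exponent = 0, seed = 21)
  hr <- compute_richness(filter_marine(gen_occupancy(cells, covs, truth)))
  expect_gt(cor(hr, covs$TRI), 0.5)
})

test_that("area thinning makes raw richness increase with land area", {
  cells <- gen_grid(grid_spec(20, 20), coastal_fraction = 1, seed = 3)
  covs <- make_iid_covariates(400, 8)
  truth <- truth_record(gamma = c(TRI = 0), gamma_int = NULL,
                        spatial_sd = 0, area_exponent = 1, seed = 2)
  hr <- compute_richness(filter_marine(gen_occupancy(cells, covs, truth)))
  coastal <- cells$land_area < 100
  expect_gt(cor(hr[coastal], cells$land_area[coastal],
                method = "spearman"), 0)
})

test_that("gen_occupancy validates shapes and is seed-deterministic", {
  cells <- gen_grid(grid_spec(4, 4), 0)
  covs <- make_iid_covariates(16, 1)
  truth <- truth_record(gamma = c(TRI = 0.5), gamma_int = NULL, seed = 5)
  expect_error(gen_occupancy(cells, covs[1:10, ], truth), "rows")
  o1 <- gen_occupancy(cells, covs, truth)
  expect_identical(o1$presence, gen_occupancy(cells, covs, truth)$presence)
  expect_equal(sum(o1$marine_flag), truth$n_marine)
  hr <- compute_richness(o1)
  expect_true(all(hr >= 0 & hr <= truth$n_habitats))
})

test_that("species counts couple to richness through kappa", {
  set.seed(31)
  hr <- rpois(900, 10)
  sr0 <- gen_species(hr, kappa = 0, lambda0 = 50, seed = 4)
  expect_lt(abs(cor(hr, sr0)), 0.1)
  sr1 <- gen_species(hr, kappa = 0.5, lambda0 = 50, seed = 4)
  expect_gt(cor(hr, sr1), 0.3)
  expect_identical(sr1, gen_species(hr, kappa = 0.5, lambda0 = 50,
                                    seed = 4))
  expect_error(gen_species(hr, 0.5, lambda0 = 0), "positive")
})
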