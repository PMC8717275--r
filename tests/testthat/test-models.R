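test_that("pairwise interaction search recovers a built-in interaction", {
  vars <- c("BIO_1", "TRI", "FRAG_IND", "POP_DENS", "NORTH")
  hits <- 0; false_pairs <- 0
  for (s in 1:10) {
    tab <- make_iid_covariates(900, 100 + s, vars = vars)
    eps <- rnorm(900, 0, 0.3)
    y_int <- 0.5 * tab$BIO_1 + 0.5 * tab$TRI -
      0.5 * tab$FRAG_IND * tab$POP_DENS + eps
    sel <- select_interactions(tab, y_int)
    lab <- vapply(sel$pairs, function(p) paste(sort(p), collapse = ":"),
                  character(1))
    hits <- hits + ("FRAG_IND:POP_DENS" %in% lab)
    y_add <- 0.5 * tab$BIO_1 + 0.5 * tab$TRI + eps
    false_pairs <- false_pairs +
      length(select_interactions(tab, y_add)$pairs)
  }
  expect_gte(hits, 9)
  # under additivity, AICc improvement > 2 corresponds to a likelihood
  # ratio > ~4, i.e. a ~4.5% per-pair false-positive rate; over
  # 10 seeds x 10 candidate pairs that is ~4.5 expected spurious pairs
  expect_lte(false_pairs, 12)
})

test_that("two covariates give exactly one candidate pair", {
  tab <- make_iid_covariates(100, 3, vars = c("A", "B"))
  sel <- select_interactions(tab, rnorm(100))
  expect_equal(nrow(sel$report), 1)
})

test_that("the linear model recovers known coefficients exactly", {
  tab <- make_iid_covariates(900, 55)
  y <- 2 + 1.5 * tab$TRI + rnorm(900, 0, 0.1)
  fit <- fit_glm(tab, y)
  expect_true(abs(coef(fit$model)["TRI"] - 1.5) < 0.05)

  y0 <- 2 + 1.5 * tab$TRI
  perfect <- fit_glm(tab, y0)
  expect_equal(perfect$d2, 1, tolerance = 1e-12)
  expect_lt(perfect$rmse, 1e-10)

  noise <- fit_glm(tab, rnorm(900, 0, 1) + 5)
  expect_lt(noise$d2, 0.05)

  tab$DUP <- tab$TRI
  expect_error(fit_glm(tab, y), "aliased")
})

test_that("the GAM beats the GLM on smooth nonlinear signal only", {
  tab <- make_iid_covariates(900, 66, vars = c("TRI", "BIO_1", "NORTH"))
  y_sin <- sin(2 * pi * tab$TRI / 4) + rnorm(900, 0, 0.2)
  glm_sin <- fit_glm(tab, y_sin)
  gam_sin <- fit_gam(tab, y_sin)
  expect_gt(gam_sin$d2 - glm_sin$d2, 0.1)

  y_lin <- 0.8 * tab$TRI - 0.3 * tab$BIO_1 + rnorm(900, 0, 0.3)
  expect_lt(abs(fit_gam(tab, y_lin)$d2 - fit_glm(tab, y_lin)$d2), 0.02)

  y_exact <- 0.8 * tab$TRI - 0.3 * tab$BIO_1
  expect_lt(suppressWarnings(fit_gam(tab, y_exact))$rmse, 1e-6)
})

test_that("boosted-tree grid search is seeded and depth-sensitive", {
  tab <- make_iid_covariates(400, 77, vars = c("A", "B", "C"))
  y <- tab$A * tab$B + 0.3 * tab$C + rnorm(400, 0, 0.2)

  one <- gbm_grid(n_trees = 300, interaction_depth = 3, shrinkage = 0.1,
                  bag_fraction = 0.8)
  r1 <- fit_gbm_grid(tab, y, one, folds = 3, seed = 5)
  expect_equal(r1$fit$meta$best$n_trees, 300)

  grid <- gbm_grid(n_trees = c(200, 400), interaction_depth = c(1, 3),
                   shrinkage = 0.1, bag_fraction = 0.8)
  r2 <- fit_gbm_grid(tab, y, grid, folds = 3, seed = 5)
  r3 <- fit_gbm_grid(tab, y, grid, folds = 3, seed = 5)
  expect_identical(r2$grid_report, r3$grid_report)
  expect_identical(r2$fit$fitted, r3$fit$fitted)

  rmse_by_depth <- tapply(r2$grid_report$cv_rmse, r2$grid_report$depth, min)
  expect_lt(rmse_by_depth[["3"]], rmse_by_depth[["1"]])
  expect_gt(r2$fit$meta$best$depth, 1)

  expect_error(fit_gbm_grid(tab[1:3, ], y[1:3], grid, folds = 5), "folds")
  expect_error(gbm_grid(bag_fraction = 1.5), "bag_fraction")
})

test_that("the residual autocovariate averages neighborhood residuals", {
  cells <- gen_grid(grid_spec(30, 30), 0)
  set.seed(42)
  white <- rnorm(900)
  ac_w <- residual_autocovariate(white, cells)
  expect_lt(abs(cor(ac_w, white)), 0.15)

  smooth <- habrich:::with_seed(7,
    habrich:::grf_points(cbind(cells$easting, cells$northing), 50, 1))
  ac_s <- residual_autocovariate(smooth, cells)
  expect_gt(cor(ac_s, smooth), 0.5)

  # a residual vector of zeros everywhere means zero autocovariate
  zeros <- rep(0, 900)
  expect_true(all(residual_autocovariate(zeros, cells) == 0))
  expect_error(residual_autocovariate(white, cells, radius = -1), "radius")
})

test_that("RAC refitting leaves spatially white fits unchanged", {
  cells <- gen_grid(grid_spec(20, 20), 0)
  tab <- make_iid_covariates(400, 9, vars = c("TRI", "BIO_1"))
  y <- 0.5 * tab$TRI + rnorm(400, 0, 0.3)
  base <- fit_glm(tab, y)
  ac <- residual_autocovariate(base, cells)
  rac <- refit_with_rac(base, ac)
  expect_true(rac$has_rac)
  expect_gte(rac$d2, base$d2)          # nested models: D2 cannot drop
  expect_lt(abs(rac$d2 - base$d2), 0.02)

  expect_message(same <- refit_with_rac(base, rep(0, 400)), "constant")
  expect_identical(same$fitted, base$fitted)
})

test_that("goodness statistics match their definitions", {
  cells <- gen_grid(grid_spec(5, 5), 0)
  tab <- make_iid_covariates(25, 2, vars = c("A", "B"))
  y <- 1 + tab$A
  fit <- fit_glm(tab, y)
  g <- goodness(fit, cells)
  expect_equal(g$d2, 1, tolerance = 1e-12)
  expect_equal(g$rmse, 0, tolerance = 1e-10)

  # D2 for the gaussian GLM equals R^2 computed independently
  y2 <- 1 + tab$A + rnorm(25, 0, 0.5)
  fit2 <- fit_glm(tab, y2)
  expect_equal(fit2$d2, summary(fit2$model)$r.squared, tolerance = 1e-12)
})

test_that("Moran's I matches the brute-force double sum and its null", {
  cells <- gen_grid(grid_spec(5, 5), 0)
  set.seed(77)
  x <- rnorm(25)
  expect_equal(morans_i(x, cells),
               oracle_moran(x, cbind(cells$easting, cells$northing), 15),
               tolerance = 1e-12)

  big <- gen_grid(grid_spec(30, 30), 0)
  ivals <- vapply(1:5, function(s) {
    set.seed(s)
    morans_i(rnorm(900), big)
  }, numeric(1))
  expect_true(all(abs(ivals) < 0.05))   # null expectation -1/(n-1)
})

test_that("GBM goodness reports D2 as absent unless requested", {
  tab <- make_iid_covariates(200, 8, vars = c("A", "B"))
  y <- tab$A + rnorm(200, 0.2)
  cells <- gen_grid(grid_spec(10, 20), 0)
  fit <- fit_gbm_grid(tab, y, gbm_grid(n_trees = 100,
                                       interaction_depth = 3,
                                       shrinkage = 0.1, bag_fraction = 0.8),
                      folds = 3, seed = 1)$fit
  expect_true(is.na(goodness(fit, cells)$d2))
  g <- goodness(fit, cells, include_gbm_d2 = TRUE)
  expect_true(g$d2 > 0 && g$d2 <= 1)
})
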