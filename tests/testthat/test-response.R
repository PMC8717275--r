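# A small fitted ensemble on iid covariates with known structure, reused
# across the response-analysis tests.
fit_small_ensemble <- function(y, tab, interactions = list(),
                               gbm_seed = 3) {
  hab_ensemble(
    glm = fit_glm(tab, y, interactions),
    gam = fit_gam(tab, y, interactions),
    gbm = fit_gbm_grid(tab, y,
                       gbm_grid(n_trees = 300, interaction_depth = 3,
                                shrinkage = 0.1, bag_fraction = 0.8),
                       folds = 3, seed = gbm_seed)$fit)
}

test_that("importance normalizes to 100 and finds the dominant driver", {
  tab <- make_iid_covariates(400, 11,
                             vars = c("TRI", "BIO_1", "NORTH", "EAST"))
  y <- 1.2 * tab$TRI + 0.2 * tab$BIO_1 + rnorm(400, 0, 0.3)
  ens <- fit_small_ensemble(y, tab)
  imp <- variable_importance(ens)
  for (m in unique(imp$model)) {
    sub <- imp[imp$model == m, ]
    expect_equal(sum(sub$influence), 100, tolerance = 1e-6)
    expect_equal(sub$variable[which.max(sub$influence)], "TRI")
  }
})

test_that("irrelevant duplicate covariates get near-zero importance", {
  tab <- make_iid_covariates(500, 13, vars = c("TRI", "JUNK_A", "JUNK_B"))
  y <- tab$TRI + rnorm(500, 0, 0.2)
  ens <- fit_small_ensemble(y, tab)
  imp <- variable_importance(ens)
  junk <- imp[imp$variable %in% c("JUNK_A", "JUNK_B"), ]
  expect_true(all(junk$influence < 3))
})

test_that("single-covariate importance is 100% and scale-free", {
  tab <- make_iid_covariates(200, 15, vars = c("TRI"))
  y <- tab$TRI + rnorm(200, 0, 0.3)
  ens <- hab_ensemble(glm = fit_glm(tab, y))
  imp <- variable_importance(ens)
  expect_equal(imp$influence, 100)

  # GLM drop-one D2 importance is invariant to affine covariate rescaling
  tab2 <- make_iid_covariates(300, 16, vars = c("TRI", "BIO_1", "NORTH"))
  y2 <- tab2$TRI - 0.5 * tab2$BIO_1 + rnorm(300, 0, 0.3)
  i1 <- variable_importance(hab_ensemble(glm = fit_glm(tab2, y2)))
  tab3 <- tab2
  tab3$TRI <- 100 * tab3$TRI - 7
  tab3$BIO_1 <- 0.01 * tab3$BIO_1 + 3
  i2 <- variable_importance(hab_ensemble(glm = fit_glm(tab3, y2)))
  expect_equal(i1$influence, i2$influence, tolerance = 1e-8)
})

test_that("group contributions sum member influences", {
  imp <- data.frame(model = "glm", variable = bold_roster,
                    influence = rep(100 / 9, 9))
  grp <- group_contributions(imp)
  expect_equal(grp$influence[grp$group == "geographic"], 100 / 3,
               tolerance = 1e-9)
  expect_equal(grp$influence[grp$group == "bioclimatic"], 400 / 9,
               tolerance = 1e-9)
  expect_equal(grp$influence[grp$group == "anthropogenic"], 200 / 9,
               tolerance = 1e-9)

  solo <- data.frame(model = "glm", variable = "TRI", influence = 100)
  g2 <- group_contributions(solo)
  expect_equal(g2$influence[g2$group == "geographic"], 100)
  expect_equal(sum(g2$influence), 100)

  bad <- data.frame(model = "glm", variable = "MYSTERY", influence = 100)
  expect_error(group_contributions(bad), "not assigned")
})

test_that("geographic drivers rank first when they dominate the truth", {
  cells <- gen_grid(grid_spec(20, 20), 0)
  covs <- make_iid_covariates(400, 19)
  truth <- truth_record(gamma = c(NORTH = -0.8, EAST = -0.6, TRI = 0.8,
                                  BIO_1 = 0.15, BIO_12 = 0.1),
                        gamma_int = NULL, spatial_sd = 0.3,
                        area_exponent = 0, seed = 5)
  occ <- gen_occupancy(cells, covs, truth)
  rt <- richness_table(occ, cells)
  ens <- fit_small_ensemble(rt$NHR, covs)
  grp <- group_contributions(variable_importance(ens))
  for (m in unique(grp$model)) {
    sub <- grp[grp$model == m, ]
    expect_equal(sub$group[which.max(sub$influence)], "geographic")
  }
})

test_that("inflated curves track the generative slopes", {
  tab <- make_iid_covariates(600, 23, vars = c("TRI", "BIO_1", "NORTH"))
  gamma <- c(TRI = 0.7, BIO_1 = -0.4, NORTH = 0)
  y <- as.matrix(tab) %*% gamma + rnorm(600, 0, 0.05)
  ens <- hab_ensemble(glm = fit_glm(tab, as.numeric(y)),
                      gam = fit_gam(tab, as.numeric(y)))
  for (v in c("TRI", "BIO_1")) {
    rc <- inflated_response_curves(ens, v, K = 30, G = 20, seed = 2)
    slopes <- apply(rc$curves, 2, function(cv)
      coef(lm(cv ~ rc$grid))[2])
    expect_true(all(sign(slopes) == sign(gamma[[v]])))
    expect_lt(sd(slopes), 0.1 * abs(gamma[[v]]))
  }
  null <- inflated_response_curves(ens, "NORTH", K = 30, G = 20, seed = 2)
  med_slope <- coef(lm(null$median ~ null$grid))[2]
  expect_lt(abs(med_slope), 0.05)
})

test_that("curves are deterministic and equal single-model predictions", {
  tab <- make_iid_covariates(300, 29, vars = c("TRI", "BIO_1"))
  y <- 0.5 * tab$TRI + 0.2 * tab$BIO_1^2 + rnorm(300, 0, 0.1)
  solo <- hab_ensemble(glm = fit_glm(tab, y))
  c1 <- inflated_response_curves(solo, "TRI", K = 1, G = 10, seed = 9)
  c2 <- inflated_response_curves(solo, "TRI", K = 1, G = 10, seed = 9)
  expect_identical(c1$curves, c2$curves)

  # the single-model curve is that model's own conditional prediction
  bg <- habrich:::with_seed(9, lhs::randomLHS(1, 1))
  q <- quantile(tab$BIO_1, c(0.01, 0.99), names = FALSE)
  nd <- data.frame(TRI = c1$grid, BIO_1 = q[1] + bg[1, 1] * (q[2] - q[1]))
  expect_equal(as.numeric(c1$curves),
               predict(solo$glm, nd), tolerance = 1e-10)

  expect_error(inflated_response_curves(solo, "AC"), "autocovariate|not a")
})

test_that("double-centered surfaces isolate real interactions", {
  tab <- make_iid_covariates(700, 31,
                             vars = c("FRAG_IND", "POP_DENS", "TRI"))
  y_add <- 0.6 * tab$FRAG_IND + 0.4 * tab$TRI + rnorm(700, 0, 0.2)
  solo <- hab_ensemble(glm = fit_glm(tab, y_add))
  s_add <- interaction_surfaces(solo, G2 = 11)
  expect_true(all(vapply(s_add, function(s) max(abs(s$z)) < 1e-10,
                         logical(1))))
  expect_false(any(vapply(s_add, `[[`, logical(1), "displayed")))

  y_int <- 0.3 * tab$FRAG_IND - 0.5 * tab$FRAG_IND * tab$POP_DENS +
    rnorm(700, 0, 0.2)
  ints <- list(c("FRAG_IND", "POP_DENS"))
  fit <- fit_glm(tab, y_int, ints)
  surf <- interaction_surfaces(hab_ensemble(glm = fit),
                               pairs = ints, G2 = 11)[[1]]
  expect_true(surf$displayed)
  expect_gt(surf$max_abs_z, 0.3)
  # fragmentation helps at low population, harms at high population
  hi <- length(surf$u); lo <- 1
  expect_gt(surf$z[hi, lo], 0)
  expect_lt(surf$z[hi, hi], 0)

  inf_thresh <- interaction_surfaces(hab_ensemble(glm = fit), pairs = ints,
                                     threshold = Inf, G2 = 11)
  expect_false(any(vapply(inf_thresh, `[[`, logical(1), "displayed")))
  expect_error(interaction_surfaces(hab_ensemble(glm = fit),
                                    pairs = list(c("AC", "TRI"))),
               "autocovariate")
})

test_that("additive surfaces double-center to zero on any 2x2 corners", {
  tab <- make_iid_covariates(200, 37, vars = c("A", "B"))
  y <- tab$A + 2 * tab$B
  surf <- interaction_surfaces(hab_ensemble(glm = fit_glm(tab, y)),
                               G2 = 5)[[1]]
  for (i in 1:4) for (j in 1:4) {
    corners <- surf$yhat[i, j] - surf$yhat[i + 1, j] -
      surf$yhat[i, j + 1] + surf$yhat[i + 1, j + 1]
    expect_lt(abs(corners), 1e-10)
  }
})
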