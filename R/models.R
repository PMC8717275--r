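# The three-model ensemble (GLM, GAM, boosted trees), pairwise-interaction
# selection, and the residuals-autocovariate (RAC) correction for spatial
# autocorrelation.
#
# Fit objects share one shape (class "hab_fit") so that prediction,
# goodness-of-fit, RAC refitting, and the response-analysis machinery can
# treat the ensemble uniformly.  The optional autocovariate always travels
# as a plain column named "AC": a linear term in GLM and GAM (never
# smoothed) and an ordinary feature for the boosted trees.

new_hab_fit <- function(kind, model, table, response, interactions,
                        fitted, d2, rmse, meta = list()) {
  res <- response - fitted
  structure(list(kind = kind, model = model, table = table,
                 response = response, interactions = interactions,
                 covariates = setdiff(names(table), c("cell_id", "AC")),
                 features = setdiff(names(table), "cell_id"),
                 has_rac = "AC" %in% names(table),
                 fitted = as.numeric(fitted), residuals = as.numeric(res),
                 d2 = d2, rmse = rmse, meta = meta),
            class = "hab_fit")
}

#' @export
print.hab_fit <- function(x, ...) {
  cat(sprintf("<hab_fit:%s> %d cells, %d covariates%s, D2 = %s, RMSE = %.4g\n",
              x$kind, length(x$response), length(x$covariates),
              if (x$has_rac) " + RAC" else "",
              if (is.na(x$d2)) "NA" else sprintf("%.3f", x$d2), x$rmse))
  invisible(x)
}

check_fit_inputs <- function(table, response) {
  vars <- setdiff(names(table), "cell_id")
  if (length(vars) < 1) stopf("no covariates in table")
  if (nrow(table) != length(response))
    stopf("response length %d does not match %d table rows",
          length(response), nrow(table))
  if (any(!is.finite(response))) stopf("response must be finite")
  if (sd(response) == 0) stopf("constant response: deviance undefined")
  vars
}

fit_stats <- function(response, fitted) {
  sse <- sum((response - fitted)^2)
  sst <- sum((response - mean(response))^2)
  list(d2 = 1 - sse / sst, rmse = sqrt(mean((response - fitted)^2)))
}

# Small-sample corrected AIC for an lm/gam fit.
aicc <- function(m) {
  k <- attr(logLik(m), "df")
  n <- length(residuals(m))
  AIC(m) + 2 * k * (k + 1) / (n - k - 1)
}

#' Select pairwise interactions by exhaustive single-pair search
#'
#' For every unordered covariate pair, fits the main-effects linear model
#' plus that single interaction and scores the improvement in
#' small-sample-corrected AIC (AICc) over the main-effects model.  Pairs
#' improving AICc by more than `delta` are retained, ranked by improvement.
#' Deterministic; pairs whose interaction is aliased are skipped with a
#' warning.
#'
#' @param table Covariate data frame (a `cell_id` column is ignored).
#' @param response Numeric response.
#' @param delta AICc improvement required to retain a pair.
#' @return List with `pairs` (list of length-2 character vectors, best
#'   first) and `report` (data frame of every candidate pair with its
#'   AICc improvement).
#' @export
select_interactions <- function(table, response, delta = 2) {
  vars <- check_fit_inputs(table, response)
  if (length(vars) < 2) stopf("need at least 2 covariates")
  df <- as.data.frame(table)[vars]
  df$.y <- response
  main <- lm(reformulate(vars, ".y"), data = df)
  a0 <- aicc(main)
  cmb <- combn(vars, 2)
  rep_rows <- lapply(seq_len(ncol(cmb)), function(i) {
    u <- cmb[1, i]; v <- cmb[2, i]
    m2 <- lm(reformulate(c(vars, paste0(u, ":", v)), ".y"), data = df)
    if (any(is.na(coef(m2)))) {
      warnf("interaction %s:%s is aliased; skipped", u, v)
      return(data.frame(var1 = u, var2 = v, delta_aicc = NA_real_))
    }
    data.frame(var1 = u, var2 = v, delta_aicc = a0 - aicc(m2))
  })
  report <- do.call(rbind, rep_rows)
  keep <- which(!is.na(report$delta_aicc) & report$delta_aicc > delta)
  keep <- keep[order(-report$delta_aicc[keep])]
  report$retained <- seq_len(nrow(report)) %in% keep
  list(pairs = lapply(keep, function(i) c(report$var1[i], report$var2[i])),
       report = report)
}

interaction_labels <- function(interactions) {
  vapply(interactions, function(p) paste0(p[1], ":", p[2]), character(1))
}

#' Fit the gaussian-identity linear model
#'
#' Exact least squares on the main effects, any retained pairwise
#' interactions, and (if a column `AC` is present) the residual
#' autocovariate as one extra linear predictor.
#'
#' @param table Covariate data frame (a `cell_id` column is ignored; an
#'   `AC` column is treated as the autocovariate).
#' @param response Numeric response (e.g. normalized habitat richness).
#' @param interactions List of length-2 character vectors, e.g. from
#'   [select_interactions()]`$pairs`.
#' @return A `hab_fit` with fitted values, residuals, explained deviance
#'   `D2` (= R^2 for this family), and in-sample RMSE.
#' @export
fit_glm <- function(table, response, interactions = list()) {
  vars <- check_fit_inputs(table, response)
  df <- as.data.frame(table)[vars]
  df$.y <- response
  f <- reformulate(c(vars, interaction_labels(interactions)), ".y")
  m <- lm(f, data = df)
  if (any(is.na(coef(m))))
    stopf("rank-deficient design; aliased terms: %s",
          paste(names(coef(m))[is.na(coef(m))], collapse = ", "))
  st <- fit_stats(response, fitted(m))
  new_hab_fit("glm", m, as.data.frame(table), response, interactions,
              fitted(m), st$d2, st$rmse)
}

#' Fit the gaussian additive model
#'
#' Penalized-spline smooths (thin-plate, basis dimension `k`) for each
#' continuous covariate, linear terms for the retained interaction
#' products and for the autocovariate column `AC` if present.  Fitted by
#' REML via \pkg{mgcv}.
#'
#' @inheritParams fit_glm
#' @param k Basis dimension of each univariate smooth.
#' @return A `hab_fit`.
#' @export
fit_gam <- function(table, response, interactions = list(), k = 6) {
  vars <- check_fit_inputs(table, response)
  smooth_vars <- setdiff(vars, "AC")
  df <- as.data.frame(table)[vars]
  df$.y <- response
  terms <- c(
    vapply(smooth_vars, function(v) {
      kk <- min(k, length(unique(df[[v]])) - 1)
      if (kk >= 3) sprintf("s(%s, k = %d)", v, kk) else v
    }, character(1)),
    vapply(interactions, function(p) sprintf("I(%s * %s)", p[1], p[2]),
           character(1)),
    if ("AC" %in% vars) "AC"
  )
  f <- as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  m <- mgcv::gam(f, data = df, method = "REML")
  st <- fit_stats(response, fitted(m))
  new_hab_fit("gam", m, as.data.frame(table), response, interactions,
              fitted(m), st$d2, st$rmse, meta = list(k = k))
}

#' Define a boosted-regression-tree hyperparameter grid
#'
#' The `"paper"` preset is the full published search grid (10000/15000/
#' 20000 trees, depths 3/5/7/9, shrinkages 0.01/0.1/0.5, bag fractions
#' 0.65/0.8/1); the `"desk"` preset is a reduced grid sized for interactive
#' work and testing.  Explicit arguments override the preset values.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param n_trees,interaction_depth,shrinkage,bag_fraction Numeric vectors
#'   of candidate values.
#' @return A `gbm_grid` list.
#' @export
gbm_grid <- function(preset = c("desk", "paper"), n_trees = NULL,
                     interaction_depth = NULL, shrinkage = NULL,
                     bag_fraction = NULL) {
  preset <- match.arg(preset)
  d <- if (preset == "paper")
    list(n_trees = c(10000, 15000, 20000),
         interaction_depth = c(3, 5, 7, 9),
         shrinkage = c(0.01, 0.1, 0.5), bag_fraction = c(0.65, 0.8, 1))
  else
    list(n_trees = c(500, 1000), interaction_depth = c(3, 5),
         shrinkage = 0.05, bag_fraction = 0.8)
  g <- list(n_trees = n_trees %||% d$n_trees,
            interaction_depth = interaction_depth %||% d$interaction_depth,
            shrinkage = shrinkage %||% d$shrinkage,
            bag_fraction = bag_fraction %||% d$bag_fraction)
  if (any(lengths(g) == 0) || any(unlist(g) <= 0) ||
      any(g$bag_fraction > 1))
    stopf("grid values must be nonempty, positive, and bag_fraction <= 1")
  structure(g, class = "gbm_grid")
}

gbm_train <- function(X, y, n_trees, depth, shrinkage, bag, seed) {
  d <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = shrinkage,
                  max_depth = as.integer(depth), subsample = bag,
                  nthread = 1, seed = as.integer(seed)),
    data = d, nrounds = as.integer(n_trees), verbose = 0)
}

#' Fit boosted regression trees with grid search by cross-validated RMSE
#'
#' Trains every combination in the hyperparameter grid, estimates RMSE on
#' held-out folds, and keeps the combination with the lowest RMSE (ties
#' resolved toward fewer trees, then shallower depth).  Trees model
#' interactions natively, so the `interactions` list used by the other
#' fitters is not needed here.  All stochastic components (fold assignment,
#' bagging) are seeded.
#'
#' @inheritParams fit_glm
#' @param grid A [gbm_grid()].
#' @param folds Number of cross-validation folds (n must be >= folds).
#' @param seed Integer seed.
#' @return List with `fit` (a `hab_fit`; `d2` is reported as `NA`, see
#'   [goodness()]) and `grid_report` (one row per combination with its
#'   cross-validated RMSE).
#' @export
fit_gbm_grid <- function(table, response, grid = gbm_grid("desk"),
                         folds = 5, seed = 1L) {
  vars <- check_fit_inputs(table, response)
  stopifnot(inherits(grid, "gbm_grid"))
  n <- length(response)
  if (!is_count(folds) || folds < 2 || n < folds)
    stopf("need integer folds >= 2 and n >= folds")
  X <- as.matrix(as.data.frame(table)[vars])
  combos <- expand.grid(n_trees = grid$n_trees,
                        depth = grid$interaction_depth,
                        shrinkage = grid$shrinkage,
                        bag = grid$bag_fraction)
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  cv_rmse <- vapply(seq_len(nrow(combos)), function(i) {
    se <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      b <- gbm_train(X[tr, , drop = FALSE], response[tr],
                     combos$n_trees[i], combos$depth[i],
                     combos$shrinkage[i], combos$bag[i],
                     derive_seed(seed, i * folds + f))
      pr <- predict(b, X[!tr, , drop = FALSE])
      se <- se + sum((response[!tr] - pr)^2)
    }
    sqrt(se / n)
  }, numeric(1))
  combos$cv_rmse <- cv_rmse
  best <- order(cv_rmse, combos$n_trees, combos$depth)[1]
  model <- gbm_train(X, response, combos$n_trees[best], combos$depth[best],
                     combos$shrinkage[best], combos$bag[best],
                     derive_seed(seed, 0))
  fitted <- predict(model, X)
  st <- fit_stats(response, fitted)
  fit <- new_hab_fit("gbm", model, as.data.frame(table), response, list(),
                     fitted, NA_real_, st$rmse,
                     meta = list(best = as.list(combos[best,
                                    c("n_trees", "depth", "shrinkage",
                                      "bag")]),
                                 cv_rmse = cv_rmse[best], folds = folds,
                                 seed = seed))
  list(fit = fit, grid_report = combos)
}

#' Predict from a fitted ensemble member
#'
#' @param object A `hab_fit`.
#' @param newdata Data frame containing the fit's covariates (and `AC` if
#'   the fit used the autocovariate).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.hab_fit <- function(object, newdata, ...) {
  missing_v <- setdiff(object$features, names(newdata))
  if (length(missing_v) > 0)
    stopf("newdata missing column(s): %s", paste(missing_v, collapse = ", "))
  if (object$kind == "gbm") {
    as.numeric(predict(object$model,
                       as.matrix(newdata[object$features])))
  } else {
    as.numeric(predict(object$model, newdata = newdata))
  }
}

#' Bundle fitted models into an ensemble
#'
#' @param ... Named `hab_fit` objects (conventionally `glm`, `gam`, `gbm`),
#'   or a single list of them.
#' @return A `hab_ensemble`; its [predict()] method averages member
#'   predictions.
#' @export
hab_ensemble <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "hab_fit"))
    fits <- fits[[1]]
  if (length(fits) == 0 ||
      !all(vapply(fits, inherits, logical(1), "hab_fit")))
    stopf("hab_ensemble needs one or more hab_fit objects")
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, `[[`, character(1), "kind")
  structure(fits, class = "hab_ensemble")
}

#' @export
predict.hab_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object, predict, numeric(nrow(newdata)),
                  newdata = newdata)
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

#' @export
print.hab_ensemble <- function(x, ...) {
  cat(sprintf("<hab_ensemble> %d models: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  for (f in x) print(f)
  invisible(x)
}

# Spatial weight matrix shared by the autocovariate and Moran's I:
# w_ij = 1/d_ij (or 1) for 0 < d_ij <= radius, else 0.
spatial_weights <- function(cells, radius,
                            weighting = c("inverse-distance", "equal")) {
  weighting <- match.arg(weighting)
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stopf("radius must be a single positive length (km)")
  D <- as.matrix(dist(cbind(cells$easting, cells$northing)))
  mask <- D > 0 & D <= radius
  W <- matrix(0, nrow(D), ncol(D))
  W[mask] <- if (weighting == "inverse-distance") 1 / D[mask] else 1
  W
}

#' Residuals autocovariate
#'
#' Computes, for each cell, the spatially weighted average of the model's
#' residuals over the cell's neighborhood:
#' `ac_i = sum_j w_ij e_j / sum_j w_ij` with `w_ij = 1/d_ij` (or equal
#' weights) for neighbors within `radius`.  Quantifying the autocovariate
#' from residuals rather than the raw response makes it capture only the
#' spatial structure the covariates leave unexplained; refitting with it
#' appended ([refit_with_rac()]) is the RAC correction.  Cells with no
#' neighbor in range get 0 and are recorded in the `"isolated"` attribute.
#'
#' @param fit A `hab_fit` with residuals for every cell.
#' @param cells The matching `cell_table`.
#' @param radius Neighborhood radius in km; default 1.5 cell sizes (the
#'   queen-contiguity analogue).
#' @param weighting `"inverse-distance"` (default) or `"equal"`.
#' @return Numeric per-cell autocovariate with attributes `radius`,
#'   `weighting`, `source`, and `isolated`.
#' @export
residual_autocovariate <- function(fit, cells, radius = NULL,
                                   weighting = c("inverse-distance",
                                                 "equal")) {
  weighting <- match.arg(weighting)
  e <- if (inherits(fit, "hab_fit")) fit$residuals else as.numeric(fit)
  if (length(e) != nrow(cells))
    stopf("fit has %d residuals but there are %d cells",
          length(e), nrow(cells))
  radius <- radius %||% (1.5 * cell_size_of(cells))
  W <- spatial_weights(cells, radius, weighting)
  rs <- rowSums(W)
  ac <- ifelse(rs > 0, as.vector(W %*% e) / rs, 0)
  attr(ac, "radius") <- radius
  attr(ac, "weighting") <- weighting
  attr(ac, "source") <- "residuals"
  attr(ac, "isolated") <- cells$cell_id[rs == 0]
  ac
}

#' Refit a model with the residual autocovariate appended
#'
#' Rebuilds the same model class on the same data with the autocovariate
#' as one additional predictor (`AC`).  A constant autocovariate carries
#' no information and is dropped with a message, returning the base fit.
#'
#' @param fit A `hab_fit` (its covariates, interactions and, for the
#'   boosted trees, selected hyperparameters are reused).
#' @param autocov Per-cell autocovariate from [residual_autocovariate()],
#'   built from this same model's residuals.
#' @return A `hab_fit` with `has_rac = TRUE`.
#' @export
refit_with_rac <- function(fit, autocov) {
  stopifnot(inherits(fit, "hab_fit"))
  if (length(autocov) != length(fit$response))
    stopf("autocovariate length does not match the fitted data")
  if (sd(autocov) == 0) {
    message("autocovariate is constant; RAC term dropped, base fit returned")
    return(fit)
  }
  table2 <- fit$table
  table2$AC <- as.numeric(autocov)
  switch(fit$kind,
    glm = fit_glm(table2, fit$response, fit$interactions),
    gam = fit_gam(table2, fit$response, fit$interactions,
                  k = fit$meta$k %||% 6),
    gbm = {
      p <- fit$meta$best
      X <- as.matrix(table2[setdiff(names(table2), "cell_id")])
      model <- gbm_train(X, fit$response, p$n_trees, p$depth, p$shrinkage,
                         p$bag, derive_seed(fit$meta$seed %||% 1L, 0))
      fitted <- predict(model, X)
      st <- fit_stats(fit$response, fitted)
      new_hab_fit("gbm", model, table2, fit$response, list(), fitted,
                  NA_real_, st$rmse, meta = fit$meta)
    },
    stopf("unknown model kind '%s'", fit$kind))
}

#' Moran's I spatial autocorrelation
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z = x - mean(x)`
#' and the same neighborhood weights as the autocovariate.  Null
#' expectation is `-1/(n-1)`.
#'
#' @param x Per-cell variable (typically model residuals).
#' @param cells The matching `cell_table`.
#' @param radius,weighting As in [residual_autocovariate()].
#' @return Moran's I (numeric scalar).
#' @export
morans_i <- function(x, cells, radius = NULL,
                     weighting = c("inverse-distance", "equal")) {
  weighting <- match.arg(weighting)
  if (length(x) != nrow(cells))
    stopf("x length does not match the cell table")
  radius <- radius %||% (1.5 * cell_size_of(cells))
  W <- spatial_weights(cells, radius, weighting)
  z <- x - mean(x)
  s0 <- sum(W)
  if (s0 == 0) stopf("no neighbor pairs within radius %g", radius)
  (length(x) / s0) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

#' Goodness-of-fit report for one model
#'
#' Explained deviance `D2 = 1 - SSE/SST` (for the gaussian fits), in-sample
#' RMSE, and Moran's I of the residuals under the autocovariate's spatial
#' weights.  For the boosted trees `D2` is reported as `NA` by default
#' (deviance is not comparable across the boosting loss); set
#' `include_gbm_d2 = TRUE` to report the pseudo-D2 from fitted values.
#'
#' @param fit A `hab_fit`.
#' @param cells The matching `cell_table`.
#' @param radius,weighting Spatial weights, as in [morans_i()].
#' @param include_gbm_d2 Report pseudo-D2 for boosted trees?
#' @return List `d2`, `rmse`, `moran_i`.
#' @export
goodness <- function(fit, cells, radius = NULL,
                     weighting = c("inverse-distance", "equal"),
                     include_gbm_d2 = FALSE) {
  stopifnot(inherits(fit, "hab_fit"))
  if (sd(fit$response) == 0) stopf("constant response: D2 undefined")
  d2 <- if (fit$kind == "gbm" && !include_gbm_d2) NA_real_
        else fit_stats(fit$response, fit$fitted)$d2
  list(d2 = d2, rmse = fit$rmse,
       moran_i = morans_i(fit$residuals, cells, radius, weighting))
}
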