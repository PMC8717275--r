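# Decomposition of the fitted ensemble: drop-one variable importance,
# inflated response curves, and double-centered interaction surfaces.

#' Default explanatory-variable groups
#'
#' @return Named list mapping group -> member variables: geographic
#'   (`NORTH`, `EAST`, `TRI`), bioclimatic (`BIO_1`, `BIO_7`, `BIO_12`,
#'   `BIO_15`), anthropogenic (`FRAG_IND`, `POP_DENS`).
#' @export
default_groups <- function() {
  list(geographic = c("NORTH", "EAST", "TRI"),
       bioclimatic = c("BIO_1", "BIO_7", "BIO_12", "BIO_15"),
       anthropogenic = c("FRAG_IND", "POP_DENS"))
}

# Group mapping covering the full candidate roster, for pipeline runs in
# which the screen retains a non-default variable set.
roster_groups <- function() {
  g <- default_groups()
  g$bioclimatic <- c(g$bioclimatic, "BIO_4", "BIO_17")
  g$anthropogenic <- c(g$anthropogenic, "STREET_LENGTH", "STREET_DENSITY")
  g
}

drop_one_refit <- function(fit, var) {
  keep <- setdiff(fit$covariates, var)
  tbl <- fit$table[c(intersect("cell_id", names(fit$table)), keep,
                     intersect("AC", names(fit$table)))]
  if (length(setdiff(names(tbl), "cell_id")) == 0) {
    # dropping the only covariate leaves the intercept-only (null) model
    return(list(d2 = 0))
  }
  ints <- Filter(function(p) !(var %in% p), fit$interactions)
  switch(fit$kind,
    glm = fit_glm(tbl, fit$response, ints),
    gam = fit_gam(tbl, fit$response, ints, k = fit$meta$k %||% 6),
    stopf("drop-one refit not defined for kind '%s'", fit$kind))
}

importance_one <- function(fit) {
  vars <- fit$covariates
  if (fit$kind == "gbm") {
    imp <- xgboost::xgb.importance(model = fit$model)
    gain <- setNames(rep(0, length(vars)), vars)
    hit <- imp$Feature %in% vars
    gain[imp$Feature[hit]] <- imp$Gain[hit]
    if (sum(gain) == 0) {
      warnf("boosted model used no covariate; zero importance reported")
      return(gain)
    }
    return(100 * gain / sum(gain))
  }
  d2_full <- fit_stats(fit$response, fit$fitted)$d2
  delta <- vapply(vars, function(v) {
    tryCatch(max(0, d2_full - drop_one_refit(fit, v)$d2),
             error = function(e) {
               warnf("drop-one refit failed for '%s': %s", v,
                     conditionMessage(e))
               NA_real_
             })
  }, numeric(1))
  tot <- sum(delta, na.rm = TRUE)
  if (tot == 0) {
    warnf("no variable changes D2; zero importance reported")
    return(replace(delta, !is.na(delta), 0))
  }
  100 * delta / tot
}

#' Drop-one variable importance across the ensemble
#'
#' For the GLM and GAM, each covariate's influence is the decrease in
#' explained deviance `D2` when that variable (and any interaction
#' containing it) is removed and the model refitted, clipped at zero and
#' normalized to sum to 100 per model.  For the boosted trees, influence is
#' the native split-gain relative importance, also normalized to 100.  The
#' autocovariate, when present, is excluded from the denominator.  A
#' failed drop-one refit yields `NA` for that variable with a warning.
#'
#' @param ensemble A [hab_ensemble()] fitted on a common covariate set.
#' @return Data frame `model`, `variable`, `influence` (percent).
#' @export
variable_importance <- function(ensemble) {
  stopifnot(inherits(ensemble, "hab_ensemble"))
  rows <- lapply(names(ensemble), function(nm) {
    inf <- importance_one(ensemble[[nm]])
    data.frame(model = nm, variable = names(inf),
               influence = unname(inf))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative importance by variable group
#'
#' Sums per-variable influences within each group (the groups must
#' partition the variables), so group contributions also sum to 100 per
#' model.
#'
#' @param imp Output of [variable_importance()].
#' @param groups Named list mapping group -> variables;
#'   see [default_groups()].
#' @return Data frame `model`, `group`, `influence`.
#' @export
group_contributions <- function(imp, groups = default_groups()) {
  vars <- unique(imp$variable)
  assigned <- unlist(groups, use.names = FALSE)
  lost <- setdiff(vars, assigned)
  if (length(lost) > 0)
    stopf("variable(s) not assigned to any group: %s",
          paste(lost, collapse = ", "))
  if (anyDuplicated(assigned))
    stopf("groups must not overlap")
  rows <- lapply(unique(imp$model), function(m) {
    sub <- imp[imp$model == m, ]
    data.frame(model = m, group = names(groups),
               influence = vapply(groups, function(g)
                 sum(sub$influence[sub$variable %in% g], na.rm = TRUE),
                 numeric(1)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ensemble_table <- function(ensemble) {
  tab <- ensemble[[1]]$table
  feats <- unique(unlist(lapply(ensemble, `[[`, "features")))
  for (f in setdiff(feats, names(tab))) {
    src <- Filter(function(x) f %in% names(x$table), ensemble)[[1]]
    tab[[f]] <- src$table[[f]]
  }
  tab
}

#' Inflated response curves for one focal variable
#'
#' Evaluates the ensemble-mean prediction along a grid of `G` focal values
#' (1st to 99th percentile) for `K` background conditioning vectors drawn
#' by Latin-hypercube sampling over the non-focal variables' observed 1st
#' to 99th percentile ranges; the autocovariate, when present, is held at
#' its mean.  Each conditioning vector yields one curve (averaged
#' pointwise across the models); the spread of the `K` curves reveals
#' interaction structure, and the pointwise median and mean curves
#' summarize the central response.
#'
#' @param ensemble A [hab_ensemble()].
#' @param focal Name of the focal covariate (not the autocovariate).
#' @param K Number of conditioning draws (curves).
#' @param G Number of focal grid points.
#' @param seed Integer seed for the Latin-hypercube draw.
#' @return A `response_curves` list: `focal`, `grid` (length `G`),
#'   `curves` (`G` x `K`), `median`, `mean`.
#' @export
inflated_response_curves <- function(ensemble, focal, K = 100, G = 50,
                                     seed = 1L) {
  stopifnot(inherits(ensemble, "hab_ensemble"))
  tab <- ensemble_table(ensemble)
  covs <- ensemble[[1]]$covariates
  if (identical(focal, "AC"))
    stopf("the autocovariate cannot be a focal variable")
  if (!focal %in% covs) stopf("'%s' is not a model covariate", focal)
  qr_ <- quantile(tab[[focal]], c(0.01, 0.99), names = FALSE)
  grid <- seq(qr_[1], qr_[2], length.out = G)
  nonfocal <- setdiff(covs, focal)
  U <- with_seed(seed, lhs::randomLHS(K, max(1, length(nonfocal))))
  nd <- data.frame(rep(grid, times = K))
  names(nd) <- focal
  for (j in seq_along(nonfocal)) {
    qj <- quantile(tab[[nonfocal[j]]], c(0.01, 0.99), names = FALSE)
    vals <- qj[1] + U[, j] * (qj[2] - qj[1])
    nd[[nonfocal[j]]] <- rep(vals, each = G)
  }
  if ("AC" %in% names(tab)) nd$AC <- mean(tab$AC)
  preds <- vapply(ensemble, predict, numeric(nrow(nd)), newdata = nd)
  curves <- matrix(rowMeans(preds), nrow = G, ncol = K)
  structure(list(focal = focal, grid = grid, curves = curves,
                 median = apply(curves, 1, median),
                 mean = rowMeans(curves)),
            class = "response_curves")
}

#' @export
as.data.frame.response_curves <- function(x, ...) {
  data.frame(focal = x$focal,
             value = rep(x$grid, times = ncol(x$curves)),
             curve = rep(seq_len(ncol(x$curves)), each = length(x$grid)),
             prediction = as.vector(x$curves))
}

#' Double-centered interaction surfaces
#'
#' For each variable pair `(u, v)`, evaluates the ensemble-mean prediction
#' on a `G2` x `G2` grid over the pair's 1st-99th percentile ranges with
#' every other covariate at its mean, and extracts the pure interaction
#' component by double centering:
#' `z(u, v) = yhat(u, v) - yhat(u, vbar) - yhat(ubar, v) + yhat(ubar, vbar)`
#' where `ubar`, `vbar` are the covariate means.  `z` is identically zero
#' for an additive prediction surface, so its magnitude isolates how
#' strongly the pair interacts; a surface is flagged for display when
#' `max |z|` exceeds `threshold`.
#'
#' @param ensemble A [hab_ensemble()].
#' @param pairs List of length-2 character vectors, or `NULL` for all
#'   covariate pairs.
#' @param threshold Display threshold on `max |z|` (response units).
#' @param G2 Grid resolution per axis.
#' @return List of `interaction_surface` objects: `pair`, `u`, `v`
#'   (grids), `yhat` (`G2` x `G2`), `z`, `max_abs_z`, `displayed`.
#' @export
interaction_surfaces <- function(ensemble, pairs = NULL, threshold = 0.3,
                                 G2 = 25) {
  stopifnot(inherits(ensemble, "hab_ensemble"))
  tab <- ensemble_table(ensemble)
  covs <- ensemble[[1]]$covariates
  if (is.null(pairs)) {
    cmb <- combn(covs, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  base <- as.data.frame(lapply(tab[setdiff(names(tab), "cell_id")], mean))
  lapply(pairs, function(p) {
    if ("AC" %in% p)
      stopf("interaction surfaces over the autocovariate are not defined")
    if (!all(p %in% covs))
      stopf("pair (%s) not in the covariate set", paste(p, collapse = ", "))
    gu <- seq(quantile(tab[[p[1]]], 0.01), quantile(tab[[p[1]]], 0.99),
              length.out = G2)
    gv <- seq(quantile(tab[[p[2]]], 0.01), quantile(tab[[p[2]]], 0.99),
              length.out = G2)
    nd <- base[rep(1, G2 * G2), , drop = FALSE]
    nd[[p[1]]] <- rep(gu, times = G2)
    nd[[p[2]]] <- rep(gv, each = G2)
    yhat <- matrix(predict(ensemble, nd), G2, G2)
    nd_u <- base[rep(1, G2), , drop = FALSE]; nd_u[[p[1]]] <- gu
    nd_v <- base[rep(1, G2), , drop = FALSE]; nd_v[[p[2]]] <- gv
    a <- predict(ensemble, nd_u)
    b <- predict(ensemble, nd_v)
    c0 <- predict(ensemble, base)
    z <- yhat - outer(a, rep(1, G2)) - outer(rep(1, G2), b) + c0
    structure(list(pair = p, u = gu, v = gv, yhat = yhat, z = z,
                   max_abs_z = max(abs(z)), threshold = threshold,
                   displayed = max(abs(z)) > threshold),
              class = "interaction_surface")
  })
}

#' @export
print.interaction_surface <- function(x, ...) {
  cat(sprintf("<interaction_surface> %s x %s: max|z| = %.3f (%s)\n",
              x$pair[1], x$pair[2], x$max_abs_z,
              if (x$displayed) "displayed" else "below threshold"))
  invisible(x)
}
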