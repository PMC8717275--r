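#' Configure a full pipeline run
#'
#' Collects every knob of the end-to-end analysis: grid geometry, the
#' generative truth, screen priority, model settings, response-analysis
#' settings, and one named seed per source of randomness.  All seeds are
#' derived deterministically from `seed` unless given explicitly; a
#' `seeds` list missing any required name is rejected before any
#' computation.
#'
#' @param seed Master integer seed.
#' @param n_rows,n_cols,cell_size Grid geometry (cells; km).
#' @param coastal_fraction Proportion of boundary cells made coastal.
#' @param truth A [truth_record()]; its `seed` is overridden by the
#'   pipeline's `occupancy` seed.
#' @param lambda0 Baseline species count for [gen_species()].
#' @param priority Keep-priority for [collinearity_screen()].
#' @param scale `"desk"` (reduced boosted-tree grid) or `"paper"` (the full
#'   published grid).
#' @param gbm A [gbm_grid()]; defaults to the preset for `scale`.
#' @param folds Cross-validation folds for the boosted-tree grid search.
#' @param radius Spatial-weight radius (km); default 1.5 cell sizes.
#' @param K,G Curves per focal variable and focal grid size.
#' @param G2,threshold Interaction-surface grid size and display threshold.
#' @param seeds Optional named list with entries `grid`, `fields`,
#'   `streets`, `occupancy`, `species`, `gbm`, `curves`.
#' @param outdir Output directory for CSV artifacts, or `NULL` to skip
#'   writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_rows = 30, n_cols = 30,
                            cell_size = 10, coastal_fraction = 0.15,
                            truth = truth_record(), lambda0 = 50,
                            priority = default_priority(),
                            scale = c("desk", "paper"), gbm = NULL,
                            folds = 5, radius = NULL,
                            K = 100, G = 50, G2 = 25, threshold = 0.3,
                            seeds = NULL, outdir = NULL) {
  scale <- match.arg(scale)
  need <- c("grid", "fields", "streets", "occupancy", "species", "gbm",
            "curves")
  if (is.null(seeds)) {
    seeds <- setNames(lapply(seq_along(need), function(i)
      derive_seed(seed, i)), need)
  }
  missing_s <- setdiff(need, names(seeds))
  if (length(missing_s) > 0)
    stopf("config is missing required seed(s): %s",
          paste(missing_s, collapse = ", "))
  if (!all(vapply(seeds[need], is.numeric, logical(1))))
    stopf("all seeds must be numeric")
  structure(list(seed = seed, n_rows = n_rows, n_cols = n_cols,
                 cell_size = cell_size,
                 coastal_fraction = coastal_fraction, truth = truth,
                 lambda0 = lambda0, priority = priority, scale = scale,
                 gbm = gbm %||% gbm_grid(scale), folds = folds,
                 radius = radius, K = K, G = G, G2 = G2,
                 threshold = threshold, seeds = seeds[need],
                 outdir = outdir),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full pipeline: simulate, normalize, screen, fit, decompose
#'
#' Executes simulate -> richness -> terrain -> assemble -> screen ->
#' interaction selection -> GLM/GAM/GBM fits -> RAC refits -> goodness
#' table -> importance, response curves, and interaction surfaces,
#' writing CSV artifacts (plus the config and truth echo) to
#' `config$outdir` when set.  Every random draw is tied to a named seed in
#' the config, so reruns are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a `pipeline_report` list with all intermediate and
#'   final tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sds <- config$seeds
  spec <- grid_spec(config$n_rows, config$n_cols, config$cell_size)

  cells <- run_stage("simulate-grid",
    gen_grid(spec, config$coastal_fraction, seed = sds$grid))
  rasters <- run_stage("simulate-fields",
    gen_fields(spec, seed = sds$fields))
  streets <- run_stage("simulate-streets",
    gen_streets(cells, rasters$POP_DENS, seed = sds$streets))

  tri_cell <- run_stage("terrain", {
    tri <- tri_raster(aggregate_mean(rasters$DEM, 1))
    tri_per_cell(tri, cells)
  })

  covariates <- run_stage("assemble",
    assemble_covariates(cells, rasters, streets, tri_cell))

  truth <- config$truth
  truth$seed <- as.integer(sds$occupancy)
  occ <- run_stage("simulate-occupancy",
    gen_occupancy(cells, covariates, truth))

  richness <- run_stage("richness", richness_table(occ, cells))
  species <- run_stage("simulate-species",
    gen_species(richness$HR, truth$kappa, config$lambda0,
                seed = sds$species))
  cor_sr <- run_stage("species-correlation",
    correlate_with_species(richness$HR, species))

  # align cells kept by both the richness table and the covariate assembly
  keep <- intersect(richness$cell_id, covariates$cell_id)
  rich <- richness[match(keep, richness$cell_id), ]
  covs <- covariates[match(keep, covariates$cell_id), ]
  cells_kept <- cells[match(keep, cells$cell_id), ]

  screen <- run_stage("screen",
    collinearity_screen(covs, 0.7, config$priority))
  X <- standardize_covariates(covs[c("cell_id", screen$retained)])
  y <- rich$NHR

  sel <- run_stage("select-interactions", select_interactions(X, y))

  fits <- run_stage("fit", list(
    glm = fit_glm(X, y, sel$pairs),
    gam = fit_gam(X, y, sel$pairs),
    gbm = fit_gbm_grid(X, y, config$gbm, config$folds,
                       seed = sds$gbm)$fit))

  rac <- run_stage("rac", lapply(fits, function(f) {
    ac <- residual_autocovariate(f, cells_kept, config$radius)
    refit_with_rac(f, ac)
  }))

  model_report <- run_stage("goodness", {
    rows <- list()
    for (nm in names(fits)) {
      g0 <- goodness(fits[[nm]], cells_kept, config$radius)
      g1 <- goodness(rac[[nm]], cells_kept, config$radius)
      rows[[length(rows) + 1]] <- data.frame(
        model = toupper(nm), rac = "no", D2 = g0$d2, RMSE = g0$rmse,
        moran_i = g0$moran_i)
      rows[[length(rows) + 1]] <- data.frame(
        model = paste(toupper(nm), "with RAC"), rac = "yes", D2 = g1$d2,
        RMSE = g1$rmse, moran_i = g1$moran_i)
    }
    do.call(rbind, rows)
  })

  ens <- hab_ensemble(fits)
  imp <- run_stage("importance", variable_importance(ens))
  grp <- run_stage("groups", group_contributions(imp, roster_groups()))
  curves <- run_stage("curves", {
    out <- lapply(screen$retained, function(v)
      inflated_response_curves(ens, v, K = config$K, G = config$G,
                               seed = sds$curves))
    names(out) <- screen$retained
    out
  })
  surfaces <- run_stage("surfaces",
    interaction_surfaces(ens, threshold = config$threshold,
                         G2 = config$G2))

  report <- structure(list(
    config = config, cells = cells, rasters = rasters, streets = streets,
    occupancy = occ, richness = richness, species = species,
    cor_species = cor_sr, covariates = covariates, screen = screen,
    interactions = sel, fits = fits, rac = rac,
    model_report = model_report, importance = imp, groups = grp,
    curves = curves, surfaces = surfaces), class = "pipeline_report")

  if (!is.null(config$outdir))
    run_stage("write", write_pipeline_report(report, config$outdir))
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d cells, %d habitats\n",
              nrow(x$cells), length(x$occupancy$habitat_ids)))
  cat(sprintf("HR in [%d, %d]; r(HR, SR) = %.3f\n",
              min(x$richness$HR), max(x$richness$HR), x$cor_species$r))
  print(x$model_report, digits = 3)
  invisible(x)
}

fmt_num <- function(x) {
  if (is.numeric(x)) sprintf("%.15g", x) else as.character(x)
}

write_table <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num))
  names(out) <- names(df)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

# Write every artifact of a pipeline run as plain text (CSV / YAML / JSON).
write_pipeline_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_table(as.data.frame(report$cells), p("cells.csv"))
  write_occupancy_csv(report$occupancy, p("occupancy.csv"))
  write_table(cbind(report$richness,
                    SR = report$species), p("richness.csv"))
  write_table(report$covariates, p("covariates.csv"))
  write_table(report$screen$dropped, p("screen_dropped.csv"))
  write_table(report$interactions$report, p("interaction_selection.csv"))
  write_table(report$model_report, p("model_report.csv"))
  write_table(report$importance, p("importance.csv"))
  write_table(report$groups, p("group_contributions.csv"))
  curves_long <- do.call(rbind, lapply(report$curves, as.data.frame))
  write_table(curves_long, p("response_curves.csv"))
  surf_long <- do.call(rbind, lapply(report$surfaces, function(s)
    data.frame(var1 = s$pair[1], var2 = s$pair[2],
               u = rep(s$u, times = length(s$v)),
               v = rep(s$v, each = length(s$u)),
               z = as.vector(s$z), displayed = s$displayed)))
  write_table(surf_long, p("interaction_surfaces.csv"))
  cfg <- report$config
  cfg$truth$gamma <- as.list(cfg$truth$gamma)
  cfg$truth$gamma_int <- as.list(cfg$truth$gamma_int)
  yaml::write_yaml(list(
    seed = cfg$seed, grid = list(n_rows = cfg$n_rows, n_cols = cfg$n_cols,
                                 cell_size = cfg$cell_size),
    coastal_fraction = cfg$coastal_fraction, scale = cfg$scale,
    folds = cfg$folds, K = cfg$K, G = cfg$G, G2 = cfg$G2,
    threshold = cfg$threshold, seeds = cfg$seeds,
    retained = report$screen$retained), p("config.yaml"))
  jsonlite::write_json(unclass(cfg$truth), p("truth.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("cells: %d (%d coastal)", nrow(report$cells),
            sum(report$cells$land_area <
                  cell_size_of(report$cells)^2 - 1e-9)),
    sprintf("habitats: %d (%d marine excluded)",
            length(report$occupancy$habitat_ids),
            sum(report$occupancy$marine_flag)),
    sprintf("HR range: %d..%d", min(report$richness$HR),
            max(report$richness$HR)),
    sprintf("r(HR, SR): %.4f (p = %.3g)", report$cor_species$r,
            report$cor_species$p),
    sprintf("retained covariates: %s",
            paste(report$screen$retained, collapse = ", ")),
    sprintf("interactions retained: %s",
            if (length(report$interactions$pairs) == 0) "none"
            else paste(interaction_labels(report$interactions$pairs),
                       collapse = ", "))), p("log.txt"))
  invisible(outdir)
}
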