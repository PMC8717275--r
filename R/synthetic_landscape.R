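#' Specify an equal-area analysis grid
#'
#' @param n_rows,n_cols Number of cell rows / columns (>= 2 each).
#' @param cell_size Cell edge length in km (default 10, the EEA reporting
#'   grid).
#' @param origin_easting,origin_northing Coordinates (km) of the grid's
#'   south-west corner.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 10,
                      origin_easting = 0, origin_northing = 0) {
  if (!is_count(n_rows) || !is_count(n_cols) || n_rows < 2 || n_cols < 2)
    stopf("n_rows and n_cols must be integer counts >= 2")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stopf("cell_size must be a single positive length (km)")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size,
                 origin = c(origin_easting, origin_northing)),
            class = "grid_spec")
}

#' Generate the analysis cell table, with partial-land coastal cells
#'
#' Interior cells carry the full cell area.  A fraction `coastal_fraction`
#' of the lattice-boundary cells is designated coastal and receives a land
#' area drawn uniformly between 5% and 95% of the full cell area,
#' mimicking grid cells whose terrestrial surface is reduced by coastline.
#'
#' @param spec A [grid_spec()].
#' @param coastal_fraction Proportion of boundary cells made coastal, in
#'   `[0, 1]`.
#' @param seed Integer seed; the result is a pure function of
#'   `(spec, coastal_fraction, seed)`.
#' @return A `cell_table` data frame with columns `cell_id`, `row`, `col`,
#'   `easting`, `northing` (cell centers, km), and `land_area` (km^2),
#'   carrying the cell size and origin as attributes.
#' @export
gen_grid <- function(spec, coastal_fraction = 0, seed = 1L) {
  stopifnot(inherits(spec, "grid_spec"))
  if (!is.numeric(coastal_fraction) || length(coastal_fraction) != 1 ||
      is.na(coastal_fraction) || coastal_fraction < 0 || coastal_fraction > 1)
    stopf("coastal_fraction must be a proportion in [0, 1]")
  cs <- spec$cell_size
  rows <- rep(seq_len(spec$n_rows), times = spec$n_cols)
  cols <- rep(seq_len(spec$n_cols), each = spec$n_rows)
  cells <- data.frame(
    cell_id = (rows - 1L) * spec$n_cols + cols,
    row = rows, col = cols,
    easting = spec$origin[1] + (cols - 0.5) * cs,
    northing = spec$origin[2] + (rows - 0.5) * cs,
    land_area = cs^2
  )
  cells <- cells[order(cells$cell_id), ]
  rownames(cells) <- NULL
  boundary <- which(cells$row == 1L | cells$row == spec$n_rows |
                    cells$col == 1L | cells$col == spec$n_cols)
  n_coastal <- round(coastal_fraction * length(boundary))
  if (n_coastal > 0) {
    with_seed(seed, {
      coastal <- sort(sample(boundary, n_coastal))
      cells$land_area[coastal] <- runif(n_coastal, 0.05 * cs^2, 0.95 * cs^2)
    })
  }
  attr(cells, "cell_size") <- cs
  attr(cells, "origin") <- spec$origin
  class(cells) <- c("cell_table", "data.frame")
  cells
}

cell_size_of <- function(cells) {
  cs <- attr(cells, "cell_size")
  if (is.null(cs)) {
    # fall back to the spacing of distinct center coordinates
    e <- sort(unique(cells$easting))
    cs <- if (length(e) > 1) min(diff(e)) else
      stopf("cannot infer cell size from a single-column cell table")
  }
  cs
}

grid_origin_of <- function(cells) {
  attr(cells, "origin") %||%
    c(min(cells$easting) - cell_size_of(cells) / 2,
      min(cells$northing) - cell_size_of(cells) / 2)
}

#' Default synthetic raster-field roster
#'
#' Configures the environmental fields the analysis consumes, emulating the
#' structure (not the values) of continental bioclimatic, terrain and
#' anthropogenic products: smooth gradient-plus-random-field bioclim
#' layers, strictly positive right-skewed population density, a bounded
#' fragmentation index, a DEM with both broad relief and fine-scale
#' roughness, and two deliberately collinear bioclim variants
#' (`BIO_4` tracks `BIO_7`, `BIO_17` tracks `BIO_12`) so the collinearity
#' screen has real work to do.
#'
#' @param spec A [grid_spec()]; gradients are scaled to the grid extent.
#' @return Named list of field configurations for [gen_fields()].
#' @export
default_field_configs <- function(spec) {
  cs <- spec$cell_size
  list(
    BIO_1  = list(type = "gradient+grf", mean = 10, slope_north = -0.008,
                  slope_east = 0, sd = 2, range = 3 * cs, pixel_size = cs),
    BIO_7  = list(type = "gradient+grf", mean = 25, slope_north = 0,
                  slope_east = 0.005, sd = 2, range = 4 * cs,
                  pixel_size = cs),
    BIO_12 = list(type = "gradient+grf", mean = 800, slope_north = 0.3,
                  slope_east = -0.25, sd = 120, range = 4 * cs,
                  pixel_size = cs),
    BIO_15 = list(type = "gradient+grf", mean = 30, slope_north = 0,
                  slope_east = 0, sd = 8, range = 4 * cs, pixel_size = cs),
    BIO_4  = list(type = "derived-noise", source = "BIO_7", noise_sd = 0.3),
    BIO_17 = list(type = "derived-noise", source = "BIO_12", noise_sd = 0.3),
    POP_DENS = list(type = "lognormal-grf", meanlog = 3, sdlog = 1.2,
                    range = 3 * cs, pixel_size = 1),
    FRAG_IND = list(type = "logit-grf", mean_logit = -1, sd = 1.5,
                    range = 3 * cs, pixel_size = 1),
    DEM = list(type = "dem", mean = 500, coarse_sd = 300,
               coarse_range = 5 * cs, fine_sd = 30, pixel_size = 0.2)
  )
}

#' Generate synthetic environmental raster fields
#'
#' Field types: `"gradient+grf"` (linear spatial gradient plus a Gaussian
#' random field with exponential covariance), `"lognormal-grf"` (exp of a
#' GRF: strictly positive, right-skewed), `"logit-grf"` (inverse-logit of a
#' GRF: bounded in (0, 1)), `"dem"` (broad-scale GRF relief plus
#' independent fine-scale Gaussian roughness), and `"derived-noise"` (an
#' already-generated field plus white noise, for inducing collinearity).
#'
#' @param spec A [grid_spec()]; every raster covers the grid extent.
#' @param field_configs Named list of configurations; see
#'   [default_field_configs()].
#' @param seed Integer seed; fields are generated in list order from a
#'   single seeded stream, so the full map is reproducible.
#' @return Named list of [raster_field()] objects.
#' @export
gen_fields <- function(spec, field_configs = default_field_configs(spec),
                       seed = 1L) {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.null(names(field_configs)) || any(names(field_configs) == ""))
    stopf("field_configs must be a fully named list")
  extent <- c(spec$n_cols, spec$n_rows) * spec$cell_size
  out <- list()
  with_seed(seed, {
    for (nm in names(field_configs)) {
      cfg <- field_configs[[nm]]
      type <- cfg$type %||% stopf("field '%s' has no type", nm)
      if (type == "derived-noise") {
        src <- out[[cfg$source %||% ""]]
        if (is.null(src))
          stopf("field '%s': derived-noise source '%s' not yet generated",
                nm, cfg$source %||% "<missing>")
        v <- src$values +
          rnorm(length(src$values), 0,
                (cfg$noise_sd %||% 0.3) * sd(src$values))
        out[[nm]] <- raster_field(v, src$pixel_size, src$origin)
        next
      }
      ps <- cfg$pixel_size %||% spec$cell_size
      npx <- round(extent / ps)
      if (any(abs(npx * ps - extent) > 1e-6))
        stopf("field '%s': pixel_size %g does not tile the %g x %g km extent",
              nm, ps, extent[1], extent[2])
      nr <- npx[2]; nc <- npx[1]
      ax_e <- spec$origin[1] + (seq_len(nc) - 0.5) * ps
      ax_n <- spec$origin[2] + (seq_len(nr) - 0.5) * ps
      v <- switch(type,
        "gradient+grf" = {
          g <- outer((ax_n - mean(ax_n)) * (cfg$slope_north %||% 0),
                     (ax_e - mean(ax_e)) * (cfg$slope_east %||% 0), `+`)
          (cfg$mean %||% 0) + g +
            grf_lattice(nr, nc, ps, cfg$range %||% (3 * spec$cell_size),
                        cfg$sd %||% 1, spec$origin)
        },
        "lognormal-grf" = {
          z <- grf_lattice(nr, nc, ps, cfg$range %||% (3 * spec$cell_size),
                           1, spec$origin)
          exp((cfg$meanlog %||% 0) + (cfg$sdlog %||% 1) * z)
        },
        "logit-grf" = {
          plogis((cfg$mean_logit %||% 0) +
                   grf_lattice(nr, nc, ps,
                               cfg$range %||% (3 * spec$cell_size),
                               cfg$sd %||% 1, spec$origin))
        },
        "dem" = {
          (cfg$mean %||% 0) +
            grf_lattice(nr, nc, ps, cfg$coarse_range %||% (5 * spec$cell_size),
                        cfg$coarse_sd %||% 100, spec$origin) +
            matrix(rnorm(nr * nc, 0, cfg$fine_sd %||% 0), nr, nc)
        },
        stopf("field '%s': unknown field type '%s'", nm, type)
      )
      out[[nm]] <- raster_field(v, ps, spec$origin)
    }
  })
  out
}

street_class_probs <- c(highway = 0.05, primary = 0.10, secondary = 0.15,
                        tertiary = 0.25, local = 0.45)

#' Generate a synthetic street network
#'
#' Seeds road segments cell by cell: the segment count in a cell is Poisson
#' with mean proportional to the density field at the cell center, so the
#' expected total street length per cell is proportional to that density.
#' Segments start at a uniform point in the cell, take a uniform direction
#' and an exponential length (they may cross cell boundaries; clipping is
#' the job of [street_metrics()]).  Road classes are drawn from a fixed
#' multinomial over highway / primary / secondary / tertiary / local.
#'
#' @param cells A `cell_table` from [gen_grid()].
#' @param density_field A nonnegative [raster_field()] (e.g. population
#'   density) steering where streets accumulate.
#' @param seed Integer seed.
#' @param rate_per_density Expected segments per cell per unit density.
#' @param mean_length Mean segment length (km).
#' @return A `line_network`: a data frame of segments with columns `x0`,
#'   `y0`, `x1`, `y1` (km) and `road_class`.
#' @export
gen_streets <- function(cells, density_field, seed = 1L,
                        rate_per_density = 0.6, mean_length = 0.8) {
  stopifnot(inherits(density_field, "raster_field"))
  d <- raster_extract(density_field, cells$easting, cells$northing)
  d[is.na(d)] <- 0
  if (any(d < 0)) stopf("density_field must be nonnegative")
  cs <- cell_size_of(cells)
  with_seed(seed, {
    n_seg <- rpois(length(d), rate_per_density * d)
    total <- sum(n_seg)
    if (total == 0) {
      segs <- data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                         y1 = numeric(0), road_class = character(0))
    } else {
      cell_idx <- rep(seq_along(n_seg), n_seg)
      x0 <- cells$easting[cell_idx] + runif(total, -cs / 2, cs / 2)
      y0 <- cells$northing[cell_idx] + runif(total, -cs / 2, cs / 2)
      ang <- runif(total, 0, 2 * pi)
      len <- rexp(total, rate = 1 / mean_length)
      segs <- data.frame(
        x0 = x0, y0 = y0,
        x1 = x0 + len * cos(ang), y1 = y0 + len * sin(ang),
        road_class = sample(names(street_class_probs), total, replace = TRUE,
                            prob = street_class_probs)
      )
    }
  })
  class(segs) <- c("line_network", "data.frame")
  segs
}

#' Record the generative truth of a synthetic landscape
#'
#' Bundles every parameter of the habitat-occupancy generating process so
#' that recovery tests can invert it: per-covariate effects on the
#' occupancy logit (`gamma`), optional pairwise interaction effects
#' (`gamma_int`, named `"A:B"`), the shared spatial random field
#' (`spatial_range` km, `spatial_sd`), the land-area thinning exponent
#' (`area_exponent`, the effect the log-log richness normalization is
#' designed to remove), habitat-level heterogeneity (`delta_sd`), baseline
#' prevalence (`alpha_mean`, `alpha_sd`), the species coupling `kappa`, and
#' the seed.
#'
#' @param gamma Named numeric vector of covariate effects on the logit.
#' @param gamma_int Named numeric vector of interaction effects; names are
#'   `"VAR1:VAR2"`.
#' @param spatial_range Range (km) of the exponential-covariance spatial
#'   field (> 0).
#' @param spatial_sd Marginal SD of the spatial field (>= 0).
#' @param area_exponent Exponent `w` on log relative land area (>= 0).
#' @param kappa Species-richness coupling strength.
#' @param n_habitats Total habitat types generated.
#' @param n_marine Leading habitats flagged marine (<= `n_habitats`).
#' @param delta_sd SD of per-habitat deviations around each `gamma`.
#' @param alpha_mean,alpha_sd Mean / SD of per-habitat baseline logits.
#' @param seed Integer seed controlling every draw in [gen_occupancy()].
#' @return An object of class `truth_record`.
#' @export
truth_record <- function(gamma,
                         gamma_int = c("FRAG_IND:POP_DENS" = -0.5),
                         spatial_range = 50, spatial_sd = 1,
                         area_exponent = 1, kappa = 0.5,
                         n_habitats = 60, n_marine = 6,
                         delta_sd = 0.2, alpha_mean = -1.5, alpha_sd = 0.5,
                         seed = 1L) {
  if (missing(gamma)) {
    gamma <- c(NORTH = -0.5, EAST = -0.3, TRI = 0.6, BIO_1 = 0.4,
               BIO_7 = 0.1, BIO_12 = 0.3, BIO_15 = 0.1, FRAG_IND = 0.2,
               POP_DENS = 0)
  }
  if (is.null(names(gamma)) && length(gamma) > 0)
    stopf("gamma must be a named vector of covariate effects")
  if (spatial_range <= 0) stopf("spatial_range must be > 0")
  if (spatial_sd < 0 || area_exponent < 0 || delta_sd < 0)
    stopf("spatial_sd, area_exponent and delta_sd must be >= 0")
  if (!is_count(n_habitats) || !is_count(n_marine) || n_marine > n_habitats)
    stopf("need integer n_marine <= n_habitats")
  structure(list(gamma = gamma, gamma_int = gamma_int,
                 spatial_range = spatial_range, spatial_sd = spatial_sd,
                 area_exponent = area_exponent, kappa = kappa,
                 n_habitats = as.integer(n_habitats),
                 n_marine = as.integer(n_marine), delta_sd = delta_sd,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 seed = as.integer(seed)),
            class = "truth_record")
}

#' Generate habitat presence/absence from known truth
#'
#' For habitat `h` in cell `i`, presence is Bernoulli with
#' `logit(p_hi) = alpha_h + sum_j (gamma_j + delta_hj) x_ij
#'   + sum interaction terms + u_i + w * log(land_area_i / cell_area)`,
#' where `u` is one Gaussian random field (exponential covariance) shared
#' by all habitats and `delta_hj ~ N(0, delta_sd^2)` lets habitats respond
#' heterogeneously around the common effects.  Covariates are standardized
#' internally before use.  The first `truth$n_marine` habitats are flagged
#' marine.  The whole draw is a pure function of `truth$seed`.
#'
#' @param cells A `cell_table`.
#' @param covariates Data frame with one row per cell; any `cell_id` column
#'   is ignored for the linear predictor.  Must contain every variable
#'   named in `truth$gamma` and `truth$gamma_int`.
#' @param truth A [truth_record()].
#' @return A `habitat_occupancy` object: `cell_ids`, `habitat_ids`, the
#'   cell x habitat 0/1 `presence` matrix, and the per-habitat
#'   `marine_flag`.
#' @export
gen_occupancy <- function(cells, covariates, truth) {
  stopifnot(inherits(truth, "truth_record"))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(cells))
    stopf("covariate table has %d rows but there are %d cells",
          nrow(covariates), nrow(cells))
  vars <- setdiff(names(covariates), "cell_id")
  int_names <- names(truth$gamma_int) %||% character(0)
  need <- unique(c(names(truth$gamma),
                   unlist(strsplit(int_names, ":", fixed = TRUE))))
  missing_v <- setdiff(need, vars)
  if (length(missing_v) > 0)
    stopf("covariates missing variable(s) named in truth: %s",
          paste(missing_v, collapse = ", "))
  X <- scale(as.matrix(covariates[vars]))
  n <- nrow(X); H <- truth$n_habitats
  gamma <- setNames(numeric(length(vars)), vars)
  gamma[names(truth$gamma)] <- truth$gamma
  cs <- cell_size_of(cells)
  area_term <- truth$area_exponent * log(cells$land_area / cs^2)
  int_term <- numeric(n)
  for (nm in int_names) {
    uv <- strsplit(nm, ":", fixed = TRUE)[[1]]
    int_term <- int_term + truth$gamma_int[[nm]] * X[, uv[1]] * X[, uv[2]]
  }
  with_seed(truth$seed, {
    u <- if (truth$spatial_sd > 0)
      grf_points(cbind(cells$easting, cells$northing),
                 truth$spatial_range, truth$spatial_sd)
    else numeric(n)
    alpha <- rnorm(H, truth$alpha_mean, truth$alpha_sd)
    delta <- matrix(rnorm(H * length(vars), 0, truth$delta_sd), H,
                    length(vars))
    base <- drop(X %*% gamma) + u + area_term + int_term
    eta <- outer(base, alpha, `+`) + X %*% t(delta)
    presence <- matrix(rbinom(n * H, 1, plogis(eta)), n, H)
  })
  habitat_occupancy(
    cell_ids = cells$cell_id,
    habitat_ids = sprintf("H%03d", seq_len(H)),
    presence = presence,
    marine_flag = seq_len(H) <= truth$n_marine
  )
}

#' Generate species richness coupled to habitat richness
#'
#' Per-cell species counts are `SR_i ~ Poisson(lambda0 * exp(kappa * z_i))`
#' where `z` is standardized habitat richness, so `kappa` controls how
#' strongly species richness tracks habitat richness and `lambda0` sets its
#' baseline level.
#'
#' @param richness Per-cell habitat richness (numeric vector).
#' @param kappa Coupling strength (0 = independent).
#' @param lambda0 Baseline expected species count (> 0).
#' @param seed Integer seed.
#' @return Integer vector of species counts.
#' @export
gen_species <- function(richness, kappa = 0.5, lambda0 = 50, seed = 1L) {
  if (!is.numeric(lambda0) || length(lambda0) != 1 || lambda0 <= 0)
    stopf("lambda0 must be a single positive rate")
  z <- if (sd(richness) > 0) (richness - mean(richness)) / sd(richness)
       else numeric(length(richness))
  with_seed(seed, rpois(length(richness), lambda0 * exp(kappa * z)))
}
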