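#' Upscale a raster to per-cell values by the median
#'
#' Skewed anthropogenic rasters (population density, fragmentation) are
#' aggregated from fine pixels to the analysis cells by the median of the
#' covered pixels, which is robust to their long right tails.  Missing
#' pixels are excluded; a cell with no valid pixel gets `NA` and its id is
#' recorded in the `"dropped"` attribute.
#'
#' @param raster A [raster_field()] whose pixels nest in the cell grid.
#' @param cells A `cell_table`.
#' @return Named numeric vector of per-cell medians, with attribute
#'   `"dropped"` (cell ids with no valid pixel).
#' @export
upscale_median <- function(raster, cells) {
  stopifnot(inherits(raster, "raster_field"))
  cs <- cell_size_of(cells)
  ratio <- cs / raster$pixel_size
  if (abs(ratio - round(ratio)) > 1e-9)
    stopf("raster pixels (%g km) do not nest in %g km cells",
          raster$pixel_size, cs)
  org <- grid_origin_of(cells)
  ax <- raster_axes(raster)
  pc <- ceiling((rep(ax$easting, each = nrow(raster$values)) - org[1]) / cs)
  pr <- ceiling((rep(ax$northing, times = ncol(raster$values)) - org[2]) / cs)
  idx <- match(paste(pr, pc), paste(cells$row, cells$col))
  vals <- as.vector(raster$values)
  keep <- !is.na(idx) & !is.na(vals)
  out <- rep(NA_real_, nrow(cells))
  if (any(keep)) {
    med <- tapply(vals[keep], idx[keep], median)
    out[as.integer(names(med))] <- as.numeric(med)
  }
  names(out) <- as.character(cells$cell_id)
  attr(out, "dropped") <- cells$cell_id[is.na(out)]
  out
}

# Length of the part of segment (x0,y0)-(x1,y1) inside the axis-aligned
# box [xlo,xhi] x [ylo,yhi] (Liang-Barsky interval clipping).
clip_length <- function(x0, y0, x1, y1, xlo, xhi, ylo, yhi) {
  dx <- x1 - x0; dy <- y1 - y0
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) return(0)
  t0 <- 0; t1 <- 1
  for (b in list(c(-dx, x0 - xlo), c(dx, xhi - x0),
                 c(-dy, y0 - ylo), c(dy, yhi - y0))) {
    p <- b[1]; q <- b[2]
    if (p == 0) {
      if (q < 0) return(0)
    } else {
      r <- q / p
      if (p < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
    }
  }
  if (t1 <= t0) return(0)
  len * (t1 - t0)
}

#' Per-cell street length and density
#'
#' Clips every segment to the cell footprints and sums the clipped lengths,
#' combining all road classes.  Street density divides the total length in
#' a cell by that cell's land area.
#'
#' @param net A `line_network` from [gen_streets()] (columns `x0`, `y0`,
#'   `x1`, `y1` in km).
#' @param cells A `cell_table`.
#' @return Data frame `cell_id`, `STREET_LENGTH` (km),
#'   `STREET_DENSITY` (km/km^2).
#' @export
street_metrics <- function(net, cells) {
  cs <- cell_size_of(cells)
  xlo <- cells$easting - cs / 2; xhi <- cells$easting + cs / 2
  ylo <- cells$northing - cs / 2; yhi <- cells$northing + cs / 2
  total <- rep(0, nrow(cells))
  if (nrow(net) > 0) {
    org <- grid_origin_of(cells)
    key <- paste(cells$row, cells$col)
    for (s in seq_len(nrow(net))) {
      sx0 <- net$x0[s]; sy0 <- net$y0[s]
      sx1 <- net$x1[s]; sy1 <- net$y1[s]
      cr <- ceiling((sort(c(sy0, sy1)) - org[2]) / cs)
      cc <- ceiling((sort(c(sx0, sx1)) - org[1]) / cs)
      for (r in cr[1]:cr[2]) for (cl in cc[1]:cc[2]) {
        i <- match(paste(r, cl), key)
        if (is.na(i)) next
        total[i] <- total[i] +
          clip_length(sx0, sy0, sx1, sy1, xlo[i], xhi[i], ylo[i], yhi[i])
      }
    }
  }
  data.frame(cell_id = cells$cell_id, STREET_LENGTH = total,
             STREET_DENSITY = total / cells$land_area)
}

#' Default keep-priority order for the collinearity screen
#'
#' Encodes the "ecological importance" judgment used when one member of a
#' strongly correlated pair must be discarded: geographic variables first
#' (they enter every model), then the core temperature/precipitation pair,
#' their seasonal companions, the anthropogenic rasters, and finally the
#' redundant candidates (seasonality duplicates and street metrics), which
#' the default screen drops.
#'
#' @return Character vector, highest keep-priority first.
#' @export
default_priority <- function() {
  c("NORTH", "EAST", "TRI", "BIO_1", "BIO_12", "BIO_7", "BIO_15",
    "FRAG_IND", "POP_DENS", "BIO_4", "BIO_17",
    "STREET_LENGTH", "STREET_DENSITY")
}

#' Screen covariates for multicollinearity
#'
#' Iteratively inspects the absolute Pearson correlation matrix: while any
#' pair exceeds `threshold`, the pair with the largest |r| (ties broken
#' alphabetically by pair name) loses its lower-priority member.  `NORTH`
#' and `EAST` are never dropped, since the geographic coordinates enter all
#' models.  Constant columns cannot be correlated and are dropped with a
#' warning before screening.
#'
#' @param table Covariate data frame (a `cell_id` column is ignored).
#' @param threshold Absolute correlation above which a pair is collinear.
#' @param priority Character vector covering all candidate variables,
#'   highest keep-priority first; see [default_priority()].
#' @return A `screen_report`: list with `retained` (character),
#'   `dropped` (data frame `variable`, `partner`, `r`), and `threshold`.
#' @export
collinearity_screen <- function(table, threshold = 0.7,
                                priority = default_priority()) {
  vars <- setdiff(names(table), "cell_id")
  X <- as.data.frame(table)[vars]
  dropped <- data.frame(variable = character(0), partner = character(0),
                        r = numeric(0))
  const <- vars[vapply(X, function(x) sd(x) == 0 || !is.finite(sd(x)),
                       logical(1))]
  if (length(const) > 0) {
    warnf("dropping constant covariate(s) before screening: %s",
          paste(const, collapse = ", "))
    dropped <- rbind(dropped, data.frame(variable = const, partner = NA,
                                         r = NA_real_))
    vars <- setdiff(vars, const)
  }
  missing_p <- setdiff(vars, priority)
  if (length(missing_p) > 0)
    stopf("priority list does not cover: %s",
          paste(missing_p, collapse = ", "))
  protected <- intersect(c("NORTH", "EAST"), vars)
  rank_of <- function(v) match(v, priority)
  repeat {
    if (length(vars) < 2) break
    C <- abs(cor(X[vars]))
    diag(C) <- 0
    pairs <- which(C > threshold, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    if (nrow(pairs) > 0) {
      # a pair where both members are protected can never be resolved
      both_prot <- vars[pairs[, 1]] %in% protected &
        vars[pairs[, 2]] %in% protected
      pairs <- pairs[!both_prot, , drop = FALSE]
    }
    if (nrow(pairs) == 0) break
    r <- C[pairs]
    nm <- paste(pmin(vars[pairs[, 1]], vars[pairs[, 2]]),
                pmax(vars[pairs[, 1]], vars[pairs[, 2]]))
    best <- order(-r, nm)[1]
    a <- vars[pairs[best, 1]]; b <- vars[pairs[best, 2]]
    # drop the lower-priority member; protected variables always win
    loser <- if (a %in% protected) b
             else if (b %in% protected) a
             else if (rank_of(a) < rank_of(b)) b else a
    winner <- setdiff(c(a, b), loser)
    dropped <- rbind(dropped, data.frame(variable = loser, partner = winner,
                                         r = r[best]))
    vars <- setdiff(vars, loser)
  }
  structure(list(retained = vars, dropped = dropped, threshold = threshold),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> |r| threshold %.2f\n", x$threshold))
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped) > 0) {
    cat("dropped:\n")
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("  %s (vs %s, r = %s)\n", x$dropped$variable[i],
                  x$dropped$partner[i],
                  ifelse(is.na(x$dropped$r[i]), "constant",
                         sprintf("%.3f", x$dropped$r[i]))))
  }
  invisible(x)
}

#' Bivariate polynomial screening against the response
#'
#' For each candidate variable, reports the Pearson correlation between the
#' response and the variable (1st order) and the multiple correlation of
#' the response on the variable plus its orthogonalized square (2nd
#' order), to display the shape of each bivariate relationship before
#' modeling.
#'
#' @param table Covariate data frame (a `cell_id` column is ignored).
#' @param response Numeric response (e.g. normalized habitat richness).
#' @return Data frame `variable`, `r_linear`, `r_quadratic`.
#' @export
bivariate_screen <- function(table, response) {
  vars <- setdiff(names(table), "cell_id")
  if (length(response) < 3) stopf("need at least 3 cells")
  rows <- lapply(vars, function(v) {
    x <- table[[v]]
    if (sd(x) == 0 || sd(response) == 0)
      return(data.frame(variable = v, r_linear = NA_real_,
                        r_quadratic = NA_real_))
    x2o <- residuals(lm(I(x^2) ~ x))
    fit <- lm(response ~ x + x2o)
    data.frame(variable = v, r_linear = cor(response, x),
               r_quadratic = sqrt(summary(fit)$r.squared))
  })
  do.call(rbind, rows)
}

#' Assemble the per-cell covariate table
#'
#' Builds the full candidate predictor roster: bioclim fields and the
#' skewed anthropogenic rasters upscaled to cells by the median, street
#' length/density from the clipped network, the per-cell TRI sum, and the
#' cell-center coordinates as `NORTH` and `EAST`.  Cells missing any value
#' are dropped and recorded in the `"dropped_cells"` attribute.
#'
#' @param cells A `cell_table`.
#' @param rasters Named list of [raster_field()]s (e.g. `BIO_*`,
#'   `POP_DENS`, `FRAG_IND`; a `DEM` entry is ignored here).
#' @param streets A `line_network`, or `NULL` to skip street metrics.
#' @param tri_cell Per-cell TRI sums from [tri_per_cell()], or `NULL`.
#' @return Data frame with `cell_id` and one named column per covariate;
#'   attribute `"provenance"` tags each column as raw, upscaled-median, or
#'   derived.
#' @export
assemble_covariates <- function(cells, rasters, streets = NULL,
                                tri_cell = NULL) {
  out <- data.frame(cell_id = cells$cell_id)
  prov <- character(0)
  for (nm in setdiff(names(rasters), "DEM")) {
    out[[nm]] <- unname(upscale_median(rasters[[nm]], cells))
    prov[nm] <- if (rasters[[nm]]$pixel_size < cell_size_of(cells))
      "upscaled-median" else "raw"
  }
  if (!is.null(streets)) {
    sm <- street_metrics(streets, cells)
    out$STREET_LENGTH <- sm$STREET_LENGTH
    out$STREET_DENSITY <- sm$STREET_DENSITY
    prov["STREET_LENGTH"] <- "derived"
    prov["STREET_DENSITY"] <- "derived"
  }
  if (!is.null(tri_cell)) {
    out$TRI <- unname(tri_cell[as.character(cells$cell_id)])
    prov["TRI"] <- "derived"
  }
  out$NORTH <- cells$northing
  out$EAST <- cells$easting
  prov["NORTH"] <- "derived"
  prov["EAST"] <- "derived"
  ok <- complete.cases(out)
  if (any(!ok))
    message(sprintf("dropping %d cell(s) with incomplete covariates",
                    sum(!ok)))
  res <- out[ok, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "provenance") <- prov
  attr(res, "dropped_cells") <- out$cell_id[!ok]
  res
}
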