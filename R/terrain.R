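#' Aggregate a raster by block arithmetic means
#'
#' Resamples a DEM (or any raster) to a coarser pixel size by averaging
#' `factor` x `factor` blocks, e.g. aggregating a fine DEM to the 200 m
#' resolution at which the ruggedness index is computed.  If the dimensions
#' are not divisible by `factor` the raster is padded with missing pixels,
#' which are excluded from the block means; an all-missing block is
#' missing in the output.
#'
#' @param dem A [raster_field()].
#' @param factor Integer aggregation factor (>= 1).
#' @return A [raster_field()] with pixel size `factor` times larger.
#' @export
aggregate_mean <- function(dem, factor) {
  stopifnot(inherits(dem, "raster_field"))
  if (!is_count(factor) || factor < 1)
    stopf("aggregation factor must be an integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(dem)
  v <- dem$values
  nrp <- ceiling(nrow(v) / factor) * factor
  ncp <- ceiling(ncol(v) / factor) * factor
  m <- matrix(NA_real_, nrp, ncp)
  m[seq_len(nrow(v)), seq_len(ncol(v))] <- v
  gr <- rep(seq_len(nrp / factor), each = factor)
  gc <- rep(seq_len(ncp / factor), each = factor)
  valid <- !is.na(m)
  m0 <- ifelse(valid, m, 0)
  S <- t(rowsum(t(rowsum(m0, gr)), gc))
  N <- t(rowsum(t(rowsum(valid + 0, gr)), gc))
  out <- S / N
  out[N == 0] <- NA_real_
  raster_field(out, dem$pixel_size * factor, dem$origin, dem$nodata)
}

#' Terrain ruggedness index raster
#'
#' Per pixel, TRI is the mean of the absolute elevation differences between
#' the pixel and its 8-neighborhood.  Edge and corner pixels average over
#' their available 5 or 3 neighbors.  Missing neighbors are skipped; a
#' pixel that is missing, or whose whole neighborhood is missing, is
#' missing in the output.  `variant = "riley"` gives the
#' root-sum-of-squared-differences form of the original index instead of
#' the mean-absolute-difference form.
#'
#' @param dem A [raster_field()] of at least 2 x 2 pixels.
#' @param variant `"mean-abs"` (default) or `"riley"`.
#' @return A [raster_field()] of nonnegative TRI values at the DEM's pixel
#'   size.
#' @export
tri_raster <- function(dem, variant = c("mean-abs", "riley")) {
  stopifnot(inherits(dem, "raster_field"))
  variant <- match.arg(variant)
  v <- dem$values
  if (nrow(v) < 2 || ncol(v) < 2) stopf("DEM must be at least 2 x 2")
  nr <- nrow(v); nc <- ncol(v)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ri <- seq_len(nr) + di
    cj <- seq_len(nc) + dj
    ok_r <- ri >= 1 & ri <= nr
    ok_c <- cj >= 1 & cj <= nc
    nb <- matrix(NA_real_, nr, nc)
    nb[ok_r, ok_c] <- v[ri[ok_r], cj[ok_c]]
    d <- abs(v - nb)
    use <- !is.na(d)
    if (variant == "riley") d <- d^2
    acc[use] <- acc[use] + d[use]
    cnt <- cnt + use
  }
  out <- if (variant == "riley") sqrt(acc) else acc / cnt
  out[cnt == 0 | is.na(v)] <- NA_real_
  raster_field(out, dem$pixel_size, dem$origin, dem$nodata)
}

#' Sum TRI pixels within each grid cell
#'
#' For each analysis cell, sums all TRI pixels whose centers fall in the
#' cell footprint (at 200 m pixels inside a 10 km cell that is 2500 pixels)
#' to give a per-cell topographic-heterogeneity covariate.  The pixel grid
#' must nest in the cell grid.  Missing pixels contribute 0 and are counted
#' in the coverage attributes.
#'
#' @param tri A TRI [raster_field()] (e.g. from [tri_raster()]).
#' @param cells A `cell_table`.
#' @return Named numeric vector of per-cell TRI sums, with attributes
#'   `"pixels_per_cell"` (contributing pixel count per cell) and
#'   `"nodata_per_cell"`.
#' @export
tri_per_cell <- function(tri, cells) {
  stopifnot(inherits(tri, "raster_field"))
  cs <- cell_size_of(cells)
  ratio <- cs / tri$pixel_size
  if (abs(ratio - round(ratio)) > 1e-9)
    stopf("TRI pixels (%g km) do not nest in %g km cells",
          tri$pixel_size, cs)
  org <- grid_origin_of(cells)
  off <- (tri$origin - org) / cs
  if (any(abs(off - round(off)) > 1e-9))
    stopf("TRI raster origin is not aligned with the cell grid")
  ax <- raster_axes(tri)
  pc <- ceiling((rep(ax$easting, each = nrow(tri$values)) - org[1]) / cs)
  pr <- ceiling((rep(ax$northing, times = ncol(tri$values)) - org[2]) / cs)
  key_cell <- paste(cells$row, cells$col)
  key_px <- paste(pr, pc)
  idx <- match(key_px, key_cell)
  vals <- as.vector(tri$values)
  inside <- !is.na(idx)
  miss <- inside & is.na(vals)
  contrib <- ifelse(is.na(vals), 0, vals)
  sums <- rep(0, nrow(cells))
  npix <- rep(0L, nrow(cells))
  nmiss <- rep(0L, nrow(cells))
  agg <- rowsum(contrib[inside], idx[inside])
  cnts <- rowsum(rep(1L, sum(inside)), idx[inside])
  sums[as.integer(rownames(agg))] <- agg[, 1]
  npix[as.integer(rownames(cnts))] <- cnts[, 1]
  if (any(miss)) {
    mg <- rowsum(rep(1L, sum(miss)), idx[miss])
    nmiss[as.integer(rownames(mg))] <- mg[, 1]
  }
  names(sums) <- as.character(cells$cell_id)
  attr(sums, "pixels_per_cell") <- npix
  attr(sums, "nodata_per_cell") <- nmiss
  sums
}
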