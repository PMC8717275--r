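#' Create a georeferenced raster field
#'
#' A minimal in-memory raster: a numeric matrix with a pixel size and an
#' origin.  Row 1 of `values` is the southernmost row, so the pixel at
#' `values[i, j]` has center coordinates
#' `origin + ((j - 0.5), (i - 0.5)) * pixel_size`.  Missing data are `NA`;
#' `nodata` is only a sentinel used when writing ESRI ASCII grids.
#'
#' @param values Numeric matrix (rows south to north).
#' @param pixel_size Pixel edge length, in km.
#' @param origin Length-2 numeric, `(easting, northing)` of the south-west
#'   corner, in km.
#' @param nodata Sentinel written in place of `NA` on export.
#' @return An object of class `raster_field`.
#' @export
raster_field <- function(values, pixel_size, origin = c(0, 0), nodata = -9999) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1 || ncol(values) < 1)
    stopf("raster values must be a numeric matrix of at least 1 x 1")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stopf("pixel_size must be a single positive number")
  if (length(origin) != 2 || !is.numeric(origin))
    stopf("origin must be a numeric (easting, northing) pair")
  structure(list(values = values, pixel_size = pixel_size,
                 origin = as.numeric(origin), nodata = nodata),
            class = "raster_field")
}

#' @export
print.raster_field <- function(x, ...) {
  cat(sprintf("<raster_field> %d x %d pixels of %g km, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              x$origin[1], x$origin[2]))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%g, %g], %d NA\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

# Pixel-center coordinates of a raster, as vectors along each axis.
raster_axes <- function(r) {
  list(easting  = r$origin[1] + (seq_len(ncol(r$values)) - 0.5) * r$pixel_size,
       northing = r$origin[2] + (seq_len(nrow(r$values)) - 0.5) * r$pixel_size)
}

#' Extract raster values at point locations (nearest pixel)
#'
#' @param r A [raster_field()].
#' @param easting,northing Coordinates, in km.
#' @return Numeric vector of pixel values (`NA` outside the raster).
#' @export
raster_extract <- function(r, easting, northing) {
  j <- ceiling((easting - r$origin[1]) / r$pixel_size)
  i <- ceiling((northing - r$origin[2]) / r$pixel_size)
  ok <- i >= 1 & i <= nrow(r$values) & j >= 1 & j <= ncol(r$values)
  out <- rep(NA_real_, length(easting))
  out[ok] <- r$values[cbind(i[ok], j[ok])]
  out
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format for the small rasters this package
#' produces.  Rows are written north to south, per the format.
#'
#' @param r A [raster_field()].
#' @param path File path.
#' @return `read_ascii_grid` returns a [raster_field()];
#'   `write_ascii_grid` returns `path` invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  v <- r$values
  v[is.na(v)] <- r$nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", r$origin[1]),
           sprintf("yllcorner %.10g", r$origin[2]),
           sprintf("cellsize %.10g", r$pixel_size),
           sprintf("NODATA_value %.10g", r$nodata))
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1,
                function(row) paste(format(row, trim = TRUE, digits = 10),
                                    collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- setNames(vapply(hdr, function(x) as.numeric(x[2]), numeric(1)),
                 tolower(vapply(hdr, `[`, character(1), 1)))
  v <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  v[v == kv[["nodata_value"]]] <- NA_real_
  raster_field(v, kv[["cellsize"]], c(kv[["xllcorner"]], kv[["yllcorner"]]),
               nodata = kv[["nodata_value"]])
}
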