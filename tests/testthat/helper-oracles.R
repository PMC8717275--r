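# Independent brute-force oracles and shared fixtures.

# Block-mean aggregation by explicit double loop.
oracle_block_mean <- function(values, factor) {
  nr <- ceiling(nrow(values) / factor)
  nc <- ceiling(ncol(values) / factor)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- ((i - 1) * factor + 1):min(i * factor, nrow(values))
    cj <- ((j - 1) * factor + 1):min(j * factor, ncol(values))
    block <- values[ri, cj]
    if (any(!is.na(block))) out[i, j] <- mean(block, na.rm = TRUE)
  }
  out
}

# TRI by explicit neighbor loops.
oracle_tri <- function(values, variant = "mean-abs") {
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(values[i, j])) next
    diffs <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (is.na(values[ii, jj])) next
      diffs <- c(diffs, abs(values[i, j] - values[ii, jj]))
    }
    if (length(diffs) > 0)
      out[i, j] <- if (variant == "riley") sqrt(sum(diffs^2))
                   else mean(diffs)
  }
  out
}

# Moran's I by explicit double sum with inverse-distance weights in
# (0, radius].
oracle_moran <- function(x, coords, radius) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d > 0 && d <= radius) {
      w <- 1 / d
      num <- num + w * z[i] * z[j]
      s0 <- s0 + w
    }
  }
  (n / s0) * num / sum(z^2)
}

# A cheap iid-covariate table named like the field roster, for model-level
# tests that do not need spatially structured fields.
make_iid_covariates <- function(n, seed,
                                vars = c("NORTH", "EAST", "TRI", "BIO_1",
                                         "BIO_7", "BIO_12", "BIO_15",
                                         "FRAG_IND", "POP_DENS")) {
  set.seed(seed)
  out <- as.data.frame(setNames(lapply(vars, function(v) rnorm(n)), vars))
  out
}

# A full synthetic landscape (cells + assembled covariates) at a chosen
# grid size, without street metrics unless asked.
make_landscape <- function(n = 30, seed = 1, coastal_fraction = 0.15,
                           streets = FALSE) {
  spec <- grid_spec(n, n)
  cells <- gen_grid(spec, coastal_fraction, seed = seed)
  rasters <- gen_fields(spec, seed = seed + 1)
  st <- if (streets) gen_streets(cells, rasters$POP_DENS, seed = seed + 2)
        else NULL
  tri <- tri_per_cell(tri_raster(rasters$DEM), cells)
  covs <- assemble_covariates(cells, rasters, st, tri)
  list(spec = spec, cells = cells, rasters = rasters, streets = st,
       covariates = covs)
}

bold_roster <- c("BIO_1", "BIO_7", "BIO_12", "BIO_15", "FRAG_IND",
                 "POP_DENS", "TRI", "NORTH", "EAST")
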