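# Gaussian random fields with exponential covariance
#
# C(d) = sd^2 * exp(-d / range).  Small point sets are simulated exactly by
# Cholesky factorization; large pixel lattices are simulated on a coarser
# exact lattice and bilinearly interpolated, plus an optional independent
# fine-scale (white noise) component where high-frequency structure is
# wanted.  Draws consume the current RNG stream, so callers seed via
# with_seed().

# Exact GRF draw at arbitrary coordinates (n x 2 matrix, km).
grf_points <- function(coords, range, sd, nugget = 1e-8) {
  n <- nrow(coords)
  if (sd == 0) return(numeric(n))
  if (range <= 0) stopf("GRF range must be > 0")
  if (n > 6000) stopf("grf_points: too many points (%d); use grf_lattice", n)
  D <- as.matrix(dist(coords))
  C <- sd^2 * exp(-D / range) + diag(nugget, n)
  U <- chol(C)
  drop(crossprod(U, rnorm(n)))
}

# Linear-interpolation weight matrix mapping values at `nodes` (sorted,
# length >= 2) to values at positions `pos`.
interp_weights <- function(pos, nodes) {
  k <- findInterval(pos, nodes, all.inside = TRUE)
  t <- (pos - nodes[k]) / (nodes[k + 1] - nodes[k])
  t <- pmin(pmax(t, 0), 1)
  W <- matrix(0, length(pos), length(nodes))
  W[cbind(seq_along(pos), k)] <- 1 - t
  W[cbind(seq_along(pos), k + 1)] <- W[cbind(seq_along(pos), k + 1)] + t
  W
}

# GRF on a regular pixel lattice.  Exact when the lattice is small; for
# large lattices the field is simulated exactly on a coarse node lattice
# (spacing about range/3, <= max_side nodes per axis) and bilinearly
# interpolated, which preserves structure at and above the target range.
grf_lattice <- function(n_rows, n_cols, pixel_size, range, sd,
                        origin = c(0, 0), max_exact = 4096, max_side = 48) {
  if (sd == 0) return(matrix(0, n_rows, n_cols))
  east <- origin[1] + (seq_len(n_cols) - 0.5) * pixel_size
  north <- origin[2] + (seq_len(n_rows) - 0.5) * pixel_size
  if (n_rows * n_cols <= max_exact) {
    coords <- cbind(rep(east, each = n_rows), rep(north, times = n_cols))
    return(matrix(grf_points(coords, range, sd), n_rows, n_cols))
  }
  spacing <- max(pixel_size, range / 3)
  n_side <- function(lo, hi, n_px) {
    max(2, min(max_side, n_px, ceiling((hi - lo) / spacing) + 1))
  }
  nodes_n <- seq(north[1], north[n_rows],
                 length.out = n_side(north[1], north[n_rows], n_rows))
  nodes_e <- seq(east[1], east[n_cols],
                 length.out = n_side(east[1], east[n_cols], n_cols))
  coords <- cbind(rep(nodes_e, each = length(nodes_n)),
                  rep(nodes_n, times = length(nodes_e)))
  coarse <- matrix(grf_points(coords, range, sd),
                   length(nodes_n), length(nodes_e))
  Wr <- interp_weights(north, nodes_n)
  Wc <- interp_weights(east, nodes_e)
  Wr %*% coarse %*% t(Wc)
}
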