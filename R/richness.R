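#' Construct a habitat occupancy incidence object
#'
#' Cell-by-habitat presence/absence with a per-habitat marine flag,
#' mirroring habitat distribution maps reported on an equal-area grid.
#'
#' @param cell_ids Unique cell identifiers (length = rows of `presence`).
#' @param habitat_ids Unique habitat identifiers (length = columns).
#' @param presence 0/1 matrix, cells x habitats.
#' @param marine_flag Logical per habitat; marine types are excluded from
#'   terrestrial richness by [filter_marine()].
#' @return An object of class `habitat_occupancy`.
#' @export
habitat_occupancy <- function(cell_ids, habitat_ids, presence, marine_flag) {
  presence <- as.matrix(presence)
  if (anyDuplicated(cell_ids) || anyDuplicated(habitat_ids))
    stopf("cell_ids and habitat_ids must be unique")
  if (nrow(presence) != length(cell_ids) ||
      ncol(presence) != length(habitat_ids))
    stopf("presence must be %d cells x %d habitats",
          length(cell_ids), length(habitat_ids))
  if (length(marine_flag) != length(habitat_ids) || !is.logical(marine_flag))
    stopf("marine_flag must be logical, one per habitat")
  if (!all(presence %in% c(0, 1)))
    stopf("presence must contain only 0/1")
  storage.mode(presence) <- "integer"
  dimnames(presence) <- list(as.character(cell_ids),
                             as.character(habitat_ids))
  structure(list(cell_ids = cell_ids, habitat_ids = habitat_ids,
                 presence = presence, marine_flag = marine_flag),
            class = "habitat_occupancy")
}

#' @export
print.habitat_occupancy <- function(x, ...) {
  cat(sprintf("<habitat_occupancy> %d cells x %d habitats (%d marine)\n",
              length(x$cell_ids), length(x$habitat_ids),
              sum(x$marine_flag)))
  invisible(x)
}

#' Drop marine habitat types from an occupancy table
#'
#' Terrestrial habitat richness counts only non-marine types; the marine
#' ones are removed up front (e.g. 231 reported types minus 9 marine gives
#' 222 terrestrial types).  The cell set is unchanged and the operation is
#' idempotent.
#'
#' @param occ A [habitat_occupancy()].
#' @return A [habitat_occupancy()] restricted to non-marine habitats.
#' @export
filter_marine <- function(occ) {
  stopifnot(inherits(occ, "habitat_occupancy"))
  keep <- !occ$marine_flag
  habitat_occupancy(occ$cell_ids, occ$habitat_ids[keep],
                    occ$presence[, keep, drop = FALSE],
                    occ$marine_flag[keep])
}

#' Count habitat richness per cell
#'
#' Habitat richness (HR) is the number of habitat types present in a cell:
#' the row sum of the incidence matrix.  Apply [filter_marine()] first if
#' marine types should not count.
#'
#' @param occ A [habitat_occupancy()].
#' @return Named integer vector of per-cell richness.
#' @export
compute_richness <- function(occ) {
  stopifnot(inherits(occ, "habitat_occupancy"))
  hr <- as.integer(rowSums(occ$presence))
  names(hr) <- as.character(occ$cell_ids)
  hr
}

#' Area-normalize habitat richness
#'
#' Cells on coastlines hold less land than interior cells, and richness
#' increases with area, so raw counts are corrected with a log-log
#' (species-area style) normalization:
#' `NHR = log10(HR + 1) / |log10(area)|`, with area in km^2.  The `+1`
#' makes empty cells map to 0 rather than -Inf, and the absolute value in
#' the denominator keeps the sign consistent for areas below 1 km^2.  The
#' normalization is undefined where `area` is (numerically) 1 km^2; such
#' cells raise an error here, and the pipeline excludes and logs them.
#'
#' @param HR Nonnegative richness counts.
#' @param land_area Land area per cell, km^2 (> 0).
#' @param eps Exclusion half-width around `|log10(area)| = 0`.
#' @return Numeric vector of normalized habitat richness.
#' @export
normalize_richness <- function(HR, land_area, eps = 1e-6) {
  if (length(land_area) == 1) land_area <- rep(land_area, length(HR))
  if (length(HR) == 1) HR <- rep(HR, length(land_area))
  if (length(HR) != length(land_area))
    stopf("HR and land_area lengths differ")
  if (any(HR < 0) || any(!is.finite(HR)))
    stopf("HR must be finite and >= 0")
  if (any(land_area <= 0))
    stopf("land_area must be > 0 km^2")
  den <- abs(log10(land_area))
  if (any(den <= eps))
    stopf("normalization undefined for land_area ~ 1 km^2 (cells: %s)",
          paste(which(den <= eps), collapse = ", "))
  log10(HR + 1) / den
}

#' Build the per-cell richness table
#'
#' Combines [compute_richness()] on marine-filtered occupancy with
#' [normalize_richness()], excluding (and recording) any cell whose land
#' area makes the normalization singular.
#'
#' @param occ A [habitat_occupancy()] (marine types are filtered here).
#' @param cells The matching `cell_table`.
#' @param eps Passed to [normalize_richness()].
#' @return Data frame `cell_id`, `land_area`, `HR`, `NHR`, with excluded
#'   cell ids in attribute `"excluded"`.
#' @export
richness_table <- function(occ, cells, eps = 1e-6) {
  occ <- filter_marine(occ)
  if (!identical(as.character(occ$cell_ids), as.character(cells$cell_id)))
    stopf("occupancy and cell table refer to different cells")
  hr <- compute_richness(occ)
  den <- abs(log10(cells$land_area))
  ok <- den > eps
  if (any(!ok))
    message(sprintf("excluding %d cell(s) with land area ~ 1 km^2: %s",
                    sum(!ok),
                    paste(cells$cell_id[!ok], collapse = ", ")))
  out <- data.frame(cell_id = cells$cell_id[ok],
                    land_area = cells$land_area[ok],
                    HR = unname(hr[ok]))
  out$NHR <- normalize_richness(out$HR, out$land_area, eps)
  attr(out, "excluded") <- cells$cell_id[!ok]
  out
}

#' Correlate habitat richness with species richness
#'
#' Pearson product-moment correlation with a two-sided test, used to check
#' that habitat richness tracks the richness of species of conservation
#' concern and can stand in as a biodiversity proxy.
#'
#' @param HR,SR Equal-length per-cell counts (n >= 3, non-constant).
#' @return List with elements `r` and `p`.
#' @export
correlate_with_species <- function(HR, SR) {
  if (length(HR) != length(SR) || length(HR) < 3)
    stopf("need equal-length vectors with at least 3 cells")
  if (sd(HR) == 0 || sd(SR) == 0)
    stopf("degenerate input: zero variance in HR or SR")
  ct <- cor.test(HR, SR, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Write / read occupancy as long-format CSV
#'
#' Columns `cell_id`, `habitat_id`, `presence`, `marine`; one row per
#' cell-habitat pair.
#'
#' @param occ A [habitat_occupancy()].
#' @param path CSV path.
#' @return `read_occupancy_csv` returns a [habitat_occupancy()].
#' @export
write_occupancy_csv <- function(occ, path) {
  long <- data.frame(
    cell_id = rep(occ$cell_ids, times = length(occ$habitat_ids)),
    habitat_id = rep(occ$habitat_ids, each = length(occ$cell_ids)),
    presence = as.vector(occ$presence),
    marine = rep(occ$marine_flag, each = length(occ$cell_ids))
  )
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occupancy_csv
#' @export
read_occupancy_csv <- function(path) {
  long <- read.csv(path)
  cell_ids <- unique(long$cell_id)
  habitat_ids <- unique(long$habitat_id)
  presence <- matrix(0L, length(cell_ids), length(habitat_ids),
                     dimnames = list(as.character(cell_ids),
                                     as.character(habitat_ids)))
  presence[cbind(match(long$cell_id, cell_ids),
                 match(long$habitat_id, habitat_ids))] <- long$presence
  marine <- long$marine[match(habitat_ids, long$habitat_id)]
  habitat_occupancy(cell_ids, habitat_ids, presence, as.logical(marine))
}
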