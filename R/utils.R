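`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`,
#' then restores the previous RNG state, so generators behave as pure
#' functions of their arguments without clobbering the caller's stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  code
}

# Deterministic child seed for a named pipeline stage; stays within 32-bit
# integer range.
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) %% 1e6) * 1009 + as.double(offset) * 101 + 17
  as.integer(s %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)
}

# Standardize numeric columns of a covariate table (cell_id untouched).
# Returns the table with attributes "center" and "scale".
standardize_covariates <- function(table) {
  vars <- setdiff(names(table), "cell_id")
  ctr <- vapply(table[vars], mean, numeric(1))
  scl <- vapply(table[vars], sd, numeric(1))
  if (any(!is.finite(scl)) || any(scl == 0)) {
    bad <- vars[!is.finite(scl) | scl == 0]
    stopf("cannot standardize constant covariate(s): %s",
          paste(bad, collapse = ", "))
  }
  out <- table
  for (v in vars) out[[v]] <- (table[[v]] - ctr[[v]]) / scl[[v]]
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}
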