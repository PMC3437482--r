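# The study-grid lattice and separable AR1xAR1 spatial covariance.

#' Map mean locations onto the study grid
#'
#' Locations in meters are converted to integer (column, row) grid
#' references relative to a south-westerly origin: `col = floor((x-x0)/cell)`,
#' `row = floor((y-y0)/cell)`, so the origin itself becomes (0, 0). Spatial
#' autocorrelation models index the distinct occupied cells.
#'
#' @param mean_locations data frame `individual`, `x`, `y` (e.g., from
#'   [mean_locations()]).
#' @param origin numeric `(x0, y0)` of the grid origin in meters; no
#'   location may lie south or west of it.
#' @param cell grid step in meters (default 100, the census resolution).
#' @return A `lattice_index`: list with `ids`, integer `row` and `col` per
#'   id, `occupied_cells` (distinct `(row, col)` pairs in row-major order),
#'   and `cell_of` (index of each id's cell in `occupied_cells`).
#' @export
grid_coordinates <- function(mean_locations, origin, cell = 100) {
  x <- mean_locations$x; y <- mean_locations$y
  ids <- as.character(mean_locations$individual)
  bad <- which(x < origin[1] | y < origin[2])
  if (length(bad))
    stop("location south/west of grid origin for individual(s): ",
         paste(ids[bad], collapse = ", "))
  col <- as.integer(floor((x - origin[1]) / cell))
  row <- as.integer(floor((y - origin[2]) / cell))
  key <- paste(row, col)
  occ_key <- unique(key[order(row, col)])        # row-major dedup
  occ <- do.call(rbind, strsplit(occ_key, " "))
  occupied <- data.frame(row = as.integer(occ[, 1]),
                         col = as.integer(occ[, 2]))
  structure(list(ids = ids, row = row, col = col,
                 occupied_cells = occupied,
                 cell_of = match(key, occ_key)),
            class = "lattice_index")
}

#' @export
print.lattice_index <- function(x, ...) {
  cat(sprintf("<lattice_index: %d ids on %d occupied cells>\n",
              length(x$ids), nrow(x$occupied_cells)))
  invisible(x)
}

#' Spatial autocorrelation parameters
#'
#' @param phi_row,phi_col per-step correlations of the row (south-north) and
#'   column (west-east) first-order autoregressive processes, each in
#'   (-1, 1).
#' @param variance trait-scale variance of the spatial effect.
#' @return An object of class `sac_parameters`.
#' @export
sac_parameters <- function(phi_row = 0, phi_col = 0, variance = 1) {
  if (abs(phi_row) >= 1 || abs(phi_col) >= 1)
    stop("|phi| must be < 1")
  if (variance < 0) stop("variance must be non-negative")
  structure(list(phi_row = phi_row, phi_col = phi_col, variance = variance),
            class = "sac_parameters")
}

#' First-order autoregressive correlation matrix
#'
#' @param n number of positions along one axis.
#' @param phi per-step correlation, |phi| < 1.
#' @return The symmetric Toeplitz matrix with `R[i, j] = phi^|i-j|`.
#' @export
ar1_correlation <- function(n, phi) {
  if (n < 1) stop("n must be >= 1")
  if (abs(phi) >= 1) stop("|phi| must be < 1")
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  phi^d
}

#' Separable AR1xAR1 covariance over occupied lattice cells
#'
#' `Cov[(r1,c1),(r2,c2)] = variance * phi_row^|r1-r2| * phi_col^|c1-c2|`:
#' the submatrix of the full Kronecker product of the two axis AR1
#' correlation matrices restricted to the cells that individuals actually
#' occupy.
#'
#' @param idx a `lattice_index`.
#' @param pars a [sac_parameters()] object.
#' @return Covariance matrix over `idx$occupied_cells` (in their stored
#'   order).
#' @export
ar1xar1_covariance <- function(idx, pars) {
  stopifnot(inherits(idx, "lattice_index"), inherits(pars, "sac_parameters"))
  if (abs(pars$phi_row) >= 1 || abs(pars$phi_col) >= 1)
    stop("|phi| must be < 1")
  r <- idx$occupied_cells$row
  cc <- idx$occupied_cells$col
  dr <- abs(outer(r, r, "-"))
  dc <- abs(outer(cc, cc, "-"))
  pars$variance * (pars$phi_row^dr) * (pars$phi_col^dc)
}
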