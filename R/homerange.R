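# Kernel home ranges: utilization distributions, isopleth sizes,
# Bhattacharyya-affinity overlap, and the S matrix.

#' Jitter location fixes
#'
#' Census fixes recorded to the nearest grid unit produce many exactly
#' coincident points, which breaks kernel density estimates. Each coordinate
#' is displaced by an independent uniform draw on `[-amplitude, amplitude]`
#' meters.
#'
#' @param fixes fix table (see [as_fixes()]).
#' @param amplitude maximum absolute displacement in meters (default 20).
#' @param seed RNG seed; the same seed reproduces the same jitter.
#' @return A copy of `fixes` with jittered `x`, `y`.
#' @export
jitter_fixes <- function(fixes, amplitude = 20, seed = 1L) {
  if (!is.numeric(amplitude) || amplitude <= 0)
    stop("jitter amplitude must be positive")
  set.seed(seed)
  n <- nrow(fixes)
  out <- fixes
  out$x <- fixes$x + stats::runif(n, -amplitude, amplitude)
  out$y <- fixes$y + stats::runif(n, -amplitude, amplitude)
  out
}

#' Kernel utilization distribution on a grid
#'
#' Bivariate product-normal kernel density estimate, stored as exact per-cell
#' masses (the kernel integrated over each cell, so discretization conserves
#' mass) on a rectangular grid covering the fixes plus `extent_pad` on every
#' side, then normalized to sum to one.
#'
#' The reference ("href") bandwidth is `h = sigma_pooled * n^(-1/6)` with
#' `sigma_pooled = sqrt((var(x) + var(y))/2)`, applied to both axes.
#'
#' @param x,y fix coordinates in meters.
#' @param bandwidth `"reference"` or a fixed numeric bandwidth in meters.
#' @param cell grid cell side length in meters.
#' @param extent_pad padding around the fix bounding box in meters; default
#'   three bandwidths.
#' @param min_fixes minimum number of fixes required.
#' @return A `utilization_distribution`: list with `origin` (lower-left
#'   corner, meters), `cell`, and `density` (matrix, rows = south-to-north,
#'   cols = west-to-east, summing to 1).
#' @export
estimate_ud <- function(x, y, bandwidth = "reference", cell = 10,
                        extent_pad = NULL, min_fixes = 10) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < min_fixes)
    stop(sprintf("only %d fixes; at least %d required", n, min_fixes))
  if (identical(bandwidth, "reference")) {
    sp <- sqrt((stats::var(x) + stats::var(y)) / 2)
    if (!is.finite(sp) || sp <= 0)
      stop("zero spatial variance in fixes; jitter the coordinates first")
    h <- sp * n^(-1 / 6)
  } else {
    h <- as.numeric(bandwidth)
    if (!is.finite(h) || h <= 0) stop("bandwidth must be positive")
  }
  if (is.null(extent_pad)) extent_pad <- 3 * h
  x0 <- min(x) - extent_pad
  y0 <- min(y) - extent_pad
  nx <- max(1L, ceiling((max(x) + extent_pad - x0) / cell))
  ny <- max(1L, ceiling((max(y) + extent_pad - y0) / cell))
  ex <- x0 + cell * (0:nx)   # cell edges
  ey <- y0 + cell * (0:ny)
  # per-fix kernel mass in each column/row of cells, via normal CDF diffs
  Px <- outer(x, ex, function(xi, e) stats::pnorm((e - xi) / h))
  Py <- outer(y, ey, function(yi, e) stats::pnorm((e - yi) / h))
  Dx <- Px[, -1, drop = FALSE] - Px[, -(nx + 1), drop = FALSE]
  Dy <- Py[, -1, drop = FALSE] - Py[, -(ny + 1), drop = FALSE]
  dens <- crossprod(Dy, Dx) / n        # ny x nx
  dens <- dens / sum(dens)
  structure(list(origin = c(x0, y0), cell = cell, density = dens,
                 bandwidth = h, n_fixes = n),
            class = "utilization_distribution")
}

#' @export
print.utilization_distribution <- function(x, ...) {
  cat(sprintf("<utilization_distribution %dx%d cells of %gm, h=%.1fm, n=%d>\n",
              nrow(x$density), ncol(x$density), x$cell, x$bandwidth,
              x$n_fixes))
  invisible(x)
}

#' Estimate utilization distributions per group, with an exclusion log
#'
#' Groups the fix table (by individual, or individual/season/year for annual
#' ranges), applies the minimum-fix filter, and estimates one UD per
#' retained group. Excluded groups are returned in a log, never dropped
#' silently.
#'
#' @param fixes fix table.
#' @param by grouping columns; `"individual"` pools an individual's lifetime
#'   fixes (the convention for overlap matrices),
#'   `c("individual","season","year")` gives seasonal annual ranges.
#' @param ... passed to [estimate_ud()].
#' @param min_fixes minimum fixes per group.
#' @return list with `uds` (named by group key, `ids` attribute giving the
#'   individual of each), and `exclusions` (data frame of skipped groups with
#'   fix counts).
#' @export
estimate_uds <- function(fixes, by = "individual", min_fixes = 10, ...) {
  key <- do.call(paste, c(fixes[by], sep = "/"))
  groups <- split(seq_len(nrow(fixes)), key)
  uds <- list()
  excl <- list()
  for (g in names(groups)) {
    rows <- groups[[g]]
    if (length(rows) < min_fixes) {
      excl[[g]] <- data.frame(group = g, n_fixes = length(rows),
                              reason = sprintf("fewer than %d fixes", min_fixes))
      next
    }
    uds[[g]] <- estimate_ud(fixes$x[rows], fixes$y[rows],
                            min_fixes = min_fixes, ...)
    attr(uds[[g]], "individual") <- fixes$individual[rows[1]]
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(group = character(), n_fixes = integer(), reason = character())
  rownames(exclusions) <- NULL
  list(uds = uds, exclusions = exclusions)
}

#' Home-range size at an isopleth
#'
#' Area of the smallest set of grid cells containing `isopleth` of the UD
#' mass: cells are accumulated in descending density order (ties broken by
#' stable cell order) until the cumulative mass first reaches the isopleth.
#'
#' @param ud a `utilization_distribution`.
#' @param isopleth mass fraction in (0, 1]; 0.95 delimits the core range.
#' @return Area in hectares.
#' @export
range_size <- function(ud, isopleth = 0.95) {
  if (!is.numeric(isopleth) || isopleth <= 0 || isopleth > 1)
    stop("isopleth must be in (0, 1]")
  m <- as.vector(ud$density)
  if (!length(m)) stop("empty utilization distribution")
  ord <- order(m, decreasing = TRUE)         # stable for ties
  cum <- cumsum(m[ord])
  k <- which(cum >= isopleth - 1e-12)[1]
  if (is.na(k)) k <- length(m)
  k * ud$cell^2 / 1e4
}

# Axis transfer matrix redistributing interval masses from a source grid
# (origin o, cell s, n cells) onto a target grid (origin O, cell c, m cells),
# proportionally to interval overlap. Conserves mass when the target covers
# the source.
.axis_transfer <- function(o, s, n, O, c, m) {
  lo_s <- o + s * (seq_len(n) - 1); hi_s <- lo_s + s
  lo_t <- O + c * (seq_len(m) - 1); hi_t <- lo_t + c
  ov <- pmax(outer(hi_s, hi_t, pmin) - outer(lo_s, lo_t, pmax), 0)
  ov / s
}

# Resample two UDs onto their common union grid at the finer cell size.
.align_uds <- function(ud1, ud2) {
  if (identical(ud1$origin, ud2$origin) && identical(ud1$cell, ud2$cell) &&
      identical(dim(ud1$density), dim(ud2$density)))
    return(list(d1 = ud1$density, d2 = ud2$density))
  cc <- min(ud1$cell, ud2$cell)
  x0 <- min(ud1$origin[1], ud2$origin[1])
  y0 <- min(ud1$origin[2], ud2$origin[2])
  xmax <- max(ud1$origin[1] + ncol(ud1$density) * ud1$cell,
              ud2$origin[1] + ncol(ud2$density) * ud2$cell)
  ymax <- max(ud1$origin[2] + nrow(ud1$density) * ud1$cell,
              ud2$origin[2] + nrow(ud2$density) * ud2$cell)
  nx <- ceiling((xmax - x0) / cc - 1e-9)
  ny <- ceiling((ymax - y0) / cc - 1e-9)
  reb <- function(ud) {
    Tx <- .axis_transfer(ud$origin[1], ud$cell, ncol(ud$density), x0, cc, nx)
    Ty <- .axis_transfer(ud$origin[2], ud$cell, nrow(ud$density), y0, cc, ny)
    crossprod(Ty, ud$density %*% Tx)   # ny x nx on the common grid
  }
  list(d1 = reb(ud1), d2 = reb(ud2))
}

#' Bhattacharyya's affinity between two utilization distributions
#'
#' `BA = sum over cells of sqrt(m1 * m2)` after the two UDs are resampled
#' onto a common grid (the union bounding box at the finer cell size, with
#' mass-conserving rebinning). BA is 1 for identical distributions and 0 for
#' disjoint ones, putting home-range overlap on the same 0-1 scale as
#' pairwise relatedness.
#'
#' @param ud1,ud2 `utilization_distribution` objects.
#' @return Overlap coefficient in \[0, 1\].
#' @export
ba_overlap <- function(ud1, ud2) {
  al <- .align_uds(ud1, ud2)
  min(1, sum(sqrt(pmax(al$d1, 0) * pmax(al$d2, 0))))
}

#' Build the home-range overlap (S) matrix
#'
#' Pairwise Bhattacharyya affinities between the lifetime UDs of all
#' individuals that have one; individuals in `all_ids` without a UD are
#' treated as unrelated in space (diagonal 1, off-diagonals 0), the
#' conservative convention for partially observed populations.
#'
#' @param uds list of `utilization_distribution` objects, named by (or
#'   carrying an `"individual"` attribute giving) the individual id.
#' @param all_ids ordered ids the matrix must cover (a superset of the UD
#'   ids); defaults to the UD ids.
#' @param psd `"none"`, or `"clip"` to raise eigenvalues below `eps` so the
#'   matrix is usable as a positive-definite mixed-model covariance.
#' @param eps eigenvalue floor for `psd = "clip"`.
#' @return An `overlap_matrix` (a `relationship_matrix` of kind `"S"` with
#'   fields `psd_adjusted` and `adjustment_magnitude`, the largest eigenvalue
#'   shift applied).
#' @export
build_s_matrix <- function(uds, all_ids = NULL, psd = c("none", "clip"),
                           eps = 1e-8) {
  psd <- match.arg(psd)
  ud_ids <- names(uds)
  if (is.null(ud_ids) || any(ud_ids == ""))
    ud_ids <- vapply(uds, function(u) as.character(attr(u, "individual")), "")
  if (anyDuplicated(ud_ids))
    stop("duplicate individual ids among utilization distributions")
  if (is.null(all_ids)) all_ids <- ud_ids
  all_ids <- as.character(all_ids)
  if (anyDuplicated(all_ids)) stop("duplicate ids in all_ids")
  if (!all(ud_ids %in% all_ids))
    stop("all_ids must contain every individual with a UD")
  k <- length(ud_ids)
  B <- diag(1, k)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        B[i, j] <- B[j, i] <- ba_overlap(uds[[i]], uds[[j]])
      }
    }
  }
  S <- align_matrix(relationship_matrix(ud_ids, B, "S"), all_ids)
  v <- S$values
  adjusted <- FALSE
  shift <- 0
  if (psd == "clip") {
    for (it in 1:20) {
      e <- eigen(v, symmetric = TRUE)
      if (min(e$values) >= eps) break
      shift <- max(shift, eps - min(e$values))
      # clip with headroom: re-fixing the diagonal shaves eigenvalues a hair
      v <- e$vectors %*% (pmax(e$values, 2 * eps) * t(e$vectors))
      d <- sqrt(diag(v))
      v <- v / outer(d, d)                  # re-fix unit diagonal
      v <- (v + t(v)) / 2
      adjusted <- TRUE
    }
  }
  out <- relationship_matrix(all_ids, v, "S")
  out$psd_adjusted <- adjusted
  out$adjustment_magnitude <- shift
  class(out) <- c("overlap_matrix", class(out))
  out
}

#' Adjust a capture weight to an estimated birth weight
#'
#' Calves gain weight between birth and capture; the estimated birth weight
#' is `capture_weight - 0.01539 * age_at_capture` with age in hours.
#'
#' @param capture_weight weight at capture, kg.
#' @param age_at_capture age at capture, hours (non-negative).
#' @return Estimated birth weight, kg.
#' @export
birth_weight_adjust <- function(capture_weight, age_at_capture) {
  if (any(age_at_capture < 0)) stop("age at capture must be non-negative")
  capture_weight - 0.01539 * age_at_capture
}

#' Assign individuals to regions and count local population sizes
#'
#' Each individual's mean location is assigned to the axis-aligned
#' rectangular region containing it; a point on a shared boundary goes to
#' the region whose label sorts first. Locations outside every region are
#' assigned to a sentinel `"outside"` region with a warning. The per-region
#' counts serve as an annual local-population-size covariate and the labels
#' as a region fixed effect.
#'
#' @param mean_locations data frame with `individual`, `x`, `y`.
#' @param regions data frame with `region`, `xmin`, `xmax`, `ymin`, `ymax`
#'   describing a partition of the study area.
#' @return list with `counts` (named integer vector over all regions, plus
#'   `"outside"` when used) and `assignment` (data frame `individual`,
#'   `region`).
#' @export
local_population_size <- function(mean_locations, regions) {
  regions <- regions[order(regions$region), , drop = FALSE]
  lab <- character(nrow(mean_locations))
  for (i in seq_len(nrow(mean_locations))) {
    inside <- mean_locations$x[i] >= regions$xmin &
      mean_locations$x[i] <= regions$xmax &
      mean_locations$y[i] >= regions$ymin &
      mean_locations$y[i] <= regions$ymax
    lab[i] <- if (any(inside)) regions$region[which(inside)[1]] else "outside"
  }
  if (any(lab == "outside"))
    warning(sum(lab == "outside"), " location(s) outside all regions; ",
            "assigned to sentinel region 'outside'")
  counts <- table(factor(lab, levels = c(regions$region,
                                         if (any(lab == "outside")) "outside")))
  list(counts = c(counts),
       assignment = data.frame(individual = mean_locations$individual,
                               region = lab, stringsAsFactors = FALSE))
}

#' Mean lifetime location per individual
#'
#' @param fixes fix table.
#' @param season optional season to restrict to.
#' @return data frame `individual`, `x`, `y` of per-individual mean
#'   coordinates (the locations used for lattice-based spatial models).
#' @export
mean_locations <- function(fixes, season = NULL) {
  if (!is.null(season)) fixes <- fixes[fixes$season %in% season, , drop = FALSE]
  agg <- stats::aggregate(fixes[c("x", "y")],
                          by = list(individual = fixes$individual), mean)
  agg[order(agg$individual), , drop = FALSE]
}
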