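# Plain-text exchange formats: triplet matrices, fixes tables, ASCII grids.

#' Write a relationship/overlap matrix as lower-triangle triplets
#'
#' The de-facto exchange dialect for mixed-model software: one line per
#' non-zero lower-triangle element, `row col value` with 1-based integer
#' indices, plus a sidecar file listing the ordered ids (one per line) that
#' the indices refer to.
#'
#' @param M a `relationship_matrix`.
#' @param path output path for the triplet file; the id sidecar is written to
#'   `paste0(path, ".ids")`.
#' @param zero_tol entries with absolute value at or below this are omitted.
#' @return `path`, invisibly.
#' @export
write_matrix_triplets <- function(M, path, zero_tol = 0) {
  v <- M$values
  n <- length(M$ids)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (i in seq_len(n)) {
    j <- seq_len(i)
    keep <- abs(v[i, j]) > zero_tol
    rows <- c(rows, rep.int(i, sum(keep)))
    cols <- c(cols, j[keep])
    vals <- c(vals, v[i, j][keep])
  }
  utils::write.table(data.frame(row = rows, col = cols, value = vals),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(M$ids, paste0(path, ".ids"))
  invisible(path)
}

#' Read a lower-triangle triplet matrix
#'
#' @param path triplet file written by [write_matrix_triplets()]; ids are
#'   read from `paste0(path, ".ids")`.
#' @param kind matrix kind tag (`"A"`, `"S"` or `"identity"`).
#' @return A [relationship_matrix()].
#' @export
read_matrix_triplets <- function(path, kind = "A") {
  ids <- readLines(paste0(path, ".ids"))
  tr <- utils::read.table(path, col.names = c("row", "col", "value"))
  n <- length(ids)
  v <- matrix(0, n, n)
  v[cbind(tr$row, tr$col)] <- tr$value
  v[cbind(tr$col, tr$row)] <- tr$value
  relationship_matrix(ids, v, kind)
}

#' Read a location-fix table from CSV
#'
#' Columns `individual`, `season`, `year`, `x`, `y` (meters on the study
#' grid).
#'
#' @param path CSV path.
#' @param seasons allowed season labels.
#' @return A validated data frame of fixes.
#' @export
read_fixes <- function(path, seasons = c("spring", "rut")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  as_fixes(df, seasons = seasons)
}

#' Validate a fix table
#' @param df data frame with `individual`, `season`, `year`, `x`, `y`.
#' @param seasons allowed season labels.
#' @return the validated data frame.
#' @export
as_fixes <- function(df, seasons = c("spring", "rut")) {
  req <- c("individual", "season", "year", "x", "y")
  if (!all(req %in% names(df)))
    stop("fix table needs columns: ", paste(setdiff(req, names(df)), collapse = ", "))
  df$individual <- as.character(df$individual)
  df$season <- as.character(df$season)
  if (!all(df$season %in% seasons))
    stop("unknown season label(s): ",
         paste(setdiff(unique(df$season), seasons), collapse = ", "))
  df$year <- as.integer(df$year)
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("non-finite coordinates in fix table")
  df
}

#' Export a utilization distribution as an ESRI ASCII grid
#'
#' @param ud a `utilization_distribution`.
#' @param path output path.
#' @param nodata value written for the NODATA_value header field.
#' @return `path`, invisibly.
#' @export
write_ud_ascii <- function(ud, path, nodata = -9999) {
  d <- ud$density
  hdr <- c(sprintf("ncols %d", ncol(d)),
           sprintf("nrows %d", nrow(d)),
           sprintf("xllcorner %.6f", ud$origin[1]),
           sprintf("yllcorner %.6f", ud$origin[2]),
           sprintf("cellsize %.6f", ud$cell),
           sprintf("NODATA_value %d", nodata))
  # ASCII grids are written north-to-south: top row first
  body <- apply(d[rev(seq_len(nrow(d))), , drop = FALSE], 1,
                function(r) paste(format(r, digits = 10, scientific = TRUE,
                                         trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
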