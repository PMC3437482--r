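# Pedigree handling and the additive genetic relationship (A) matrix.

#' Construct a validated pedigree table
#'
#' Validates a data frame of individual/dam/sire triples and returns it in a
#' topological order in which every parent precedes its offspring. Parents
#' that are named but never listed as individuals are either appended as
#' founder rows (`founder_policy = "implicit"`) or rejected.
#'
#' @param x data frame with columns `individual`, `dam`, `sire` and
#'   optionally `sex` and `cohort`. Identifiers are coerced to character.
#' @param founder_policy `"implicit"` to append unlisted parents as founders,
#'   `"error"` to reject them.
#' @param unknown character vector of sentinel values (in addition to `NA`)
#'   that encode an unknown parent.
#' @return A `pedigree_table`: a data frame with columns `individual`, `dam`,
#'   `sire` (unknown parents as `NA`), plus any of `sex`/`cohort` supplied,
#'   sorted so parents precede offspring.
#' @export
as_pedigree <- function(x, founder_policy = c("implicit", "error"),
                        unknown = c("", "0", "NA")) {
  founder_policy <- match.arg(founder_policy)
  req <- c("individual", "dam", "sire")
  if (!all(req %in% names(x)))
    stop("pedigree needs columns: ", paste(setdiff(req, names(x)), collapse = ", "))
  ped <- data.frame(individual = as.character(x$individual),
                    dam = as.character(x$dam),
                    sire = as.character(x$sire),
                    stringsAsFactors = FALSE)
  for (col in c("dam", "sire"))
    ped[[col]][ped[[col]] %in% unknown] <- NA_character_
  if (!is.null(x$sex)) ped$sex <- as.character(x$sex)
  if (!is.null(x$cohort)) ped$cohort <- as.integer(x$cohort)

  dup <- ped$individual[duplicated(ped$individual)]
  if (length(dup))
    stop("duplicate individual id(s): ", paste(unique(dup), collapse = ", "))
  if (any(is.na(ped$individual) | ped$individual == ""))
    stop("missing individual id")

  parents <- setdiff(stats::na.omit(c(ped$dam, ped$sire)), ped$individual)
  if (length(parents)) {
    if (founder_policy == "error")
      stop("parent(s) not listed as individuals: ",
           paste(parents, collapse = ", "))
    extra <- data.frame(individual = parents, dam = NA_character_,
                        sire = NA_character_, stringsAsFactors = FALSE)
    for (col in setdiff(names(ped), names(extra))) extra[[col]] <- NA
    ped <- rbind(ped, extra[names(ped)])
  }

  ped <- toposort_pedigree(ped)
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Read a pedigree from CSV
#'
#' Expects a header with columns `individual`, `dam`, `sire` (optionally
#' `sex`, `cohort`); row order in the file is irrelevant.
#'
#' @param path path to a CSV file.
#' @inheritParams as_pedigree
#' @return A [as_pedigree()] `pedigree_table`.
#' @export
read_pedigree <- function(path, founder_policy = c("implicit", "error"),
                          unknown = c("", "0", "NA")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  names(df) <- tolower(names(df))
  as_pedigree(df, founder_policy = founder_policy, unknown = unknown)
}

# Kahn topological sort; errors on cycles naming one individual involved.
toposort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$individual
  dam <- idx[ped$dam]
  sire <- idx[ped$sire]
  if (any(ped$individual == ped$dam, na.rm = TRUE) ||
      any(ped$individual == ped$sire, na.rm = TRUE)) {
    bad <- ped$individual[which(ped$individual == ped$dam |
                                ped$individual == ped$sire)[1]]
    stop("pedigree cycle: individual ", bad, " is its own parent")
  }
  # children adjacency
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(dam[i], sire[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    bad <- ped$individual[setdiff(seq_len(n), out)[1]]
    stop("pedigree cycle detected involving individual ", bad)
  }
  ped[out, , drop = FALSE]
}

#' Relationship matrix container
#'
#' A symmetric matrix of pairwise similarity coefficients with an ordered id
#' vector: additive relatedness (`kind = "A"`), home-range overlap
#' (`kind = "S"`), or identity.
#'
#' @param ids ordered character vector of identifiers.
#' @param values symmetric numeric matrix, `length(ids)` square.
#' @param kind one of `"A"`, `"S"`, `"identity"`.
#' @return An object of class `relationship_matrix`.
#' @export
relationship_matrix <- function(ids, values, kind = c("A", "S", "identity")) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(ids), ncol(values) == length(ids))
  if (length(ids) && max(abs(values - t(values))) > 1e-8)
    stop("relationship matrix must be symmetric")
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, kind = kind),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix kind=%s, %d ids>\n", x$kind, length(x$ids)))
  invisible(x)
}

#' Additive genetic relationship matrix (tabular method)
#'
#' Builds the A matrix by Henderson's tabular recursion in topological order:
#' `a_ii = 1 + a(dam_i, sire_i)/2` (the inbreeding-adjusted diagonal; 1 when
#' either parent is unknown) and `a_ij = (a(j, dam_i) + a(j, sire_i))/2` for
#' every earlier individual `j`, with unknown parents contributing zero.
#'
#' @param ped a `pedigree_table` (sorted internally if needed).
#' @return A [relationship_matrix()] with `kind = "A"` over the pedigree ids.
#' @export
additive_relationship <- function(ped) {
  if (!inherits(ped, "pedigree_table")) ped <- as_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$individual
  dam <- unname(idx[ped$dam])
  sire <- unname(idx[ped$sire])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- dam[i]; s <- sire[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- numeric(i - 1L)
      if (!is.na(d)) aj <- aj + A[j, d]
      if (!is.na(s)) aj <- aj + A[j, s]
      aj <- aj / 2
      A[j, i] <- aj
      A[i, j] <- aj
    }
    A[i, i] <- 1 + if (!is.na(d) && !is.na(s)) 0.5 * A[d, s] else 0
  }
  relationship_matrix(ped$individual, A, "A")
}

#' Reorder/subset a relationship matrix onto a target id set
#'
#' Individuals requested but absent from the matrix are filled in as
#' unrelated: diagonal 1, off-diagonals 0 (`missing_policy = "identity_row"`).
#' This is the standard convention for fitting a similarity matrix that
#' covers only part of the modelled population.
#'
#' @param M a `relationship_matrix`.
#' @param ids target ordered identifier vector (no duplicates).
#' @param missing_policy only `"identity_row"` is implemented.
#' @return A `relationship_matrix` of the same `kind` over `ids`.
#' @export
align_matrix <- function(M, ids, missing_policy = "identity_row") {
  missing_policy <- match.arg(missing_policy, "identity_row")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate ids in alignment request")
  n <- length(ids)
  out <- diag(1, n)
  present <- ids %in% M$ids
  if (any(present)) {
    pos <- match(ids[present], M$ids)
    out[present, present] <- M$values[pos, pos, drop = FALSE]
  }
  relationship_matrix(ids, out, M$kind)
}

#' Monte-Carlo gene-dropping kinship
#'
#' Independent check on the tabular A matrix: founder alleles are dropped
#' through the pedigree `n_drops` times and pairwise kinship is estimated as
#' the probability that alleles sampled from two individuals are identical
#' by descent. Twice the kinship estimates the additive relatedness.
#'
#' @param ped a `pedigree_table`.
#' @param n_drops number of independent allele drops.
#' @param seed RNG seed.
#' @return list with `ids`, `relatedness` (2 x kinship matrix), `se`
#'   (elementwise empirical Monte-Carlo standard error of `relatedness`), and
#'   `se_bound` (`1/sqrt(n_drops)`, a distribution-free upper bound on every
#'   element's Monte-Carlo standard error, since each per-drop relatedness
#'   contribution lies in [0, 2]).
#' @export
gene_drop_kinship <- function(ped, n_drops = 1e5, seed = 1L) {
  if (!inherits(ped, "pedigree_table")) ped <- as_pedigree(ped)
  set.seed(seed)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$individual
  dam <- unname(idx[ped$dam])
  sire <- unname(idx[ped$sire])
  # allele labels per individual per drop; founders/unknown parents get
  # globally unique alleles (non-IBD by construction)
  A1 <- matrix(0L, n, n_drops)
  A2 <- matrix(0L, n, n_drops)
  next_allele <- 1L
  for (i in seq_len(n)) {
    for (side in 1:2) {
      p <- if (side == 1) dam[i] else sire[i]
      if (is.na(p)) {
        al <- rep.int(next_allele, n_drops)
        next_allele <- next_allele + 1L
      } else {
        pick <- stats::runif(n_drops) < 0.5
        al <- ifelse(pick, A1[p, ], A2[p, ])
      }
      if (side == 1) A1[i, ] <- al else A2[i, ] <- al
    }
  }
  rel <- matrix(0, n, n)
  se <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        v <- 1 + (A1[i, ] == A2[i, ])            # per-drop a_ii
      } else {
        v <- ((A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
              (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])) / 2
      }
      m <- mean(v)
      rel[i, j] <- rel[j, i] <- m
      s <- stats::sd(v) / sqrt(n_drops)
      se[i, j] <- se[j, i] <- s
    }
  }
  dimnames(rel) <- dimnames(se) <- list(ped$individual, ped$individual)
  list(ids = ped$individual, relatedness = rel, se = se,
       se_bound = 1 / sqrt(n_drops))
}
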