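# Synthetic populations with known truth: a female-philopatric pedigree,
# matrilineally clustered space use, and phenotypes simulated from the
# animal model so every pipeline stage can be scored against known variance
# components.

#' Simulation configuration
#'
#' Defaults emulate a mid-sized intensively monitored ungulate study
#' population: a few dozen founder matrilines, discrete generations with
#' strong female philopatry (daughters settle a short displacement from
#' their mother's range center), repeated seasonal censuses, and traits
#' drawn from an animal model with configurable variance components.
#'
#' @param seed master RNG seed; every downstream simulation derives its
#'   stream from it.
#' @param n_founder_females founder matriline count.
#' @param n_generations discrete generations including the founders.
#' @param offspring_per_female mean daughters per female per generation
#'   (Poisson).
#' @param unknown_father_fraction probability a daughter's sire is
#'   unrecorded.
#' @param n_males size of the external sire pool per generation.
#' @param dispersal_sd SD (meters) of the isotropic Gaussian displacement of
#'   a daughter's range center from her mother's.
#' @param range_sd SD (meters) of within-individual fix scatter about the
#'   range center.
#' @param fixes_per_season census fixes per individual per season per year.
#' @param seasons season labels.
#' @param n_years measurement years for repeated traits.
#' @param study_extent `(width, height)` in meters of the rectangle on which
#'   founder range centers are uniform.
#' @param mu trait mean (latent scale).
#' @param true_components named variances: `V_A`, `V_PE`, `V_M`, `V_Year`,
#'   `V_Smatrix`, `V_Residual` (any omitted default to 0 except
#'   `V_Residual`).
#' @param sac optional list `(phi_row, phi_col, variance)`: carry the
#'   spatial effect by an AR1xAR1 field on the 100-m lattice of mean
#'   locations instead of the overlap matrix.
#' @param trait_design `"repeated"` (one record per female-year) or
#'   `"single_measure"` (one record per female, year = cohort of birth).
#' @param log_scale if `TRUE` the observed trait is `exp(latent)`, so models
#'   should set `log_transform = TRUE`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_founder_females = 75L,
                       n_generations = 4L,
                       offspring_per_female = 1.0,
                       unknown_father_fraction = 0.2,
                       n_males = 30L,
                       dispersal_sd = 100,
                       range_sd = 150,
                       fixes_per_season = 20L,
                       seasons = c("spring", "rut"),
                       n_years = 4L,
                       study_extent = c(2000, 2000),
                       mu = 10,
                       true_components = c(V_A = 0.3, V_Smatrix = 0.5,
                                           V_Residual = 0.2),
                       sac = NULL,
                       trait_design = c("repeated", "single_measure"),
                       log_scale = FALSE) {
  trait_design <- match.arg(trait_design)
  comp <- c(V_A = 0, V_PE = 0, V_M = 0, V_Year = 0, V_Smatrix = 0,
            V_Residual = 0)
  comp[names(true_components)] <- true_components
  if (any(comp < 0)) stop("variances must be non-negative")
  if (dispersal_sd < 0 || range_sd <= 0) stop("invalid spatial SDs")
  if (n_founder_females < 1) stop("need at least one founder female")
  structure(list(seed = as.integer(seed),
                 n_founder_females = as.integer(n_founder_females),
                 n_generations = as.integer(n_generations),
                 offspring_per_female = offspring_per_female,
                 unknown_father_fraction = unknown_father_fraction,
                 n_males = as.integer(n_males),
                 dispersal_sd = dispersal_sd, range_sd = range_sd,
                 fixes_per_season = as.integer(fixes_per_season),
                 seasons = seasons, n_years = as.integer(n_years),
                 study_extent = study_extent, mu = mu,
                 true_components = comp, sac = sac,
                 trait_design = trait_design, log_scale = log_scale),
            class = "sim_config")
}

#' Simulate a female-philopatric pedigree
#'
#' Discrete generations: every female's dam is recorded; sires are drawn
#' from an external male pool and unrecorded with probability
#' `unknown_father_fraction`, emulating field pedigrees in which a fraction
#' of individuals have unknown parents. Sires never listed as individuals
#' enter the pedigree as implicit founders.
#'
#' @param cfg a [sim_config()].
#' @return A `pedigree_table` with `sex` (`"F"` for study females) and
#'   `cohort` (generation index) columns.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  rows <- data.frame(individual = sprintf("F%04d", seq_len(cfg$n_founder_females)),
                     dam = NA_character_, sire = NA_character_,
                     sex = "F", cohort = 1L, stringsAsFactors = FALSE)
  current <- rows$individual
  next_id <- cfg$n_founder_females + 1L
  for (g in seq_len(cfg$n_generations - 1L)) {
    males <- sprintf("M%02d%03d", g, seq_len(cfg$n_males))
    kids <- list()
    for (mom in current) {
      nd <- stats::rpois(1, cfg$offspring_per_female)
      if (nd == 0) next
      sire <- sample(males, nd, replace = TRUE)
      sire[stats::runif(nd) < cfg$unknown_father_fraction] <- NA_character_
      ids <- sprintf("F%04d", next_id:(next_id + nd - 1L))
      next_id <- next_id + nd
      kids[[mom]] <- data.frame(individual = ids, dam = mom, sire = sire,
                                sex = "F", cohort = g + 1L,
                                stringsAsFactors = FALSE)
    }
    if (!length(kids)) break
    newrows <- do.call(rbind, kids)
    rownames(newrows) <- NULL
    rows <- rbind(rows, newrows)
    current <- newrows$individual
  }
  as_pedigree(rows, founder_policy = "implicit")
}

#' Simulate philopatric space use
#'
#' Founder range centers are uniform on the study rectangle; each
#' daughter's center is her mother's plus an isotropic Gaussian displacement
#' (`dispersal_sd`), so matrilines form spatial clusters. Fixes per
#' individual-season-year are isotropic Gaussian (`range_sd`) about the
#' center.
#'
#' @param ped a `pedigree_table` from [simulate_pedigree()].
#' @param cfg the same [sim_config()].
#' @param fixes if `FALSE`, draw range centers only and return an empty fix
#'   table (sufficient when overlap is taken from the generative closed
#'   form rather than estimated from fixes).
#' @return list with `fixes` (fix table for all study females) and
#'   `centers` (data frame `individual`, `x`, `y` of true range centers).
#' @export
simulate_locations <- function(ped, cfg, fixes = TRUE) {
  stopifnot(inherits(ped, "pedigree_table"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  fem <- ped[!is.na(ped$sex) & ped$sex == "F", , drop = FALSE]
  n <- nrow(fem)
  cx <- numeric(n); cy <- numeric(n)
  names(cx) <- names(cy) <- fem$individual
  for (i in seq_len(n)) {           # pedigree order: mothers precede daughters
    d <- fem$dam[i]
    if (is.na(d) || !(d %in% names(cx))) {
      cx[i] <- stats::runif(1, 0, cfg$study_extent[1])
      cy[i] <- stats::runif(1, 0, cfg$study_extent[2])
    } else {
      cx[i] <- cx[d] + stats::rnorm(1, 0, cfg$dispersal_sd)
      cy[i] <- cy[d] + stats::rnorm(1, 0, cfg$dispersal_sd)
    }
  }
  centers <- data.frame(individual = fem$individual, x = unname(cx),
                        y = unname(cy), stringsAsFactors = FALSE)
  if (!fixes) {
    empty <- data.frame(individual = character(), season = character(),
                        year = integer(), x = numeric(), y = numeric(),
                        stringsAsFactors = FALSE)
    return(list(fixes = empty, centers = centers))
  }
  nf <- cfg$fixes_per_season
  blocks <- vector("list", n * length(cfg$seasons) * cfg$n_years)
  b <- 0L
  for (i in seq_len(n)) {
    for (yr in seq_len(cfg$n_years)) {
      for (s in cfg$seasons) {
        b <- b + 1L
        blocks[[b]] <- data.frame(
          individual = fem$individual[i], season = s, year = yr,
          x = stats::rnorm(nf, cx[i], cfg$range_sd),
          y = stats::rnorm(nf, cy[i], cfg$range_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  fixtab <- do.call(rbind, blocks)
  rownames(fixtab) <- NULL
  list(fixes = as_fixes(fixtab, seasons = cfg$seasons), centers = centers)
}

#' Exact overlap matrix of the generative Gaussian ranges
#'
#' For equal circular Gaussian utilization distributions with common SD
#' `sigma`, Bhattacharyya's affinity has the closed form
#' `exp(-d^2 / (8 sigma^2))` for centers a distance `d` apart. Applied to
#' the true simulated range centers this gives the exact S matrix of the
#' generative model, free of kernel-estimation noise -- the reference
#' against which pipeline-estimated S matrices are validated.
#'
#' @param centers data frame `individual`, `x`, `y`.
#' @param sigma range SD in meters (the generator's `range_sd`).
#' @return An `overlap_matrix` over the individuals in `centers`.
#' @export
true_overlap_matrix <- function(centers, sigma) {
  d2 <- outer(centers$x, centers$x, "-")^2 + outer(centers$y, centers$y, "-")^2
  v <- exp(-d2 / (8 * sigma^2))
  out <- relationship_matrix(centers$individual, v, "S")
  out$psd_adjusted <- FALSE
  out$adjustment_magnitude <- 0
  class(out) <- c("overlap_matrix", class(out))
  out
}

# eigenvalue-based square root draw: works for PSD (possibly singular) G
.mvn_draw <- function(n_draws, G) {
  e <- eigen(G, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(G))
  L %*% matrix(stats::rnorm(nrow(G) * n_draws), nrow(G), n_draws)
}

#' Simulate phenotypes from the animal model
#'
#' Draws `y = mu + a + pe + m_dam + u_year + s + e` with `a ~ N(0, V_A A)`,
#' `s ~ N(0, V_Smatrix S)` (or an AR1xAR1 field on the occupied lattice when
#' `cfg$sac` is set), and iid permanent-environment, maternal, year and
#' residual effects. Repeated designs emit one record per female-year;
#' single-measure designs one record per female with `year` set to her birth
#' cohort.
#'
#' @param ped `pedigree_table`.
#' @param A additive relationship matrix covering the pedigree ids.
#' @param S overlap matrix covering the study females (ignored when
#'   `cfg$sac` is set), or `NULL` when `V_Smatrix = 0`.
#' @param cfg the [sim_config()].
#' @param centers true range centers (required for `cfg$sac`).
#' @return list with `phenotypes` (data frame `individual`, `dam`, `year`,
#'   `cohort`, `age`, `y`) and `truth` (realized random-effect vectors and
#'   the true variance components).
#' @export
simulate_phenotypes <- function(ped, A, S = NULL, cfg, centers = NULL) {
  stopifnot(inherits(ped, "pedigree_table"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  comp <- cfg$true_components
  fem <- ped[!is.na(ped$sex) & ped$sex == "F", , drop = FALSE]
  ids <- fem$individual
  n <- length(ids)

  a <- stats::setNames(numeric(n), ids)
  if (comp["V_A"] > 0) {
    Af <- align_matrix(A, ids)
    a[] <- drop(.mvn_draw(1, comp["V_A"] * Af$values))
  }
  pe <- stats::rnorm(n, 0, sqrt(comp["V_PE"]))
  names(pe) <- ids
  dams <- unique(stats::na.omit(fem$dam))
  m_eff <- stats::setNames(stats::rnorm(length(dams), 0, sqrt(comp["V_M"])),
                           dams)
  m_of <- function(d) ifelse(is.na(d), stats::rnorm(length(d), 0,
                                                    sqrt(comp["V_M"])),
                             m_eff[d])

  s_eff <- stats::setNames(numeric(n), ids)
  spatial_var <- comp["V_Smatrix"]
  if (!is.null(cfg$sac)) {
    if (is.null(centers)) stop("centers required for an AR1xAR1 field")
    idx <- grid_coordinates(centers,
                            origin = c(min(centers$x), min(centers$y)))
    G <- ar1xar1_covariance(idx, sac_parameters(cfg$sac$phi_row,
                                                cfg$sac$phi_col,
                                                cfg$sac$variance))
    field <- drop(.mvn_draw(1, G))
    s_eff[idx$ids] <- field[idx$cell_of]
    spatial_var <- cfg$sac$variance
  } else if (spatial_var > 0) {
    if (is.null(S)) stop("V_Smatrix > 0 but no S matrix supplied")
    Sf <- align_matrix(S, ids)
    if (min(eigen(Sf$values, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-6)
      stop("S matrix is not positive semi-definite; apply PSD repair first")
    s_eff[] <- drop(.mvn_draw(1, spatial_var * Sf$values))
  }

  years <- if (cfg$trait_design == "repeated") seq_len(cfg$n_years) else NA
  recs <- list()
  for (i in seq_len(n)) {
    yrs <- if (cfg$trait_design == "repeated") years else fem$cohort[i]
    recs[[i]] <- data.frame(individual = ids[i], dam = fem$dam[i],
                            year = yrs, cohort = fem$cohort[i],
                            stringsAsFactors = FALSE)
  }
  ph <- do.call(rbind, recs)
  rownames(ph) <- NULL
  u_years <- sort(unique(ph$year))
  u_eff <- stats::setNames(stats::rnorm(length(u_years), 0,
                                        sqrt(comp["V_Year"])),
                           as.character(u_years))
  e <- stats::rnorm(nrow(ph), 0, sqrt(comp["V_Residual"]))
  mi <- match(ph$individual, ids)
  latent <- cfg$mu + a[mi] + pe[mi] + m_of(ph$dam) +
    u_eff[as.character(ph$year)] + s_eff[mi] + e
  ph$age <- ph$year - ph$cohort + cfg$n_generations
  ph$y <- if (cfg$log_scale) exp(latent) else latent
  list(phenotypes = ph,
       truth = list(components = comp, spatial_variance = unname(spatial_var),
                    a = a, pe = pe, maternal = m_eff, year = u_eff,
                    spatial = s_eff, mu = cfg$mu))
}

#' Simulate a complete analysis-ready dataset
#'
#' Runs the pedigree, location and phenotype generators and assembles the
#' matrices the models need: the A matrix from the pedigree, the S matrix
#' either as the exact overlap of the generative Gaussian ranges
#' (`s_matrix = "true"`) or estimated through the full kernel home-range
#' pipeline (`s_matrix = "estimated"`), and the 100-m lattice index of mean
#' locations.
#'
#' @param cfg a [sim_config()].
#' @param s_matrix `"true"`, `"estimated"`, or `"none"`.
#' @param cell_size KDE grid cell (meters) for the estimated pipeline.
#' @param fixes generate census fixes; defaults to `TRUE` only when the
#'   estimated-overlap pipeline needs them. Without fixes the lattice index
#'   is built from the true range centers.
#' @return list with `pedigree`, `fixes`, `centers`, `phenotypes`, `truth`,
#'   `A`, `S`, `lattice`, `exclusions`.
#' @export
simulate_dataset <- function(cfg, s_matrix = c("true", "estimated", "none"),
                             cell_size = 50,
                             fixes = (s_matrix == "estimated")) {
  s_matrix <- match.arg(s_matrix)
  force(fixes)
  ped <- simulate_pedigree(cfg)
  loc <- simulate_locations(ped, cfg, fixes = fixes)
  A <- additive_relationship(ped)
  excl <- NULL
  S <- NULL
  if (s_matrix == "true") {
    S <- true_overlap_matrix(loc$centers, cfg$range_sd)
  } else if (s_matrix == "estimated") {
    est <- estimate_uds(loc$fixes, by = "individual", cell = cell_size)
    excl <- est$exclusions
    S <- build_s_matrix(est$uds,
                        all_ids = unique(loc$fixes$individual),
                        psd = "clip")
  }
  ml <- if (nrow(loc$fixes)) mean_locations(loc$fixes) else
    loc$centers[order(loc$centers$individual), , drop = FALSE]
  idx <- grid_coordinates(ml, origin = c(min(ml$x), min(ml$y)))
  phen <- simulate_phenotypes(ped, A, S, cfg, centers = loc$centers)
  list(pedigree = ped, fixes = loc$fixes, centers = loc$centers,
       phenotypes = phen$phenotypes, truth = phen$truth,
       A = A, S = S, lattice = idx, exclusions = excl)
}

#' Named simulation presets
#'
#' Illustrative variance mixes for the four focal trait types: repeated
#' range sizes in the two seasons (`rhr`, `shr`, log-scale, spatial variance
#' dominant), a repeated maternal trait (`bw`, weak spatial variance), and a
#' single-measure fitness trait (`lbs`, log-scale, strong cohort and spatial
#' variance). The mixes echo the qualitative pattern of spatially
#' confounded field traits and are not estimates from any real population.
#'
#' @param name one of `"rhr"`, `"shr"`, `"bw"`, `"lbs"`.
#' @param seed master seed.
#' @param ... overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
preset_config <- function(name = c("rhr", "shr", "bw", "lbs"), seed = 1L,
                          ...) {
  name <- match.arg(name)
  base <- switch(name,
    rhr = list(true_components = c(V_A = 0.10, V_PE = 0.02, V_M = 0.06,
                                   V_Year = 0.02, V_Smatrix = 0.45,
                                   V_Residual = 0.35),
               log_scale = TRUE, trait_design = "repeated", mu = 2),
    shr = list(true_components = c(V_A = 0.15, V_PE = 0.02, V_M = 0.02,
                                   V_Year = 0.02, V_Smatrix = 0.50,
                                   V_Residual = 0.29),
               log_scale = TRUE, trait_design = "repeated", mu = 2),
    bw = list(true_components = c(V_A = 0.25, V_PE = 0.05, V_M = 0.08,
                                  V_Year = 0.06, V_Smatrix = 0.06,
                                  V_Residual = 0.50),
              log_scale = FALSE, trait_design = "repeated", mu = 7),
    lbs = list(true_components = c(V_A = 0.05, V_M = 0.05, V_Year = 0.15,
                                   V_Smatrix = 0.30, V_Residual = 0.45),
               log_scale = TRUE, trait_design = "single_measure", mu = 1.5))
  do.call(sim_config, utils::modifyList(c(list(seed = seed), base),
                                        list(...)))
}
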