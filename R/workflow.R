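# Orchestration: fit one trait across spatial variants and render the
# comparative variance-component report.

#' Configure a trait analysis
#'
#' @param trait response column name.
#' @param log_transform log the response before fitting.
#' @param fixed one-sided formula of fixed effects.
#' @param base_terms which non-spatial random effects to include, in
#'   build-up order; `"permanent_environment"` is normally dropped for
#'   single-measure traits.
#' @param spatial_variants subset of `"none"`, `"column"`, `"row"`,
#'   `"column_and_row"`, `"smatrix"`; `"none"` is always included.
#' @param baseline_for_sumv variant anchoring the total-variance
#'   credibility check.
#' @param credibility_factor flag threshold on Sum V ratios.
#' @param phi_bounds search interval for AR1 correlations.
#' @param reml_options options passed to [reml_fit()].
#' @return A `trait_analysis_config`.
#' @export
trait_analysis_config <- function(trait, log_transform = FALSE,
                                  fixed = ~1,
                                  base_terms = c("permanent_environment",
                                                 "animal", "year",
                                                 "maternal"),
                                  spatial_variants = c("none", "smatrix"),
                                  baseline_for_sumv = "none",
                                  credibility_factor = 3,
                                  phi_bounds = c(0, 0.999),
                                  reml_options = list()) {
  spatial_variants <- unique(c("none", spatial_variants))
  ok <- c("none", "column", "row", "column_and_row", "smatrix")
  if (!all(spatial_variants %in% ok))
    stop("unknown spatial variant(s): ",
         paste(setdiff(spatial_variants, ok), collapse = ", "))
  base_terms <- match.arg(base_terms,
                          c("permanent_environment", "animal", "year",
                            "maternal"), several.ok = TRUE)
  structure(list(trait = trait, log_transform = log_transform, fixed = fixed,
                 base_terms = base_terms, spatial_variants = spatial_variants,
                 baseline_for_sumv = baseline_for_sumv,
                 credibility_factor = credibility_factor,
                 phi_bounds = phi_bounds, reml_options = reml_options),
            class = "trait_analysis_config")
}

#' Default fixed-effect sets for the four archetypal traits
#'
#' The covariate sets conventionally retained for each trait type: rut
#' range size (age, region, local population size, number of fixes), spring
#' range size (adds a quadratic age term and reproductive status, drops fix
#' count), offspring birth weight (age, age squared, status, region,
#' offspring sex), and lifetime breeding success (region only). For birth
#' weight under spatial-autocorrelation variants, `sac = TRUE` drops the
#' region term, which is confounded with the lattice process and causes
#' singular fits; pass `sac = FALSE` to keep it.
#'
#' @param trait one of `"rhr"`, `"shr"`, `"bw"`, `"lbs"`.
#' @param sac whether the model will include an AR1xAR1 term.
#' @return A one-sided formula usable as `trait_analysis_config(fixed =)`.
#' @export
trait_fixed_defaults <- function(trait = c("rhr", "shr", "bw", "lbs"),
                                 sac = FALSE) {
  trait <- match.arg(trait)
  f <- switch(trait,
    rhr = ~ age + region + local_population_size + n_fixes,
    shr = ~ age + I(age^2) + local_population_size + region + status,
    bw = if (sac) ~ age + I(age^2) + status + offspring_sex
         else ~ age + I(age^2) + status + region + offspring_sex,
    lbs = ~ region)
  f
}

#' Load a trait analysis configuration from YAML
#'
#' Recognized keys: `trait`, `log_transform`, `fixed` (a formula string such
#' as `"~ age + region"`), `base_terms`, `spatial_variants`,
#' `baseline_for_sumv`, `credibility_factor`, `phi_bounds`.
#'
#' @param path YAML file path.
#' @return A [trait_analysis_config()].
#' @export
read_trait_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$fixed)) y$fixed <- stats::as.formula(y$fixed)
  if (!is.null(y$phi_bounds)) y$phi_bounds <- as.numeric(y$phi_bounds)
  do.call(trait_analysis_config, y)
}

.variant_terms <- function(variant, base, A, S, lattice, phi_bounds) {
  terms <- list()
  for (b in base) {
    terms[[b]] <- switch(b,
      permanent_environment = pe_term(),
      animal = animal_term(A),
      year = year_term(),
      maternal = maternal_term())
  }
  spatial <- switch(variant,
    none = NULL,
    column = sac_term(lattice, axes = "col", phi_bounds = phi_bounds),
    row = sac_term(lattice, axes = "row", phi_bounds = phi_bounds),
    column_and_row = sac_term(lattice, axes = c("row", "col"),
                              phi_bounds = phi_bounds),
    smatrix = smatrix_term(S))
  if (!is.null(spatial)) terms$spatial <- spatial
  unname(terms)
}

#' Run the three-stage analysis of one trait
#'
#' Fits the base random-effect model (the no-spatial variant), then each
#' requested spatial variant (single-axis or separable AR1xAR1
#' autocorrelation, or the home-range overlap matrix), and assembles
#' likelihood-ratio tests against the base model, an AIC ranking over the
#' converged fits, variance partitions, and credibility flags for variants
#' whose total variance departs from the baseline's.
#'
#' @param cfg a [trait_analysis_config()].
#' @param data list with `phenotypes` (data frame), `A`
#'   (relationship matrix), `S` (overlap matrix, when the smatrix variant is
#'   requested), and `lattice` (a `lattice_index`, when any SAC variant is
#'   requested). Matrices must cover the phenotyped individuals.
#' @return A `comparison_report`: per-variant `fits` and `partitions`,
#'   `lrt` table, `aic` table, `sum_v` per variant, and a structured `log`
#'   of non-convergence, bound hits and credibility flags.
#' @export
run_trait_analysis <- function(cfg, data) {
  stopifnot(inherits(cfg, "trait_analysis_config"))
  need_s <- "smatrix" %in% cfg$spatial_variants
  need_lat <- any(c("column", "row", "column_and_row") %in%
                  cfg$spatial_variants)
  if (need_s && is.null(data$S)) stop("smatrix variant requested but no S")
  if (need_lat && is.null(data$lattice))
    stop("SAC variant requested but no lattice index")

  fits <- list(); parts <- list(); logs <- list()
  for (v in cfg$spatial_variants) {
    spec <- model_spec(cfg$trait, fixed = cfg$fixed,
                       random = .variant_terms(v, cfg$base_terms, data$A,
                                               data$S, data$lattice,
                                               cfg$phi_bounds),
                       log_transform = cfg$log_transform)
    fit <- reml_fit(spec, data$phenotypes, options = cfg$reml_options)
    fits[[v]] <- fit
    if (!fit$converged)
      logs[[length(logs) + 1L]] <- data.frame(
        variant = v, event = "non_convergence", detail = "")
    for (i in which(fit$variance_estimates$bound))
      logs[[length(logs) + 1L]] <- data.frame(
        variant = v, event = "variance_bound_at_0",
        detail = fit$variance_estimates$symbol[i])
    for (i in which(fit$phi_estimates$bound))
      logs[[length(logs) + 1L]] <- data.frame(
        variant = v, event = "phi_at_bound",
        detail = paste0(fit$phi_estimates$symbol[i], ":",
                        fit$phi_estimates$parameter[i]))
  }

  base_fit <- fits[[cfg$baseline_for_sumv]]
  baseline_sum_v <- if (!is.null(base_fit) && base_fit$converged)
    sum(base_fit$variance_estimates$estimate) else NULL
  for (v in names(fits)) {
    if (!fits[[v]]$converged) next
    parts[[v]] <- partition(fits[[v]], baseline_sum_v = baseline_sum_v,
                            credibility_factor = cfg$credibility_factor)
    if (parts[[v]]$credibility_flag)
      logs[[length(logs) + 1L]] <- data.frame(
        variant = v, event = "sum_v_not_credible",
        detail = sprintf("sum_v=%.4g baseline=%.4g", parts[[v]]$sum_v,
                         baseline_sum_v))
  }

  lrts <- list()
  for (v in setdiff(names(fits), "none")) {
    if (fits[[v]]$converged && fits[["none"]]$converged) {
      t <- lrt(fits[["none"]], fits[[v]])
      lrts[[v]] <- data.frame(variant = v, chi2 = t$chi2, df = t$df,
                              p = t$p, stringsAsFactors = FALSE)
    }
  }
  lrt_table <- if (length(lrts)) do.call(rbind, lrts) else
    data.frame(variant = character(), chi2 = numeric(), df = integer(),
               p = numeric())
  rownames(lrt_table) <- NULL

  conv <- fits[vapply(fits, `[[`, TRUE, "converged")]
  aics <- if (length(conv) > 1) aic_table(conv) else
    data.frame(model = names(conv),
               aic = vapply(conv, aic, 0), n_parameters =
                 vapply(conv, `[[`, 0L, "n_parameters"))
  rownames(aics) <- NULL

  structure(list(trait = cfg$trait, config = cfg, fits = fits,
                 partitions = parts, lrt = lrt_table, aic = aics,
                 sum_v = vapply(parts, `[[`, 0, "sum_v"),
                 log = if (length(logs)) do.call(rbind, logs) else
                   data.frame(variant = character(), event = character(),
                              detail = character())),
            class = "comparison_report")
}

# deterministic number formatting for reports
.fmt <- function(x, d = 3) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = d))
}

#' Render a comparison report
#'
#' Produces the standard comparative layout: one Var./Prop. column pair per
#' variant, a row per variance component with standard errors in brackets,
#' the AR1 correlation (phi) rows, the total variance (Sum V) row and
#' heritability in percent. Estimates at a boundary are marked with `*`.
#' Output is byte-stable for identical inputs.
#'
#' @param report a `comparison_report`.
#' @param format `"text"` for the aligned table, `"csv"` for a tidy
#'   long-format table.
#' @param path optional output file; when omitted the lines are returned.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
render_report <- function(report, format = c("text", "csv"), path = NULL) {
  format <- match.arg(format)
  variants <- names(report$fits)
  symbols <- unique(unlist(lapply(report$fits, function(f)
    f$variance_estimates$symbol)))
  symbols <- c(setdiff(symbols, "V_Residual"), "V_Residual")

  if (format == "csv") {
    rows <- list()
    for (v in variants) {
      f <- report$fits[[v]]
      ve <- f$variance_estimates
      pr <- report$partitions[[v]]
      for (i in seq_len(nrow(ve))) {
        j <- if (!is.null(pr)) match(ve$symbol[i], pr$proportions$symbol)
             else NA
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v, component = ve$symbol[i], variance = ve$estimate[i],
          variance_se = ve$se[i],
          proportion = if (!is.na(j)) pr$proportions$proportion[j] else NA,
          proportion_se = if (!is.na(j)) pr$proportions$se[j] else NA,
          bound = ve$bound[i], converged = f$converged,
          stringsAsFactors = FALSE)
      }
      pe <- f$phi_estimates
      for (i in seq_len(nrow(pe)))
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v, component = paste0(pe$parameter[i]),
          variance = pe$estimate[i], variance_se = pe$se[i],
          proportion = NA, proportion_se = NA, bound = pe$bound[i],
          converged = f$converged, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, component = "Sum_V",
        variance = if (!is.null(pr)) pr$sum_v else NA, variance_se = NA,
        proportion = NA, proportion_se = NA, bound = FALSE,
        converged = f$converged, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, component = "h2_percent",
        variance = if (!is.null(pr)) pr$h2 else NA,
        variance_se = if (!is.null(pr)) pr$h2_se else NA,
        proportion = NA, proportion_se = NA, bound = FALSE,
        converged = f$converged, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    lines <- c(paste(names(tab), collapse = ","),
               apply(tab, 1, function(r) paste(trimws(r), collapse = ",")))
  } else {
    cell <- function(est, se, bound)
      ifelse(is.na(est), "", paste0(.fmt(est), " (", .fmt(se), ")",
                                    ifelse(bound, "*", " ")))
    header <- c(sprintf("Trait: %s", report$trait),
                paste(c(sprintf("%-16s", ""),
                        sprintf("%-28s", variants)), collapse = ""))
    sub <- paste(c(sprintf("%-16s", ""),
                   sprintf("%-14s%-14s", rep("Var.", length(variants)),
                           rep("Prop.", length(variants)))), collapse = "")
    body <- character(0)
    for (s in symbols) {
      cells <- character(0)
      for (v in variants) {
        f <- report$fits[[v]]
        ve <- f$variance_estimates
        i <- match(s, ve$symbol)
        pr <- report$partitions[[v]]
        j <- if (!is.null(pr)) match(s, pr$proportions$symbol) else NA
        cells <- c(cells,
                   sprintf("%-14s", if (is.na(i)) "" else
                     cell(ve$estimate[i], ve$se[i], ve$bound[i])),
                   sprintf("%-14s", if (is.na(j) || is.null(pr)) "" else
                     cell(pr$proportions$proportion[j], pr$proportions$se[j],
                          ve$bound[i])))
      }
      body <- c(body, paste(c(sprintf("%-16s", s), cells), collapse = ""))
    }
    for (pn in c("phi_col", "phi_row")) {
      lab <- if (pn == "phi_col") "Column phi" else "Row phi"
      cells <- character(0)
      any_row <- FALSE
      for (v in variants) {
        pe <- report$fits[[v]]$phi_estimates
        i <- which(pe$parameter == pn)
        if (length(i)) any_row <- TRUE
        cells <- c(cells, sprintf("%-28s", if (!length(i)) "" else
          cell(pe$estimate[i], pe$se[i], pe$bound[i])))
      }
      if (any_row)
        body <- c(body, paste(c(sprintf("%-16s", lab), cells), collapse = ""))
    }
    sumv <- vapply(variants, function(v)
      if (!is.null(report$partitions[[v]]))
        .fmt(report$partitions[[v]]$sum_v) else "", "")
    h2 <- vapply(variants, function(v)
      if (!is.null(report$partitions[[v]]))
        .fmt(report$partitions[[v]]$h2, 2) else "", "")
    body <- c(body,
              paste(c(sprintf("%-16s", "Sum V"), sprintf("%-28s", sumv)),
                    collapse = ""),
              paste(c(sprintf("%-16s", "h2 (%)"), sprintf("%-28s", h2)),
                    collapse = ""),
              "", "* estimate at a boundary")
    if (nrow(report$log)) {
      body <- c(body, "", "Run log:",
                sprintf("  [%s] %s %s", report$log$variant,
                        report$log$event, report$log$detail))
    }
    lines <- c(header, sub, body)
  }
  lines <- sub("[ ]+$", "", lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}
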