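# REML estimation for animal models with arbitrary per-term covariance
# structures, and the downstream inference layer (LRT, Wald, AIC,
# variance partitioning).

#' Declare one random effect and its covariance structure
#'
#' A random term maps observations to levels of a grouping column and gives
#' the levels a covariance: identity (iid levels), a relationship or overlap
#' matrix, or a separable AR1xAR1 lattice process.
#'
#' @param group name of the data column holding the level of each
#'   observation.
#' @param covariance `NULL` for identity, a `relationship_matrix` /
#'   `overlap_matrix`, or a `lattice_index` wrapped by [sac_term()].
#' @param label term label (permanent_environment, animal, year, maternal,
#'   sac, smatrix, or custom).
#' @param symbol name of the variance component the term estimates (used in
#'   reports, e.g. `"V_A"`).
#' @return A `random_term` object.
#' @export
random_term <- function(group, covariance = NULL, label = "custom",
                        symbol = paste0("V_", label)) {
  structure(list(group = group, covariance = covariance, label = label,
                 symbol = symbol), class = "random_term")
}

#' @rdname random_term
#' @export
pe_term <- function(group = "individual")
  random_term(group, NULL, "permanent_environment", "V_PE")

#' @rdname random_term
#' @param A additive relationship matrix from [additive_relationship()].
#' @export
animal_term <- function(A, group = "individual") {
  stopifnot(inherits(A, "relationship_matrix"))
  random_term(group, A, "animal", "V_A")
}

#' @rdname random_term
#' @export
year_term <- function(group = "year") random_term(group, NULL, "year", "V_Year")

#' @rdname random_term
#' @export
maternal_term <- function(group = "dam")
  random_term(group, NULL, "maternal", "V_M")

#' @rdname random_term
#' @param S overlap matrix from [build_s_matrix()].
#' @export
smatrix_term <- function(S, group = "individual") {
  stopifnot(inherits(S, "relationship_matrix"))
  random_term(group, S, "smatrix", "V_Smatrix")
}

#' Separable AR1xAR1 spatial autocorrelation term
#'
#' Fits a spatial random effect indexed by occupied 100-m grid cells with
#' correlation `phi_row^|dr| * phi_col^|dc|` between cells. Restricting
#' `axes` to `"col"` or `"row"` fixes the other correlation at zero,
#' giving single-axis (column- or row-process) models.
#'
#' @param index a `lattice_index` mapping individuals to cells.
#' @param axes which autoregressive correlations to estimate.
#' @param phi_bounds search interval for each phi; extend the lower bound
#'   to negative values to represent competitive (negative) autocorrelation.
#' @param group data column naming the individual.
#' @return A `random_term` of label `"sac"`.
#' @export
sac_term <- function(index, axes = c("row", "col"), phi_bounds = c(0, 0.999),
                     group = "individual") {
  stopifnot(inherits(index, "lattice_index"))
  axes <- match.arg(axes, c("row", "col"), several.ok = TRUE)
  symbol <- if (length(axes) == 2) "V_Columnandrow"
            else if (axes == "col") "V_Column" else "V_Row"
  t <- random_term(group, NULL, "sac", symbol)
  t$index <- index
  t$axes <- axes
  t$phi_bounds <- phi_bounds
  t
}

#' Specify a mixed model
#'
#' @param response name of the trait column.
#' @param fixed one-sided formula of fixed effects (e.g.
#'   `~ age + I(age^2) + status`); categorical covariates are
#'   reference-coded against their first (sorted) level.
#' @param random list of [random_term()] objects, in build-up order.
#' @param log_transform log the response before fitting (traits with
#'   right-skewed residuals such as range sizes and breeding success).
#' @return A `model_spec` object.
#' @export
model_spec <- function(response, fixed = ~1, random = list(),
                       log_transform = FALSE) {
  stopifnot(is.character(response), inherits(fixed, "formula"))
  if (!all(vapply(random, inherits, TRUE, "random_term")))
    stop("random must be a list of random_term objects")
  structure(list(response = response, fixed = fixed, random = random,
                 log_transform = log_transform, residual_symbol = "V_Residual"),
            class = "model_spec")
}

#' Build the numerical design bundle for a model
#'
#' Applies listwise deletion of observations with missing response,
#' covariates, or random-effect levels (with a logged count), builds the
#' fixed-effect design matrix with reference coding, checks its rank, and
#' materializes each random term's incidence matrix and covariance factory.
#'
#' @param spec a [model_spec()].
#' @param data phenotype data frame.
#' @return A `design_bundle` list: `y`, `X`, `terms` (per random term:
#'   incidence `Z`, fixed `M = Z G Z'` or AR1xAR1 distance structures),
#'   `n_dropped`, and bookkeeping used by [reml_fit()].
#' @export
build_design <- function(spec, data) {
  vars <- all.vars(spec$fixed)
  miss <- setdiff(c(spec$response, vars), names(data))
  if (length(miss)) stop("column(s) not in data: ", paste(miss, collapse = ", "))
  for (v in c(spec$response, vars))
    if (all(is.na(data[[v]]))) stop("covariate entirely missing: ", v)
  groups <- unique(vapply(spec$random, `[[`, "", "group"))
  gm <- setdiff(groups, names(data))
  if (length(gm)) stop("random-effect column(s) not in data: ",
                       paste(gm, collapse = ", "))

  keep <- !is.na(data[[spec$response]])
  for (v in vars) keep <- keep & !is.na(data[[v]])
  for (g in groups) keep <- keep & !is.na(data[[g]])
  n_dropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  if (!nrow(d)) stop("no observations left after removing missing data")

  y <- d[[spec$response]]
  if (spec$log_transform) {
    if (any(y <= 0)) stop("log transform requires a positive response")
    y <- log(y)
  }
  # sorted-first-level reference coding, deterministic column order
  for (v in vars)
    if (is.character(d[[v]]) || is.factor(d[[v]]))
      d[[v]] <- factor(as.character(d[[v]]), levels = sort(unique(as.character(d[[v]]))))
  X <- stats::model.matrix(spec$fixed, d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  n <- nrow(d)
  terms <- lapply(spec$random, function(t) {
    g <- as.character(d[[t$group]])
    if (t$label == "sac") {
      pos <- match(g, t$index$ids)
      if (anyNA(pos))
        stop("individual(s) missing from lattice index: ",
             paste(unique(g[is.na(pos)]), collapse = ", "))
      cells_used <- sort(unique(t$index$cell_of[pos]))
      Z <- matrix(0, n, length(cells_used))
      Z[cbind(seq_len(n), match(t$index$cell_of[pos], cells_used))] <- 1
      occ <- t$index$occupied_cells[cells_used, , drop = FALSE]
      list(label = t$label, symbol = t$symbol, kind = "sac", Z = Z,
           rowd = abs(outer(occ$row, occ$row, "-")),
           cold = abs(outer(occ$col, occ$col, "-")),
           axes = t$axes, phi_bounds = t$phi_bounds)
    } else {
      if (is.null(t$covariance)) {
        lev <- sort(unique(g))
        G <- diag(1, length(lev))
      } else {
        lev <- sort(unique(g))
        absent <- setdiff(lev, t$covariance$ids)
        if (length(absent))
          stop("level(s) of '", t$group, "' missing from ", t$covariance$kind,
               " matrix: ", paste(absent, collapse = ", "))
        G <- t$covariance$values[lev, lev, drop = FALSE]
      }
      Z <- matrix(0, n, length(lev))
      Z[cbind(seq_len(n), match(g, lev))] <- 1
      list(label = t$label, symbol = t$symbol, kind = "fixedcov",
           Z = Z, M = Z %*% G %*% t(Z))
    }
  })

  # duplicate (aliased) random structures are legal but non-identifiable
  fixedcov <- which(vapply(terms, `[[`, "", "kind") == "fixedcov")
  if (length(fixedcov) > 1) {
    for (a in seq_along(fixedcov)[-1]) {
      for (b in seq_len(a - 1)) {
        if (isTRUE(all.equal(terms[[fixedcov[a]]]$M, terms[[fixedcov[b]]]$M,
                             tolerance = 1e-12)))
          warning("random terms '", terms[[fixedcov[a]]]$symbol, "' and '",
                  terms[[fixedcov[b]]]$symbol, "' have identical covariance ",
                  "structures and are not separately identifiable")
      }
    }
  }

  structure(list(y = y, X = X, terms = terms, data = d,
                 n = n, n_dropped = n_dropped,
                 assign = attr(X, "assign"),
                 term_labels = attr(stats::terms(spec$fixed), "term.labels")),
            class = "design_bundle")
}

# Shared likelihood machinery -------------------------------------------

# Evaluate the restricted log-likelihood and its gradient at
# theta (variances, incl. residual last) and phi (per sac term).
# Returns list(loglik, grad_theta, grad_phi, Py, P, beta, beta_cov).
.reml_eval <- function(des, theta, phis, want_grad = TRUE) {
  n <- des$n
  K <- length(des$terms)
  dV <- vector("list", K)       # dV/dtheta_k
  V <- diag(theta[K + 1], n)
  pi <- 1L
  for (k in seq_len(K)) {
    t <- des$terms[[k]]
    if (t$kind == "fixedcov") {
      dV[[k]] <- t$M
    } else {
      pr <- if ("row" %in% t$axes) phis[[k]][["phi_row"]] else 0
      pc <- if ("col" %in% t$axes) phis[[k]][["phi_col"]] else 0
      G <- (pr^t$rowd) * (pc^t$cold)
      dV[[k]] <- t$Z %*% G %*% t(t$Z)
    }
    V <- V + theta[k] * dV[[k]]
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  W <- Vi %*% des$X
  XtViX <- crossprod(des$X, W)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(NULL)
  logdetX <- 2 * sum(log(diag(chx)))
  beta_cov <- chol2inv(chx)
  Wty <- crossprod(W, des$y)
  beta <- beta_cov %*% Wty
  P <- Vi - W %*% beta_cov %*% t(W)
  Py <- P %*% des$y
  yPy <- sum(des$y * Py)
  ll <- -0.5 * (logdetV + logdetX + yPy)
  out <- list(loglik = ll, P = P, Py = Py,
              beta = drop(beta), beta_cov = beta_cov)
  if (want_grad) {
    gt <- numeric(K + 1)
    for (k in seq_len(K))
      gt[k] <- -0.5 * (sum(P * dV[[k]]) - sum(Py * (dV[[k]] %*% Py)))
    gt[K + 1] <- -0.5 * (sum(diag(P)) - sum(Py * Py))
    gp <- vector("list", K)
    for (k in seq_len(K)) {
      t <- des$terms[[k]]
      if (t$kind != "sac") next
      pr <- if ("row" %in% t$axes) phis[[k]][["phi_row"]] else 0
      pc <- if ("col" %in% t$axes) phis[[k]][["phi_col"]] else 0
      g <- c()
      if ("row" %in% t$axes) {
        dG <- ifelse(t$rowd == 0, 0, t$rowd * pr^pmax(t$rowd - 1, 0)) *
          (pc^t$cold)
        dVp <- theta[k] * (t$Z %*% dG %*% t(t$Z))
        g <- c(g, phi_row = -0.5 * (sum(P * dVp) - sum(Py * (dVp %*% Py))))
      }
      if ("col" %in% t$axes) {
        dG <- (pr^t$rowd) *
          ifelse(t$cold == 0, 0, t$cold * pc^pmax(t$cold - 1, 0))
        dVp <- theta[k] * (t$Z %*% dG %*% t(t$Z))
        g <- c(g, phi_col = -0.5 * (sum(P * dVp) - sum(Py * (dVp %*% Py))))
      }
      gp[[k]] <- g
    }
    out$grad_theta <- gt
    out$grad_phi <- gp
  }
  out
}

# Average-information matrix over all free parameters at (theta, phis);
# param list gives, per parameter, the matrix dV/dpar.
.reml_ai <- function(des, theta, phis, ev) {
  K <- length(des$terms)
  dVs <- list()
  nms <- character(0)
  for (k in seq_len(K)) {
    t <- des$terms[[k]]
    if (t$kind == "fixedcov") {
      dVs <- c(dVs, list(t$M)); nms <- c(nms, t$symbol)
    } else {
      pr <- if ("row" %in% t$axes) phis[[k]][["phi_row"]] else 0
      pc <- if ("col" %in% t$axes) phis[[k]][["phi_col"]] else 0
      G <- (pr^t$rowd) * (pc^t$cold)
      dVs <- c(dVs, list(t$Z %*% G %*% t(t$Z))); nms <- c(nms, t$symbol)
      if ("row" %in% t$axes) {
        dG <- ifelse(t$rowd == 0, 0, t$rowd * pr^pmax(t$rowd - 1, 0)) * (pc^t$cold)
        dVs <- c(dVs, list(theta[k] * (t$Z %*% dG %*% t(t$Z))))
        nms <- c(nms, paste0(t$symbol, ":phi_row"))
      }
      if ("col" %in% t$axes) {
        dG <- (pr^t$rowd) * ifelse(t$cold == 0, 0, t$cold * pc^pmax(t$cold - 1, 0))
        dVs <- c(dVs, list(theta[k] * (t$Z %*% dG %*% t(t$Z))))
        nms <- c(nms, paste0(t$symbol, ":phi_col"))
      }
    }
  }
  dVs <- c(dVs, list(diag(1, des$n))); nms <- c(nms, "V_Residual")
  q <- length(dVs)
  u <- lapply(dVs, function(M) M %*% ev$Py)
  AI <- matrix(0, q, q, dimnames = list(nms, nms))
  for (a in seq_len(q)) {
    Pu <- ev$P %*% u[[a]]
    for (b in a:q) AI[a, b] <- AI[b, a] <- 0.5 * sum(u[[b]] * Pu)
  }
  AI
}

#' Fit a mixed model by restricted maximum likelihood
#'
#' Maximizes the restricted log-likelihood
#' `l_R = -1/2 (log|V| + log|X' V^-1 X| + y' P y)` with
#' `V = sum_k theta_k Z_k G_k Z_k' + theta_e I` over the variance components
#' (log scale internally, so estimates are bound at zero externally) and any
#' AR1 correlation parameters (scaled-logit internally), using a bounded
#' quasi-Newton optimizer with analytic gradients and seeded random
#' restarts. Standard errors come from the inverse average-information
#' matrix at the optimum.
#'
#' @param spec a [model_spec()].
#' @param data phenotype data frame.
#' @param options list; recognized entries `tolerance` (relative convergence
#'   factor, default 1e-10), `max_iter` (default 200), `n_starts` (default
#'   3: one moment-based start plus random restarts), `seed_for_starts`
#'   (default 1), `bound_tol` (variance-at-zero detection threshold as a
#'   fraction of the phenotypic variance, default 1e-6), and `phi_bound_tol`
#'   (default 1e-3).
#' @return A `reml_fit` object: `variance_estimates` and `phi_estimates`
#'   (data frames with estimates, SEs and at-bound flags), `fixed_effects`
#'   (coefficients and their covariance), `restricted_loglik`,
#'   `n_parameters`, `converged`, `iterations`, the accepted-likelihood
#'   `trace`, and the parameter covariance used for delta-method summaries.
#' @export
reml_fit <- function(spec, data, options = list()) {
  opt <- utils::modifyList(list(tolerance = 1e-10, max_iter = 200L,
                                n_starts = 3L, seed_for_starts = 1L,
                                bound_tol = 1e-6, phi_bound_tol = 1e-3),
                           options)
  des <- build_design(spec, data)
  K <- length(des$terms)
  vy <- stats::var(des$y)
  if (!is.finite(vy) || vy <= 0) stop("response has no variance")

  # parameter packing: log-variances (K+1), then scaled-logit phis
  phi_info <- list()   # per sac term: names + bounds
  for (k in seq_len(K)) {
    t <- des$terms[[k]]
    if (t$kind == "sac")
      phi_info[[as.character(k)]] <-
        list(k = k, names = paste0("phi_", t$axes), bounds = t$phi_bounds)
  }
  n_phi <- sum(vapply(phi_info, function(p) length(p$names), 0L))

  unpack <- function(par) {
    theta <- exp(par[seq_len(K + 1)])
    phis <- vector("list", K)
    i <- K + 1L
    for (p in phi_info) {
      lo <- p$bounds[1]; hi <- p$bounds[2]
      v <- numeric(0)
      for (nm in p$names) {
        i <- i + 1L
        s <- 1 / (1 + exp(-par[i]))
        v[nm] <- lo + (hi - lo) * s
      }
      phis[[p$k]] <- v
    }
    list(theta = theta, phis = phis)
  }

  trace_env <- new.env()
  trace_env$ll <- numeric(0)
  cache <- new.env()
  evaluate <- function(par) {
    key <- paste(format(par, digits = 17), collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    up <- unpack(par)
    ev <- .reml_eval(des, up$theta, up$phis, want_grad = TRUE)
    if (is.null(ev)) {
      val <- list(obj = 1e10, grad = rep(0, length(par)))
    } else {
      # chain rule onto the transformed scale
      g <- ev$grad_theta * up$theta
      i <- K + 1L
      for (p in phi_info) {
        lo <- p$bounds[1]; hi <- p$bounds[2]
        for (nm in p$names) {
          i <- i + 1L
          s <- 1 / (1 + exp(-par[i]))
          g <- c(g, ev$grad_phi[[p$k]][[nm]] * (hi - lo) * s * (1 - s))
        }
      }
      trace_env$ll <- c(trace_env$ll, ev$loglik)
      val <- list(obj = -ev$loglik, grad = -g)
    }
    cache$key <- key; cache$val <- val
    val
  }

  lv0 <- log(vy)
  start0 <- c(rep(log(vy * 0.5 / max(K, 1)), K), log(vy * 0.5))
  if (n_phi) start0 <- c(start0, rep(0.5, n_phi))
  lower <- c(rep(lv0 - 25, K + 1), rep(-12, n_phi))
  upper <- c(rep(lv0 + 10, K + 1), rep(12, n_phi))

  starts <- list(start0)
  if (opt$n_starts > 1) {
    # draw restart jitter from a private stream; never disturb the
    # caller's RNG state
    rng_state <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(opt$seed_for_starts)
    for (s in seq_len(opt$n_starts - 1))
      starts[[s + 1]] <- start0 + c(stats::rnorm(K + 1, 0, 1.5),
                                    if (n_phi) stats::rnorm(n_phi, 0, 2))
    if (is.null(rng_state)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", rng_state, envir = globalenv())
    }
  }

  best <- NULL
  total_evals <- 0L
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, fn = function(p) evaluate(p)$obj,
                   gr = function(p) evaluate(p)$grad,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = opt$max_iter,
                                  factr = opt$tolerance / 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    total_evals <- total_evals + fit$counts[1]
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("REML optimization failed from every start; ",
                          "check that every covariance matrix is positive ",
                          "definite (PSD repair of S may be needed)")
  # polish from the best optimum; a line-search failure here just means the
  # incumbent cannot be improved at machine precision
  converged <- best$convergence == 0
  pol <- tryCatch(
    stats::optim(best$par, fn = function(p) evaluate(p)$obj,
                 gr = function(p) evaluate(p)$grad,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = opt$max_iter,
                                factr = opt$tolerance / 1e-15)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value) {
    total_evals <- total_evals + pol$counts[1]
    converged <- converged || pol$convergence == 0
    best <- pol
  }
  # Newton refinement on the natural scale with the average-information
  # matrix: sharpens interior optima to near machine precision (closed-form
  # balanced designs then agree to ~1e-8); parameters at their bounds are
  # frozen
  up <- unpack(best$par)
  theta <- up$theta; phis <- up$phis
  ev <- .reml_eval(des, theta, phis, want_grad = TRUE)
  if (!is.null(ev)) {
    ll_cur <- ev$loglik
    # parameter map in the row order used by .reml_ai
    par_map <- list()
    for (k in seq_len(K)) {
      par_map[[length(par_map) + 1L]] <- list(type = "theta", k = k)
      t <- des$terms[[k]]
      if (t$kind == "sac")
        for (nm in paste0("phi_", t$axes))
          par_map[[length(par_map) + 1L]] <- list(type = "phi", k = k,
                                                  nm = nm)
    }
    par_map[[length(par_map) + 1L]] <- list(type = "theta", k = K + 1L)
    grad_vec <- function(ev) {
      vapply(par_map, function(pm)
        if (pm$type == "theta") ev$grad_theta[pm$k]
        else ev$grad_phi[[pm$k]][[pm$nm]], 0)
    }
    is_free <- function() {
      vapply(par_map, function(pm) {
        if (pm$type == "theta") theta[pm$k] > 1e-7 * vy
        else {
          b <- phi_info[[as.character(pm$k)]]$bounds
          v <- phis[[pm$k]][[pm$nm]]
          v > b[1] + 1e-4 && v < b[2] - 1e-4
        }
      }, TRUE)
    }
    for (it in 1:25) {
      g <- grad_vec(ev)
      free <- which(is_free())
      if (!length(free) || max(abs(g[free])) < 1e-9 * (1 + abs(ll_cur)))
        break
      AI <- .reml_ai(des, theta, phis, ev)
      delta <- tryCatch(solve(AI[free, free, drop = FALSE], g[free]),
                        error = function(e) NULL)
      if (is.null(delta)) break
      step <- 1
      improved <- FALSE
      while (step > 1e-4) {
        ct <- theta; cp <- phis
        ok <- TRUE
        for (a in seq_along(free)) {
          pm <- par_map[[free[a]]]
          if (pm$type == "theta") {
            ct[pm$k] <- theta[pm$k] + step * delta[a]
            if (ct[pm$k] <= 0) ok <- FALSE
          } else {
            b <- phi_info[[as.character(pm$k)]]$bounds
            cp[[pm$k]][[pm$nm]] <- phis[[pm$k]][[pm$nm]] + step * delta[a]
            if (cp[[pm$k]][[pm$nm]] <= b[1] || cp[[pm$k]][[pm$nm]] >= b[2])
              ok <- FALSE
          }
        }
        if (ok) {
          evc <- .reml_eval(des, ct, cp, want_grad = TRUE)
          if (!is.null(evc) && evc$loglik >= ll_cur - 1e-12) {
            theta <- ct; phis <- cp; ev <- evc; ll_cur <- evc$loglik
            improved <- TRUE
            break
          }
        }
        step <- step / 2
      }
      total_evals <- total_evals + 1L
      if (!improved) break
    }
    trace_env$ll <- c(trace_env$ll, ll_cur)
    # repack so downstream reporting sees the refined parameters
    newpar <- pmin(pmax(log(theta), lower[seq_len(K + 1)]),
                   upper[seq_len(K + 1)])
    for (p in phi_info) {
      lo <- p$bounds[1]; hi <- p$bounds[2]
      for (nm in p$names) {
        s <- (phis[[p$k]][[nm]] - lo) / (hi - lo)
        s <- min(max(s, 1e-9), 1 - 1e-9)
        newpar <- c(newpar, log(s / (1 - s)))
      }
    }
    if (-ll_cur <= best$value) {
      best$par <- newpar
      best$value <- -ll_cur
    }
  }

  # optimizer status codes aside, accept a point whose (transformed-scale)
  # gradient is numerically zero away from the box bounds
  proj <- evaluate(best$par)$grad
  proj[best$par <= lower + 1e-8 & proj > 0] <- 0   # pushing below the bound
  proj[best$par >= upper - 1e-8 & proj < 0] <- 0
  converged <- converged || max(abs(proj)) < 1e-3 * (1 + abs(best$value))

  up <- unpack(best$par)
  ev <- .reml_eval(des, up$theta, up$phis, want_grad = FALSE)
  AI <- .reml_ai(des, up$theta, up$phis, ev)
  vc <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, nrow(AI),
                                                       ncol(AI),
                                                       dimnames = dimnames(AI)))
  ses <- sqrt(pmax(diag(vc), 0))

  sym <- c(vapply(des$terms, `[[`, "", "symbol"), "V_Residual")
  theta_names <- sym
  # AI rows: variances interleaved with phis; map by name
  ai_names <- rownames(AI)
  var_se <- ses[match(sym, ai_names)]
  bound0 <- up$theta[seq_len(K + 1)] <= opt$bound_tol * vy
  variance_estimates <- data.frame(symbol = sym,
                                   estimate = up$theta,
                                   se = var_se,
                                   bound = bound0,
                                   stringsAsFactors = FALSE)

  phi_estimates <- data.frame(symbol = character(), parameter = character(),
                              estimate = numeric(), se = numeric(),
                              bound = logical(), stringsAsFactors = FALSE)
  for (p in phi_info) {
    t <- des$terms[[p$k]]
    for (nm in p$names) {
      est <- up$phis[[p$k]][[nm]]
      aboard <- min(abs(est - p$bounds)) <= opt$phi_bound_tol
      phi_estimates <- rbind(phi_estimates, data.frame(
        symbol = t$symbol, parameter = nm, estimate = est,
        se = ses[match(paste0(t$symbol, ":", nm), ai_names)],
        bound = aboard, stringsAsFactors = FALSE))
    }
  }

  beta <- ev$beta
  names(beta) <- colnames(des$X)
  structure(list(
    spec = spec,
    variance_estimates = variance_estimates,
    phi_estimates = phi_estimates,
    fixed_effects = list(coef = beta, vcov = ev$beta_cov,
                         assign = des$assign,
                         term_labels = des$term_labels),
    restricted_loglik = -best$value,
    n_parameters = K + 1L + n_phi,
    converged = converged,
    iterations = as.integer(total_evals),
    trace = cummax(trace_env$ll[is.finite(trace_env$ll)]),
    vcov_theta = vc[match(theta_names, ai_names),
                    match(theta_names, ai_names), drop = FALSE],
    n_obs = des$n,
    n_dropped = des$n_dropped,
    fingerprint = list(n = des$n, sum_y = sum(des$y), ss_y = sum(des$y^2),
                       fixed = deparse(spec$fixed))),
    class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit: %s%s, n = %d obs%s\n", x$spec$response,
              if (x$spec$log_transform) " (log)" else "", x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  v <- x$variance_estimates
  for (i in seq_len(nrow(v)))
    cat(sprintf("  %-16s %10.5f (%.5f)%s\n", v$symbol[i], v$estimate[i],
                v$se[i], if (v$bound[i]) "  [bound]" else ""))
  if (nrow(x$phi_estimates)) {
    p <- x$phi_estimates
    for (i in seq_len(nrow(p)))
      cat(sprintf("  %-16s %10.4f (%.4f)%s\n",
                  paste0(p$symbol[i], ":", p$parameter[i]), p$estimate[i],
                  p$se[i], if (p$bound[i]) "  [bound]" else ""))
  }
  cat(sprintf("  restricted log-likelihood: %.4f (%d parameters)\n",
              x$restricted_loglik, x$n_parameters))
  invisible(x)
}

#' Likelihood-ratio test between nested REML fits
#'
#' @param null_fit,alt_fit `reml_fit` objects on the same data and fixed
#'   effects; the null model's random terms must be a subset of the
#'   alternative's.
#' @param boundary if `TRUE` and the test adds a single variance component,
#'   use the 50:50 chi-square mixture appropriate when the null pins the
#'   parameter to its boundary; the default follows the naive
#'   chi-square-with-df-equal-to-added-parameters convention.
#' @return list with `chi2`, `df`, `p`.
#' @export
lrt <- function(null_fit, alt_fit, boundary = FALSE) {
  stopifnot(inherits(null_fit, "reml_fit"), inherits(alt_fit, "reml_fit"))
  f0 <- null_fit$fingerprint; f1 <- alt_fit$fingerprint
  if (f0$n != f1$n || abs(f0$sum_y - f1$sum_y) > 1e-8 * (1 + abs(f1$sum_y)) ||
      abs(f0$ss_y - f1$ss_y) > 1e-8 * (1 + abs(f1$ss_y)))
    stop("fits are not on the same data")
  if (!identical(f0$fixed, f1$fixed))
    stop("fits have different fixed effects; LRT on REML likelihoods invalid")
  s0 <- null_fit$variance_estimates$symbol
  s1 <- alt_fit$variance_estimates$symbol
  if (!all(s0 %in% s1))
    stop("null model terms are not a subset of the alternative's")
  df <- alt_fit$n_parameters - null_fit$n_parameters
  if (df < 0) stop("alternative model has fewer parameters than the null")
  chi2 <- max(0, 2 * (alt_fit$restricted_loglik - null_fit$restricted_loglik))
  p <- if (df == 0) as.numeric(chi2 <= 1e-6)
  else if (boundary && df == 1)
    0.5 * stats::pchisq(chi2, 1, lower.tail = FALSE) +
      0.5 * (chi2 <= 0)
  else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Wald tests of fixed-effect terms
#'
#' For each fixed-effect term the joint Wald chi-square `b' C^-1 b` over the
#' term's coefficients, with df equal to the number of coefficients.
#'
#' @param fit a converged `reml_fit`.
#' @return data frame with `term`, `chi2`, `df`, `p`.
#' @export
wald_fixed <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (!fit$converged) stop("Wald tests require a converged fit")
  fe <- fit$fixed_effects
  term_name <- function(a) if (a == 0) "(Intercept)" else fe$term_labels[a]
  out <- lapply(unique(fe$assign), function(a) {
    idx <- which(fe$assign == a)
    b <- fe$coef[idx]
    C <- fe$vcov[idx, idx, drop = FALSE]
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) stop("singular coefficient covariance for term ",
                          term_name(a))
    w <- sum(backsolve(ch, b, transpose = TRUE)^2)
    data.frame(term = term_name(a), chi2 = w, df = length(idx),
               p = stats::pchisq(w, length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Partition phenotypic variance
#'
#' Expresses every fitted variance component as a proportion of the total
#' (the sum of all components including the residual), with delta-method
#' standard errors from the average-information parameter covariance, and
#' reports heritability `h2 = V_A / Sum V` in percent. When a baseline total
#' is supplied, a credibility flag marks fits whose total variance departs
#' from it by more than `credibility_factor` either way -- large jumps in
#' Sum V signal a poorly estimated model.
#'
#' @param fit a converged `reml_fit`.
#' @param baseline_sum_v optional total variance of a reference (usually
#'   non-spatial) fit of the same trait.
#' @param credibility_factor flag threshold on the Sum V ratio (default 3).
#' @return A `variance_partition`: data frame `proportions` (symbol,
#'   proportion, se), `h2` and `h2_se` in percent (`NA` when the model has
#'   no additive genetic term), `sum_v`, and `credibility_flag`.
#' @export
partition <- function(fit, baseline_sum_v = NULL, credibility_factor = 3) {
  stopifnot(inherits(fit, "reml_fit"))
  if (!fit$converged) stop("variance partition requires a converged fit")
  v <- fit$variance_estimates
  theta <- v$estimate
  total <- sum(theta)
  if (total <= 0) stop("total variance is not positive")
  prop <- theta / total
  Kp <- length(theta)
  # delta method: d(prop_i)/d(theta_j) = (I[i==j] * total - theta_i) / total^2
  J <- (diag(total, Kp) - matrix(theta, Kp, Kp)) / total^2
  C <- fit$vcov_theta
  pse <- if (all(is.finite(C))) sqrt(pmax(diag(J %*% C %*% t(J)), 0))
         else rep(NA_real_, Kp)
  ia <- match("V_A", v$symbol)
  h2 <- if (is.na(ia)) NA_real_ else 100 * prop[ia]
  h2_se <- if (is.na(ia)) NA_real_ else 100 * pse[ia]
  flag <- FALSE
  if (!is.null(baseline_sum_v) && baseline_sum_v > 0) {
    r <- total / baseline_sum_v
    flag <- r > credibility_factor || r < 1 / credibility_factor
  }
  structure(list(proportions = data.frame(symbol = v$symbol,
                                          proportion = prop, se = pse,
                                          bound = v$bound,
                                          stringsAsFactors = FALSE),
                 h2 = h2, h2_se = h2_se, sum_v = total,
                 credibility_flag = flag),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  p <- x$proportions
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-16s %6.3f (%.3f)%s\n", p$symbol[i], p$proportion[i],
                p$se[i], if (p$bound[i]) "  [bound]" else ""))
  cat(sprintf("  Sum V: %.4f   h2: %s%%%s\n", x$sum_v,
              ifelse(is.na(x$h2), "NA", sprintf("%.2f", x$h2)),
              if (x$credibility_flag) "   [Sum V not credible]" else ""))
  invisible(x)
}

#' Akaike information criterion of a REML fit
#'
#' `-2 * restricted_loglik + 2 * n_parameters`, counting (co)variance
#' parameters only. REML-based AICs are comparable only between models with
#' identical fixed effects; use [aic_table()] to compare safely.
#'
#' @param fit a converged `reml_fit`.
#' @return numeric AIC.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (!fit$converged) stop("AIC requires a converged fit")
  -2 * fit$restricted_loglik + 2 * fit$n_parameters
}

#' @rdname aic
#' @param fits named list of `reml_fit` objects sharing data and fixed
#'   effects.
#' @return For `aic_table()`, a data frame of AICs sorted ascending.
#' @export
aic_table <- function(fits) {
  fps <- lapply(fits, function(f) f$fingerprint$fixed)
  if (length(unique(unlist(fps))) > 1)
    stop("fits have different fixed effects; REML AICs are not comparable")
  out <- data.frame(model = names(fits),
                    aic = vapply(fits, aic, 0),
                    n_parameters = vapply(fits, `[[`, 0L, "n_parameters"),
                    stringsAsFactors = FALSE)
  out[order(out$aic), , drop = FALSE]
}
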