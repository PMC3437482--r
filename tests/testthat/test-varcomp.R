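test_that("design matrices use reference coding, polynomials, and listwise
           deletion with rank checks", {
  set.seed(12)
  d <- data.frame(y = rnorm(20), age = rep(1:5, 4),
                  status = sample(rep(c("milk", "naive", "summer.yeld",
                                        "true.yeld", "winter.yeld"), 4)),
                  individual = sprintf("i%d", rep(1:10, 2)))
  spec <- model_spec("y", ~ age + I(age^2) + status, list(pe_term()))
  des <- build_design(spec, d)
  expect_equal(des$X[, "I(age^2)"], des$X[, "age"]^2)
  expect_equal(sum(grepl("^status", colnames(des$X))), 4L)  # 5 levels -> 4
  # reference level is the first sorted level
  expect_false("statusmilk" %in% colnames(des$X))

  d2 <- d; d2$age[1:3] <- NA
  expect_equal(build_design(spec, d2)$n_dropped, 3L)
  d3 <- d; d3$age <- NA
  expect_error(build_design(spec, d3), "age")
  expect_error(
    build_design(model_spec("y", ~ age + I(2 * age), list(pe_term())), d),
    "aliased")
})

test_that("REML reproduces the balanced one-way ANOVA estimators", {
  for (seed in c(31, 32, 33)) {
    d <- one_way_data(seed)
    fit <- reml_fit(model_spec("y", ~1, list(pe_term())), d,
                    options = list(n_starts = 1))
    av <- stats::anova(stats::lm(y ~ individual, d))
    msb <- av[1, 3]; msw <- av[2, 3]
    expect_true(fit$converged)
    est <- fit$variance_estimates$estimate
    expect_equal(est[1], max((msb - msw) / 10, 0), tolerance = 1e-6)
    expect_equal(est[2], msw, tolerance = 1e-6)
  }
})

test_that("REML matches lme4 on an unbalanced crossed design", {
  skip_if_not_installed("lme4")
  set.seed(41)
  n <- 180
  d <- data.frame(individual = sample(sprintf("i%02d", 1:40), n, TRUE),
                  year = sample(2001:2006, n, TRUE),
                  x = rnorm(n))
  u <- rnorm(40, 0, 1); v <- rnorm(6, 0, 0.7)
  d$y <- 2 + 0.5 * d$x + u[match(d$individual, sprintf("i%02d", 1:40))] +
    v[d$year - 2000] + rnorm(n, 0, 1.2)
  fit <- reml_fit(model_spec("y", ~x, list(pe_term(), year_term())), d,
                  options = list(n_starts = 2))
  lf <- lme4::lmer(y ~ x + (1 | individual) + (1 | year), d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  ref <- vc$vcov[match(c("individual", "year", "Residual"), vc$grp)]
  expect_equal(fit$variance_estimates$estimate, ref, tolerance = 1e-4)
  expect_equal(unname(fit$fixed_effects$coef),
               unname(lme4::fixef(lf)), tolerance = 1e-4)
})

test_that("the reported optimum maximizes an independently coded restricted
           likelihood", {
  cfg <- sim_config(seed = 51, n_founder_females = 20,
                    trait_design = "single_measure")
  dat <- simulate_dataset(cfg, s_matrix = "true")
  spec <- model_spec("y", ~1, list(animal_term(dat$A), smatrix_term(dat$S)))
  fit <- reml_fit(spec, dat$phenotypes, options = list(n_starts = 1))
  expect_true(fit$converged)

  des <- build_design(spec, dat$phenotypes)
  direct_ll <- function(theta) {
    V <- theta[1] * des$terms[[1]]$M + theta[2] * des$terms[[2]]$M +
      theta[3] * diag(des$n)
    Vi <- solve(V)
    XtViX <- t(des$X) %*% Vi %*% des$X
    P <- Vi - Vi %*% des$X %*% solve(XtViX) %*% t(des$X) %*% Vi
    -0.5 * (as.numeric(determinant(V)$modulus) +
              as.numeric(determinant(XtViX)$modulus) +
              drop(t(des$y) %*% P %*% des$y))
  }
  th <- fit$variance_estimates$estimate
  expect_equal(direct_ll(th), fit$restricted_loglik, tolerance = 1e-8)
  # local optimum: nearby parameter values never do better
  set.seed(52)
  for (i in 1:8) {
    pert <- th * exp(rnorm(3, 0, 0.03))
    expect_lte(direct_ll(pert), fit$restricted_loglik + 1e-7)
  }
})

test_that("duplicated random structures raise a non-identifiability warning", {
  d <- one_way_data(34, n_groups = 10, reps = 4)
  expect_warning(
    build_design(model_spec("y", ~1, list(pe_term(), pe_term())), d),
    "not separately identifiable")
})

test_that("likelihood-ratio tests count added covariance parameters", {
  cfg <- sim_config(seed = 61, n_founder_females = 25,
                    trait_design = "single_measure",
                    true_components = c(V_A = 0.3, V_Smatrix = 0.3,
                                        V_Residual = 0.4))
  dat <- simulate_dataset(cfg, s_matrix = "true")
  base <- model_spec("y", ~1, list(animal_term(dat$A)))
  f0 <- reml_fit(base, dat$phenotypes, options = list(n_starts = 1))
  # identical fits: chi2 = 0, p = 1
  same <- lrt(f0, reml_fit(base, dat$phenotypes,
                           options = list(n_starts = 1)))
  expect_equal(same$chi2, 0, tolerance = 1e-6)
  expect_equal(same$p, 1, tolerance = 1e-4)
  # adding the S matrix adds one parameter
  f1 <- reml_fit(model_spec("y", ~1, list(animal_term(dat$A),
                                          smatrix_term(dat$S))),
                 dat$phenotypes, options = list(n_starts = 1))
  t1 <- lrt(f0, f1)
  expect_equal(t1$df, 1L)
  # adding a two-axis SAC process adds variance + 2 correlations
  f3 <- reml_fit(model_spec("y", ~1,
                            list(animal_term(dat$A),
                                 sac_term(dat$lattice,
                                          axes = c("row", "col")))),
                 dat$phenotypes, options = list(n_starts = 1))
  expect_equal(lrt(f0, f3)$df, 3L)
  # different data is refused
  other <- dat$phenotypes
  other$y <- other$y + 1
  fo <- reml_fit(base, other, options = list(n_starts = 1))
  expect_error(lrt(fo, f1), "same data")
})

test_that("Wald statistics square the z-ratio and pool factor columns", {
  set.seed(71)
  d <- data.frame(y = rnorm(80), x = rnorm(80),
                  grp = sample(letters[1:4], 80, TRUE),
                  individual = sprintf("i%02d", rep(1:40, 2)))
  d$y <- d$y + 0.8 * d$x
  fit <- reml_fit(model_spec("y", ~ x + grp, list(pe_term())), d,
                  options = list(n_starts = 1))
  w <- wald_fixed(fit)
  b <- fit$fixed_effects$coef["x"]
  se <- sqrt(diag(fit$fixed_effects$vcov))[2]
  expect_equal(w$chi2[w$term == "x"], unname((b / se)^2), tolerance = 1e-10)
  expect_equal(w$df[w$term == "grp"], 3L)   # 4 levels reference-coded
  expect_equal(w$df[w$term == "x"], 1L)
})

test_that("variance partitions are normalized with delta-method SEs matching
           a parametric bootstrap", {
  # forced arithmetic: V_A = 1, V_Residual = 3 -> h2 = 25%
  fake <- structure(list(
    variance_estimates = data.frame(symbol = c("V_A", "V_Residual"),
                                    estimate = c(1, 3), se = NA,
                                    bound = FALSE),
    vcov_theta = diag(c(0.01, 0.01)), converged = TRUE),
    class = "reml_fit")
  p <- partition(fake)
  expect_equal(p$h2, 25)
  expect_equal(sum(p$proportions$proportion), 1, tolerance = 1e-8)
  fake0 <- fake
  fake0$variance_estimates$estimate <- c(0, 3)
  expect_equal(partition(fake0)$h2, 0)

  # delta-method SE of a proportion vs parametric bootstrap
  true_g <- 1.5; true_e <- 2
  d <- one_way_data(81, n_groups = 15, reps = 5, sd_g = sqrt(true_g),
                    sd_e = sqrt(true_e))
  spec <- model_spec("y", ~1, list(pe_term()))
  fit <- reml_fit(spec, d, options = list(n_starts = 1))
  est <- fit$variance_estimates$estimate
  pr <- partition(fit)
  set.seed(82)
  boot <- replicate(300, {
    db <- data.frame(
      y = rnorm(15, 0, sqrt(est[1]))[rep(1:15, each = 5)] +
        rnorm(75, 0, sqrt(est[2])),
      individual = sprintf("i%02d", rep(1:15, each = 5)))
    fb <- reml_fit(spec, db, options = list(n_starts = 1))
    fb$variance_estimates$estimate[1] / sum(fb$variance_estimates$estimate)
  })
  expect_lt(abs(pr$proportions$se[1] - stats::sd(boot)) / stats::sd(boot),
            0.15)

  # credibility flag trips when Sum V explodes relative to a baseline
  expect_true(partition(fake, baseline_sum_v = 1)$credibility_flag)
  expect_false(partition(fake, baseline_sum_v = 4.1)$credibility_flag)
})

test_that("AIC counts covariance parameters and refuses mixed fixed
           effects", {
  d <- one_way_data(91)
  spec <- model_spec("y", ~1, list(pe_term()))
  f1 <- reml_fit(spec, d, options = list(n_starts = 1))
  f2 <- reml_fit(spec, d, options = list(n_starts = 1))
  expect_equal(aic(f1), aic(f2))
  expect_equal(aic(f1), -2 * f1$restricted_loglik + 2 * 2)
  d$x <- rnorm(nrow(d))
  fx <- reml_fit(model_spec("y", ~x, list(pe_term())), d,
                 options = list(n_starts = 1))
  expect_error(aic_table(list(a = f1, b = fx)), "not comparable")
})
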