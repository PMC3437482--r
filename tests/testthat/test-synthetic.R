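test_that("simulation is fully deterministic under a seed", {
  cfg <- sim_config(seed = 7, n_founder_females = 12, fixes_per_season = 5)
  d1 <- simulate_dataset(cfg, s_matrix = "estimated")
  d2 <- simulate_dataset(cfg, s_matrix = "estimated")
  expect_identical(d1$pedigree, d2$pedigree)
  expect_identical(d1$fixes, d2$fixes)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$S$values, d2$S$values)
  # a different seed moves the data
  d3 <- simulate_dataset(sim_config(seed = 8, n_founder_females = 12,
                                    fixes_per_season = 5),
                         s_matrix = "estimated")
  expect_false(identical(d1$phenotypes$y, d3$phenotypes$y))
})

test_that("pedigree generator honors its degenerate settings and growth
           expectation", {
  one <- simulate_pedigree(sim_config(seed = 2, n_generations = 1,
                                      n_founder_females = 10))
  expect_equal(nrow(one), 10)
  expect_true(all(is.na(one$dam)))

  nodad <- simulate_pedigree(sim_config(seed = 3, n_founder_females = 10,
                                        unknown_father_fraction = 1))
  expect_true(all(is.na(nodad$sire)))

  # branching process: expected female count = F * sum(m^g)
  m <- 1.2; Fo <- 20; gens <- 4
  sizes <- vapply(1:40, function(s) {
    p <- simulate_pedigree(sim_config(seed = 100 + s, n_founder_females = Fo,
                                      n_generations = gens,
                                      offspring_per_female = m))
    sum(!is.na(p$sex) & p$sex == "F")
  }, 0)
  expected <- Fo * sum(m^(0:(gens - 1)))
  expect_lt(abs(mean(sizes) - expected), 3 * stats::sd(sizes) / sqrt(40))
})

test_that("daughters settle near their mothers (Rayleigh dispersal)", {
  cfg <- sim_config(seed = 5, n_founder_females = 60, dispersal_sd = 100,
                    offspring_per_female = 1.5)
  ped <- simulate_pedigree(cfg)
  loc <- simulate_locations(ped, cfg, fixes = FALSE)
  cx <- stats::setNames(loc$centers$x, loc$centers$individual)
  cy <- stats::setNames(loc$centers$y, loc$centers$individual)
  fem <- ped[!is.na(ped$sex) & ped$sex == "F" & !is.na(ped$dam), ]
  d <- sqrt((cx[fem$individual] - cx[fem$dam])^2 +
              (cy[fem$individual] - cy[fem$dam])^2)
  # mean of a Rayleigh(sigma) is sigma * sqrt(pi/2)
  expect_lt(abs(mean(d) - 100 * sqrt(pi / 2)),
            3 * stats::sd(d) / sqrt(length(d)))

  # zero dispersal collapses each matriline onto one center
  cfg0 <- sim_config(seed = 5, n_founder_females = 10, dispersal_sd = 0)
  loc0 <- simulate_locations(simulate_pedigree(cfg0), cfg0, fixes = FALSE)
  ped0 <- simulate_pedigree(cfg0)
  cx0 <- stats::setNames(loc0$centers$x, loc0$centers$individual)
  fem0 <- ped0[!is.na(ped0$sex) & ped0$sex == "F" & !is.na(ped0$dam), ]
  expect_equal(unname(cx0[fem0$individual]), unname(cx0[fem0$dam]))
})

test_that("phenotypes carry the requested variance structure", {
  # residual-only: sample variance near 1
  cfg <- sim_config(seed = 21, n_founder_females = 60,
                    offspring_per_female = 1.3,
                    true_components = c(V_Residual = 1),
                    trait_design = "repeated", n_years = 4)
  dat <- simulate_dataset(cfg, s_matrix = "none", fixes = FALSE)
  n <- nrow(dat$phenotypes)
  expect_gt(n, 800)
  expect_lt(abs(stats::var(dat$phenotypes$y) - 1), 3 * sqrt(2 / n))

  # additive-only: mother-daughter covariance ~ V_A / 2
  cfgA <- sim_config(seed = 22, n_founder_females = 150,
                     offspring_per_female = 1.3, n_generations = 5,
                     true_components = c(V_A = 1, V_Residual = 0.001),
                     trait_design = "single_measure")
  datA <- simulate_dataset(cfgA, s_matrix = "none", fixes = FALSE)
  ph <- datA$phenotypes
  yv <- stats::setNames(ph$y, ph$individual)
  pairs <- ph[!is.na(ph$dam) & ph$dam %in% names(yv), ]
  cv <- stats::cov(yv[pairs$individual], yv[pairs$dam])
  expect_gt(nrow(pairs), 300)
  expect_lt(abs(cv - 0.5), 0.15)
})

test_that("an identity S aliases with the residual", {
  cfg <- sim_config(seed = 23, n_founder_females = 40,
                    trait_design = "single_measure",
                    true_components = c(V_Smatrix = 1, V_Residual = 0.0001))
  ped <- simulate_pedigree(cfg)
  ids <- ped$individual[!is.na(ped$sex) & ped$sex == "F"]
  S_id <- relationship_matrix(ids, diag(length(ids)), "S")
  phen <- simulate_phenotypes(ped, additive_relationship(ped), S_id, cfg)
  fit <- reml_fit(model_spec("y", ~1, list(smatrix_term(S_id))),
                  phen$phenotypes, options = list(n_starts = 1))
  est <- fit$variance_estimates$estimate
  # only the sum is identified; it should match the realized variance
  expect_equal(sum(est), stats::var(phen$phenotypes$y), tolerance = 0.05)
})

test_that("philopatry makes overlap higher within matrilines than between", {
  cfg <- sim_config(seed = 24, n_founder_females = 12,
                    fixes_per_season = 10, n_years = 2)
  ped <- simulate_pedigree(cfg)
  loc <- simulate_locations(ped, cfg)
  est <- estimate_uds(loc$fixes, by = "individual", cell = 50)
  S <- build_s_matrix(est$uds)
  # matriline = founder ancestress of each female
  root <- stats::setNames(ped$individual, ped$individual)
  for (i in seq_len(nrow(ped)))
    if (!is.na(ped$dam[i])) root[ped$individual[i]] <- root[ped$dam[i]]
  ids <- S$ids
  same <- outer(root[ids], root[ids], "==")
  off <- upper.tri(S$values)
  expect_gt(mean(S$values[off & same]), mean(S$values[off & !same]))
})
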