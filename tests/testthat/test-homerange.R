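test_that("jitter is bounded, seeded, and leaves the input untouched", {
  fixes <- as_fixes(data.frame(individual = "a", season = "spring",
                               year = 1, x = seq(0, 900, 100), y = 0))
  j1 <- jitter_fixes(fixes, amplitude = 20, seed = 5)
  j2 <- jitter_fixes(fixes, amplitude = 20, seed = 5)
  expect_identical(j1, j2)
  expect_true(all(abs(j1$x - fixes$x) <= 20))
  expect_true(all(abs(j1$y - fixes$y) <= 20))
  expect_false(identical(jitter_fixes(fixes, seed = 6)$x, j1$x))
  # amplitude -> 0 limit recovers the input
  tiny <- jitter_fixes(fixes, amplitude = 1e-9, seed = 5)
  expect_equal(tiny$x, fixes$x, tolerance = 1e-8)
  expect_error(jitter_fixes(fixes, amplitude = 0), "positive")
})

test_that("utilization distributions are normalized nonnegative cell masses", {
  set.seed(1)
  ud <- estimate_ud(rnorm(40, 0, 50), rnorm(40, 0, 50), cell = 10)
  expect_equal(sum(ud$density), 1, tolerance = 1e-9)
  expect_true(all(ud$density >= 0))
  expect_error(estimate_ud(rnorm(9), rnorm(9)), "at least 10")
  expect_error(estimate_ud(rep(0, 12), rep(0, 12)), "jitter")
})

test_that("minimum-fix filter logs exclusions rather than failing", {
  set.seed(2)
  fixes <- as_fixes(rbind(
    data.frame(individual = "few", season = "spring", year = 1,
               x = rnorm(9, 0, 40), y = rnorm(9, 0, 40)),
    data.frame(individual = "many", season = "spring", year = 1,
               x = rnorm(15, 0, 40), y = rnorm(15, 0, 40))))
  res <- estimate_uds(fixes, by = "individual", min_fixes = 10)
  expect_named(res$uds, "many")
  expect_equal(res$exclusions$group, "few")
  expect_equal(res$exclusions$n_fixes, 9L)
})

test_that("cell masses match brute-force quadrature of the kernel mixture", {
  set.seed(3)
  x <- rnorm(60, 0, 80); y <- rnorm(60, 0, 80)
  h <- 40; cell <- 20
  ud <- estimate_ud(x, y, bandwidth = h, cell = cell, extent_pad = 3 * h)
  # independent oracle: midpoint quadrature of the mixture density on a
  # 5x5 subgrid of every cell
  sub <- (seq_len(5) - 0.5) / 5 * cell
  q <- matrix(0, nrow(ud$density), ncol(ud$density))
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(ncol(q))) {
      cx <- ud$origin[1] + (j - 1) * cell + sub
      cy <- ud$origin[2] + (i - 1) * cell + sub
      dens <- outer(cy, cx, function(yy, xx) {
        v <- 0
        for (k in seq_along(x))
          v <- v + stats::dnorm(xx, x[k], h) * stats::dnorm(yy, y[k], h)
        v / length(x)
      })
      q[i, j] <- mean(dens) * cell^2
    }
  }
  q <- q / sum(q)
  expect_lt(0.5 * sum(abs(ud$density - q)), 1e-3)
})

test_that("KDE of many Gaussian fixes approaches the convolved density", {
  set.seed(4)
  n <- 10000
  x <- rnorm(n, 0, 100); y <- rnorm(n, 0, 100)
  ud <- estimate_ud(x, y, bandwidth = 30, cell = 10, extent_pad = 150)
  s <- sqrt(100^2 + 30^2)
  ex <- ud$origin[1] + 10 * (0:ncol(ud$density))
  ey <- ud$origin[2] + 10 * (0:nrow(ud$density))
  q <- outer(diff(stats::pnorm(ey, 0, s)), diff(stats::pnorm(ex, 0, s)))
  q <- q / sum(q)
  # total variation is dominated by the sampling error of the n fixes
  expect_lt(0.5 * sum(abs(ud$density - q)), 0.05)
})

test_that("range size follows the closed forms and grows with isopleth", {
  # uniform UD over k cells at isopleth 1
  ud <- structure(list(origin = c(0, 0), cell = 10,
                       density = matrix(1 / 12, 3, 4)),
                  class = "utilization_distribution")
  expect_equal(range_size(ud, 1), 12 * 100 / 1e4)
  # circular Gaussian: area(0.95) = pi * qchisq(.95, 2) * sigma^2
  g <- gaussian_ud(0, 0, sigma = 100, cell = 5)
  expected <- pi * stats::qchisq(0.95, 2) * 100^2 / 1e4
  expect_lt(abs(range_size(g, 0.95) - expected) / expected, 0.02)
  # monotone in isopleth
  iso <- seq(0.1, 1, by = 0.1)
  areas <- vapply(iso, function(p) range_size(g, p), 0)
  expect_true(all(diff(areas) >= 0))
  expect_error(range_size(g, 0), "isopleth")
  expect_error(range_size(g, 1.2), "isopleth")
})

test_that("Bhattacharyya affinity obeys its identities and closed form", {
  g0 <- gaussian_ud(0, 0)
  expect_equal(ba_overlap(g0, g0), 1)
  # equal circular Gaussians d apart: BA = exp(-d^2 / (8 sigma^2))
  for (d in c(100, 200)) {
    gd <- gaussian_ud(d, 0)
    expect_equal(ba_overlap(g0, gd), exp(-d^2 / (8 * 100^2)),
                 tolerance = 1e-3)
  }
  # disjoint supports
  far <- gaussian_ud(5000, 5000, sigma = 50, pad = 200)
  near <- gaussian_ud(0, 0, sigma = 50, pad = 200)
  expect_equal(ba_overlap(near, far), 0, tolerance = 1e-6)
  # symmetry and the Cauchy-Schwarz bound on random UDs
  for (seed in 1:4) {
    u1 <- random_ud(seed); u2 <- random_ud(seed + 50)
    b12 <- ba_overlap(u1, u2)
    expect_equal(b12, ba_overlap(u2, u1), tolerance = 1e-12)
    expect_lte(b12, 1)
  }
})

test_that("S matrix follows the missing-individual convention and PSD clip
           contract", {
  u <- gaussian_ud(0, 0, sigma = 50, cell = 10, pad = 200)
  uds <- list(i1 = u, i2 = u)
  S <- build_s_matrix(uds, all_ids = c("i1", "i2", "i3"))
  expect_equal(unname(S$values),
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)),
               tolerance = 1e-9)
  expect_false(S$psd_adjusted)

  Sc <- build_s_matrix(uds, all_ids = c("i1", "i2", "i3"), psd = "clip",
                       eps = 1e-8)
  ev <- eigen(Sc$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-8)
  expect_equal(unname(diag(Sc$values)), rep(1, 3))
  expect_true(Sc$psd_adjusted)
  expect_gt(Sc$adjustment_magnitude, 0)

  # nobody has a UD -> identity
  S0 <- build_s_matrix(list(), all_ids = c("a", "b"))
  expect_equal(unname(S0$values), diag(2))
  expect_error(build_s_matrix(uds, all_ids = c("i1", "i1", "i2")),
               "duplicate")
})

test_that("birth-weight adjustment applies the hourly growth correction", {
  expect_equal(birth_weight_adjust(8.0, 0), 8.0)
  expect_equal(birth_weight_adjust(8.0, 10), 7.8461)
  expect_equal(birth_weight_adjust(6.5, 100), 4.961)
  expect_error(birth_weight_adjust(8, -1), "non-negative")
})

test_that("region assignment counts, breaks boundary ties by label order,
           and warns on outsiders", {
  regions <- data.frame(region = c("north", "south"),
                        xmin = 0, xmax = 100,
                        ymin = c(50, 0), ymax = c(100, 50))
  ml <- data.frame(individual = c("a", "b", "c"),
                   x = c(10, 20, 30), y = c(80, 90, 70))
  res <- local_population_size(ml, regions)
  expect_equal(unname(res$counts["north"]), 3L)
  expect_equal(unname(res$counts["south"]), 0L)
  # point on the shared y = 50 boundary goes to the first-sorted label
  tie <- local_population_size(data.frame(individual = "t", x = 10, y = 50),
                               regions)
  expect_equal(tie$assignment$region, "north")
  expect_warning(
    out <- local_population_size(data.frame(individual = "o", x = -5, y = 5),
                                 regions),
    "outside")
  expect_equal(out$assignment$region, "outside")
  # empty individual set: all counts zero
  none <- local_population_size(data.frame(individual = character(),
                                           x = numeric(), y = numeric()),
                                regions)
  expect_true(all(none$counts == 0))
})
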