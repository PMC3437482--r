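# Shared fixtures, all built in code.

# two founder pairs -> two full sibs, plus an inbred full-sib mating
ped_inbred <- function() {
  as_pedigree(data.frame(
    individual = c("A", "B", "C", "D", "E"),
    dam = c(NA, NA, "A", "A", "C"),
    sire = c(NA, NA, "B", "B", "D")))
}

# circular Gaussian UD via a single-fix KDE with fixed bandwidth = sigma
gaussian_ud <- function(cx, cy, sigma = 100, cell = 5, pad = 500) {
  estimate_ud(cx, cy, bandwidth = sigma, cell = cell, extent_pad = pad,
              min_fixes = 1)
}

# random small pedigree for property tests
random_pedigree <- function(seed, n_founders = 8, generations = 4) {
  cfg <- sim_config(seed = seed, n_founder_females = n_founders,
                    n_generations = generations,
                    offspring_per_female = 1.2,
                    unknown_father_fraction = 0.3, n_males = 4)
  simulate_pedigree(cfg)
}

# random UD from a handful of scattered fixes
random_ud <- function(seed, n = 25, spread = 150) {
  set.seed(seed)
  estimate_ud(rnorm(n, runif(1, 0, 500), spread),
              rnorm(n, runif(1, 0, 500), spread),
              cell = 20, min_fixes = 5)
}

# balanced one-way layout with known group/residual variances
one_way_data <- function(seed, n_groups = 20, reps = 10, sd_g = 1, sd_e = 2) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = reps)
  data.frame(y = rnorm(n_groups, 0, sd_g)[g] + rnorm(n_groups * reps, 0, sd_e),
             individual = sprintf("i%02d", g))
}
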