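test_that("the generation chain is deterministic under a seed", {
  h1 <- small_gaussian_herd(seed = 9)
  h2 <- small_gaussian_herd(seed = 9)
  expect_identical(h1$phenotypes, h2$phenotypes)
  expect_identical(as.data.frame(h1$pedigree), as.data.frame(h2$pedigree))
  h3 <- small_gaussian_herd(seed = 10)
  expect_false(identical(h1$phenotypes, h3$phenotypes))
})

test_that("default herd scale matches the emulated study population", {
  for (s in 1:3) {
    cfg <- sim_config(seed = s)
    ped <- simulate_pedigree(cfg)
    n_off <- sum(attr(ped, "is_offspring"))
    expect_lt(abs(n_off - 1004) / 1004, 0.10)
    ## 31 sires and 135 dams are the parents of the phenotyped generation
    off <- as.data.frame(ped)[attr(ped, "is_offspring"), ]
    expect_lte(length(unique(off$sire)), 31L)
    expect_equal(length(unique(off$dam)), 135L)
  }
})

test_that("generation depth 0 makes all parents founders", {
  cfg <- sim_config(n_sires = 2, n_dams = 2, litter_size_mean = 4,
                    generation_depth = 0, seed = 1)
  ped <- simulate_pedigree(cfg)
  parents <- as.data.frame(ped)[ped$animal %in% c(ped$sire, ped$dam), ]
  expect_true(all(is.na(parents$sire)) && all(is.na(parents$dam)))
})

test_that("liability decomposition has the configured moments", {
  ## all variances zero: values equal mu + fixed effects exactly
  cfg <- sim_config(n_sires = 3, n_dams = 6, litter_size_mean = 5, seed = 2,
                    traits = list(y = trait_sim_spec(
                      1.5, 0, 0, 0, "gaussian",
                      fixed_effects = list(sex = c(0, 1)))))
  herd <- simulate_herd(cfg)
  expected <- 1.5 + (herd$phenotypes$sex == "gilt") * 1
  expect_equal(herd$phenotypes$y, unname(expected))

  ## sigma2_a = 0: total variance ~ sigma2_le + sigma2_e within 5% at n ~ 10000
  cfg <- sim_config(n_sires = 40, n_dams = 500, litter_size_mean = 20,
                    generation_depth = 0, seed = 4,
                    traits = list(y = trait_sim_spec(0, 0, 0.3, 0.7, "gaussian")))
  herd <- simulate_herd(cfg)
  expect_gt(nrow(herd$phenotypes), 9000)
  expect_lt(abs(var(herd$phenotypes$y) - 1.0), 0.05)
  ## and realized between-family genetic variance is nil: breeding values all 0
  expect_equal(max(abs(herd$truth$y$breeding_values)), 0)
})

test_that("simulate_liabilities composes the declared effects", {
  ped <- simulate_pedigree(sim_config(n_sires = 3, n_dams = 8,
                                      litter_size_mean = 5, seed = 6))
  factors <- assign_factors(ped, seed = 6)
  spec <- trait_sim_spec(2, 0, 0, 0, "gaussian",
                         fixed_effects = list(breed = c(0, 0.5)))
  liab <- simulate_liabilities(ped, spec, factors, seed = 1)
  off <- attr(ped, "is_offspring")
  expect_equal(unname(liab[off]),
               2 + 0.5 * (factors$breed[off] == "pure"))
  ## seeded draws are reproducible
  spec2 <- trait_sim_spec(0, 0.5, 0.2, 0.3, "gaussian")
  expect_identical(simulate_liabilities(ped, spec2, seed = 9),
                   simulate_liabilities(ped, spec2, seed = 9))
})

test_that("full-sib phenotypic covariance matches 0.5 sigma2_a + sigma2_le", {
  cfg <- sim_config(n_sires = 100, n_dams = 2000, litter_size_mean = 2,
                    generation_depth = 0, seed = 8,
                    traits = list(y = trait_sim_spec(0, 0.52, 0.08, 0.87,
                                                     "gaussian")))
  herd <- simulate_herd(cfg)
  ph <- herd$phenotypes
  pairs <- do.call(rbind, lapply(split(ph$y, ph$litter), function(v) {
    if (length(v) >= 2) v[1:2] else NULL
  }))
  expect_gt(nrow(pairs), 1000)
  got <- cov(pairs[, 1], pairs[, 2])
  expect_lt(abs(got - (0.5 * 0.52 + 0.08)), 0.10)
})

test_that("discretize is a monotone step map onto the declared support", {
  expect_equal(discretize(c(-5, 0, 5), numeric(0), support = 7L),
               rep(7L, 3))
  x <- sort(rnorm(200))
  sc <- discretize(x, c(-1, 0.2, 1), support = 1:4)
  expect_true(all(diff(sc) >= 0))
  expect_true(all(sc %in% 1:4))
  expect_error(discretize(x, c(1, 0.5), support = 1:3), "strictly increasing")
  expect_error(discretize(x, c(0, 1), support = 1:5), "length")
  expect_true(is.na(discretize(NA_real_, 0, support = 1:2)))
})

test_that("moment-matched thresholds reproduce the piglet scale score", {
  thr <- thresholds_for_moments(1:3, target_mean = 2.0, target_sd = 0.8,
                                mu = 2.0, sigma2 = 0.63)
  set.seed(21)
  sc <- discretize(rnorm(5000, 2.0, sqrt(0.63)), thr, support = 1:3)
  expect_lt(abs(mean(sc) - 2.0), 0.05)
  expect_lt(abs(sd(sc) - 0.8), 0.05)
})

test_that("study presets stay on their declared supports", {
  cfg <- sim_config(n_sires = 8, n_dams = 30, litter_size_mean = 6, seed = 13,
                    traits = study_traits())
  herd <- simulate_herd(cfg)
  sup <- list(BT1 = 0:9, BT2 = 0:9, INJ = 1:4, PSS = 1:3, RLS = 1:3,
              RSS = 1:3, FLS = 1:3, FSS = 1:3, LS1 = 1:4, LS2 = 1:4)
  for (nm in names(sup)) {
    vals <- stats::na.omit(herd$phenotypes[[nm]])
    expect_true(all(vals %in% sup[[nm]]), label = paste(nm, "support"))
  }
  ## litter members share their dam
  off <- herd$phenotypes
  ped <- as.data.frame(herd$pedigree)
  dam_of <- ped$dam[match(off$animal, ped$animal)]
  expect_true(all(tapply(dam_of, off$litter,
                         function(v) length(unique(v)) == 1L)))
})

test_that("missingness masking is Bernoulli per trait and leaves NA only", {
  ph <- data.frame(animal = sprintf("A%04d", 1:1004), y = rnorm(1004))
  expect_identical(apply_missingness(ph, list(y = 0), seed = 1), ph)
  masked <- apply_missingness(ph, list(y = 0.23), seed = 1)
  kept <- sum(!is.na(masked$y))
  ## binomial(1004, 0.77): mean 773, sd 13.4 -- allow 4.5 sd
  expect_lt(abs(kept - 1004 * 0.77), 60)
  expect_true(all(is.na(masked$y) | masked$y == ph$y))
})
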