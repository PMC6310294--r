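test_that("sparse MME restricted likelihood equals the dense-V oracle", {
  herd <- small_gaussian_herd(seed = 3)
  dsg <- reml_design(herd$phenotypes, herd$pedigree, model_spec("y"))
  for (th in list(c(0.5, 0.1, 0.9), c(0.2, 0.3, 1.5), c(1e-4, 0.5, 0.7))) {
    expect_equal(reml_loglik(dsg, th[1], th[2], th[3]),
                 dense_reml_loglik(dsg, herd$pedigree, th[1], th[2], th[3]),
                 tolerance = 1e-9)
  }
})

test_that("heritability arithmetic and delta-method guards", {
  expect_equal(heritability(0.52, 0.08, 0.87), 0.52 / 1.47)
  expect_equal(heritability(1, 0, 0), 1)
  expect_equal(heritability(c(0.52, 5707.2), c(0.08, 1234.3),
                            c(0.87, 2859.2)),
               c(0.52 / 1.47, 5707.2 / 9800.7))
  expect_error(heritability(0, 0, 0), "positive")
})

test_that("univariate REML recovers simulated components and beats a local grid", {
  herd <- study_scale_herd(seed = 1)
  fit <- fit_univariate(herd$phenotypes, herd$pedigree, model_spec("y"))
  expect_true(fit$converged)
  expect_lt(abs(fit$h2 - 0.52 / 1.47), 0.12)
  expect_true(all(fit$se >= 0) && fit$se_h2 >= 0)
  expect_true(all(fit$components > 0))
  expect_gte(fit$h2, 0)
  expect_lte(fit$h2, 1)
  ## converged point beats a surrounding grid, by the independent dense oracle
  herd_s <- small_gaussian_herd(seed = 6, n_sires = 5, n_dams = 12,
                                litter_size_mean = 5)
  fit_s <- fit_univariate(herd_s$phenotypes, herd_s$pedigree, model_spec("y"),
                          se = FALSE)
  dsg_s <- fit_s$design
  best <- dense_reml_loglik(dsg_s, herd_s$pedigree, fit_s$components[1],
                            fit_s$components[2], fit_s$components[3])
  grid <- expand.grid(a = fit_s$components[1] * exp(seq(-0.6, 0.6, len = 5)),
                      p = fit_s$components[2] * exp(seq(-0.6, 0.6, len = 5)),
                      e = fit_s$components[3] * exp(seq(-0.6, 0.6, len = 5)))
  ll <- mapply(function(a, p, e) dense_reml_loglik(dsg_s, herd_s$pedigree,
                                                   a, p, e),
               grid$a, grid$p, grid$e)
  expect_gte(best, max(ll) - 1e-3)
})

test_that("a trait without genetic variance is estimated at the boundary", {
  for (s in c(101, 104)) {
    cfg <- sim_config(n_sires = 20, n_dams = 80, litters_per_dam = 2,
                      litter_size_mean = 6, seed = s,
                      traits = list(y = trait_sim_spec(0, 0, 0.15, 0.85,
                                                       "gaussian")))
    herd <- simulate_herd(cfg)
    fit <- fit_univariate(herd$phenotypes, herd$pedigree, model_spec("y"),
                          se = FALSE)
    expect_lt(fit$components[["sigma2_a"]] / sum(fit$components), 0.06)
  }
})

test_that("REML estimates are invariant to row order and factor relabelling", {
  herd <- small_gaussian_herd(seed = 4)
  fit0 <- fit_univariate(herd$phenotypes, herd$pedigree, model_spec("y"),
                         se = FALSE)
  perm <- sample(nrow(herd$phenotypes))
  ph <- herd$phenotypes[perm, ]
  ph$sex <- c(barrow = "zz_male", gilt = "aa_female")[ph$sex]
  fit1 <- fit_univariate(ph, herd$pedigree, model_spec("y"), se = FALSE)
  expect_equal(fit1$components, fit0$components, tolerance = 1e-5)
  expect_equal(fit1$h2, fit0$h2, tolerance = 1e-5)
})

test_that("degenerate inputs fail with named errors", {
  herd <- small_gaussian_herd(seed = 4)
  ph <- herd$phenotypes
  ph$y <- 1
  expect_error(fit_univariate(ph, herd$pedigree, model_spec("y")), "constant")
  expect_error(reml_design(herd$phenotypes, herd$pedigree, model_spec("zz")),
               "zz")
  ## two factors that are copies of each other are confounded
  ph2 <- herd$phenotypes
  ph2$breed <- ph2$sex
  expect_error(
    reml_design(ph2, herd$pedigree,
                model_spec("y", c("sex", "breed"))), "confounded")
})

test_that("BLUP solutions behave like BLUP", {
  herd <- small_gaussian_herd(seed = 12)
  comp <- c(0.52, 0.08, 0.87)
  sol <- solve_mme(herd$phenotypes, herd$pedigree, model_spec("y"), comp)
  expect_lte(sol$residual_rel, 1e-8)
  ## an unrelated founder with no record has EBV exactly 0
  ped_df <- as.data.frame(herd$pedigree)
  extra <- validate_pedigree(c(ped_df$animal, "LONER"),
                             c(ped_df$sire, NA), c(ped_df$dam, NA))
  sol2 <- solve_mme(herd$phenotypes, extra, model_spec("y"), comp)
  expect_equal(sol2$ebv$ebv[sol2$ebv$animal == "LONER"], 0)
  expect_false(sol2$ebv$with_own_record[sol2$ebv$animal == "LONER"])
  ## sigma2_a >> sigma2_e: EBV approaches the fixed-effect-corrected record
  solL <- solve_mme(herd$phenotypes, herd$pedigree, model_spec("y"),
                    c(1e6, 0.08, 0.87))
  dsg <- reml_design(herd$phenotypes, herd$pedigree, model_spec("y"))
  corrected <- dsg$y - as.vector(dsg$X %*% solL$fixef) -
    solL$litter_effects[match(herd$phenotypes$litter[
      match(dsg$animal, herd$phenotypes$animal)], names(solL$litter_effects))]
  ebv_rec <- solL$ebv$ebv[match(dsg$animal, solL$ebv$animal)]
  expect_gt(cor(ebv_rec, corrected), 0.999)
})

test_that("EBVs regress one-to-one on true breeding values", {
  cfg <- sim_config(n_sires = 31, n_dams = 135, litters_per_dam = 2,
                    litter_size_mean = 7.44, seed = 17,
                    traits = list(y = trait_sim_spec(0, 0.5, 0.1, 0.4,
                                                     "gaussian")))
  herd <- simulate_herd(cfg)
  sol <- solve_mme(herd$phenotypes, herd$pedigree, model_spec("y"),
                   c(0.5, 0.1, 0.4))
  tb <- herd$truth$y$breeding_values[match(sol$ebv$animal,
                                           herd$pedigree$animal)]
  slope <- coef(lm(tb ~ sol$ebv$ebv))[2]
  expect_lt(abs(slope - 1), 0.1)
})

test_that("bivariate REML: self-pair, independence and correlated recovery", {
  herd <- small_gaussian_herd(seed = 19, n_sires = 8, n_dams = 30,
                              litter_size_mean = 7)
  ph <- herd$phenotypes
  ph$y2 <- ph$y
  self <- fit_bivariate(ph, herd$pedigree, model_spec("y"),
                        model_spec("y2", study_fixed("y")), se = FALSE)
  expect_gt(self$r_g, 0.98)
  expect_gt(self$r_p, 0.98)

  rg <- replicate(4, NA_real_)
  rg0 <- replicate(4, NA_real_)
  for (s in 1:4) {
    cfg <- sim_config(n_sires = 10, n_dams = 60, litter_size_mean = 6,
                      seed = 100 + s)
    spec_a <- trait_sim_spec(0, 0.45, 0.1, 0.9, "gaussian")
    spec_b <- trait_sim_spec(0, 0.45, 0.1, 0.9, "gaussian")
    pair <- simulate_trait_pair(cfg, spec_a, spec_b, r_g = 0.8)
    fit <- fit_bivariate(pair$phenotypes, pair$pedigree,
                         model_spec("t1", c("sex", "breed")),
                         model_spec("t2", c("sex", "breed")), se = FALSE)
    rg[s] <- fit$r_g
    pair0 <- simulate_trait_pair(cfg, spec_a, spec_b, r_g = 0)
    fit0 <- fit_bivariate(pair0$phenotypes, pair0$pedigree,
                          model_spec("t1", c("sex", "breed")),
                          model_spec("t2", c("sex", "breed")), se = FALSE)
    rg0[s] <- fit0$r_g
  }
  expect_lt(abs(mean(rg) - 0.8), 0.15)
  expect_lt(abs(mean(rg0)), 0.25)
  expect_true(all(abs(c(rg, rg0)) <= 1))
})
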