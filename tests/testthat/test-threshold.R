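test_that("study recoding schemes reproduce the published cut-points", {
  inj <- study_recoding("INJ")
  expect_equal(recode_binary(c(1, 2, 3, 4), inj, "INJ"), c(0L, 0L, 1L, 1L))
  bt <- study_recoding("BT2")
  expect_equal(recode_binary(c(0, 2, 3, 9), bt, "BT2"), c(0L, 0L, 1L, 1L))
  ls <- study_recoding("LS1")
  expect_equal(recode_binary(c(1, 4), ls, "LS1"), c(0L, 1L))
  scale <- study_recoding("FSS")
  expect_equal(recode_binary(1:3, scale, "FSS"), c(0L, 1L, 1L))
  ## missing stays missing; out-of-support values are named errors
  expect_equal(recode_binary(c(2, NA, 3), inj, "INJ"), c(0L, NA, 1L))
  expect_error(recode_binary(5, inj, "INJ"), "5.*INJ")
  ## schemes are order-preserving by construction
  expect_error(recoding_scheme(1:3, cut = 4), "single category")
})

test_that("recoding schemes round-trip through key-value text", {
  sch <- study_recoding("BT1")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_recoding(sch, path)
  back <- read_recoding(path)
  expect_identical(unname(back), unname(sch))
  expect_identical(names(back), names(sch))
  bad <- withr::local_tempfile(lines = c("'1': 1", "'2': 0"))
  expect_error(read_recoding(bad), "order-preserving")
})

test_that("median split balances the two classes", {
  scores <- c(rep(1, 40), rep(2, 35), rep(3, 25))
  sch <- median_split(scores)
  expect_equal(unname(sch), c(0L, 1L, 1L))
  p <- mean(recode_binary(scores, sch))
  expect_lt(abs(p - 0.5), 0.25)
})

test_that("the threshold residual is the logistic variance pi^2/3", {
  expect_identical(LOGIT_RESIDUAL_VARIANCE, pi^2 / 3)
  expect_equal(round(LOGIT_RESIDUAL_VARIANCE, 2), 3.29)
  ## liability heritability uses it, never an estimate
  expect_equal(liability_heritability(0.47, 0.11),
               0.47 / (0.47 + 0.11 + pi^2 / 3))
  expect_equal(liability_heritability(0, 5), 0)
  ## monotone increasing in sigma2_a, decreasing in sigma2_pe
  a <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(liability_heritability(a, 0.3)) > 0))
  expect_true(all(diff(liability_heritability(0.5, a)) < 0))
})

test_that("recoding is invariant to monotone relabelling preserving the cut", {
  scores <- sample(1:4, 100, replace = TRUE)
  sch <- recoding_scheme(1:4, cut = 3)
  relabelled <- c(10, 20, 30, 40)[scores] # strictly monotone relabelling
  sch2 <- recoding_scheme(c(10, 20, 30, 40), cut = 30)
  expect_identical(recode_binary(scores, sch),
                   recode_binary(relabelled, sch2))
})

test_that("the Laplace logit fit recovers liability components", {
  herd <- binary_liability_herd(seed = 11, n_sires = 15, n_dams = 60,
                                litter_size_mean = 7)
  fit <- fit_binary(herd$phenotypes, herd$pedigree,
                    model_spec("yb", c("sex", "breed")))
  expect_true(fit$converged)
  expect_equal(fit$residual, pi^2 / 3)
  truth <- 1 / (1.3 + pi^2 / 3)
  expect_lt(abs(fit$h2 - truth), 0.17) # one replicate at n ~ 800
  expect_true(all(fit$se >= 0 | is.na(fit$se)))
  expect_equal(nrow(fit$ebv), nrow(herd$pedigree))
})

test_that("no genetic signal drives sigma2_a to the boundary", {
  ## binary data with litter structure only
  cfg <- sim_config(n_sires = 10, n_dams = 60, litter_size_mean = 7,
                    generation_depth = 0, seed = 23,
                    traits = list(yb = trait_sim_spec(
                      0, 0, 0.3, LOGIT_RESIDUAL_VARIANCE, "gaussian",
                      residual = "logistic")))
  herd <- simulate_herd(cfg)
  herd$phenotypes$yb <- as.integer(herd$phenotypes$yb > 0)
  fit <- fit_binary(herd$phenotypes, herd$pedigree,
                    model_spec("yb", c("sex", "breed")), se = FALSE)
  expect_lt(liability_heritability(fit), 0.06)

  ## single-category trait is a degenerate input
  herd$phenotypes$yb <- 1L
  expect_error(fit_binary(herd$phenotypes, herd$pedigree,
                          model_spec("yb", c("sex", "breed"))),
               "single response|constant")
})

test_that("the Gibbs reference sampler produces coherent posteriors", {
  herd <- binary_liability_herd(seed = 31, n_sires = 5, n_dams = 18,
                                litters_per_dam = 1, litter_size_mean = 6)
  g <- gibbs_threshold(herd$phenotypes, herd$pedigree,
                       model_spec("yb", c("sex", "breed")),
                       n_iter = 600, burnin = 200, seed = 7)
  expect_true(all(g$h2 >= 0 & g$h2 <= 1))
  expect_true(all(g$sigma2_a > 0))
  expect_true(is.finite(g$estimate["h2"]))
  expect_gt(g$h2_mcse, 0)
})
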