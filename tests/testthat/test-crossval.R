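test_that("fold construction is balanced, exhaustive and reproducible", {
  ids <- sprintf("P%04d", 1:1004)
  f <- make_folds(ids, 4, seed = 2)
  expect_equal(unname(table(f)), rep(251L, 4), ignore_attr = TRUE)
  expect_setequal(names(f), ids)
  expect_identical(f, make_folds(ids, 4, seed = 2))
  expect_false(identical(f, make_folds(ids, 4, seed = 3)))

  f2 <- make_folds(letters[1:5], 2, seed = 1)
  expect_equal(as.integer(sort(table(f2))), c(2L, 3L))
  expect_error(make_folds(letters[1:3], 5), "exceeds")
  expect_error(make_folds(letters[1:3], 1), "at least 2")
})

test_that("cross-validation bookkeeping is sound for both model families", {
  herd <- binary_liability_herd(seed = 41, n_sires = 8, n_dams = 30,
                                litters_per_dam = 1, litter_size_mean = 6)
  plan <- crossval_plan("yb", k = 3, repeats = 2,
                        models = c("gaussian", "logit"), seed = 5)
  cv <- run_crossval(herd$phenotypes, herd$pedigree, plan,
                     spec = model_spec("yb", c("sex", "breed")))
  expect_equal(nrow(cv$folds), 2 * 3 * 2)
  expect_true(all(abs(cv$folds$r) <= 1, na.rm = TRUE))
  for (m in c("gaussian", "logit")) {
    raw <- cv$folds$r[cv$folds$model == m]
    expect_equal(cv$summary$mean_r[cv$summary$model == m],
                 mean(raw, na.rm = TRUE))
    expect_equal(cv$summary$sd_r[cv$summary$model == m],
                 sd(raw, na.rm = TRUE))
  }
})

test_that("masked animals keep pedigree-predicted breeding values", {
  herd <- small_gaussian_herd(seed = 43)
  folds <- make_folds(herd$phenotypes$animal, 4, seed = 1)
  fold_ids <- names(folds)[folds == 1]
  train <- herd$phenotypes
  train$y[train$animal %in% fold_ids] <- NA
  sol <- solve_mme(train, herd$pedigree, model_spec("y"),
                   c(0.52, 0.08, 0.87))
  expect_true(all(fold_ids %in% sol$ebv$animal))
  masked_ebv <- sol$ebv$ebv[sol$ebv$animal %in% fold_ids]
  expect_true(any(masked_ebv != 0)) # informed by relatives, not dropped
  expect_false(any(sol$ebv$with_own_record[sol$ebv$animal %in% fold_ids]))
})

test_that("per-fold component re-estimation is available as a switch", {
  herd <- small_gaussian_herd(seed = 44, n_sires = 5, n_dams = 14,
                              litter_size_mean = 5)
  plan <- crossval_plan("y", k = 2, repeats = 1, models = "gaussian",
                        seed = 3, refit_components = TRUE)
  cv <- run_crossval(herd$phenotypes, herd$pedigree, plan)
  expect_equal(sum(!is.na(cv$folds$r)), 2)
  expect_true(all(abs(cv$folds$r) <= 1))
})
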