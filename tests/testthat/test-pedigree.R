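test_that("pedigree validation sorts parents first and adds implicit founders", {
  ped <- validate_pedigree(c("S", "D", "X"), c(NA, NA, "S"), c(NA, NA, "D"))
  expect_s3_class(ped, "pedigree")
  expect_equal(ped$animal, c("S", "D", "X"))

  ## offspring listed before its dam is reordered with the dam first
  ped2 <- validate_pedigree(c("X", "D", "S"), c("S", NA, NA), c("D", NA, NA))
  expect_lt(match("D", ped2$animal), match("X", ped2$animal))
  expect_lt(match("S", ped2$animal), match("X", ped2$animal))

  ## parents referenced but never listed become founder records
  ped3 <- validate_pedigree("X", "S", "D")
  expect_setequal(ped3$animal, c("S", "D", "X"))
  expect_true(all(is.na(ped3$sire[ped3$animal %in% c("S", "D")])))

  ## unknown-parent sentinels: empty string and "0" both mean founder
  ped4 <- validate_pedigree(c("A", "B"), c("", "0"), c("0", ""))
  expect_true(all(is.na(ped4$sire)) && all(is.na(ped4$dam)))
})

test_that("cycles and duplicate ids are rejected with informative errors", {
  expect_error(validate_pedigree("A", "A", NA), "cycle.*A")
  expect_error(
    validate_pedigree(c("A", "B"), c("B", "A"), c(NA, NA)), "cycle")
  expect_error(
    validate_pedigree(c("A", "A"), c(NA, NA), c(NA, NA)), "duplicate.*A")
})

test_that("tabular relationship matrix reproduces hand-derived cases", {
  founders <- validate_pedigree(c("F1", "F2", "F3"), rep(NA, 3), rep(NA, 3))
  expect_equal(unname(relationship_matrix(founders)), diag(3))

  ## parent-offspring with the other parent unknown
  po <- validate_pedigree(c("P", "X"), c(NA, "P"), c(NA, NA))
  A <- relationship_matrix(po)
  expect_equal(A["P", "X"], 0.5)
  expect_equal(unname(diag(A)), c(1, 1))

  ## two full sibs, and an offspring of the full-sib mating (F = 0.25)
  fs <- validate_pedigree(c("P1", "P2", "B1", "B2", "C"),
                          c(NA, NA, "P1", "P1", "B1"),
                          c(NA, NA, "P2", "P2", "B2"))
  A <- relationship_matrix(fs)
  expect_equal(A["B1", "B2"], 0.5)
  expect_equal(A["C", "C"], 1.25)
  expect_equal(unname(inbreeding(fs)["C"]), 0.25)
})

test_that("relationship inverse matches hand-derived trio and dense inversion", {
  trio <- validate_pedigree(c("S", "D", "X"), c(NA, NA, "S"), c(NA, NA, "D"))
  Ai <- as.matrix(relationship_inverse(trio))
  expect_equal(Ai["X", "X"], 2.0)
  expect_equal(Ai["X", "S"], -1.0)
  expect_equal(Ai["X", "D"], -1.0)
  expect_equal(Ai["S", "D"], 0.5)

  founders <- validate_pedigree(c("F1", "F2"), c(NA, NA), c(NA, NA))
  expect_equal(as.matrix(relationship_inverse(founders)), diag(2),
               ignore_attr = TRUE)

  ped <- random_pedigree(50, seed = 11)
  A <- relationship_matrix(ped)
  Ai <- relationship_inverse(ped)
  expect_lt(max(abs(as.matrix(Ai) - solve(A))), 1e-8)
  expect_lt(max(abs(as.matrix(Ai %*% A) - diag(nrow(ped)))), 1e-8)
})

test_that("tabular A agrees with the coancestry oracle and is PSD", {
  for (case in list(c(60, 10, 1), c(120, 15, 2), c(200, 20, 3))) {
    ped <- random_pedigree(case[1], case[2], seed = case[3])
    A <- relationship_matrix(ped)
    expect_lt(max(abs(A - kinship_oracle_matrix(ped))), 1e-12)
    expect_true(isSymmetric(A))
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    expect_true(all(diag(A) >= 1))
    expect_true(all(A >= 0))
    ## inverse consistency and log-determinant
    Ai <- relationship_inverse(ped)
    expect_lt(max(abs(as.matrix(Ai %*% A) - diag(nrow(ped)))), 1e-8)
    expect_equal(attr(Ai, "logdet"), determinant(A)$modulus[1],
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("pedigree files round-trip in both dialects", {
  ped <- random_pedigree(25, 8, seed = 5)
  for (sep in c(",", "\t")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_pedigree(ped, path, sep = sep)
    back <- read_pedigree(path)
    expect_equal(as.data.frame(back)[, c("animal", "sire", "dam")],
                 as.data.frame(ped)[, c("animal", "sire", "dam")])
  }
  expect_error(read_pedigree(withr::local_tempfile(lines = "a,b,c\n1,2,3")),
               "animal, sire, dam")
})
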