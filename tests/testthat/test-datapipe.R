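# ee <-> ddG conversion, aggregation, database I/O, preprocessing, splits.

test_that("ee to ddG conversion matches the closed form", {
  # 95 % ee at 0 C: the trans-class median equivalence
  expect_equal(eeToDdg(0.95), 1.99, tolerance = 0.01 / 1.99)
  expect_identical(eeToDdg(0), 0)
  # high-precision closed-form value at 50 % ee
  expect_equal(eeToDdg(0.50), 1.987204e-3 * 273.15 * log(3),
               tolerance = 1e-12)
  expect_equal(eeToDdg(0.50), 0.59632, tolerance = 1e-4)
  # strictly increasing
  ee <- seq(0, 0.999, length.out = 200)
  expect_true(all(diff(eeToDdg(ee)) > 0))
  expect_error(eeToDdg(1), "diverges")
  expect_error(eeToDdg(-0.1), "\\[0, 1\\)")
})

test_that("conversion round-trips to 1e-12 relative error", {
  ee <- seq(0, 0.999, length.out = 500)
  back <- ddgToEe(eeToDdg(ee))
  expect_lt(max(abs(back - ee)), 1e-12)
})

test_that("alpha/beta aggregation is the mean of magnitudes", {
  expect_identical(aggregatePair(1, 2)$ddg_kcal, 1.5)
  expect_identical(aggregatePair(0.7, 0.7)$ddg_kcal, 0.7)
  expect_identical(aggregatePair(1, 2)$ddg_kcal,
                   aggregatePair(2, 1)$ddg_kcal)   # commutative
  expect_identical(aggregatePair(1, 2)$source, "averaged-pair")
  # closed-form per-mix then mean: alpha 90 % ee, beta 94 % ee at 0 C
  got <- aggregatePair(eeToDdg(0.90), eeToDdg(0.94))$ddg_kcal
  expect_equal(got, mean(c(1.987204e-3 * 273.15 * log(1.9 / 0.1),
                           1.987204e-3 * 273.15 * log(1.94 / 0.06))),
               tolerance = 1e-12)
})

test_that("database reading canonicalizes, deduplicates and rejects", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "reactant_smiles,product_smiles,ad_mix,ee_percent",
    "C=Cc1ccccc1,OC[C@H](O)c1ccccc1,alpha,95",
    "C(=C)c1ccccc1,OC[C@H](O)c1ccccc1,alpha,95",   # same after canonicalization
    "C/C=C/C,,beta,80",
    "C=CC,,alpha,101",                              # out of range
    "C=CCC,,gamma,50"                               # bad ad_mix
  ), path)
  db <- readDatabase(path)
  expect_identical(nrow(db$records), 2L)
  expect_identical(nrow(db$duplicates), 1L)
  expect_identical(nrow(db$rejected), 2L)
  expect_true(any(grepl("ee_percent", db$rejected$reason)))
  expect_identical(db$records$reactant_smiles[1], "C=Cc1ccccc1")
  expect_equal(db$records$ddg_kcal[1], eeToDdg(0.95), tolerance = 1e-12)
  # round trip: writing and re-reading reproduces the records
  path2 <- tempfile(fileext = ".csv")
  write.csv(db$records[, setdiff(names(db$records), "ddg_kcal")], path2,
            row.names = FALSE)
  db2 <- readDatabase(path2)
  expect_identical(db2$records$reactant_smiles, db$records$reactant_smiles)
  expect_identical(db2$records$ee_percent, db$records$ee_percent)
  # schema violations are fatal
  path3 <- tempfile(fileext = ".csv")
  writeLines(c("reactant_smiles,ad_mix,ee_percent,bogus",
               "C=CC,alpha,50,1"), path3)
  expect_error(readDatabase(path3), "unknown database column")
})

test_that("preprocessing scales, filters correlation, and reapplies", {
  set.seed(10)
  X <- matrix(rnorm(500 * 6), 500,
              dimnames = list(NULL, paste0("f", 1:6)))
  X <- cbind(X, dup = X[, 1], const = 7)   # exact duplicate + zero variance
  colnames(X)[7:8] <- c("dup", "const")
  pp <- preprocessFeatures(X)
  expect_identical(pp$transform$dropped_zero_var, "const")
  expect_identical(pp$transform$dropped_correlated, "dup")  # keeps f1
  expect_identical(pp$transform$keep, paste0("f", 1:6))
  # independent random columns survive a 0.95 threshold
  expect_identical(ncol(pp$X), 6L)
  # reapplication reproduces zero mean / unit variance
  Z <- applyPreprocess(X, pp$transform)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-9)
  expect_identical(Z, pp$X)
  expect_error(applyPreprocess(X[, 1:3], pp$transform), "missing")
})

test_that("splits are stratified, exhaustive and seed-deterministic", {
  classes <- rep("Mono", 10)
  s1 <- splitData(classes, seed = 4)
  expect_identical(length(s1$train), 8L)
  expect_identical(length(s1$test), 2L)
  expect_identical(sort(c(s1$train, s1$test)), 1:10)
  expect_identical(splitData(classes, seed = 4), s1)
  expect_false(identical(splitData(classes, seed = 5), s1))
  # the cis-sized case: 41 records -> 33/8 under round()
  s41 <- splitData(rep("Cis", 41), seed = 1)
  expect_identical(length(s41$train), 33L)
  expect_identical(length(s41$test), 8L)
  # stratification: per-class proportions are preserved
  cls <- c(rep("Mono", 20), rep("Tetra", 10))
  sp <- splitData(cls, seed = 2)
  expect_identical(sum(cls[sp$train] == "Mono"), 16L)
  expect_identical(sum(cls[sp$train] == "Tetra"), 8L)
  expect_warning(splitData(c(rep("Mono", 8), rep("Cis", 2)), seed = 1),
                 "only")
  expect_error(splitData(rep("Mono", 4)), "at least 5")
})
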