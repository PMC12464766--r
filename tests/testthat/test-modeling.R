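# Q2F3 metric suite, estimator registry, search, CV and SHAP attribution.

test_that("Q2F3 matches hand-computed fixtures", {
  # PRESS = 0.5 over 2, TSS = 5 over 4: 1 - 0.25/1.25
  expect_identical(q2f3(c(0, 1, 2, 3), c(1, 2), c(1.5, 2.5)), 0.8)
  expect_identical(q2f3(c(0, 1, 2), c(1, 2), c(1, 2)), 1)   # perfect
  # translation invariance (not general affine invariance)
  expect_equal(q2f3(c(0, 1, 2, 3) + 5, c(1, 2) + 5, c(1.5, 2.5) + 5), 0.8,
               tolerance = 1e-12)
  expect_error(q2f3(rep(1, 4), c(1, 2), c(1, 2)), "constant")
})

test_that("predicting the training mean scores near zero in expectation", {
  set.seed(31)
  n <- 1e4
  y_train <- rnorm(n, 2, 0.7)
  y_test <- rnorm(n, 2, 0.7)
  q <- q2f3(y_train, y_test, rep(mean(y_train), n))
  expect_lt(abs(q), 0.05)
})

test_that("the estimator registry is complete and extensible", {
  expect_true(all(c("gbr", "rf", "gpr", "svr", "ridge", "lasso") %in%
                    estimatorKinds()))
  expect_error(crossValidate(matrix(1:20, 10), rnorm(10), kind = "nope"),
               "unknown estimator")
  expect_identical(defaultEstimatorFor("Trans"), "rf")
  expect_identical(defaultEstimatorFor("Tetra"), "gpr")
  expect_identical(defaultEstimatorFor("Mono"), "gbr")
})

test_that("cross-validation is fold-deterministic; noise gives q2 <= 0", {
  fx <- fx_regression()
  cv1 <- crossValidate(fx$X, fx$y, kind = "ridge",
                       params = list(log_lambda = -4), seed = 3)
  cv2 <- crossValidate(fx$X, fx$y, kind = "ridge",
                       params = list(log_lambda = -4), seed = 3)
  expect_identical(cv1, cv2)
  expect_gt(cv1$q2, 0.5)   # informative target is learnable
  # pure-noise targets: out-of-fold q2 is non-positive in expectation
  set.seed(77)
  qs <- replicate(40, {
    yn <- rnorm(60)
    Xn <- matrix(rnorm(60 * 5), 60, dimnames = list(NULL, paste0("g", 1:5)))
    crossValidate(Xn, yn, kind = "ridge",
                  params = list(log_lambda = -6), seed = 11)$q2
  })
  expect_lt(mean(qs), 0)
  # LOO mode equals n folds
  cvl <- crossValidate(fx$X[1:20, ], fx$y[1:20], kind = "ridge",
                       params = list(log_lambda = -4), mode = "loo")
  expect_length(cvl$oof, 20L)
})

test_that("model fitting is seed-deterministic and recovers structure", {
  fx <- fx_regression()
  b1 <- fitClassModel(fx$X, fx$y, alkeneClass = "Mono", nRandom = 5,
                      nBayes = 2, seed = 6)
  b2 <- fitClassModel(fx$X, fx$y, alkeneClass = "Mono", nRandom = 5,
                      nBayes = 2, seed = 6)
  expect_identical(b1@manifest$best_params, b2@manifest$best_params)
  expect_identical(predictBundle(b1, fx$X), predictBundle(b2, fx$X))
  expect_identical(b1@estimatorKind, "gbr")
  expect_length(b1@manifest$trace, 7L)
  # a noiseless linear target is interpolated on the training set
  set.seed(8)
  Xl <- matrix(rnorm(200 * 5), 200, dimnames = list(NULL, paste0("f", 1:5)))
  yl <- 1 + 0.9 * Xl[, 1] - 0.6 * Xl[, 2]
  bl <- fitClassModel(Xl, yl, alkeneClass = "Mono", nRandom = 14,
                      nBayes = 6, seed = 2)
  expect_lt(mean(abs(yl - predictBundle(bl, Xl))), 0.05)
  # constant targets are refused by the metric, not the fit
  expect_error(fitClassModel(Xl[1:5, ], yl[1:5]), "at least 10")
  expect_error(fitClassModel(Xl, yl, nRandom = 0), "budget")
})

test_that("evaluation separates r2 from R2 and fills the report", {
  fx <- fx_regression()
  idx <- splitData(rep("Mono", nrow(fx$X)), seed = 1)
  b <- fitClassModel(fx$X[idx$train, ], fx$y[idx$train], nRandom = 6,
                     nBayes = 2, seed = 4)
  rep <- evaluateModel(b, fx$X[idx$train, ], fx$y[idx$train],
                       fx$X[idx$test, ], fx$y[idx$test])
  expect_true(all(c("train_R2", "test_r2", "q2f3", "mae_train", "mae_test",
                    "n_train", "n_test") %in% names(rep)))
  expect_lte(rep$q2f3, 1)
  expect_gte(rep$mae_test, 0)
  # a constant shift leaves r2 at 1 but lowers R2: check the definitions
  # directly on predictions
  obs <- fx$y[idx$test]
  shifted <- obs + 0.5
  expect_equal(cor(obs, shifted)^2, 1, tolerance = 1e-12)
  expect_lt(1 - sum((obs - shifted)^2) / sum((obs - mean(obs))^2), 1)
})

test_that("attributions satisfy local accuracy for tree and kernel paths", {
  fx <- fx_regression()
  b <- fitClassModel(fx$X, fx$y, nRandom = 5, nBayes = 1, seed = 3)
  for (r in c(1, 7, 33)) {
    att <- attributePrediction(b, fx$X[r, ], fx$X)
    expect_lt(abs(att@baseValue + sum(att@contributions) - att@prediction),
              1e-6)
    expect_equal(att@prediction, predictBundle(b, fx$X[r, , drop = FALSE]),
                 tolerance = 1e-5)
  }
  # kernel path (non-tree estimator) keeps the same exact contract
  bs <- fitClassModel(fx$X, fx$y, kind = "svr", nRandom = 3, nBayes = 1,
                      seed = 3)
  att <- attributePrediction(bs, fx$X[2, ], fx$X[1:40, ], nsamples = 300,
                             seed = 5)
  expect_lt(abs(att@baseValue + sum(att@contributions) - att@prediction),
            1e-6)
  expect_error(attributePrediction(b, fx$X[1, 1:3], fx$X), "missing")
})

test_that("a single informative feature carries the attribution mass", {
  set.seed(12)
  X <- matrix(rnorm(150 * 4), 150, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 2 + 1.5 * X[, 2]
  b <- fitClassModel(X, y, kind = "lasso", nRandom = 10, nBayes = 4,
                     seed = 9)
  att <- attributeSet(b, X[1:25, ], X, nsamples = 400)
  phi <- do.call(rbind, lapply(att, shapContributions))
  mass <- colSums(abs(phi))
  expect_gte(mass[["f2"]] / sum(mass), 0.95)
})

test_that("duplicated features split Shapley credit symmetrically", {
  # direct check on the kernel engine: f(x) = x1 + x2 with x2 == x1
  f <- function(Xm) Xm[, 1] + Xm[, 2]
  set.seed(3)
  bg <- matrix(rnorm(80), 40, 2)
  bg[, 2] <- bg[, 1]
  res <- ADquadrant:::.kernelShap(f, x = c(1.3, 1.3), background = bg,
                                  nsamples = 500, seed = 2)
  expect_equal(res$phi[1], res$phi[2], tolerance = 0.05)
  expect_equal(sum(res$phi), res$prediction - res$base, tolerance = 1e-9)
})

test_that("beeswarm export ranks deterministically", {
  fx <- fx_regression()
  b <- fitClassModel(fx$X, fx$y, nRandom = 5, nBayes = 1, seed = 3)
  att <- attributeSet(b, fx$X[1:20, ], fx$X)
  e1 <- beeswarmExport(att, fx$X[1:20, ], topK = 5)
  e2 <- beeswarmExport(att, fx$X[1:20, ], topK = 5)
  expect_identical(e1$table, e2$table)
  expect_lte(nrow(e1$table), 5L)
  expect_true(all(diff(e1$table$mean_abs_shap) <= 0))
  expect_warning(beeswarmExport(att, topK = 100L), "clipped")
  # all-zero contributions produce an empty ranking
  z <- new("Attribution", baseValue = 1,
           contributions = c(a = 0, b = 0), prediction = 1)
  e0 <- beeswarmExport(list(z, z), topK = 2)
  expect_identical(nrow(e0$table), 0L)
})
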