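# Per-class regression modeling: estimator registry, the Q2F3 metric suite,
# cross-validation, and randomized + Bayesian hyperparameter search.

#' Q2F3 external-validation metric
#'
#' \code{1 - (PRESS / n_EXT) / (TSS / n_TR)} with PRESS the predicted
#' residual sum of squares on the external (test) set and TSS the total sum
#' of squares of the training targets around their mean. Robust to test-set
#' size and distribution, and bounded above by 1.
#'
#' @param y_train numeric training targets.
#' @param y_test numeric test targets.
#' @param y_pred_test predictions for \code{y_test}.
#' @return the Q2F3 value.
#' @examples
#' q2f3(c(0, 1, 2, 3), c(1, 2), c(1.5, 2.5))   # 0.8
#' @export
q2f3 <- function(y_train, y_test, y_pred_test) {
  stopifnot(length(y_test) == length(y_pred_test),
            length(y_train) > 0, length(y_test) > 0)
  tss <- sum((y_train - mean(y_train))^2)
  if (tss < 1e-12)
    stop("Q2F3 undefined: training target is constant (zero TSS)",
         call. = FALSE)
  press <- sum((y_test - y_pred_test)^2)
  1 - (press / length(y_test)) / (tss / length(y_train))
}

# ---- estimator registry -----------------------------------------------------

.estimatorRegistry <- new.env(parent = emptyenv())

#' Estimator registry
#'
#' Thin adapters around established regression learners. Each entry
#' provides a documented hyperparameter space (\code{sample} draws one
#' random configuration; \code{bounds} gives box constraints for Bayesian
#' refinement), a \code{fit(X, y, params, seed)} and a
#' \code{predict(fit, X)}. Registered kinds: "gbr" (gradient boosting,
#' xgboost), "rf" (random forest), "gpr" (Gaussian process, kernlab),
#' "svr" (support vector regression, e1071), "ridge" and "lasso" (glmnet).
#'
#' @return \code{estimatorKinds()}: names of registered estimators.
#' @export
estimatorKinds <- function() sort(ls(.estimatorRegistry))

#' @rdname estimatorKinds
#' @param kind estimator name.
#' @param spec list with \code{sample}, \code{bounds}, \code{fit},
#'   \code{predict}.
#' @export
registerEstimator <- function(kind, spec) {
  stopifnot(is.character(kind), length(kind) == 1L,
            all(c("sample", "bounds", "fit", "predict") %in% names(spec)))
  assign(kind, spec, envir = .estimatorRegistry)
  invisible(kind)
}

.getEstimator <- function(kind) {
  if (!exists(kind, envir = .estimatorRegistry, inherits = FALSE))
    stop("unknown estimator kind '", kind, "'; registered: ",
         paste(estimatorKinds(), collapse = ", "), call. = FALSE)
  get(kind, envir = .estimatorRegistry)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

registerEstimator("gbr", list(
  bounds = list(eta = c(0.02, 0.5), max_depth = c(1, 6),
                nrounds = c(50, 600), subsample = c(0.5, 1),
                colsample_bytree = c(0.4, 1), min_child_weight = c(1, 8)),
  sample = function() list(
    eta = stats::runif(1, 0.02, 0.5),
    max_depth = sample(1:6, 1),
    nrounds = sample(50:600, 1),
    subsample = stats::runif(1, 0.5, 1),
    colsample_bytree = stats::runif(1, 0.4, 1),
    min_child_weight = stats::runif(1, 1, 8)),
  fit = function(X, y, params, seed) {
    xgboost::xgboost(
      x = X, y = y, nrounds = as.integer(round(params$nrounds)),
      learning_rate = params$eta,
      max_depth = as.integer(round(params$max_depth)),
      subsample = params$subsample,
      colsample_bytree = params$colsample_bytree,
      min_child_weight = params$min_child_weight,
      objective = "reg:squarederror",
      nthreads = 1, seed = seed, verbosity = 0)
  },
  predict = function(fit, X) stats::predict(fit, X)
))

registerEstimator("rf", list(
  bounds = list(mtry_frac = c(0.1, 1), ntree = c(100, 800),
                nodesize = c(1, 10)),
  sample = function() list(
    mtry_frac = stats::runif(1, 0.1, 1),
    ntree = sample(100:800, 1),
    nodesize = sample(1:10, 1)),
  fit = function(X, y, params, seed) {
    .withSeed(seed, randomForest::randomForest(
      x = X, y = y,
      mtry = max(1L, as.integer(round(params$mtry_frac * ncol(X)))),
      ntree = as.integer(round(params$ntree)),
      nodesize = as.integer(round(params$nodesize))))
  },
  predict = function(fit, X) unname(stats::predict(fit, X))
))

registerEstimator("gpr", list(
  bounds = list(log_sigma = c(-4, 2), log_var = c(-6, 0)),
  sample = function() list(
    log_sigma = stats::runif(1, -4, 2),
    log_var = stats::runif(1, -6, 0)),
  fit = function(X, y, params, seed) {
    .withSeed(seed, kernlab::gausspr(
      x = X, y = y, kernel = "rbfdot",
      kpar = list(sigma = exp(params$log_sigma)),
      var = exp(params$log_var), scaled = FALSE))
  },
  predict = function(fit, X) drop(stats::predict(fit, X))
))

registerEstimator("svr", list(
  bounds = list(log_cost = c(-3, 5), log_gamma = c(-7, 1),
                epsilon = c(0.01, 0.4)),
  sample = function() list(
    log_cost = stats::runif(1, -3, 5),
    log_gamma = stats::runif(1, -7, 1),
    epsilon = stats::runif(1, 0.01, 0.4)),
  fit = function(X, y, params, seed) {
    e1071::svm(x = X, y = y, type = "eps-regression",
               cost = exp(params$log_cost), gamma = exp(params$log_gamma),
               epsilon = params$epsilon)
  },
  predict = function(fit, X) unname(stats::predict(fit, X))
))

.glmnetSpec <- function(alpha) list(
  bounds = list(log_lambda = c(-8, 2)),
  sample = function() list(log_lambda = stats::runif(1, -8, 2)),
  fit = function(X, y, params, seed) {
    glmnet::glmnet(X, y, alpha = alpha, lambda = exp(params$log_lambda))
  },
  predict = function(fit, X) drop(stats::predict(fit, X))
)
registerEstimator("ridge", .glmnetSpec(0))
registerEstimator("lasso", .glmnetSpec(1))

#' Default estimator kind for an alkene class
#'
#' Gradient boosting for every class except Trans (random forest) and
#' Tetra (Gaussian process), the per-class architectures that emerged from
#' model screening.
#'
#' @param alkeneClass class label.
#' @return estimator kind string.
#' @export
defaultEstimatorFor <- function(alkeneClass) {
  switch(alkeneClass, Trans = "rf", Tetra = "gpr", "gbr")
}

# ---- cross-validation -------------------------------------------------------

.foldAssignment <- function(n, folds, seed) {
  .withSeed(seed, sample(rep(seq_len(folds), length.out = n)))
}

.cvScore <- function(X, y, kind, params, folds, seed) {
  est <- .getEstimator(kind)
  fold <- .foldAssignment(length(y), folds, seed)
  preds <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- est$fit(X[tr, , drop = FALSE], y[tr], params, seed + f)
    preds[!tr] <- est$predict(fit, X[!tr, , drop = FALSE])
  }
  list(mae = mean(abs(y - preds)),
       q2 = 1 - sum((y - preds)^2) / sum((y - mean(y))^2),
       oof = preds)
}

#' Cross-validated q2 of a model configuration
#'
#' Assembles out-of-fold predictions under seed-deterministic fold
#' assignment and returns \code{q2 = 1 - SS_res / SS_tot}. \code{mode}
#' "loo" uses leave-one-out (with a cost warning above 500 records).
#'
#' @param X preprocessed feature matrix.
#' @param y targets (kcal/mol).
#' @param kind estimator kind.
#' @param params hyperparameter list for the estimator (defaults drawn from
#'   a seeded sample if NULL).
#' @param mode "5-fold" or "loo".
#' @param seed integer seed.
#' @return list: \code{q2}, \code{mae}, \code{oof} (out-of-fold
#'   predictions).
#' @export
crossValidate <- function(X, y, kind = "gbr", params = NULL,
                          mode = c("5-fold", "loo"), seed = 1L) {
  mode <- match.arg(mode)
  folds <- if (mode == "loo") length(y) else 5L
  if (length(y) < folds) stop("need at least ", folds, " records", call. = FALSE)
  if (mode == "loo" && length(y) > 500L)
    warning("leave-one-out on ", length(y), " records is expensive",
            call. = FALSE)
  if (is.null(params)) params <- .withSeed(seed, .getEstimator(kind)$sample())
  .cvScore(X, y, kind, params, folds, seed)
}

# ---- hyperparameter search --------------------------------------------------

.paramsToUnit <- function(params, bounds) {
  vapply(names(bounds), function(nm) {
    b <- bounds[[nm]]
    (as.numeric(params[[nm]]) - b[1]) / (b[2] - b[1])
  }, numeric(1))
}

.unitToParams <- function(u, bounds) {
  out <- lapply(seq_along(bounds), function(k) {
    b <- bounds[[k]]
    b[1] + .clamp(u[k], 0, 1) * (b[2] - b[1])
  })
  names(out) <- names(bounds)
  out
}

# expected improvement of candidate points under a GP surrogate fitted to
# the (unit-scaled params -> CV MAE) evaluations
.eiPropose <- function(evals, bounds, n_cand, seed) {
  U <- do.call(rbind, lapply(evals, function(e) e$unit))
  yv <- vapply(evals, function(e) e$score, numeric(1))
  best <- min(yv)
  cand <- .withSeed(seed, matrix(stats::runif(n_cand * ncol(U)), n_cand))
  gp <- tryCatch(
    .withSeed(seed, kernlab::gausspr(x = U, y = yv, kernel = "rbfdot",
                                     kpar = list(sigma = 1), var = 1e-4,
                                     variance.model = TRUE, scaled = FALSE)),
    error = function(e) NULL)
  if (is.null(gp)) return(cand[1, ])
  mu <- drop(stats::predict(gp, cand))
  sdv <- tryCatch(drop(stats::predict(gp, cand, type = "sdeviation")),
                  error = function(e) rep(1e-3, nrow(cand)))
  sdv <- pmax(sdv, 1e-9)
  z <- (best - mu) / sdv
  ei <- sdv * (z * stats::pnorm(z) + stats::dnorm(z))
  cand[which.max(ei), ]
}

#' Fit a per-class selectivity model with staged hyperparameter search
#'
#' Runs a randomized search over the estimator's documented hyperparameter
#' space, then Bayesian (expected-improvement) refinement, both scored by
#' 5-fold cross-validated MAE with seed-controlled fold assignment, and
#' refits the best configuration on the full training partition. The full
#' search trace is kept in the manifest, so runs are auditable and
#' reproducible.
#'
#' @param X raw (unscaled) training feature matrix with the canonical
#'   columns.
#' @param y training targets, ddG magnitudes in kcal/mol.
#' @param alkeneClass class label for the bundle (also picks the default
#'   estimator kind).
#' @param kind estimator kind; default per \code{\link{defaultEstimatorFor}}.
#' @param nRandom randomized-search iterations (default 50).
#' @param nBayes Bayesian refinement iterations (default 25).
#' @param folds CV folds (default 5).
#' @param seed integer seed.
#' @param corThreshold correlation-filter threshold for preprocessing.
#' @return a \linkS4class{ModelBundle}.
#' @export
fitClassModel <- function(X, y, alkeneClass = "Mono", kind = NULL,
                          nRandom = 50L, nBayes = 25L, folds = 5L,
                          seed = 1L, corThreshold = 0.95) {
  if (length(y) < 10L) stop("need at least 10 training records", call. = FALSE)
  if (nRandom < 1L) stop("search budget must allow at least 1 iteration",
                         call. = FALSE)
  if (is.null(kind)) kind <- defaultEstimatorFor(alkeneClass)
  est <- .getEstimator(kind)
  prep <- preprocessFeatures(X, corThreshold = corThreshold)
  Xp <- prep$X
  evals <- list()
  for (i in seq_len(nRandom)) {
    params <- .withSeed(seed * 1000L + i, est$sample())
    sc <- .cvScore(Xp, y, kind, params, folds, seed)
    evals[[length(evals) + 1L]] <-
      list(params = params, unit = .paramsToUnit(params, est$bounds),
           score = sc$mae, stage = "random")
  }
  for (i in seq_len(nBayes)) {
    u <- .eiPropose(evals, est$bounds, n_cand = 256L, seed = seed * 2000L + i)
    params <- .unitToParams(u, est$bounds)
    sc <- .cvScore(Xp, y, kind, params, folds, seed)
    evals[[length(evals) + 1L]] <-
      list(params = params, unit = .paramsToUnit(params, est$bounds),
           score = sc$mae, stage = "bayes")
  }
  scores <- vapply(evals, `[[`, numeric(1), "score")
  best <- evals[[which.min(scores)]]
  fit <- est$fit(Xp, y, best$params, seed)
  new("ModelBundle",
      alkeneClass = alkeneClass,
      estimatorKind = kind,
      fit = fit,
      transform = prep$transform,
      manifest = list(seed = seed, folds = folds,
                      n_random = nRandom, n_bayes = nBayes,
                      best_params = best$params, best_cv_mae = min(scores),
                      trace = lapply(evals, function(e)
                        c(e$params, score = e$score, stage = e$stage)),
                      n_train = length(y)))
}

#' Predict ddG magnitudes with a fitted bundle
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param X raw feature matrix with the canonical columns.
#' @return numeric predictions in kcal/mol.
#' @export
predictBundle <- function(bundle, X) {
  est <- .getEstimator(bundle@estimatorKind)
  est$predict(bundle@fit, applyPreprocess(X, bundle@transform))
}

#' Metric suite for a fitted bundle
#'
#' Computes the evaluation metrics on train and test partitions: MAE,
#' coefficient of determination R2, squared Pearson correlation r2 (the
#' two are distinct: a constant shift leaves r2 at 1 but lowers R2), and
#' Q2F3 on the test set.
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param X_train,y_train training partition (raw features).
#' @param X_test,y_test test partition.
#' @return list (MetricReport): train_R2, test_r2, test_R2, q2f3,
#'   mae_train, mae_test, n_train, n_test.
#' @export
evaluateModel <- function(bundle, X_train, y_train, X_test, y_test) {
  pr_tr <- predictBundle(bundle, X_train)
  pr_te <- predictBundle(bundle, X_test)
  r2 <- function(obs, pred) {
    if (length(obs) < 2L || stats::sd(pred) < 1e-12) return(NA_real_)
    stats::cor(obs, pred)^2
  }
  R2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  if (length(y_test) < 2L)
    warning("fewer than 2 test records; r2 is omitted", call. = FALSE)
  list(train_R2 = R2(y_train, pr_tr),
       train_r2 = r2(y_train, pr_tr),
       test_R2 = R2(y_test, pr_te),
       test_r2 = r2(y_test, pr_te),
       q2f3 = q2f3(y_train, y_test, pr_te),
       mae_train = mean(abs(y_train - pr_tr)),
       mae_test = mean(abs(y_test - pr_te)),
       n_train = length(y_train), n_test = length(y_test))
}
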