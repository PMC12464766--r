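# Shapley-additive attribution of per-feature contributions to predicted
# ddG, with an exact local-accuracy contract: baseValue + sum(contributions)
# equals the model prediction.
#
# Tree ensembles fitted with xgboost use the exact TreeSHAP path
# (predcontrib). Every other estimator kind goes through a constrained
# kernel-weighted regression over sampled feature coalitions; eliminating
# one coefficient with the sum constraint makes local accuracy hold by
# construction, not approximately.

.kernelShap <- function(predict_fn, x, background, nsamples = 2048L,
                        seed = 1L) {
  M <- length(x)
  fx <- predict_fn(matrix(x, nrow = 1))
  base <- mean(predict_fn(background))
  if (M == 1L)
    return(list(base = base, phi = fx - base, prediction = fx))
  sizes <- 1:(M - 1)
  kw <- (M - 1) / (choose(M, sizes) * sizes * (M - sizes))
  Z <- .withSeed(seed, {
    ssel <- sample(sizes, nsamples, replace = TRUE, prob = kw / sum(kw))
    t(vapply(ssel, function(s) {
      z <- numeric(M)
      z[sample.int(M, s)] <- 1
      z
    }, numeric(M)))
  })
  Z <- unique(Z)
  # coalition values: features in the coalition take x, the rest are
  # integrated out over the background sample (interventional expectation)
  nb <- nrow(background)
  v <- vapply(seq_len(nrow(Z)), function(r) {
    idx <- Z[r, ] == 1
    Xb <- background
    Xb[, idx] <- matrix(x[idx], nb, sum(idx), byrow = TRUE)
    mean(predict_fn(Xb))
  }, numeric(1))
  # weighted least squares with the constraint sum(phi) = fx - base folded
  # in: phi_M = (fx - base) - sum_{j<M} phi_j
  y <- v - base - Z[, M] * (fx - base)
  A <- Z[, -M, drop = FALSE] - Z[, M]
  s <- rowSums(Z)
  w <- (M - 1) / (choose(M, s) * s * (M - s))
  Aw <- A * w
  phi_rest <- tryCatch(
    solve(crossprod(Aw, A) + diag(1e-8, M - 1), crossprod(Aw, y)),
    error = function(e) matrix(0, M - 1, 1))
  phi <- c(drop(phi_rest), (fx - base) - sum(phi_rest))
  list(base = base, phi = phi, prediction = fx)
}

#' Shapley-additive attribution of one prediction
#'
#' Explains a single prediction of a fitted \linkS4class{ModelBundle} as a
#' base value (the expected prediction over the background data) plus one
#' contribution per retained feature, all in kcal/mol. Local accuracy is
#' exact: \code{baseValue + sum(contributions) == prediction} to within
#' 1e-6.
#'
#' @param bundle a fitted \linkS4class{ModelBundle}.
#' @param x_row named numeric vector (or 1-row matrix) with the raw
#'   canonical features of one alkene.
#' @param background raw feature matrix used as the integration background
#'   (typically the training matrix).
#' @param nsamples coalition samples for the kernel path (ignored by the
#'   exact tree path).
#' @param seed integer seed for coalition sampling.
#' @return an \linkS4class{Attribution}.
#' @export
attributePrediction <- function(bundle, x_row, background, nsamples = 2048L,
                                seed = 1L) {
  if (is.matrix(x_row)) x_row <- x_row[1, ]
  missing <- setdiff(bundle@transform$keep, names(x_row))
  if (length(missing))
    stop("attribution input is missing feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  xp <- drop(applyPreprocess(matrix(x_row, nrow = 1,
                                    dimnames = list(NULL, names(x_row))),
                             bundle@transform))
  bg <- applyPreprocess(background, bundle@transform)
  feats <- bundle@transform$keep
  if (bundle@estimatorKind == "gbr") {
    xm <- matrix(xp, nrow = 1, dimnames = list(NULL, feats))
    contrib <- drop(stats::predict(bundle@fit, xm, type = "contrib"))
    base <- unname(contrib[length(contrib)])   # BIAS column
    phi <- contrib[-length(contrib)]
    pred <- base + sum(phi)
  } else {
    est <- .getEstimator(bundle@estimatorKind)
    res <- .kernelShap(function(Xm) {
      colnames(Xm) <- feats
      est$predict(bundle@fit, Xm)
    }, xp, bg, nsamples = nsamples, seed = seed)
    base <- res$base
    phi <- res$phi
    pred <- res$prediction
  }
  names(phi) <- feats
  new("Attribution", baseValue = base, contributions = phi,
      prediction = unname(pred))
}

#' Attribute every row of a feature matrix
#'
#' @param bundle a fitted \linkS4class{ModelBundle}.
#' @param X raw feature matrix.
#' @param background background matrix (defaults to \code{X}).
#' @param ... passed to \code{\link{attributePrediction}}.
#' @return list of \linkS4class{Attribution}.
#' @export
attributeSet <- function(bundle, X, background = X, ...) {
  lapply(seq_len(nrow(X)), function(r)
    attributePrediction(bundle, X[r, ], background, ...))
}

#' Rank features by mean absolute SHAP contribution; beeswarm export
#'
#' Produces the ranked importance table (feature, mean |contribution|) and
#' a beeswarm-style plot of the per-molecule contributions colored by
#' feature magnitude, the standard presentation of a SHAP analysis of a
#' whole data set.
#'
#' @param attributions list of \linkS4class{Attribution}.
#' @param X raw feature matrix (for point coloring), optional.
#' @param topK number of features to keep (clipped with a warning when it
#'   exceeds the feature count).
#' @param path optional file path; when given, the plot is written there
#'   (device chosen by extension: pdf or png).
#' @return list: \code{table} (data.frame feature / mean_abs_shap, ranked),
#'   \code{plot} (a ggplot object or NULL when no contributions are
#'   nonzero).
#' @export
beeswarmExport <- function(attributions, X = NULL, topK = 10L, path = NULL) {
  stopifnot(length(attributions) > 0)
  phi <- do.call(rbind, lapply(attributions, shapContributions))
  imp <- sort(colMeans(abs(phi)), decreasing = TRUE)
  imp <- imp[imp > 0]
  tab <- data.frame(feature = names(imp), mean_abs_shap = unname(imp))
  if (topK > nrow(tab)) {
    warning("topK exceeds the number of contributing features; clipped",
            call. = FALSE)
    topK <- nrow(tab)
  }
  tab <- utils::head(tab, topK)
  plt <- NULL
  if (nrow(tab) > 0) {
    keep <- tab$feature
    long <- do.call(rbind, lapply(seq_len(nrow(phi)), function(r) {
      data.frame(feature = keep, shap = phi[r, keep],
                 value = if (is.null(X)) NA_real_ else X[r, keep])
    }))
    long$feature <- factor(long$feature, levels = rev(keep))
    plt <- ggplot2::ggplot(long, ggplot2::aes(
      x = .data$shap, y = .data$feature, colour = .data$value)) +
      ggplot2::geom_jitter(height = 0.25, width = 0, alpha = 0.8, size = 1) +
      ggplot2::scale_colour_gradient(low = "#2166ac", high = "#b2182b",
                                     na.value = "grey40") +
      ggplot2::labs(x = "SHAP value (kcal/mol)", y = NULL,
                    colour = "feature value") +
      ggplot2::theme_minimal()
    if (!is.null(path)) {
      ext <- tolower(tools::file_ext(path))
      dev <- switch(ext, png = function(p) grDevices::png(p, 900, 700,
                                                          res = 120),
                    function(p) grDevices::pdf(p, width = 8, height = 6))
      dev(path)
      print(plt)
      grDevices::dev.off()
    }
  }
  list(table = tab, plot = plt)
}
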