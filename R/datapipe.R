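# Reaction-record handling: database reading, ee <-> ddG conversion,
# alpha/beta aggregation, feature preprocessing and data splitting.

.R_KCAL <- 1.987204e-3          # gas constant, kcal/(mol K)
.T_CONVERSION_K <- 273.15       # all conversions fixed at 0 degrees C
.EE_CAP <- 0.999                # reported ee >= 99.9 % is capped pre-conversion

.DB_COLUMNS <- c("reactant_smiles", "product_smiles", "ad_mix", "ee_percent",
                 "temperature_C", "oxidant", "additive", "solvent",
                 "yield_percent", "alkene_class")

#' Convert enantiomeric excess to an activation free-energy difference
#'
#' \code{eeToDdg} computes \code{R T ln((1 + ee) / (1 - ee))} in kcal/mol;
#' \code{ddgToEe} is its exact inverse. The conversion is strictly
#' increasing in ee and diverges at ee = 1, so exact unity is rejected with
#' a pointer to the capping convention used by \code{\link{readDatabase}}.
#'
#' @param ee enantiomeric excess as a fraction in [0, 1).
#' @param T_K absolute temperature in kelvin (default 273.15 K, i.e. 0
#'   degrees C, the library's standard condition).
#' @return \code{eeToDdg}: ddG in kcal/mol; \code{ddgToEe}: ee fraction.
#' @examples
#' eeToDdg(0.95)    # 1.99 kcal/mol at 0 C
#' @export
eeToDdg <- function(ee, T_K = .T_CONVERSION_K) {
  stopifnot(is.numeric(ee), is.numeric(T_K), all(T_K > 0))
  if (any(ee < 0 | ee > 1)) stop("ee must lie in [0, 1)", call. = FALSE)
  if (any(ee == 1))
    stop("ee = 1 diverges; cap reported ee at ", .EE_CAP,
         " before conversion", call. = FALSE)
  .R_KCAL * T_K * log((1 + ee) / (1 - ee))
}

#' @rdname eeToDdg
#' @param ddg free-energy difference in kcal/mol (>= 0).
#' @export
ddgToEe <- function(ddg, T_K = .T_CONVERSION_K) {
  stopifnot(is.numeric(ddg), all(ddg >= 0))
  x <- exp(ddg / (.R_KCAL * T_K))
  (x - 1) / (x + 1)
}

#' Average the selectivity magnitudes of an alpha/beta pair
#'
#' Reactions run with both AD-mix alpha and beta are collapsed to one
#' target: the arithmetic mean of the two (positive) ddG magnitudes, which
#' focuses modeling on the magnitude of enantioselectivity rather than the
#' enantiomer produced.
#'
#' @param ddg_alpha,ddg_beta nonnegative ddG magnitudes in kcal/mol for the
#'   same reactant.
#' @return list (SelectivityValue): \code{ddg_kcal}, \code{source},
#'   \code{T_K}.
#' @export
aggregatePair <- function(ddg_alpha, ddg_beta) {
  stopifnot(is.numeric(ddg_alpha), is.numeric(ddg_beta),
            length(ddg_alpha) == 1L, length(ddg_beta) == 1L,
            ddg_alpha >= 0, ddg_beta >= 0)
  list(ddg_kcal = mean(c(ddg_alpha, ddg_beta)),
       source = "averaged-pair", T_K = .T_CONVERSION_K)
}

#' Read and standardize a reaction database
#'
#' Reads the documented CSV schema (reactant_smiles, product_smiles,
#' ad_mix, ee_percent, temperature_C, oxidant, additive, solvent,
#' yield_percent, alkene_class), canonicalizes the structures,
#' deduplicates exact repeats (same canonical reactant/product/ad_mix/ee)
#' and validates ranges. Rows failing validation are rejected with a
#' reason, not fatal; unknown columns are a schema error. Per-record ddG
#' magnitudes are attached at the fixed 0 degrees C convention, capping ee
#' at 99.9 %.
#'
#' @param path CSV file path.
#' @return list: \code{records} (data.frame with canonical structures and
#'   \code{ddg_kcal}), \code{rejected} (data.frame of row, reason),
#'   \code{duplicates} (log of collapsed repeats).
#' @export
readDatabase <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  unknown <- setdiff(names(df), .DB_COLUMNS)
  if (length(unknown))
    stop("unknown database column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(c("reactant_smiles", "ad_mix", "ee_percent"), names(df))
  if (length(missing))
    stop("database is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in setdiff(.DB_COLUMNS, names(df))) df[[col]] <- NA
  df$ad_mix <- tolower(trimws(df$ad_mix))
  df$ad_mix[df$ad_mix %in% c("α", "a")] <- "alpha"
  df$ad_mix[df$ad_mix %in% c("β", "b")] <- "beta"
  reasons <- rep(NA_character_, nrow(df))
  ee <- suppressWarnings(as.numeric(df$ee_percent))
  reasons[is.na(ee) | ee < 0 | ee > 100] <- "ee_percent outside [0, 100]"
  reasons[!df$ad_mix %in% c("alpha", "beta")] <-
    "ad_mix must be alpha or beta"
  reasons[!nzchar(trimws(as.character(df$reactant_smiles)))] <-
    "empty reactant_smiles"
  keep <- is.na(reasons)
  rejected <- data.frame(row = which(!keep), reason = reasons[!keep])
  df <- df[keep, , drop = FALSE]
  ee <- ee[keep]
  if (nrow(df)) {
    can_r <- vapply(.rdParseSmiles(df$reactant_smiles, seed = 1L),
                    function(p) if (is.null(p$error)) p$canonical
                    else NA_character_, character(1))
    has_prod <- !is.na(df$product_smiles) & nzchar(trimws(df$product_smiles))
    can_p <- rep(NA_character_, nrow(df))
    if (any(has_prod)) {
      can_p[has_prod] <- vapply(
        .rdParseSmiles(df$product_smiles[has_prod], seed = 1L),
        function(p) if (is.null(p$error)) p$canonical else NA_character_,
        character(1))
    }
    bad <- is.na(can_r)
    if (any(bad)) {
      rejected <- rbind(rejected,
                        data.frame(row = which(keep)[bad],
                                   reason = "unparseable reactant_smiles"))
      df <- df[!bad, , drop = FALSE]; ee <- ee[!bad]
      can_r <- can_r[!bad]; can_p <- can_p[!bad]
    }
    df$reactant_smiles <- can_r
    df$product_smiles <- can_p
    key <- paste(can_r, can_p, df$ad_mix, ee, sep = "|")
    dup <- duplicated(key)
    duplicates <- data.frame(key = key[dup])
    df <- df[!dup, , drop = FALSE]
    ee <- ee[!dup]
  } else duplicates <- data.frame(key = character())
  df$ee_percent <- ee
  df$ddg_kcal <- eeToDdg(pmin(ee / 100, .EE_CAP))
  rownames(df) <- NULL
  list(records = df, rejected = rejected, duplicates = duplicates)
}

#' Scale features and drop highly correlated columns
#'
#' Fits a preprocessing transform on a training feature matrix:
#' zero-variance columns are dropped (logged), each retained column is
#' standardized to zero mean and unit variance, and for every pair with
#' absolute Pearson correlation above the threshold the later canonical
#' column is dropped (the earlier one is kept). The returned transform
#' record reapplies the exact same centering, scaling and column selection
#' to new data.
#'
#' @param X numeric matrix with named columns (57 canonical features).
#' @param corThreshold absolute correlation above which the later column of
#'   a pair is dropped (default 0.95).
#' @return list: \code{X} (transformed training matrix), \code{transform}
#'   (record with \code{keep}, \code{center}, \code{scale},
#'   \code{dropped_zero_var}, \code{dropped_correlated}).
#' @export
preprocessFeatures <- function(X, corThreshold = 0.95) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  sds <- apply(X, 2, stats::sd)
  zero <- sds < 1e-12
  keep <- colnames(X)[!zero]
  Xk <- X[, keep, drop = FALSE]
  dropped_cor <- character()
  if (ncol(Xk) > 1L) {
    C <- abs(suppressWarnings(stats::cor(Xk)))
    C[is.na(C)] <- 0
    drop <- rep(FALSE, ncol(Xk))
    for (j in seq_len(ncol(Xk))) {
      if (drop[j]) next
      hits <- which(C[, j] > corThreshold)
      hits <- hits[hits > j & !drop[hits]]
      drop[hits] <- TRUE
    }
    dropped_cor <- colnames(Xk)[drop]
    Xk <- Xk[, !drop, drop = FALSE]
  }
  center <- colMeans(Xk)
  scale <- apply(Xk, 2, stats::sd)
  transform <- list(keep = colnames(Xk), center = center, scale = scale,
                    dropped_zero_var = colnames(X)[zero],
                    dropped_correlated = dropped_cor,
                    cor_threshold = corThreshold)
  list(X = applyPreprocess(X, transform), transform = transform)
}

#' @rdname preprocessFeatures
#' @param transform a transform record from \code{preprocessFeatures}.
#' @export
applyPreprocess <- function(X, transform) {
  missing <- setdiff(transform$keep, colnames(X))
  if (length(missing))
    stop("feature matrix is missing transformed column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  Xk <- X[, transform$keep, drop = FALSE]
  scale(Xk, center = transform$center, scale = transform$scale)[, ,
                                                                drop = FALSE]
}

#' Stratified, seed-deterministic train/test split
#'
#' Splits records 80/20 (by default) within each alkene class: the training
#' share of a class of size n is round(fraction * n), with at least one
#' test member forced; classes smaller than 5 raise a warning but are still
#' split. Same seed, same membership.
#'
#' @param classes character vector of per-record class labels.
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
splitData <- function(classes, fraction = 0.8, seed = 1L) {
  n <- length(classes)
  if (n < 5L) stop("need at least 5 records to split", call. = FALSE)
  train <- integer()
  .withSeed(seed, {
    for (cl in sort(unique(classes))) {
      idx <- which(classes == cl)
      if (length(idx) < 5L)
        warning("class ", cl, " has only ", length(idx),
                " records; splitting anyway", call. = FALSE)
      n_tr <- min(round(fraction * length(idx)), length(idx) - 1L)
      n_tr <- max(n_tr, 1L)
      train <- c(train, sort(sample(idx, n_tr)))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}
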