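# The Q1 priority alignment cascade and feature-vector assembly.

# The four candidate frames: each position can be rotated or mirrored into
# the bottom-left quadrant with the alkene geometry preserved. Q1/Q4 share a
# carbon, Q2 is cis to Q1, Q3 is trans. In-plane rotations (A, B) preserve
# the molecular top/bottom faces; out-of-plane flips (C, D) mirror them.
.FRAMES <- list(
  A = list(map = c(Q1 = "bottom_left", Q2 = "bottom_right",
                   Q3 = "top_right", Q4 = "top_left"), flip = FALSE),
  B = list(map = c(Q1 = "top_right", Q2 = "top_left",
                   Q3 = "bottom_left", Q4 = "bottom_right"), flip = FALSE),
  C = list(map = c(Q1 = "bottom_right", Q2 = "bottom_left",
                   Q3 = "top_left", Q4 = "top_right"), flip = TRUE),
  D = list(map = c(Q1 = "top_left", Q2 = "top_right",
                   Q3 = "bottom_right", Q4 = "bottom_left"), flip = TRUE)
)

.VOL_TIE_REL <- 0.02      # volumes tie below 2 % relative difference
.ESP_TIE_ABS <- 0.5       # ESP values tie below 0.5 kcal/mol
.POL_TIE_ABS <- 1e-9      # polarizabilities tie on equal element table value

#' Per-position quadrant descriptors of an alkene
#'
#' Computes the steric and electrostatic descriptors of each of the four
#' positional substituents: Sterimol L/B1/B5 (3-heavy-atom truncation), the
#' full and 3-BFS van der Waals volumes, ESP_MIN/ESP_99, and the
#' polarizability of the attachment atom. Hydrogen positions are evaluated
#' on their one-atom fragment, so every position is dense.
#'
#' @param u an \linkS4class{AlkeneUnit}.
#' @param s the parent \linkS4class{Structure3D} (conformers embedded,
#'   charges assigned).
#' @return named list of per-position descriptor lists.
#' @export
quadrantDescriptors <- function(u, s) {
  out <- lapply(.POSITION_KEYS, function(key) {
    f <- u@positions[[key]]
    carbon <- if (key %in% c("bottom_left", "top_left")) u@c1 else u@c2
    st <- sterimol3(f, s, alkeneCarbon = carbon)
    esp <- espStats(f, s)
    list(
      L = unname(st["L"]), B1 = unname(st["B1"]), B5 = unname(st["B5"]),
      max_volume = maxVolume(f, s),
      bfs3_volume = bfs3Volume(f, s),
      esp_min = unname(esp["esp_min"]),
      esp_99 = unname(esp["esp_99"]),
      polarizability = atomPolarizability(s@elements[f@attachmentAtom]),
      signature = .fragmentSignature(f, s)
    )
  })
  names(out) <- .POSITION_KEYS
  out
}

#' Align the alkene: choose which substituent occupies Q1
#'
#' Enumerates the four candidate frames and applies the six priority rules
#' in order, each filtering the surviving frames: (1) Q1 holds the largest
#' volume substituent (by the chosen criterion), (2) the smallest-volume
#' substituent lands cis to Q1 (in Q2), (3) Q1 holds the largest ESP_99,
#' (4) the largest ESP_99 lands trans to Q1 (in Q3), (5) the Q1 attachment
#' atom has the largest polarizability, (6) the largest-polarizability
#' attachment atom lands trans. The first rule leaving a unique survivor is
#' recorded; if all six leave several frames, the tie is broken by
#' lexicographic fragment-signature order and flagged.
#'
#' @param u an \linkS4class{AlkeneUnit}.
#' @param qd quadrant descriptors from \code{\link{quadrantDescriptors}}.
#' @param criterion "max_volume" or "bfs3_volume".
#' @return a \linkS4class{QuadrantAssignment}.
#' @export
alignQ1 <- function(u, qd, criterion = c("max_volume", "bfs3_volume")) {
  criterion <- match.arg(criterion)
  missing <- setdiff(.POSITION_KEYS, names(qd))
  if (length(missing))
    stop("missing quadrant descriptors for position(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  volKey <- criterion
  val <- function(frame, q, field) qd[[frame$map[[q]]]][[field]]
  rules <- list(
    list(fn = function(fr) val(fr, "Q1", volKey), tol = NA, rel = TRUE),
    list(fn = function(fr) -val(fr, "Q2", volKey), tol = NA, rel = TRUE),
    list(fn = function(fr) val(fr, "Q1", "esp_99"), tol = .ESP_TIE_ABS, rel = FALSE),
    list(fn = function(fr) val(fr, "Q3", "esp_99"), tol = .ESP_TIE_ABS, rel = FALSE),
    list(fn = function(fr) val(fr, "Q1", "polarizability"), tol = .POL_TIE_ABS, rel = FALSE),
    list(fn = function(fr) val(fr, "Q3", "polarizability"), tol = .POL_TIE_ABS, rel = FALSE)
  )
  surv <- .FRAMES
  deciding <- 0L
  for (r in seq_along(rules)) {
    surv <- .filterByRule(surv, rules[[r]]$fn, rules[[r]]$tol, rules[[r]]$rel)
    if (length(surv) == 1L) { deciding <- r; break }
  }
  tie <- length(surv) > 1L
  if (tie) {
    sig <- vapply(surv, function(fr) {
      paste(vapply(c("Q1", "Q2", "Q3", "Q4"),
                   function(q) qd[[fr$map[[q]]]]$signature, character(1)),
            collapse = "/")
    }, character(1))
    surv <- surv[order(sig)][1]
  }
  chosen <- surv[[1]]
  new("QuadrantAssignment",
      quadrantOf = chosen$map,
      criterion = criterion,
      decidingRule = as.integer(deciding),
      tieBroken = tie,
      faceFlip = chosen$flip)
}

# relative tolerance uses |values| so rule 2 (negated volumes) works too
.filterByRule <- function(frames, value_of, tol, relative) {
  vals <- vapply(frames, value_of, numeric(1))
  best <- max(vals)
  keep <- if (relative) {
    abs(vals - best) <= .VOL_TIE_REL * max(abs(vals), abs(best))
  } else {
    vals >= best - tol
  }
  frames[keep]
}

#' Canonical names of the 57-feature space
#'
#' Order: the Q1..Q4 quadrant blocks concatenated counterclockwise around
#' the alkene (L, B1, B5, Max Volume, 3-BFS Volume, ESP_MIN, ESP_99 per
#' quadrant), the C1 and C2 radial distribution blocks (spheres 1..7), then
#' the 15 whole-alkene electronic features.
#'
#' @return character vector of length 57.
#' @export
adFeatureNames <- function() {
  qblock <- c("L", "B1", "B5", "Max Volume", "3-BFS Volume",
              "ESP_MIN", "ESP_99")
  c(as.vector(t(outer(c("Q1", "Q2", "Q3", "Q4"), qblock, paste))),
    paste("C1 RDF", 1:7), paste("C2 RDF", 1:7),
    .ELECTRONIC_NAMES)
}

#' Assemble the aligned 57-feature vector
#'
#' @param u an \linkS4class{AlkeneUnit}.
#' @param a its \linkS4class{QuadrantAssignment}.
#' @param qd quadrant descriptors from \code{\link{quadrantDescriptors}}.
#' @param gd global descriptors: a list with \code{rdf} (14 values from
#'   \code{\link{rdfBlock}}) and \code{electronic} (15 values from
#'   \code{\link{electronicBlock}}).
#' @return a \linkS4class{FeatureVector}.
#' @export
assembleFeatures <- function(u, a, qd, gd) {
  if (length(gd$rdf) != 14L)
    stop("feature assembly: RDF block must have 14 values, got ",
         length(gd$rdf), call. = FALSE)
  if (length(gd$electronic) != 15L)
    stop("feature assembly: electronic block must have 15 values, got ",
         length(gd$electronic), call. = FALSE)
  qvals <- unlist(lapply(c("Q1", "Q2", "Q3", "Q4"), function(q) {
    d <- qd[[a@quadrantOf[[q]]]]
    c(d$L, d$B1, d$B5, d$max_volume, d$bfs3_volume, d$esp_min, d$esp_99)
  }))
  values <- c(qvals, unname(gd$rdf), unname(gd$electronic))
  names(values) <- adFeatureNames()
  new("FeatureVector", values = values,
      alkeneClass = classifyAlkene(u, a),
      criterion = a@criterion)
}

#' Featurize one prepared structure
#'
#' Runs alkene identification, quadrant descriptor computation, the Q1
#' alignment cascade, and block assembly for a structure whose conformers
#' and partial charges are already prepared.
#'
#' @param s a \linkS4class{Structure3D}.
#' @param criterion alignment volume criterion.
#' @param selector optional alkene selector (see \code{\link{findAlkene}}).
#' @return list with elements \code{features} (\linkS4class{FeatureVector}),
#'   \code{unit}, \code{assignment}.
#' @export
featurizeAlkene <- function(s, criterion = c("max_volume", "bfs3_volume"),
                            selector = NULL) {
  criterion <- match.arg(criterion)
  u <- findAlkene(s, selector = selector)
  qd <- quadrantDescriptors(u, s)
  a <- alignQ1(u, qd, criterion = criterion)
  gd <- list(rdf = rdfBlock(u, s), electronic = electronicBlock(u, s, a))
  list(features = assembleFeatures(u, a, qd, gd), unit = u, assignment = a)
}

#' Featurize a set of molecules end to end
#'
#' Batch pipeline: parse SMILES (one RDKit subprocess), embed conformer
#' ensembles, assign charges, and featurize every molecule. Returns the
#' feature matrix with molecules in rows.
#'
#' @param smiles character vector of SMILES.
#' @param criterion alignment volume criterion.
#' @param nConf conformers per molecule (see \code{\link{embedConformers}}).
#' @param seed integer; seeds both embedding stages.
#' @return list: \code{features} (numeric matrix, one row per molecule, 57
#'   columns), \code{classes} (character), \code{audit} (per-molecule list
#'   of criterion, deciding rule, quadrant map, face flip),
#'   \code{structures}.
#' @export
featurizeSet <- function(smiles, criterion = c("max_volume", "bfs3_volume"),
                         nConf = 5L, seed = 1L) {
  criterion <- match.arg(criterion)
  structures <- parseStructures(smiles, embedSeed = seed)
  structures <- lapply(structures, embedConformers, nConf = nConf, seed = seed)
  res <- lapply(structures, featurizeAlkene, criterion = criterion)
  X <- do.call(rbind, lapply(res, function(r) featureValues(r$features)))
  rownames(X) <- vapply(structures, canonicalId, character(1))
  audit <- lapply(res, function(r) {
    list(criterion = r$assignment@criterion,
         deciding_rule = if (r$assignment@tieBroken) "tie_broken"
                         else r$assignment@decidingRule,
         quadrant_of = as.list(r$assignment@quadrantOf),
         face_flip = r$assignment@faceFlip)
  })
  list(features = X,
       classes = vapply(res, function(r) alkeneClassOf(r$features), character(1)),
       audit = audit,
       structures = structures,
       units = lapply(res, `[[`, "unit"),
       assignments = lapply(res, `[[`, "assignment"))
}

#' Write a feature matrix as delimited text with the fixed 57-column header
#'
#' @param X numeric matrix from \code{\link{featurizeSet}}.
#' @param path output CSV path.
#' @export
writeFeatureMatrix <- function(X, path) {
  stopifnot(identical(colnames(X), adFeatureNames()))
  df <- data.frame(canonical_id = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
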