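#' @import methods
NULL

#' Structure3D: a molecule with conformer ensemble and partial charges
#'
#' The central molecular container. Atoms carry element symbols and formal
#' charges; bonds are an edge table with integer orders; conformers are a
#' list of n_atom x 3 coordinate matrices (Angstrom) with nonnegative
#' weights summing to one; partial charges are per-atom values in units of
#' the elementary charge. \code{canonicalId} is the canonical SMILES of the
#' molecule as produced by OpenBabel, fixed per release.
#'
#' @slot elements character, element symbol per atom.
#' @slot formalCharges integer, formal charge per atom.
#' @slot bonds data.frame with columns \code{i}, \code{j}, \code{order}.
#' @slot conformers list of numeric matrices (n_atom x 3), coordinates in
#'   Angstrom.
#' @slot conformerWeights numeric, one weight per conformer, summing to 1.
#' @slot partialCharges numeric, per-atom partial charges (length 0 until
#'   assigned).
#' @slot aromatic logical, per-atom aromaticity flag.
#' @slot stereoBonds data.frame with columns \code{i}, \code{j}: double bonds
#'   whose cis/trans configuration is defined by the input.
#' @slot canonicalId character, canonical SMILES.
#' @slot chargeModel character, name of the charge backend used (or "").
#' @export
setClass("Structure3D", representation(
  elements = "character",
  formalCharges = "integer",
  bonds = "data.frame",
  conformers = "list",
  conformerWeights = "numeric",
  partialCharges = "numeric",
  aromatic = "logical",
  stereoBonds = "data.frame",
  canonicalId = "character",
  chargeModel = "character"
))

setValidity("Structure3D", function(object) {
  n <- length(object@elements)
  msgs <- character()
  if (length(object@formalCharges) != n)
    msgs <- c(msgs, "formalCharges length must equal atom count")
  if (nrow(object@bonds) > 0 &&
      !all(c("i", "j", "order") %in% names(object@bonds)))
    msgs <- c(msgs, "bonds must have columns i, j, order")
  for (cf in object@conformers) {
    if (!is.matrix(cf) || nrow(cf) != n || ncol(cf) != 3) {
      msgs <- c(msgs, "every conformer must be an n_atom x 3 matrix")
      break
    }
  }
  if (length(object@conformers) > 0) {
    if (length(object@conformerWeights) != length(object@conformers))
      msgs <- c(msgs, "one weight per conformer required")
    else if (any(object@conformerWeights < 0))
      msgs <- c(msgs, "conformer weights must be nonnegative")
    else if (abs(sum(object@conformerWeights) - 1) > 1e-9)
      msgs <- c(msgs, "conformer weights must sum to 1 (within 1e-9)")
  }
  if (length(object@partialCharges) > 0) {
    if (length(object@partialCharges) != n)
      msgs <- c(msgs, "partialCharges length must equal atom count")
    else if (abs(sum(object@partialCharges) - sum(object@formalCharges)) > 1e-6)
      msgs <- c(msgs, "partial charges must sum to the total formal charge")
  }
  if (length(msgs)) msgs else TRUE
})

#' SubstituentFragment: one positional substituent of an alkene
#'
#' @slot attachmentAtom integer, atom bonded to an alkene carbon.
#' @slot memberAtoms integer, all atoms of the fragment (attachment first in
#'   \code{bfsOrder}).
#' @slot bfsOrder integer, deterministic breadth-first ordering of
#'   \code{memberAtoms} starting at the attachment atom; ties broken by
#'   canonical atom rank.
#' @slot isHydrogen logical, TRUE when the position holds a lone hydrogen.
#' @export
setClass("SubstituentFragment", representation(
  attachmentAtom = "integer",
  memberAtoms = "integer",
  bfsOrder = "integer",
  isHydrogen = "logical"
))

setValidity("SubstituentFragment", function(object) {
  msgs <- character()
  if (!(object@attachmentAtom %in% object@memberAtoms))
    msgs <- c(msgs, "attachment atom must be a member atom")
  if (length(object@bfsOrder) != length(object@memberAtoms) ||
      !setequal(object@bfsOrder, object@memberAtoms))
    msgs <- c(msgs, "bfsOrder must be a permutation of memberAtoms")
  if (length(object@bfsOrder) > 0 &&
      object@bfsOrder[1] != object@attachmentAtom)
    msgs <- c(msgs, "bfsOrder must start at the attachment atom")
  if (length(msgs)) msgs else TRUE
})

#' AlkeneUnit: the target C=C with its four positional substituents
#'
#' Positions use frame-independent geometric keys: \code{bottom_left} and
#' \code{top_left} attach to carbon \code{c1}; \code{bottom_right} and
#' \code{top_right} attach to \code{c2}. The cis pairs are
#' (bottom_left, bottom_right) and (top_left, top_right).
#'
#' @slot c1,c2 integer atom indices of the alkene carbons.
#' @slot positions named list of \linkS4class{SubstituentFragment} with keys
#'   bottom_left, bottom_right, top_right, top_left.
#' @slot stereoDefined logical; TRUE when the input either fixes the alkene
#'   geometry or the alkene is not stereogenic.
#' @export
setClass("AlkeneUnit", representation(
  c1 = "integer",
  c2 = "integer",
  positions = "list",
  stereoDefined = "logical"
))

.POSITION_KEYS <- c("bottom_left", "bottom_right", "top_right", "top_left")

setValidity("AlkeneUnit", function(object) {
  msgs <- character()
  if (!identical(sort(names(object@positions)), sort(.POSITION_KEYS)))
    msgs <- c(msgs, "positions must be keyed bottom_left, bottom_right, top_right, top_left")
  if (length(msgs)) msgs else TRUE
})

#' QuadrantAssignment: the aligned frame chosen by the Q1 priority cascade
#'
#' @slot quadrantOf named character, mapping Q1..Q4 to position keys of the
#'   \linkS4class{AlkeneUnit}.
#' @slot criterion character, "max_volume" or "bfs3_volume".
#' @slot decidingRule integer 1..6, or 0 when the frame was tie-broken.
#' @slot tieBroken logical.
#' @slot faceFlip logical; TRUE when the chosen frame mirrors the molecular
#'   top/bottom faces.
#' @export
setClass("QuadrantAssignment", representation(
  quadrantOf = "character",
  criterion = "character",
  decidingRule = "integer",
  tieBroken = "logical",
  faceFlip = "logical"
))

setValidity("QuadrantAssignment", function(object) {
  msgs <- character()
  if (!identical(sort(names(object@quadrantOf)), c("Q1", "Q2", "Q3", "Q4")))
    msgs <- c(msgs, "quadrantOf must be named Q1..Q4")
  if (!object@criterion %in% c("max_volume", "bfs3_volume"))
    msgs <- c(msgs, "criterion must be max_volume or bfs3_volume")
  if (length(msgs)) msgs else TRUE
})

#' FeatureVector: the aligned 57-descriptor vector of one alkene
#'
#' @slot values named numeric of length 57 in canonical order: the Q1..Q4
#'   quadrant blocks concatenated counterclockwise, the C1 and C2 radial
#'   distribution blocks, then the 15 whole-alkene electronic features.
#' @slot alkeneClass character, one of the eight substitution classes.
#' @slot criterion character, alignment volume criterion used.
#' @export
setClass("FeatureVector", representation(
  values = "numeric",
  alkeneClass = "character",
  criterion = "character"
))

setValidity("FeatureVector", function(object) {
  msgs <- character()
  if (length(object@values) != 57L)
    msgs <- c(msgs, "feature vector must have exactly 57 values")
  if (!identical(names(object@values), adFeatureNames()))
    msgs <- c(msgs, "feature names must match the canonical 57-name order")
  if (anyNA(object@values))
    msgs <- c(msgs, "feature values must not be missing")
  if (length(msgs)) msgs else TRUE
})

#' ModelBundle: a fitted per-class selectivity model
#'
#' @slot alkeneClass character.
#' @slot estimatorKind character, a registered estimator kind.
#' @slot fit ANY, the fitted estimator handle.
#' @slot transform list, the preprocessing transform record
#'   (see \code{\link{preprocessFeatures}}).
#' @slot manifest list: seed, hyperparameters, search trace, split sizes.
#' @export
setClass("ModelBundle", representation(
  alkeneClass = "character",
  estimatorKind = "character",
  fit = "ANY",
  transform = "list",
  manifest = "list"
))

#' Attribution: Shapley-additive explanation of one prediction
#'
#' Satisfies local accuracy: \code{baseValue + sum(contributions)} equals the
#' model prediction to within 1e-6 kcal/mol.
#'
#' @slot baseValue numeric scalar, kcal/mol.
#' @slot contributions named numeric, per-feature contributions in kcal/mol.
#' @slot prediction numeric scalar, kcal/mol.
#' @export
setClass("Attribution", representation(
  baseValue = "numeric",
  contributions = "numeric",
  prediction = "numeric"
))

setValidity("Attribution", function(object) {
  if (abs(object@baseValue + sum(object@contributions) - object@prediction) > 1e-6)
    "local accuracy violated: base + sum(contributions) != prediction"
  else TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "Structure3D", function(object) {
  cat("Structure3D:", object@canonicalId, "\n")
  cat("  ", length(object@elements), "atoms,", nrow(object@bonds), "bonds,",
      length(object@conformers), "conformer(s)\n")
  if (length(object@partialCharges))
    cat("  partial charges:", object@chargeModel, "\n")
})

setMethod("show", "AlkeneUnit", function(object) {
  subs <- vapply(object@positions, function(f) {
    if (f@isHydrogen) "H" else paste0("[", length(f@memberAtoms), " atoms]")
  }, character(1))
  cat("AlkeneUnit: C", object@c1, "=C", object@c2, "\n", sep = "")
  for (k in .POSITION_KEYS) cat("  ", k, ": ", subs[[k]], "\n", sep = "")
})

setMethod("show", "QuadrantAssignment", function(object) {
  cat("QuadrantAssignment (", object@criterion, ")\n", sep = "")
  for (q in c("Q1", "Q2", "Q3", "Q4"))
    cat("  ", q, " <- ", object@quadrantOf[[q]], "\n", sep = "")
  cat("  deciding rule:",
      if (object@tieBroken) "tie_broken" else object@decidingRule,
      "| face flip:", object@faceFlip, "\n")
})

setMethod("show", "FeatureVector", function(object) {
  cat("FeatureVector (57 features,", object@alkeneClass, "alkene,",
      object@criterion, "alignment)\n")
  print(head(object@values, 7))
})

setMethod("show", "ModelBundle", function(object) {
  cat("ModelBundle:", object@estimatorKind, "model for", object@alkeneClass,
      "alkenes\n")
  cat("  retained features:", length(object@transform$keep), "\n")
})

# ---- accessors --------------------------------------------------------------

#' @rdname Structure3D-class
#' @param x a Structure3D.
#' @export
atomElements <- function(x) x@elements

#' @rdname Structure3D-class
#' @export
atomBonds <- function(x) x@bonds

#' @rdname Structure3D-class
#' @export
conformerCoords <- function(x) x@conformers

#' @rdname Structure3D-class
#' @export
conformerWeights <- function(x) x@conformerWeights

#' @rdname Structure3D-class
#' @export
partialCharges <- function(x) x@partialCharges

#' @rdname Structure3D-class
#' @export
canonicalId <- function(x) x@canonicalId

#' @rdname FeatureVector-class
#' @param x a FeatureVector.
#' @export
featureValues <- function(x) x@values

#' @rdname FeatureVector-class
#' @export
alkeneClassOf <- function(x) x@alkeneClass

#' @rdname Attribution-class
#' @param x an Attribution.
#' @export
shapContributions <- function(x) x@contributions

#' The eight alkene substitution classes
#' @return character vector of the canonical class labels.
#' @export
alkeneClasses <- function() {
  c("Mono", "Gem", "Cis", "Trans", "TriQ2", "TriQ3", "TriQ4", "Tetra")
}
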