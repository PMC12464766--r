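# Reactant-to-diol mapping and CIP-independent facial-selectivity assignment.
#
# The face of dihydroxylation is read off geometrically: the product is
# placed (conceptually) in the aligned quadrant frame of its parent alkene
# (Q1 bottom-left), and the side on which the two hydroxyl oxygens sit
# relative to the frame normal decides "top" versus "bottom". No CIP
# priorities are involved, so highly diverse substituents cannot flip the
# label through priority reordering.

#' FaceLabel: top/bottom face of dihydroxylation in the aligned frame
#'
#' @slot value "top" or "bottom".
#' @slot degenerate logical; TRUE when both faces give the same compound
#'   (e.g. meso diols of symmetric cis-alkenes), in which case the label is
#'   reported but carries no information.
#' @export
setClass("FaceLabel", representation(value = "character",
                                     degenerate = "logical"))

setMethod("show", "FaceLabel", function(object) {
  cat("FaceLabel:", object@value,
      if (object@degenerate) "(degenerate)" else "", "\n")
})

.heavyGraph <- function(elements, bonds, extra_vertices = NULL,
                        extra_edges = NULL) {
  heavy <- which(elements != "H")
  sub <- bonds[bonds$i %in% heavy & bonds$j %in% heavy, c("i", "j")]
  verts <- data.frame(name = c(heavy, extra_vertices))
  edges <- rbind(sub, extra_edges)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

.elementColors <- function(symbols) {
  as.integer(factor(symbols, levels = c("H", "B", "C", "N", "O", "F", "Si",
                                        "P", "S", "Cl", "Br", "I")))
}

#' Map a reactant alkene onto its dihydroxylation product
#'
#' Matches the reactant's heavy-atom skeleton, with the C=C replaced by a
#' saturated C-C bearing one oxygen on each carbon, against the product's
#' heavy-atom graph (element-colored isomorphism). Mapping failures are
#' data, not errors: records that do not match are reported with a reason
#' and excluded from downstream accuracy denominators.
#'
#' @param reactant a \linkS4class{Structure3D} containing the alkene.
#' @param u the reactant's \linkS4class{AlkeneUnit}.
#' @param product a \linkS4class{Structure3D} of the putative diol.
#' @return a list (MappingResult): \code{matched} (logical),
#'   \code{failure_reason}, \code{atom_map} (named integer: reactant c1/c2
#'   to product carbons), \code{o1}, \code{o2} (product oxygens), and
#'   \code{mappings}, the full list of skeleton isomorphisms.
#' @export
mapAlkeneToDiol <- function(reactant, u, product) {
  fail <- function(reason) list(matched = FALSE, failure_reason = reason,
                                atom_map = NULL, mappings = list())
  nR <- sum(reactant@elements != "H")
  nP <- sum(product@elements != "H")
  if (nP != nR + 2L)
    return(fail(sprintf(
      "heavy-atom count mismatch: diol should add exactly 2 oxygens (%d vs %d)",
      nP, nR + 2L)))
  n_at <- length(reactant@elements)
  # pattern: reactant skeleton with two pseudo-oxygens grafted on c1/c2
  pat_bonds <- reactant@bonds[, c("i", "j")]
  pat <- .heavyGraph(reactant@elements, reactant@bonds,
                     extra_vertices = c(n_at + 1L, n_at + 2L),
                     extra_edges = data.frame(i = c(u@c1, u@c2),
                                              j = c(n_at + 1L, n_at + 2L)))
  pat_elem <- c(reactant@elements[reactant@elements != "H"], "O", "O")
  tgt <- .heavyGraph(product@elements, product@bonds)
  tgt_elem <- product@elements[product@elements != "H"]
  # LAD with element-identity domains; equal sizes make 'induced' exact
  domains <- lapply(pat_elem, function(e) which(tgt_elem == e))
  if (any(lengths(domains) == 0L))
    return(fail("element composition mismatch between skeleton and product"))
  maps <- igraph::subgraph_isomorphisms(pattern = pat, target = tgt,
                                        method = "lad", induced = TRUE,
                                        domains = domains)
  if (length(maps) == 0L)
    return(fail("skeleton mismatch: product does not contain the saturated diol skeleton"))
  pat_names <- as.integer(igraph::V(pat)$name)
  tgt_names <- as.integer(igraph::V(tgt)$name)
  pat_edges <- igraph::as_edgelist(pat, names = FALSE)
  decoded <- lapply(maps, function(m) {
    mp <- as.integer(m)
    # defensive validity check of the matcher's output
    stopifnot(all(pat_elem == tgt_elem[mp]),
              all(apply(pat_edges, 1, function(e)
                igraph::are_adjacent(tgt, mp[e[1]], mp[e[2]]))))
    to <- tgt_names[mp]
    names(to) <- pat_names
    to
  })
  # the mapped oxygens must be hydroxyls (carry a hydrogen) in the product
  hasOH <- function(o) {
    nb <- .bondedAtoms(product, o)
    any(product@elements[nb] == "H")
  }
  ok <- vapply(decoded, function(m) {
    hasOH(m[[as.character(n_at + 1L)]]) && hasOH(m[[as.character(n_at + 2L)]])
  }, logical(1))
  decoded <- decoded[ok]
  if (length(decoded) == 0L)
    return(fail("matched oxygens are not hydroxyl groups"))
  m1 <- decoded[[1]]
  list(matched = TRUE, failure_reason = "",
       atom_map = c(c1 = m1[[as.character(u@c1)]],
                    c2 = m1[[as.character(u@c2)]]),
       o1 = m1[[as.character(n_at + 1L)]],
       o2 = m1[[as.character(n_at + 2L)]],
       mappings = decoded,
       pseudo = c(n_at + 1L, n_at + 2L),
       reactant = reactant)
}

# Tetrahedral parity of one mapped carbinol carbon against the aligned
# frame. The parity of (O, other-alkene-carbon, bottom-quadrant substituent)
# around the carbon is conformation-independent, so it survives relaxation
# of the product geometry; its sign decides the face the oxygen added from.
# Returns "top", "bottom", or NA when the carbon has no stereo information
# (two hydrogen positions).
.faceAtCarbon <- function(rc, mp, u, a, product, cf, oxy, reactant) {
  q1pos <- a@quadrantOf[["Q1"]]
  bearsQ1 <- rc == if (q1pos %in% c("bottom_left", "top_left")) u@c1 else u@c2
  keys <- c(bottom = unname(a@quadrantOf[[if (bearsQ1) "Q1" else "Q2"]]),
            top = unname(a@quadrantOf[[if (bearsQ1) "Q4" else "Q3"]]))
  bottomFrag <- u@positions[[keys[["bottom"]]]]
  topFrag <- u@positions[[keys[["top"]]]]
  # structurally identical geminal substituents: no stereocenter here
  if (.fragmentSignature(bottomFrag, reactant) ==
      .fragmentSignature(topFrag, reactant)) return(NA_character_)
  pc <- mp[[as.character(rc)]]
  other_r <- if (rc == u@c1) u@c2 else u@c1
  pother <- mp[[as.character(other_r)]]
  refAtom <- function(frag) {
    if (!frag@isHydrogen) return(mp[[as.character(frag@attachmentAtom)]])
    hs <- .bondedAtoms(product, pc)
    hs <- hs[product@elements[hs] == "H"]
    if (length(hs) == 1L) hs else NA_integer_
  }
  refB <- refAtom(bottomFrag)
  refSign <- 1
  if (is.na(refB) || (bottomFrag@isHydrogen && topFrag@isHydrogen)) {
    if (topFrag@isHydrogen) return(NA_character_)
    refB <- refAtom(topFrag)
    refSign <- -1   # using the top substituent mirrors the parity
    if (is.na(refB)) return(NA_character_)
  }
  if (bottomFrag@isHydrogen && topFrag@isHydrogen) return(NA_character_)
  vO <- cf[oxy, ] - cf[pc, ]
  vX <- cf[pother, ] - cf[pc, ]
  vB <- refSign * (cf[refB, ] - cf[pc, ])
  p <- det(rbind(vO, vX, vB))
  side <- if (bearsQ1) 1 else -1
  if (abs(p) < 1e-8) return(NA_character_)
  if (p * side < 0) "top" else "bottom"
}

.faceOneMapping <- function(mp, m, u, a, product, cf) {
  oC1 <- mp[[as.character(m$pseudo[1])]]
  oC2 <- mp[[as.character(m$pseudo[2])]]
  f1 <- .faceAtCarbon(u@c1, mp, u, a, product, cf, oC1, m$reactant)
  f2 <- .faceAtCarbon(u@c2, mp, u, a, product, cf, oC2, m$reactant)
  fs <- stats::na.omit(c(f1, f2))
  if (length(fs) == 0L)
    stop("no stereocenter arises from the alkene carbons; the face label ",
         "is undefined for this diol", call. = FALSE)
  if (length(unique(fs)) > 1L)
    stop("inconsistent diastereomer: hydroxyls show an anti-addition ",
         "pattern", call. = FALSE)
  fs[[1]]
}

.mirrorCanonical <- function(s) {
  cf <- s@conformers[[1]]
  cf[, 1] <- -cf[, 1]
  .rdCanonFromSdf(.sdfText(s@elements, cf, s@bonds))
}

.canonicalFrom3d <- function(s) {
  .rdCanonFromSdf(.sdfText(s@elements, s@conformers[[1]], s@bonds))
}

#' Assign the face of dihydroxylation from a mapped product
#'
#' For every skeleton mapping, the product's hydroxyl oxygens are projected
#' onto the normal of the aligned quadrant frame reconstructed in the
#' product geometry; a positive projection of both oxygens means top-face
#' addition, negative means bottom-face. Enantiomeric products yield
#' opposite labels. When different mappings (molecular symmetry) yield both
#' labels the product is face-degenerate and flagged as such.
#'
#' @param m MappingResult from \code{\link{mapAlkeneToDiol}} with
#'   \code{matched = TRUE}.
#' @param u the reactant \linkS4class{AlkeneUnit}.
#' @param a the reactant's \linkS4class{QuadrantAssignment}.
#' @param product the product \linkS4class{Structure3D} (3-D coordinates
#'   realize its declared stereochemistry).
#' @return a \linkS4class{FaceLabel}.
#' @export
assignFace <- function(m, u, a, product) {
  if (!isTRUE(m$matched))
    stop("cannot assign a face for an unmatched mapping (",
         m$failure_reason, ")", call. = FALSE)
  cf <- product@conformers[[1]]
  faces <- vapply(m$mappings, .faceOneMapping, character(1),
                  m = m, u = u, a = a, product = product, cf = cf)
  degenerate <- length(unique(faces)) > 1L
  if (!degenerate) {
    # a chiral product whose input did not declare stereochemistry got an
    # arbitrary 3-D realization: refuse to guess
    can3d <- .canonicalFrom3d(product)
    mir <- .mirrorCanonical(product)
    chiral <- !identical(can3d, mir)
    if (chiral && !grepl("@", product@canonicalId, fixed = TRUE))
      stop("product stereocenters are undefined; declare stereochemistry ",
           "for ", product@canonicalId, call. = FALSE)
  }
  new("FaceLabel", value = faces[[1]], degenerate = degenerate)
}

#' Mnemonic accuracy of face labels against AD-mix identities
#'
#' The Sharpless mnemonic expects AD-mix alpha to deliver bottom-face and
#' AD-mix beta top-face dihydroxylation in the aligned frame.
#'
#' @param faces list of \linkS4class{FaceLabel} (or character "top"/"bottom").
#' @param admix character vector, "alpha" or "beta", parallel to
#'   \code{faces}.
#' @return fraction of records consistent with the mnemonic.
#' @export
mnemonicAccuracy <- function(faces, admix) {
  if (length(faces) == 0L) stop("empty record list", call. = FALSE)
  if (length(faces) != length(admix))
    stop("faces and admix must be parallel vectors", call. = FALSE)
  fv <- vapply(faces, function(f) {
    if (is(f, "FaceLabel")) f@value else as.character(f)
  }, character(1))
  admix <- tolower(admix)
  stopifnot(all(admix %in% c("alpha", "beta")))
  mean((admix == "alpha" & fv == "bottom") | (admix == "beta" & fv == "top"))
}

#' Construct the syn-addition diol of a chosen face in 3-D
#'
#' Explicitly adds two hydroxyl groups to the requested face of the aligned
#' alkene (both oxygens on the same side of the alkene plane, 1.43 Angstrom
#' from the carbons along the frame normal) and perceives the resulting
#' stereochemistry from the constructed geometry. This is the generative
#' counterpart of \code{\link{assignFace}} and the engine of the synthetic
#' face-labeled diol sets.
#'
#' @param s reactant \linkS4class{Structure3D}.
#' @param u its \linkS4class{AlkeneUnit}.
#' @param a its \linkS4class{QuadrantAssignment}.
#' @param face "top" or "bottom" in the aligned frame.
#' @return list: \code{smiles} (canonical isomeric SMILES of the diol),
#'   \code{sdf} (the constructed V2000 record).
#' @export
buildSynDiol <- function(s, u, a, face = c("top", "bottom")) {
  face <- match.arg(face)
  cf <- s@conformers[[1]]
  q1pos <- a@quadrantOf[["Q1"]]
  onC1 <- q1pos %in% c("bottom_left", "top_left")
  cLeft <- if (onC1) u@c1 else u@c2
  cRight <- if (onC1) u@c2 else u@c1
  att <- u@positions[[q1pos]]@attachmentAtom
  x <- cf[cRight, ] - cf[cLeft, ]
  x <- x / sqrt(sum(x^2))
  ydown <- .perpComponent(cf[att, ] - cf[cLeft, ], x)
  ydown <- ydown / sqrt(sum(ydown^2))
  yup <- -ydown
  z <- c(x[2] * yup[3] - x[3] * yup[2],
         x[3] * yup[1] - x[1] * yup[3],
         x[1] * yup[2] - x[2] * yup[1])
  sgn <- if (face == "top") 1 else -1
  # pyramidalize the former sp2 carbons toward the incoming oxygens so the
  # constructed geometry is unambiguously tetrahedral: the carbon moves off
  # the plane of its three remaining substituents, which tilt away from O
  cf[cLeft, ] <- cf[cLeft, ] + 0.40 * sgn * z
  cf[cRight, ] <- cf[cRight, ] + 0.40 * sgn * z
  o1 <- cf[cLeft, ] + 1.43 * sgn * z
  o2 <- cf[cRight, ] + 1.43 * sgn * z
  h1dir <- sgn * z - 0.6 * x
  h2dir <- sgn * z + 0.6 * x
  h1 <- o1 + 0.97 * h1dir / sqrt(sum(h1dir^2))
  h2 <- o2 + 0.97 * h2dir / sqrt(sum(h2dir^2))
  n <- length(s@elements)
  elements <- c(s@elements, "O", "H", "O", "H")
  coords <- rbind(cf, o1, h1, o2, h2)
  bonds <- s@bonds
  dbl <- which((bonds$i == u@c1 & bonds$j == u@c2) |
                 (bonds$i == u@c2 & bonds$j == u@c1))
  bonds$order[dbl] <- 1L
  bonds <- rbind(bonds,
                 data.frame(i = c(cLeft, n + 1L, cRight, n + 3L),
                            j = c(n + 1L, n + 2L, n + 3L, n + 4L),
                            order = 1L))
  sdf <- .sdfText(elements, coords, bonds, title = "syn diol")
  smiles <- .rdCanonFromSdf(sdf)
  if (is.na(smiles))
    stop("constructed diol geometry could not be perceived", call. = FALSE)
  list(smiles = smiles, sdf = sdf)
}
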