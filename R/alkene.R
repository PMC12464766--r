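# Alkene identification, substituent fragment extraction and classification.

.bondedAtoms <- function(s, i) {
  b <- s@bonds
  sort(c(b$j[b$i == i], b$i[b$j == i]))
}

.perpComponent <- function(v, axis) {
  v - sum(v * axis) * axis
}

# deterministic BFS of the fragment reachable from `attachment` without
# passing through the alkene carbons; neighbor ties broken by atom index
# (canonical rank under canonical parsing)
.fragmentBfs <- function(s, attachment, forbidden) {
  order <- integer()
  seen <- c(forbidden, attachment)
  queue <- attachment
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    nb <- setdiff(.bondedAtoms(s, v), seen)
    seen <- c(seen, nb)
    queue <- c(queue, nb)
  }
  order
}

.makeFragment <- function(s, attachment, c1, c2) {
  ord <- .fragmentBfs(s, attachment, forbidden = c(c1, c2))
  new("SubstituentFragment",
      attachmentAtom = as.integer(attachment),
      memberAtoms = as.integer(sort(ord)),
      bfsOrder = as.integer(ord),
      isHydrogen = identical(s@elements[ord], "H"))
}

# compact structural signature of a fragment, used for deterministic
# tie-breaking and graph-level substituent comparison
.fragmentSignature <- function(f, s) {
  ord <- f@bfsOrder
  paste0(paste(s@elements[ord], collapse = ""), "|",
         paste(sort(s@bonds$order[s@bonds$i %in% ord | s@bonds$j %in% ord]),
               collapse = ""))
}

.alkeneCandidates <- function(s) {
  b <- s@bonds
  # carbons engaged in any other multiple bond (cumulated dienes etc.)
  multi <- table(c(b$i[b$order >= 2], b$j[b$order >= 2]))
  inMulti2 <- function(a) !is.na(multi[as.character(a)]) &&
    multi[as.character(a)] > 1
  keep <- which(b$order == 2L &
                  s@elements[b$i] == "C" & s@elements[b$j] == "C" &
                  !s@aromatic[b$i] & !s@aromatic[b$j])
  keep <- keep[!vapply(keep, function(k) inMulti2(b$i[k]) || inMulti2(b$j[k]),
                       logical(1))]
  b[keep, c("i", "j"), drop = FALSE]
}

.bondInRing <- function(s, i, j) {
  g <- .moleculeGraph(s)
  eid <- igraph::get_edge_ids(g, c(i, j))
  !(eid %in% as.integer(igraph::bridges(g)))
}

#' Locate the target alkene and extract its four positional substituents
#'
#' Finds the unique nonaromatic, noncumulated C=C bond, assigns its four
#' substituent positions from the 3-D geometry of conformer 1 (cis pairs are
#' (bottom_left, bottom_right) and (top_left, top_right)), and extracts each
#' substituent as a breadth-first fragment. Hydrogen positions carry a
#' one-atom hydrogen fragment.
#'
#' @param s a \linkS4class{Structure3D} with at least one conformer.
#' @param selector optional integer pair of atom indices naming the alkene
#'   carbons when the molecule contains several candidate alkenes.
#' @return an \linkS4class{AlkeneUnit}.
#' @export
findAlkene <- function(s, selector = NULL) {
  cand <- .alkeneCandidates(s)
  if (nrow(cand) == 0L)
    stop("no nonaromatic C=C bond found in ", s@canonicalId, call. = FALSE)
  if (!is.null(selector)) {
    sel <- sort(as.integer(selector))
    hit <- which(pmin(cand$i, cand$j) == sel[1] & pmax(cand$i, cand$j) == sel[2])
    if (length(hit) != 1L)
      stop("selector (", sel[1], ",", sel[2], ") does not name a candidate ",
           "alkene", call. = FALSE)
    cand <- cand[hit, , drop = FALSE]
  }
  if (nrow(cand) > 1L) {
    stop("ambiguous alkene: ", nrow(cand), " candidate C=C bonds (",
         paste(sprintf("%d=%d", cand$i, cand$j), collapse = ", "),
         "); pass a selector", call. = FALSE)
  }
  c1 <- min(cand$i[1], cand$j[1])
  c2 <- max(cand$i[1], cand$j[1])
  n1 <- setdiff(.bondedAtoms(s, c1), c2)
  n2 <- setdiff(.bondedAtoms(s, c2), c1)
  if (length(n1) != 2L || length(n2) != 2L)
    stop("alkene carbons must each bear exactly two substituent positions",
         call. = FALSE)
  cf <- s@conformers[[1]]
  x <- cf[c2, ] - cf[c1, ]
  x <- x / sqrt(sum(x^2))
  # bottom-left is the lower-index neighbor of c1 by convention; the
  # alignment cascade later considers all mirror/rotation frames
  u11 <- .perpComponent(cf[n1[1], ] - cf[c1, ], x)
  y_down <- u11 / sqrt(sum(u11^2))
  sideOf <- function(a, center) {
    w <- .perpComponent(cf[a, ] - cf[center, ], x)
    sum(w * y_down)
  }
  br_first <- sideOf(n2[1], c2) > 0
  pos_atoms <- c(bottom_left = n1[1],
                 bottom_right = if (br_first) n2[1] else n2[2],
                 top_right = if (br_first) n2[2] else n2[1],
                 top_left = n1[2])
  positions <- lapply(pos_atoms, .makeFragment, s = s, c1 = c1, c2 = c2)
  # stereo: a stereogenic alkene must have its geometry fixed by the input
  # (explicit bond stereo) or by a ring
  frags1 <- vapply(positions[c("bottom_left", "top_left")],
                   .fragmentSignature, character(1), s = s)
  frags2 <- vapply(positions[c("bottom_right", "top_right")],
                   .fragmentSignature, character(1), s = s)
  stereogenic <- (frags1[1] != frags1[2]) && (frags2[1] != frags2[2]) &&
    !all(vapply(positions, function(f) f@isHydrogen, logical(1)))
  declared <- nrow(s@stereoBonds) > 0 &&
    any((s@stereoBonds$i == c1 & s@stereoBonds$j == c2) |
          (s@stereoBonds$i == c2 & s@stereoBonds$j == c1))
  stereoDefined <- !stereogenic || declared || .bondInRing(s, c1, c2)
  if (!stereoDefined)
    stop("stereochemistry undefined for stereogenic alkene in ",
         s@canonicalId, call. = FALSE)
  new("AlkeneUnit", c1 = as.integer(c1), c2 = as.integer(c2),
      positions = positions, stereoDefined = stereoDefined)
}

#' List candidate alkenes of a structure
#'
#' @param s a \linkS4class{Structure3D}.
#' @return data.frame with columns \code{i}, \code{j} of candidate C=C bonds.
#' @export
alkeneCandidates <- function(s) {
  out <- .alkeneCandidates(s)
  rownames(out) <- NULL
  out
}

#' Classify the substitution pattern of an aligned alkene
#'
#' Mono/Gem/Cis/Trans follow from the hydrogen-count pattern; trisubstituted
#' alkenes are suffixed with the quadrant holding the lone hydrogen under
#' the given alignment (TriQ3 means the hydrogen sits in Q3); Tetra has no
#' hydrogen positions.
#'
#' @param u an \linkS4class{AlkeneUnit}.
#' @param a the \linkS4class{QuadrantAssignment} computed for \code{u}.
#' @return one of the eight class labels (see \code{\link{alkeneClasses}}).
#' @export
classifyAlkene <- function(u, a) {
  if (!identical(sort(names(a@quadrantOf)), c("Q1", "Q2", "Q3", "Q4")))
    stop("invalid assignment for classification", call. = FALSE)
  isH <- vapply(u@positions, function(f) f@isHydrogen, logical(1))
  nH <- sum(isH)
  if (nH == 3L) return("Mono")
  if (nH == 0L) return("Tetra")
  if (nH == 1L) {
    hpos <- names(isH)[isH]
    q <- names(a@quadrantOf)[a@quadrantOf == hpos]
    if (length(q) != 1L)
      stop("assignment does not cover the hydrogen position '", hpos, "'",
           call. = FALSE)
    return(paste0("Tri", q))
  }
  if (nH == 2L) {
    hkeys <- names(isH)[isH]
    onC1 <- hkeys %in% c("bottom_left", "top_left")
    if (all(onC1) || all(!onC1)) return("Gem")
    cis_pairs <- list(c("bottom_left", "bottom_right"),
                      c("top_left", "top_right"))
    hcis <- any(vapply(cis_pairs, function(p) setequal(hkeys, p), logical(1)))
    # hydrogens cis to each other means the substituents are cis as well
    return(if (hcis) "Cis" else "Trans")
  }
  # ethylene itself: featurizable, but outside the eight substituted classes
  "Unsub"
}
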