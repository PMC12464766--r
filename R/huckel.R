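# Hueckel-level surrogate for the whole-alkene electronic block.
#
# A topological pi-electron model stands in for natural bond orbital
# analysis: pi/pi* energies and occupancies come from diagonalizing a
# Hueckel matrix over the conjugated system containing the alkene, frontier
# energies from its filled spectrum, and "natural-type" charges from the
# structure's empirical partial-charge model. The energy scale is
# alpha = -6.3 eV, beta = -3.2 eV; values are surrogate-level trends, not
# quantum-chemical observables, but they order conjugation effects
# (e.g. acceptor-conjugated alkenes have lower LUMOs).

.HUCKEL_ALPHA <- -6.3
.HUCKEL_BETA <- -3.2

# heteroatom Coulomb parameters h (diagonal, in units of beta) and electron
# counts, split by participation: "multiple" = atom inside a double/aromatic
# bond (contributes 1 electron), "donor" = lone-pair donor attached to the
# pi system (contributes 2)
.HUCKEL_H <- list(
  multiple = c(C = 0, N = 0.5, O = 1.0, S = 0.5),
  donor = c(N = 1.5, O = 2.0, S = 1.3, F = 3.0, Cl = 2.0, Br = 1.5)
)

# bond resonance factors k (in units of beta) for C-X pi bonds; pairs of
# heteroatoms use the geometric mean of their C-X factors
.HUCKEL_K <- c(C = 1.0, N = 0.9, O = 0.9, S = 0.7, F = 0.7, Cl = 0.4,
               Br = 0.3)
.HUCKEL_K_SINGLE <- 0.9   # single bond between two pi atoms (conjugation)

.piSystem <- function(s, u) {
  b <- s@bonds
  inMultiple <- rep(FALSE, length(s@elements))
  mb <- b[b$order >= 2L | (b$order == 4L), , drop = FALSE]
  inMultiple[c(mb$i, mb$j)] <- TRUE
  inMultiple <- inMultiple |
    (s@aromatic & s@elements %in% names(.HUCKEL_K))
  core <- which(inMultiple & s@elements %in% c("C", "N", "O", "S"))
  # lone-pair donors directly bonded to a core atom
  donors <- integer()
  for (k in seq_len(nrow(b))) {
    for (pair in list(c(b$i[k], b$j[k]), c(b$j[k], b$i[k]))) {
      a <- pair[1]; o <- pair[2]
      if (!(a %in% core) && (o %in% core) && b$order[k] == 1L &&
          s@elements[a] %in% names(.HUCKEL_H$donor)) {
        donors <- c(donors, a)
      }
    }
  }
  atoms <- sort(unique(c(core, donors)))
  # restrict to the connected pi component containing the alkene
  sub <- b[b$i %in% atoms & b$j %in% atoms, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    sub[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = atoms))
  comp <- igraph::components(g)$membership
  hit <- comp[as.character(u@c1)]
  atoms <- atoms[comp[as.character(atoms)] == hit]
  list(atoms = atoms, isDonor = !(atoms %in% core))
}

.huckelSolve <- function(s, pi_sys) {
  atoms <- pi_sys$atoms
  n <- length(atoms)
  el <- s@elements[atoms]
  M <- matrix(0, n, n)
  electrons <- numeric(n)
  for (k in seq_len(n)) {
    if (pi_sys$isDonor[k]) {
      M[k, k] <- .HUCKEL_H$donor[[el[k]]]
      electrons[k] <- 2
    } else {
      M[k, k] <- .HUCKEL_H$multiple[[el[k]]]
      electrons[k] <- 1
      # aromatic N/O with three connections donate their lone pair
      if (el[k] %in% c("N", "O") && s@aromatic[atoms[k]]) {
        deg <- length(.bondedAtoms(s, atoms[k]))
        if (el[k] == "O" || deg >= 3L) {
          M[k, k] <- .HUCKEL_H$donor[[el[k]]]
          electrons[k] <- 2
        }
      }
    }
  }
  b <- s@bonds
  idx <- match(seq_along(s@elements), atoms)
  for (r in seq_len(nrow(b))) {
    ki <- idx[b$i[r]]; kj <- idx[b$j[r]]
    if (is.na(ki) || is.na(kj)) next
    kfac <- sqrt(.HUCKEL_K[[el[ki]]] * .HUCKEL_K[[el[kj]]])
    if (b$order[r] == 1L && !pi_sys$isDonor[ki] && !pi_sys$isDonor[kj])
      kfac <- kfac * .HUCKEL_K_SINGLE
    M[ki, kj] <- M[ki, kj] + kfac
    M[kj, ki] <- M[kj, ki] + kfac
  }
  eig <- eigen(M, symmetric = TRUE)
  # energies E = alpha + x*beta; beta < 0, so large x = low (bonding) energy
  energies <- .HUCKEL_ALPHA + eig$values * .HUCKEL_BETA
  ord <- order(energies)
  energies <- energies[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  ne <- sum(electrons)
  occ <- numeric(n)
  full <- min(n, floor(ne / 2))
  occ[seq_len(full)] <- 2
  if (ne / 2 > full && full < n) occ[full + 1L] <- ne - 2 * full
  list(atoms = atoms, energies = energies, vectors = vectors, occ = occ)
}

#' Whole-alkene electronic descriptor block (Hueckel-level surrogate)
#'
#' Returns the 15 electronic features of the aligned alkene: pi and pi*
#' orbital energies and occupancies (from projection of the local C1=C2
#' pi-bond orbital onto the Hueckel eigenvectors), HOMO and LUMO energies
#' and their gap, the conformer-averaged dipole magnitude from the partial
#' charges (Debye), natural-type charges on C1, C2 and the four quadrant
#' attachment atoms, and the summed charge of the alkene unit.
#'
#' @param u an \linkS4class{AlkeneUnit}.
#' @param s the parent \linkS4class{Structure3D} with charges assigned.
#' @param a the \linkS4class{QuadrantAssignment} for \code{u} (orders the
#'   per-quadrant charges).
#' @return named numeric of length 15.
#' @export
electronicBlock <- function(u, s, a) {
  if (length(s@partialCharges) == 0L)
    stop("electronic block requires assigned partial charges", call. = FALSE)
  sol <- .huckelSolve(s, .piSystem(s, u))
  k1 <- match(u@c1, sol$atoms)
  k2 <- match(u@c2, sol$atoms)
  stopifnot(!is.na(k1), !is.na(k2))
  n <- length(sol$atoms)
  bond <- numeric(n); bond[c(k1, k2)] <- 1 / sqrt(2)
  star <- numeric(n); star[k1] <- 1 / sqrt(2); star[k2] <- -1 / sqrt(2)
  w_bond <- drop(crossprod(sol$vectors, bond))^2
  w_star <- drop(crossprod(sol$vectors, star))^2
  pi_idx <- which.max(w_bond)
  star_idx <- which.max(w_star)
  occupied <- sol$occ > 0
  homo <- max(sol$energies[occupied])
  lumo <- if (any(!occupied)) min(sol$energies[!occupied]) else homo
  q <- s@partialCharges
  dip <- vapply(s@conformers, function(cf) {
    sqrt(sum(colSums(cf * q)^2))
  }, numeric(1))
  dipole <- sum(dip * s@conformerWeights) * 4.803  # e*Angstrom -> Debye
  att <- vapply(c("Q1", "Q2", "Q3", "Q4"), function(qq) {
    u@positions[[a@quadrantOf[[qq]]]]@attachmentAtom
  }, integer(1))
  out <- c(
    sol$energies[pi_idx],
    sol$energies[star_idx],
    sum(sol$occ * w_bond),
    sum(sol$occ * w_star),
    homo,
    lumo,
    lumo - homo,
    dipole,
    q[u@c1],
    q[u@c2],
    q[att],
    q[u@c1] + q[u@c2] + sum(q[att])
  )
  names(out) <- .ELECTRONIC_NAMES
  out
}

.ELECTRONIC_NAMES <- c(
  "pi energy", "pi* energy", "pi occupancy", "pi* occupancy",
  "HOMO", "LUMO", "HOMO-LUMO gap", "dipole",
  "C1 natural charge", "C2 natural charge",
  "Q1 natural charge", "Q2 natural charge", "Q3 natural charge",
  "Q4 natural charge", "alkene charge sum")
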