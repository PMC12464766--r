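# Steric, electrostatic, radial-distribution and electronic descriptors.
#
# All fragment descriptors are conformer-averaged with the structure's
# conformer weights, and all are invariant to rigid motions of the
# conformers (they depend only on interatomic geometry relative to the
# alkene frame).

.COULOMB_KCAL <- 332.06                      # kcal*Angstrom/(mol*e^2)
.RDF_B <- 20                                 # Gaussian smoothing, 1/Angstrom^2
.RDF_RADII <- 1:7                            # sphere centers, Angstrom
.VOL_GRID <- 0.2                             # volume grid spacing, Angstrom
.ESP_SURFACE_SCALE <- 1.2                    # vdW scaling of the ESP surface
.ESP_POINT_DENSITY <- 2                      # surface points per Angstrom^2

# fragment atoms for steric work: heavy members plus their bonded hydrogens
.fragmentAtomsWithH <- function(f, s) {
  mem <- f@memberAtoms
  b <- s@bonds
  hs <- c(b$j[b$i %in% mem & s@elements[b$j] == "H"],
          b$i[b$j %in% mem & s@elements[b$i] == "H"])
  sort(unique(c(mem, hs)))
}

# first three heavy atoms of the BFS order plus their hydrogens
.bfs3Atoms <- function(f, s) {
  if (f@isHydrogen) return(f@memberAtoms)
  heavy <- f@bfsOrder[s@elements[f@bfsOrder] != "H"]
  first3 <- head(heavy, 3L)
  sub <- f
  sub@memberAtoms <- first3
  sub@bfsOrder <- first3
  .fragmentAtomsWithH(sub, s)
}

# ---- Sterimol ---------------------------------------------------------------

.sterimolOne <- function(coords, radii, origin, axis) {
  # L along the attachment axis measured from the alkene carbon (origin);
  # B1/B5 as min/max perpendicular half-widths over sampled directions
  rel <- sweep(coords, 2, origin)
  proj <- drop(rel %*% axis)
  L <- max(proj + radii)
  perp <- rel - outer(proj, axis)
  # orthonormal basis of the plane perpendicular to the axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  u <- drop(perp %*% e1)
  v <- drop(perp %*% e2)
  theta <- seq(0, 2 * pi, length.out = 361L)[-361L]
  ext <- vapply(theta, function(th) {
    max(u * cos(th) + v * sin(th) + radii)
  }, numeric(1))
  c(L = L, B1 = min(ext), B5 = max(ext))
}

#' Sterimol parameters of a substituent fragment (3-heavy-atom truncation)
#'
#' L, B1 and B5 of the fragment truncated to the first three heavy atoms of
#' its breadth-first order (plus their hydrogens), measured along the axis
#' from the alkene carbon to the attachment atom and conformer-averaged.
#' Hydrogen positions are processed identically (the fragment is the lone
#' hydrogen atom), yielding well-defined dense descriptor values.
#'
#' @param f a \linkS4class{SubstituentFragment}.
#' @param s the parent \linkS4class{Structure3D}.
#' @param alkeneCarbon atom index of the alkene carbon the fragment attaches
#'   to.
#' @return named numeric: L, B1, B5 in Angstrom.
#' @export
sterimol3 <- function(f, s, alkeneCarbon) {
  atoms <- .bfs3Atoms(f, s)
  radii <- vdwRadius(s@elements[atoms])
  vals <- vapply(seq_along(s@conformers), function(k) {
    cf <- s@conformers[[k]]
    origin <- cf[alkeneCarbon, ]
    axis <- cf[f@attachmentAtom, ] - origin
    axis <- axis / sqrt(sum(axis^2))
    .sterimolOne(cf[atoms, , drop = FALSE], radii, origin, axis)
  }, numeric(3))
  drop(vals %*% s@conformerWeights)
}

# ---- van der Waals volumes --------------------------------------------------

# Four interleaved sublattice offsets (face-centered pattern): averaging
# the counts cancels the lattice-alignment bias of a single grid, keeping
# small-sphere volumes accurate to a few tenths of a percent at 0.2 A.
.VOL_OFFSETS <- list(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5),
                     c(0, 0.5, 0.5))

.unionVolumeOne <- function(coords, radii, spacing = .VOL_GRID) {
  ests <- vapply(.VOL_OFFSETS, function(off) {
    lo <- apply(coords - radii, 2, min) - spacing + off * spacing
    hi <- apply(coords + radii, 2, max) + spacing
    gx <- seq(lo[1], hi[1], by = spacing)
    gy <- seq(lo[2], hi[2], by = spacing)
    gz <- seq(lo[3], hi[3], by = spacing)
    inside <- array(FALSE, c(length(gx), length(gy), length(gz)))
    for (a in seq_len(nrow(coords))) {
      r <- radii[a]
      ix <- which(abs(gx - coords[a, 1]) <= r)
      iy <- which(abs(gy - coords[a, 2]) <= r)
      iz <- which(abs(gz - coords[a, 3]) <= r)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (gx[ix] - coords[a, 1])^2
      dy2 <- (gy[iy] - coords[a, 2])^2
      dz2 <- (gz[iz] - coords[a, 3])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      inside[ix, iy, iz] <- inside[ix, iy, iz] | (d2 <= r^2)
    }
    sum(inside) * spacing^3
  }, numeric(1))
  mean(ests)
}

.volumeOfAtoms <- function(atoms, s) {
  radii <- vdwRadius(s@elements[atoms])
  vals <- vapply(s@conformers, function(cf) {
    .unionVolumeOne(cf[atoms, , drop = FALSE], radii)
  }, numeric(1))
  sum(vals * s@conformerWeights)
}

#' Van der Waals union volumes of a substituent fragment
#'
#' \code{maxVolume} integrates the union volume of all fragment atoms (with
#' hydrogens) on a 0.2 Angstrom grid; \code{bfs3Volume} restricts the union
#' to the first three heavy atoms of the BFS order plus their hydrogens, so
#' \code{bfs3Volume <= maxVolume} always. Fragments with fewer than three
#' heavy atoms use all available atoms. Conformer-averaged.
#'
#' @inheritParams sterimol3
#' @return volume in Angstrom^3.
#' @export
maxVolume <- function(f, s) {
  .volumeOfAtoms(.fragmentAtomsWithH(f, s), s)
}

#' @rdname maxVolume
#' @export
bfs3Volume <- function(f, s) {
  .volumeOfAtoms(.bfs3Atoms(f, s), s)
}

# ---- electrostatic potential statistics ------------------------------------

.fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Surface points over `atoms` (indices into coords_all), excluded against
# the scaled spheres of every atom of the molecule so no point sits inside
# the molecular surface.
.espSurfacePoints <- function(atoms, coords_all, radii_all) {
  scaled <- radii_all * .ESP_SURFACE_SCALE
  pts <- vector("list", length(atoms))
  for (k in seq_along(atoms)) {
    a <- atoms[k]
    n <- max(8L, ceiling(.ESP_POINT_DENSITY * 4 * pi * scaled[a]^2))
    sp <- sweep(.fibonacciSphere(n) * scaled[a], 2, coords_all[a, ], "+")
    keep <- rep(TRUE, nrow(sp))
    for (o in seq_len(nrow(coords_all))) {
      if (o == a) next
      d2 <- rowSums(sweep(sp, 2, coords_all[o, ])^2)
      keep <- keep & d2 > (scaled[o] - 1e-9)^2
    }
    pts[[k]] <- sp[keep, , drop = FALSE]
  }
  do.call(rbind, pts)
}

#' Electrostatic-potential statistics over a fragment surface
#'
#' The potential of all atomic point charges of the molecule is evaluated on
#' the solvent-excluded surface of the fragment's atoms (vdW radii scaled by
#' 1.2, about 2 points per square Angstrom). Returns the minimum and the
#' 99th percentile (nearest-rank convention), conformer-averaged, in
#' kcal/mol.
#'
#' @inheritParams sterimol3
#' @return named numeric: \code{esp_min}, \code{esp_99}.
#' @export
espStats <- function(f, s) {
  if (length(s@partialCharges) == 0L)
    stop("partial charges have not been assigned", call. = FALSE)
  atoms <- .fragmentAtomsWithH(f, s)
  radii_all <- vdwRadius(s@elements)
  q <- s@partialCharges
  vals <- vapply(s@conformers, function(cf) {
    pts <- .espSurfacePoints(atoms, cf, radii_all)
    if (nrow(pts) == 0L) return(c(0, 0))  # fully buried fragment surface
    v <- numeric(nrow(pts))
    for (a in seq_along(q)) {
      d <- sqrt(rowSums(sweep(pts, 2, cf[a, ])^2))
      d[d < 1e-6] <- 1e-6
      v <- v + q[a] / d
    }
    v <- v * .COULOMB_KCAL
    n99 <- max(1L, ceiling(0.99 * length(v)))
    c(min(v), sort(v)[n99])
  }, numeric(2))
  est <- drop(vals %*% s@conformerWeights)
  c(esp_min = est[1], esp_99 = est[2])
}

# ---- radial distribution block ---------------------------------------------

#' Conformer-averaged radial distribution descriptors around the alkene
#'
#' For each alkene carbon and each sphere radius r_k = k Angstrom
#' (k = 1..7), sums the polarizability-weighted Gaussian-smoothed density
#' \code{sum_a p_a exp(-B (d(c,a) - r_k)^2)} over all atoms except the two
#' alkene carbons, with smoothing B = 20 per square Angstrom, then averages
#' over conformers. Captures average dispersion, steric occupancy and
#' conformational flexibility around the reacting bond.
#'
#' @param u an \linkS4class{AlkeneUnit}.
#' @param s the parent \linkS4class{Structure3D}.
#' @return named numeric of length 14: \code{C1 RDF 1..7}, \code{C2 RDF 1..7}.
#' @export
rdfBlock <- function(u, s) {
  if (length(s@conformers) == 0L) stop("no conformers available", call. = FALSE)
  others <- setdiff(seq_along(s@elements), c(u@c1, u@c2))
  p <- if (length(others)) atomPolarizability(s@elements[others]) else numeric()
  one <- function(center_idx) {
    vals <- vapply(s@conformers, function(cf) {
      if (!length(others)) return(numeric(7))
      d <- sqrt(rowSums(sweep(cf[others, , drop = FALSE], 2,
                              cf[center_idx, ])^2))
      vapply(.RDF_RADII, function(rk) {
        sum(p * exp(-.RDF_B * (d - rk)^2))
      }, numeric(1))
    }, numeric(7))
    drop(vals %*% s@conformerWeights)
  }
  out <- c(one(u@c1), one(u@c2))
  names(out) <- c(paste("C1 RDF", 1:7), paste("C2 RDF", 1:7))
  out
}
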