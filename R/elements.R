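# Fixed element data tables.
#
# Van der Waals radii (Angstrom) follow Bondi (1964) with the Rowland &
# Taylor value for hydrogen. Static dipole polarizabilities (Angstrom^3)
# follow the CRC compilation of atomic polarizabilities. Both tables are
# deliberately shipped as code: they are small, immutable inputs of the
# descriptor definitions, not tunables.

.VDW_RADII <- c(
  H = 1.10, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98
)

.ATOM_POLARIZABILITY <- c(
  H = 0.667, B = 3.03, C = 1.76, N = 1.10, O = 0.802, F = 0.557,
  Si = 5.38, P = 3.63, S = 2.90, Cl = 2.18, Br = 3.05, I = 5.35
)

#' Van der Waals radii used by the steric descriptors
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
vdwRadius <- function(elements) {
  r <- .VDW_RADII[elements]
  if (anyNA(r)) {
    stop("no van der Waals radius tabulated for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  unname(r)
}

#' Atomic dipole polarizabilities
#'
#' Used as the per-atom weights of the radial distribution descriptor and as
#' the tie-breaking quantity of alignment cascade rules 5 and 6.
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of polarizabilities in Angstrom^3.
#' @export
atomPolarizability <- function(elements) {
  p <- .ATOM_POLARIZABILITY[elements]
  if (anyNA(p)) {
    stop("no polarizability tabulated for element(s): ",
         paste(unique(elements[is.na(p)]), collapse = ", "), call. = FALSE)
  }
  unname(p)
}
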