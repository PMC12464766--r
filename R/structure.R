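# Structure parsing, conformer-ensemble generation and partial charges.

.payloadToStructure <- function(p, chargeModel = "gasteiger") {
  if (!is.null(p$error)) {
    stop("failed to parse input",
         if (!is.null(p$input)) paste0(" '", p$input, "'"), ": ", p$error,
         call. = FALSE)
  }
  coords <- do.call(rbind, lapply(p$coords, as.numeric))
  bonds <- if (length(p$bonds)) {
    data.frame(
      i = vapply(p$bonds, function(b) as.integer(b[[1]]), integer(1)),
      j = vapply(p$bonds, function(b) as.integer(b[[2]]), integer(1)),
      order = vapply(p$bonds, function(b) as.integer(b[[3]]), integer(1)))
  } else data.frame(i = integer(), j = integer(), order = integer())
  sb <- if (length(p$stereo_bonds)) {
    data.frame(
      i = vapply(p$stereo_bonds, function(b) as.integer(b[[1]]), integer(1)),
      j = vapply(p$stereo_bonds, function(b) as.integer(b[[2]]), integer(1)))
  } else data.frame(i = integer(), j = integer())
  fc <- vapply(p$formal_charges, as.integer, integer(1))
  q <- vapply(p$charges, as.numeric, numeric(1))
  q <- q + (sum(fc) - sum(q)) / length(q)  # exact charge conservation
  new("Structure3D",
      elements = vapply(p$elements, as.character, character(1)),
      formalCharges = fc,
      bonds = bonds,
      conformers = list(coords),
      conformerWeights = 1,
      partialCharges = q,
      aromatic = vapply(p$aromatic, isTRUE, logical(1)),
      stereoBonds = sb,
      canonicalId = p$canonical,
      chargeModel = chargeModel)
}

#' Parse molecules into Structure3D objects
#'
#' \code{parseStructures} is the batch entry point: all molecules are handed
#' to the RDKit helper in a single subprocess call, which canonicalizes,
#' materializes explicit hydrogens, embeds one 3-D conformer (seeded ETKDG
#' followed by an MMFF cleanup, so coordinates are bit-reproducible) and
#' assigns Gasteiger partial charges. \code{parseStructure} parses a single
#' molecule.
#'
#' SMILES inputs are rebuilt from their canonical form, so atom ordering
#' (and every downstream descriptor) is invariant to the input atom
#' ordering; parsing the \code{canonicalId} of a parsed structure reproduces
#' the same \code{canonicalId}. SDF inputs keep their given coordinates as
#' conformer 1 (hydrogens are added with generated coordinates if missing).
#'
#' @param texts character vector of SMILES strings, or the text lines of an
#'   SDF (V2000) file when \code{format = "sdf"}.
#' @param format "smiles" or "sdf".
#' @param embedSeed integer seed for the 3-D embedding of SMILES inputs.
#' @return \code{parseStructures}: a list of \linkS4class{Structure3D};
#'   \code{parseStructure}: a single \linkS4class{Structure3D}.
#' @examples
#' \dontrun{
#' s <- parseStructure("C=Cc1ccccc1")   # styrene
#' canonicalId(s)
#' }
#' @export
parseStructures <- function(texts, format = c("smiles", "sdf"),
                            embedSeed = 7L) {
  format <- match.arg(format)
  if (format == "smiles") {
    if (length(texts) == 0L) stop("empty input: no SMILES given", call. = FALSE)
    if (any(!nzchar(trimws(texts))))
      stop("empty input: blank SMILES at position ",
           which(!nzchar(trimws(texts)))[1], call. = FALSE)
    payloads <- .rdParseSmiles(texts, seed = embedSeed)
  } else {
    if (length(texts) == 0L || !any(nzchar(texts)))
      stop("empty input: no SDF text given", call. = FALSE)
    payloads <- .rdParseSdf(texts)
  }
  lapply(payloads, .payloadToStructure)
}

#' @rdname parseStructures
#' @param text one SMILES string or the lines of one SDF record.
#' @export
parseStructure <- function(text, format = c("smiles", "sdf"), embedSeed = 7L) {
  format <- match.arg(format)
  if (format == "smiles" && (length(text) != 1L || !nzchar(trimws(text))))
    stop("empty input: expected one SMILES string", call. = FALSE)
  parseStructures(text, format = format, embedSeed = embedSeed)[[1]]
}

# ---- conformers -------------------------------------------------------------

.kabschRmsd <- function(A, B) {
  # optimal-superposition RMSD of two n x 3 coordinate sets
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(Ac, Bc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((Bc - Ac %*% t(R))^2)))
}

.moleculeGraph <- function(s) {
  igraph::graph_from_data_frame(
    s@bonds[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_along(s@elements)))
}

.rotatableBonds <- function(s) {
  b <- s@bonds
  heavy <- s@elements != "H"
  deg <- tabulate(c(b$i, b$j), nbins = length(s@elements))
  g <- .moleculeGraph(s)
  is_bridge <- rep(FALSE, nrow(b))
  is_bridge[as.integer(igraph::bridges(g))] <- TRUE
  keep <- b$order == 1L & is_bridge & heavy[b$i] & heavy[b$j] &
    deg[b$i] > 1L & deg[b$j] > 1L
  b[keep, , drop = FALSE]
}

.bondSideAtoms <- function(s, i, j) {
  # atoms on the j-side once bond i-j is cut
  b <- s@bonds
  n <- length(s@elements)
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    if ((b$i[k] == i && b$j[k] == j) || (b$i[k] == j && b$j[k] == i)) next
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  seen <- logical(n)
  seen[j] <- TRUE
  queue <- j
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  which(seen)
}

.rotateAboutAxis <- function(coords, idx, p0, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  shifted <- sweep(coords[idx, , drop = FALSE], 2, p0)
  coords[idx, ] <- sweep(shifted %*% t(R), 2, -p0)
  coords
}

.graphDistances <- function(s) {
  igraph::distances(.moleculeGraph(s))
}

.hasClash <- function(s, coords, gd, scale = 0.55) {
  r <- vdwRadius(s@elements)
  D <- as.matrix(stats::dist(coords))
  lim <- outer(r, r, "+") * scale
  nb <- gd >= 3
  any(D[nb] < lim[nb])
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a seed-deterministic conformer ensemble
#'
#' Conformers are produced by torsion driving: every rotatable single bond is
#' assigned a perturbed dihedral drawn from the staggered wells, the subtree
#' is rotated rigidly, sterically clashing candidates are rejected, and
#' survivors are pruned at an RMSD threshold (0.5 Angstrom by default).
#' Molecules without rotatable bonds replicate the base conformer so the
#' ensemble always has \code{nConf} members. Weights are uniform. Identical
#' \code{(structure, nConf, seed)} give bit-identical coordinates.
#'
#' @param s a \linkS4class{Structure3D} with at least one conformer.
#' @param nConf positive integer, ensemble size target (default 25).
#' @param seed integer seed.
#' @param rmsdPrune RMSD pruning threshold in Angstrom (default 0.5).
#' @return the structure with its conformer list replaced by the ensemble.
#' @export
embedConformers <- function(s, nConf = 25L, seed = 1L, rmsdPrune = 0.5) {
  if (!is.numeric(nConf) || nConf < 1) stop("nConf must be >= 1", call. = FALSE)
  nConf <- as.integer(nConf)
  base <- s@conformers[[1]]
  rot <- .rotatableBonds(s)
  if (nrow(rot) == 0L) {
    s@conformers <- rep(list(base), nConf)
    s@conformerWeights <- rep(1 / nConf, nConf)
    return(s)
  }
  sides <- lapply(seq_len(nrow(rot)),
                  function(k) .bondSideAtoms(s, rot$i[k], rot$j[k]))
  gd <- .graphDistances(s)
  heavy <- s@elements != "H"
  kept <- .withSeed(seed, {
    kept <- list(base)
    trials <- 0L
    max_trials <- 60L * nConf
    while (length(kept) < nConf && trials < max_trials) {
      trials <- trials + 1L
      cand <- base
      for (k in seq_len(nrow(rot))) {
        ang <- (sample(c(0, 120, 240), 1) + stats::rnorm(1, 0, 15)) * pi / 180
        cand <- .rotateAboutAxis(cand, sides[[k]], cand[rot$i[k], ],
                                 cand[rot$j[k], ] - cand[rot$i[k], ], ang)
      }
      if (.hasClash(s, cand, gd)) next
      ok <- all(vapply(kept, function(kc)
        .kabschRmsd(kc[heavy, , drop = FALSE],
                    cand[heavy, , drop = FALSE]) >= rmsdPrune,
        logical(1)))
      if (ok) kept <- c(kept, list(cand))
    }
    kept
  })
  s@conformers <- kept
  s@conformerWeights <- rep(1 / length(kept), length(kept))
  s
}

# ---- partial charges --------------------------------------------------------

.chargeRegistry <- new.env(parent = emptyenv())

.rdkitGasteigerBackend <- function(s) {
  sdf <- .sdfText(s@elements, s@conformers[[1]], s@bonds)
  p <- .rdParseSdf(sdf)[[1]]
  if (!is.null(p$error)) stop("charge assignment failed: ", p$error, call. = FALSE)
  vapply(p$charges, as.numeric, numeric(1))
}

.obChargeBackend <- function(model) {
  force(model)
  function(s) {
    sdf <- .sdfText(s@elements, s@conformers[[1]], s@bonds)
    atoms <- .parseMol2Atoms(.splitMol2Records(
      .obSdfToMol2(sdf, charge_model = model))[[1]])
    atoms$charge
  }
}

assign("gasteiger", .rdkitGasteigerBackend, envir = .chargeRegistry)
for (.m in c("eem", "mmff94", "qeq", "eqeq")) {
  assign(.m, .obChargeBackend(.m), envir = .chargeRegistry)
}
rm(.m)

#' Charge-model registry
#'
#' The default backend is "gasteiger": partial equalization of orbital
#' electronegativity, a fast empirical model that depends only on
#' connectivity (symmetry-equivalent atoms receive identical charges).
#' OpenBabel's geometry-aware models (eem, mmff94, qeq, eqeq) are also
#' pre-registered, and \code{registerChargeBackend} accepts any function
#' taking a \linkS4class{Structure3D} and returning per-atom charges in
#' elementary charge units, so a semiempirical or DFT-level backend can be
#' plugged in without touching the descriptor code.
#'
#' @return \code{chargeBackends()}: names of registered backends.
#' @export
chargeBackends <- function() sort(ls(.chargeRegistry))

#' @rdname chargeBackends
#' @param name backend name.
#' @param fun function(Structure3D) -> numeric charges.
#' @export
registerChargeBackend <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .chargeRegistry)
  invisible(name)
}

#' Assign per-atom partial charges
#'
#' @param s a \linkS4class{Structure3D}.
#' @param method a registered charge backend name.
#' @return the structure with \code{partialCharges} populated; the total
#'   charge equals the total formal charge.
#' @export
assignPartialCharges <- function(s, method = "gasteiger") {
  if (!exists(method, envir = .chargeRegistry, inherits = FALSE)) {
    stop("unknown charge method '", method, "'; registered backends: ",
         paste(chargeBackends(), collapse = ", "), call. = FALSE)
  }
  q <- get(method, envir = .chargeRegistry)(s)
  stopifnot(length(q) == length(s@elements))
  q <- q + (sum(s@formalCharges) - sum(q)) / length(q)
  s@partialCharges <- q
  s@chargeModel <- method
  s
}

#' Write structures to an SDF file, one record per conformer
#'
#' @param structures list of \linkS4class{Structure3D}.
#' @param path output file path.
#' @return invisibly, the number of records written.
#' @export
writeStructuresSdf <- function(structures, path) {
  lines <- unlist(lapply(structures, function(s) {
    unlist(lapply(seq_along(s@conformers), function(k) {
      .sdfText(s@elements, s@conformers[[k]], s@bonds,
               title = paste0(s@canonicalId, " conformer ", k))
    }))
  }))
  writeLines(lines, path)
  invisible(sum(grepl("^\\$\\$\\$\\$", lines)))
}
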