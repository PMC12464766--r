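# Steric, electrostatic, RDF and electronic descriptor blocks.

# bare structure with hand-placed coordinates for closed-form oracles
.syntheticStructure <- function(elements, coords, bonds = NULL,
                                charges = NULL, formal = NULL) {
  n <- length(elements)
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(),
                                          order = integer())
  if (is.null(formal)) formal <- integer(n)
  new("Structure3D", elements = elements,
      formalCharges = as.integer(formal), bonds = bonds,
      conformers = list(coords), conformerWeights = 1,
      partialCharges = if (is.null(charges)) numeric() else charges,
      aromatic = rep(FALSE, n),
      stereoBonds = data.frame(i = integer(), j = integer()),
      canonicalId = "synthetic", chargeModel = "synthetic")
}

.fragmentOf <- function(atoms) {
  new("SubstituentFragment", attachmentAtom = atoms[1],
      memberAtoms = as.integer(sort(atoms)), bfsOrder = as.integer(atoms),
      isHydrogen = FALSE)
}

test_that("methyl Sterimol widths bracket the literature profile", {
  s <- parseStructure("C=CC")
  u <- findAlkene(s)
  isH <- vapply(u@positions, function(f) f@isHydrogen, logical(1))
  f <- u@positions[[names(isH)[!isH]]]
  carbon <- if (names(isH)[!isH] %in% c("bottom_left", "top_left")) u@c1
            else u@c2
  st <- sterimol3(f, s, carbon)
  # the threefold group has a non-circular width profile: B1 between the
  # hydrogens, B5 over one of them (classic values ~1.5 and ~2.0)
  expect_gt(st["B5"], st["B1"])
  expect_gt(st["B1"], 1.3); expect_lt(st["B1"], 1.9)
  expect_gt(st["B5"], 1.8); expect_lt(st["B5"], 2.3)
  expect_gt(st["L"], st["B5"])
})

test_that("Sterimol truncation makes long tails invisible", {
  s <- parseStructure("C=CCCCCCC")   # n-hexyl substituent
  u <- findAlkene(s)
  isH <- vapply(u@positions, function(f) f@isHydrogen, logical(1))
  key <- names(isH)[!isH]
  f <- u@positions[[key]]
  carbon <- if (key %in% c("bottom_left", "top_left")) u@c1 else u@c2
  before <- sterimol3(f, s, carbon)
  # displace every fragment atom beyond the 3-heavy-atom cutoff far away:
  # the truncated Sterimol values must not move at all
  kept <- ADquadrant:::.bfs3Atoms(f, s)
  tail_atoms <- setdiff(f@memberAtoms, kept)
  tail_h <- ADquadrant:::.fragmentAtomsWithH(f, s)
  tail_atoms <- union(tail_atoms, setdiff(tail_h, kept))
  s2 <- s
  cf <- s2@conformers[[1]]
  cf[tail_atoms, ] <- cf[tail_atoms, , drop = FALSE] + 50
  s2@conformers <- list(cf)
  after <- sterimol3(f, s2, carbon)
  expect_identical(before, after)
  # the full volume sees the tail, the truncated volume does not
  expect_identical(bfs3Volume(f, s), bfs3Volume(f, s2))
})

test_that("tert-butyl is wider than deep: B5 exceeds B1, with oracle", {
  s <- parseStructure("C=CC(C)(C)C")
  u <- findAlkene(s)
  isH <- vapply(u@positions, function(f) f@isHydrogen, logical(1))
  key <- names(isH)[!isH]
  f <- u@positions[[key]]
  carbon <- if (key %in% c("bottom_left", "top_left")) u@c1 else u@c2
  st <- sterimol3(f, s, carbon)
  expect_gt(st["B5"], st["B1"])
  # independent projection oracle on the single conformer
  atoms <- ADquadrant:::.bfs3Atoms(f, s)
  cf <- conformerCoords(s)[[1]]
  radii <- vdwRadius(atomElements(s)[atoms])
  origin <- cf[carbon, ]
  axis <- cf[f@attachmentAtom, ] - origin
  axis <- axis / sqrt(sum(axis^2))
  proj <- drop(sweep(cf[atoms, ], 2, origin) %*% axis)
  expect_equal(unname(st["L"]), max(proj + radii), tolerance = 1e-9)
})

test_that("volumes match closed forms and Monte-Carlo sampling", {
  # one sphere: a lone hydrogen fragment
  rH <- vdwRadius("H")
  s1 <- .syntheticStructure("H", matrix(0, 1, 3))
  f1 <- .fragmentOf(1L)
  v1 <- maxVolume(f1, s1)
  expect_equal(v1, 4 / 3 * pi * rH^3, tolerance = 0.02)
  # two far-apart spheres add
  s2 <- .syntheticStructure(c("C", "C"),
                            rbind(c(0, 0, 0), c(50, 0, 0)),
                            bonds = data.frame(i = 1L, j = 2L, order = 1L))
  v2 <- maxVolume(.fragmentOf(c(1L, 2L)), s2)
  expect_equal(v2, 2 * 4 / 3 * pi * vdwRadius("C")^3, tolerance = 0.01)
  # Monte-Carlo oracle on a real overlapping fragment (<= 10 atoms)
  s <- parseStructure("C=CCC")   # ethyl substituent
  u <- findAlkene(s)
  isH <- vapply(u@positions, function(f) f@isHydrogen, logical(1))
  f <- u@positions[[names(isH)[!isH]]]
  atoms <- ADquadrant:::.fragmentAtomsWithH(f, s)
  expect_lte(length(atoms), 10L)
  cf <- conformerCoords(s)[[1]][atoms, , drop = FALSE]
  radii <- vdwRadius(atomElements(s)[atoms])
  set.seed(4)
  lo <- apply(cf - radii, 2, min); hi <- apply(cf + radii, 2, max)
  pts <- cbind(runif(2e5, lo[1], hi[1]), runif(2e5, lo[2], hi[2]),
               runif(2e5, lo[3], hi[3]))
  inside <- rep(FALSE, nrow(pts))
  for (a in seq_along(radii))
    inside <- inside | rowSums(sweep(pts, 2, cf[a, ])^2) <= radii[a]^2
  v_mc <- mean(inside) * prod(hi - lo)
  expect_equal(maxVolume(f, s), v_mc, tolerance = 0.02)
})

test_that("bfs3 volume equals max volume up to three heavy atoms", {
  fx <- fx_genset()
  X <- fx$features
  for (q in c("Q1", "Q2", "Q3", "Q4")) {
    expect_true(all(X[, paste(q, "3-BFS Volume")] <=
                      X[, paste(q, "Max Volume")] + 1e-9))
  }
  # methyl: fragment smaller than the cutoff
  pr <- featurizeAlkene(parseStructure("C=CC"))
  v <- featureValues(pr$features)
  expect_equal(unname(v["Q1 3-BFS Volume"]), unname(v["Q1 Max Volume"]),
               tolerance = 1e-9)
  # hexyl: truncated
  hx <- featureValues(featurizeAlkene(parseStructure("C=CCCCCCC"))$features)
  expect_lt(hx["Q1 3-BFS Volume"], hx["Q1 Max Volume"])
  # propyl: exactly three heavy atoms, equal within grid tolerance
  py <- featureValues(featurizeAlkene(parseStructure("C=CCCC"))$features)
  expect_equal(unname(py["Q1 3-BFS Volume"]), unname(py["Q1 Max Volume"]),
               tolerance = 0.02)
})

test_that("ESP statistics obey the Coulomb closed form", {
  # all charges zero
  s0 <- .syntheticStructure(c("C", "C"), rbind(c(0, 0, 0), c(3, 0, 0)),
                            bonds = data.frame(i = 1L, j = 2L, order = 1L),
                            charges = c(0, 0))
  e0 <- espStats(.fragmentOf(1L), s0)
  expect_identical(unname(e0), c(0, 0))
  # a single charged atom: every surface point sits at 1.2 * r, so the
  # potential is exactly 332.06 q / (1.2 r) and min == p99
  q <- 1
  s1 <- .syntheticStructure("C", matrix(0, 1, 3), charges = q, formal = 1L)
  e1 <- espStats(.fragmentOf(1L), s1)
  expected <- 332.06 * q / (1.2 * vdwRadius("C"))
  expect_equal(unname(e1["esp_min"]), expected, tolerance = 1e-9)
  expect_equal(unname(e1["esp_99"]), expected, tolerance = 1e-9)
  # charges are a precondition
  sNo <- .syntheticStructure("C", matrix(0, 1, 3))
  expect_error(espStats(.fragmentOf(1L), sNo), "charges")
})

test_that("CF3 surfaces are more positive than methyl surfaces", {
  v_cf3 <- featureValues(featurizeAlkene(parseStructure("C=CC(F)(F)F"))$features)
  v_me <- featureValues(featurizeAlkene(parseStructure("C=CC"))$features)
  expect_gt(v_cf3["Q1 ESP_99"], v_me["Q1 ESP_99"])
  expect_true(all(fx_genset()$features[, "Q1 ESP_99"] >=
                    fx_genset()$features[, "Q1 ESP_MIN"]))
})

test_that("RDF matches direct formula evaluation and is rigid-motion
           invariant", {
  s <- parseStructure("C=CCC")
  u <- findAlkene(s)
  blk <- rdfBlock(u, s)
  # independent evaluation of the Gaussian-smoothed dispersion sum
  cf <- conformerCoords(s)[[1]]
  others <- setdiff(seq_along(atomElements(s)), c(u@c1, u@c2))
  p <- atomPolarizability(atomElements(s)[others])
  oracle <- vapply(1:7, function(k) {
    d <- sqrt(rowSums(sweep(cf[others, ], 2, cf[u@c1, ])^2))
    sum(p * exp(-20 * (d - k)^2))
  }, numeric(1))
  expect_equal(unname(blk[1:7]), oracle, tolerance = 1e-12)
  # rotation + translation leaves the block unchanged
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  s2 <- s
  s2@conformers <- list(sweep(cf %*% R, 2, c(5, -3, 2), "+"))
  expect_equal(rdfBlock(u, s2), blk, tolerance = 1e-9)
  expect_true(all(blk >= 0))
})

test_that("electronic block has exact gap and symmetry properties", {
  v <- featureValues(featurizeAlkene(parseStructure("C=C"))$features)
  expect_identical(unname(v["HOMO-LUMO gap"]),
                   unname(v["LUMO"] - v["HOMO"]))
  expect_lt(abs(v["C1 natural charge"] - v["C2 natural charge"]), 1e-6)
  expect_equal(unname(v["pi occupancy"]), 2, tolerance = 1e-9)
  expect_equal(unname(v["pi* occupancy"]), 0, tolerance = 1e-9)
  # conjugation with an acceptor lowers the LUMO
  van <- featureValues(featurizeAlkene(parseStructure("C=CC#N"))$features)
  expect_lt(van["LUMO"], v["LUMO"])
  # occupancies stay within [0, 2] across the generated set
  X <- fx_genset()$features
  expect_true(all(X[, "pi occupancy"] >= 0 & X[, "pi occupancy"] <= 2))
  expect_true(all(X[, "pi* occupancy"] >= 0 & X[, "pi* occupancy"] <= 2))
  expect_equal(unname(X[, "HOMO-LUMO gap"]),
               unname(X[, "LUMO"] - X[, "HOMO"]), tolerance = 1e-9)
})
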