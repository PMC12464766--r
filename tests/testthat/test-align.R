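# The Q1 priority cascade and feature assembly.

# independent frame enumeration from the geometric constraints: Q4 shares
# Q1's carbon, Q2 is cis to Q1, Q3 is the remainder
.enumFrames <- function() {
  same_carbon <- list(bottom_left = "top_left", top_left = "bottom_left",
                      bottom_right = "top_right", top_right = "bottom_right")
  cis_of <- list(bottom_left = "bottom_right", bottom_right = "bottom_left",
                 top_left = "top_right", top_right = "top_left")
  lapply(c("bottom_left", "bottom_right", "top_right", "top_left"),
         function(q1) {
    q4 <- same_carbon[[q1]]
    q2 <- cis_of[[q1]]
    q3 <- setdiff(c("bottom_left", "bottom_right", "top_right", "top_left"),
                  c(q1, q2, q4))
    c(Q1 = q1, Q2 = q2, Q3 = q3, Q4 = q4)
  })
}

.randomQd <- function(rng_seed) {
  set.seed(rng_seed)
  keys <- c("bottom_left", "bottom_right", "top_right", "top_left")
  # volumes drawn as permutations of well-separated values so the 2 %
  # tie tolerance never fires and the tolerance-free oracle applies
  maxv <- sample(c(10, 25, 50, 90))
  bfsv <- sample(c(8, 20, 40, 70))
  qd <- lapply(seq_along(keys), function(k) {
    list(L = runif(1, 1, 8), B1 = runif(1, 1, 3), B5 = runif(1, 2, 6),
         max_volume = maxv[k], bfs3_volume = bfsv[k],
         esp_min = runif(1, -30, 0), esp_99 = runif(1, 0, 30),
         polarizability = sample(c(0.667, 1.76, 0.557, 2.18), 1),
         signature = paste0(keys[k], "-sig"))
  })
  names(qd) <- keys
  qd
}

test_that("styrene resolves on rule 1 with the phenyl in Q1", {
  fx <- fx_styrene()
  a <- fx$assignment
  expect_identical(a@decidingRule, 1L)
  expect_false(a@tieBroken)
  q1frag <- fx$unit@positions[[a@quadrantOf[["Q1"]]]]
  expect_false(q1frag@isHydrogen)
  expect_identical(length(q1frag@memberAtoms), 11L)  # C6H5
})

# assign the per-position values of one descriptor field
.setField <- function(qd, field, values) {
  keys <- c("bottom_left", "top_left", "bottom_right", "top_right")
  for (k in seq_along(keys)) qd[[keys[k]]][[field]] <- values[k]
  qd
}

# descriptor sets constructed so that cascade rule `r` is the first
# discriminating rule; exact ties below r keep the tolerance-free
# lexicographic oracle applicable (order: bl, tl, br, tr)
.tieredQd <- function(r, rng_seed) {
  qd <- .randomQd(rng_seed)
  eq <- rep(40, 4)
  vols <- switch(as.character(r),
    "1" = sample(c(10, 25, 50, 90)),
    "2" = c(90, 20, 5, 90),
    eq)
  esp <- switch(as.character(r),
    "3" = sample(c(2, 9, 17, 26)),
    "4" = c(10, 10, 3, 7),
    if (r < 3) sample(c(2, 9, 17, 26)) else rep(5, 4))
  pol <- switch(as.character(r),
    "5" = sample(c(0.557, 0.667, 1.76, 2.18)),
    "6" = c(2.18, 2.18, 0.667, 1.76),
    sample(c(0.557, 0.667, 1.76, 2.18)))
  qd <- .setField(qd, "max_volume", vols)
  qd <- .setField(qd, "bfs3_volume", vols)
  qd <- .setField(qd, "esp_99", esp)
  .setField(qd, "polarizability", pol)
}

test_that("the cascade equals brute-force lexicographic frame scoring", {
  for (rep_seed in 1:4) {
    for (r in 1:6) {
      qd <- .tieredQd(r, rep_seed * 100 + r)
      a <- alignQ1(NULL, qd, criterion = "max_volume")
      expect_identical(a@decidingRule, r)
      frames <- .enumFrames()
      scores <- lapply(frames, function(fr) {
        c(qd[[fr[["Q1"]]]]$max_volume,
          -qd[[fr[["Q2"]]]]$max_volume,
          qd[[fr[["Q1"]]]]$esp_99,
          qd[[fr[["Q3"]]]]$esp_99,
          qd[[fr[["Q1"]]]]$polarizability,
          qd[[fr[["Q3"]]]]$polarizability)
      })
      best <- 1L
      for (k in 2:4) {
        cmp <- sign(scores[[k]] - scores[[best]])
        first <- cmp[cmp != 0][1]
        if (!is.na(first) && first > 0) best <- k
      }
      expect_identical(unname(a@quadrantOf[c("Q1", "Q2", "Q3", "Q4")]),
                       unname(frames[[best]]))
    }
  }
})

test_that("a constructed volume tie resolves on ESP_99 (rule 3)", {
  qd <- .randomQd(99)
  # two positions with volumes equal within tolerance but distinct ESP_99;
  # arrange the smallest-volume substituent cis to both so rule 2 cannot
  # discriminate between their frames
  qd$bottom_left$max_volume <- 100
  qd$top_left$max_volume <- 99.5          # ties within 2 %
  qd$bottom_right$max_volume <- 1
  qd$top_right$max_volume <- 1.004        # smallest ties too
  qd$bottom_left$esp_99 <- 25
  qd$top_left$esp_99 <- 5                 # far apart (> 0.5 kcal/mol)
  qd$bottom_right$esp_99 <- 1
  qd$top_right$esp_99 <- 1.1
  a <- alignQ1(NULL, qd, criterion = "max_volume")
  expect_identical(a@decidingRule, 3L)
  expect_identical(unname(a@quadrantOf[["Q1"]]), "bottom_left")
})

test_that("fully symmetric descriptors fall through to the tie-break", {
  qd <- .randomQd(7)
  qd$top_right <- qd$bottom_left
  qd$top_left <- qd$bottom_right
  qd$top_right$signature <- qd$bottom_left$signature
  a <- alignQ1(NULL, qd, criterion = "max_volume")
  expect_true(a@tieBroken)
  expect_identical(a@decidingRule, 0L)
})

test_that("feature vectors have the canonical 57-name layout", {
  nm <- adFeatureNames()
  expect_length(nm, 57L)
  expect_identical(nm[1], "Q1 L")
  expect_identical(nm[8], "Q2 L")
  expect_identical(nm[29], "C1 RDF 1")
  expect_identical(nm[42], "C2 RDF 7")
  expect_identical(nm[57], "alkene charge sum")
  fx <- fx_panel()
  expect_identical(dim(fx$features), c(6L, 57L))
  expect_identical(colnames(fx$features), nm)
  expect_false(anyNA(fx$features))
})

test_that("feature vectors are invariant to input atom ordering", {
  a <- featurizeSet("C(=C)c1ccccc1", nConf = 2, seed = 5)$features
  b <- featurizeSet("c1ccccc1C=C", nConf = 2, seed = 5)$features
  expect_identical(a, b)
})

test_that("stilbene's two surviving frames give near-identical blocks", {
  st <- featurizeSet("c1ccccc1/C=C/c1ccccc1", nConf = 1, seed = 1)
  expect_identical(st$classes, "Trans")
  expect_identical(st$audit[[1]]$deciding_rule, "tie_broken")
  v <- st$features[1, ]
  # phenyl blocks Q1 vs Q3 and hydrogen blocks Q2 vs Q4 agree up to the
  # small geometric asymmetry of the embedded conformer (the two phenyl
  # torsions relax to slightly different angles)
  rel <- abs(v[1:7] - v[15:21]) / pmax(abs(v[1:7]), 1)
  expect_lt(max(rel), 0.05)
  expect_lt(max(abs(v[8:14] - v[22:28])), 1.5)
})

test_that("assembly errors name the offending block", {
  fx <- fx_styrene()
  qd <- quadrantDescriptors(fx$unit, fx$s)
  gd <- list(rdf = rep(0, 13), electronic = rep(0, 15))
  expect_error(assembleFeatures(fx$unit, fx$assignment, qd, gd), "RDF")
  gd <- list(rdf = rep(0, 14), electronic = rep(0, 14))
  expect_error(assembleFeatures(fx$unit, fx$assignment, qd, gd),
               "electronic")
})

test_that("alignment requires descriptors for all four positions", {
  fx <- fx_styrene()
  qd <- quadrantDescriptors(fx$unit, fx$s)
  expect_error(alignQ1(fx$unit, qd[1:3]), "missing quadrant descriptors")
})
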