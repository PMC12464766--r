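# Session-level fixture cache: expensive molecule preparations are built
# once per test run and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# styrene, fully featurized
fx_styrene <- function() fixture("styrene", function() {
  s <- parseStructure("C=Cc1ccccc1")
  c(list(s = s), featurizeAlkene(s))
})

# a small mixed-class molecule panel, featurized with 2 conformers
fx_panel <- function() fixture("panel", function() {
  featurizeSet(c("C=CCC(C)C",            # Mono
                 "C=C(C)CC",             # Gem
                 "C/C=C\\CC",            # Cis
                 "CC/C=C/c1ccccc1",      # Trans
                 "CC(C)=CC",             # TriQ2-ish
                 "CC/C(C)=C(\\C)CF"),    # Tetra
               nConf = 2, seed = 1)
})

# exhaustive generated set covering the eight classes (verified contract)
fx_genset <- function() fixture("genset", function() {
  generateAlkeneSet(nPerClass = 2L, seed = 3L, nConf = 1L, verify = TRUE)
})

# synthetic regression problem reused by modeling tests: 3 informative
# standardized features + gaussian noise
fx_regression <- function() fixture("regression", function() {
  set.seed(42)
  n <- 120
  X <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("f", 1:8)))
  y <- pmax(1.5 + 0.8 * X[, 1] + 0.5 * X[, 2] + 0.4 * X[, 3] +
              rnorm(n, 0, 0.1), 0)
  list(X = X, y = y)
})
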