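# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# Small virtual clade exercising all three tiers (40x40 grid, 12 species).
smallClade <- function() cached("smallClade", function() {
  simulateVirtualClade(
    nrows = 40, ncols = 40, nClimateLayers = 5, nLulcLayers = 3,
    nSpecies = 12,
    occurrenceCounts = c(3, 4, 20, 40, 50, 60, 35, 45, 55, 38, 42, 48),
    seed = 11)
})

smallBackground <- function() cached("smallBackground", function() {
  sampleBackground(smallClade()$stack, 1500, seed = 2)
})

smallStd <- function() cached("smallStd", function() {
  standardizeStack(smallClade()$stack, smallBackground())
})

# ENFA models of the well-sampled (>= 15 cells) species of smallClade.
smallEnfaModels <- function() cached("smallEnfaModels", function() {
  clade <- smallClade()
  rich <- names(clade$counts)[clade$counts >= 15]
  setNames(lapply(rich, function(sp)
    fitEnfa(smallStd()$stack, clade$occurrences[[sp]]$cellIds,
            smallBackground()$cellIds)), rich)
})

smallTraitTable <- function() cached("smallTraitTable", function() {
  nicheTraitTable(smallEnfaModels())
})

# The default study fixture (60x60, 32 species), used by the recovery suite.
defaultClade <- function() cached("defaultClade", function() {
  simulateVirtualClade(seed = 1)
})

defaultBackground <- function() cached("defaultBackground", function() {
  suppressWarnings(sampleBackground(defaultClade()$stack, 10000, seed = 2))
})

defaultStd <- function() cached("defaultStd", function() {
  standardizeStack(defaultClade()$stack, defaultBackground())
})

# A flat all-valid stack whose layer values we control cell-by-cell:
# values drawn N(0,1) per layer so background standardization is benign.
syntheticStack <- function(nrows = 30, ncols = 40, V = 4, seed = 5) {
  withr::local_seed(seed)
  layers <- setNames(lapply(seq_len(V), function(i)
    matrix(rnorm(nrows * ncols), nrows, ncols)),
    paste0("v", seq_len(V)))
  envStack(layers)
}

# Brute-force AUC by pair counting (independent oracle).
bruteAuc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Brute-force TSS via explicit confusion matrices over all candidate
# thresholds (independent oracle).
bruteTss <- function(pos, neg) {
  best <- -1
  for (t in unique(c(pos, neg))) {
    tp <- sum(pos >= t); fn <- sum(pos < t)
    tn <- sum(neg < t); fp <- sum(neg >= t)
    best <- max(best, tp / (tp + fn) + tn / (tn + fp) - 1)
  }
  best
}

# The antagonistic condition in its long three-way union form, for a,b > 0.
antagonisticUnion <- function(a, b, c) {
  (c < min(a, b)) || (c < max(a, b)) || (max(a, b) <= c && c < a + b)
}
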