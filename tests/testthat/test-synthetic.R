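test_that("landscape simulation is seed-deterministic", {
  a <- simulateLandscape(20, 20, 2, 1, seed = 4)
  b <- simulateLandscape(20, 20, 2, 1, seed = 4)
  expect_identical(a@values, b@values)
  expect_false(identical(a@values,
                         simulateLandscape(20, 20, 2, 1, seed = 5)@values))
})

test_that("zero correlation range gives spatially white climate noise", {
  # lag-1 (rook) Moran's I of white noise is near the null mean -1/(n-1);
  # detrend the oriented gradient first so only the noise field remains
  stk <- simulateLandscape(25, 25, 1, 0, spatialCorrRange = 0, seed = 9)
  m <- getLayer(stk, 1)
  rows <- row(m); cols <- col(m)
  m <- matrix(resid(lm(as.numeric(m) ~ as.numeric(rows) * as.numeric(cols))),
              25, 25)
  z <- as.numeric(m) - mean(m)
  n <- length(z)
  idx <- matrix(seq_len(n), 25, 25)
  wij <- rbind(cbind(as.numeric(idx[-25, ]), as.numeric(idx[-1, ])),
               cbind(as.numeric(idx[, -25]), as.numeric(idx[, -1])))
  num <- sum(z[wij[, 1]] * z[wij[, 2]]) * 2
  I <- (n / (2 * nrow(wij))) * num / sum(z^2)
  expect_lt(abs(I - (-1 / (n - 1))), 0.06)

  # positive range must induce positive lag-1 autocorrelation
  stk2 <- simulateLandscape(25, 25, 1, 0, spatialCorrRange = 3, seed = 9)
  m2 <- getLayer(stk2, 1)
  z2 <- as.numeric(m2) - mean(m2)
  I2 <- (n / (2 * nrow(wij))) *
    sum(z2[wij[, 1]] * z2[wij[, 2]]) * 2 / sum(z2^2)
  expect_gt(I2, 0.5)
})

test_that("distance layers radiate from their patches", {
  # a single patch at the (0,0) corner puts the distance maximum at the
  # opposite corner
  d <- phyloSDM:::distanceTransform(15, 20, 1, rbind(c(0, 0)))
  expect_equal(d[1, 1], 0)
  expect_equal(which(d == max(d)), 15L * 20L)   # last cell, column-major
  expect_equal(max(d), sqrt(14^2 + 19^2))
})

test_that("tree and niche simulation honours the Brownian model", {
  # bmRate = 0 collapses every optimum onto the root state
  tn0 <- simulateTreeAndNiches(8, nLayers = 3, bmRate = 0, rootState = 2,
                               seed = 3)
  expect_true(all(tn0$optima == 2))
  expect_equal(max(ape::node.depth.edgelength(tn0$tree)), 1, tolerance = 1e-9)

  # sister tips with near-zero divergence get near-identical optima
  tn <- simulateTreeAndNiches(16, nLayers = 4, bmRate = 1, seed = 7)
  D <- ape::cophenetic.phylo(tn$tree)
  diag(D) <- Inf
  pair <- which(D == min(D), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(mean((tn$optima[pair[1], ] - tn$optima[pair[2], ])^2)),
            3 * sqrt(min(D)))

  expect_error(simulateTreeAndNiches(8, deathRate = 2, birthRate = 1),
               "death")
})

test_that("tip divergence grows linearly with patristic distance at rate bmRate", {
  # Monte-Carlo check of the Brownian property: E[(x_i - x_j)^2] = rate * d_ij
  slopes <- vapply(1:20, function(s) {
    tn <- simulateTreeAndNiches(64, nLayers = 1, bmRate = 1, seed = 100 + s)
    D <- ape::cophenetic.phylo(tn$tree)
    x <- tn$optima[rownames(D), 1]
    iu <- upper.tri(D)
    d2 <- outer(x, x, `-`)^2
    coef(lm(d2[iu] ~ 0 + D[iu]))[[1]]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.2)
})

test_that("niche optima carry positive phylogenetic signal", {
  skip_if_not_installed("picante")
  ks <- vapply(1:5, function(s) {
    tn <- simulateTreeAndNiches(32, nLayers = 1, bmRate = 1, seed = 200 + s)
    picante::Kcalc(tn$optima[tn$tree$tip.label, 1], tn$tree)
  }, numeric(1))
  expect_gt(mean(ks), 0.5)   # BM-evolved traits: K near 1, well above 0
})

test_that("true suitability follows the Gaussian niche form", {
  stk <- syntheticStack(10, 10, V = 2)
  # force one cell exactly onto the optimum
  stk@values[3, 4, ] <- c(0.7, -0.2)
  s <- trueSuitability(stk, c(0.7, -0.2), c(1, 1))
  expect_equal(s[3, 4], 1.0)
  expect_true(all(s <= 1 & s >= 0, na.rm = TRUE))

  # hand case: optimum (0,0), breadth (1,1), x = (1,1) -> exp(-1)
  stk@values[5, 5, ] <- c(1, 1)
  s2 <- trueSuitability(stk, c(0, 0), c(1, 1))
  expect_equal(s2[5, 5], exp(-1), tolerance = 1e-12)

  # infinite breadth saturates everywhere
  s3 <- trueSuitability(stk, c(0, 0), c(1e9, 1e9))
  expect_true(all(abs(s3 - 1) < 1e-12))

  expect_error(trueSuitability(stk, c(0, 0), c(1, 0)), "positive")
})

test_that("occurrence sampling is weighted by suitability", {
  stk <- syntheticStack(5, 5, V = 1)
  point <- matrix(0, 5, 5); point[2, 3] <- 1
  occ <- sampleOccurrences(point, stk, 1, seed = 1)
  expect_equal(as.integer(occ$cellIds[1, ]), c(1L, 2L))

  unif <- matrix(1, 5, 5)
  occ2 <- sampleOccurrences(unif, stk, 2, seed = 1)
  expect_equal(nrow(unique(occ2$cellIds)), 2L)

  # sampling distribution matches the weights (chi-square GoF at n=1)
  w <- matrix(0, 5, 5); w[1, 1] <- 0.5; w[1, 2] <- 0.3; w[1, 3] <- 0.2
  counts <- table(vapply(1:1000, function(s) {
    o <- sampleOccurrences(w, stk, 1, seed = s)
    paste(o$cellIds[1, ], collapse = ",")
  }, character(1)))
  expect_gt(chisq.test(as.numeric(counts[c("0,0", "0,1", "0,2")]),
                       p = c(0.5, 0.3, 0.2))$p.value, 0.01)

  expect_warning(sampleOccurrences(w, stk, 10, seed = 1), "capped")
})

test_that("scenario factorial holds the right components constant", {
  cur <- simulateLandscape(20, 20, 2, 2, seed = 6)
  sc <- makeFutureScenarios(cur, climateShift = 1,
                            lulcRegenerateFraction = 0.5, nGcm = 2,
                            gcmJitterSd = 0.1, seed = 3)
  expect_equal(nrow(sc$index), 2 * (2 + 1 + 2))   # per ssp: 2 climate, 1 lulc, 2 both
  climL <- grep("^clim", layerNames(cur))
  lulcL <- grep("^lulc", layerNames(cur))
  for (nm in names(sc$scenarios)) {
    stk <- sc$scenarios[[nm]]
    expect_identical(layerNames(stk), layerNames(cur))
    expect_identical(dim(stk@values), dim(cur@values))
    if (startsWith(nm, "climate")) {
      expect_identical(stk@values[, , lulcL], cur@values[, , lulcL])
      expect_false(identical(stk@values[, , climL], cur@values[, , climL]))
    }
    if (startsWith(nm, "lulc"))
      expect_identical(stk@values[, , climL], cur@values[, , climL])
  }

  # zero shift and zero relocation reproduce the current stack exactly
  sc0 <- makeFutureScenarios(cur, climateShift = 0,
                             lulcRegenerateFraction = 0, nGcm = 1,
                             gcmJitterSd = 0, seed = 3)
  for (nm in names(sc0$scenarios))
    expect_equal(sc0$scenarios[[nm]]@values, cur@values, tolerance = 0)
})

test_that("virtual clade fixture populates all tiers and round-trips to disk", {
  clade <- smallClade()
  tiers <- vapply(clade$counts, function(n) assignTier(n)$tier, character(1))
  expect_setequal(unique(tiers), c("ENPHYLO", "ESM", "SDM"))
  expect_true(any(clade$counts >= 2 & clade$counts <= 4))
  for (sp in names(clade$occurrences))
    expect_equal(nrow(clade$occurrences[[sp]]$cellIds),
                 unname(clade$counts[sp]))

  dir <- withr::local_tempdir()
  writeVirtualClade(clade, dir)
  expect_true(file.exists(file.path(dir, "tree.nwk")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- loadEnvStack(list.files(file.path(dir, "layers"),
                                  full.names = TRUE))
  expect_equal(nLayers(back), nLayers(clade$stack))
})
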