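test_that("imputation equals the sister's trait at zero divergence", {
  tree <- ape::read.tree(text =
    "((A:0.000001,B:0.000001):1,(C:1,D:0.6):0.4):0;")
  traits <- rbind(A = c(1.5, -2, 0.3), C = c(0, 1, 1), D = c(2, 2, 2))
  tt <- list(traits = traits, observed = c(A = TRUE, C = TRUE, D = TRUE),
             V = 3, s = 0)
  imp <- imputeTipTraits(tree, tt, "B")
  expect_equal(unname(imp$trait), c(1.5, -2, 0.3), tolerance = 1e-4)
  expect_true(all(imp$condVar >= 0))
  expect_lt(max(imp$condVar), 1e-4)
})

test_that("imputation on a star tree is the arithmetic mean of tips", {
  tree <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  traits <- rbind(A = c(1, 10), B = c(2, 20), C = c(3, 30))
  tt <- list(traits = traits, observed = c(A = TRUE, B = TRUE, C = TRUE),
             V = 2, s = 0)
  imp <- imputeTipTraits(tree, tt, "D")
  # on a star phylogeny C_to = 0, so the imputed value is the GLS root
  # state, which reduces to the plain mean for equal branch lengths
  expect_equal(unname(imp$trait), c(2, 20), tolerance = 1e-9)
})

test_that("imputation errors are informative", {
  tree <- ape::read.tree(text = "(A:1,(B:1,(C:1,D:1):1):1);")
  traits <- rbind(A = 1, B = 2, C = 3)
  tt <- list(traits = traits, observed = c(A = TRUE, B = TRUE, C = TRUE),
             V = 1, s = 0)
  expect_error(imputeTipTraits(tree, tt, "nope"), "not a tip")
  tt2 <- list(traits = traits[1:2, , drop = FALSE])
  expect_error(imputeTipTraits(tree, tt2, "D"), "fewer than 3")
})

test_that("masked Brownian traits are recovered from the phylogeny", {
  # parameter-recovery simulation: simulate BM vectors on a 64-tip tree,
  # mask 20% of tips, impute them, correlate with truth
  rs <- vapply(1:20, function(s) {
    tn <- simulateTreeAndNiches(64, nLayers = 12, bmRate = 1,
                                seed = 400 + s)
    tips <- tn$tree$tip.label
    masked <- tips[seq(1, 64, by = 5)]        # 13 tips ~ 20%
    tt <- list(traits = tn$optima[setdiff(tips, masked), , drop = FALSE])
    mean(vapply(masked, function(sp) {
      imp <- imputeTipTraits(tn$tree, tt, sp)
      cor(imp$trait, tn$optima[sp, ])
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean(rs), 0.7)
})

test_that("tree perturbation is deterministic, label-preserving and real", {
  skip_if_not_installed("phangorn")
  tn <- simulateTreeAndNiches(16, nLayers = 1, seed = 5)
  p1 <- perturbTree(tn$tree, seed = 3)
  p2 <- perturbTree(tn$tree, seed = 3)
  expect_identical(ape::write.tree(p1), ape::write.tree(p2))
  expect_setequal(p1$tip.label, tn$tree$tip.label)
  expect_false(identical(p1$edge.length, tn$tree$edge.length))

  rf <- vapply(1:50, function(s)
    phangorn::RF.dist(perturbTree(tn$tree, seed = s), tn$tree),
    numeric(1))
  expect_gt(sum(rf > 0), 0)

  small <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_warning(unchanged <- perturbTree(small, seed = 1), "fewer than 4")
  expect_identical(unchanged, small)
})

test_that("knight-move candidates follow chess geometry", {
  stk <- syntheticStack(10, 10)
  # interior reference: all 8 knight cells
  cand <- knightCandidates(rbind(c(5, 5)), stk)
  expect_equal(nrow(cand), 8L)
  d <- abs(sweep(cand, 2L, c(5L, 5L)))
  expect_true(all((d[, 1] == 1 & d[, 2] == 2) | (d[, 1] == 2 & d[, 2] == 1)))

  # corner reference: clipped to 2
  cand0 <- knightCandidates(rbind(c(0, 0)), stk)
  expect_equal(nrow(cand0), 2L)
  expect_true(all(cand0 == rbind(c(1L, 2L), c(2L, 1L))))

  # overlapping knight sets union without duplicates
  two <- knightCandidates(rbind(c(4, 4), c(5, 5)), stk)
  expect_equal(nrow(two), nrow(unique(two)))
  expect_lt(nrow(two), 16L)

  # nodata and reference cells are excluded
  masked <- stk
  masked@nodataMask[6 + 1, 7 + 1] <- TRUE   # knight cell (6,7) of (5,5)
  candM <- knightCandidates(rbind(c(5, 5)), masked)
  expect_equal(nrow(candM), 7L)
})

test_that("angle similarity is the mean Pearson correlation to references", {
  stk <- syntheticStack(6, 6, V = 3)
  stk@values[1, 1, ] <- c(1, 0, 1)    # candidate, cell (0, 0)
  stk@values[2, 2, ] <- c(1, 1, 0)    # reference, cell (1, 1)
  stk@values[3, 3, ] <- c(1, 0, 1)    # identical twin, cell (2, 2)
  stk@values[4, 4, ] <- c(-1, 0, -1)  # negated, cell (3, 3)
  stk@metadata$standardized <- TRUE
  expect_equal(angleSimilarity(c(0, 0), rbind(c(1, 1)), stk), -0.5)
  expect_equal(angleSimilarity(c(0, 0), rbind(c(1, 1), c(1, 1)), stk), -0.5)
  expect_equal(angleSimilarity(c(0, 0), rbind(c(2, 2)), stk), 1.0)
  expect_equal(angleSimilarity(c(0, 0), rbind(c(3, 3)), stk), -1.0)
  expect_equal(angleSimilarity(c(0, 0), rbind(c(2, 2), c(1, 1)), stk), 0.25)

  stk@values[5, 5, ] <- c(2, 2, 2)    # constant vector: no defined angle
  expect_warning(s <- angleSimilarity(c(4, 4), rbind(c(1, 1)), stk),
                 "constant")
  expect_identical(s, -Inf)
})

test_that("pseudo-presence selection reaches five cells with best-ranked candidates", {
  std <- smallStd()$stack
  for (nref in 2:4) {
    refs <- rbind(c(10, 10), c(12, 14), c(20, 20), c(25, 8))[seq_len(nref), ,
                                                             drop = FALSE]
    sel <- selectPseudoPresences(refs, std)
    expect_equal(nrow(sel), 5L - nref)
    expect_equal(nrow(unique(rbind(refs, sel))), 5L)

    # optimality: every selected candidate scores >= every unselected one
    cand <- knightCandidates(refs, std)
    sims <- vapply(seq_len(nrow(cand)), function(i)
      suppressWarnings(angleSimilarity(cand[i, ], refs, std)), numeric(1))
    selKeys <- paste(sel[, 1], sel[, 2])
    allKeys <- paste(cand[, 1], cand[, 2])
    selSims <- sims[allKeys %in% selKeys]
    unselSims <- sims[!allKeys %in% selKeys]
    expect_gte(min(selSims), max(unselSims) - 1e-12)
  }

  expect_equal(nrow(selectPseudoPresences(rbind(c(1, 1), c(3, 3), c(5, 5),
                                                c(7, 7), c(9, 9)), std)), 0L)
  expect_error(selectPseudoPresences(rbind(c(1, 1)), std), "single-cell")
})

test_that("similarity ties break toward the geographically closer candidate", {
  # two candidate cells with IDENTICAL environmental vectors but different
  # distances to the references
  withr::local_seed(44)
  vals <- lapply(1:3, function(i) matrix(rnorm(400), 20, 20))
  stk <- envStack(setNames(vals, paste0("v", 1:3)))
  refs <- rbind(c(5, 5), c(5, 9), c(9, 5), c(9, 9))   # 4 refs -> pick 1
  cand <- knightCandidates(refs, stk)
  # make every candidate's vector identical (all tie on similarity)
  proto <- c(1.2, -0.4, 0.7)
  for (i in seq_len(nrow(cand)))
    stk@values[cand[i, 1] + 1, cand[i, 2] + 1, ] <- proto
  stk@metadata$standardized <- TRUE
  sel <- selectPseudoPresences(refs, stk)
  expect_equal(nrow(sel), 1L)
  d <- function(cell) min(sqrt(colSums((t(refs) - as.numeric(cell))^2)))
  dists <- vapply(seq_len(nrow(cand)), function(i) d(cand[i, ]), numeric(1))
  expect_equal(d(sel[1, ]), min(dists))
})

test_that("the rare-species fit selects trees deterministically and recovers truth", {
  clade <- smallClade()
  bg <- smallBackground()
  tt <- smallTraitTable()
  rare <- names(clade$counts)[clade$counts == 3][1]
  refs <- clade$occurrences[[rare]]$cellIds

  rf <- fitEnphylo(rare, refs, clade$tree, tt, clade$stack, bg,
                   nTreeReps = 10, seed = 42)
  expect_s4_class(rf, "RareFit")
  expect_equal(nrow(rf@referenceCells) + nrow(rf@pseudoCells), 5L)
  expect_gte(rf@evalRecord$meanAUC, 0.7)

  # determinism
  rf2 <- fitEnphylo(rare, refs, clade$tree, tt, clade$stack, bg,
                    nTreeReps = 10, seed = 42)
  expect_identical(rf@chosenTreeIndex, rf2@chosenTreeIndex)
  expect_identical(rf@evalRecord$replicates, rf2@evalRecord$replicates)

  # truth recovery on the known Gaussian niche
  truth <- clade$truth[[rare]]
  ok <- !is.na(truth) & !is.na(rf@suitability)
  expect_gt(cor(truth[ok], rf@suitability[ok], method = "spearman"), 0.5)

  # a single replicate must use the input tree
  rf1 <- fitEnphylo(rare, refs, clade$tree, tt, clade$stack, bg,
                    nTreeReps = 1, seed = 42)
  expect_identical(rf1@chosenTreeIndex, 1L)
})

test_that("rare fits agree with full-data ENFA when data are masked", {
  # treat a data-rich species as rare by masking all but 4 of its cells;
  # the imputed fit must rank habitat like the full-data ENFA fit
  clade <- smallClade()
  bg <- smallBackground()
  std <- smallStd()
  rich <- names(clade$counts)[clade$counts >= 50][1]
  cells <- clade$occurrences[[rich]]$cellIds
  models <- smallEnfaModels()
  ttMasked <- nicheTraitTable(models[setdiff(names(models), rich)])

  full <- mahalanobisSuitability(models[[rich]], std$stack)
  withr::local_seed(55)
  keep <- sort(sample(nrow(cells), 4))   # random mask of its range
  rf <- fitEnphylo(rich, cells[keep, ], clade$tree, ttMasked, clade$stack,
                   bg, nTreeReps = 5, seed = 7)
  ok <- !is.na(full) & !is.na(rf@suitability)
  expect_gt(cor(full[ok], rf@suitability[ok], method = "spearman"), 0.5)
})

test_that("RareFit validity enforces the five-cell contract", {
  clade <- smallClade()
  bg <- smallBackground()
  tt <- smallTraitTable()
  rare <- names(clade$counts)[clade$counts == 3][1]
  rf <- fitEnphylo(rare, clade$occurrences[[rare]]$cellIds, clade$tree, tt,
                   clade$stack, bg, nTreeReps = 2, seed = 1)
  bad <- rf
  bad@pseudoCells <- bad@pseudoCells[-1, , drop = FALSE]
  expect_error(validObject(bad), "total 5")
})
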