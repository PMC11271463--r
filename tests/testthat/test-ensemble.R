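test_that("tier routing partitions occurrence counts exactly", {
  expect_equal(assignTier(14)$tier, "ENPHYLO")
  expect_equal(assignTier(15)$tier, "ESM")
  expect_equal(assignTier(30)$tier, "ESM")
  expect_equal(assignTier(31)$tier, "SDM")
  expect_equal(assignTier(2)$tier, "ENPHYLO")
  expect_error(assignTier(1), "single cell")

  # exhaustive and exclusive over the whole relevant range
  tiers <- vapply(2:60, function(n) assignTier(n)$tier, character(1))
  expect_true(all(tiers %in% c("ENPHYLO", "ESM", "SDM")))
  expect_equal(as.vector(table(tiers)[c("ENPHYLO", "ESM", "SDM")]),
               c(13L, 16L, 30L))
})

test_that("AUC matches the Mann-Whitney pair count", {
  expect_equal(aucScore(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(aucScore(c(0.8, 0.4), c(0.6, 0.2)), 0.75)
  expect_error(aucScore(numeric(0), 1), "non-empty")

  # brute-force equivalence, including ties, on random instances
  withr::local_seed(17)
  for (i in 1:20) {
    pos <- sample(seq(0, 1, by = 0.1), sample(2:25, 1), replace = TRUE)
    neg <- sample(seq(0, 1, by = 0.1), sample(2:25, 1), replace = TRUE)
    expect_equal(aucScore(pos, neg), bruteAuc(pos, neg))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(23)
  pos <- rnorm(40, 1); neg <- rnorm(60)
  expect_equal(aucScore(pos, neg),
               as.numeric(pROC::auc(pROC::roc(
                 response = c(rep(1, 40), rep(0, 60)),
                 predictor = c(pos, neg), quiet = TRUE))))
})

test_that("TSS equals the exhaustive threshold scan", {
  expect_equal(tssScore(c(0.8, 0.4), c(0.6, 0.2)), 0.5)
  expect_equal(tssScore(c(0.9, 0.8), c(0.2, 0.1)), 1.0)
  withr::local_seed(29)
  for (i in 1:20) {
    pos <- round(runif(sample(3:20, 1)), 2)
    neg <- round(runif(sample(3:20, 1)), 2)
    expect_equal(tssScore(pos, neg), bruteTss(pos, neg))
  }
})

test_that("Boyce index tracks where presences sit in the score range", {
  withr::local_seed(37)
  bgS <- runif(3000)
  # presence density proportional to score: P/E rises monotonically
  expect_gt(boyceIndex(sqrt(runif(800)), bgS), 0.9)
  # mirror construction: P/E falls monotonically
  expect_lt(boyceIndex(1 - sqrt(runif(800)), bgS), -0.9)
  # presences in the top decile still score clearly positive
  expect_gt(boyceIndex(runif(200, 0.9, 1), bgS), 0.4)
  # identical constant scores: undefined
  expect_warning(b <- boyceIndex(rep(0.5, 10), rep(0.5, 50)), "Boyce")
  expect_true(is.na(b))
})

test_that("learners score a null species at chance and a separable one perfectly", {
  withr::local_seed(41)
  stk <- syntheticStack(30, 40, V = 3, seed = 41)
  stk@metadata$standardized <- TRUE
  cells <- validCells(stk)
  pick <- sample(nrow(cells), 400)
  pres <- cells[pick[1:100], ]
  bg <- cells[pick[101:300], ]
  hold <- cells[pick[301:400], ]
  for (kind in c("GLM_QUAD", "RF", "MAXENT_LIKE")) {
    s <- suppressWarnings(
      fitLearner(kind, pres, bg, stk, seed = 1))
    a <- aucScore(scoreCells(s, stk, hold[1:50, ]),
                  scoreCells(s, stk, hold[51:100, ]))
    expect_lt(abs(a - 0.5), 0.12)   # null model: both classes same distribution
  }

  # linearly separable toy: layer 1 high on presences
  sep <- stk
  idx <- cbind(pres[, 1] + 1L, pres[, 2] + 1L)
  m <- sep@values[, , 1]; m[idx] <- m[idx] + 10; sep@values[, , 1] <- m
  for (kind in c("GLM_QUAD", "RF", "MAXENT_LIKE")) {
    s <- suppressWarnings(fitLearner(kind, pres, bg, sep,
      layerSubset = if (kind == "RF") "v1" else c("v1", "v2"), seed = 1))
    a <- aucScore(scoreCells(s, sep, pres), scoreCells(s, sep, bg))
    expect_gt(a, 0.98)
  }
})

test_that("the quadratic GLM recovers an interior optimum", {
  withr::local_seed(43)
  stk <- syntheticStack(40, 40, V = 2, seed = 43)
  stk@metadata$standardized <- TRUE
  cells <- validCells(stk)
  x <- cellValues(stk, cells)
  suit <- exp(-((x[, 1] - 0.5)^2 + (x[, 2] + 0.25)^2))
  pres <- cells[sample(nrow(cells), 500, prob = suit), ]
  bg <- cells[sample(nrow(cells), 500), ]
  s <- suppressWarnings(fitLearner("GLM_QUAD", pres, bg, stk, seed = 2))
  sc <- scoreCells(s, stk, cells)
  best <- x[which.max(sc), ]
  expect_lt(sqrt(sum((best - c(0.5, -0.25))^2)), 0.35)
})

test_that("bootstrap evaluation is deterministic and honours a perfect scorer", {
  stk <- syntheticStack(20, 20, V = 2, seed = 3)
  stk@metadata$standardized <- TRUE
  cells <- validCells(stk)
  pres <- cells[1:30, ]
  bg <- cells[101:300, ]
  presKeys <- pres[, 1] * 20 + pres[, 2]
  oracle <- functionScorer(function(stack, cells)
    as.numeric((cells[, 1] * 20 + cells[, 2]) %in% presKeys))
  ev <- bootstrapEvaluate(function(tp, tb) oracle, pres, bg, stk, seed = 5)
  expect_equal(nrow(ev$replicates), 10L)      # the default replicate count
  expect_true(all(ev$replicates$AUC == 1))
  expect_true(all(ev$replicates$TSS == 1))
  expect_true(ev$passFlag)

  ev2 <- bootstrapEvaluate(function(tp, tb) oracle, pres, bg, stk, seed = 5)
  expect_identical(ev$replicates, ev2$replicates)
})

test_that("ensembles of small models enumerate bivariate combinations", {
  # combination counts: C(2,2) = 1, C(5,2) = 10
  expect_equal(ncol(combn(2, 2)), 1L)
  stk <- smallStd()$stack
  clade <- smallClade()
  bg <- smallBackground()
  sp <- names(clade$counts)[clade$counts == 20][1]
  esm <- suppressWarnings(
    fitEsm(clade$occurrences[[sp]]$cellIds, bg$cellIds, stk,
           learnerKinds = "GLM_QUAD", cvReps = 3, seed = 9))
  expect_equal(nrow(esm$members), choose(nLayers(stk), 2))
  expect_s3_class(esm$scorer, "weightedScorer")
  # ensemble scores stay within [0, 1]
  sc <- scoreCells(esm$scorer, stk, bg$cellIds[1:100, ])
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("AUC weighting averages scorers as stated", {
  mk <- function(v) functionScorer(function(stack, cells)
    rep(v, nrow(cells)))
  stk <- syntheticStack(5, 5, seed = 1)
  cells <- validCells(stk)[1:3, ]

  # single scorer: identity
  e1 <- ensembleAverage(list(mk(0.42)), aucs = 0.9)
  expect_equal(scoreCells(e1, stk, cells), rep(0.42, 3))

  # equal AUCs: plain mean
  e2 <- ensembleAverage(list(mk(0.2), mk(0.6)), aucs = c(0.8, 0.8))
  expect_equal(scoreCells(e2, stk, cells), rep(0.4, 3))

  # p = (1, 0) with AUCs 0.8/0.9 -> 0.8/1.7
  e3 <- ensembleAverage(list(mk(1), mk(0)), aucs = c(0.8, 0.9))
  expect_equal(scoreCells(e3, stk, cells), rep(0.8 / 1.7, 3))

  # failing scorers are dropped first; none passing is an error
  e4 <- ensembleAverage(list(mk(1), mk(0)), aucs = c(0.8, 0.9),
                        passFlags = c(TRUE, FALSE))
  expect_equal(scoreCells(e4, stk, cells), rep(1, 3))
  expect_error(ensembleAverage(list(mk(1)), aucs = 0.6, passFlags = FALSE),
               "rejected")
})
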