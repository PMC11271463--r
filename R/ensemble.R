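# Tier routing, base learners, ensembles of small models, bootstrap
# evaluation (AUC / TSS / Boyce) and AUC-weighted averaging.

#' Route a species to a modelling tier by occurrence count
#'
#' Fewer than 15 cells goes to the phylogenetically imputed rare-species
#' model, 15--30 (inclusive) to ensembles of small models, more than 30 to
#' the conventional ensemble; single-cell species are excluded.
#'
#' @param nCells occupied-cell count after per-cell deduplication.
#' @param speciesId optional label carried on the result.
#' @return list with `speciesId`, `nCells` and `tier` in
#'   \code{c("ENPHYLO", "ESM", "SDM")}.
#' @export
assignTier <- function(nCells, speciesId = NA_character_) {
  if (nCells < 2)
    stop("species occupying a single cell are excluded from modelling")
  tier <- if (nCells < 15) "ENPHYLO" else if (nCells <= 30) "ESM" else "SDM"
  list(speciesId = speciesId, nCells = as.integer(nCells), tier = tier)
}

#' Area under the ROC curve
#'
#' Mann--Whitney formulation: the probability a random presence score
#' exceeds a random background score, counting ties as one half.
#'
#' @param scoresPos,scoresNeg numeric score vectors (both non-empty).
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scoresPos, scoresNeg) {
  np <- length(scoresPos); nn <- length(scoresNeg)
  if (!np || !nn) stop("both score classes must be non-empty")
  r <- rank(c(scoresPos, scoresNeg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' True skill statistic
#'
#' Maximum over candidate thresholds (every observed score) of
#' sensitivity + specificity - 1, with presence declared at score >=
#' threshold.
#'
#' @inheritParams aucScore
#' @return TSS in [-1, 1].
#' @export
tssScore <- function(scoresPos, scoresNeg) {
  if (!length(scoresPos) || !length(scoresNeg))
    stop("both score classes must be non-empty")
  thr <- sort(unique(c(scoresPos, scoresNeg)))
  best <- -1
  for (t in thr) {
    sens <- mean(scoresPos >= t)
    spec <- mean(scoresNeg < t)
    best <- max(best, sens + spec - 1)
  }
  best
}

#' Continuous Boyce index
#'
#' 101 overlapping windows of width (max - min)/10 span the background
#' score range; each window's predicted-to-expected ratio P/E is the
#' presence fraction over the background fraction, and the index is the
#' Spearman correlation of P/E against the window midpoints.  Windows with
#' zero background fraction are dropped; fewer than 3 usable windows (or a
#' constant P/E) leaves the index undefined (NA, with a warning).
#'
#' @param scoresPos presence scores.
#' @param scoresBackground background scores.
#' @param nWindows number of overlapping windows (default 101).
#' @return Boyce index in [-1, 1], or NA.
#' @export
boyceIndex <- function(scoresPos, scoresBackground, nWindows = 101) {
  rng <- range(scoresBackground)
  w <- diff(rng) / 10
  if (w <= 0) {
    warning("degenerate background score range; Boyce undefined")
    return(NA_real_)
  }
  mids <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = nWindows)
  pe <- vapply(mids, function(mid) {
    lo <- mid - w / 2; hi <- mid + w / 2
    e <- mean(scoresBackground >= lo & scoresBackground <= hi)
    if (e == 0) return(NA_real_)
    mean(scoresPos >= lo & scoresPos <= hi) / e
  }, numeric(1))
  ok <- !is.na(pe)
  if (sum(ok) < 3L) {
    warning("fewer than 3 usable Boyce windows; index undefined")
    return(NA_real_)
  }
  if (length(unique(pe[ok])) < 2L) {
    warning("constant P/E ratio; Boyce undefined")
    return(NA_real_)
  }
  suppressWarnings(cor(pe[ok], mids[ok], method = "spearman"))
}

#' Fit one presence--background learner
#'
#' \code{GLM_QUAD} is a binomial GLM on linear + quadratic terms of each
#' layer plus pairwise products of the linear terms (interaction level 1);
#' perfect separation falls back to a ridge-penalized fit with a warning.
#' \code{RF} is a 500-tree random forest classifier scoring by vote
#' fraction.  \code{MAXENT_LIKE} is an L1-penalized presence--background
#' logistic model on the same expanded features, background-weighted so
#' the two classes carry equal total weight, with the penalty chosen by
#' 5-fold cross-validation on the training data.
#'
#' @param kind one of "GLM_QUAD", "RF", "MAXENT_LIKE".
#' @param presenceCells,backgroundCells (row, col) matrices (>= 5
#'   presences; background non-empty).
#' @param stdStack standardized \linkS4class{EnvStack}.
#' @param layerSubset layer names used (default all); a single layer is
#'   allowed for RF only.
#' @param interactions include pairwise product features (default TRUE).
#' @param nTrees random-forest tree count (default 500).
#' @param seed integer seed.
#' @return a scorer usable on any stack with matching layers.
#' @export
fitLearner <- function(kind, presenceCells, backgroundCells, stdStack,
                       layerSubset = NULL, interactions = TRUE,
                       nTrees = 500, seed = NULL) {
  kind <- match.arg(kind, c("GLM_QUAD", "RF", "MAXENT_LIKE"))
  presenceCells <- asCellMatrix(presenceCells)
  backgroundCells <- asCellMatrix(backgroundCells)
  if (nrow(presenceCells) < 5L) stop("at least 5 presence cells required")
  if (!nrow(backgroundCells)) stop("empty background")
  if (is.null(layerSubset)) layerSubset <- layerNames(stdStack)
  if (length(layerSubset) < 2L && kind != "RF")
    stop("at least 2 layers required for ", kind)
  X <- rbind(cellValues(stdStack, presenceCells)[, layerSubset, drop = FALSE],
             cellValues(stdStack, backgroundCells)[, layerSubset, drop = FALSE])
  y <- c(rep(1L, nrow(presenceCells)), rep(0L, nrow(backgroundCells)))
  Xf <- featureMatrix(X, interactions)
  ridged <- FALSE
  fit <- withSeed(seed, switch(kind,
    GLM_QUAD = {
      sep <- FALSE
      g <- withCallingHandlers(
        glm(y ~ ., data = data.frame(y = y, Xf, check.names = FALSE),
            family = binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1",
                    conditionMessage(w)))
            sep <<- TRUE
          invokeRestart("muffleWarning")
        })
      if (sep || !g$converged) {
        warning("perfect separation in GLM; ridge fallback applied")
        ridged <- TRUE
        glmnet::cv.glmnet(Xf, y, family = "binomial", alpha = 0, nfolds = 5)
      } else g
    },
    RF = randomForest::randomForest(
      x = as.data.frame(Xf), y = factor(y, levels = c(0, 1)),
      ntree = nTrees),
    MAXENT_LIKE = {
      wts <- ifelse(y == 1, 1, sum(y == 1) / sum(y == 0))
      glmnet::cv.glmnet(Xf, y, family = "binomial", alpha = 1,
                        weights = wts, nfolds = 5)
    }))
  structure(list(kind = kind, layers = layerSubset, fit = fit,
                 interactions = interactions, ridged = ridged,
                 standardization = stdStack@metadata$standardization),
            class = c("learnerScorer", "sdmScorer"))
}

#' Bootstrap cross-validation of a model fitter
#'
#' Per replicate, a random 20\% of presences and of background is set
#' aside untouched; a training multiset of size \code{ceiling(split * n)}
#' is drawn with replacement from the remaining 80\%; the model is fitted
#' on the training draw and AUC, TSS and Boyce are computed on the test
#' partition.  Replicates whose test partition lacks a presence or a
#' background point are skipped with a warning.
#'
#' @param modelFitter function(trainPresenceCells, trainBackgroundCells)
#'   returning a scorer.
#' @param presenceCells,backgroundCells (row, col) matrices.
#' @param stdStack standardized \linkS4class{EnvStack} scored on.
#' @param nReps bootstrap replicates (default 10).
#' @param split training fraction (default 0.8).
#' @param aucMin pass floor on mean AUC (default 0.7).
#' @param seed integer seed.
#' @return evaluation record: list with `replicates` (data.frame of AUC,
#'   TSS, Boyce), `meanAUC`, `meanTSS`, `meanBoyce`, the sds, and
#'   `passFlag` (mean AUC >= `aucMin`).
#' @export
bootstrapEvaluate <- function(modelFitter, presenceCells, backgroundCells,
                              stdStack, nReps = 10, split = 0.8,
                              aucMin = 0.7, seed = NULL) {
  presenceCells <- asCellMatrix(presenceCells)
  backgroundCells <- asCellMatrix(backgroundCells)
  np <- nrow(presenceCells); nb <- nrow(backgroundCells)
  rows <- vector("list", nReps)
  withSeed(seed, {
    for (r in seq_len(nReps)) {
      testP <- sample(np, max(1L, floor((1 - split) * np)))
      testB <- sample(nb, max(1L, floor((1 - split) * nb)))
      poolP <- setdiff(seq_len(np), testP)
      poolB <- setdiff(seq_len(nb), testB)
      if (!length(testP) || !length(testB) ||
          !length(poolP) || !length(poolB)) {
        warning("replicate ", r, " skipped: empty partition")
        next
      }
      trainP <- sample(poolP, ceiling(split * np), replace = TRUE)
      trainB <- sample(poolB, ceiling(split * nb), replace = TRUE)
      scorer <- modelFitter(presenceCells[trainP, , drop = FALSE],
                            backgroundCells[trainB, , drop = FALSE])
      sPos <- scoreCells(scorer, stdStack,
                         presenceCells[testP, , drop = FALSE])
      sNeg <- scoreCells(scorer, stdStack,
                         backgroundCells[testB, , drop = FALSE])
      rows[[r]] <- data.frame(
        replicate = r, AUC = aucScore(sPos, sNeg),
        TSS = tssScore(sPos, sNeg),
        Boyce = suppressWarnings(boyceIndex(sPos, sNeg)))
    }
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("every bootstrap replicate was skipped")
  reps <- do.call(rbind, rows)
  list(replicates = reps,
       meanAUC = mean(reps$AUC), sdAUC = sd(reps$AUC),
       meanTSS = mean(reps$TSS), sdTSS = sd(reps$TSS),
       meanBoyce = mean(reps$Boyce, na.rm = TRUE),
       sdBoyce = sd(reps$Boyce, na.rm = TRUE),
       passFlag = mean(reps$AUC) >= aucMin)
}

#' AUC-weighted average of scorers
#'
#' Cell score = sum(AUC_i * p_i) / sum(AUC_i) over the passing scorers.
#'
#' @param scorers list of scorers.
#' @param aucs numeric AUC weights, one per scorer.
#' @param passFlags logical; scorers with FALSE are dropped first
#'   (default: all pass).
#' @return a weighted scorer.
#' @export
ensembleAverage <- function(scorers, aucs, passFlags = NULL) {
  if (is.null(passFlags)) passFlags <- rep(TRUE, length(scorers))
  keep <- which(passFlags)
  if (!length(keep)) stop("model rejected: no passing scorer to average")
  structure(list(scorers = scorers[keep], weights = aucs[keep]),
            class = c("weightedScorer", "sdmScorer"))
}

#' Ensemble of small models
#'
#' Fits every bivariate layer combination per learner kind, evaluates each
#' small model by bootstrap cross-validation, drops those with mean AUC
#' below \code{aucMin}, and averages the survivors weighted by their AUC.
#'
#' @param presenceCells,backgroundCells (row, col) matrices (15--30
#'   presences expected).
#' @param stdStack standardized \linkS4class{EnvStack} (>= 2 layers).
#' @param learnerKinds learner kinds entering the ensemble.
#' @param cvReps,split,aucMin evaluation settings.
#' @param seed integer seed.
#' @return list with `scorer` (the weighted ensemble), `members`
#'   (data.frame of layer pair, kind, mean AUC, pass flag) and `evals`.
#' @export
fitEsm <- function(presenceCells, backgroundCells, stdStack,
                   learnerKinds = c("GLM_QUAD", "RF", "MAXENT_LIKE"),
                   cvReps = 10, split = 0.8, aucMin = 0.7, seed = NULL) {
  V <- nLayers(stdStack)
  if (V < 2L) stop("at least 2 layers required")
  pairs <- combn(layerNames(stdStack), 2L)
  scorers <- list(); rowsOut <- NULL; evals <- list()
  for (j in seq_len(ncol(pairs))) {
    subset <- pairs[, j]
    for (kind in learnerKinds) {
      sd_ <- subSeed(seed, "esm", paste(kind, j))
      fitter <- function(tp, tb)
        fitLearner(kind, tp, tb, stdStack, layerSubset = subset,
                   seed = sd_)
      ev <- bootstrapEvaluate(fitter, presenceCells, backgroundCells,
                              stdStack, nReps = cvReps, split = split,
                              aucMin = aucMin, seed = sd_)
      scorers[[length(scorers) + 1L]] <-
        fitLearner(kind, presenceCells, backgroundCells, stdStack,
                   layerSubset = subset, seed = sd_)
      evals[[length(evals) + 1L]] <- ev
      rowsOut <- rbind(rowsOut, data.frame(
        pair = paste(subset, collapse = "+"), kind = kind,
        meanAUC = ev$meanAUC, pass = ev$passFlag))
    }
  }
  if (!any(rowsOut$pass))
    stop("model rejected: every small model scored mean AUC < ", aucMin)
  scorer <- ensembleAverage(scorers, rowsOut$meanAUC, rowsOut$pass)
  list(scorer = scorer, members = rowsOut, evals = evals)
}

#' Conventional multi-learner ensemble for data-rich species
#'
#' Fits each learner on the full layer set, evaluates it by bootstrap
#' cross-validation, drops learners with mean AUC below \code{aucMin} and
#' AUC-weight-averages the rest.
#'
#' @inheritParams fitEsm
#' @return list with `scorer`, `members` and `evals` (as \code{fitEsm}).
#' @export
fitSdmEnsemble <- function(presenceCells, backgroundCells, stdStack,
                           learnerKinds = c("GLM_QUAD", "RF", "MAXENT_LIKE"),
                           cvReps = 10, split = 0.8, aucMin = 0.7,
                           seed = NULL) {
  scorers <- list(); rowsOut <- NULL; evals <- list()
  for (kind in learnerKinds) {
    sd_ <- subSeed(seed, "sdm", kind)
    fitter <- function(tp, tb)
      fitLearner(kind, tp, tb, stdStack, seed = sd_)
    ev <- bootstrapEvaluate(fitter, presenceCells, backgroundCells,
                            stdStack, nReps = cvReps, split = split,
                            aucMin = aucMin, seed = sd_)
    scorers[[length(scorers) + 1L]] <-
      fitLearner(kind, presenceCells, backgroundCells, stdStack, seed = sd_)
    evals[[length(evals) + 1L]] <- ev
    rowsOut <- rbind(rowsOut, data.frame(kind = kind, meanAUC = ev$meanAUC,
                                         pass = ev$passFlag))
  }
  if (!any(rowsOut$pass))
    stop("model rejected: every learner scored mean AUC < ", aucMin)
  list(scorer = ensembleAverage(scorers, rowsOut$meanAUC, rowsOut$pass),
       members = rowsOut, evals = evals)
}
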