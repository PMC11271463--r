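# Phylogenetic imputation of niche axes, tree perturbation, the
# knight-move pseudo-presence extension, and the full rare-species fit.

#' Build a niche trait table from fitted ENFA models
#'
#' @param models named list of \linkS4class{EnfaModel}s for the observed
#'   (well-sampled) species.
#' @param s specialization axes encoded per species (default 2).
#' @return list with `traits` (species x dimensions matrix), `observed`
#'   (logical named vector), `V` (layer count) and `s`.
#' @export
nicheTraitTable <- function(models, s = 2) {
  if (length(models) < 3L)
    stop("at least 3 observed species are required for imputation")
  traits <- t(vapply(models, enfaToTrait, s = s,
                     numeric((s + 1L) * length(models[[1L]]@layerNames))))
  rownames(traits) <- names(models)
  list(traits = traits,
       observed = setNames(rep(TRUE, nrow(traits)), rownames(traits)),
       V = length(models[[1L]]@layerNames), s = s)
}

#' Impute a tip's niche traits under Brownian motion
#'
#' With \code{C} the phylogenetic variance--covariance matrix, the root
#' state is estimated by generalized least squares over the observed tips
#' and the target's trait is the Brownian conditional expectation
#' \code{mu + C_to C_oo^-1 (x_obs - mu)}, applied per trait dimension; the
#' per-dimension conditional variance (GLS rate times the Schur
#' complement) is returned alongside.
#'
#' @param tree ape phylo with branch lengths.
#' @param traitTable from \code{\link{nicheTraitTable}}.
#' @param targetSpecies tip label to impute.
#' @return list with `trait` (numeric vector) and `condVar` (numeric
#'   vector, one value per trait dimension).
#' @export
imputeTipTraits <- function(tree, traitTable, targetSpecies) {
  if (!targetSpecies %in% tree$tip.label)
    stop("target species is not a tip of the tree")
  if (any(tree$edge.length < 0) || sum(tree$edge.length) <= 0)
    stop("tree must have positive branch lengths")
  obsSpecies <- rownames(traitTable$traits)
  obsSpecies <- setdiff(intersect(obsSpecies, tree$tip.label), targetSpecies)
  if (length(obsSpecies) < 3L)
    stop("fewer than 3 observed relatives in the tree for '",
         targetSpecies, "'")
  C <- ape::vcv(tree)
  Coo <- C[obsSpecies, obsSpecies, drop = FALSE]
  Cto <- C[targetSpecies, obsSpecies, drop = FALSE]
  Ctt <- C[targetSpecies, targetSpecies]
  CooInv <- solve(ridgePD(Coo, 1e-10))
  one <- rep(1, length(obsSpecies))
  X <- traitTable$traits[obsSpecies, , drop = FALSE]
  denom <- drop(one %*% CooInv %*% one)
  mu <- drop(one %*% CooInv %*% X) / denom       # GLS root state per dim
  centered <- sweep(X, 2L, mu)
  w <- drop(Cto %*% CooInv)
  trait <- mu + drop(w %*% centered)
  # per-dimension BM rate from the GLS residuals, times the Schur factor
  schur <- max(Ctt - drop(Cto %*% CooInv %*% t(Cto)), 0)
  sigma2 <- colSums(centered * (CooInv %*% centered)) / length(obsSpecies)
  list(trait = trait, condVar = sigma2 * schur)
}

#' Randomly perturb a phylogeny
#'
#' One random nearest-neighbour tip swap (the labels of a random tip and
#' its closest non-identical tip by patristic distance are exchanged) plus
#' multiplicative log-normal jitter (sd 0.1 on the log scale) on every
#' branch length; ultrametricity is not enforced.  Deterministic under
#' `seed`.
#'
#' @param tree ape phylo.
#' @param seed integer seed.
#' @param jitterSd sd of the log-normal branch jitter.
#' @return perturbed phylo with the same tip set.
#' @export
perturbTree <- function(tree, seed = NULL, jitterSd = 0.1) {
  n <- length(tree$tip.label)
  if (n < 4L) {
    warning("tree has fewer than 4 tips; returned unchanged")
    return(tree)
  }
  withSeed(seed, {
    D <- ape::cophenetic.phylo(tree)
    i <- sample(n, 1L)
    di <- D[i, ]
    di[i] <- Inf
    nearest <- which(di == min(di))
    j <- nearest[sample(length(nearest), 1L)]
    lab <- tree$tip.label
    lab[c(i, j)] <- lab[c(j, i)]
    out <- tree
    out$tip.label <- lab
    out$edge.length <- out$edge.length *
      rlnorm(length(out$edge.length), 0, jitterSd)
    out
  })
}

#' Knight-move pseudo-presence candidates
#'
#' The union over reference cells of the 8 chess-knight neighbours
#' ((+-1, +-2) and (+-2, +-1)); off-grid, nodata and reference cells are
#' excluded and the result is de-duplicated in row-major order.
#'
#' @param referenceCells (row, col) matrix of true presence cells.
#' @param stack an \linkS4class{EnvStack}.
#' @return (row, col) matrix of candidate cells.
#' @export
knightCandidates <- function(referenceCells, stack) {
  referenceCells <- asCellMatrix(referenceCells)
  g <- gridGeometry(stack)
  moves <- cbind(c(-2, -2, -1, -1, 1, 1, 2, 2),
                 c(-1, 1, -2, 2, -2, 2, -1, 1))
  cand <- NULL
  for (i in seq_len(nrow(referenceCells)))
    cand <- rbind(cand, sweep(moves, 2L, referenceCells[i, ], `+`))
  on <- cand[, 1L] >= 0 & cand[, 1L] < g$nrows &
    cand[, 2L] >= 0 & cand[, 2L] < g$ncols
  cand <- cand[on, , drop = FALSE]
  if (nrow(cand)) {
    bad <- stack@nodataMask[cbind(cand[, 1L] + 1L, cand[, 2L] + 1L)]
    cand <- cand[!bad, , drop = FALSE]
  }
  keys <- setdiff(unique(cellKeys(cand, g$ncols)),
                  cellKeys(referenceCells, g$ncols))
  if (!length(keys)) stop("no valid pseudo-presence candidates")
  keysToCells(sort(keys), g$ncols)
}

#' Environmental angle similarity of a candidate cell
#'
#' The Pearson correlation (the cosine of the angle between centred
#' vectors) between the candidate's standardized environmental vector and
#' each reference cell's vector, averaged over references.  A constant
#' vector has no defined angle and scores \code{-Inf} (always ranked
#' last) with a warning.
#'
#' @param candidateCell single (row, col) cell.
#' @param referenceCells (row, col) matrix.
#' @param stdStack standardized \linkS4class{EnvStack}.
#' @return numeric in [-1, 1] (or -Inf sentinel).
#' @export
angleSimilarity <- function(candidateCell, referenceCells, stdStack) {
  v <- drop(cellValues(stdStack, asCellMatrix(candidateCell)))
  R <- cellValues(stdStack, referenceCells)
  if (popSd(v) == 0) {
    warning("candidate has a constant environmental vector")
    return(-Inf)
  }
  sims <- apply(R, 1L, function(r) {
    if (popSd(r) == 0) return(NA_real_)
    cor(v, r)
  })
  if (all(is.na(sims))) {
    warning("all reference vectors are constant")
    return(-Inf)
  }
  mean(sims, na.rm = TRUE)
}

#' Select pseudo-presences to reach five potential presence cells
#'
#' Takes the \code{n = 5 - nReferences} knight-move candidates with the
#' highest mean angle similarity to the references; ties are broken by
#' smaller Euclidean distance to the nearest reference, then by row-major
#' cell index.  Species already holding 5+ cells need no extension and get
#' an empty set; single-cell species are excluded upstream.
#'
#' @param referenceCells (row, col) matrix with 2--4 rows (>= 5 rows
#'   returns an empty matrix).
#' @param stdStack standardized \linkS4class{EnvStack}.
#' @return (row, col) matrix of selected cells (fewer than `n` rows, with
#'   a warning, when candidates run short).
#' @export
selectPseudoPresences <- function(referenceCells, stdStack) {
  referenceCells <- asCellMatrix(referenceCells)
  nref <- nrow(referenceCells)
  if (nref < 2L) stop("single-cell species are excluded from modelling")
  if (nref >= 5L) return(asCellMatrix(matrix(integer(0), 0, 2)))
  n <- 5L - nref
  cand <- knightCandidates(referenceCells, stdStack)
  sims <- vapply(seq_len(nrow(cand)), function(i)
    suppressWarnings(angleSimilarity(cand[i, ], referenceCells, stdStack)),
    numeric(1))
  refXY <- cellCentroids(stdStack, referenceCells)
  candXY <- cellCentroids(stdStack, cand)
  nearest <- vapply(seq_len(nrow(cand)), function(i)
    min(sqrt((refXY[, 1] - candXY[i, 1])^2 + (refXY[, 2] - candXY[i, 2])^2)),
    numeric(1))
  ord <- order(-sims, nearest, cellKeys(cand, gridGeometry(stdStack)$ncols))
  if (nrow(cand) < n) {
    warning("only ", nrow(cand), " pseudo-presence candidates available")
    n <- nrow(cand)
  }
  cand[ord[seq_len(n)], , drop = FALSE]
}

#' Fit the full rare-species phylogenetic niche model
#'
#' The rare species' presence set is its reference cells, extended by
#' knight-move pseudo-presences to 5 cells when fewer than 5 references
#' exist.  For the input tree and each of \code{nTreeReps - 1} random
#' perturbations, its niche trait vector is imputed from the well-sampled
#' relatives, decoded into an ENFA model, and scored by bootstrap
#' cross-validation; replicates with mean AUC below \code{aucMin} are
#' discarded and the best surviving replicate wins model selection.
#'
#' @param speciesId tip label of the rare species.
#' @param referenceCells (row, col) matrix of its occurrence cells (2--14).
#' @param tree ape phylo containing the species.
#' @param traitTable from \code{\link{nicheTraitTable}} (observed species
#'   only).
#' @param stack raw \linkS4class{EnvStack}.
#' @param background background sample (see \code{\link{sampleBackground}}).
#' @param nTreeReps tree replicates tested (default 50).
#' @param cvReps,split bootstrap evaluation settings (default 10 and 0.8).
#' @param aucMin acceptance floor on mean AUC (default 0.7).
#' @param seed integer seed.
#' @return a \linkS4class{RareFit}.
#' @export
fitEnphylo <- function(speciesId, referenceCells, tree, traitTable, stack,
                       background, nTreeReps = 50, cvReps = 10, split = 0.8,
                       aucMin = 0.7, seed = NULL) {
  referenceCells <- asCellMatrix(referenceCells)
  nref <- nrow(referenceCells)
  if (nref < 2L) stop("single-cell species are excluded from modelling")
  if (nref >= 15L)
    stop("species has 15+ cells: use the ensemble tiers")
  std <- standardizeStack(stack, background)
  stdStack <- std$stack
  pseudo <- if (nref < 5L) selectPseudoPresences(referenceCells, stdStack)
            else asCellMatrix(matrix(integer(0), 0, 2))
  presences <- rbind(referenceCells, pseudo)

  fits <- vector("list", nTreeReps)
  for (r in seq_len(nTreeReps)) {
    treeR <- if (r == 1L) tree else
      perturbTree(tree, seed = subSeed(seed, "tree-rep", paste0(speciesId, r)))
    imp <- try(imputeTipTraits(treeR, traitTable, speciesId), silent = TRUE)
    if (inherits(imp, "try-error")) next
    modelR <- traitToEnfa(imp$trait, stdStack, presences)
    fitter <- function(trainPres, trainBg)
      enfaScorer(traitToEnfa(imp$trait, stdStack, trainPres))
    ev <- try(bootstrapEvaluate(fitter, presences, background$cellIds,
                                stdStack, nReps = cvReps, split = split,
                                aucMin = aucMin,
                                seed = subSeed(seed, "cv",
                                               paste0(speciesId, r))),
              silent = TRUE)
    if (inherits(ev, "try-error")) next
    fits[[r]] <- list(model = modelR, eval = ev, index = r)
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("no tree replicate could be evaluated for '", speciesId, "'")
  aucs <- vapply(fits, function(f) f$eval$meanAUC, numeric(1))
  passing <- which(aucs >= aucMin)
  if (!length(passing))
    stop("model rejected: every tree replicate scored mean AUC < ", aucMin,
         " for '", speciesId, "'")
  best <- passing[which.max(aucs[passing])]
  chosen <- fits[[best]]
  suit <- mahalanobisSuitability(chosen$model, stdStack)
  new("RareFit", speciesId = speciesId, referenceCells = referenceCells,
      pseudoCells = pseudo, model = chosen$model, suitability = suit,
      evalRecord = chosen$eval, chosenTreeIndex = as.integer(chosen$index))
}
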