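# Virtual landscapes, phylogenies, phylogenetically structured niches,
# occurrence samples and future scenarios with known ground truth.

# Separable Gaussian smoothing of a matrix (reflecting edges); width in
# cells is the kernel sd.
gaussSmooth <- function(m, width) {
  if (width <= 0) return(m)
  half <- max(1L, ceiling(3 * width))
  k <- exp(-0.5 * ((-half:half) / width)^2)
  k <- k / sum(k)
  pad <- function(v) c(rev(v[seq_len(half)]), v, rev(v[length(v) - seq_len(half) + 1L]))
  smooth1 <- function(v) {
    out <- stats::filter(pad(v), k, sides = 2L)
    as.numeric(out[(half + 1L):(half + length(v))])
  }
  m <- apply(m, 2L, smooth1)
  t(apply(m, 1L, smooth1))
}

# Min Euclidean distance (km) from every cell centroid to a set of cells.
distanceTransform <- function(nrows, ncols, cellSize, seedCells) {
  sc <- asCellMatrix(seedCells)
  rows <- matrix(seq_len(nrows) - 1L, nrows, ncols)
  cols <- matrix(seq_len(ncols) - 1L, nrows, ncols, byrow = TRUE)
  d2 <- matrix(Inf, nrows, ncols)
  for (i in seq_len(nrow(sc))) {
    di <- (rows - sc[i, 1L])^2 + (cols - sc[i, 2L])^2
    d2 <- pmin(d2, di)
  }
  sqrt(d2) * cellSize
}

#' Simulate a multi-layer virtual landscape
#'
#' Climate layers are a smooth oriented gradient plus spatially
#' autocorrelated noise (Gaussian-kernel-smoothed white noise, kernel sd =
#' \code{spatialCorrRange} km, rescaled to unit variance); land-cover
#' layers are Euclidean distance transforms from randomly seeded category
#' patches, emulating per-category land-use distance predictors.
#'
#' @param nrows,ncols grid dimensions (>= 10 each).
#' @param nClimateLayers,nLulcLayers layer counts.
#' @param spatialCorrRange autocorrelation range in km (0 = white noise).
#' @param nPatches patch seeds per land-cover layer.
#' @param cellSize cell edge in km.
#' @param seed integer seed (fully deterministic output).
#' @return an \linkS4class{EnvStack}; land-cover patch seeds are kept in
#'   \code{metadata$lulcSeeds} so scenario generation can relocate them.
#' @export
simulateLandscape <- function(nrows = 60, ncols = 60, nClimateLayers = 5,
                              nLulcLayers = 3, spatialCorrRange = 6,
                              nPatches = 5, cellSize = 1, seed = NULL) {
  stopifnot(nrows >= 10, ncols >= 10)
  withSeed(seed, {
    layers <- list()
    rows <- matrix(seq_len(nrows) - 1L, nrows, ncols) / nrows
    cols <- matrix(seq_len(ncols) - 1L, nrows, ncols, byrow = TRUE) / ncols
    for (i in seq_len(nClimateLayers)) {
      theta <- runif(1, 0, 2 * pi)
      grad <- 2 * (cos(theta) * rows + sin(theta) * cols)
      noise <- matrix(rnorm(nrows * ncols), nrows, ncols)
      noise <- gaussSmooth(noise, spatialCorrRange / cellSize)
      s <- popSd(as.numeric(noise))
      if (s > 0) noise <- noise / s
      layers[[paste0("clim", i)]] <- grad + noise
    }
    lulcSeeds <- list()
    for (i in seq_len(nLulcLayers)) {
      sc <- asCellMatrix(cbind(sample(nrows, nPatches) - 1L,
                               sample(ncols, nPatches) - 1L))
      lulcSeeds[[paste0("lulc", i)]] <- sc
      layers[[paste0("lulc", i)]] <-
        distanceTransform(nrows, ncols, cellSize, sc)
    }
    stk <- envStack(layers, cellSize = cellSize)
    stk@metadata$lulcSeeds <- lulcSeeds
    stk
  })
}

#' Simulate a clade and phylogenetically structured niche optima
#'
#' A birth--death tree with the requested tip count is rescaled to unit
#' height; per-layer niche optima then evolve by Brownian motion with
#' variance rate \code{bmRate} from a root state, so closely related
#' species have similar climatic preferences (positive phylogenetic
#' signal by construction).
#'
#' @param nSpecies number of tips (>= 4).
#' @param nLayers number of niche dimensions (layers) to evolve.
#' @param bmRate Brownian variance accumulated over the unit tree height.
#' @param birthRate,deathRate birth--death rates (death < birth).
#' @param rootState numeric scalar or length-nLayers vector.
#' @param seed integer seed.
#' @return list with `tree` (ape phylo, unit height) and `optima`
#'   (nSpecies x nLayers matrix, rownames = tip labels).
#' @export
simulateTreeAndNiches <- function(nSpecies = 32, nLayers = 8, bmRate = 1,
                                  birthRate = 1, deathRate = 0,
                                  rootState = 0, seed = NULL) {
  stopifnot(nSpecies >= 4)
  if (deathRate >= birthRate)
    stop("deathRate must be smaller than birthRate")
  withSeed(seed, {
    tree <- ape::rphylo(nSpecies, birth = birthRate, death = deathRate)
    tree$tip.label <- sprintf("sp%02d", seq_len(nSpecies))
    h <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / h
    C <- ape::vcv(tree)
    root <- rep_len(rootState, nLayers)
    optima <- matrix(0, nSpecies, nLayers,
                     dimnames = list(rownames(C), NULL))
    if (bmRate > 0) {
      L <- chol(bmRate * C)
      for (j in seq_len(nLayers))
        optima[, j] <- root[j] + drop(t(L) %*% rnorm(nSpecies))
    } else {
      optima[] <- rep(root, each = nSpecies)
    }
    list(tree = tree, optima = optima)
  })
}

#' Gaussian true suitability surface
#'
#' \code{suitability(cell) = exp(-0.5 * sum_v ((x_v - optimum_v) /
#' breadth_v)^2)}: 1 at the optimum, monotone decreasing in standardized
#' environmental distance.
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param optimum numeric, one entry per layer.
#' @param breadth positive numeric, one entry per layer (recycled).
#' @return numeric matrix in [0, 1]; NA at nodata cells.
#' @export
trueSuitability <- function(stack, optimum, breadth) {
  breadth <- rep_len(breadth, nLayers(stack))
  if (any(breadth <= 0)) stop("breadth must be positive")
  stopifnot(length(optimum) == nLayers(stack))
  g <- gridGeometry(stack)
  d2 <- matrix(0, g$nrows, g$ncols)
  for (l in seq_len(nLayers(stack)))
    d2 <- d2 + ((stack@values[, , l] - optimum[l]) / breadth[l])^2
  out <- exp(-0.5 * d2)
  out[stack@nodataMask] <- NA_real_
  out
}

#' Sample occurrence cells from a truth surface
#'
#' Cells are drawn without replacement with probability proportional to
#' suitability; supports samples as small as two cells.
#'
#' @param truthGrid suitability matrix (NA = unusable).
#' @param stack the \linkS4class{EnvStack} the grid lives on.
#' @param n cells requested; capped (warning) at the positive-suitability
#'   cell count.
#' @param speciesId label for the result.
#' @param seed integer seed.
#' @return an occurrence set (as \code{\link{rasterizeOccurrences}}).
#' @export
sampleOccurrences <- function(truthGrid, stack, n, speciesId = "species",
                              seed = NULL) {
  w <- t(truthGrid)                       # row-major
  cand <- which(!is.na(w) & w > 0) - 1L
  if (!length(cand)) stop("no cells with positive suitability")
  if (n > length(cand)) {
    warning("only ", length(cand), " cells have positive suitability; capped")
    n <- length(cand)
  }
  keys <- withSeed(seed,
                   cand[sample.int(length(cand), n, prob = w[cand + 1L])])
  cells <- keysToCells(sort(keys), ncol(truthGrid))
  structure(list(speciesId = speciesId,
                 points = cellCentroids(stack, cells),
                 cellIds = cells),
            class = "OccurrenceSet")
}

#' Build the factorial of future scenario stacks
#'
#' Emits the scenario structure the projection pipeline consumes:
#' dynamic-climate members (climate layers shifted, land-cover copied
#' verbatim from current), dynamic-land-use members (climate copied,
#' a fraction of land-cover patches relocated and distances recomputed),
#' and dynamic-both members.  The mild scenario applies half the stated
#' climate shift and half the patch relocations; the severe scenario the
#' full amounts.  Each "GCM" analogue adds independent per-layer jitter
#' around the shared shift.
#'
#' @param current an \linkS4class{EnvStack} from
#'   \code{\link{simulateLandscape}} (patch seeds in metadata).
#' @param climateShift numeric offset per climate layer (recycled).
#' @param lulcRegenerateFraction fraction of patches relocated under the
#'   severe scenario.
#' @param nGcm number of GCM analogues (>= 1).
#' @param gcmJitterSd sd of the per-GCM, per-layer additive jitter.
#' @param seed integer seed.
#' @return list with `current`, `scenarios` (named list of EnvStacks) and
#'   `index` (data.frame scenario/gcm/ssp/name).
#' @export
makeFutureScenarios <- function(current, climateShift = 1,
                                lulcRegenerateFraction = 0.4, nGcm = 3,
                                gcmJitterSd = 0.1, seed = NULL) {
  if (nGcm < 1) stop("nGcm must be >= 1")
  climIdx <- grep("^clim", layerNames(current))
  lulcIdx <- grep("^lulc", layerNames(current))
  shift <- rep_len(climateShift, length(climIdx))
  ssps <- c(mild = 0.5, severe = 1)
  gcms <- paste0("gcm", seq_len(nGcm))
  g <- gridGeometry(current)

  withSeed(seed, {
    jitter <- array(rnorm(nGcm * length(climIdx), 0, gcmJitterSd),
                    dim = c(nGcm, length(climIdx)))
    # relocated patch sets, shared between lulc and both members per ssp
    lulcFuture <- list()
    baseSeeds <- current@metadata$lulcSeeds
    if (is.null(baseSeeds) && length(lulcIdx)) {
      # stacks loaded from disk carry no patch metadata: recover the patch
      # cells as the zero-distance cells of each distance layer
      baseSeeds <- list()
      for (li in lulcIdx) {
        m <- current@values[, , li]
        at <- which(m <= min(m) + 1e-9, arr.ind = TRUE)
        baseSeeds[[layerNames(current)[li]]] <-
          asCellMatrix(cbind(at[, 1] - 1L, at[, 2] - 1L))
      }
    }
    for (sspName in names(ssps)) {
      frac <- ssps[[sspName]] * lulcRegenerateFraction
      seeds <- baseSeeds
      newLayers <- list()
      for (nm in names(seeds)) {
        sc <- seeds[[nm]]
        nMove <- round(frac * nrow(sc))
        if (nMove > 0) {
          mv <- sample(nrow(sc), nMove)
          sc[mv, ] <- cbind(sample(g$nrows, nMove) - 1L,
                            sample(g$ncols, nMove) - 1L)
          sc <- asCellMatrix(sc)
        }
        newLayers[[nm]] <- distanceTransform(g$nrows, g$ncols, g$cellSize, sc)
      }
      lulcFuture[[sspName]] <- newLayers
    }

    applyMember <- function(dynClim, dynLulc, gcmI, sspName) {
      vals <- current@values
      if (dynClim) {
        f <- ssps[[sspName]]
        for (jj in seq_along(climIdx))
          vals[, , climIdx[jj]] <- vals[, , climIdx[jj]] +
            f * shift[jj] + jitter[gcmI, jj]
      }
      if (dynLulc) {
        newLayers <- lulcFuture[[sspName]]
        for (jj in seq_along(lulcIdx))
          vals[, , lulcIdx[jj]] <-
            newLayers[[layerNames(current)[lulcIdx[jj]]]]
      }
      out <- current
      out@values <- vals
      out@metadata$scenario <- list(dynClim = dynClim, dynLulc = dynLulc,
                                    gcm = if (dynClim) gcms[gcmI] else NA,
                                    ssp = sspName)
      out
    }

    scen <- list()
    idx <- NULL
    for (sspName in names(ssps)) {
      for (gi in seq_len(nGcm)) {
        nm <- sprintf("climate__%s__%s", gcms[gi], sspName)
        scen[[nm]] <- applyMember(TRUE, FALSE, gi, sspName)
        idx <- rbind(idx, data.frame(scenario = "climate", gcm = gcms[gi],
                                     ssp = sspName, name = nm))
      }
      nm <- sprintf("lulc__%s", sspName)
      scen[[nm]] <- applyMember(FALSE, TRUE, 1L, sspName)
      idx <- rbind(idx, data.frame(scenario = "lulc", gcm = NA,
                                   ssp = sspName, name = nm))
      for (gi in seq_len(nGcm)) {
        nm <- sprintf("both__%s__%s", gcms[gi], sspName)
        scen[[nm]] <- applyMember(TRUE, TRUE, gi, sspName)
        idx <- rbind(idx, data.frame(scenario = "both", gcm = gcms[gi],
                                     ssp = sspName, name = nm))
      }
    }
    list(current = current, scenarios = scen, index = idx)
  })
}

#' Simulate a full virtual clade with known truth
#'
#' The default fixture every downstream module is validated on: a
#' landscape, a clade whose niche optima carry phylogenetic signal,
#' per-species Gaussian truth surfaces, and occurrence samples whose
#' counts populate all three modelling tiers (including 2--4-cell
#' species for the rare extension).
#'
#' @param nrows,ncols landscape dimensions.
#' @param nClimateLayers,nLulcLayers layer counts.
#' @param nSpecies clade size.
#' @param bmRate Brownian rate for niche evolution.
#' @param breadthRange range of the per-species niche breadth multiplier
#'   (times each layer's background sd); smaller = rarer.
#' @param occurrenceCounts integer vector recycled over species; the
#'   default spans 2 to 60 so rare (<15), intermediate (15--30) and
#'   data-rich (>30) tiers are all populated.
#' @param seed integer seed.
#' @return list: `stack`, `tree`, `optima`, `breadths`, `truth` (list of
#'   matrices), `occurrences` (list of occurrence sets), `counts`.
#' @export
simulateVirtualClade <- function(nrows = 60, ncols = 60, nClimateLayers = 5,
                                 nLulcLayers = 3, nSpecies = 32, bmRate = 1,
                                 breadthRange = c(0.6, 1.4),
                                 occurrenceCounts = c(2, 3, 4, 6, 10, 13,
                                                      18, 25, 30, 40, 50, 60),
                                 seed = 1) {
  stack <- simulateLandscape(nrows, ncols, nClimateLayers, nLulcLayers,
                             seed = subSeed(seed, "landscape"))
  V <- nLayers(stack)
  tn <- simulateTreeAndNiches(nSpecies, nLayers = V, bmRate = bmRate,
                              seed = subSeed(seed, "tree"))
  # niche optima live on each layer's own scale: affinely map the evolved
  # (root 0, rate bmRate) states onto mean +/- sd of the layer values
  layMean <- apply(stack@values, 3L, mean)
  laySd <- apply(stack@values, 3L, popSd)
  optima <- sweep(sweep(tn$optima, 2L, laySd / sqrt(bmRate), `*`),
                  2L, layMean, `+`)
  counts <- rep_len(occurrenceCounts, nSpecies)
  truth <- list(); occ <- list(); breadths <- matrix(0, nSpecies, V)
  sp <- tn$tree$tip.label
  withSeed(subSeed(seed, "breadths"), {
    bMult <- runif(nSpecies, breadthRange[1], breadthRange[2])
  })
  for (i in seq_len(nSpecies)) {
    breadths[i, ] <- bMult[i] * laySd
    truth[[sp[i]]] <- trueSuitability(stack, optima[sp[i], ], breadths[i, ])
    occ[[sp[i]]] <- sampleOccurrences(truth[[sp[i]]], stack, counts[i],
                                      speciesId = sp[i],
                                      seed = subSeed(seed, "occ", sp[i]))
  }
  rownames(breadths) <- sp
  list(stack = stack, tree = tn$tree, optima = optima, breadths = breadths,
       truth = truth, occurrences = occ,
       counts = setNames(counts, sp), seed = seed)
}

#' Write a virtual clade fixture to disk
#'
#' Emits the same text formats the loaders read: one ASCII grid per layer,
#' an occurrences CSV, a Newick tree, and a `truth.json` recording optima,
#' breadths, counts and seeds.
#'
#' @param clade result of \code{\link{simulateVirtualClade}}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeVirtualClade <- function(clade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEnvStack(clade$stack, file.path(dir, "layers"))
  ape::write.tree(clade$tree, file.path(dir, "tree.nwk"))
  occ <- do.call(rbind, lapply(clade$occurrences, function(o)
    data.frame(species = o$speciesId, x = o$points[, 1], y = o$points[, 2])))
  write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(optima = clade$optima, breadths = clade$breadths,
         counts = as.list(clade$counts), seed = clade$seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
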