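# Configuration and end-to-end orchestration: clean -> rasterize ->
# screen -> tier -> fit -> evaluate -> project -> binarize -> dispersal ->
# stack -> interactions, with a machine-readable manifest.

#' Subset the layers of an EnvStack
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param keep layer names (or indices) retained, in stack order.
#' @return an \linkS4class{EnvStack} with the retained layers.
#' @export
subsetLayers <- function(stack, keep) {
  if (is.character(keep)) keep <- match(keep, layerNames(stack))
  if (anyNA(keep)) stop("unknown layer in subset")
  out <- stack
  out@values <- stack@values[, , keep, drop = FALSE]
  out@layerNames <- stack@layerNames[keep]
  out@metadata$standardization <- NULL
  out@metadata$standardized <- NULL
  out
}

#' Default run configuration
#'
#' Holds the pipeline's fixed constants: 10,000 background points, a 0.7
#' collinearity threshold, tier bounds at 15 and 30 cells, a 5-cell
#' presence target for the rare extension, 50 tree replicates, 10-fold
#' bootstrap evaluation with an 80/20 split and a 0.7 AUC acceptance
#' floor, three binarization thresholds, and a 1 km/yr dispersal rate
#' over 2010--2070.
#'
#' @param ... named overrides of any configuration entry.
#' @return configuration list.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    simulate = TRUE,
    fixture = list(nrows = 60, ncols = 60, nClimateLayers = 5,
                   nLulcLayers = 3, nSpecies = 32, bmRate = 1),
    paths = NULL,
    backgroundN = 10000, rThreshold = 0.7,
    presenceTarget = 5, treeReps = 50, cvReps = 10, split = 0.8,
    aucMin = 0.7, kSpec = 2,
    thresholds = c("SensSpec", "MaxSensSpec", "TenPerc"),
    learnerKinds = c("GLM_QUAD", "RF", "MAXENT_LIKE"),
    scenario = list(climateShift = 1, lulcRegenerateFraction = 0.4,
                    nGcm = 3, gcmJitterSd = 0.1),
    dispersalRate = 1, years = c(2010, 2070),
    seed = 1, outDir = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a YAML/JSON run configuration
#'
#' @param path configuration file; entries override
#'   \code{\link{defaultConfig}}.
#' @return configuration list.
#' @export
readConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(defaultConfig, cfg)
}

loadPipelineInputs <- function(cfg) {
  seed <- cfg$seed
  if (isTRUE(cfg$simulate)) {
    fx <- cfg$fixture
    fx <- fx[intersect(names(fx), names(formals(simulateVirtualClade)))]
    fx$seed <- subSeed(seed, "fixture")
    clade <- do.call(simulateVirtualClade, fx)
    list(stack = clade$stack, tree = clade$tree,
         occurrences = clade$occurrences, clade = clade)
  } else {
    p <- cfg$paths
    stack <- loadEnvStack(p$rasters)
    tree <- ape::read.tree(p$tree)
    raw <- read.csv(p$occurrences)
    g <- gridGeometry(stack)
    bbox <- c(g$origin[1], g$origin[1] + g$ncols * g$cellSize,
              g$origin[2], g$origin[2] + g$nrows * g$cellSize)
    raw <- cleanOccurrences(raw, bbox)
    occ <- lapply(split(raw, raw$species), function(d)
      rasterizeOccurrences(as.matrix(d[, c("x", "y")]), stack,
                           speciesId = d$species[1]))
    list(stack = stack, tree = tree, occurrences = occ, clade = NULL)
  }
}

#' Run the full modelling pipeline
#'
#' Executes every stage on either the synthetic virtual clade (default)
#' or user-supplied rasters/occurrences/tree, and returns a manifest
#' recording seeds, per-stage counts, per-species tiers and evaluations,
#' diversity surfaces and interaction summaries.  Species whose every
#' model is rejected (mean AUC below the floor) are reported, not fatal.
#' When \code{config$outDir} is set, grids and tables are also written to
#' disk.
#'
#' @param config list from \code{\link{defaultConfig}} or
#'   \code{\link{readConfig}}.
#' @return manifest list (also the in-memory results: scorers, maps,
#'   diversity stacks, interaction summaries).
#' @export
runPipeline <- function(config = defaultConfig()) {
  cfg <- config
  seed <- cfg$seed
  inputs <- loadPipelineInputs(cfg)
  stack <- inputs$stack

  # --- background + collinearity screening -------------------------------
  bg <- sampleBackground(stack, cfg$backgroundN,
                         seed = subSeed(seed, "background"))
  retained <- collinearityFilter(stack, bg$cellIds, cfg$rThreshold)
  stack <- subsetLayers(stack, retained)

  # --- scenarios ---------------------------------------------------------
  sc <- cfg$scenario
  scen <- makeFutureScenarios(stack, climateShift = sc$climateShift,
                              lulcRegenerateFraction = sc$lulcRegenerateFraction,
                              nGcm = sc$nGcm, gcmJitterSd = sc$gcmJitterSd,
                              seed = subSeed(seed, "scenarios"))
  std <- standardizeStack(stack, bg)
  stdStack <- std$stack

  # --- tiers -------------------------------------------------------------
  occ <- inputs$occurrences
  tiers <- list(); excluded <- character(0)
  for (sp in names(occ)) {
    n <- nrow(occ[[sp]]$cellIds)
    if (n < 2) { excluded <- c(excluded, sp); next }
    tiers[[sp]] <- assignTier(n, sp)
  }

  # --- fit per tier ------------------------------------------------------
  wellSampled <- names(tiers)[vapply(tiers, function(t)
    t$tier != "ENPHYLO", logical(1))]
  enfaModels <- list()
  for (sp in wellSampled)
    enfaModels[[sp]] <- fitEnfa(stdStack, occ[[sp]]$cellIds, bg$cellIds,
                                kSpec = cfg$kSpec)
  traitTable <- if (length(enfaModels) >= 3L)
    nicheTraitTable(enfaModels, s = cfg$kSpec) else NULL

  scorers <- list(); evals <- list(); rejected <- character(0)
  rareFits <- list()
  for (sp in names(tiers)) {
    tier <- tiers[[sp]]$tier
    res <- try(switch(tier,
      ENPHYLO = {
        if (is.null(traitTable))
          stop("no well-sampled relatives available for imputation")
        rf <- fitEnphylo(sp, occ[[sp]]$cellIds, inputs$tree, traitTable,
                         stack, bg, nTreeReps = cfg$treeReps,
                         cvReps = cfg$cvReps, split = cfg$split,
                         aucMin = cfg$aucMin, seed = subSeed(seed, "fit", sp))
        rareFits[[sp]] <- rf
        list(scorer = enfaScorer(rf@model), eval = rf@evalRecord)
      },
      ESM = {
        fit <- fitEsm(occ[[sp]]$cellIds, bg$cellIds, stdStack,
                      learnerKinds = cfg$learnerKinds, cvReps = cfg$cvReps,
                      split = cfg$split, aucMin = cfg$aucMin,
                      seed = subSeed(seed, "fit", sp))
        list(scorer = fit$scorer,
             eval = list(meanAUC = sum(fit$members$meanAUC *
                                         fit$members$pass) /
                           sum(fit$members$pass),
                         members = fit$members, passFlag = TRUE))
      },
      SDM = {
        fit <- fitSdmEnsemble(occ[[sp]]$cellIds, bg$cellIds, stdStack,
                              learnerKinds = cfg$learnerKinds,
                              cvReps = cfg$cvReps, split = cfg$split,
                              aucMin = cfg$aucMin,
                              seed = subSeed(seed, "fit", sp))
        list(scorer = fit$scorer,
             eval = list(meanAUC = sum(fit$members$meanAUC *
                                         fit$members$pass) /
                           sum(fit$members$pass),
                         members = fit$members, passFlag = TRUE))
      }), silent = TRUE)
    if (inherits(res, "try-error")) {
      rejected <- c(rejected, sp)
    } else {
      scorers[[sp]] <- res$scorer
      evals[[sp]] <- res$eval
    }
  }

  # --- project, threshold, binarize, dispersal ---------------------------
  gcms <- paste0("gcm", seq_len(sc$nGcm))
  keys <- enumeratePredictions(cfg$thresholds, gcms, c("mild", "severe"))
  binaryMaps <- list()
  for (sp in names(scorers)) {
    scorer <- scorers[[sp]]
    curGrid <- predictGrid(scorer, stdStack)
    presScores <- scoreCells(scorer, stdStack, occ[[sp]]$cellIds)
    bgScores <- scoreCells(scorer, stdStack, bg$cellIds)
    rules <- lapply(cfg$thresholds, computeThreshold,
                    presenceScores = presScores,
                    backgroundScores = bgScores)
    names(rules) <- cfg$thresholds
    constraint <- dispersalMask(occ[[sp]], stack,
                                rateKmPerYear = cfg$dispersalRate,
                                yearFrom = cfg$years[1],
                                yearTo = cfg$years[2])
    spMaps <- list()
    for (i in seq_len(nrow(keys))) {
      k <- keys[i, ]
      grid <- if (k$scenario == "current") curGrid else {
        nm <- if (k$scenario == "lulc") sprintf("lulc__%s", k$ssp)
              else sprintf("%s__%s__%s", k$scenario, k$gcm, k$ssp)
        predictGrid(scorer, scen$scenarios[[nm]])
      }
      bmap <- applyDispersal(binarize(grid, rules[[k$threshold]]),
                             constraint)
      spMaps[[do.call(paste, c(as.list(unlist(k)), sep = "|"))]] <- bmap
    }
    binaryMaps[[sp]] <- spMaps
  }

  # --- diversity + interactions ------------------------------------------
  keyName <- function(scenario, gcm, ssp, thr)
    paste(scenario, gcm, ssp, thr, sep = "|")
  diversity <- list(); lossCat <- list(); gainCat <- list()
  if (length(binaryMaps)) {
    for (ssp in c("mild", "severe")) {
      for (thr in cfg$thresholds) for (g in gcms) {
        cur <- lapply(binaryMaps, `[[`, keyName("current", NA, NA, thr))
        pick <- function(scenario, gcmL)
          lapply(binaryMaps, `[[`, keyName(scenario, gcmL, ssp, thr))
        dClim <- stackDiversity(cur, pick("climate", g))
        dLulc <- stackDiversity(cur, pick("lulc", NA))
        dBoth <- stackDiversity(cur, pick("both", g))
        combo <- paste(thr, g, ssp, sep = "|")
        diversity[[combo]] <- list(climate = dClim, lulc = dLulc,
                                   both = dBoth)
        lossCat[[combo]] <- classifyInteraction(dLulc$L, dClim$L, dBoth$L)
        gainCat[[combo]] <- classifyInteraction(dLulc$G, dClim$G, dBoth$G)
      }
    }
  }
  summaries <- list()
  for (ssp in c("mild", "severe")) {
    sel <- grep(paste0("\\|", ssp, "$"), names(lossCat), value = TRUE)
    if (!length(sel)) next
    s <- try(rbind(
      cbind(ssp = ssp, interactionSummary(lossCat[sel], "loss")),
      cbind(ssp = ssp, interactionSummary(gainCat[sel], "gain"))),
      silent = TRUE)
    if (!inherits(s, "try-error")) summaries[[ssp]] <- s
  }

  manifest <- list(
    config = cfg[setdiff(names(cfg), "paths")],
    seed = seed,
    retainedLayers = retained,
    nBackground = bg$count,
    species = data.frame(
      species = names(tiers),
      nCells = vapply(tiers, `[[`, integer(1), "nCells"),
      tier = vapply(tiers, `[[`, character(1), "tier"),
      modelled = names(tiers) %in% names(scorers),
      meanAUC = vapply(names(tiers), function(sp)
        if (sp %in% names(evals)) evals[[sp]]$meanAUC else NA_real_,
        numeric(1)),
      row.names = NULL),
    excludedSingletons = excluded,
    rejectedSpecies = rejected,
    nModelled = length(scorers),
    nPredictionKeys = nrow(keys))

  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(manifest$species,
              file.path(cfg$outDir, "species_evaluation.csv"),
              row.names = FALSE)
    for (ssp in names(summaries))
      write.csv(summaries[[ssp]],
                file.path(cfg$outDir,
                          sprintf("interaction_summary_%s.csv", ssp)),
                row.names = FALSE)
    jsonlite::write_json(manifest[c("seed", "retainedLayers", "nBackground",
                                    "excludedSingletons", "rejectedSpecies",
                                    "nModelled", "nPredictionKeys")],
                         file.path(cfg$outDir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }

  c(manifest,
    list(scorers = scorers, evals = evals, rareFits = rareFits,
         binaryMaps = binaryMaps, diversity = diversity,
         interactionSummaries = summaries, keys = keys,
         stack = stack, stdStack = stdStack, background = bg,
         scenarios = scen, occurrences = occ, clade = inputs$clade))
}
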