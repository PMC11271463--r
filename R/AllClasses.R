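#' EnvStack: an aligned multi-layer environmental grid
#'
#' The unit every model in the package consumes and projects onto: a set of
#' co-registered raster layers on a planar km grid with a shared nodata
#' mask.  Values are held as an \code{nrows x ncols x nlayers} array; the
#' mask marks cells unusable in any layer.
#'
#' @slot values numeric array, \code{nrows x ncols x nlayers}.
#' @slot layerNames character, unique variable identifiers.
#' @slot cellSize numeric, cell edge in km (> 0).
#' @slot origin numeric length 2, \code{(x0, y0)} of the corner of cell
#'   \code{(0, 0)} in km.
#' @slot nodataMask logical matrix, \code{TRUE} = unusable cell.
#' @slot metadata list of free-form annotations (standardization record,
#'   land-cover patch seeds, scenario tags).
#' @export
setClass("EnvStack",
  representation(values = "array", layerNames = "character",
                 cellSize = "numeric", origin = "numeric",
                 nodataMask = "matrix", metadata = "list"),
  prototype(cellSize = 1, origin = c(0, 0), metadata = list()))

setValidity("EnvStack", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3-d array (rows, cols, layers)")
  if (d[3L] != length(object@layerNames))
    return("layerNames length must match the number of layers")
  if (anyDuplicated(object@layerNames)) return("layerNames must be unique")
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    return("cellSize must be a single positive number")
  if (length(object@origin) != 2L) return("origin must have length 2")
  if (!identical(dim(object@nodataMask), d[1:2]))
    return("nodataMask must match the grid shape")
  if (!is.logical(object@nodataMask)) return("nodataMask must be logical")
  TRUE
})

#' EnfaModel: a fitted ecological-niche factor analysis
#'
#' Holds the marginality vector, the specialization axes and eigenvalues,
#' and the presence cloud's centroid and covariance in the retained factor
#' space -- everything needed to score habitat suitability on any stack
#' standardized with the same background, and the object the phylogenetic
#' imputation machinery transfers between species.
#'
#' @slot layerNames character, the variables the model was fitted on.
#' @slot m numeric, marginality vector in background-sd units.
#' @slot M numeric, overall marginality \code{norm(m)/1.96}.
#' @slot U matrix, specialization axes as unit columns (sign-fixed).
#' @slot lambda numeric, specialization eigenvalues (background/presence
#'   variance ratio, sorted descending).
#' @slot k integer, retained factor count (marginality axis first).
#' @slot axes matrix, the \code{V x k} projection actually used for scoring.
#' @slot muF numeric, presence centroid in factor space.
#' @slot SF matrix, ridged presence covariance in factor space.
#' @slot standardization list with per-layer \code{mean} and \code{sd} over
#'   background cells, reused verbatim when projecting future stacks.
#' @export
setClass("EnfaModel",
  representation(layerNames = "character", m = "numeric", M = "numeric",
                 U = "matrix", lambda = "numeric", k = "integer",
                 axes = "matrix", muF = "numeric", SF = "matrix",
                 standardization = "list"))

setValidity("EnfaModel", function(object) {
  V <- length(object@layerNames)
  if (length(object@m) != V) return("m must have one entry per layer")
  if (nrow(object@axes) != V || ncol(object@axes) != object@k)
    return("axes must be V x k")
  if (length(object@muF) != object@k) return("muF must have length k")
  if (!identical(dim(object@SF), c(object@k, object@k)))
    return("SF must be k x k")
  if (max(abs(object@SF - t(object@SF))) > 1e-8) return("SF must be symmetric")
  ev <- eigen(object@SF, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return("SF must be positive definite")
  if (any(object@lambda < 0)) return("lambda must be non-negative")
  TRUE
})

#' RareFit: a rare-species model with its pseudo-presences
#'
#' The result of the rare-species pipeline: reference cells, the knight-move
#' pseudo-presences promoted to reach five potential presences, the
#' phylogenetically imputed niche model, the suitability surface, and the
#' evaluation of the tree replicate that won model selection.
#'
#' @slot speciesId character.
#' @slot referenceCells integer matrix of true occurrence cells (row, col).
#' @slot pseudoCells integer matrix of promoted cells (possibly 0 rows).
#' @slot model the imputed \linkS4class{EnfaModel}.
#' @slot suitability numeric matrix in [0, 1] (NA on nodata).
#' @slot evalRecord list: per-replicate AUC/TSS/Boyce plus summaries.
#' @slot chosenTreeIndex integer, which tree replicate won (1 = input tree).
#' @export
setClass("RareFit",
  representation(speciesId = "character", referenceCells = "matrix",
                 pseudoCells = "matrix", model = "EnfaModel",
                 suitability = "matrix", evalRecord = "list",
                 chosenTreeIndex = "integer"))

setValidity("RareFit", function(object) {
  nref <- nrow(object@referenceCells)
  nps <- nrow(object@pseudoCells)
  if (nref < 2L) return("at least two reference cells required")
  if (nref < 5L && nref + nps != 5L)
    return("references + pseudo-presences must total 5 when references < 5")
  if (nps > 0L) {
    both <- rbind(object@referenceCells, object@pseudoCells)
    if (anyDuplicated(both)) return("pseudo cells must be disjoint from references")
  }
  TRUE
})

setMethod("show", "EnvStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("EnvStack: %d x %d cells, %d layer(s), cell %.3g km\n",
              d[1], d[2], d[3], object@cellSize))
  cat("  layers:", paste(object@layerNames, collapse = ", "), "\n")
  cat(sprintf("  nodata cells: %d of %d\n", sum(object@nodataMask), d[1] * d[2]))
})

setMethod("show", "EnfaModel", function(object) {
  cat(sprintf("EnfaModel on %d layers: M = %.3f, k = %d factors\n",
              length(object@layerNames), object@M, object@k))
  cat("  specialization eigenvalues:",
      paste(sprintf("%.3g", object@lambda), collapse = ", "), "\n")
})

setMethod("show", "RareFit", function(object) {
  cat(sprintf("RareFit '%s': %d reference + %d pseudo-presence cells\n",
              object@speciesId, nrow(object@referenceCells),
              nrow(object@pseudoCells)))
  cat(sprintf("  chosen tree replicate: %d; mean AUC = %.3f\n",
              object@chosenTreeIndex, object@evalRecord$meanAUC))
})

#' @describeIn EnvStack-class number of layers
#' @param x an \code{EnvStack}
#' @export
nLayers <- function(x) dim(x@values)[3L]

#' Layer names of an EnvStack
#' @param x an \code{EnvStack}
#' @return character vector of variable identifiers.
#' @export
layerNames <- function(x) x@layerNames

#' Extract one layer of an EnvStack as a matrix
#' @param x an \code{EnvStack}
#' @param layer layer name or index.
#' @return numeric matrix with NA at nodata cells.
#' @export
getLayer <- function(x, layer) {
  if (is.character(layer)) layer <- match(layer, x@layerNames)
  if (is.na(layer) || layer < 1L || layer > nLayers(x))
    stop("unknown layer")
  m <- x@values[, , layer]
  dim(m) <- dim(x@values)[1:2]
  m[x@nodataMask] <- NA_real_
  m
}

#' Grid geometry of an EnvStack
#' @param x an \code{EnvStack}
#' @return list with nrows, ncols, cellSize, origin.
#' @export
gridGeometry <- function(x) {
  d <- dim(x@values)
  list(nrows = d[1L], ncols = d[2L], cellSize = x@cellSize, origin = x@origin)
}

sameGeometry <- function(a, b) {
  ga <- gridGeometry(a); gb <- gridGeometry(b)
  ga$nrows == gb$nrows && ga$ncols == gb$ncols &&
    isTRUE(all.equal(ga$cellSize, gb$cellSize)) &&
    isTRUE(all.equal(ga$origin, gb$origin))
}

#' All usable (non-nodata) cells of an EnvStack
#' @param x an \code{EnvStack}
#' @return integer matrix of 0-based (row, col) pairs, row-major order.
#' @export
validCells <- function(x) {
  ok <- which(!t(x@nodataMask)) - 1L       # row-major order
  nc <- ncol(x@nodataMask)
  asCellMatrix(cbind(ok %/% nc, ok %% nc))
}

#' Environmental values at a set of cells
#' @param x an \code{EnvStack}
#' @param cells integer matrix of 0-based (row, col) pairs.
#' @return numeric matrix, one row per cell, one column per layer.
#' @export
cellValues <- function(x, cells) {
  cells <- asCellMatrix(cells)
  idx <- cbind(cells[, 1L] + 1L, cells[, 2L] + 1L)
  d <- dim(x@values)
  out <- vapply(seq_len(nLayers(x)), function(l) {
    m <- x@values[, , l]
    dim(m) <- d[1:2]      # guard against 1-row/1-col dimension dropping
    m[idx]
  }, numeric(nrow(cells)))
  out <- matrix(out, nrow = nrow(cells),
                dimnames = list(NULL, x@layerNames))
  out
}

#' Cell centroids in km
#' @param x an \code{EnvStack}
#' @param cells integer matrix of 0-based (row, col) pairs.
#' @return numeric matrix with columns x, y.
#' @export
cellCentroids <- function(x, cells) {
  cells <- asCellMatrix(cells)
  cbind(x = x@origin[1L] + (cells[, 2L] + 0.5) * x@cellSize,
        y = x@origin[2L] + (cells[, 1L] + 0.5) * x@cellSize)
}
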