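# Grid / occurrence data model, I/O, cleaning, background sampling and
# collinearity screening.

#' Construct an EnvStack from matrices
#'
#' @param layers named list of numeric matrices (identical shape) or a 3-d
#'   array with dimnames on the third margin.
#' @param cellSize cell edge in km.
#' @param origin numeric (x0, y0) of the corner of cell (0, 0), km.
#' @param nodataMask optional logical matrix; NA cells in any layer are
#'   added to it automatically.
#' @return an \linkS4class{EnvStack}.
#' @export
envStack <- function(layers, cellSize = 1, origin = c(0, 0),
                     nodataMask = NULL) {
  if (is.array(layers) && length(dim(layers)) == 3L) {
    nm <- dimnames(layers)[[3L]]
    layers <- lapply(seq_len(dim(layers)[3L]), function(i) layers[, , i])
    names(layers) <- nm
  }
  if (!length(layers)) stop("no layers supplied")
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- paste0("layer", seq_along(layers))
  shp <- dim(layers[[1L]])
  if (!all(vapply(layers, function(m) identical(dim(m), shp), logical(1))))
    stop("all layers must share the same grid shape")
  vals <- array(unlist(layers, use.names = FALSE),
                dim = c(shp, length(layers)))
  mask <- if (is.null(nodataMask)) matrix(FALSE, shp[1], shp[2]) else nodataMask
  for (m in layers) mask <- mask | is.na(m)
  vals[is.na(vals)] <- 0
  new("EnvStack", values = vals, layerNames = names(layers),
      cellSize = as.numeric(cellSize), origin = as.numeric(origin),
      nodataMask = mask)
}

#' Read one ESRI ASCII grid
#'
#' @param path path to a `.asc` file.
#' @return list with `values` (matrix, NA for nodata), `cellSize`, `origin`.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header: ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("grid body does not match header dimensions: ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m, cellSize = hdr$cellsize,
       origin = c(hdr$xllcorner, hdr$yllcorner))
}

#' Write one matrix as an ESRI ASCII grid
#'
#' @param m numeric matrix (NA = nodata).
#' @param path output path.
#' @param cellSize,origin grid geometry.
#' @param digits significant digits written (default keeps full precision).
#' @export
writeAsciiGrid <- function(m, path, cellSize = 1, origin = c(0, 0),
                           digits = 17) {
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", origin[1L]),
           sprintf("yllcorner %.10g", origin[2L]),
           sprintf("cellsize %.10g", cellSize),
           "NODATA_value -9999")
  body <- apply(m, 1L, function(r) {
    r[is.na(r)] <- -9999
    paste(formatC(r, digits = digits, format = "g"), collapse = " ")
  })
  writeLines(c(hdr, body), path)
}

#' Load aligned rasters into an EnvStack
#'
#' Layers must share shape, cell size and origin; the nodata mask is the
#' union of per-layer nodata.
#'
#' @param paths character vector of `.asc` paths.
#' @param layerNames optional names (default: file basenames).
#' @return an \linkS4class{EnvStack}.
#' @export
loadEnvStack <- function(paths, layerNames = NULL) {
  if (!length(paths)) stop("no raster paths supplied")
  grids <- lapply(paths, readAsciiGrid)
  g1 <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!identical(dim(g$values), dim(g1$values)) ||
        !isTRUE(all.equal(g$cellSize, g1$cellSize)) ||
        !isTRUE(all.equal(g$origin, g1$origin)))
      stop("rasters are not aligned: shape/geotransform mismatch")
  }
  if (is.null(layerNames))
    layerNames <- sub("\\.asc$", "", basename(paths))
  envStack(setNames(lapply(grids, `[[`, "values"), layerNames),
           cellSize = g1$cellSize, origin = g1$origin)
}

#' Write an EnvStack as one ASCII grid per layer
#'
#' @param x an \linkS4class{EnvStack}.
#' @param dir output directory (created if needed).
#' @return character vector of paths written, named by layer.
#' @export
writeEnvStack <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(x@layerNames, ".asc"))
  for (i in seq_along(paths))
    writeAsciiGrid(getLayer(x, i), paths[i], x@cellSize, x@origin)
  setNames(paths, x@layerNames)
}

#' Clean raw occurrence records
#'
#' Drops records whose stated coordinate precision is below two decimal
#' places, exact duplicate rows, and records outside the bounding box.
#' Precision comes from the source table, never inferred from trailing
#' zeros.
#'
#' @param raw data.frame with columns species, x, y and optionally
#'   precision (decimal places of the source record; missing column =
#'   assumed precise).
#' @param bbox numeric (xmin, xmax, ymin, ymax).
#' @param minPrecision minimum decimal places retained (default 2).
#' @return cleaned data.frame (possibly 0 rows).
#' @export
cleanOccurrences <- function(raw, bbox, minPrecision = 2) {
  stopifnot(all(c("species", "x", "y") %in% names(raw)))
  keep <- rep(TRUE, nrow(raw))
  if ("precision" %in% names(raw))
    keep <- keep & raw$precision >= minPrecision
  keep <- keep & raw$x >= bbox[1] & raw$x <= bbox[2] &
    raw$y >= bbox[3] & raw$y <= bbox[4]
  out <- raw[keep, , drop = FALSE]
  out <- out[!duplicated(out[, c("species", "x", "y")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rasterize occurrence points onto a stack
#'
#' One cell id per occupied usable cell; points on nodata cells are dropped
#' with a warning, duplicates per cell collapse to one.
#'
#' @param points two-column matrix/data.frame of (x, y) in km.
#' @param stack an \linkS4class{EnvStack}.
#' @param speciesId label carried on the result.
#' @return an occurrence set: list with `speciesId`, `points`, `cellIds`
#'   (0-based (row, col) matrix, row-major order).
#' @export
rasterizeOccurrences <- function(points, stack, speciesId = "species") {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  g <- gridGeometry(stack)
  col <- floor((pts[, 1L] - g$origin[1L]) / g$cellSize)
  row <- floor((pts[, 2L] - g$origin[2L]) / g$cellSize)
  on <- row >= 0 & row < g$nrows & col >= 0 & col < g$ncols
  if (!any(on)) stop("all points fall off the grid")
  row <- row[on]; col <- col[on]
  bad <- stack@nodataMask[cbind(row + 1L, col + 1L)]
  if (any(bad))
    warning(sum(bad), " point(s) on nodata cells dropped")
  cells <- asCellMatrix(cbind(row[!bad], col[!bad]))
  if (!nrow(cells)) stop("all points fall on nodata cells")
  keys <- sort(unique(cellKeys(cells, g$ncols)))
  structure(list(speciesId = speciesId, points = pts[on, , drop = FALSE],
                 cellIds = keysToCells(keys, g$ncols)),
            class = "OccurrenceSet")
}

#' Sample background cells
#'
#' Uniform draw without replacement from the usable cells (optionally
#' intersected with a mask); deterministic under `seed`.
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param n number of cells requested; capped (with a warning) at the
#'   number available.
#' @param mask optional logical matrix restricting the candidate cells.
#' @param seed integer seed.
#' @return list with `cellIds` ((row, col) matrix) and `count`.
#' @export
sampleBackground <- function(stack, n, mask = NULL, seed = NULL) {
  stopifnot(n >= 1)
  ok <- !stack@nodataMask
  if (!is.null(mask)) ok <- ok & mask
  cand <- which(t(ok)) - 1L              # row-major keys
  if (!length(cand)) stop("no candidate background cells")
  if (n > length(cand)) {
    warning("requested ", n, " background cells but only ", length(cand),
            " available; capped")
    n <- length(cand)
  }
  keys <- withSeed(seed, sort(cand[sample.int(length(cand), n)]))
  list(cellIds = keysToCells(keys, ncol(ok)), count = n)
}

#' Greedy collinearity filter
#'
#' While any layer pair has |Pearson r| above the threshold over the sample
#' cells, removes the layer with the largest mean absolute correlation to
#' all remaining layers (ties keep the earlier layer); zero-variance layers
#' are removed first with a warning.  Survivors are returned in input
#' order.
#'
#' @param stack an \linkS4class{EnvStack} (>= 2 layers).
#' @param sampleCells (row, col) matrix of cells to correlate over (>= 3).
#' @param rThreshold absolute-correlation cutoff (default 0.7).
#' @return character vector of retained layer names.
#' @export
collinearityFilter <- function(stack, sampleCells, rThreshold = 0.7) {
  stopifnot(nLayers(stack) >= 2L, nrow(asCellMatrix(sampleCells)) >= 3L)
  X <- cellValues(stack, sampleCells)
  keep <- colnames(X)
  sds <- apply(X, 2L, popSd)
  if (any(sds == 0)) {
    warning("zero-variance layer(s) removed: ",
            paste(keep[sds == 0], collapse = ", "))
    keep <- keep[sds > 0]
  }
  while (length(keep) >= 2L) {
    R <- abs(cor(X[, keep, drop = FALSE]))
    diag(R) <- 0
    if (max(R) <= rThreshold) break
    meanAbs <- rowMeans(R) * length(keep) / (length(keep) - 1L)
    offender <- which(meanAbs == max(meanAbs))
    # drop the LATEST tied layer so earlier input order survives
    keep <- keep[-offender[length(offender)]]
  }
  keep
}
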