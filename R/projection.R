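# Scenario projection: thresholding, binarization and the dispersal
# constraint.

#' Compute a binarization threshold
#'
#' \code{SensSpec} picks the candidate score minimizing
#' |sensitivity - specificity|; \code{MaxSensSpec} maximizes
#' sensitivity + specificity - 1 (the TSS); \code{TenPerc} is the
#' nearest-rank 10th percentile of the training presence scores.
#' Presence is declared at score >= threshold throughout.
#'
#' @param scheme one of "SensSpec", "MaxSensSpec", "TenPerc".
#' @param presenceScores training presence scores (>= 2).
#' @param backgroundScores training background scores (required for the
#'   two sensitivity/specificity schemes).
#' @return threshold rule: list with `scheme`, `value`, `provenance`.
#' @export
computeThreshold <- function(scheme, presenceScores,
                             backgroundScores = NULL) {
  scheme <- match.arg(scheme, c("SensSpec", "MaxSensSpec", "TenPerc"))
  if (length(presenceScores) < 2L)
    stop("at least 2 presence scores required")
  value <- switch(scheme,
    TenPerc = {
      srt <- sort(presenceScores)
      srt[max(1L, ceiling(0.10 * length(srt)))]
    },
    {
      if (is.null(backgroundScores) || !length(backgroundScores))
        stop("background scores required for scheme ", scheme)
      cand <- sort(unique(c(presenceScores, backgroundScores)))
      sens <- vapply(cand, function(t) mean(presenceScores >= t), numeric(1))
      spec <- vapply(cand, function(t) mean(backgroundScores < t), numeric(1))
      if (scheme == "SensSpec") cand[which.min(abs(sens - spec))]
      else cand[which.max(sens + spec - 1)]
    })
  list(scheme = scheme, value = value,
       provenance = list(nPresence = length(presenceScores),
                         nBackground = length(backgroundScores)))
}

#' Binarize a suitability grid
#'
#' Cells with score >= the rule's value become presence; nodata (NA) is
#' preserved.
#'
#' @param grid numeric suitability matrix.
#' @param rule threshold rule from \code{\link{computeThreshold}}.
#' @return logical matrix (NA preserved).
#' @export
binarize <- function(grid, rule) {
  grid >= rule$value
}

# Distance from points to a convex polygon (vertices in order); 0 inside.
pointPolyDistance <- function(px, py, poly) {
  nv <- nrow(poly)
  if (nv == 1L) return(sqrt((px - poly[1, 1])^2 + (py - poly[1, 2])^2))
  segDist <- function(x, y, x1, y1, x2, y2) {
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) 0 else pmin(pmax(((x - x1) * dx + (y - y1) * dy) / L2, 0), 1)
    sqrt((x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2)
  }
  d <- rep(Inf, length(px))
  for (i in seq_len(if (nv == 2L) 1L else nv)) {
    j <- if (i == nv) 1L else i + 1L
    d <- pmin(d, segDist(px, py, poly[i, 1], poly[i, 2],
                         poly[j, 1], poly[j, 2]))
  }
  if (nv >= 3L) {
    # even-odd point-in-polygon test
    inside <- rep(FALSE, length(px))
    j <- nv
    for (i in seq_len(nv)) {
      cross <- (poly[i, 2] > py) != (poly[j, 2] > py)
      xi <- poly[j, 1] + (py - poly[j, 2]) *
        (poly[i, 1] - poly[j, 1]) / (poly[i, 2] - poly[j, 2])
      inside <- xor(inside, cross & (px < xi))
      j <- i
    }
    d[inside] <- 0
  }
  d
}

#' Dispersal constraint from occurrences
#'
#' The minimum convex polygon of the occurrence-cell centroids (a segment
#' when the points are collinear) is dilated by
#' \code{rate * (yearTo - yearFrom)} km; the mask holds every cell whose
#' centroid lies within that buffer, and always contains the occurrence
#' cells themselves.
#'
#' @param occurrences occurrence set (needs `$cellIds`).
#' @param stack an \linkS4class{EnvStack} providing the grid.
#' @param rateKmPerYear maximum annual dispersal rate (km/yr, >= 0).
#' @param yearFrom,yearTo dispersal horizon (default 2010 to 2070, giving
#'   a 60 km buffer at 1 km/yr).
#' @return list with `mcp` (vertex matrix), `bufferKm`, `mask` (logical
#'   grid).
#' @export
dispersalMask <- function(occurrences, stack, rateKmPerYear = 1,
                          yearFrom = 2010, yearTo = 2070) {
  if (rateKmPerYear < 0) stop("dispersal rate must be non-negative")
  if (yearTo <= yearFrom) stop("yearTo must exceed yearFrom")
  cells <- asCellMatrix(occurrences$cellIds)
  if (nrow(cells) < 2L) stop("at least 2 occurrence cells required")
  bufferKm <- rateKmPerYear * (yearTo - yearFrom)
  pts <- cellCentroids(stack, cells)
  hull <- chull(pts)
  poly <- pts[hull, , drop = FALSE]
  g <- gridGeometry(stack)
  all <- asCellMatrix(cbind(rep(0:(g$nrows - 1L), each = g$ncols),
                            rep(0:(g$ncols - 1L), g$nrows)))
  cen <- cellCentroids(stack, all)
  d <- pointPolyDistance(cen[, 1], cen[, 2], poly)
  mask <- matrix(FALSE, g$nrows, g$ncols)
  mask[cbind(all[, 1L] + 1L, all[, 2L] + 1L)] <- d <= bufferKm
  mask[cbind(cells[, 1L] + 1L, cells[, 2L] + 1L)] <- TRUE
  list(mcp = poly, bufferKm = bufferKm, mask = mask)
}

#' Crop a binary map by a dispersal constraint
#'
#' Cells outside the constraint mask are forced absent; cells inside are
#' untouched, so the operation never creates presences and is idempotent.
#'
#' @param binaryGrid logical matrix (NA = nodata).
#' @param constraint from \code{\link{dispersalMask}}.
#' @return logical matrix.
#' @export
applyDispersal <- function(binaryGrid, constraint) {
  if (!identical(dim(binaryGrid), dim(constraint$mask)))
    stop("grid and dispersal mask geometries differ")
  binaryGrid & constraint$mask
}

#' Enumerate the per-species prediction keys
#'
#' Current maps per threshold, dynamic-climate maps per GCM x SSP x
#' threshold, dynamic-land-use maps per SSP x threshold (GCM-free: climate
#' held constant), and dynamic-both maps per GCM x SSP x threshold.  The
#' default factorial (3 thresholds, 3 GCMs, 2 SSPs) yields 45 keys.
#'
#' @param thresholds threshold scheme labels.
#' @param gcms GCM labels.
#' @param ssps SSP labels.
#' @return data.frame with columns scenario, gcm, ssp, threshold.
#' @export
enumeratePredictions <- function(thresholds = c("SensSpec", "MaxSensSpec",
                                                "TenPerc"),
                                 gcms = paste0("gcm", 1:3),
                                 ssps = c("mild", "severe")) {
  cur <- data.frame(scenario = "current", gcm = NA_character_,
                    ssp = NA_character_, threshold = thresholds)
  clim <- expand.grid(scenario = "climate", gcm = gcms, ssp = ssps,
                      threshold = thresholds, stringsAsFactors = FALSE)
  lulc <- expand.grid(scenario = "lulc", gcm = NA_character_, ssp = ssps,
                      threshold = thresholds, stringsAsFactors = FALSE)
  both <- expand.grid(scenario = "both", gcm = gcms, ssp = ssps,
                      threshold = thresholds, stringsAsFactors = FALSE)
  out <- rbind(cur, clim, lulc, both)
  rownames(out) <- NULL
  out
}
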