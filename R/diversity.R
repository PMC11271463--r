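# Stacked diversity surfaces, the climate-by-land-use interaction
# classifier, percentage summaries, and Moran's I residual correlograms.

#' Stack binary maps into richness, loss and gain surfaces
#'
#' Per cell: SR is the presence count, L the count of species present now
#' and absent in the future, G the reverse, and delta the richness change,
#' so \code{SR_future = SR_current - L + G} holds everywhere.
#'
#' @param currentMaps,futureMaps named lists of logical matrices, same
#'   species set and grid in both epochs.
#' @return list with `SRcurrent`, `SRfuture`, `L`, `G`, `delta` (integer
#'   matrices, NA propagated from nodata).
#' @export
stackDiversity <- function(currentMaps, futureMaps) {
  if (!setequal(names(currentMaps), names(futureMaps)) ||
      is.null(names(currentMaps)))
    stop("current and future maps must cover the same species set")
  futureMaps <- futureMaps[names(currentMaps)]
  add <- function(maps, f) Reduce(`+`, lapply(maps, f))
  SRc <- add(currentMaps, function(m) m * 1L)
  SRf <- add(futureMaps, function(m) m * 1L)
  L <- Reduce(`+`, Map(function(cu, fu) (cu & !fu) * 1L,
                       currentMaps, futureMaps))
  G <- Reduce(`+`, Map(function(cu, fu) (!cu & fu) * 1L,
                       currentMaps, futureMaps))
  list(SRcurrent = SRc, SRfuture = SRf, L = L, G = G, delta = SRf - SRc)
}

#' Classify the climate-by-land-use interaction of a cell
#'
#' Inputs are the per-cell species loss (or gain) counts under the
#' dynamic-land-use scenario (`a`), the dynamic-climate scenario (`b`)
#' and the combined scenario (`c`).  Cells with a = b = c = 0 carry no
#' interaction; a = 0 with b > 0 is climate-only, b = 0 with a > 0 is
#' land-use-only; otherwise the combined effect is synergistic when
#' c > a + b, additive when c = a + b, and antagonistic when c < a + b.
#'
#' @param a,b,c non-negative integer vectors/matrices (recycled
#'   together).
#' @return character vector/matrix over \code{c("none", "only_climate",
#'   "only_LULC", "synergistic", "additive", "antagonistic")}; NA inputs
#'   give NA.
#' @export
classifyInteraction <- function(a, b, c) {
  if (any(a < 0 | b < 0 | c < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  out <- rep(NA_character_, length(a))
  ok <- !(is.na(a) | is.na(b) | is.na(c))
  av <- a[ok]; bv <- b[ok]; cv <- c[ok]
  res <- ifelse(av == 0 & bv == 0 & cv == 0, "none",
         ifelse(av == 0 & bv > 0, "only_climate",
         ifelse(bv == 0 & av > 0, "only_LULC",
         ifelse(cv > av + bv, "synergistic",
         ifelse(cv == av + bv, "additive", "antagonistic")))))
  out[ok] <- res
  if (!is.null(dim(a))) dim(out) <- dim(a)
  out
}

#' Summarize interaction percentages over combinations
#'
#' Per (threshold, GCM) combination, the percentage of classifiable cells
#' (category != none) in each of the five categories; the summary is the
#' mean of those percentages across combinations, computed separately for
#' loss and gain.
#'
#' @param categoryGrids named list (one entry per combination) of
#'   category matrices from \code{\link{classifyInteraction}}.
#' @param mode label carried on the output ("loss" or "gain").
#' @return data.frame with columns mode, category, percent (mean across
#'   combinations) plus one column per combination.
#' @export
interactionSummary <- function(categoryGrids, mode = "loss") {
  cats <- c("synergistic", "additive", "only_climate", "antagonistic",
            "only_LULC")
  percs <- NULL
  used <- character(0)
  for (nm in names(categoryGrids)) {
    g <- categoryGrids[[nm]]
    vals <- g[!is.na(g) & g != "none"]
    if (!length(vals)) {
      warning("combination '", nm, "' has no classifiable cells; skipped")
      next
    }
    p <- vapply(cats, function(ct) 100 * mean(vals == ct), numeric(1))
    percs <- cbind(percs, p)
    used <- c(used, nm)
  }
  if (is.null(percs)) stop("no combination had classifiable cells")
  colnames(percs) <- used
  out <- data.frame(mode = mode, category = cats,
                    percent = rowMeans(percs))
  cbind(out, as.data.frame(percs))
}

#' Moran's I correlogram with permutation tests
#'
#' For each distance class (binary weights w_ij = 1 when the pair
#' distance falls in the class), Moran's
#' \code{I = (n/W) * sum_ij w_ij z_i z_j / sum_i z_i^2} on the centred
#' residuals, with a permutation p-value (residuals shuffled over
#' locations; two-sided around the null mean -1/(n-1)).
#'
#' @param coords n x 2 matrix of point locations (km).
#' @param residuals numeric length n (e.g. observed 0/1 minus predicted
#'   score at evaluation points).
#' @param distanceBreaks increasing class edges in km.
#' @param nPermutations permutations per class (default 199).
#' @param seed integer seed.
#' @return list with `classes` (data.frame: lower, upper, nPairs, I, p),
#'   `meanI` and `fracSignificant` (share of classes with p < 0.05).
#' @export
moransCorrelogram <- function(coords, residuals, distanceBreaks,
                              nPermutations = 199, seed = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 10L) stop("at least 10 points required")
  z <- residuals - mean(residuals)
  denom <- sum(z^2)
  D <- as.matrix(dist(coords))
  eNull <- -1 / (n - 1)
  classes <- NULL
  permI <- function(W, Wsum, zz) (n / Wsum) * sum(W * tcrossprod(zz)) / sum(zz^2)
  withSeed(seed, {
    for (k in seq_len(length(distanceBreaks) - 1L)) {
      lo <- distanceBreaks[k]; hi <- distanceBreaks[k + 1L]
      W <- (D > lo & D <= hi) * 1
      diag(W) <- 0
      Wsum <- sum(W)
      if (Wsum == 0) {
        warning("empty distance class (", lo, ", ", hi, "]; dropped")
        next
      }
      I <- (n / Wsum) * sum(W * tcrossprod(z)) / denom
      exceed <- 0L
      for (p in seq_len(nPermutations)) {
        zp <- z[sample(n)]
        Ip <- permI(W, Wsum, zp)
        if (abs(Ip - eNull) >= abs(I - eNull)) exceed <- exceed + 1L
      }
      pval <- (exceed + 1) / (nPermutations + 1)
      classes <- rbind(classes,
                       data.frame(lower = lo, upper = hi, nPairs = Wsum / 2,
                                  I = I, p = pval))
    }
  })
  if (is.null(classes)) stop("all distance classes were empty")
  list(classes = classes, meanI = mean(classes$I),
       fracSignificant = mean(classes$p < 0.05), expectedNull = eNull)
}
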