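# Ecological-Niche Factor Analysis and Mahalanobis-distance suitability:
# the niche engine the phylogenetic imputation transfers between species.

#' Standardize a stack over background cells
#'
#' Each layer is centred and scaled to mean 0, sd 1 over the background
#' cells (population sd, consistent with the 1/n estimators used in the
#' niche fits).  The transformation is stored so future stacks can be
#' projected with the SAME parameters.
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param background background sample from \code{\link{sampleBackground}}
#'   (or any (row, col) matrix in \code{$cellIds}).
#' @return list with `standardization` (per-layer mean/sd) and `stack`
#'   (the standardized EnvStack, flagged in metadata).
#' @export
standardizeStack <- function(stack, background) {
  X <- cellValues(stack, background$cellIds)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, popSd)
  if (any(sdv == 0))
    stop("zero-variance layer over background: ",
         paste(layerNames(stack)[sdv == 0], collapse = ", "))
  std <- list(mean = mu, sd = sdv, layerNames = layerNames(stack))
  list(standardization = std,
       stack = applyStandardization(stack, std))
}

#' Apply a stored standardization to a stack
#'
#' @param stack an \linkS4class{EnvStack} with the same layers.
#' @param standardization record from \code{\link{standardizeStack}}.
#' @return standardized \linkS4class{EnvStack}.
#' @export
applyStandardization <- function(stack, standardization) {
  if (!identical(layerNames(stack), standardization$layerNames))
    stop("layer names do not match the standardization record")
  vals <- stack@values
  for (l in seq_len(nLayers(stack)))
    vals[, , l] <- (vals[, , l] - standardization$mean[l]) /
      standardization$sd[l]
  out <- stack
  out@values <- vals
  out@metadata$standardized <- TRUE
  out@metadata$standardization <- standardization
  out
}

# Sign-fix axes: scale each column so its largest-|loading| entry is
# positive (comparability of imputed axes across species).
signFix <- function(U) {
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

# Orthonormal basis of the orthogonal complement of v (V x (V-1)).
orthComplement <- function(v) {
  V <- length(v)
  qr.Q(qr(cbind(v, diag(V))))[, 2:V, drop = FALSE]
}

#' Fit an ecological-niche factor analysis
#'
#' Marginality is the presence mean in background-standardized space
#' (overall marginality \code{M = norm(m)/1.96}).  Specialization axes are
#' the eigenvectors of the background-to-presence variance-ratio operator
#' restricted to the orthogonal complement of the marginality direction;
#' eigenvalues (background variance / presence variance along the axis)
#' are sorted descending and the axes sign-fixed.  The presence cloud is
#' then projected on the retained factors (marginality axis first) to give
#' the centroid and ridged covariance that Mahalanobis scoring uses.
#'
#' @param stdStack standardized \linkS4class{EnvStack} (see
#'   \code{\link{standardizeStack}}).
#' @param presenceCells (row, col) matrix, >= 5 cells.
#' @param backgroundCells (row, col) matrix of background cells.
#' @param kSpec requested specialization axes; the retained factor count is
#'   \code{k = min(kSpec + 1, nLayers, nPresences - 2)}.
#' @return an \linkS4class{EnfaModel}.
#' @export
fitEnfa <- function(stdStack, presenceCells, backgroundCells, kSpec = 2) {
  presenceCells <- asCellMatrix(presenceCells)
  if (nrow(presenceCells) < 5L)
    stop("fewer than 5 presence cells: use the rare-species extension ",
         "(fitEnphylo)")
  Zp <- cellValues(stdStack, presenceCells)
  Zg <- cellValues(stdStack, backgroundCells)
  V <- ncol(Zp)
  m <- colMeans(Zp)
  Sp <- popCov(Zp)
  Sg <- popCov(Zg)
  if (min(eigen(Sp, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
    warning("singular presence covariance; ridge applied")
    Sp <- ridgePD(Sp, 1e-6 * sum(diag(Sp)) / V)
  }
  mdir <- if (sqrt(sum(m^2)) > 1e-10) m / sqrt(sum(m^2)) else {
    warning("marginality is numerically zero; using first layer axis")
    c(1, rep(0, V - 1L))
  }
  W <- orthComplement(mdir)
  A <- t(W) %*% Sp %*% W
  B <- t(W) %*% Sg %*% W
  R <- chol(ridgePD(A, 1e-12))
  Rinv <- backsolve(R, diag(V - 1L))
  Msym <- t(Rinv) %*% B %*% Rinv
  eig <- eigen((Msym + t(Msym)) / 2, symmetric = TRUE)
  U <- W %*% (Rinv %*% eig$vectors)
  U <- apply(U, 2L, function(u) u / sqrt(sum(u^2)))
  U <- signFix(matrix(U, nrow = V))
  lambda <- pmax(eig$values, 0)
  k <- min(kSpec + 1L, V, nrow(Zp) - 2L)
  axes <- cbind(mdir, U[, seq_len(k - 1L), drop = FALSE])
  colnames(axes) <- c("marginality", paste0("spec", seq_len(k - 1L)))
  Fp <- Zp %*% axes
  muF <- colMeans(Fp)
  SF <- ridgePD(popCov(Fp))
  std <- stdStack@metadata$standardization
  if (is.null(std)) std <- list()
  new("EnfaModel", layerNames = layerNames(stdStack), m = m,
      M = sqrt(sum(m^2)) / 1.96, U = U, lambda = lambda, k = as.integer(k),
      axes = axes, muF = muF, SF = SF, standardization = std)
}

#' Mahalanobis habitat suitability
#'
#' Every usable cell is projected into the model's factor space; the
#' squared Mahalanobis distance to the presence centroid is converted to a
#' calibrated [0, 1] suitability as the upper-tail probability of a
#' chi-square with \code{df = k}: 1 where the cell matches the mean used
#' habitat, decreasing monotonically with environmental distance.
#'
#' @param model an \linkS4class{EnfaModel}.
#' @param stdStack a stack standardized with the model's own
#'   standardization (a raw stack is standardized automatically when the
#'   model carries its record).
#' @return numeric matrix in [0, 1]; NA at nodata cells.
#' @export
mahalanobisSuitability <- function(model, stdStack) {
  if (!isTRUE(stdStack@metadata$standardized)) {
    if (!length(model@standardization))
      stop("stack is not standardized and the model has no record")
    stdStack <- applyStandardization(stdStack, model@standardization)
  }
  cells <- validCells(stdStack)
  Z <- cellValues(stdStack, cells)
  Fz <- Z %*% model@axes
  d2 <- mahalanobis(Fz, model@muF, model@SF)
  suit <- pchisq(d2, df = model@k, lower.tail = FALSE)
  g <- gridGeometry(stdStack)
  out <- matrix(NA_real_, g$nrows, g$ncols)
  out[cbind(cells[, 1L] + 1L, cells[, 2L] + 1L)] <- suit
  out
}

#' Encode an EnfaModel as an imputable niche trait vector
#'
#' Concatenates the marginality vector with the first \code{s} sign-fixed
#' specialization axes scaled by the square root of their eigenvalues, so
#' specialization magnitude survives phylogenetic averaging.
#'
#' @param model an \linkS4class{EnfaModel}.
#' @param s number of specialization axes encoded (default 2).
#' @return numeric vector of length \code{(s + 1) * nLayers}.
#' @export
enfaToTrait <- function(model, s = 2) {
  if (ncol(model@U) < s)
    stop("model has fewer than ", s, " specialization axes")
  c(model@m, as.numeric(model@U[, seq_len(s), drop = FALSE] %*%
                          diag(sqrt(model@lambda[seq_len(s)]), s)))
}

#' Reconstruct an EnfaModel from an imputed trait vector
#'
#' Inverts \code{\link{enfaToTrait}}: the first block is the marginality
#' vector; each following block is an axis whose norm restores the
#' eigenvalue.  The presence centroid and (ridged) covariance in factor
#' space are recomputed from the supplied presence cells.
#'
#' @param trait numeric vector of length \code{(s + 1) * V}.
#' @param stdStack standardized stack (supplies layers + standardization).
#' @param presenceCells (row, col) matrix of >= 4 presence cells used for
#'   the factor-space moments.
#' @return an \linkS4class{EnfaModel}.
#' @export
traitToEnfa <- function(trait, stdStack, presenceCells) {
  V <- nLayers(stdStack)
  if (length(trait) %% V != 0L || length(trait) < 2L * V)
    stop("trait length must be a multiple of the layer count (>= 2 blocks)")
  s <- length(trait) %/% V - 1L
  m <- trait[seq_len(V)]
  U <- matrix(0, V, s)
  lambda <- numeric(s)
  for (j in seq_len(s)) {
    w <- trait[j * V + seq_len(V)]
    nw <- sqrt(sum(w^2))
    lambda[j] <- nw^2
    U[, j] <- if (nw > 1e-12) w / nw else c(1, rep(0, V - 1L))
  }
  U <- signFix(U)
  presenceCells <- asCellMatrix(presenceCells)
  k <- min(s + 1L, V, max(nrow(presenceCells) - 2L, 2L))
  mdir <- if (sqrt(sum(m^2)) > 1e-10) m / sqrt(sum(m^2)) else
    c(1, rep(0, V - 1L))
  axes <- cbind(mdir, U[, seq_len(k - 1L), drop = FALSE])
  colnames(axes) <- c("marginality", paste0("spec", seq_len(k - 1L)))
  Fp <- cellValues(stdStack, presenceCells) %*% axes
  muF <- colMeans(Fp)
  # covariances from <10 points get an eigenvalue floor (1% of the
  # background-unit variance) so Mahalanobis distances stay finite enough
  # for the chi-square tail not to underflow at scoreable cells
  eps <- if (nrow(Fp) < 10L)
    max(1e-6 * sum(diag(popCov(Fp))) / k, 1e-2) else NULL
  SF <- ridgePD(popCov(Fp), eps)
  std <- stdStack@metadata$standardization
  if (is.null(std)) std <- list()
  new("EnfaModel", layerNames = layerNames(stdStack), m = m,
      M = sqrt(sum(m^2)) / 1.96, U = U, lambda = lambda, k = as.integer(k),
      axes = axes, muF = muF, SF = SF, standardization = std)
}

#' Serialize / restore an EnfaModel as JSON
#'
#' @param model an \linkS4class{EnfaModel}.
#' @param path output (input) file path.
#' @return \code{readEnfaModel} returns the restored model.
#' @export
writeEnfaModel <- function(model, path) {
  jsonlite::write_json(
    list(layerNames = model@layerNames, m = model@m, M = model@M,
         U = model@U, lambda = model@lambda, k = model@k,
         axes = model@axes, muF = model@muF, SF = model@SF,
         standardization = model@standardization),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeEnfaModel
#' @export
readEnfaModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- if (is.null(x$standardization)) list() else
    lapply(x$standardization, unlist)
  k <- as.integer(x$k)
  axes <- as.matrix(x$axes)
  fnames <- c("marginality", if (k > 1L) paste0("spec", seq_len(k - 1L)))
  dimnames(axes) <- list(x$layerNames, fnames)
  SF <- as.matrix(x$SF)
  dimnames(SF) <- list(fnames, fnames)
  new("EnfaModel", layerNames = x$layerNames,
      m = setNames(x$m, x$layerNames), M = x$M,
      U = as.matrix(x$U), lambda = x$lambda, k = k,
      axes = axes, muF = setNames(as.numeric(x$muF), fnames), SF = SF,
      standardization = std)
}
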