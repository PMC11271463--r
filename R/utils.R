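# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards so package functions never perturb user RNG.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit sub-seed from a master seed, a stage label and a
# species label, so adding a species never perturbs another species' stream.
subSeed <- function(seed, stage, id = "") {
  h <- 0
  for (ch in utf8ToInt(paste0(stage, "::", id)))
    h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(seed) + h) %% 2147483629)
}

# Cells are integer matrices with columns (row, col), 0-based.
asCellMatrix <- function(cells) {
  if (is.null(dim(cells))) cells <- matrix(cells, ncol = 2, byrow = TRUE)
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  colnames(cells) <- c("row", "col")
  cells
}

cellKeys <- function(cells, ncols) {
  cells <- asCellMatrix(cells)
  cells[, 1L] * as.numeric(ncols) + cells[, 2L]
}

keysToCells <- function(keys, ncols) {
  asCellMatrix(cbind(keys %/% ncols, keys %% ncols))
}

# Population (1/n) covariance and sd, used throughout so 5-point and
# 500-point fits share an estimator.
popCov <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  xc <- sweep(x, 2L, colMeans(x))
  crossprod(xc) / n
}

popSd <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

# Symmetrize and ridge a covariance matrix until positive definite.
ridgePD <- function(S, eps = NULL) {
  S <- (S + t(S)) / 2
  k <- nrow(S)
  if (is.null(eps)) eps <- max(1e-6 * sum(diag(S)) / k, 1e-10)
  S <- S + diag(eps, k)
  while (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 1e-12) {
    eps <- eps * 10
    S <- S + diag(eps, k)
  }
  S
}
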