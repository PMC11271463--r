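# A common scorer interface: every fitted model (ENFA/Mahalanobis,
# single learners, small-model ensembles, weighted averages) scores cells
# of any stack carrying the same layers, standardizing raw stacks with
# the training standardization automatically.

#' Score cells with a fitted model
#'
#' @param scorer a scorer object (from \code{\link{fitLearner}},
#'   \code{\link{fitEsm}}, \code{\link{ensembleAverage}} or
#'   \code{\link{enfaScorer}}).
#' @param stack an \linkS4class{EnvStack} (raw or standardized).
#' @param cells (row, col) matrix.
#' @return numeric vector of scores in [0, 1].
#' @export
scoreCells <- function(scorer, stack, cells) UseMethod("scoreCells")

#' Project a scorer onto a whole stack
#'
#' @inheritParams scoreCells
#' @return numeric matrix of scores; NA at nodata cells.
#' @export
predictGrid <- function(scorer, stack) {
  cells <- validCells(stack)
  g <- gridGeometry(stack)
  out <- matrix(NA_real_, g$nrows, g$ncols)
  out[cbind(cells[, 1L] + 1L, cells[, 2L] + 1L)] <-
    scoreCells(scorer, stack, cells)
  out
}

ensureStandardized <- function(stack, standardization) {
  if (isTRUE(stack@metadata$standardized)) stack
  else applyStandardization(stack, standardization)
}

#' Wrap an EnfaModel as a scorer
#'
#' @param model an \linkS4class{EnfaModel}.
#' @return a scorer whose scores are the Mahalanobis chi-square
#'   suitability of the model.
#' @export
enfaScorer <- function(model) {
  structure(list(model = model), class = c("enfaScorer", "sdmScorer"))
}

#' @export
scoreCells.enfaScorer <- function(scorer, stack, cells) {
  m <- scorer$model
  stack <- ensureStandardized(stack, m@standardization)
  Fz <- cellValues(stack, cells) %*% m@axes
  pchisq(mahalanobis(Fz, m@muF, m@SF), df = m@k, lower.tail = FALSE)
}

#' Wrap a plain function as a scorer
#'
#' Lets any \code{function(stack, cells) -> scores} participate in
#' evaluation and ensemble averaging; useful for reference scorers and
#' for plugging in external models.
#'
#' @param fun function taking an \linkS4class{EnvStack} and a (row, col)
#'   cell matrix, returning one score per cell.
#' @return a scorer.
#' @export
functionScorer <- function(fun) {
  structure(list(fun = fun), class = c("functionScorer", "sdmScorer"))
}

#' @export
scoreCells.functionScorer <- function(scorer, stack, cells) {
  scorer$fun(stack, asCellMatrix(cells))
}

# Quadratic feature expansion: linear + squared terms per layer, plus
# pairwise products of linear terms (interaction level 1) when requested.
featureMatrix <- function(X, interactions = TRUE) {
  X <- as.matrix(X)
  nm <- colnames(X)
  out <- cbind(X, X^2)
  colnames(out) <- c(nm, paste0(nm, "_sq"))
  if (interactions && ncol(X) >= 2L) {
    pairs <- combn(ncol(X), 2L)
    prods <- X[, pairs[1L, ], drop = FALSE] * X[, pairs[2L, ], drop = FALSE]
    colnames(prods) <- paste0(nm[pairs[1L, ]], "_x_", nm[pairs[2L, ]])
    out <- cbind(out, prods)
  }
  out
}

#' @export
scoreCells.learnerScorer <- function(scorer, stack, cells) {
  stack <- ensureStandardized(stack, scorer$standardization)
  X <- cellValues(stack, cells)[, scorer$layers, drop = FALSE]
  Xf <- featureMatrix(X, scorer$interactions)
  p <- switch(scorer$kind,
    GLM_QUAD = {
      if (scorer$ridged)
        drop(predict(scorer$fit, newx = Xf, s = "lambda.min",
                     type = "response"))
      else
        predict(scorer$fit, newdata = as.data.frame(Xf), type = "response")
    },
    RF = predict(scorer$fit, newdata = as.data.frame(Xf),
                 type = "prob")[, "1"],
    MAXENT_LIKE = drop(predict(scorer$fit, newx = Xf, s = "lambda.min",
                               type = "response")),
    stop("unknown learner kind: ", scorer$kind))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
scoreCells.weightedScorer <- function(scorer, stack, cells) {
  scores <- vapply(scorer$scorers, scoreCells, stack = stack, cells = cells,
                   numeric(nrow(asCellMatrix(cells))))
  scores <- matrix(scores, ncol = length(scorer$scorers))
  drop(scores %*% scorer$weights) / sum(scorer$weights)
}
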