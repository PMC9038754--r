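#' @importFrom stats cor cov sd var rnorm runif rbinom setNames aggregate
#'   coef lm pt ks.test p.adjust quantile cutree hclust as.dist
NULL

# Fisher r-to-z with clipping so r = +/-1 stays finite; perfect
# correlations would otherwise map to infinite z-scores.
fisherZ <- function(r, eps = 1e-7) atanh(pmin(pmax(r, -1 + eps), 1 - eps))

fisherInv <- function(z) tanh(z)

#' Fisher-average a set of correlations
#'
#' Correlations are Fisher r-to-z transformed, averaged, and transformed
#' back; missing values are dropped.
#'
#' @param r numeric vector of correlations.
#' @param na.rm drop missing values (default \code{TRUE}); the number
#'   dropped is reported via an attribute \code{"nMissing"}.
#' @return the back-transformed mean correlation.
#' @export
aggregateAccuracy <- function(r, na.rm = TRUE) {
  nmiss <- sum(is.na(r))
  if (na.rm) r <- r[!is.na(r)]
  out <- fisherInv(mean(fisherZ(r)))
  attr(out, "nMissing") <- nmiss
  out
}

#' Pearson accuracy and coefficient of determination
#'
#' @param observed observed (residualized) test values.
#' @param predicted model predictions for the same participants.
#' @param trainMean mean of the residualized target on the training set;
#'   the out-of-sample COD baseline.
#' @return list with \code{r} (Pearson correlation; \code{NA} when fewer
#'   than 3 points or a constant vector) and \code{cod}
#'   (\eqn{1 - \sum(o-p)^2 / \sum(o-\bar y_{train})^2}).
#' @export
accuracyMetrics <- function(observed, predicted, trainMean) {
  ok <- is.finite(observed) & is.finite(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 3)
    return(list(r = NA_real_, cod = NA_real_))
  r <- if (sd(observed) == 0 || sd(predicted) == 0) NA_real_
       else cor(observed, predicted)
  cod <- 1 - sum((observed - predicted)^2) / sum((observed - trainMean)^2)
  list(r = r, cod = cod)
}

# All weight vectors with entries on a grid of the given step summing to 1
# (simplex lattice). Rows are weight vectors.
simplexGrid <- function(nStates, step = 0.25) {
  stopifnot(step > 0, step <= 1)
  k <- round(1 / step)
  if (abs(k * step - 1) > 1e-8) stop("1/step must be an integer")
  grid <- expand.grid(rep(list(0:k), nStates))
  grid <- grid[rowSums(grid) == k, , drop = FALSE]
  w <- as.matrix(grid) / k
  colnames(w) <- NULL
  w[order(apply(w, 1, paste, collapse = ",")), , drop = FALSE]
}

# Shannon entropy of a weight vector (0 log 0 = 0); used to break ties
# toward simpler kernel combinations.
weightEntropy <- function(w) {
  w <- w[w > 0]
  -sum(w * log(w))
}

#' Default ridge-penalty grid
#'
#' Thirteen log-spaced values spanning 1e-4 to 1e4.
#' @return numeric vector of penalties.
#' @export
defaultLambdaGrid <- function() 10^seq(-4, 4, length.out = 13)
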