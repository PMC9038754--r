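#' Within-site permutation test of prediction accuracy
#'
#' Builds the null distribution of the Fisher-averaged cross-validated
#' accuracy by shuffling the behavioral measure across participants
#' within each acquisition site (sites are the exchangeable blocks; a
#' site with a single participant contributes no shuffling) and
#' repeating the full leave-k-site-clusters-out nested cross-validation
#' for every permutation. All permuted targets are evaluated in one
#' batched [nestedCV()] call. One-tailed for above-chance accuracy, with
#' the add-one estimator.
#'
#' @param cset a [ConnectomeSet-class].
#' @param y the behavioral measure (raw).
#' @param nPerm number of permutations (default 99).
#' @param seed RNG seed.
#' @param ... passed to [nestedCV()] (family, state, grids, clusters,
#'   \code{fixedLambda}, ...).
#' @return list with \code{p}, \code{observed} (Fisher-mean r),
#'   \code{null} (permutation accuracies), and the observed
#'   [PredictionResult-class] as \code{result}.
#' @export
permutationNullAccuracy <- function(cset, y, nPerm = 99, seed = 1L, ...) {
  if (nPerm < 1) stop("nPerm must be at least 1")
  n <- ncol(cset)
  stopifnot(length(y) == n)
  site <- as.character(colData(cset)$site)
  singletons <- names(which(table(site) == 1))
  if (length(singletons) > 0)
    message(length(singletons), " site(s) with one participant contribute no shuffling")
  Yperm <- withSeed(seed, {
    vapply(seq_len(nPerm), function(b) {
      out <- y
      for (s in unique(site)) {
        idx <- which(site == s)
        if (length(idx) > 1) out[idx] <- y[sample(idx)]
      }
      out
    }, numeric(n))
  })
  Y <- cbind(observed = y, Yperm)
  colnames(Y) <- c("observed", sprintf("perm%04d", seq_len(nPerm)))
  res <- nestedCV(cset, Y, keepPredictions = FALSE, keepTrainFitted = FALSE, ...)
  acc <- apply(res@r, 2, aggregateAccuracy)
  observed <- acc[1]
  null <- acc[-1]
  p <- (1 + sum(null >= observed)) / (1 + nPerm)
  list(p = p, observed = unname(observed), null = unname(null), result = res)
}

#' Corrected resampled t-test for fold-paired accuracy differences
#'
#' Cross-validation folds share training data, so their accuracy
#' differences are not independent and the naive one-sample t-test is
#' anti-conservative. The corrected variant inflates the variance by the
#' train/test size ratio:
#' \deqn{t = \bar d \Big/ \sqrt{\left(\tfrac{1}{K} +
#'   \tfrac{n_{test}}{n_{train}}\right)\,\widehat{var}(d)}}
#' with K - 1 degrees of freedom, two-tailed. As
#' \eqn{n_{test}/n_{train} \to 0} it reduces to the classical t-test.
#'
#' @param d per-fold paired metric differences (length K >= 2).
#' @param nTest,nTrain representative test and training set sizes per
#'   fold; vectors are averaged into a single ratio.
#' @return list with \code{t}, \code{p}, \code{df}.
#' @export
correctedResampledTtest <- function(d, nTest, nTrain) {
  d <- d[is.finite(d)]
  K <- length(d)
  if (K < 2) stop("need at least 2 fold differences")
  ratio <- mean(nTest) / mean(nTrain)
  v <- var(d)
  if (v == 0) {
    warning("zero variance of fold differences")
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p = if (mean(d) == 0) 1 else 0, df = K - 1))
  }
  t <- mean(d) / sqrt((1 / K + ratio) * v)
  list(t = t, p = 2 * pt(-abs(t), df = K - 1), df = K - 1)
}

#' Kolmogorov-Smirnov check of the Gaussianity assumption
#'
#' The corrected resampled t-test assumes Gaussian fold differences;
#' this standardizes the differences and runs a one-sample KS test
#' against the standard normal.
#'
#' @param d per-fold differences.
#' @return list with \code{statistic}, \code{p}; degenerate (constant)
#'   input yields \code{NA} with a warning.
#' @export
gaussianityCheck <- function(d) {
  d <- d[is.finite(d)]
  if (sd(d) == 0) {
    warning("constant differences: Gaussianity check degenerate")
    return(list(statistic = NA_real_, p = NA_real_))
  }
  z <- (d - mean(d)) / sd(d)
  kt <- ks.test(z, "pnorm")
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up FDR correction at level q; returns the rejection mask and the
#' largest rejected p-value (the realized threshold).
#'
#' @param p vector of p-values.
#' @param q FDR level (default 0.05).
#' @return list with \code{mask} (logical), \code{threshold} (0 when
#'   nothing is rejected), and \code{padj}.
#' @export
fdrBH <- function(p, q = 0.05) {
  padj <- p.adjust(p, method = "BH")
  mask <- !is.na(padj) & padj <= q
  threshold <- if (any(mask)) max(p[mask]) else 0
  list(mask = mask, threshold = threshold, padj = padj)
}
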