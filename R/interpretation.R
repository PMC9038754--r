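# Per-fold Haufe features: covariance between each edge and the model's
# fitted target over the training participants. edges: E x n matrices
# (one per state); fitted: nTrain x m fitted values.
haufeFold <- function(edgesList, trainIdx, fitted) {
  nTr <- length(trainIdx)
  Fc <- sweep(fitted, 2, colMeans(fitted))
  lapply(edgesList, function(X) {
    Xtr <- X[, trainIdx, drop = FALSE]
    Xc <- Xtr - rowMeans(Xtr)
    (Xc %*% Fc) / (nTr - 1)
  })
}

featureEdges <- function(cset, states) {
  setNames(lapply(states, function(s) {
    if (s == "mean_fc") meanFCEdges(cset) else assay(cset, s)
  }), states)
}

#' Haufe inversion of fitted prediction models
#'
#' Converts a predictive model into interpretable features: for each
#' edge and brain state, the training-set covariance between the edge's
#' connectivity and the model's predicted target, computed per
#' cross-validation fold and averaged across folds. Unlike raw
#' regression weights, these features are robust to suppressor
#' variables: an input that helps prediction only by cancelling noise
#' receives a feature of zero. A positive feature means higher
#' connectivity predicts higher behavioral scores.
#'
#' @param cset the [ConnectomeSet-class] the model was fit on.
#' @param result a [PredictionResult-class] from [nestedCV()] with
#'   retained training fitted values.
#' @param states states whose edges are inverted (default: for
#'   multikernel models, every state; otherwise the model's input).
#' @return a [PredictiveFeatures-class].
#' @export
haufeInvert <- function(cset, result,
                        states = if (result@family == "multikernel")
                          stateNames(cset) else result@states) {
  if (length(result@trainFitted) == 0)
    stop("PredictionResult has no retained training fitted values; ",
         "rerun nestedCV with keepTrainFitted = TRUE")
  edgesList <- featureEdges(cset, states)
  E <- nrow(cset); m <- length(result@measures)
  acc <- lapply(states, function(s) matrix(0, E, m))
  names(acc) <- states
  K <- length(result@folds)
  for (f in seq_len(K)) {
    tf <- result@trainFitted[[f]]
    if (length(tf$trainIdx) < 3) stop("fold with fewer than 3 training participants")
    ff <- haufeFold(edgesList, tf$trainIdx, tf$fitted)
    for (s in states) acc[[s]] <- acc[[s]] + ff[[s]]
  }
  feats <- lapply(acc, function(M) {
    M <- M / K
    colnames(M) <- result@measures
    M
  })
  new("PredictiveFeatures", features = feats, states = states,
      measures = result@measures, regionNames = regionNames(cset),
      provenance = list(family = result@family, nFolds = K))
}

#' Similarity between predictive-feature matrices
#'
#' Pearson correlation of vectorized predictive features between
#' behavioral measures. In \code{"concat_states"} mode the edge vectors
#' are concatenated across brain states before correlating (the
#' behavior-by-behavior similarity used for domain clustering); in
#' \code{"per_state"} mode one similarity matrix is returned per state.
#'
#' @param a a [PredictiveFeatures-class].
#' @param b optional second object (default \code{a}); states and edge
#'   counts must match.
#' @param mode \code{"concat_states"} or \code{"per_state"}.
#' @return measures(a)-by-measures(b) correlation matrix, or a named
#'   list of such matrices in per-state mode.
#' @export
featureSimilarity <- function(a, b = a, mode = c("concat_states", "per_state")) {
  mode <- match.arg(mode)
  if (!identical(a@states, b@states) ||
      nrow(a@features[[1]]) != nrow(b@features[[1]]))
    stop("feature objects have mismatched states or edge counts")
  if (mode == "concat_states") {
    A <- do.call(rbind, a@features[a@states])
    B <- do.call(rbind, b@features[b@states])
    cor(A, B)
  } else {
    setNames(lapply(a@states, function(s) cor(a@features[[s]], b@features[[s]])),
             a@states)
  }
}

#' Sign consistency between two block matrices
#'
#' Over the unique within- and between-network blocks, the fraction
#' whose feature values have the same sign in both matrices. Exact zeros
#' count as consistent only with zero. Missing blocks are excluded
#' pairwise (count reported as an attribute).
#'
#' @param a,b symmetric G-by-G block matrices ([blockAverage()]).
#' @return proportion in [0, 1] with attribute \code{"nExcluded"}.
#' @export
signConsistency <- function(a, b) {
  va <- uniqueBlocks(a); vb <- uniqueBlocks(b)
  if (length(va) != length(vb)) stop("block matrices differ in size")
  ok <- !is.na(va) & !is.na(vb)
  out <- mean(sign(va[ok]) == sign(vb[ok]))
  attr(out, "nExcluded") <- sum(!ok)
  out
}

#' Analytic chance level of sign agreement
#'
#' With a pooled fraction p of positive block values, the probability
#' that two independent draws share a sign is \eqn{p^2 + (1-p)^2} (e.g.
#' p = 0.493 gives 50.01\%).
#'
#' @param blockValues pooled block values (positive fraction computed as
#'   the fraction strictly above zero), or
#' @param positiveFraction the positive fraction p directly.
#' @return chance proportion in [0.5, 1].
#' @export
consistencyChanceLevel <- function(blockValues = NULL, positiveFraction = NULL) {
  if (is.null(positiveFraction)) {
    blockValues <- blockValues[!is.na(blockValues)]
    if (length(blockValues) == 0) stop("empty block value pool")
    positiveFraction <- mean(blockValues > 0)
  }
  positiveFraction^2 + (1 - positiveFraction)^2
}

#' Average-linkage (UPGMA) clustering of behaviors by feature similarity
#'
#' Hierarchical agglomerative clustering with average linkage on the
#' correlation distance 1 - r between predictive-feature profiles.
#'
#' @param similarity symmetric behavior-by-behavior correlation matrix.
#' @param k number of flat clusters to cut (default 3, one per expected
#'   behavioral domain).
#' @return list with \code{tree} (an \code{hclust}) and \code{clusters}
#'   (named integer labels).
#' @export
clusterBehaviors <- function(similarity, k = 3) {
  similarity <- as.matrix(similarity)
  if (max(abs(similarity - t(similarity))) > 1e-8)
    stop("similarity matrix must be symmetric")
  d <- as.dist(1 - similarity)
  tree <- hclust(d, method = "average")
  list(tree = tree, clusters = cutree(tree, k = k))
}

#' Permutation test of network-block predictive features
#'
#' Tests each unique within- and between-network block of the
#' predictive-feature matrix against a null built by shuffling the
#' behavioral measure across participants within each site, re-running
#' every cross-validation fold (confound regression, ridge refit with
#' the fold's previously selected hyperparameters, Haufe inversion) and
#' block-averaging. Two-tailed p-values use the add-one permutation
#' estimator \eqn{p = (1 + \#\{|null| \ge |obs|\})/(1 + n_{perm})}.
#'
#' @param cset the [ConnectomeSet-class].
#' @param y the behavioral measure (raw, pre-residualization).
#' @param result the fitted [PredictionResult-class] for this measure
#'   (single-measure result; its per-fold hyperparameters are reused —
#'   set \code{reselect = TRUE} to re-run the inner search per
#'   permutation).
#' @param state state whose edges are inverted (or \code{"mean_fc"}).
#' @param labels region-to-network labeling (default from \code{cset}).
#' @param confounds as in [nestedCV()].
#' @param nPerm number of permutations (default 2000).
#' @param seed RNG seed for the permutations.
#' @param reselect re-run inner-loop hyperparameter selection for every
#'   permutation (slower; default FALSE).
#' @param lambdaGrid,weightStep grids used when \code{reselect = TRUE}.
#' @return data.frame with columns \code{groupA}, \code{groupB},
#'   \code{value}, \code{p} for every unique non-missing block, plus the
#'   observed block matrix as attribute \code{"blocks"}.
#' @export
blockSignificance <- function(cset, y, result, state,
                              labels = networkLabels(cset),
                              confounds = c("meanFD", "meanDVARS"),
                              nPerm = 2000, seed = 1L, reselect = FALSE,
                              lambdaGrid = defaultLambdaGrid(),
                              weightStep = 0.25) {
  if (nPerm < 1) stop("nPerm must be at least 1")
  if (nPerm < 100) warning("fewer than 100 permutations: unstable p-values")
  if (length(result@measures) != 1)
    stop("blockSignificance expects a single-measure PredictionResult")
  n <- ncol(cset)
  stopifnot(length(y) == n)
  site <- as.character(colData(cset)$site)
  if (is.character(confounds))
    confounds <- as.matrix(as.data.frame(colData(cset)[, confounds, drop = FALSE]))

  # edge matrices: model-input states for the kernels, requested state
  # for the features
  modelStates <- result@states
  kernEdges <- featureEdges(cset, modelStates)
  featX <- featureEdges(cset, state)[[1]]
  kernels <- lapply(kernEdges, function(X) correlationKernel(t(X)))
  weightGrid <- if (result@family == "multikernel")
    simplexGrid(length(modelStates), weightStep) else matrix(1, 1, 1)

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

  E <- nrow(cset)
  K <- length(result@folds)
  obsAcc <- numeric(E)
  nullAcc <- matrix(0, E, nPerm)
  Yall <- cbind(y, Yperm)
  for (f in seq_len(K)) {
    testClusters <- result@folds[[f]]
    trainIdx <- which(!(result@clusters %in% testClusters))
    trainClusters <- result@clusters[trainIdx]
    if (is.null(confounds)) {
      Ytr <- Yall[trainIdx, , drop = FALSE]
    } else {
      res <- regressConfounds(Yall, confounds, trainIdx,
                              setdiff(seq_len(n), trainIdx))
      Ytr <- as.matrix(res$train)
    }
    mu <- colMeans(Ytr)
    Yc <- sweep(Ytr, 2, mu)

    if (reselect) {
      kernTrain <- lapply(kernels, function(Kf) Kf[trainIdx, trainIdx, drop = FALSE])
      sel <- innerSelect(kernTrain, Ytr, trainClusters, lambdaGrid, weightGrid)
      lamPerCol <- lambdaGrid[sel$lIdx]
      wPerCol <- weightGrid[sel$wIdx, , drop = FALSE]
    } else {
      lamPerCol <- rep(result@lambda[f, 1], ncol(Yall))
      wPerCol <- matrix(result@weights[f, 1, ], ncol(Yall),
                        length(modelStates), byrow = TRUE)
    }

    fitted <- matrix(NA_real_, length(trainIdx), ncol(Yall))
    wKey <- apply(wPerCol, 1, paste, collapse = ",")
    for (key in unique(wKey)) {
      cols <- which(wKey == key)
      Kc <- combineKernels(kernels, wPerCol[cols[1], ])[trainIdx, trainIdx,
                                                        drop = FALSE]
      eig <- krrEigen(Kc)
      for (l in unique(lamPerCol[cols])) {
        cl <- cols[lamPerCol[cols] == l]
        fitted[, cl] <- krrPredictPath(eig, Kc, Yc[, cl, drop = FALSE], l)[[1]]
      }
    }
    ff <- haufeFold(list(featX), trainIdx, fitted)[[1]]
    obsAcc <- obsAcc + ff[, 1]
    nullAcc <- nullAcc + ff[, -1, drop = FALSE]
  }
  obsAcc <- obsAcc / K
  nullAcc <- nullAcc / K

  obsBlocks <- blockAverage(devectorizeFC(obsAcc, diagValue = 0) |>
                              `dimnames<-`(list(regionNames(cset),
                                                regionNames(cset))), labels)
  G <- nrow(obsBlocks)
  groups <- rownames(obsBlocks)
  ut <- which(upper.tri(obsBlocks, diag = TRUE), arr.ind = TRUE)
  # block-average the null features via group aggregation on edge ids
  gi <- as.integer(factor(labels[regionNames(cset)], levels = groups))
  pairs <- edgePairs(length(gi))
  ga <- pmin(gi[pairs$i], gi[pairs$j]); gb <- pmax(gi[pairs$i], gi[pairs$j])
  key <- (ga - 1L) * G + gb
  nullBlocks <- rowsum(nullAcc, key) / as.vector(table(key))
  keyOf <- (pmin(ut[, 1], ut[, 2]) - 1L) * G + pmax(ut[, 1], ut[, 2])
  rowsOf <- match(keyOf, as.integer(rownames(nullBlocks)))

  obsVec <- obsBlocks[ut]
  p <- vapply(seq_along(obsVec), function(i) {
    if (is.na(obsVec[i]) || is.na(rowsOf[i])) return(NA_real_)
    (1 + sum(abs(nullBlocks[rowsOf[i], ]) >= abs(obsVec[i]))) / (1 + nPerm)
  }, numeric(1))
  out <- data.frame(groupA = groups[pmin(ut[, 1], ut[, 2])],
                    groupB = groups[pmax(ut[, 1], ut[, 2])],
                    value = obsVec, p = p)
  out <- out[!is.na(out$value), ]
  attr(out, "blocks") <- obsBlocks
  out
}

#' Conjunction of network blocks across brain states
#'
#' Keeps only blocks that are statistically significant in every brain
#' state with the same sign everywhere; surviving blocks carry their
#' cross-state mean, all others are masked (\code{NA}).
#'
#' @param blockList named list of G-by-G block matrices, one per state.
#' @param sigList matching list of logical significance masks.
#' @return G-by-G conjunction matrix (masked blocks \code{NA}).
#' @export
conjunctionAcrossStates <- function(blockList, sigList) {
  if (!identical(names(blockList), names(sigList)))
    stop("state sets of blocks and significance masks differ")
  dims <- vapply(blockList, nrow, integer(1))
  if (length(unique(dims)) != 1) stop("block matrices differ in size")
  arr <- simplify2array(blockList)
  sig <- simplify2array(sigList)
  allSig <- apply(sig, c(1, 2), all)
  sgn <- sign(arr)
  sameSign <- apply(sgn, c(1, 2), function(v) all(v == v[1]) && v[1] != 0)
  out <- apply(arr, c(1, 2), mean)
  out[!(allSig & sameSign)] <- NA_real_
  dimnames(out) <- dimnames(blockList[[1]])
  out
}

#' Region-level predictability maps
#'
#' For each region, the sum of positive feature values across its row of
#' a (conjunction-masked) symmetric feature matrix, the sum of absolute
#' negative values, and their percentile ranks across regions.
#'
#' @param mat symmetric region-by-region matrix; masked (\code{NA})
#'   entries contribute zero.
#' @return data.frame with region, positive, negative, positivePct,
#'   negativePct.
#' @export
regionPredictability <- function(mat) {
  m <- as.matrix(mat)
  m[is.na(m)] <- 0
  pos <- rowSums(pmax(m, 0))
  neg <- rowSums(pmax(-m, 0))
  R <- nrow(m)
  pct <- function(x) if (R == 1) rep(100, 1) else 100 * (rank(x) - 1) / (R - 1)
  data.frame(region = if (is.null(rownames(m))) as.character(seq_len(R))
                      else rownames(m),
             positive = pos, negative = neg,
             positivePct = pct(pos), negativePct = pct(neg),
             row.names = NULL)
}

#' Domain-averaged predictive features
#'
#' Elementwise mean of predictive-feature matrices over the (optionally
#' accuracy-filtered) behaviors of each domain, per brain state; measures
#' within a domain are weighted equally.
#'
#' @param features a [PredictiveFeatures-class].
#' @param domains named character vector mapping measure to domain.
#' @param include measures to keep (default all) — typically the ones
#'   significantly predicted.
#' @param standardize divide each domain matrix by its own standard
#'   deviation (display scaling; default FALSE).
#' @return a [PredictiveFeatures-class] whose "measures" are domains.
#' @export
domainAverageFeatures <- function(features, domains, include = features@measures,
                                  standardize = FALSE) {
  keep <- intersect(features@measures, include)
  domains <- domains[keep]
  doms <- unique(domains)
  feats <- lapply(features@features, function(M) {
    out <- vapply(doms, function(d) {
      cols <- keep[domains == d]
      if (length(cols) == 0) stop("empty domain after inclusion filter: ", d)
      v <- rowMeans(M[, cols, drop = FALSE])
      if (standardize) v <- v / sd(v)
      v
    }, numeric(nrow(M)))
    colnames(out) <- doms
    out
  })
  new("PredictiveFeatures", features = feats, states = features@states,
      measures = doms, regionNames = features@regionNames,
      provenance = c(features@provenance, list(domainAveraged = TRUE)))
}
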