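#' Group acquisition sites into site clusters
#'
#' Combines sites into a fixed number of clusters used as the
#' cross-validation unit, so that participants from the same site are
#' never split between training and test. Sites are sorted by descending
#' size (ties broken by site name) and each is assigned to the currently
#' smallest cluster (ties to the lowest cluster index), a deterministic
#' greedy balancing.
#'
#' @param siteLabels per-participant site labels.
#' @param nClusters number of clusters (default 10).
#' @param minSize minimum participants per cluster (default 150). When
#'   the cohort is too small to support \code{nClusters * minSize}
#'   participants the constraint is relaxed with a warning (synthetic /
#'   desk scale).
#' @return integer cluster index (1..nClusters) per participant, with a
#'   \code{"siteAssignment"} attribute mapping site to cluster.
#' @export
buildSiteClusters <- function(siteLabels, nClusters = 10, minSize = 150) {
  siteLabels <- as.character(siteLabels)
  sizes <- table(siteLabels)
  if (length(sizes) < nClusters)
    stop(sprintf("only %d sites but %d clusters requested", length(sizes), nClusters))
  n <- length(siteLabels)
  relaxed <- FALSE
  if (n < nClusters * minSize) {
    warning(sprintf(
      "cohort of %d cannot support %d clusters of >= %d; relaxing minSize",
      n, nClusters, minSize))
    relaxed <- TRUE
  }
  ord <- order(-as.integer(sizes), names(sizes))
  totals <- numeric(nClusters)
  assign <- setNames(integer(length(sizes)), names(sizes)[ord])
  for (s in names(assign)) {
    k <- which.min(totals)
    assign[s] <- k
    totals[k] <- totals[k] + sizes[[s]]
  }
  if (!relaxed && any(totals < minSize))
    stop("greedy clustering produced a cluster below minSize")
  out <- assign[siteLabels]
  names(out) <- NULL
  attr(out, "siteAssignment") <- assign
  out
}

#' Enumerate leave-k-clusters-out folds
#'
#' All \eqn{\binom{n}{k}} choices of test clusters, in deterministic
#' lexicographic order. With 10 clusters and k = 3 this yields the 120
#' replications of leave-3-site-clusters-out cross-validation, each
#' cluster appearing in exactly 36 test sets.
#'
#' @param nClusters total number of site clusters.
#' @param kTest number of clusters held out per fold.
#' @return list of integer vectors of test cluster ids.
#' @export
enumerateFolds <- function(nClusters, kTest = 3) {
  if (kTest >= nClusters) stop("kTest must be smaller than nClusters")
  cmb <- utils::combn(nClusters, kTest)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

#' Train-fold nuisance regression of behavior
#'
#' Ordinary least squares of the target(s) on the confounds (plus an
#' intercept), with coefficients estimated on the training participants
#' only and applied to both training and test participants — the motion
#' (mean FD, mean DVARS) deconfounding step performed before each
#' cross-validation fold.
#'
#' @param y numeric vector or participants-by-measures matrix.
#' @param confounds participants-by-confounds numeric matrix.
#' @param trainIdx,testIdx row indices of training and test participants.
#' @return list with \code{train} and \code{test} residual matrices (or
#'   vectors if \code{y} was one) and the \code{coef} matrix.
#' @export
regressConfounds <- function(y, confounds, trainIdx, testIdx) {
  vec <- is.null(dim(y))
  Y <- as.matrix(y)
  confounds <- as.matrix(confounds)
  X <- cbind(`(Intercept)` = 1, confounds)
  Xtr <- X[trainIdx, , drop = FALSE]
  q <- qr(Xtr)
  if (q$rank < ncol(Xtr)) {
    bad <- colnames(Xtr)[q$pivot[(q$rank + 1):ncol(Xtr)]]
    stop("confound matrix rank-deficient on training set; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(q, Y[trainIdx, , drop = FALSE])
  resTrain <- Y[trainIdx, , drop = FALSE] - Xtr %*% beta
  resTest <- Y[testIdx, , drop = FALSE] - X[testIdx, , drop = FALSE] %*% beta
  if (vec) {
    resTrain <- drop(resTrain); resTest <- drop(resTest)
  }
  list(train = resTrain, test = resTest, coef = beta)
}

#' Correlation kernel between sets of edge vectors
#'
#' Kernel entry (i, t) is the Pearson correlation between participant
#' i's and participant t's vectorized connectomes — the similarity
#' function of the kernel regression model.
#'
#' @param A numeric matrix, participants in rows, edges in columns.
#' @param B optional second matrix (defaults to \code{A}).
#' @return \code{nrow(A)} by \code{nrow(B)} kernel matrix.
#' @export
correlationKernel <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (any(apply(A, 1, sd) == 0) || any(apply(B, 1, sd) == 0))
    stop("zero-variance edge vector: correlation kernel undefined")
  K <- cor(t(A), t(B))
  if (identical(dim(A), dim(B)) && isTRUE(all.equal(A, B, tolerance = 0))) {
    K <- (K + t(K)) / 2
    diag(K) <- 1
  }
  K
}

# ---- internal kernel ridge machinery ---------------------------------------

# Eigen-based ridge path: predictions at every lambda for every target
# column, sharing one eigendecomposition. Eigenvalues are floored at zero
# (correlation kernels are Gram matrices; only round-off dips below) and a
# small jitter keeps the solve well-posed. Errors if the kernel is
# indefinite beyond tolerance.
krrEigen <- function(Ktt, tolNeg = 1e-6) {
  e <- eigen(Ktt, symmetric = TRUE)
  dmax <- max(abs(e$values), 1e-12)
  if (min(e$values) < -tolNeg * dmax)
    stop("kernel is not positive semidefinite beyond jitter tolerance")
  e$values <- pmax(e$values, 0)
  e$jitter <- 1e-8 * sum(e$values) / length(e$values)
  e
}

# Predictions (centered scale) for each lambda: list over lambdas of
# x-by-m matrices. B = Kxt %*% vectors is precomputed by the caller when
# reused.
krrPredictPath <- function(eig, Kxt, Yc, lambdas) {
  Tm <- crossprod(eig$vectors, Yc)
  B <- Kxt %*% eig$vectors
  lapply(lambdas, function(l) B %*% (Tm / (eig$values + l + eig$jitter)))
}

# Column-wise Pearson correlation between two equally shaped matrices.
colCor <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  sa <- sqrt(colSums(A^2)); sb <- sqrt(colSums(B^2))
  out <- colSums(A * B) / (sa * sb)
  out[sa == 0 | sb == 0] <- NA_real_
  out
}

combineKernels <- function(kernels, w) {
  K <- kernels[[1]] * w[1]
  if (length(kernels) > 1)
    for (s in 2:length(kernels)) if (w[s] != 0) K <- K + kernels[[s]] * w[s]
  K
}

# Inner-loop hyperparameter selection: leave-one-cluster-out over the
# training clusters, Fisher-averaged validation correlation per
# (weights, lambda) candidate and target column. Ties break toward larger
# lambda (more regularization), then smaller weight entropy.
# `kernels` must cover the training participants only, rows aligned with Y.
innerSelect <- function(kernels, Y, clusters, lambdaGrid, weightGrid) {
  m <- ncol(Y)
  nW <- nrow(weightGrid); nL <- length(lambdaGrid)
  uc <- sort(unique(clusters))
  zsum <- array(0, c(nW, nL, m))
  for (hold in uc) {
    itr <- which(clusters != hold)
    ival <- which(clusters == hold)
    Yitr <- Y[itr, , drop = FALSE]
    mu <- colMeans(Yitr)
    Yc <- sweep(Yitr, 2, mu)
    obs <- Y[ival, , drop = FALSE]
    for (wi in seq_len(nW)) {
      K <- combineKernels(kernels, weightGrid[wi, ])
      eig <- krrEigen(K[itr, itr, drop = FALSE])
      preds <- krrPredictPath(eig, K[ival, itr, drop = FALSE], Yc, lambdaGrid)
      for (li in seq_len(nL)) {
        r <- colCor(preds[[li]], obs)
        z <- fisherZ(r)
        z[is.na(z)] <- 0
        zsum[wi, li, ] <- zsum[wi, li, ] + z
      }
    }
  }
  ent <- apply(weightGrid, 1, weightEntropy)
  sel <- lapply(seq_len(m), function(j) {
    sc <- zsum[, , j, drop = FALSE][, , 1]
    sc <- matrix(sc, nW, nL)
    best <- max(sc)
    cand <- which(sc >= best - 1e-12, arr.ind = TRUE)
    # ties: larger lambda first, then smaller weight entropy
    ord <- order(-lambdaGrid[cand[, 2]], ent[cand[, 1]])
    pick <- cand[ord[1], ]
    list(wIdx = pick[1], lIdx = pick[2], score = best / length(uc))
  })
  list(wIdx = vapply(sel, `[[`, integer(1), "wIdx"),
       lIdx = vapply(sel, `[[`, integer(1), "lIdx"),
       score = vapply(sel, `[[`, numeric(1), "score"))
}

#' Fit kernel ridge regression at a fixed penalty
#'
#' Solves the dual system \eqn{\alpha = (K + \lambda I)^{-1} (y - \bar
#' y)}; predictions are \eqn{K_{x,train}\,\alpha + \bar y}. The target is
#' mean-centered before the solve and the training mean serves as the
#' intercept.
#'
#' @param K training kernel matrix.
#' @param y training targets.
#' @param lambda ridge penalty (> 0, or 0 for interpolation when K is
#'   invertible).
#' @return list with \code{alpha}, \code{trainMean}, \code{lambda}.
#' @export
fitKRR <- function(K, y, lambda) {
  eig <- krrEigen(K)
  mu <- mean(y)
  alpha <- eig$vectors %*% (crossprod(eig$vectors, y - mu) /
                              (eig$values + lambda + eig$jitter))
  list(alpha = drop(alpha), trainMean = mu, lambda = lambda)
}

#' Predict from a fitted kernel ridge model
#' @param model result of [fitKRR()].
#' @param Kxt kernel between new participants (rows) and the training
#'   participants (columns).
#' @return predicted values.
#' @export
predictKRR <- function(model, Kxt) {
  drop(Kxt %*% model$alpha) + model$trainMean
}

#' Fit a multikernel ridge model with inner-loop selection
#'
#' The combined kernel is a convex combination \eqn{K = \sum_s w_s K_s}
#' of per-state correlation kernels, with the weight vector on a simplex
#' lattice and the penalty on a log-spaced grid; both are selected by
#' leave-one-cluster-out cross-validation on the training clusters
#' (Fisher-averaged validation correlation), then the model is refit on
#' the full training set. At a simplex vertex the model reduces exactly
#' to single-kernel regression on that state.
#'
#' @param kernels named list of training kernels (identical participants).
#' @param y training targets.
#' @param clusters training-participant cluster labels for the inner loop.
#' @param lambdaGrid penalty grid (default [defaultLambdaGrid()]).
#' @param weightGrid matrix of candidate weight rows (default simplex
#'   lattice with step 0.25).
#' @return list with \code{alpha}, \code{trainMean}, \code{lambda},
#'   \code{weights}, \code{innerScore}.
#' @export
fitMultikernel <- function(kernels, y, clusters,
                           lambdaGrid = defaultLambdaGrid(),
                           weightGrid = simplexGrid(length(kernels), 0.25)) {
  if (length(lambdaGrid) == 0 || nrow(weightGrid) == 0)
    stop("empty hyperparameter grid")
  Y <- matrix(y, ncol = 1)
  sel <- innerSelect(kernels, Y, clusters, lambdaGrid, weightGrid)
  w <- weightGrid[sel$wIdx[1], ]
  K <- combineKernels(kernels, w)
  fit <- fitKRR(K, y, lambdaGrid[sel$lIdx[1]])
  fit$weights <- w
  fit$innerScore <- sel$score[1]
  fit
}

#' Fisher-mean connectome across states
#'
#' Averages each participant's edge values across all brain states in
#' Fisher-z space (the "Mean FC" control model input).
#'
#' @param cset a [ConnectomeSet-class].
#' @return edges-by-participants matrix on the correlation scale.
#' @export
meanFCEdges <- function(cset) {
  states <- stateNames(cset)
  for (s in states) {
    if (any(is.na(assay(cset, s)))) stop("missing state data for some participant")
  }
  z <- Reduce(`+`, lapply(states, function(s) fisherZ(assay(cset, s))))
  fisherInv(z / length(states))
}

#' Fit linear ridge regression (primal form)
#'
#' Ridge on standardized edge features with an intercept; the control
#' regression family used to test robustness of predictive features.
#'
#' @param X participants-by-features matrix.
#' @param y training targets.
#' @param lambda ridge penalty.
#' @return list with \code{weights} (on the standardized scale),
#'   \code{center}, \code{scale}, \code{intercept}.
#' @export
fitLinearRidge <- function(X, y, lambda) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  mu <- mean(y)
  E <- ncol(Xs); n <- nrow(Xs)
  yc <- y - mu
  if (E <= n) {
    w <- solve(crossprod(Xs) + diag(lambda, E), crossprod(Xs, yc))
  } else {
    alpha <- solve(tcrossprod(Xs) + diag(lambda, n), yc)
    w <- crossprod(Xs, alpha)
  }
  list(weights = drop(w), center = ctr, scale = scl, intercept = mu)
}

#' Predict from a fitted linear ridge model
#' @param model result of [fitLinearRidge()].
#' @param X new participants-by-features matrix.
#' @return predicted values.
#' @export
predictLinearRidge <- function(model, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, model$center), 2, model$scale, `/`)
  drop(Xs %*% model$weights) + model$intercept
}

# Build the per-family kernel list for a fold. Correlation kernels are
# precomputed once; the linear-ridge kernel is rebuilt per fold because
# edge standardization uses training statistics only.
foldKernels <- function(family, precomp, edges, trainIdx) {
  if (family != "linear_ridge") return(precomp)
  X <- edges[[1]]
  mu <- rowMeans(X[, trainIdx, drop = FALSE])
  s <- apply(X[, trainIdx, drop = FALSE], 1, sd)
  s[s == 0] <- 1
  Xs <- (X - mu) / s
  list(linear = crossprod(Xs) / nrow(Xs))
}

#' Site-clustered nested cross-validation prediction
#'
#' The full evaluation loop: for every leave-k-site-clusters-out fold,
#' regress the confounds from each behavioral measure (training
#' coefficients applied to the test clusters), select the ridge penalty
#' (and kernel weights for the multikernel family) by leave-one-cluster-
#' out cross-validation within the training clusters, refit on the full
#' training set, and predict the held-out participants. Multiple
#' behavioral measures (or permuted targets) are evaluated
#' simultaneously as columns of \code{Y}, sharing the per-fold kernel
#' eigendecompositions.
#'
#' @param cset a [ConnectomeSet-class].
#' @param Y numeric vector or participants-by-measures matrix of targets
#'   (participant order must match \code{cset} columns).
#' @param family one of \code{"single_kernel"}, \code{"multikernel"},
#'   \code{"mean_fc"}, \code{"linear_ridge"}.
#' @param state state name for the single-kernel family (default first
#'   state).
#' @param confounds matrix of per-participant confounds, or character
#'   names of \code{colData} columns (default mean FD and mean DVARS);
#'   \code{NULL} skips deconfounding.
#' @param clusters integer site-cluster assignment; computed from
#'   \code{colData(cset)$site} via [buildSiteClusters()] when missing.
#' @param nClusters,kTest fold geometry (default leave-3-of-10-out,
#'   yielding 120 folds).
#' @param folds explicit list of test-cluster sets (overrides
#'   \code{kTest}).
#' @param lambdaGrid ridge penalty grid.
#' @param weightStep simplex lattice step for multikernel weights
#'   (default 0.25).
#' @param fixedLambda optional penalty (scalar or folds-by-measures
#'   matrix) bypassing the inner loop — used for permutation nulls that
#'   reuse previously selected hyperparameters.
#' @param fixedWeights optional weight vector or folds-by-measures-by-
#'   states array, as \code{fixedLambda}.
#' @param keepPredictions retain per-fold test predictions (default
#'   TRUE; disable for large permutation batches).
#' @param keepTrainFitted retain per-fold training fitted values, needed
#'   by [haufeInvert()] (default = \code{keepPredictions}).
#' @return a [PredictionResult-class].
#' @export
nestedCV <- function(cset, Y,
                     family = c("single_kernel", "multikernel", "mean_fc",
                                "linear_ridge"),
                     state = NULL,
                     confounds = c("meanFD", "meanDVARS"),
                     clusters = NULL, nClusters = 10, kTest = 3,
                     folds = NULL,
                     lambdaGrid = defaultLambdaGrid(),
                     weightStep = 0.25,
                     fixedLambda = NULL, fixedWeights = NULL,
                     keepPredictions = TRUE,
                     keepTrainFitted = keepPredictions) {
  family <- match.arg(family)
  Y <- as.matrix(Y)
  n <- ncol(cset)
  stopifnot(nrow(Y) == n)
  if (is.null(colnames(Y)))
    colnames(Y) <- sprintf("y%03d", seq_len(ncol(Y)))
  m <- ncol(Y)

  if (is.character(confounds))
    confounds <- as.matrix(as.data.frame(colData(cset)[, confounds, drop = FALSE]))
  if (is.null(clusters)) {
    if (!"site" %in% colnames(colData(cset)))
      stop("no clusters given and no site column in colData")
    clusters <- buildSiteClusters(colData(cset)$site, nClusters = nClusters)
  }
  nClusters <- max(clusters)
  if (is.null(folds)) folds <- enumerateFolds(nClusters, kTest)
  K <- length(folds)

  states <- switch(family,
    single_kernel = {
      if (is.null(state)) state <- stateNames(cset)[1]
      state
    },
    multikernel = stateNames(cset),
    mean_fc = "mean_fc",
    linear_ridge = {
      if (is.null(state)) state <- stateNames(cset)[1]
      state
    })
  S <- length(states)

  edges <- switch(family,
    single_kernel = setNames(list(assay(cset, state)), state),
    multikernel = setNames(lapply(states, function(s) assay(cset, s)), states),
    mean_fc = list(mean_fc = meanFCEdges(cset)),
    linear_ridge = setNames(list(assay(cset, state)), state))

  precompK <- if (family == "linear_ridge") NULL
              else lapply(edges, function(X) correlationKernel(t(X)))

  weightGrid <- if (family == "multikernel") simplexGrid(S, weightStep)
                else matrix(1, 1, 1)

  fixed <- !is.null(fixedLambda)
  if (fixed) {
    if (length(fixedLambda) == 1) fixedLambda <- matrix(fixedLambda, K, m)
    if (is.null(fixedWeights)) fixedWeights <- rep(1, max(S, 1))
    if (is.null(dim(fixedWeights)) || length(dim(fixedWeights)) != 3) {
      fixedWeights <- aperm(array(fixedWeights, c(S, K, m)), c(2, 3, 1))
    }
  }

  rMat <- matrix(NA_real_, K, m, dimnames = list(NULL, colnames(Y)))
  codMat <- rMat; lamMat <- rMat; tmMat <- rMat
  wArr <- array(NA_real_, c(K, m, S))
  predsList <- vector("list", if (keepPredictions) K else 0)
  trainList <- vector("list", if (keepTrainFitted) K else 0)
  warnedConst <- FALSE

  for (f in seq_len(K)) {
    testClusters <- folds[[f]]
    testIdx <- which(clusters %in% testClusters)
    trainIdx <- which(!(clusters %in% testClusters))
    trainClusters <- clusters[trainIdx]
    if (!fixed && length(unique(trainClusters)) < 3)
      stop("inner loop needs at least 3 training clusters")

    kern <- foldKernels(family, precompK, edges, trainIdx)

    if (is.null(confounds)) {
      Ytr <- Y[trainIdx, , drop = FALSE]
      Yte <- Y[testIdx, , drop = FALSE]
    } else {
      res <- regressConfounds(Y, confounds, trainIdx, testIdx)
      Ytr <- as.matrix(res$train); Yte <- as.matrix(res$test)
    }

    if (fixed) {
      lamPerCol <- fixedLambda[f, ]
      wPerCol <- matrix(fixedWeights[f, , ], nrow = m)
    } else {
      kernTrain <- lapply(kern, function(Kf) Kf[trainIdx, trainIdx, drop = FALSE])
      sel <- innerSelect(kernTrain, Ytr, trainClusters, lambdaGrid, weightGrid)
      lamPerCol <- lambdaGrid[sel$lIdx]
      wPerCol <- weightGrid[sel$wIdx, , drop = FALSE]
    }

    mu <- colMeans(Ytr)
    Yc <- sweep(Ytr, 2, mu)
    predTest <- matrix(NA_real_, length(testIdx), m,
                       dimnames = list(NULL, colnames(Y)))
    predTrain <- if (keepTrainFitted)
      matrix(NA_real_, length(trainIdx), m,
             dimnames = list(NULL, colnames(Y))) else NULL

    # group target columns sharing a weight vector to share eigendecompositions
    wKey <- apply(wPerCol, 1, paste, collapse = ",")
    for (key in unique(wKey)) {
      cols <- which(wKey == key)
      w <- wPerCol[cols[1], ]
      Kc <- combineKernels(kern, w)
      eig <- krrEigen(Kc[trainIdx, trainIdx, drop = FALSE])
      lamSet <- unique(lamPerCol[cols])
      for (l in lamSet) {
        cl <- cols[lamPerCol[cols] == l]
        p <- krrPredictPath(eig, Kc[testIdx, trainIdx, drop = FALSE],
                            Yc[, cl, drop = FALSE], l)[[1]]
        predTest[, cl] <- sweep(p, 2, mu[cl], `+`)
        if (keepTrainFitted) {
          pt <- krrPredictPath(eig, Kc[trainIdx, trainIdx, drop = FALSE],
                               Yc[, cl, drop = FALSE], l)[[1]]
          predTrain[, cl] <- sweep(pt, 2, mu[cl], `+`)
        }
      }
    }

    if (nrow(Yte) < 3) {
      rMat[f, ] <- NA_real_; codMat[f, ] <- NA_real_
    } else {
      rrow <- colCor(predTest, Yte)
      if (anyNA(rrow) && !warnedConst) {
        warning("behavior constant within a fold; accuracy recorded as missing")
        warnedConst <- TRUE
      }
      rMat[f, ] <- rrow
      codMat[f, ] <- 1 - colSums((Yte - predTest)^2) /
        colSums(sweep(Yte, 2, mu)^2)
    }
    lamMat[f, ] <- lamPerCol
    tmMat[f, ] <- mu
    wArr[f, , ] <- wPerCol
    if (keepPredictions)
      predsList[[f]] <- list(testIdx = testIdx,
                             observed = Yte, predicted = predTest)
    if (keepTrainFitted)
      trainList[[f]] <- list(trainIdx = trainIdx, fitted = predTrain)
  }

  new("PredictionResult",
      family = family, states = states, measures = colnames(Y),
      folds = folds, clusters = as.integer(clusters),
      r = rMat, cod = codMat, lambda = lamMat, weights = wArr,
      predictions = predsList, trainFitted = trainList, trainMeans = tmMat)
}
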