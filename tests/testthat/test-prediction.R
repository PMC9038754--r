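test_that("greedy site clustering balances sizes and respects constraints", {
  # identity case: as many sites as clusters, all big enough
  labels <- rep(sprintf("s%02d", 1:10), each = 150)
  cl <- buildSiteClusters(labels, nClusters = 10, minSize = 150)
  expect_equal(length(unique(cl)), 10)
  expect_true(all(table(cl) == 150))
  expect_true(all(table(attr(cl, "siteAssignment")) == 1))

  # hand-traced greedy on fixed sizes {300,200,180,160,150,150} into 3 clusters:
  # sorted desc: 300->c1, 200->c2, 180->c3; 160 -> c3 (340); 150 -> c2 (350);
  # 150 -> c1 (450). Cluster totals: 450, 350, 340.
  sizes <- c(a = 300, b = 200, c = 180, d = 160, e = 150, f = 150)
  labels <- rep(names(sizes), sizes)
  cl <- buildSiteClusters(labels, nClusters = 3, minSize = 150)
  assign <- attr(cl, "siteAssignment")
  expect_equal(unname(assign[c("a", "b", "c", "d", "e", "f")]),
               c(1, 2, 3, 3, 2, 1))
  expect_equal(as.vector(rowsum(sizes[names(assign)], assign)), c(450, 350, 340))

  # sites are never split across clusters
  expect_true(all(tapply(cl, labels, function(v) length(unique(v))) == 1))

  expect_error(buildSiteClusters(rep("x", 100), nClusters = 2), "sites")
  expect_warning(buildSiteClusters(rep(sprintf("s%d", 1:10), each = 10),
                                   nClusters = 10, minSize = 150),
                 "relaxing")
})

test_that("fold enumeration covers all combinations with balanced test membership", {
  folds <- enumerateFolds(10, 3)
  expect_equal(length(folds), 120)
  counts <- table(unlist(folds))
  expect_true(all(counts == 36))  # C(9, 2)
  expect_equal(enumerateFolds(2, 1), list(1L, 2L))
  expect_error(enumerateFolds(3, 3), "smaller")
  # deterministic lexicographic order
  expect_equal(folds[[1]], c(1L, 2L, 3L))
  expect_equal(folds[[120]], c(8L, 9L, 10L))
})

test_that("confound regression fits on training participants only", {
  set.seed(31)
  n <- 100
  conf <- cbind(meanFD = rnorm(n), meanDVARS = rnorm(n))
  tr <- 1:70; te <- 71:100

  # confound orthogonal to y: y returned unchanged up to mean-centering
  y <- rnorm(n)
  yOrth <- resid(lm(y ~ conf[, 1] + conf[, 2]))  # exactly orthogonal on all
  res <- regressConfounds(yOrth, conf, seq_len(n), integer(0))
  expect_equal(res$train, yOrth - mean(yOrth) + mean(res$train), tolerance = 1e-10)

  # y driven by motion: training residuals uncorrelated with motion
  y2 <- 2 * conf[, 1] + rnorm(n, 0, 0.1)
  res2 <- regressConfounds(y2, conf, tr, te)
  expect_lt(abs(cor(res2$train, conf[tr, 1])), 1e-10)
  # test residuals use the training coefficients
  beta <- coef(lm(y2[tr] ~ conf[tr, 1] + conf[tr, 2]))
  expect_equal(unname(res2$test),
               unname(y2[te] - cbind(1, conf[te, ]) %*% beta)[, 1],
               tolerance = 1e-10)

  conf3 <- cbind(fd = rnorm(n), flat = rep(1, n))
  expect_error(regressConfounds(y, conf3, tr, te), "flat")
})

test_that("correlation kernel equals pairwise Pearson correlations", {
  expect_equal(correlationKernel(matrix(rnorm(20), 1)), matrix(1))
  v <- rnorm(30)
  K <- correlationKernel(rbind(v, -v + 5))
  expect_equal(K[1, 2], -1)
  set.seed(41)
  A <- matrix(rnorm(5 * 20), 5, 20)
  B <- matrix(rnorm(4 * 20), 4, 20)
  K2 <- correlationKernel(A, B)
  for (i in 1:5) for (j in 1:4)
    expect_equal(K2[i, j], cor(A[i, ], B[j, ]), tolerance = 1e-12)
  expect_error(correlationKernel(rbind(rep(1, 10), rnorm(10))), "zero-variance")
})

test_that("kernel ridge solutions match the closed-form solve and its limits", {
  set.seed(51)
  X <- matrix(rnorm(6 * 40), 6, 40)
  K <- correlationKernel(X)
  y <- rnorm(6)

  # direct 6x6 solve oracle at lambda = 1
  fit <- fitKRR(K, y, 1)
  alphaOracle <- solve(K + diag(1, 6), y - mean(y))
  expect_equal(fit$alpha, drop(alphaOracle), tolerance = 1e-7)

  # lambda -> 0: interpolation of the training data
  fit0 <- fitKRR(K, y, 1e-12)
  expect_equal(predictKRR(fit0, K), y, tolerance = 1e-4)

  # lambda -> Inf: predictions shrink to the training mean
  fitInf <- fitKRR(K, y, 1e12)
  expect_equal(predictKRR(fitInf, K), rep(mean(y), 6), tolerance = 1e-6)

  expect_error(krrEigen(matrix(c(1, 2, 2, 1), 2, 2)), "positive semidefinite")
})

test_that("multikernel reduces to single-kernel at simplex vertices and under equal kernels", {
  set.seed(61)
  n <- 60
  X1 <- matrix(rnorm(n * 50), n, 50)
  X2 <- matrix(rnorm(n * 50), n, 50)
  K1 <- correlationKernel(X1); K2 <- correlationKernel(X2)
  y <- rnorm(n)
  clusters <- rep(1:4, each = 15)

  # all weight mass on state 1: identical to the single-kernel model
  fitV <- fitMultikernel(list(a = K1, b = K2), y, clusters,
                         lambdaGrid = c(0.1, 1, 10),
                         weightGrid = matrix(c(1, 0), 1))
  fitS <- fitKRR(K1, y, fitV$lambda)
  expect_equal(fitV$alpha, fitS$alpha, tolerance = 1e-12)

  # identical kernels: any weight vector gives identical predictions
  p1 <- predictKRR(fitKRR(0.3 * K1 + 0.7 * K1, y, 1), K1)
  p2 <- predictKRR(fitKRR(K1, y, 1), K1)
  expect_equal(p1, p2, tolerance = 1e-10)

  expect_error(fitMultikernel(list(a = K1), y, clusters,
                              lambdaGrid = numeric(0)), "empty")

  # full selection path runs and returns simplex weights
  fit <- fitMultikernel(list(a = K1, b = K2), y, clusters,
                        lambdaGrid = c(0.1, 1, 10),
                        weightGrid = simplexGrid(2, 0.5))
  expect_equal(sum(fit$weights), 1)
})

test_that("mean-FC input is the per-edge Fisher mean across states", {
  coh <- tinyCohort()
  cset <- coh$connectomes
  X <- meanFCEdges(cset)
  zmean <- (atanh(edgeMatrix(cset, 1)[5, 3]) + atanh(edgeMatrix(cset, 2)[5, 3]) +
            atanh(edgeMatrix(cset, 3)[5, 3]) + atanh(edgeMatrix(cset, 4)[5, 3])) / 4
  expect_equal(X[5, 3], tanh(zmean), tolerance = 1e-7)

  # single state: mean FC is that state
  cfg <- cohortConfig(nParticipants = 20, nRegions = 8, nNetworks = 2,
                      nSites = 2, states = "rest", seed = 3)
  cset1 <- generateCohort(cfg)$connectomes
  expect_equal(meanFCEdges(cset1), edgeMatrix(cset1, "rest"), tolerance = 1e-7)
})

test_that("linear ridge agrees between primal and dual routes and recovers noiseless weights", {
  set.seed(71)
  # n > E, lambda ~ 0, noiseless linear target: OLS limit recovers weights
  n <- 200; E <- 10
  X <- matrix(rnorm(n * E), n, E)
  w <- rnorm(E)
  y <- drop(X %*% w) + 3
  fit <- fitLinearRidge(X, y, 1e-10)
  expect_equal(fit$weights * (1 / fit$scale), w, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(predictLinearRidge(fit, X), y, tolerance = 1e-6)

  # E > n: implementation takes the dual route; primal normal equations as oracle
  n2 <- 30; E2 <- 100
  X2 <- matrix(rnorm(n2 * E2), n2, E2)
  y2 <- rnorm(n2)
  fit2 <- fitLinearRidge(X2, y2, 5)
  Xs <- scale(X2)
  wOracle <- solve(crossprod(Xs) + diag(5, E2), crossprod(Xs, y2 - mean(y2)))
  expect_equal(fit2$weights, drop(wOracle), tolerance = 1e-8,
               ignore_attr = TRUE)

  # constant target: zero weights, intercept = the constant
  fit3 <- fitLinearRidge(X, rep(4, n), 1)
  expect_equal(fit3$weights, rep(0, E), ignore_attr = TRUE)
  expect_equal(fit3$intercept, 4)
})

test_that("accuracy metrics match hand-computed values and handle degenerate cases", {
  obs <- c(1, 2, 3, 4, 5); pred <- c(1.2, 1.8, 3.3, 3.9, 5.1)
  met <- accuracyMetrics(obs, pred, trainMean = 2.8)
  expect_equal(met$r, cor(obs, pred))
  expect_equal(met$cod, 1 - sum((obs - pred)^2) / sum((obs - 2.8)^2))

  perfect <- accuracyMetrics(obs, obs, 3)
  expect_equal(perfect$r, 1); expect_equal(perfect$cod, 1)

  # constant prediction at the training mean: COD ~ 0, r undefined
  const <- accuracyMetrics(obs, rep(3, 5), 3)
  expect_true(is.na(const$r))
  expect_equal(const$cod, 0)

  expect_true(is.na(accuracyMetrics(c(1, 2), c(1, 2), 1)$r))
})

test_that("Fisher-averaged accuracy behaves as the transform dictates", {
  expect_equal(aggregateAccuracy(c(0.4, 0.4, 0.4)), 0.4, ignore_attr = TRUE)
  # direct formula evaluation: tanh((atanh .2 + atanh .6)/2)
  expect_equal(aggregateAccuracy(c(0.2, 0.6)), 0.4202041,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(aggregateAccuracy(c(-0.35, 0.35)), 0, ignore_attr = TRUE)
  out <- aggregateAccuracy(c(0.2, NA, 0.6))
  expect_equal(attr(out, "nMissing"), 1L)
})

test_that("nested CV never leaks participants or splits sites across the fold boundary", {
  coh <- tinyCohort()
  cset <- coh$connectomes
  clusters <- tinyClusters()
  site <- colDataOf(cset)$site
  folds <- enumerateFolds(max(clusters), 2)
  for (f in folds) {
    testIdx <- which(clusters %in% f)
    trainIdx <- which(!(clusters %in% f))
    expect_length(intersect(testIdx, trainIdx), 0)
    expect_length(union(testIdx, trainIdx), ncol(cset))
    expect_length(intersect(site[testIdx], site[trainIdx]), 0)
  }
})

test_that("single-kernel accuracy is invariant to positive affine rescaling of the target", {
  coh <- tinyCohort()
  cset <- coh$connectomes
  clusters <- tinyClusters()
  y <- coh$behavior$cognition_01
  grid <- 10^seq(-2, 2, length.out = 5)
  r1 <- nestedCV(cset, y, family = "single_kernel", clusters = clusters,
                 kTest = 2, lambdaGrid = grid, keepPredictions = FALSE)
  r2 <- nestedCV(cset, 3 * y + 2, family = "single_kernel", clusters = clusters,
                 kTest = 2, lambdaGrid = grid, keepPredictions = FALSE)
  expect_equal(r1@r, r2@r, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(r1@cod, r2@cod, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(r1@lambda, r2@lambda, ignore_attr = TRUE)
})

test_that("nested CV results do not depend on participant order", {
  coh <- tinyCohort()
  cset <- coh$connectomes
  clusters <- tinyClusters()
  y <- coh$behavior$personality_01
  grid <- 10^seq(-2, 2, length.out = 5)
  r1 <- nestedCV(cset, y, family = "single_kernel", clusters = clusters,
                 kTest = 2, lambdaGrid = grid, keepPredictions = FALSE)
  set.seed(81)
  perm <- sample(ncol(cset))
  r2 <- nestedCV(cset[, perm], y[perm], family = "single_kernel",
                 clusters = clusters[perm], kTest = 2, lambdaGrid = grid,
                 keepPredictions = FALSE)
  expect_equal(r1@r, r2@r, tolerance = 1e-8)
})

test_that("pure-noise targets predict at chance while planted signal is recovered", {
  coh <- tinyCohort()
  cset <- coh$connectomes
  clusters <- tinyClusters()
  set.seed(91)
  noise <- rnorm(ncol(cset))
  grid <- 10^seq(-2, 3, length.out = 6)
  rNoise <- nestedCV(cset, noise, family = "single_kernel", clusters = clusters,
                     kTest = 2, lambdaGrid = grid, keepPredictions = FALSE)
  z <- fisherZ(rNoise@r[, 1])
  expect_lt(abs(mean(z)) / (sd(z) / sqrt(length(z))), 4)

  rSig <- nestedCV(cset, coh$behavior$cognition_01, family = "single_kernel",
                   clusters = clusters, kTest = 2, lambdaGrid = grid,
                   keepPredictions = FALSE)
  expect_gt(aggregateAccuracy(rSig@r[, 1]), aggregateAccuracy(rNoise@r[, 1]))
})

test_that("multikernel with identical state kernels reproduces single-kernel predictions", {
  cfg <- cohortConfig(nParticipants = 80, nRegions = 10, nNetworks = 2,
                      nSites = 4, stateModulationSd = 0,
                      measuresPerDomain = c(cognition = 1, personality = 1,
                                            mental_health = 1), seed = 17)
  coh <- generateCohort(cfg)
  cset <- coh$connectomes
  clusters <- suppressWarnings(buildSiteClusters(colDataOf(cset)$site, nClusters = 4))
  y <- coh$behavior$cognition_01
  grid <- c(0.1, 1, 10)
  rs <- nestedCV(cset, y, family = "single_kernel", state = "rest",
                 clusters = clusters, kTest = 1, lambdaGrid = grid)
  rm <- nestedCV(cset, y, family = "multikernel", clusters = clusters,
                 kTest = 1, lambdaGrid = grid, weightStep = 0.5)
  for (f in seq_along(rs@folds))
    expect_equal(rm@predictions[[f]]$predicted, rs@predictions[[f]]$predicted,
                 tolerance = 1e-8)
})
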