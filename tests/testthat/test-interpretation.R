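test_that("Haufe inversion equals a brute-force per-edge covariance loop", {
  coh <- tinyCohort()
  cset <- coh$connectomes
  clusters <- tinyClusters()
  Y <- as.matrix(coh$behavior[, c("cognition_01", "personality_01")])
  res <- nestedCV(cset, Y, family = "single_kernel", state = "rest",
                  clusters = clusters, kTest = 2,
                  lambdaGrid = 10^seq(-1, 2, length.out = 4))
  feats <- haufeInvert(cset, res, states = "rest")

  X <- edgeMatrix(cset, "rest")
  K <- length(res@folds)
  for (j in 1:2) {
    acc <- numeric(nrow(X))
    for (f in seq_len(K)) {
      tf <- res@trainFitted[[f]]
      yhat <- tf$fitted[, j]
      for (e in seq_len(nrow(X)))
        acc[e] <- acc[e] + cov(X[e, tf$trainIdx], yhat)
    }
    expect_equal(feats@features$rest[, j], acc / K, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("suppressor variables get zero Haufe features despite unit regression weights", {
  set.seed(101)
  n <- 10000
  y <- rnorm(n); motion <- rnorm(n)
  fc1 <- y - motion; fc2 <- motion
  yhat <- fc1 + fc2  # the perfect-accuracy model

  # raw regression weights are both one
  expect_equal(unname(coef(lm(y ~ fc1 + fc2))[-1]), c(1, 1), tolerance = 1e-10)

  # Haufe features: cov with the model prediction
  h1 <- cov(fc1, yhat); h2 <- cov(fc2, yhat)
  se2 <- sqrt((var(fc2) * var(yhat)) / n)
  expect_lt(abs(h2), 3 * se2)          # suppressor goes to zero
  expect_equal(h1, var(y), tolerance = 5 * sqrt(2 / n) * 3)  # true signal ~ var(y)

  # constant prediction yields all-zero features
  fitted <- matrix(5, 50, 1)
  edges <- list(s = matrix(rnorm(20 * 50), 20, 50))
  ff <- predictome:::haufeFold(edges, 1:50, fitted)
  expect_equal(ff$s, matrix(0, 20, 1), tolerance = 1e-12)
})

test_that("feature similarity is a correlation with the expected extremes", {
  coh <- tinyCohort()
  res <- nestedCV(coh$connectomes, as.matrix(coh$behavior[, c("cognition_01",
                                                              "cognition_02")]),
                  family = "single_kernel", clusters = tinyClusters(),
                  kTest = 2, lambdaGrid = c(0.1, 10))
  f <- haufeInvert(coh$connectomes, res, states = "rest")
  expect_equal(diag(featureSimilarity(f)), c(1, 1), ignore_attr = TRUE)

  neg <- f
  neg@features <- lapply(f@features, function(m) -m)
  expect_equal(featureSimilarity(f, neg)[1, 1], -1)

  perState <- featureSimilarity(f, mode = "per_state")
  expect_named(perState, "rest")
})

test_that("sign consistency counts unique blocks with conservative zero handling", {
  a <- devectorizeFC(c(1, -2, 3), diagValue = 0); diag(a) <- c(0.5, -1, 2)
  expect_equal(as.numeric(signConsistency(a, a)), 1)
  expect_equal(as.numeric(signConsistency(a, -a)), 0)

  # hand count over the 6 unique blocks of a 3x3 pair
  b <- a; b[1, 2] <- b[2, 1] <- -5   # flip one off-diagonal block
  expect_equal(as.numeric(signConsistency(a, b)), 5 / 6)

  # zero agrees only with zero
  z1 <- matrix(0, 2, 2); z2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(as.numeric(signConsistency(z1, z1)), 1)
  expect_equal(as.numeric(signConsistency(z1, z2)), 2 / 3)

  # missing blocks excluded pairwise
  a2 <- a; a2[2, 2] <- NA
  out <- signConsistency(a2, a)
  expect_equal(attr(out, "nExcluded"), 1L)
  expect_equal(as.numeric(out), 1)
})

test_that("the analytic chance level matches p^2 + (1-p)^2", {
  expect_equal(round(100 * consistencyChanceLevel(positiveFraction = 0.493), 2),
               50.01)
  expect_equal(consistencyChanceLevel(positiveFraction = 0.5), 0.5)
  expect_equal(consistencyChanceLevel(positiveFraction = 1), 1)
  expect_equal(consistencyChanceLevel(c(-1, 2, 3, -4)),
               0.5^2 + 0.5^2)
  expect_error(consistencyChanceLevel(numeric(0)), "empty")
})

test_that("UPGMA clustering reproduces hand-computed merge heights and separable groups", {
  # 4 items, hand-worked: d(a,b)=2, d(c,d)=3, cross distances 7,9,8,10
  # merge ab at 2, cd at 3, then (ab)-(cd) at mean(7,9,8,10) = 8.5
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- 2; d["c", "d"] <- 3
  d["a", "c"] <- 7; d["a", "d"] <- 9; d["b", "c"] <- 8; d["b", "d"] <- 10
  d <- d + t(d)
  sim <- 1 - d  # clusterBehaviors converts back to distance 1 - sim
  cl <- clusterBehaviors(sim, k = 2)
  expect_equal(cl$tree$height, c(2, 3, 8.5))
  expect_equal(unname(cl$clusters), c(1, 1, 2, 2))

  # block-diagonal similarity: three perfect groups recovered exactly
  g <- rep(1:3, each = 4)
  sim3 <- outer(g, g, function(x, y) ifelse(x == y, 0.9, 0.05))
  diag(sim3) <- 1
  cl3 <- clusterBehaviors(sim3, k = 3)
  expect_equal(ari(cl3$clusters, g), 1)

  # permuting input order: same partition up to relabeling, same heights
  perm <- c(7, 2, 11, 4, 9, 1, 12, 3, 5, 10, 8, 6)
  cl3p <- clusterBehaviors(sim3[perm, perm], k = 3)
  expect_equal(sort(cl3p$tree$height), sort(cl3$tree$height))
  expect_equal(ari(cl3p$clusters, g[perm]), 1)

  expect_error(clusterBehaviors(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("block permutation tests floor on planted signal and stay calm on noise", {
  cfg <- cohortConfig(nParticipants = 150, nRegions = 16, nNetworks = 4,
                      nSites = 5, edgeSignalDensity = 0.15,
                      edgeEffectSize = 0.8, individualSd = 0.3,
                      noiseSd = 0.1, motionBehaviorCorr = 0,
                      measuresPerDomain = c(cognition = 1, personality = 1,
                                            mental_health = 1), seed = 23)
  coh <- generateCohort(cfg)
  cset <- coh$connectomes
  clusters <- suppressWarnings(buildSiteClusters(colDataOf(cset)$site, nClusters = 5))
  y <- coh$behavior$cognition_01
  res <- nestedCV(cset, y, family = "single_kernel", state = "rest",
                  clusters = clusters, kTest = 1,
                  lambdaGrid = c(0.1, 1, 10, 100))
  tab <- blockSignificance(cset, y, res, state = "rest", nPerm = 199, seed = 3)
  expect_true(all(tab$p >= 1 / 200 & tab$p <= 1))
  expect_equal(min(tab$p), 1 / 200)  # strong planted signal hits the floor

  # unrelated target: no block should dominate; p-values spread out
  set.seed(11)
  yNull <- rnorm(ncol(cset))
  resN <- nestedCV(cset, yNull, family = "single_kernel", state = "rest",
                   clusters = clusters, kTest = 1,
                   lambdaGrid = c(0.1, 1, 10, 100))
  tabN <- blockSignificance(cset, yNull, resN, state = "rest", nPerm = 199,
                            seed = 3)
  expect_gt(median(tabN$p), 0.1)

  expect_error(blockSignificance(cset, y, res, state = "rest", nPerm = 0),
               "at least 1")
  expect_warning(blockSignificance(cset, y, res, state = "rest", nPerm = 50,
                                   seed = 1),
                 "unstable")
})

test_that("cross-state conjunction keeps only consistently signed, always-significant blocks", {
  states <- c("rest", "mid", "sst", "nback")
  base <- matrix(c(1, 0.5, 0.5, -2), 2, 2)
  blocks <- setNames(lapply(c(1, 2, 3, 4), function(k) base * k), states)
  sig <- setNames(rep(list(matrix(TRUE, 2, 2)), 4), states)

  conj <- conjunctionAcrossStates(blocks, sig)
  expect_equal(conj[1, 1], mean(c(1, 2, 3, 4)))   # {1,2,3,4} -> 2.5
  expect_equal(conj[2, 2], mean(c(-2, -4, -6, -8)))

  # significant in only 3 of 4 states -> masked
  sig3 <- sig; sig3$nback[1, 1] <- FALSE
  expect_true(is.na(conjunctionAcrossStates(blocks, sig3)[1, 1]))

  # sign flip in one state, significant everywhere -> masked
  flip <- blocks; flip$mid[1, 1] <- -flip$mid[1, 1]
  expect_true(is.na(conjunctionAcrossStates(flip, sig)[1, 1]))

  expect_error(conjunctionAcrossStates(blocks, sig[c(2, 1, 3, 4)]), "differ")
})

test_that("region predictability maps split positive and negative contributions", {
  m <- matrix(c(0, 1, 2, 0.5,
                1, 0, -1, 3,
                2, -1, 0, -0.5,
                0.5, 3, -0.5, 0), 4, 4, byrow = TRUE)
  out <- regionPredictability(m)
  expect_equal(out$positive, c(3.5, 4, 2, 3.5))
  expect_equal(out$negative, c(0, 1, 1.5, 0.5))
  expect_true(all(out$positivePct >= 0 & out$positivePct <= 100))
  expect_equal(order(out$negativePct), order(out$negative))

  allPos <- matrix(abs(m), 4, 4)
  expect_equal(regionPredictability(allPos)$negative, rep(0, 4))
})

test_that("domain averaging weights measures equally and supports display scaling", {
  coh <- tinyCohort()
  Y <- as.matrix(coh$behavior[, names(coh$domains)])
  res <- nestedCV(coh$connectomes, Y, family = "single_kernel",
                  clusters = tinyClusters(), kTest = 2,
                  lambdaGrid = c(0.1, 10))
  f <- haufeInvert(coh$connectomes, res, states = "rest")

  dom <- domainAverageFeatures(f, coh$domains)
  cogCols <- names(coh$domains)[coh$domains == "cognition"]
  expect_equal(dom@features$rest[, "cognition"],
               rowMeans(f@features$rest[, cogCols]), ignore_attr = TRUE)

  # single-behavior domain: identity
  one <- domainAverageFeatures(f, coh$domains, include = c("cognition_01"))
  expect_equal(one@features$rest[, "cognition"], f@features$rest[, "cognition_01"],
               ignore_attr = TRUE)

  # M and -M average to zero
  f2 <- f
  f2@features$rest[, "cognition_02"] <- -f2@features$rest[, "cognition_01"]
  z <- domainAverageFeatures(f2, coh$domains,
                             include = c("cognition_01", "cognition_02"))
  expect_equal(max(abs(z@features$rest[, "cognition"])), 0)

  std <- domainAverageFeatures(f, coh$domains, standardize = TRUE)
  expect_equal(sd(std@features$rest[, "cognition"]), 1, tolerance = 1e-10)

  expect_error(domainAverageFeatures(f, coh$domains, include = cogCols)@features[[1]][, "personality"],
               "subscript|empty")
})
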