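# Run code under a temporary RNG state so generators are reproducible
# without clobbering the caller's stream.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Configuration of a synthetic cohort
#'
#' Defines the study conditions the generator emulates: several brain
#' states whose connectivity shares a dominant individual component with
#' small state-specific modulation; behavioral measures grouped into
#' domains, each driven by a domain-shared latent factor expressed on a
#' planted edge set; a motion confound entering both connectivity and
#' behavior; and balanced site assignment with site-level behavior
#' offsets.
#'
#' @param nParticipants cohort size (default 400).
#' @param nRegions number of brain regions (default 60; the real-data
#'   scale is 419).
#' @param nNetworks number of network groups (default 6; real-data scale
#'   18).
#' @param nSites number of acquisition sites (default 10; at least 10 is
#'   needed when site-cluster cross-validation is exercised).
#' @param states brain-state names (default rest + three tasks).
#' @param measuresPerDomain named counts of measures per behavioral
#'   domain (default cognition 16, personality 9, mental_health 11).
#' @param edgeSignalDensity fraction of edges planted per domain
#'   (default 0.05).
#' @param withinDomainFeatureOverlap in [0,1]: share of each measure's
#'   variance carried by the domain-shared latent factor (the remainder
#'   is measure-specific and brain-unrelated). High values make
#'   within-domain measures share predictive features (default 0.8).
#' @param edgeEffectSize scale of the planted edge effects in Fisher-z
#'   units (default 0.35).
#' @param individualSd sd of the state-shared individual edge component
#'   (default 0.5); kept large relative to \code{stateModulationSd} so
#'   individual differences dominate task modulation.
#' @param stateModulationSd sd of state-specific connectivity modulation
#'   in Fisher-z units (default 0.1).
#' @param noiseSd sd of unstructured noise in connectivity (shared
#'   across states) and in behavior (default 0.3).
#' @param motionBehaviorCorr target correlation between mean FD and every
#'   behavioral measure, in (-1, 1) (default 0.3).
#' @param motionFcBeta Fisher-z connectivity shift per sd of mean FD,
#'   applied uniformly to all edges (default 0.15).
#' @param siteEffectSd sd of additive site-level behavior offsets
#'   (default 0.2).
#' @param seed integer RNG seed.
#' @return a validated list of class \code{CohortConfig}.
#' @export
cohortConfig <- function(nParticipants = 400, nRegions = 60, nNetworks = 6,
                         nSites = 10,
                         states = c("rest", "mid", "sst", "nback"),
                         measuresPerDomain = c(cognition = 16, personality = 9,
                                               mental_health = 11),
                         edgeSignalDensity = 0.05,
                         withinDomainFeatureOverlap = 0.8,
                         edgeEffectSize = 0.35,
                         individualSd = 0.5,
                         stateModulationSd = 0.1,
                         noiseSd = 0.3,
                         motionBehaviorCorr = 0.3,
                         motionFcBeta = 0.15,
                         siteEffectSd = 0.2,
                         seed = 1L) {
  cfg <- list(nParticipants = as.integer(nParticipants),
              nRegions = as.integer(nRegions),
              nNetworks = as.integer(nNetworks),
              nSites = as.integer(nSites),
              states = as.character(states),
              measuresPerDomain = measuresPerDomain,
              edgeSignalDensity = edgeSignalDensity,
              withinDomainFeatureOverlap = withinDomainFeatureOverlap,
              edgeEffectSize = edgeEffectSize,
              individualSd = individualSd,
              stateModulationSd = stateModulationSd,
              noiseSd = noiseSd,
              motionBehaviorCorr = motionBehaviorCorr,
              motionFcBeta = motionFcBeta,
              siteEffectSd = siteEffectSd,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(nParticipants > 0, nRegions > 2, nNetworks > 0, nSites > 0,
              length(states) >= 1,
              all(measuresPerDomain > 0), !is.null(names(measuresPerDomain)),
              edgeSignalDensity >= 0, edgeSignalDensity <= 1,
              withinDomainFeatureOverlap >= 0, withinDomainFeatureOverlap <= 1,
              stateModulationSd >= 0, noiseSd >= 0,
              motionBehaviorCorr > -1, motionBehaviorCorr < 1)
  })
  if (cfg$nSites < 2) stop("nSites must be at least 2 for site-based cross-validation")
  class(cfg) <- "CohortConfig"
  cfg
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Connectivity is built in Fisher-z space (closed under addition) and
#' mapped back through tanh, guaranteeing entries in (-1, 1):
#' \deqn{z_{i,s,e} = \mu_e + a_{i,e} + \sum_d F_{i,d}\beta_{d,e} +
#'   \gamma\,\tilde{FD}_i + \epsilon_{i,e} + s_{i,s,e}}
#' with a participant-level individual profile \eqn{a} shared across
#' states, planted domain effects \eqn{\beta} on disjoint edge sets, a
#' uniform motion shift, state-shared noise \eqn{\epsilon}, and
#' state-specific modulation \eqn{s} (zero when
#' \code{stateModulationSd = 0}, making all states identical). Each
#' behavioral measure mixes its domain factor with a measure-specific
#' factor, a motion confound calibrated to \code{motionBehaviorCorr},
#' a site offset, and noise.
#'
#' @param config a [cohortConfig()].
#' @return list with elements
#'   \describe{
#'     \item{connectomes}{a [ConnectomeSet-class] (per-state edge
#'       matrices, cohort table in \code{colData}, network labels in
#'       metadata)}
#'     \item{behavior}{data.frame participant x measure}
#'     \item{domains}{named character: measure to domain map}
#'     \item{truth}{planted edges, edge effects, latent factors and
#'       confound coefficients (ground truth for recovery tests)}
#'   }
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "CohortConfig"))
  withSeed(config$seed, {
    n <- config$nParticipants
    R <- config$nRegions
    E <- R * (R - 1) / 2
    domains <- names(config$measuresPerDomain)
    D <- length(domains)

    nPlant <- round(config$edgeSignalDensity * E)
    if (nPlant < 1) stop("edgeSignalDensity implies 0 planted edges per domain")
    if (nPlant * D > E) stop("edgeSignalDensity too high for disjoint domain edge sets")

    regionNames <- sprintf("R%03d", seq_len(R))
    networks <- sprintf("net%02d", seq_len(config$nNetworks))
    netLabels <- setNames(networks[rep_len(seq_len(config$nNetworks), R)],
                          regionNames)

    ids <- sprintf("sub%04d", seq_len(n))
    site <- sample(rep_len(seq_len(config$nSites), n))
    siteName <- sprintf("site%02d", site)

    meanFD <- 0.05 + abs(rnorm(n, 0.10, 0.08))
    fdz <- as.numeric(scale(meanFD))
    meanDVARS <- 25 + 8 * fdz + rnorm(n, 0, 3)
    age <- runif(n, 9, 11)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    raceBin <- sample(sprintf("race%d", 1:5), n, replace = TRUE,
                      prob = c(0.5, 0.2, 0.15, 0.1, 0.05))
    incomeBin <- sample(sprintf("income%d", 1:4), n, replace = TRUE)

    # planted edge sets, disjoint across domains
    planted <- sample.int(E, nPlant * D)
    plantedEdges <- setNames(split(planted, rep(domains, each = nPlant)), domains)
    plantedEdges <- plantedEdges[domains]
    edgeBetas <- lapply(plantedEdges, function(idx) {
      setNames(sample(c(-1, 1), length(idx), replace = TRUE) *
                 runif(length(idx), 0.5, 1) * config$edgeEffectSize, idx)
    })

    FF <- matrix(rnorm(n * D), n, D, dimnames = list(ids, domains))
    B <- matrix(0, E, D)
    for (d in seq_len(D)) B[plantedEdges[[d]], d] <- edgeBetas[[d]]

    mu <- rnorm(E, 0.15, 0.10)
    zShared <- matrix(mu, E, n) +
      matrix(rnorm(E * n, 0, config$individualSd), E, n) +
      B %*% t(FF) +
      matrix(config$motionFcBeta * fdz, E, n, byrow = TRUE) +
      matrix(rnorm(E * n, 0, config$noiseSd), E, n)

    edges <- lapply(config$states, function(s) {
      z <- zShared
      if (config$stateModulationSd > 0) {
        z <- z + rnorm(E, 0, config$stateModulationSd) +          # common task shift
          matrix(rnorm(E * n, 0, config$stateModulationSd), E, n) # individual modulation
      }
      tanh(z)
    })
    names(edges) <- config$states

    # behaviors
    mNames <- unlist(lapply(domains, function(d)
      sprintf("%s_%02d", d, seq_len(config$measuresPerDomain[[d]]))))
    domainOf <- setNames(rep(domains, config$measuresPerDomain), mNames)
    M <- length(mNames)
    w <- config$withinDomainFeatureOverlap
    loadings <- setNames(runif(M, 0.8, 1.2), mNames)
    rho <- config$motionBehaviorCorr
    siteOffsets <- matrix(rnorm(config$nSites * M, 0, config$siteEffectSd),
                          config$nSites, M)
    Y <- matrix(NA_real_, n, M, dimnames = list(ids, mNames))
    confoundBeta <- setNames(numeric(M), mNames)
    for (m in seq_len(M)) {
      d <- match(domainOf[m], domains)
      lat <- sqrt(w) * FF[, d] + sqrt(1 - w) * rnorm(n)
      vSig <- loadings[m]^2 + config$siteEffectSd^2 + config$noiseSd^2
      cc <- if (rho == 0) 0 else rho * sqrt(vSig / (1 - rho^2))
      confoundBeta[m] <- cc
      Y[, m] <- loadings[m] * lat + cc * fdz + siteOffsets[site, m] +
        rnorm(n, 0, config$noiseSd)
    }

    meta <- data.frame(participant = ids, site = siteName,
                       meanFD = meanFD, meanDVARS = meanDVARS,
                       age = age, sex = sex, raceBin = raceBin,
                       incomeBin = incomeBin, stringsAsFactors = FALSE)

    cset <- ConnectomeSet(edges, meta, regionNames, netLabels)
    truth <- list(plantedEdges = plantedEdges, edgeBetas = edgeBetas,
                  latentFactors = FF, confoundBeta = confoundBeta,
                  motionFcBeta = config$motionFcBeta,
                  loadings = loadings, config = config)
    list(connectomes = cset,
         behavior = data.frame(participant = ids, Y, stringsAsFactors = FALSE),
         domains = domainOf,
         truth = truth)
  })
}

#' Simulate one fMRI run targeting a given FC matrix
#'
#' Draws frames from a multivariate normal whose correlation converges to
#' \code{fcTarget} (repaired to the nearest positive semidefinite
#' correlation matrix if needed), with an FD trace that exceeds the 0.3 mm
#' censoring threshold exactly at \code{fdSpikes}.
#'
#' @param nFrames number of frames.
#' @param fcTarget an [FCMatrix-class] or correlation matrix.
#' @param fdSpikes integer frame indices given high (0.4 mm) FD.
#' @param seed RNG seed.
#' @return An [ROITimeSeriesRun-class] with all frames marked usable
#'   (apply [censorFrames()] downstream).
#' @export
generateTimeseriesRun <- function(nFrames, fcTarget, fdSpikes = integer(0),
                                  seed = 1L) {
  target <- if (is(fcTarget, "FCMatrix")) fcTarget@values else as.matrix(fcTarget)
  R <- nrow(target)
  if (nFrames < R + 1)
    warning("nFrames < nRegions + 1: empirical FC will be rank-deficient")
  ev <- eigen(target, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    target <- as.matrix(Matrix::nearPD(target, corr = TRUE)$mat)
  }
  withSeed(seed, {
    L <- chol(target + diag(1e-10, R))
    X <- matrix(rnorm(nFrames * R), nFrames, R) %*% L
    colnames(X) <- rownames(target)
    fd <- runif(nFrames, 0.02, 0.25)
    fd[fdSpikes] <- 0.4
    dvars <- runif(nFrames, 10, 40)
    ROITimeSeriesRun(X, fd, dvars)
  })
}
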