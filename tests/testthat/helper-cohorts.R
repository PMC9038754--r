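# Shared fixtures, built in code and memoised for the test run.

.cohortCache <- new.env(parent = emptyenv())

cachedCohort <- function(key, config) {
  if (is.null(.cohortCache[[key]]))
    .cohortCache[[key]] <- generateCohort(config)
  .cohortCache[[key]]
}

# desk-scale cohort: the generator's default study conditions
defaultCohort <- function() cachedCohort("default", cohortConfig(seed = 1))

defaultClusters <- function() {
  if (is.null(.cohortCache$clusters)) {
    cset <- defaultCohort()$connectomes
    .cohortCache$clusters <- suppressWarnings(
      buildSiteClusters(SummarizedExperiment::colData(cset)$site,
                        nClusters = 10))
  }
  .cohortCache$clusters
}

# small cohort for fast module tests
tinyCohort <- function() cachedCohort(
  "tiny", cohortConfig(nParticipants = 120, nRegions = 16, nNetworks = 4,
                       nSites = 6, measuresPerDomain = c(cognition = 3,
                                                         personality = 3,
                                                         mental_health = 3),
                       seed = 7))

tinyClusters <- function() {
  cset <- tinyCohort()$connectomes
  suppressWarnings(buildSiteClusters(SummarizedExperiment::colData(cset)$site,
                                     nClusters = 6))
}

colDataOf <- function(cset) as.data.frame(SummarizedExperiment::colData(cset))

# adjusted Rand index between two partitions
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
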