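#' @importFrom utils read.csv write.csv combn
NULL

#' Read a behavior table
#'
#' CSV with a \code{participant} column and one column per behavioral
#' measure. Participants missing any measure are dropped (with a
#' message); duplicated ids are an error.
#'
#' @param path CSV path.
#' @return data.frame with participant ids and complete measures.
#' @export
readBehaviorTable <- function(path) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"participant" %in% names(tab)) stop("behavior table needs a participant column")
  if (anyDuplicated(tab$participant)) stop("duplicated participant id in behavior table")
  complete <- stats::complete.cases(tab)
  if (any(!complete))
    message(sum(!complete), " participant(s) without all behavioral measures excluded")
  tab[complete, , drop = FALSE]
}

#' Read a cohort (meta) table
#'
#' CSV with at least \code{participant} and \code{site} columns.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readCohortMeta <- function(path) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("participant", "site")
  if (!all(need %in% names(tab)))
    stop("meta table needs columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  if (anyDuplicated(tab$participant)) stop("duplicated participant id in meta table")
  tab
}

#' Read a region-to-network labeling
#'
#' Two-column CSV (region, group).
#'
#' @param path CSV path.
#' @return named character vector, region -> group.
#' @export
readNetworkLabels <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("labels file needs two columns: region, group")
  setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Write / read one FC matrix as delimited text
#'
#' Square matrix with a region-name header; state and frame count go in
#' a JSON sidecar (\code{<path>.json}).
#'
#' @param fc an [FCMatrix-class].
#' @param path output CSV path.
#' @return (write) the path, invisibly; (read) an [FCMatrix-class].
#' @export
writeFCMatrix <- function(fc, path) {
  stopifnot(is(fc, "FCMatrix"))
  write.csv(as.data.frame(fc@values), path, row.names = FALSE)
  jsonlite::write_json(list(state = fc@state, nFramesUsed = fc@nFramesUsed),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFCMatrix
#' @export
readFCMatrix <- function(path) {
  m <- as.matrix(read.csv(path, check.names = FALSE))
  rownames(m) <- colnames(m)
  state <- "unknown"; nf <- nrow(m)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    hdr <- jsonlite::read_json(side, simplifyVector = TRUE)
    state <- hdr$state; nf <- hdr$nFramesUsed
  }
  FCMatrix(m, state = state, nFramesUsed = nf)
}

#' Write and re-read a synthetic cohort
#'
#' \code{writeCohort} lays a generated cohort out on disk: one delimited
#' FC matrix per participant and state under \code{fc/}, behavior and
#' cohort tables as CSV, network labels as CSV, ground truth as JSON.
#' \code{readCohort} reconstructs the [ConnectomeSet-class] and tables,
#' aligning rows by participant id (never by order).
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory.
#' @return (write) \code{dir}, invisibly; (read) a list like
#'   [generateCohort()]'s (without truth unless present on disk).
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "fc"), recursive = TRUE, showWarnings = FALSE)
  cset <- cohort$connectomes
  write.csv(cohort$behavior, file.path(dir, "behavior.csv"), row.names = FALSE)
  write.csv(as.data.frame(colData(cset)), file.path(dir, "meta.csv"),
            row.names = FALSE)
  lab <- networkLabels(cset)
  write.csv(data.frame(region = names(lab), group = unname(lab)),
            file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(domains = as.list(cohort$domains),
         states = stateNames(cset),
         plantedEdges = cohort$truth$plantedEdges,
         confoundBeta = as.list(cohort$truth$confoundBeta)),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  for (id in colnames(cset)) {
    for (s in stateNames(cset)) {
      writeFCMatrix(fcMatrix(cset, id, s),
                    file.path(dir, "fc", sprintf("%s_%s.csv", id, s)))
    }
  }
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  behavior <- readBehaviorTable(file.path(dir, "behavior.csv"))
  meta <- readCohortMeta(file.path(dir, "meta.csv"))
  lab <- readNetworkLabels(file.path(dir, "labels.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  states <- truth$states
  ids <- meta$participant
  regionNames <- NULL
  edges <- lapply(states, function(s) {
    cols <- lapply(ids, function(id) {
      fc <- readFCMatrix(file.path(dir, "fc", sprintf("%s_%s.csv", id, s)))
      if (is.null(regionNames)) regionNames <<- rownames(fc@values)
      vectorizeFC(fc)
    })
    do.call(cbind, cols)
  })
  names(edges) <- states
  cset <- ConnectomeSet(edges, meta, regionNames, lab[regionNames])
  behavior <- behavior[match(ids, behavior$participant), , drop = FALSE]
  list(connectomes = cset, behavior = behavior,
       domains = unlist(truth$domains), truth = truth)
}

#' Stratified subsampling matched to reference marginals
#'
#' Draws a subset whose joint distribution over binned characteristics
#' (sex, race, income, binned age and behavior, ...) matches a reference
#' sample: within each joint bin, \code{round(targetPct * targetN)}
#' participants are drawn without replacement, where \code{targetPct} is
#' the reference sample's share in the bin. If any bin's demand exceeds
#' its supply the procedure fails with a shortfall report; reference
#' bins absent from the sample are skipped.
#'
#' @param meta sample table (must contain \code{participant} and the
#'   stratification variables).
#' @param reference reference table with the same variables.
#' @param vars character vector of stratification variables.
#' @param bins named integer vector: number of quantile bins for each
#'   numeric variable (categorical variables use their levels).
#' @param targetN target subset size M.
#' @param seed RNG seed.
#' @return character vector of selected participant ids.
#' @export
matchSubsample <- function(meta, reference, vars, bins = integer(0),
                           targetN, seed = 1L) {
  binize <- function(tab) {
    out <- lapply(vars, function(v) {
      x <- tab[[v]]
      if (is.numeric(x) && v %in% names(bins)) {
        br <- unique(quantile(reference[[v]], probs = seq(0, 1, length.out = bins[[v]] + 1),
                              na.rm = TRUE))
        as.character(cut(x, breaks = br, include.lowest = TRUE))
      } else as.character(x)
    })
    do.call(paste, c(out, sep = "|"))
  }
  sampleBin <- binize(meta)
  refBin <- binize(reference)
  refTab <- table(refBin) / length(refBin)
  chosen <- character(0)
  shortfall <- list()
  withSeed(seed, {
    for (b in names(refTab)) {
      need <- round(refTab[[b]] * targetN)
      if (need == 0) next
      avail <- which(sampleBin == b)
      if (length(avail) == 0) next  # empty reference bin in the sample: skipped
      if (need > length(avail)) {
        shortfall[[b]] <- c(need = need, supply = length(avail))
        next
      }
      chosen <- c(chosen, meta$participant[sample(avail, need)])
    }
  })
  if (length(shortfall) > 0) {
    msg <- paste(vapply(names(shortfall), function(b)
      sprintf("%s: need %d, supply %d", b, shortfall[[b]]["need"],
              shortfall[[b]]["supply"]), character(1)), collapse = "; ")
    stop("stratified subsampling infeasible at targetN = ", targetN, ": ", msg)
  }
  chosen
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates (or reads) a cohort, fits the requested model families
#' under site-clustered nested cross-validation, inverts the best model
#' into predictive features, computes feature similarity and domain
#' clustering, cross-behavior transfer, and a permutation test of the
#' first measure; writes CSV outputs and a JSON run manifest.
#'
#' @param config a [cohortConfig()].
#' @param outDir output directory.
#' @param families model families to fit (default single-kernel on the
#'   first state, mean FC and multikernel).
#' @param measures measures to analyse (default all).
#' @param nPerm permutations for the accuracy test (default 99).
#' @param kTest held-out clusters per fold (default 3).
#' @param lambdaGrid ridge grid.
#' @param weightStep multikernel simplex step.
#' @return list with the per-family results, features, similarity,
#'   clusters, transfer table and manifest (also written to disk).
#' @export
runPipeline <- function(config = cohortConfig(), outDir,
                        families = c("single_kernel", "mean_fc", "multikernel"),
                        measures = NULL, nPerm = 99, kTest = 3,
                        lambdaGrid = defaultLambdaGrid(), weightStep = 0.25) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  cohort <- generateCohort(config)
  cset <- cohort$connectomes
  if (is.null(measures)) measures <- names(cohort$domains)
  Y <- as.matrix(cohort$behavior[, measures, drop = FALSE])
  clusters <- buildSiteClusters(colData(cset)$site,
                                nClusters = min(config$nSites, 10),
                                minSize = 150)

  results <- list()
  for (fam in families) {
    results[[fam]] <- nestedCV(cset, Y, family = fam, clusters = clusters,
                               kTest = kTest, lambdaGrid = lambdaGrid,
                               weightStep = weightStep)
  }
  accTab <- do.call(rbind, lapply(names(results), function(fam) {
    data.frame(family = fam, measure = measures,
               r = apply(results[[fam]]@r, 2, aggregateAccuracy),
               cod = colMeans(results[[fam]]@cod, na.rm = TRUE),
               row.names = NULL)
  }))
  write.csv(accTab, file.path(outDir, "accuracy.csv"), row.names = FALSE)

  best <- results[[families[length(families)]]]
  feats <- haufeInvert(cset, best)
  sim <- featureSimilarity(feats)
  write.csv(sim, file.path(outDir, "feature_similarity.csv"))
  cl <- clusterBehaviors(sim, k = length(unique(cohort$domains[measures])))
  write.csv(data.frame(measure = names(cl$clusters), cluster = cl$clusters),
            file.path(outDir, "behavior_clusters.csv"), row.names = FALSE)

  perm <- permutationNullAccuracy(cset, Y[, 1], nPerm = nPerm, seed = config$seed,
                                  family = families[1], clusters = clusters,
                                  kTest = kTest, lambdaGrid = lambdaGrid)
  domains <- cohort$domains[measures]
  target <- measures[1]
  same <- setdiff(measures[domains == domains[target]], target)
  diff <- measures[domains != domains[target]]
  transfer <- rbind(
    if (length(same)) cbind(crossBehaviorModelPredict(best, target, same),
                            donors = "same_domain"),
    if (length(diff)) cbind(crossBehaviorModelPredict(best, target, diff),
                            donors = "different_domain"))
  write.csv(transfer, file.path(outDir, "transfer.csv"), row.names = FALSE)

  manifest <- list(
    config = config[setdiff(names(config), "states")],
    states = config$states,
    families = families, nPerm = nPerm, kTest = kTest,
    nFolds = length(best@folds),
    permutationP = perm$p,
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, features = feats, similarity = sim,
                 clusters = cl, transfer = transfer, permutation = perm,
                 manifest = manifest))
}
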