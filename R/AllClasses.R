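#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData
NULL

#' One fMRI run of region-averaged time series with motion-quality traces
#'
#' Container for a single functional run: the frames-by-regions signal
#' matrix together with its per-frame framewise displacement (FD, mm),
#' DVARS trace and a censor mask (\code{TRUE} = frame usable).
#'
#' @slot signals numeric matrix, frames in rows, regions in columns.
#' @slot fd non-negative numeric, one value per frame (mm).
#' @slot dvars numeric, one value per frame.
#' @slot censorMask logical, one value per frame; \code{TRUE} marks a
#'   usable (non-censored) frame.
#'
#' @seealso [censorFrames()], [computeFC()], [runPassesQC()]
#' @export
setClass("ROITimeSeriesRun",
  representation(
    signals = "matrix",
    fd = "numeric",
    dvars = "numeric",
    censorMask = "logical"
  )
)

setValidity("ROITimeSeriesRun", function(object) {
  n <- nrow(object@signals)
  msg <- character()
  if (length(object@fd) != n) msg <- c(msg, "fd length must equal frame count")
  if (length(object@dvars) != n) msg <- c(msg, "dvars length must equal frame count")
  if (length(object@censorMask) != n) msg <- c(msg, "censorMask length must equal frame count")
  if (any(object@fd < 0)) msg <- c(msg, "fd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an ROITimeSeriesRun
#'
#' @param signals frames-by-regions numeric matrix.
#' @param fd per-frame framewise displacement (mm).
#' @param dvars per-frame DVARS.
#' @param censorMask optional logical mask (\code{TRUE} = usable). When
#'   \code{NULL} every frame is marked usable.
#' @return An [ROITimeSeriesRun-class] object.
#' @export
ROITimeSeriesRun <- function(signals, fd, dvars, censorMask = NULL) {
  signals <- as.matrix(signals)
  if (is.null(censorMask)) censorMask <- rep(TRUE, nrow(signals))
  new("ROITimeSeriesRun", signals = signals, fd = as.numeric(fd),
      dvars = as.numeric(dvars), censorMask = as.logical(censorMask))
}

#' @describeIn ROITimeSeriesRun-class brief display
#' @param object an \code{ROITimeSeriesRun}
#' @export
setMethod("show", "ROITimeSeriesRun", function(object) {
  cat(sprintf("ROITimeSeriesRun: %d frames x %d regions (%d usable frames)\n",
              nrow(object@signals), ncol(object@signals), sum(object@censorMask)))
})

#' A symmetric functional-connectivity matrix for one brain state
#'
#' Region-by-region Pearson correlation matrix computed over usable
#' frames, tagged with its acquisition state and the number of frames
#' that entered the correlation.
#'
#' @slot values symmetric numeric matrix with unit diagonal, entries in
#'   \eqn{[-1, 1]}.
#' @slot state character state name (e.g. "rest", "nback").
#' @slot nFramesUsed integer count of frames used.
#'
#' @export
setClass("FCMatrix",
  representation(values = "matrix", state = "character",
                 nFramesUsed = "integer")
)

setValidity("FCMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  else {
    if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "values must be symmetric")
    if (max(abs(diag(v) - 1)) > 1e-8) msg <- c(msg, "diagonal must be 1")
    if (any(v < -1 - 1e-12 | v > 1 + 1e-12)) msg <- c(msg, "entries must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an FCMatrix
#' @param values symmetric correlation matrix (unit diagonal).
#' @param state state name.
#' @param nFramesUsed number of frames the correlations were computed on.
#' @return An [FCMatrix-class] object.
#' @export
FCMatrix <- function(values, state = "unknown", nFramesUsed = nrow(values)) {
  values <- as.matrix(values)
  values <- (values + t(values)) / 2
  diag(values) <- 1
  new("FCMatrix", values = values, state = as.character(state),
      nFramesUsed = as.integer(nFramesUsed))
}

#' @describeIn FCMatrix-class brief display
#' @param object an \code{FCMatrix}
#' @export
setMethod("show", "FCMatrix", function(object) {
  cat(sprintf("FCMatrix (%s): %d x %d, %d frames used\n", object@state,
              nrow(object@values), ncol(object@values), object@nFramesUsed))
})

#' Multi-state connectome collection for a cohort
#'
#' Extends \code{SummarizedExperiment}: one assay per brain state, each an
#' edges-by-participants matrix of vectorized functional connectivity
#' (strict lower triangle, row-major — see [vectorizeFC()]). \code{colData}
#' carries the cohort table (site, motion summaries, demographics);
#' \code{rowData} the two region endpoints of every edge; \code{metadata}
#' the region names and the region-to-network labeling.
#'
#' @seealso [ConnectomeSet()], [generateCohort()], [nestedCV()]
#' @export
setClass("ConnectomeSet", contains = "SummarizedExperiment")

setValidity("ConnectomeSet", function(object) {
  msg <- character()
  rn <- metadata(object)$regionNames
  if (is.null(rn)) return("metadata must contain regionNames")
  R <- length(rn)
  if (nrow(object) != R * (R - 1) / 2)
    msg <- c(msg, sprintf("edge count %d does not match %d regions", nrow(object), R))
  if (length(assays(object)) < 1) msg <- c(msg, "at least one state assay required")
  lab <- metadata(object)$networkLabels
  if (!is.null(lab) && !all(rn %in% names(lab)))
    msg <- c(msg, "networkLabels must cover every region")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicated participant ids")
  if (length(msg)) msg else TRUE
})

#' Construct a ConnectomeSet
#'
#' @param edges named list of edges-by-participants matrices, one per
#'   brain state, identical dimensions; values on the correlation scale.
#' @param meta data.frame of per-participant covariates (one row per
#'   participant, in assay column order); must contain a \code{participant}
#'   column used as column names.
#' @param regionNames character vector of region names (length R, where
#'   each assay has R(R-1)/2 rows).
#' @param networkLabels optional named character/factor mapping region
#'   name to network group.
#' @return A [ConnectomeSet-class].
#' @export
ConnectomeSet <- function(edges, meta, regionNames, networkLabels = NULL) {
  stopifnot(is.list(edges), length(edges) >= 1, !is.null(names(edges)))
  edges <- lapply(edges, as.matrix)
  ids <- as.character(meta$participant)
  edges <- lapply(edges, function(m) { colnames(m) <- ids; m })
  R <- length(regionNames)
  pairs <- edgePairs(R)
  rd <- DataFrame(regionA = regionNames[pairs$i], regionB = regionNames[pairs$j])
  se <- SummarizedExperiment(
    assays = edges,
    rowData = rd,
    colData = DataFrame(meta, row.names = ids)
  )
  md <- list(regionNames = regionNames)
  if (!is.null(networkLabels)) md$networkLabels <- networkLabels
  se@metadata <- md
  new("ConnectomeSet", se)
}

#' @describeIn ConnectomeSet-class number of brain regions
#' @param x a \code{ConnectomeSet}
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @export
setMethod("nRegions", "ConnectomeSet", function(x) length(metadata(x)$regionNames))

#' @describeIn ConnectomeSet-class region names
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' @export
setMethod("regionNames", "ConnectomeSet", function(x) metadata(x)$regionNames)

#' @describeIn ConnectomeSet-class region-to-network labeling (named vector)
#' @export
setGeneric("networkLabels", function(x) standardGeneric("networkLabels"))

#' @export
setMethod("networkLabels", "ConnectomeSet", function(x) metadata(x)$networkLabels)

#' Brain-state names of a ConnectomeSet
#' @param x a \code{ConnectomeSet}
#' @return character vector of state (assay) names.
#' @export
stateNames <- function(x) assayNames(x)

#' Extract one state's edge matrix
#' @param x a \code{ConnectomeSet}
#' @param state state name or index.
#' @return edges-by-participants numeric matrix.
#' @export
edgeMatrix <- function(x, state) assay(x, state)

#' Reconstruct one participant's FC matrix for a state
#' @param x a \code{ConnectomeSet}
#' @param participant participant id or column index.
#' @param state state name or index.
#' @return An [FCMatrix-class].
#' @export
fcMatrix <- function(x, participant, state) {
  v <- assay(x, state)[, participant]
  m <- devectorizeFC(v)
  dimnames(m) <- list(regionNames(x), regionNames(x))
  FCMatrix(m, state = if (is.character(state)) state else stateNames(x)[state])
}

#' @export
setMethod("show", "ConnectomeSet", function(object) {
  cat(sprintf("ConnectomeSet: %d regions (%d edges) x %d participants\n",
              nRegions(object), nrow(object), ncol(object)))
  cat("  states:", paste(stateNames(object), collapse = ", "), "\n")
  lab <- networkLabels(object)
  if (!is.null(lab))
    cat(sprintf("  networks: %d groups\n", length(unique(lab))))
  if ("site" %in% colnames(colData(object)))
    cat(sprintf("  sites: %d\n", length(unique(colData(object)$site))))
})

#' Nested cross-validation prediction results
#'
#' Per-fold predictions, accuracies and selected hyperparameters from
#' [nestedCV()]. Accuracy matrices are folds-by-measures.
#'
#' @slot family model family ("single_kernel", "multikernel", "mean_fc"
#'   or "linear_ridge").
#' @slot states states entering the kernel(s).
#' @slot measures behavioral measure names (columns of the target matrix).
#' @slot folds list of fold specifications (test cluster ids).
#' @slot clusters integer site-cluster assignment per participant.
#' @slot r folds-by-measures matrix of test Pearson accuracies.
#' @slot cod folds-by-measures matrix of coefficients of determination.
#' @slot lambda folds-by-measures matrix of selected ridge penalties.
#' @slot weights selected kernel weights, folds x measures x states array
#'   (or 0-length array for single-kernel families).
#' @slot predictions per-fold list: test ids, observed (residualized) and
#'   predicted matrices; empty if not retained.
#' @slot trainFitted per-fold list of training-set fitted values (needed
#'   for Haufe inversion); empty if not retained.
#' @slot trainMeans folds-by-measures matrix of training means of the
#'   residualized targets (the COD baseline).
#'
#' @export
setClass("PredictionResult",
  representation(
    family = "character", states = "character", measures = "character",
    folds = "list", clusters = "integer",
    r = "matrix", cod = "matrix", lambda = "matrix", weights = "array",
    predictions = "list", trainFitted = "list", trainMeans = "matrix"
  )
)

#' @describeIn PredictionResult-class summary display
#' @param object a \code{PredictionResult}
#' @export
setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult (%s): %d folds x %d measure(s)\n",
              object@family, length(object@folds), length(object@measures)))
  rbar <- apply(object@r, 2, aggregateAccuracy)
  show_n <- min(8L, length(rbar))
  cat("  Fisher-mean r:",
      paste(sprintf("%s=%.3f", object@measures[seq_len(show_n)], rbar[seq_len(show_n)]),
            collapse = ", "),
      if (length(rbar) > show_n) "..." else "", "\n")
})

#' Per-fold accuracies as a data.frame
#' @param object a [PredictionResult-class]
#' @return long data.frame with fold, measure, r, cod, lambda.
#' @export
foldAccuracy <- function(object) {
  stopifnot(is(object, "PredictionResult"))
  K <- length(object@folds); m <- length(object@measures)
  data.frame(
    fold = rep(seq_len(K), times = m),
    measure = rep(object@measures, each = K),
    r = as.vector(object@r),
    cod = as.vector(object@cod),
    lambda = as.vector(object@lambda)
  )
}

#' Edge-level predictive-feature matrices from Haufe inversion
#'
#' For each brain state, an edges-by-measures matrix of predictive
#' features: the training-set covariance between each edge's connectivity
#' and the model's predicted target, averaged across cross-validation
#' folds. Positive values mean higher connectivity predicts higher
#' behavioral scores.
#'
#' @slot features named list (one per state) of edges-by-measures
#'   matrices.
#' @slot states state names.
#' @slot measures behavioral measure names.
#' @slot regionNames region names (defines the edge ordering).
#' @slot provenance list describing the model the features came from.
#'
#' @seealso [haufeInvert()], [featureMatrix()]
#' @export
setClass("PredictiveFeatures",
  representation(features = "list", states = "character",
                 measures = "character", regionNames = "character",
                 provenance = "list")
)

#' @describeIn PredictiveFeatures-class summary display
#' @param object a \code{PredictiveFeatures}
#' @export
setMethod("show", "PredictiveFeatures", function(object) {
  cat(sprintf("PredictiveFeatures: %d state(s) x %d measure(s), %d regions\n",
              length(object@states), length(object@measures),
              length(object@regionNames)))
})

#' Extract one behavior-state predictive-feature matrix
#' @param object a [PredictiveFeatures-class]
#' @param state state name.
#' @param measure measure name or index.
#' @return symmetric region-by-region matrix, zero diagonal.
#' @export
featureMatrix <- function(object, state, measure) {
  v <- object@features[[state]][, measure]
  m <- devectorizeFC(v, diagValue = 0)
  dimnames(m) <- list(object@regionNames, object@regionNames)
  m
}
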