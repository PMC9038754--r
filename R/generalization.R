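#' Cross-behavior model transfer
#'
#' Predicts a target behavior by averaging the test-set predictions of
#' models fitted to other (donor) behaviors on the same folds: each
#' donor's predictions are z-scored within the fold, averaged across
#' donors, and correlated with the target's residualized observed
#' values. The donor set never includes the target.
#'
#' @param result a multi-measure [PredictionResult-class] with retained
#'   predictions (all measures fitted on identical folds).
#' @param target target measure name.
#' @param donors donor measure names (must exclude the target).
#' @return data.frame with fold and r (per-fold transfer accuracy).
#' @export
crossBehaviorModelPredict <- function(result, target, donors) {
  if (length(donors) == 0) stop("empty donor set")
  if (target %in% donors) stop("donor set must exclude the target")
  stopifnot(all(c(target, donors) %in% result@measures))
  if (length(result@predictions) == 0)
    stop("result has no retained predictions")
  K <- length(result@folds)
  r <- vapply(seq_len(K), function(f) {
    pr <- result@predictions[[f]]
    donorPred <- pr$predicted[, donors, drop = FALSE]
    donorZ <- apply(donorPred, 2, function(v) {
      s <- sd(v); if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
    combined <- rowMeans(donorZ)
    obs <- pr$observed[, target]
    if (sd(combined) == 0 || sd(obs) == 0) NA_real_ else cor(combined, obs)
  }, numeric(1))
  data.frame(fold = seq_len(K), r = r)
}

#' Cross-behavior feature transfer (aggregate-FC predictor)
#'
#' Predicts a target behavior from donor predictive features alone: the
#' donors' fold-specific Haufe features are averaged across donors and
#' across all brain states, the top fraction of edges by absolute
#' feature value is selected (training-fold information only), and each
#' test participant's prediction is the mean connectivity over selected
#' positive-feature edges minus the mean over selected negative-feature
#' edges. The aggregate is scale-free: accuracy is the Pearson
#' correlation with the observed target.
#'
#' @param cset the [ConnectomeSet-class].
#' @param result a multi-measure [PredictionResult-class] with retained
#'   predictions and training fitted values.
#' @param target target measure name.
#' @param donors donor measure names (exclude the target).
#' @param topFrac fraction of edges selected (default 0.10).
#' @param states states averaged into the donor features and into each
#'   participant's connectivity (default all; participant FC is the
#'   Fisher-mean across them).
#' @param donorFeatureVector optional externally supplied edge-level
#'   donor feature vector used for every fold instead of the
#'   fold-specific Haufe average (e.g. ground-truth effects in
#'   validation studies).
#' @return data.frame with fold and r.
#' @export
crossBehaviorFeaturePredict <- function(cset, result, target, donors,
                                        topFrac = 0.10,
                                        states = stateNames(cset),
                                        donorFeatureVector = NULL) {
  if (length(donors) == 0) stop("empty donor set")
  if (target %in% donors) stop("donor set must exclude the target")
  stopifnot(all(c(target, donors) %in% result@measures))
  if (length(result@trainFitted) == 0 || length(result@predictions) == 0)
    stop("result must retain predictions and training fitted values")
  edgesList <- featureEdges(cset, states)
  z <- Reduce(`+`, lapply(edgesList, fisherZ))
  X <- fisherInv(z / length(edgesList))
  E <- nrow(cset)
  nSel <- max(1L, round(topFrac * E))
  K <- length(result@folds)
  r <- vapply(seq_len(K), function(f) {
    avg <- if (is.null(donorFeatureVector)) {
      tf <- result@trainFitted[[f]]
      ff <- haufeFold(edgesList, tf$trainIdx,
                      tf$fitted[, donors, drop = FALSE])
      rowMeans(do.call(cbind, lapply(ff, rowMeans)))
    } else donorFeatureVector
    sel <- order(-abs(avg), seq_len(E))[seq_len(nSel)]
    pos <- sel[avg[sel] > 0]; neg <- sel[avg[sel] < 0]
    if (length(pos) == 0 || length(neg) == 0)
      warning("all selected edges carry one sign; absent-sign mean set to 0")
    pr <- result@predictions[[f]]
    Xt <- X[, pr$testIdx, drop = FALSE]
    agg <- (if (length(pos)) colMeans(Xt[pos, , drop = FALSE]) else 0) -
           (if (length(neg)) colMeans(Xt[neg, , drop = FALSE]) else 0)
    obs <- pr$observed[, target]
    if (sd(agg) == 0 || sd(obs) == 0) NA_real_ else cor(agg, obs)
  }, numeric(1))
  data.frame(fold = seq_len(K), r = r)
}
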