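#' Edge ordering of vectorized connectivity
#'
#' The canonical edge ordering used throughout the package is the strict
#' lower triangle of the symmetric FC matrix read row by row, i.e. edges
#' (2,1); (3,1), (3,2); (4,1), (4,2), (4,3); ... For a symmetric matrix
#' this equals the upper triangle read column by column, which is how R
#' stores \code{m[upper.tri(m)]}.
#'
#' @param nRegions number of regions R.
#' @return data.frame with columns \code{i}, \code{j} (region indices,
#'   \code{i < j}) of length R(R-1)/2, in canonical edge order.
#' @export
edgePairs <- function(nRegions) {
  j <- rep.int(2:nRegions, 1:(nRegions - 1))
  i <- sequence(1:(nRegions - 1))
  data.frame(i = i, j = j)
}

#' Vectorize a symmetric FC matrix into its canonical edge vector
#'
#' @param fc an [FCMatrix-class] or a symmetric numeric matrix.
#' @param tol symmetry tolerance.
#' @return numeric vector of length R(R-1)/2 in canonical edge order
#'   (see [edgePairs()]).
#' @export
vectorizeFC <- function(fc, tol = 1e-8) {
  m <- if (is(fc, "FCMatrix")) fc@values else as.matrix(fc)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > tol)
    stop("matrix is asymmetric beyond tolerance; cannot vectorize")
  m[upper.tri(m)]
}

#' Rebuild a symmetric matrix from a canonical edge vector
#'
#' Inverse of [vectorizeFC()].
#'
#' @param v edge vector of length R(R-1)/2.
#' @param diagValue value placed on the diagonal (1 for correlation
#'   matrices, 0 for feature matrices).
#' @return symmetric R-by-R matrix.
#' @export
devectorizeFC <- function(v, diagValue = 1) {
  E <- length(v)
  R <- (1 + sqrt(1 + 8 * E)) / 2
  if (abs(R - round(R)) > 1e-9) stop("length is not R(R-1)/2 for integer R")
  R <- as.integer(round(R))
  m <- matrix(0, R, R)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diagValue
  m
}

#' Motion-based frame censoring
#'
#' Frames whose framewise displacement exceeds \code{fdThresh} (mm) or
#' whose DVARS exceeds \code{dvarsThresh} are marked as outliers, together
#' with \code{nBefore} frames before and \code{nAfter} frames after each
#' outlier (clipped at run boundaries). Any remaining stretch of usable
#' frames shorter than \code{minSegment} contiguous volumes is also
#' censored.
#'
#' @param fd per-frame framewise displacement (mm).
#' @param dvars per-frame DVARS.
#' @param fdThresh FD threshold, default 0.3 mm.
#' @param dvarsThresh DVARS threshold, default 50.
#' @param nBefore frames censored before each outlier, default 1.
#' @param nAfter frames censored after each outlier, default 2.
#' @param minSegment minimum usable segment length, default 5.
#' @return logical censor mask, \code{TRUE} = usable frame.
#' @export
censorFrames <- function(fd, dvars, fdThresh = 0.3, dvarsThresh = 50,
                         nBefore = 1L, nAfter = 2L, minSegment = 5L) {
  n <- length(fd)
  if (n == 0) stop("empty motion traces")
  if (length(dvars) != n) stop("fd and dvars must have the same length")
  bad <- fd > fdThresh | dvars > dvarsThresh
  if (any(bad)) {
    idx <- which(bad)
    spans <- unlist(lapply(idx, function(k) seq(k - nBefore, k + nAfter)))
    spans <- spans[spans >= 1 & spans <= n]
    bad[spans] <- TRUE
  }
  # censor short surviving segments
  runs <- rle(!bad)
  pos <- cumsum(c(1L, runs$lengths))
  for (k in seq_along(runs$lengths)) {
    if (runs$values[k] && runs$lengths[k] < minSegment) {
      bad[seq(pos[k], length.out = runs$lengths[k])] <- TRUE
    }
  }
  !bad
}

#' Run-level quality control
#'
#' A run fails when more than \code{maxCensoredFrac} of its volumes are
#' censored or its maximum FD exceeds \code{maxFd} mm.
#'
#' @param mask logical censor mask from [censorFrames()].
#' @param fd per-frame FD (mm).
#' @param maxCensoredFrac maximum tolerated censored fraction, default 0.5.
#' @param maxFd maximum tolerated FD, default 5 mm.
#' @return \code{TRUE} if the run is kept.
#' @export
runPassesQC <- function(mask, fd, maxCensoredFrac = 0.5, maxFd = 5.0) {
  stopifnot(length(mask) == length(fd))
  censoredFrac <- mean(!mask)
  censoredFrac <= maxCensoredFrac && max(fd) <= maxFd
}

#' State-level quality control (minimum usable scan time)
#'
#' A brain state is kept only if its surviving runs together retain at
#' least \code{minSeconds} of usable data.
#'
#' @param masks list of censor masks, one per surviving run.
#' @param trSeconds repetition time in seconds.
#' @param minSeconds minimum usable time, default 240 s (4 minutes).
#' @return \code{TRUE} if the state is kept.
#' @export
statePassesQC <- function(masks, trSeconds, minSeconds = 240) {
  if (length(masks) == 0) return(FALSE)
  usable <- sum(vapply(masks, sum, integer(1)))
  usable * trSeconds >= minSeconds
}

#' Pearson FC over usable frames
#'
#' Computes the region-by-region Pearson correlation matrix of a run's
#' average time series, ignoring censored frames.
#'
#' @param run an [ROITimeSeriesRun-class].
#' @param state state name stored on the result.
#' @return An [FCMatrix-class].
#' @export
computeFC <- function(run, state = "unknown") {
  stopifnot(is(run, "ROITimeSeriesRun"))
  x <- run@signals[run@censorMask, , drop = FALSE]
  if (nrow(x) < 3) stop("fewer than 3 usable frames")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- colnames(x)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("constant region(s) over usable frames: ", paste(nm, collapse = ", "))
  }
  FCMatrix(cor(x), state = state, nFramesUsed = nrow(x))
}

#' Fisher-z average of FC matrices across runs
#'
#' Correlations are r-to-z transformed (with clipping near +/-1),
#' averaged elementwise, and transformed back; the diagonal is reset to 1.
#'
#' @param runs list of [FCMatrix-class] objects (or plain matrices) of
#'   identical dimension.
#' @return An [FCMatrix-class]; \code{nFramesUsed} is the total across
#'   runs.
#' @export
averageFC <- function(runs) {
  if (length(runs) < 1) stop("need at least one run")
  mats <- lapply(runs, function(r) if (is(r, "FCMatrix")) r@values else as.matrix(r))
  dims <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1 ||
      length(unique(vapply(mats, ncol, integer(1)))) != 1)
    stop("mismatched FC matrix shapes")
  z <- Reduce(`+`, lapply(mats, fisherZ)) / length(mats)
  out <- fisherInv(z)
  diag(out) <- 1
  nf <- sum(vapply(runs, function(r) if (is(r, "FCMatrix")) r@nFramesUsed else 0L,
                   numeric(1)))
  state <- if (is(runs[[1]], "FCMatrix")) runs[[1]]@state else "unknown"
  FCMatrix(out, state = state, nFramesUsed = nf)
}

#' Assemble a state's FC from its runs with full quality control
#'
#' Convenience wrapper: censors each run, drops runs failing QC, checks
#' the minimum usable time, computes per-run FC and Fisher-averages.
#'
#' @param runs list of [ROITimeSeriesRun-class] (censor masks are
#'   recomputed from the FD/DVARS traces).
#' @param trSeconds repetition time (s).
#' @param state state name.
#' @param ... thresholds passed to [censorFrames()].
#' @return An [FCMatrix-class], or \code{NULL} when the state fails QC.
#' @export
stateFC <- function(runs, trSeconds, state = "unknown", ...) {
  censored <- lapply(runs, function(r) {
    mask <- censorFrames(r@fd, r@dvars, ...)
    ROITimeSeriesRun(r@signals, r@fd, r@dvars, mask)
  })
  keep <- vapply(censored, function(r) runPassesQC(r@censorMask, r@fd), logical(1))
  censored <- censored[keep]
  if (!statePassesQC(lapply(censored, function(r) r@censorMask), trSeconds))
    return(NULL)
  averageFC(lapply(censored, computeFC, state = state))
}

#' Network-block averaging of an edge-level matrix
#'
#' Averages a symmetric region-by-region matrix within and between
#' network groups: block (a, b) is the mean over all unique off-diagonal
#' region pairs with one endpoint in group a and the other in group b
#' (for a = b, unique pairs inside the group, no double counting). A
#' singleton group has no within-group pair; its diagonal block is
#' \code{NA} and flagged.
#'
#' @param mat symmetric region-by-region matrix (diagonal ignored).
#' @param labels region-to-group labeling: either a vector of group
#'   labels in region order, or a named vector matching rownames.
#' @return symmetric G-by-G matrix of block means with group dimnames;
#'   attribute \code{"nMissing"} counts undefined blocks.
#' @export
blockAverage <- function(mat, labels) {
  mat <- as.matrix(mat)
  R <- nrow(mat)
  if (!is.null(names(labels)) && !is.null(rownames(mat))) {
    if (!all(rownames(mat) %in% names(labels)))
      stop("labels must cover all regions")
    labels <- labels[rownames(mat)]
  }
  if (length(labels) != R) stop("labels must cover all regions")
  g <- as.factor(labels)
  groups <- levels(g)
  G <- length(groups)
  gi <- as.integer(g)
  pairs <- edgePairs(R)
  v <- mat[upper.tri(mat)]
  a <- pmin(gi[pairs$i], gi[pairs$j])
  b <- pmax(gi[pairs$i], gi[pairs$j])
  key <- (a - 1L) * G + b
  sums <- tapply(v, key, mean)
  out <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
  kk <- as.integer(names(sums))
  ai <- (kk - 1L) %/% G + 1L
  bi <- (kk - 1L) %% G + 1L
  out[cbind(ai, bi)] <- sums
  out[cbind(bi, ai)] <- sums
  attr(out, "nMissing") <- sum(is.na(out[upper.tri(out, diag = TRUE)]))
  out
}

#' Unique block values of a symmetric block matrix
#'
#' @param blocks G-by-G symmetric matrix from [blockAverage()].
#' @return vector of the G(G+1)/2 unique block values (upper triangle
#'   including the diagonal, column-major).
#' @export
uniqueBlocks <- function(blocks) blocks[upper.tri(blocks, diag = TRUE)]
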