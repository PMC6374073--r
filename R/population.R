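#' Voxelwise correlation map
#'
#' Pearson correlation of each voxel's time course with a regressor.
#' Zero-variance voxels get r = 0 and are flagged.
#'
#' @param signals numeric matrix, time x voxels (or list of
#'   [TimeSeries-class]).
#' @param regressor numeric vector or [TimeSeries-class] on the same clock.
#' @return list: `r` (per-voxel correlations), `flagged` (zero-variance
#'   voxel indices).
#' @export
correlationMap <- function(signals, regressor) {
  if (is.list(signals))
    signals <- vapply(signals, tsValues, numeric(length(signals[[1]])))
  y <- if (is(regressor, "TimeSeries")) tsValues(regressor)
       else as.numeric(regressor)
  stopifnot(nrow(signals) == length(y))
  sds <- apply(signals, 2, stats::sd)
  flagged <- unname(which(sds == 0 | !is.finite(sds)))
  r <- suppressWarnings(as.numeric(stats::cor(signals, y)))
  r[flagged] <- 0
  list(r = r, flagged = flagged)
}

#' Sensory-versus-motor preference map
#'
#' Labels each pixel sensory when the sensory map exceeds the motor map by
#' at least `minDistance`, motor for the converse, and neutral when the
#' difference is below the minimum distance.
#'
#' @param sensoryMap,motorMap numeric arrays of equal shape.
#' @param minDistance minimum difference for a non-neutral label.
#' @return character array of labels ("sensory", "motor", "neutral").
#' @export
preferenceMap <- function(sensoryMap, motorMap, minDistance = 0.2) {
  if (!identical(dim(sensoryMap), dim(motorMap)) ||
      length(sensoryMap) != length(motorMap))
    stop("maps must have identical shape")
  d <- sensoryMap - motorMap
  out <- ifelse(d >= minDistance, "sensory",
                ifelse(-d >= minDistance, "motor", "neutral"))
  if (!is.null(dim(sensoryMap))) dim(out) <- dim(sensoryMap)
  out
}

#' PCA and k-means functional clustering of response vectors
#'
#' PCA on the centered per-ROI feature vectors (correlations with all
#' regressors, or coefficient weights), then k-means on the first `nPC`
#' scores with a fixed seed and multiple restarts.
#'
#' @param features numeric matrix, ROIs x features.
#' @param nPC number of principal components kept (default 10).
#' @param k number of clusters (default 10).
#' @param seed RNG seed for k-means restarts.
#' @param nStart k-means restarts.
#' @return list of class "ClusterReport": `labels`, `varianceExplained`,
#'   `scores`, `centers`, `k`.
#' @export
pcaKmeans <- function(features, nPC = 10, k = 10, seed = 7, nStart = 50) {
  features <- as.matrix(features)
  if (nrow(features) < k) stop("need at least k ROIs")
  if (all(apply(features, 2, stats::sd) < .Machine$double.eps))
    stop("degenerate input: identical feature vectors")
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  nPC <- min(nPC, ncol(pc$x))
  km <- .withSeed(seed,
    stats::kmeans(pc$x[, seq_len(nPC), drop = FALSE], centers = k,
                  nstart = nStart, iter.max = 100))
  structure(list(labels = km$cluster, varianceExplained = ve,
                 scores = pc$x, centers = km$centers, k = k),
            class = "ClusterReport")
}

#' @export
print.ClusterReport <- function(x, ...) {
  cat(sprintf("ClusterReport: %d ROIs in %d clusters; top-%d PCs explain %.0f%%\n",
              length(x$labels), x$k, min(10, length(x$varianceExplained)),
              100 * sum(x$varianceExplained[seq_len(min(10,
                length(x$varianceExplained)))])))
  invisible(x)
}

# Mean pairwise distance within a set of rows.
.meanPairDist <- function(xy) {
  if (nrow(xy) < 2) return(NA_real_)
  mean(stats::dist(xy))
}

#' Anatomical clustering index
#'
#' For each cluster and fish: the average distance between an ROI of the
#' cluster and a randomly chosen ROI of that fish (computed exactly as the
#' mean over all other ROIs), divided by the average within-cluster
#' distance in that fish. Values above 1 indicate spatial clustering;
#' 1 is chance. Fish are averaged with equal weight.
#'
#' @param labels cluster labels per ROI.
#' @param coords ROI coordinates (n x 3 matrix, um).
#' @param fishIds fish identifier per ROI.
#' @param monteCarlo if > 0, estimate the random-ROI distance from this
#'   many random draws instead of the exact mean.
#' @return named numeric: index per cluster (NA when no fish has >= 2
#'   cluster members).
#' @export
anatomicalClusteringIndex <- function(labels, coords, fishIds = NULL,
                                      monteCarlo = 0) {
  coords <- as.matrix(coords)
  if (is.null(fishIds)) fishIds <- rep(1L, nrow(coords))
  out <- c()
  for (cl in sort(unique(labels))) {
    perFish <- c()
    for (f in unique(fishIds)) {
      inF <- fishIds == f
      inC <- inF & labels == cl
      if (sum(inC) < 2 || sum(inF) < 3) next
      within <- .meanPairDist(coords[inC, , drop = FALSE])
      if (!is.finite(within) || within == 0) next
      idxC <- which(inC); idxF <- which(inF)
      rnd <- mean(vapply(idxC, function(i) {
        others <- setdiff(idxF, i)
        if (monteCarlo > 0)
          others <- sample(others, monteCarlo, replace = TRUE)
        mean(sqrt(colSums((t(coords[others, , drop = FALSE]) -
                             coords[i, ])^2)))
      }, numeric(1)))
      perFish <- c(perFish, rnd / within)
    }
    out[as.character(cl)] <- if (length(perFish)) mean(perFish) else NA_real_
  }
  out
}

#' Stereotypy index
#'
#' Cross-fish positional consistency of a cluster: the average distance
#' between an ROI of the cluster and ROIs of other clusters in other fish,
#' divided by the average distance to ROIs of the same cluster in other
#' fish. Requires coordinates registered to a shared reference frame.
#' Values above 1 indicate stereotypy; clusters confined to one fish are
#' skipped (NA).
#'
#' @inheritParams anatomicalClusteringIndex
#' @return named numeric: index per cluster.
#' @export
stereotypyIndex <- function(labels, coords, fishIds) {
  coords <- as.matrix(coords)
  out <- c()
  for (cl in sort(unique(labels))) {
    perFish <- c()
    for (f in unique(fishIds)) {
      inC <- fishIds == f & labels == cl
      otherSame <- fishIds != f & labels == cl
      otherDiff <- fishIds != f & labels != cl
      if (!sum(inC) || !sum(otherSame) || !sum(otherDiff)) next
      same <- mean(vapply(which(inC), function(i)
        mean(sqrt(colSums((t(coords[otherSame, , drop = FALSE]) -
                             coords[i, ])^2))), numeric(1)))
      diffd <- mean(vapply(which(inC), function(i)
        mean(sqrt(colSums((t(coords[otherDiff, , drop = FALSE]) -
                             coords[i, ])^2))), numeric(1)))
      if (same > 0) perFish <- c(perFish, diffd / same)
    }
    out[as.character(cl)] <- if (length(perFish)) mean(perFish) else NA_real_
  }
  out
}
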