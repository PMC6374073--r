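#' Count nuclei by 3D spherical-Gaussian template matching
#'
#' Computes the zero-normalized cross-correlation of the volume with a
#' spherical Gaussian template (FFT-based), then takes local maxima above
#' the score threshold with greedy non-maximum suppression at
#' `minSeparation`.
#'
#' @param volume 3D numeric array.
#' @param sigma template standard deviation, voxels.
#' @param threshold minimum normalized correlation score (in [-1, 1]).
#' @param minSeparation minimum distance between detections, voxels.
#' @return list of class "NucleiDetection": `centroids` (n x 3 voxel
#'   coordinates), `count`, `scores`, `sigma`.
#' @export
countNuclei <- function(volume, sigma = 2, threshold = 0.3,
                        minSeparation = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  dims <- dim(volume)
  if (length(dims) != 3) stop("volume must be a 3D array")
  r <- ceiling(3 * sigma)
  if (any(dims < 2 * r + 1)) stop("sigma too large for the volume")
  if (is.null(minSeparation)) minSeparation <- 3 * sigma
  ax <- (-r):r
  g1 <- exp(-ax^2 / (2 * sigma^2))
  tmpl <- outer(outer(g1, g1), g1)
  tmpl <- tmpl - mean(tmpl)
  nt <- length(tmpl)
  tnorm <- sqrt(sum(tmpl^2))
  # FFT cross-correlation with the template wrapped so its center sits at
  # the origin: the correlation at voxel i is then the window centered at i
  padCentered <- function(a) {
    out <- array(0, dims)
    ix <- ((-r):r %% dims[1]) + 1
    iy <- ((-r):r %% dims[2]) + 1
    iz <- ((-r):r %% dims[3]) + 1
    out[ix, iy, iz] <- a
    out
  }
  Fv <- stats::fft(volume)
  Ft <- stats::fft(padCentered(tmpl))
  num <- Re(stats::fft(Fv * Conj(Ft), inverse = TRUE)) / prod(dims)
  ones <- padCentered(array(1, dim = c(2 * r + 1, 2 * r + 1, 2 * r + 1)))
  Fo <- stats::fft(ones)
  locSum <- Re(stats::fft(Fv * Conj(Fo), inverse = TRUE)) / prod(dims)
  locSum2 <- Re(stats::fft(stats::fft(volume^2) * Conj(Fo),
                           inverse = TRUE)) / prod(dims)
  locVar <- pmax(locSum2 - locSum^2 / nt, 0)
  score <- num / (tnorm * sqrt(locVar))
  score[locVar < .Machine$double.eps] <- 0
  # discard margins where the window wraps
  valid <- array(FALSE, dims)
  valid[(r + 1):(dims[1] - r), (r + 1):(dims[2] - r),
        (r + 1):(dims[3] - r)] <- TRUE
  score[!valid] <- -Inf
  cand <- which(score > threshold)
  if (!length(cand))
    return(structure(list(centroids = matrix(numeric(0), 0, 3), count = 0L,
                          scores = numeric(0), sigma = sigma),
                     class = "NucleiDetection"))
  sc <- score[cand]
  o <- order(sc, decreasing = TRUE)
  cand <- cand[o]; sc <- sc[o]
  xyz <- cbind((cand - 1) %% dims[1] + 1,
               ((cand - 1) %/% dims[1]) %% dims[2] + 1,
               (cand - 1) %/% (dims[1] * dims[2]) + 1)
  keep <- logical(length(cand))
  sel <- matrix(numeric(0), 0, 3)
  for (i in seq_along(cand)) {
    p <- xyz[i, ]
    if (!nrow(sel) ||
        min(sqrt(colSums((t(sel) - p)^2))) >= minSeparation) {
      keep[i] <- TRUE
      sel <- rbind(sel, p)
    }
  }
  structure(list(centroids = xyz[keep, , drop = FALSE],
                 count = sum(keep), scores = sc[keep], sigma = sigma),
            class = "NucleiDetection")
}

#' @export
print.NucleiDetection <- function(x, ...) {
  cat(sprintf("NucleiDetection: %d nuclei (sigma = %g voxels)\n",
              x$count, x$sigma))
  invisible(x)
}

#' Dendritic planarity from a 3D point set
#'
#' Ratio of the third to the second principal component of the point
#' covariance. Planar point sets give ratios approaching 0, isotropic sets
#' approach 1. By default the ratio of eigenvalues (variances); use
#' `type = "sd"` for the singular-value (standard deviation) convention.
#'
#' @param points n x 3 matrix of coordinates.
#' @param type "variance" (eigenvalue ratio, default) or "sd".
#' @return ratio in [0, 1].
#' @export
planarity <- function(points, type = c("variance", "sd")) {
  type <- match.arg(type)
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  ev <- eigen(stats::cov(points), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (ev[2] < max(ev[1], 1) * 1e-12)
    stop("degenerate (collinear) point set: second principal component ",
         "has no variance")
  r <- ev[3] / ev[2]
  if (type == "sd") sqrt(r) else r
}

#' Read an SWC morphology file
#'
#' @param path SWC file path.
#' @return data.frame with columns id, type, x, y, z, radius, parent.
#' @export
readSWC <- function(path) {
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("id", "type", "x", "y", "z",
                                       "radius", "parent"))
  d
}

#' Write an SWC morphology file
#'
#' @param points n x 3 coordinate matrix (a chain topology is written).
#' @param path output path.
#' @param radius node radius.
#' @export
writeSWC <- function(points, path, radius = 0.5) {
  n <- nrow(points)
  d <- data.frame(id = seq_len(n), type = 3, x = points[, 1],
                  y = points[, 2], z = points[, 3], radius = radius,
                  parent = c(-1, seq_len(n - 1)))
  utils::write.table(d, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
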