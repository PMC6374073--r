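#' GCaMP response kernel specification
#'
#' @param tau decay constant, s (default 1.6).
#' @return list of class "KernelSpec".
#' @export
kernelSpec <- function(tau = 1.6) {
  if (tau <= 0) stop("tau must be positive")
  structure(list(tau = tau, kind = "single-exponential"),
            class = "KernelSpec")
}

.catMap <- function(names, category)
  stats::setNames(rep(category, length(names)), names)

#' Sensory regressors from a stimulus protocol
#'
#' Builds the stimulus-feature design columns. In `ephys` mode: one 500-ms
#' onset-window boxcar per motion direction, one duration boxcar per
#' direction, graded grating speed, whole-field windmill velocity rectified
#' by direction (CW/CCW), half-field windmill velocities, windmill
#' direction-change impulses, luminance increase/decrease onset windows,
#' and ambient luminance. In `imaging` mode the coarser set without onset
#' windows (duration, speed, rotation velocities, luminance).
#'
#' @param protocol a [StimulusProtocol-class].
#' @param mode "ephys" or "imaging".
#' @param rate output sampling rate, samples/s.
#' @param onsetWindow onset-window length, s.
#' @return A [RegressorMatrix-class].
#' @export
sensoryRegressors <- function(protocol, mode = c("ephys", "imaging"),
                              rate = 1000, onsetWindow = 0.5) {
  mode <- match.arg(mode)
  if (!nrow(epochs(protocol))) stop("protocol has no epochs")
  dur <- protocolDuration(protocol)
  n <- round(dur * rate)
  tt <- (seq_len(n) - 1) / rate
  cols <- list()
  cat <- c()
  boxcar <- function(on, off) as.numeric(.inWindows(tt, on, off))
  dirs <- c("forward", "reverse", "left", "right")
  if (mode == "ephys") {
    for (d in dirs) {
      w <- .epochWindows(protocol, "grating", d)
      cols[[paste0("onset_", d)]] <- boxcar(w$on, pmin(w$on + onsetWindow,
                                                       w$off))
    }
    cat <- c(cat, .catMap(paste0("onset_", dirs), "motion_onset"))
  }
  for (d in dirs) {
    w <- .epochWindows(protocol, "grating", d)
    cols[[paste0("dur_", d)]] <- boxcar(w$on, w$off)
  }
  cat <- c(cat, .catMap(paste0("dur_", dirs), "motion_duration"))
  ep <- epochs(protocol)
  gr <- ep[ep$kind == "grating", , drop = FALSE]
  speed <- numeric(n)
  for (i in seq_len(nrow(gr)))
    speed[tt >= gr$t_on[i] & tt < gr$t_off[i]] <- gr$speed[i]
  cols[["grating_speed"]] <- speed
  cat <- c(cat, .catMap("grating_speed", "motion_velocity"))
  v <- .windmillVelocityAt(protocol, tt, "none")
  cols[["rot_cw"]] <- pmax(v, 0)
  cols[["rot_ccw"]] <- pmax(-v, 0)
  cols[["rot_half_left"]] <- .windmillVelocityAt(protocol, tt, "left")
  cols[["rot_half_right"]] <- .windmillVelocityAt(protocol, tt, "right")
  cat <- c(cat, .catMap(c("rot_cw", "rot_ccw", "rot_half_left",
                          "rot_half_right"), "rotation"))
  if (mode == "ephys") {
    # direction changes: zero crossings of the whole-field velocity
    sgn <- sign(v)
    flips <- which(diff(sgn) != 0 & sgn[-n] != 0 & sgn[-1] != 0) + 1L
    dc <- numeric(n)
    dc[flips] <- 1
    cols[["rot_dirchange"]] <- dc
    cat <- c(cat, .catMap("rot_dirchange", "rotation"))
  }
  lumEv <- .luminanceEvents(protocol)
  for (d in c("increase", "decrease")) {
    e <- lumEv$t[lumEv$direction == d]
    cols[[paste0("lum_", d)]] <-
      if (mode == "ephys") boxcar(e, e + onsetWindow)
      else { z <- numeric(n); z[round(e * rate) + 1L] <- 1; z }
  }
  cols[["lum_ambient"]] <- .luminanceAt(protocol, tt)
  cat <- c(cat, .catMap(c("lum_increase", "lum_decrease", "lum_ambient"),
                        "luminance"))
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  RegressorMatrix(X, cat, rate)
}

#' Motor regressors from bouts, vigor, and eye kinematics
#'
#' Columns: bout-onset impulses, bout-offset impulses, a bout-duration
#' boxcar, continuous vigor (max-normalized), three derived swim-timing
#' variants (early-bout boxcar over the first 150 ms, late-bout boxcar,
#' and a 500-ms post-bout window), and the twelve eye channels when
#' provided.
#'
#' @param boutTable a [BoutTable-class].
#' @param vigor optional [TimeSeries-class] vigor trace.
#' @param eyes optional output of [eyeKinematics()].
#' @param rate output sampling rate, samples/s.
#' @param duration output duration, s (default: end of the last input).
#' @param timingVariants include the derived swim-timing columns.
#' @return A [RegressorMatrix-class].
#' @export
motorRegressors <- function(boutTable, vigor = NULL, eyes = NULL,
                            rate = 1000, duration = NULL,
                            timingVariants = TRUE) {
  b <- bouts(boutTable)
  if (is.null(duration)) {
    duration <- max(c(if (nrow(b)) max(b$t_off),
                      if (!is.null(vigor)) tsDuration(vigor),
                      if (!is.null(eyes)) tsDuration(eyes[[1]]), 0))
  }
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1) / rate
  imp <- function(times) {
    z <- numeric(n)
    i <- round(times * rate) + 1L
    z[i[i >= 1 & i <= n]] <- 1
    z
  }
  cols <- list(
    swim_onset = imp(b$t_on),
    swim_offset = imp(b$t_off),
    swim_duration = as.numeric(.inWindows(tt, b$t_on, b$t_off)))
  if (!is.null(vigor)) {
    v <- .resampleTo(vigor, rate, n)
    if (max(v) > 0) v <- v / max(v)
    cols$swim_vigor <- v
  } else {
    # fall back on the bout table's vigor summaries
    v <- numeric(n)
    for (i in seq_len(nrow(b)))
      v[tt >= b$t_on[i] & tt < b$t_off[i]] <- b$mean_vigor[i]
    if (length(v) && max(v, na.rm = TRUE) > 0) v <- v / max(v, na.rm = TRUE)
    v[!is.finite(v)] <- 0
    cols$swim_vigor <- v
  }
  if (timingVariants) {
    cols$swim_early <- as.numeric(.inWindows(tt, b$t_on,
                                             pmin(b$t_on + 0.150, b$t_off)))
    cols$swim_late <- as.numeric(.inWindows(tt, pmin(b$t_on + 0.150,
                                                     b$t_off), b$t_off))
    cols$swim_post <- as.numeric(.inWindows(tt, b$t_off, b$t_off + 0.5))
  }
  cat <- .catMap(names(cols), "swim")
  if (!is.null(eyes)) {
    for (nm in names(eyes)) {
      cols[[paste0("eye_", nm)]] <- .resampleTo(eyes[[nm]], rate, n)
      cat <- c(cat, .catMap(paste0("eye_", nm), "eye"))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  RegressorMatrix(X, cat, rate)
}

#' Combine regressor matrices column-wise
#'
#' @param ... [RegressorMatrix-class] objects on a common clock.
#' @return A [RegressorMatrix-class].
#' @export
combineRegressors <- function(...) {
  xs <- list(...)
  rate <- tsRate(xs[[1]])
  n <- min(vapply(xs, function(x) nrow(designMatrix(x)), integer(1)))
  X <- do.call(cbind, lapply(xs, function(x)
    designMatrix(x)[seq_len(n), , drop = FALSE]))
  cat <- do.call(c, lapply(xs, regressorCategories))
  RegressorMatrix(X, cat, rate, t0 = xs[[1]]@t0)
}

#' Convolve regressors with the GCaMP kernel
#'
#' Each column is causally convolved with k(t) = exp(-t/tau) and then
#' renormalized to unit maximum (columns that remain all-zero are left
#' unchanged).
#'
#' @param X a [RegressorMatrix-class].
#' @param kernel a [kernelSpec()].
#' @return A [RegressorMatrix-class].
#' @export
convolveKernel <- function(X, kernel = kernelSpec()) {
  V <- designMatrix(X)
  rate <- tsRate(X)
  out <- apply(V, 2, function(col) {
    y <- .expFilter(col, rate, kernel$tau)
    m <- max(abs(y))
    if (m > 0) y / m else y
  })
  RegressorMatrix(out, regressorCategories(X), rate, t0 = X@t0)
}

#' Smooth regressors with the firing-rate boxcar
#'
#' Unit-area boxcar smoothing (default 20 ms) per column, matching the
#' filter applied to spike trains when converting them to firing rates.
#' Column integrals are preserved.
#'
#' @param X a [RegressorMatrix-class].
#' @param width boxcar width, s.
#' @return A [RegressorMatrix-class].
#' @export
smoothRate <- function(X, width = 0.020) {
  V <- designMatrix(X)
  rate <- tsRate(X)
  out <- apply(V, 2, .boxcarFilter, rate = rate, width = width)
  RegressorMatrix(out, regressorCategories(X), rate, t0 = X@t0)
}

#' The canonical electrophysiology design matrix
#'
#' Assembles the full stimulus-plus-motor design used for spiking analyses:
#' sensory columns (onset, duration, speed, rotation, luminance) and swim
#' motor columns, all smoothed with the 20-ms rate filter. The full set has
#' 24 columns; complex spike analyses drop two derived swim-timing variants
#' (`swim_late`, `swim_post`), leaving 22.
#'
#' @param protocol a [StimulusProtocol-class].
#' @param boutTable a [BoutTable-class].
#' @param vigor optional vigor [TimeSeries-class].
#' @param rate sampling rate, samples/s.
#' @param target "ss" for the 24-column set, "cs" for the 22-column set.
#' @param smooth apply the 20-ms rate filter.
#' @return A [RegressorMatrix-class].
#' @export
ephysDesign <- function(protocol, boutTable, vigor = NULL, rate = 1000,
                        target = c("ss", "cs"), smooth = TRUE) {
  target <- match.arg(target)
  S <- sensoryRegressors(protocol, "ephys", rate)
  M <- motorRegressors(boutTable, vigor, rate = rate,
                       duration = protocolDuration(protocol))
  X <- combineRegressors(S, M)
  if (target == "cs") {
    keep <- setdiff(regressorNames(X), c("swim_late", "swim_post"))
    X <- RegressorMatrix(designMatrix(X)[, keep, drop = FALSE],
                         regressorCategories(X)[keep], rate, t0 = X@t0)
  }
  if (smooth) smoothRate(X) else X
}
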