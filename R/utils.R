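# Internal numeric helpers shared across modules.

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a child seed from a parent seed and an integer salt, keeping the
# result inside the 32-bit integer range.
.childSeed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(salt) * 104729) %% 2147483647)
}

# Centered rolling standard deviation with shrink-to-valid edge handling.
# O(n) via cumulative sums; window given in samples.
.rollingSD <- function(x, w) {
  n <- length(x)
  if (w < 2L) stop("rolling window must span at least 2 samples")
  if (w > n) stop("rolling window longer than the trace")
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + (w - half - 1L), n)
  m <- hi - lo + 1L
  s <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  v <- (s2 - s^2 / m) / pmax(m - 1L, 1L)
  v[v < 0] <- 0  # numeric guard
  sqrt(v)
}

# Centered rolling median (odd window, shrink-to-valid edges).
.rollingMedian <- function(x, w) {
  n <- length(x)
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) w <- w + 1L
  half <- w %/% 2L
  out <- stats::runmed(x, k = min(w, if (n %% 2L) n else n - 1L),
                       endrule = "median")
  out[seq_len(min(n, length(out)))]
}

# Unit-area boxcar smoothing of a sampled signal; width in seconds.
# The output has the same length; edges are zero-padded (the filter is a
# moving average of a delta-rate signal, so the integral is preserved up to
# events within half a window of the edges). Cumulative-sum implementation:
# no NA edge values.
.boxcarFilter <- function(x, rate, width) {
  w <- max(1L, round(width * rate))
  if (w == 1L) return(x)
  n <- length(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + (w - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / w
}

# Causal single-exponential filter: y = x convolved with exp(-t/tau) (unit
# amplitude at lag zero), computed recursively so the decay is exact per step.
.expFilter <- function(x, rate, tau) {
  a <- exp(-1 / (rate * tau))
  as.numeric(stats::filter(x, a, method = "recursive"))
}

# Bin event times onto a sampling grid: counts per sample.
.binEvents <- function(times, rate, n, t0 = 0) {
  idx <- floor((times - t0) * rate) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  tabulate(idx, nbins = n)
}

# Sample an inhomogeneous Poisson process by thinning, with an absolute
# refractory period. `intensity` is a function(t) -> rate (Hz); `lambda_max`
# a bound on it over [0, duration].
.samplePoisson <- function(intensity, duration, lambda_max, refractory = 0.002) {
  if (lambda_max <= 0 || duration <= 0) return(numeric(0))
  n <- stats::rpois(1, lambda_max * duration)
  cand <- sort(stats::runif(n, 0, duration))
  keep <- stats::runif(length(cand)) < intensity(cand) / lambda_max
  t <- cand[keep]
  if (refractory > 0 && length(t) > 1) {
    out <- t[1]
    last <- t[1]
    for (ti in t[-1]) {
      if (ti - last >= refractory) {
        out <- c(out, ti)
        last <- ti
      }
    }
    t <- out
  }
  t
}

# Piecewise-constant intensity lookup helper: given breakpoints and levels,
# returns a vectorized function(t).
.stepIntensity <- function(breaks, levels) {
  function(t) levels[findInterval(t, breaks, rightmost.closed = FALSE) + 1L]
}

# Mean of x over a set of [on, off) windows, as total count / total time for
# event times, or the time-weighted mean for sampled signals.
.inWindows <- function(t, on, off) {
  if (!length(on)) return(logical(length(t)))
  o <- order(on)
  on <- on[o]; off <- pmax(off[o], on[o])
  if (length(on) > 1) { # union of possibly-overlapping windows
    mOn <- on[1]; mOff <- off[1]
    uOn <- uOff <- numeric(0)
    for (i in seq_along(on)[-1]) {
      if (on[i] <= mOff) mOff <- max(mOff, off[i])
      else { uOn <- c(uOn, mOn); uOff <- c(uOff, mOff); mOn <- on[i]; mOff <- off[i] }
    }
    on <- c(uOn, mOn); off <- c(uOff, mOff)
  }
  idx <- findInterval(t, as.vector(rbind(on, off)))
  idx %% 2L == 1L
}

.rateInWindows <- function(times, on, off) {
  tot <- sum(off - on)
  if (tot <= 0) return(NA_real_)
  sum(.inWindows(times, on, off)) / tot
}

# Linear-interpolation resampling of a TimeSeries onto a new rate/grid.
.resampleTo <- function(ts, rate, n, t0 = 0) {
  tt <- t0 + (seq_len(n) - 1) / rate
  stats::approx(tsTimes(ts), tsValues(ts), xout = tt, rule = 2)$y
}

# z-score columns; zero-variance columns are left at zero and reported.
.zscore <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  dead <- !is.finite(sd) | sd < .Machine$double.eps^0.5
  sd[dead] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
  Z[, dead] <- 0
  attr(Z, "dead") <- dead
  Z
}
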