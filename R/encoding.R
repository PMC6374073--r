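#' Elastic-net penalty specification
#'
#' @param alpha L1/L2 mixing parameter in (0, 1]. The default 0.2 gives a
#'   modestly sparsifying fit approaching ridge regression.
#' @param lambda non-negative regularization strength. Conventional values
#'   on z-scored spiking data: 0.9 for complex spike analyses, 0.8 for
#'   simple spike analyses.
#' @return list of class "PenaltySpec".
#' @export
penaltySpec <- function(alpha = 0.2, lambda = 0.9) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(alpha = alpha, lambda = lambda), class = "PenaltySpec")
}

# Collapse a regressor name to its phenotype-level label.
.phenotypeOfRegressor <- function(name, category) {
  cat <- category[[name]]
  switch(cat,
         motion_onset = "motion_onset",
         rotation = "rotational_velocity",
         luminance = "luminance",
         swim = "motor",
         eye = "motor",
         motion_duration = "motion_duration",
         motion_velocity = "motion_duration",
         "unclassified")
}

# Assemble an EncodingFit from coefficients.
.makeFit <- function(beta, intercept, r2, category, flags = character(0),
                     zeroTol = 1e-10) {
  nz <- sum(abs(beta) > zeroTol)
  tot <- sum(abs(beta))
  w <- if (tot > 0) abs(beta) / tot else abs(beta)
  cats <- sort(unique(category))
  cf <- vapply(cats, function(cc)
    sum(w[names(beta)[category[names(beta)] == cc]]), numeric(1))
  if (tot == 0) {
    best <- "none"; bestCat <- "unclassified"
    flags <- union(flags, "all_zero")
  } else {
    best <- names(beta)[which.max(w)]
    cls <- .classifyWithTies(beta, category)
    bestCat <- cls$label
    if (cls$ambiguous) flags <- union(flags, "ambiguous")
  }
  new("EncodingFit", coefficients = beta, intercept = intercept,
      rSquared = r2, nonzeroCount = as.integer(nz), normalizedWeights = w,
      categoryFractions = cf, bestRegressor = best, bestCategory = bestCat,
      flags = flags)
}

.asResponse <- function(y) {
  if (is(y, "TimeSeries")) tsValues(y) else as.numeric(y)
}

#' Ordinary least-squares encoding fit
#'
#' z-scores the design columns and regresses the response on them. Rank
#' deficiency is flagged and resolved with the pseudoinverse solution.
#'
#' @param y response ([TimeSeries-class] or numeric vector).
#' @param X a [RegressorMatrix-class].
#' @return An [EncodingFit-class]; coefficients are on the z-scored design
#'   scale.
#' @export
fitOLS <- function(y, X) {
  yv <- .asResponse(y)
  V <- designMatrix(X)
  stopifnot(length(yv) == nrow(V))
  Z <- .zscore(V)
  dead <- attr(Z, "dead")
  flags <- character(0)
  A <- cbind(1, Z)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    flags <- "rank_deficient"
    co <- as.numeric(MASS::ginv(A) %*% yv)
  } else co <- qr.coef(qrA, yv)
  beta <- stats::setNames(co[-1], colnames(V))
  beta[dead] <- 0
  fitted <- as.numeric(A %*% c(co[1], beta))
  ssr <- sum((yv - fitted)^2)
  sst <- sum((yv - mean(yv))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  .makeFit(beta, co[1], r2, regressorCategories(X), flags)
}

# Elastic-net objective: (1/2N) RSS + lambda * sum((1-a)/2 b^2 + a|b|)
.enObjective <- function(yv, Z, b0, beta, alpha, lambda) {
  r <- yv - b0 - as.numeric(Z %*% beta)
  sum(r^2) / (2 * length(yv)) +
    lambda * sum((1 - alpha) / 2 * beta^2 + alpha * abs(beta))
}

#' Elastic-net encoding fit by cyclic coordinate descent
#'
#' Minimizes (1/2N) sum (y_i - b0 - x_i' b)^2 + lambda * P_alpha(b) with
#' P_alpha(b) = sum_j (1-alpha)/2 b_j^2 + alpha |b_j|, over z-scored
#' design columns (and a z-scored response when `standardizeY`). The
#' intercept is never penalized. Convergence: relative objective change
#' below `tol`.
#'
#' @param y response ([TimeSeries-class] or numeric).
#' @param X a [RegressorMatrix-class].
#' @param penalty a [penaltySpec()].
#' @param standardizeY z-score the response before fitting (the
#'   convention for spiking analyses at the default lambdas).
#' @param tol relative objective-change convergence tolerance.
#' @param maxIter maximum coordinate-descent sweeps.
#' @return An [EncodingFit-class].
#' @export
fitElasticNet <- function(y, X, penalty = penaltySpec(),
                          standardizeY = TRUE, tol = 1e-8,
                          maxIter = 10000L) {
  alpha <- penalty$alpha; lambda <- penalty$lambda
  yv <- .asResponse(y)
  V <- designMatrix(X)
  stopifnot(length(yv) == nrow(V))
  ysd <- 1
  if (standardizeY) {
    ysd <- stats::sd(yv)
    if (!is.finite(ysd) || ysd == 0) ysd <- 1
    yv <- (yv - mean(yv)) / ysd
  }
  Z <- .zscore(V)
  dead <- attr(Z, "dead")
  n <- length(yv)
  p <- ncol(Z)
  xss <- colSums(Z^2) / n
  beta <- numeric(p)
  b0 <- mean(yv)
  r <- yv - b0
  obj <- .enObjective(yv, Z, b0, beta, alpha, lambda)
  for (it in seq_len(maxIter)) {
    for (j in seq_len(p)) {
      if (dead[j]) next
      bj <- beta[j]
      rho <- sum(Z[, j] * r) / n + xss[j] * bj
      bnew <- sign(rho) * max(0, abs(rho) - lambda * alpha) /
        (xss[j] + lambda * (1 - alpha))
      if (bnew != bj) {
        r <- r - Z[, j] * (bnew - bj)
        beta[j] <- bnew
      }
    }
    b0new <- b0 + mean(r)
    r <- r - (b0new - b0)
    b0 <- b0new
    objNew <- .enObjective(yv, Z, b0, beta, alpha, lambda)
    if (abs(obj - objNew) <= tol * max(1e-12, abs(obj))) break
    obj <- objNew
  }
  names(beta) <- colnames(V)
  fitted <- b0 + as.numeric(Z %*% beta)
  sst <- sum((yv - mean(yv))^2)
  r2 <- if (sst > 0) 1 - sum((yv - fitted)^2) / sst else NA_real_
  .makeFit(beta, b0, r2, regressorCategories(X))
}

#' Select lambda by total root-mean-squared error across signals
#'
#' Fits every signal at every lambda in the grid and returns the lambda
#' minimizing the summed RMSE; ties go to the larger (sparser) lambda.
#'
#' @param signals list of responses.
#' @param X a [RegressorMatrix-class].
#' @param grid numeric vector of candidate lambdas.
#' @param alpha elastic-net mixing parameter.
#' @return the selected lambda.
#' @export
selectLambda <- function(signals, X, grid, alpha = 0.2) {
  if (!length(signals) || !length(grid)) stop("empty signals or grid")
  grid <- sort(grid)
  tot <- vapply(grid, function(lam) {
    sum(vapply(signals, function(y) {
      fit <- fitElasticNet(y, X, penaltySpec(alpha, lam))
      yv <- .asResponse(y)
      yz <- (yv - mean(yv)) / max(stats::sd(yv), .Machine$double.eps)
      Z <- .zscore(designMatrix(X))
      res <- yz - fit@intercept - as.numeric(Z %*% fit@coefficients)
      sqrt(mean(res^2))
    }, numeric(1)))
  }, numeric(1))
  # ties (within numerical noise) resolved toward the sparser model
  best <- max(grid[tot <= min(tot) + 1e-12])
  best
}

#' Classify the complex spike phenotype from an encoding fit
#'
#' The label is the phenotype-level category of the regressor with the
#' largest normalized weight: per-direction onset regressors collapse to
#' `motion_onset`, CW/CCW (and half-field) rotation to
#' `rotational_velocity`, luminance transitions to `luminance`, swim and
#' eye regressors to `motor`, duration/velocity to `motion_duration`.
#' Equal top weights across two categories are broken by the summed
#' category weight, then by a fixed category order, and flagged ambiguous.
#'
#' @param fit an [EncodingFit-class].
#' @return character label (one of motion_onset, rotational_velocity,
#'   luminance, motor, motion_duration, or "unclassified").
#' @export
classifyPhenotype <- function(fit) {
  if ("all_zero" %in% fit@flags || fit@nonzeroCount == 0L)
    return("unclassified")
  fit@bestCategory
}

# Phenotype label with explicit tie handling over normalized weights.
.classifyWithTies <- function(beta, category) {
  w <- abs(beta) / sum(abs(beta))
  phen <- vapply(names(beta), .phenotypeOfRegressor, character(1),
                 category = category)
  top <- max(w)
  cand <- unique(phen[w >= top - 1e-12])
  if (length(cand) == 1L) return(list(label = cand, ambiguous = FALSE))
  sums <- vapply(cand, function(cc) sum(w[phen == cc]), numeric(1))
  best <- cand[sums >= max(sums) - 1e-12]
  order <- c("motion_onset", "rotational_velocity", "luminance", "motor",
             "motion_duration")
  list(label = order[order %in% best][1], ambiguous = TRUE)
}

#' Fraction of encoding weight in a category group
#'
#' Sum of normalized absolute coefficients over the named categories
#' (nonzero coefficients only, which is all of them after elastic-net
#' selection).
#'
#' @param fit an [EncodingFit-class].
#' @param categories character: regressor categories to pool (e.g.
#'   `c("swim", "eye")` for the motor fraction).
#' @param categoryMap the design's category map.
#' @return fraction in [0, 1].
#' @export
categoryFraction <- function(fit, categories, categoryMap) {
  beta <- fit@coefficients
  if (sum(abs(beta)) == 0) stop("all-zero fit has no category fractions")
  sum(abs(beta)[categoryMap[names(beta)] %in% categories]) / sum(abs(beta))
}

#' Decompose a calcium signal into complex and simple spike contributions
#'
#' Regresses dF/F on the kernel-convolved CS and SS spike trains and
#' reports each source's contribution as |beta_s| * SD(regressor_s),
#' normalized across sources and expressed in percent.
#'
#' @param dff a [TimeSeries-class] dF/F trace.
#' @param cs,ss [SpikeTrain-class] paired spike trains.
#' @param kernel a [kernelSpec()].
#' @return list with `cs_percent`, `ss_percent`, `r_squared`, and `flags`.
#' @export
decomposeCalcium <- function(dff, cs, ss, kernel = kernelSpec()) {
  rate <- tsRate(dff)
  n <- length(dff)
  flags <- character(0)
  if (nSpikes(cs) == 0 || nSpikes(ss) == 0) {
    flags <- "degenerate"
    if (nSpikes(cs) == 0 && nSpikes(ss) == 0)
      stop("no spikes of either type")
    pct <- if (nSpikes(cs) > 0) c(100, 0) else c(0, 100)
    return(list(cs_percent = pct[1], ss_percent = pct[2],
                r_squared = NA_real_, flags = flags))
  }
  mk <- function(train) .expFilter(.binEvents(spikeTimes(train), rate, n),
                                   rate, kernel$tau)
  Xcs <- mk(cs); Xss <- mk(ss)
  A <- cbind(1, Xcs, Xss)
  co <- unname(qr.coef(qr(A), tsValues(dff)))
  co[is.na(co)] <- 0
  contrib <- c(abs(co[2]) * stats::sd(Xcs), abs(co[3]) * stats::sd(Xss))
  tot <- sum(contrib)
  fitted <- as.numeric(A %*% co)
  sst <- sum((tsValues(dff) - mean(tsValues(dff)))^2)
  r2 <- if (sst > 0) 1 - sum((tsValues(dff) - fitted)^2) / sst else NA_real_
  if (tot == 0) {
    flags <- union(flags, "degenerate")
    return(list(cs_percent = NA_real_, ss_percent = NA_real_,
                r_squared = r2, flags = flags))
  }
  list(cs_percent = 100 * contrib[1] / tot,
       ss_percent = 100 * contrib[2] / tot,
       r_squared = r2, flags = flags)
}
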