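mkDesign <- function(n, p, seed = 1, cats = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("r", seq_len(p))))
  if (is.null(cats))
    cats <- stats::setNames(rep(c("swim", "luminance", "rotation"),
                                length.out = p), colnames(X))
  RegressorMatrix(X, cats, 10)
}

test_that("OLS recovers exact linear structure", {
  X <- mkDesign(200, 4, seed = 2)
  V <- designMatrix(X)
  # y equals one z-scored column -> beta_j = 1, others 0, R^2 = 1
  Z <- zebellum:::.zscore(V)
  f1 <- fitOLS(Z[, 2], X)
  expect_equal(unname(fitCoefficients(f1)),
               c(0, 1, 0, 0), tolerance = 1e-10)
  expect_equal(rSquared(f1), 1)
  # y = 2 a - b reconstructed
  f2 <- fitOLS(2 * Z[, 1] - Z[, 3], X)
  expect_equal(unname(fitCoefficients(f2)), c(2, 0, -1, 0),
               tolerance = 1e-10)
  # independent noise: R^2 near zero at large T
  set.seed(5)
  f3 <- fitOLS(rnorm(200), X)
  expect_lt(rSquared(f3), 0.06)
})

test_that("rank-deficient designs are flagged and solved by pseudoinverse", {
  set.seed(6)
  a <- rnorm(50)
  V <- cbind(a = a, b = a, c = rnorm(50))
  X <- RegressorMatrix(V, c(a = "swim", b = "swim", c = "rotation"), 10)
  f <- fitOLS(V[, "c"], X)
  expect_true("rank_deficient" %in% f@flags)
  expect_equal(rSquared(f), 1, tolerance = 1e-8)
})

test_that("elastic net matches its limiting cases", {
  X <- mkDesign(150, 3, seed = 7)
  Z <- zebellum:::.zscore(designMatrix(X))
  set.seed(8)
  y <- Z %*% c(1.5, -0.5, 0) + rnorm(150, 0, 0.3)
  # lambda large enough -> all beta zero, intercept = mean(y)
  fBig <- fitElasticNet(y, X, penaltySpec(0.5, 50), standardizeY = FALSE)
  expect_equal(fBig@nonzeroCount, 0L)
  expect_equal(fBig@intercept, mean(y), tolerance = 1e-8)
  expect_equal(classifyPhenotype(fBig), "unclassified")
  # lambda -> 0 recovers OLS
  f0 <- fitElasticNet(y, X, penaltySpec(0.2, 0), standardizeY = FALSE)
  fo <- fitOLS(y, X)
  expect_equal(fitCoefficients(f0), fitCoefficients(fo), tolerance = 1e-6)
})

test_that("coordinate descent minimizes the objective (grid-search oracle)", {
  # all <= 3-regressor systems: dense grid search over beta space
  # (vectorized: residual matrix over all candidate beta vectors at once)
  gridOracle <- function(yv, Z, alpha, lambda, lim = 1.5, step = NULL) {
    p <- ncol(Z)
    if (is.null(step)) step <- c(0.005, 0.01, 0.025)[p]
    g <- seq(-lim, lim, by = step)
    grid <- as.matrix(do.call(expand.grid, rep(list(g), p)))
    R <- yv - Z %*% t(grid)
    R <- sweep(R, 2, colMeans(R))
    pen <- colSums((1 - alpha) / 2 * t(grid)^2 + alpha * abs(t(grid)))
    vals <- colSums(R^2) / (2 * length(yv)) + lambda * pen
    grid[which.min(vals), ]
  }
  set.seed(9)
  for (case in 1:6) {
    p <- sample(1:3, 1)
    n <- sample(c(9, 30), 1)
    X <- mkDesign(n, p, seed = 20 + case)
    yv <- as.numeric(rnorm(n))
    alpha <- sample(c(0.2, 0.6, 1), 1)
    lambda <- sample(c(0.1, 0.5), 1)
    fit <- fitElasticNet(yv, X, penaltySpec(alpha, lambda),
                         standardizeY = FALSE)
    Z <- zebellum:::.zscore(designMatrix(X))
    ref <- gridOracle(yv, Z, alpha, lambda)
    oCD <- zebellum:::.enObjective(yv, Z, fit@intercept,
                                   fitCoefficients(fit), alpha, lambda)
    oGrid <- zebellum:::.enObjective(yv, Z, mean(yv - Z %*% ref), ref,
                                     alpha, lambda)
    expect_lte(oCD, oGrid + 1e-9)
    # agreement up to the grid resolution
    expect_lt(max(abs(unname(fitCoefficients(fit)) - unname(ref))), 0.026)
  }
})

test_that("the number of nonzero coefficients is non-increasing in lambda", {
  set.seed(10)
  for (rep in 1:4) {
    X <- mkDesign(120, 6, seed = 30 + rep)
    Z <- zebellum:::.zscore(designMatrix(X))
    y <- Z %*% rnorm(6) + rnorm(120, 0, 0.5)
    nz <- sapply(c(0.01, 0.05, 0.1, 0.3, 0.6, 1), function(l)
      fitElasticNet(y, X, penaltySpec(0.2, l),
                    standardizeY = FALSE)@nonzeroCount)
    expect_true(all(diff(nz) <= 0))
  }
})

test_that("lambda selection minimizes summed RMSE with sparser ties", {
  X <- mkDesign(100, 2, seed = 11)
  Z <- zebellum:::.zscore(designMatrix(X))
  # noiseless signal equal to one regressor: the unpenalized end wins
  expect_equal(selectLambda(list(Z[, 1]), X, c(1e-6, 10)), 1e-6)
  # pure-noise signals: training RMSE still prefers the least shrinkage,
  # so the argmin is the smallest lambda (fits shrink toward the mean)
  set.seed(12)
  noise <- lapply(1:3, function(i) rnorm(100))
  expect_equal(selectLambda(noise, X, c(0.05, 0.5, 5)), 0.05)
  # a one-element grid returns that element
  expect_equal(selectLambda(list(Z[, 1]), X, 0.7), 0.7)
})

test_that("phenotype labels collapse regressors and break ties as stated", {
  cats <- c(rot_cw = "rotation", rot_ccw = "rotation",
            onset_forward = "motion_onset", swim_vigor = "swim",
            lum_increase = "luminance")
  mk <- function(beta) zebellum:::.makeFit(beta, 0, 0.5, cats)
  f <- mk(c(rot_cw = 0.9, rot_ccw = 0, onset_forward = 0.1,
            swim_vigor = 0, lum_increase = 0))
  expect_equal(classifyPhenotype(f), "rotational_velocity")
  # equal top weights across two categories: tie broken by summed weight
  f2 <- mk(c(rot_cw = 0.5, rot_ccw = 0.2, onset_forward = 0.5,
             swim_vigor = 0, lum_increase = 0))
  expect_equal(classifyPhenotype(f2), "rotational_velocity")
  expect_true("ambiguous" %in% f2@flags)
  f3 <- mk(c(rot_cw = 0.5, rot_ccw = 0, onset_forward = 0.5,
             swim_vigor = 0, lum_increase = 0))
  expect_equal(classifyPhenotype(f3), "motion_onset")  # fixed order
})

test_that("category fractions partition the absolute weight", {
  cats <- c(a = "swim", b = "rotation", c = "eye")
  f <- zebellum:::.makeFit(c(a = 0.4, b = 0, c = 0), 0, 0.3, cats)
  expect_equal(categoryFraction(f, c("swim", "eye"), cats), 1)
  f2 <- zebellum:::.makeFit(c(a = 0.3, b = -0.3, c = 0), 0, 0.3, cats)
  expect_equal(categoryFraction(f2, "swim", cats), 0.5)
  expect_equal(sum(categoryFractions(f2)), 1)
  f0 <- zebellum:::.makeFit(c(a = 0, b = 0, c = 0), 0, 0, cats)
  expect_error(categoryFraction(f0, "swim", cats), "all-zero")
})

test_that("best-category labels are stable across alpha in [0.1, 0.5]", {
  cfg <- smallConfig()
  p <- smallProtocol()
  beh <- smallBehavior()
  X <- ephysDesign(p, beh$boutTruth, rate = 50, target = "cs")
  dur <- protocolDuration(p)
  for (s in 1:3) {
    cell <- simulatePurkinje(p, beh, "rotational_velocity", cfg,
                             seed = 40 + s)
    y <- rateFromTrain(cell$cs, 50, duration = dur)
    labs <- sapply(c(0.1, 0.2, 0.5), function(a) {
      f <- fitElasticNet(y, X, penaltySpec(a, 0.9), standardizeY = FALSE)
      if (f@nonzeroCount == 0) classifyPhenotype(fitOLS(y, X))
      else classifyPhenotype(f)
    })
    expect_equal(length(unique(labs)), 1L)
  }
})

test_that("calcium decomposition attributes signal to the right source", {
  cfg <- generatorConfig(seed = 3)
  cs <- poissonTrain(0.5, 120, seed = 13, label = "complex")
  ss <- poissonTrain(10, 120, seed = 14)
  # dF/F built from CS only -> (100, 0)
  caCS <- simulateCalcium(cs, SpikeTrain(numeric(0), "simple", 120), cfg,
                          noiseSD = 0)
  d <- decomposeCalcium(caCS, cs, ss)
  expect_equal(d$cs_percent, 100, tolerance = 0.5)
  # equal amplitudes and rates -> ~50/50
  csA <- poissonTrain(5, 200, seed = 15, label = "complex")
  ssA <- poissonTrain(5, 200, seed = 16)
  rate <- cfg$imagingRate
  n <- 200 * rate
  drive <- zebellum:::.binEvents(spikeTimes(csA), rate, n) +
    zebellum:::.binEvents(spikeTimes(ssA), rate, n)
  ca <- TimeSeries(zebellum:::.expFilter(drive, rate, 1.6), rate)
  d2 <- decomposeCalcium(ca, csA, ssA)
  expect_equal(d2$cs_percent, 50, tolerance = 6)
  # degenerate: no SS spikes -> flagged 100/0 split
  d3 <- decomposeCalcium(caCS, cs, SpikeTrain(numeric(0), "simple", 120))
  expect_true("degenerate" %in% d3$flags)
  expect_equal(d3$cs_percent, 100)
})

test_that("sensory CS tuning is not attributed to motor regressors", {
  # cells with purely sensory tuning, behavior correlated with the stimulus
  cfg <- smallConfig()
  p <- smallProtocol()
  beh <- smallBehavior()
  X <- ephysDesign(p, beh$boutTruth, rate = 50, target = "cs")
  cats <- regressorCategories(X)
  dur <- protocolDuration(p)
  fr <- sapply(1:5, function(s) {
    cell <- simulatePurkinje(p, beh, "rotational_velocity", cfg,
                             seed = 50 + s)
    y <- rateFromTrain(cell$cs, 50, duration = dur)
    f <- fitElasticNet(y, X, penaltySpec(0.2, 0.9), standardizeY = FALSE)
    if (f@nonzeroCount == 0) return(NA)
    categoryFraction(f, c("swim", "eye"), cats)
  })
  expect_lt(mean(fr, na.rm = TRUE), 0.1)
})

test_that("coordinate descent agrees with an independent library solver", {
  library(glmnet)
  set.seed(60)
  V <- matrix(rnorm(400 * 6), 400, 6,
              dimnames = list(NULL, paste0("r", 1:6)))
  X <- RegressorMatrix(V, stats::setNames(rep(c("swim", "rotation"), 3),
                                          colnames(V)), 10)
  Z <- zebellum:::.zscore(V)
  y <- as.numeric(Z %*% c(1.2, 0, -0.7, 0, 0.4, 0) + rnorm(400, 0, 0.5))
  ys <- (y - mean(y)) / sd(y)
  for (prm in list(c(0.2, 0.1), c(0.5, 0.05), c(1, 0.2))) {
    ours <- fitElasticNet(ys, X, penaltySpec(prm[1], prm[2]),
                          standardizeY = FALSE)
    ref <- glmnet(Z, ys, alpha = prm[1], lambda = prm[2],
                  standardize = FALSE, thresh = 1e-12)
    expect_equal(unname(fitCoefficients(ours)),
                 as.numeric(coef(ref))[-1], tolerance = 1e-4)
  }
})
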