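test_that("PCA handles rank-1 input, reconstructs, and matches an eigensolve", {
  set.seed(30)
  v <- rnorm(25)
  X <- namedMatrix(rep(v, 3), 25, 3) # 3 copies of one variable
  p1 <- fitPCA(X, 1)
  expect_equal(p1@explainedVariance[1] / (3 * var(v)), 1, tolerance = 1e-10)
  expect_error(fitPCA(X, 2), "rank")

  Y <- namedMatrix(rnorm(30 * 8), 30, 8)
  pa <- fitPCA(Y, 8)
  # completeness: all components reproduce the centered data
  rec <- pa@scores %*% t(pa@basis)
  expect_equal(rec, scale(Y, scale = FALSE), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(pa@basis), diag(8), tolerance = 1e-8,
               ignore_attr = TRUE)
  # explained variances equal covariance eigenvalues
  expect_equal(pa@explainedVariance, eigen(cov(Y))$values, tolerance = 1e-8)
  expect_true(all(diff(pa@explainedVariance) <= 1e-12))
})

test_that("CCA degenerates correctly in the 1-D and self cases", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  cc <- fitCCA(matrix(x), matrix(y), 1)
  expect_equal(cc@canonicalCorrs, abs(cor(x, y)), tolerance = 1e-10)

  xo <- c(1, -1, 1, -1); yo <- c(1, 1, -1, -1)
  expect_lt(fitCCA(matrix(xo), matrix(yo), 1)@canonicalCorrs, 1e-10)

  set.seed(31)
  A <- matrix(rnorm(40 * 3), 40, 3)
  self <- fitCCA(A, A, 3)
  expect_equal(self@canonicalCorrs, rep(1, 3), tolerance = 1e-10)
  expect_error(fitCCA(cbind(A, 0), A, 3), "zero-variance")
})

test_that("the QR/SVD route matches the generalized-eigenproblem oracle", {
  set.seed(32)
  for (i in 1:20) {
    X <- matrix(rnorm(50 * 5), 50, 5)
    Y <- matrix(rnorm(50 * 4), 50, 4)
    cc <- fitCCA(X, Y, 4)
    expect_equal(cc@canonicalCorrs, ccaOracle(X, Y)[1:4], tolerance = 1e-8)
    # contract: corr(U_k, V_k) equals the canonical correlation, variates
    # mutually uncorrelated with unit variance
    expect_equal(diag(cor(cc@U, cc@V)), cc@canonicalCorrs, tolerance = 1e-8)
    expect_equal(cor(cc@U), diag(4), tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(apply(cc@U, 2, sd), rep(1, 4), tolerance = 1e-8)
  }
})

test_that("ICA rotation is trivial in 1-D and orthonormal in general", {
  sim <- tinySim(n = 300, pBrain = 15, pBehav = 15, rho = c(0.9, 0.8, 0.7),
                 seed = 33)
  pX <- fitPCA(blockValues(sim$imaging), 10)
  pY <- fitPCA(blockValues(sim$behaviour), 10)
  cc <- fitCCA(pX@scores, pY@scores, 1)
  m1 <- fitICARotation(cc, K = 1, seed = 1)
  expect_equal(abs(m1@unmixing[1, 1]), 1)
  expect_equal(m1@modeCorrs, cc@canonicalCorrs[1], tolerance = 1e-12)

  cc3 <- fitCCA(pX@scores, pY@scores, 3)
  m3 <- fitICARotation(cc3, K = 3, seed = 1)
  expect_equal(m3@unmixing %*% t(m3@unmixing), diag(3), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(diff(m3@modeCorrs) <= 1e-12))
})

test_that("ICA recovers planted non-Gaussian sources mixed into canonical scores", {
  set.seed(34)
  n <- 1000
  u <- matrix(runif(n * 2) - 0.5, n, 2)
  S <- -sign(u) * log(1 - 2 * abs(u)) / sqrt(2) # standardized Laplace pair
  S <- scale(S)
  th <- 0.6
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  U <- S %*% t(R) # mixed sources masquerading as canonical variates
  rownames(U) <- sprintf("p%04d", 1:n)
  cc <- new("CCAResult", brainWeights = diag(2), behavWeights = diag(2),
            U = U, V = U, canonicalCorrs = c(1, 1))
  m <- fitICARotation(cc, K = 2, seed = 2)
  rec <- bestAbsCor(m@brainModeLoadings, S)
  expect_true(all(rec >= 0.99))
})

test_that("variable loadings cover the self, partial, and degenerate cases", {
  sim <- tinySim(n = 120, pBrain = 10, pBehav = 12, seed = 35)
  m <- runFullDecomposition(sim$imaging, sim$behaviour, K = 2, seed = 3)
  # a variable identical to the mode loadings correlates at exactly 1
  X2 <- cbind(blockValues(sim$imaging), clone = m@brainModeLoadings[, 1])
  vl <- computeVariableLoadings(m, DataBlock(X2), sim$behaviour)
  expect_equal(vl$loading[vl$variable == "clone" & vl$mode == 1], 1,
               tolerance = 1e-10)
  # constant variable -> undefined loading, not zero
  X3 <- cbind(blockValues(sim$imaging), flat = 1)
  vl3 <- computeVariableLoadings(m, DataBlock(X3), sim$behaviour)
  expect_true(all(is.na(vl3$loading[vl3$variable == "flat"])))
})

test_that("partialling an orthogonal covariate changes nothing", {
  sim <- tinySim(n = 150, pBrain = 8, pBehav = 8, seed = 36)
  m <- runFullDecomposition(sim$imaging, sim$behaviour, K = 2, seed = 3)
  # construct a covariate exactly orthogonal to every variable and loading
  set.seed(37)
  B <- cbind(blockValues(sim$imaging), blockValues(sim$behaviour),
             m@brainModeLoadings, m@behavModeLoadings, 1)
  cv <- qr.resid(qr(B), rnorm(150))
  conf <- data.frame(participant_id = participantIds(sim$imaging), orth = cv)
  plain <- computeVariableLoadings(m, sim$imaging, sim$behaviour)
  part <- computeVariableLoadings(m, sim$imaging, sim$behaviour,
                                  partialCovariates = "orth", confounds = conf)
  expect_equal(part$loading, plain$loading, tolerance = 1e-10)
})

test_that("partial correlations match the closed-form textbook formula", {
  set.seed(38)
  n <- 12
  z <- rnorm(n)
  x <- 0.5 * z + rnorm(n)
  y <- -0.3 * z + rnorm(n)
  sim <- list() # one-variable blocks around x; loadings replaced by y
  X <- namedMatrix(x, n, 1, prefix = "var")
  m <- new("ModeSet", unmixing = matrix(1), brainModeLoadings = matrix(y),
           behavModeLoadings = matrix(y), modeCorrs = 1,
           brainProjection = matrix(1), behavProjection = matrix(1),
           brainCenter = 0, behavCenter = 0,
           variableLoadings = data.frame(), canonicalCorrs = 1, seed = 1L)
  conf <- data.frame(participant_id = rownames(X), z = z)
  vl <- computeVariableLoadings(m, DataBlock(X), DataBlock(X),
                                partialCovariates = "z", confounds = conf)
  expect_equal(vl$loading[1], partialCorOracle(x, y, z), tolerance = 1e-10)
})

test_that("the full decomposition is deterministic and self-consistent", {
  sim <- tinySim(n = 250, pBrain = 20, pBehav = 25, seed = 39)
  m1 <- runFullDecomposition(sim$imaging, sim$behaviour, K = 2, seed = 5)
  m2 <- runFullDecomposition(sim$imaging, sim$behaviour, K = 2, seed = 5)
  expect_identical(m1@brainModeLoadings, m2@brainModeLoadings)
  expect_identical(m1@variableLoadings, m2@variableLoadings)

  # composition: centered data through the composed projection reproduces
  # the participant loadings (the out-of-sample map applied in-sample)
  Xc <- sweep(blockValues(sim$imaging), 2, m1@brainCenter, "-")
  expect_equal(Xc %*% m1@brainProjection, m1@brainModeLoadings,
               tolerance = 1e-8, ignore_attr = TRUE)
  Yc <- sweep(blockValues(sim$behaviour), 2, m1@behavCenter, "-")
  expect_equal(Yc %*% m1@behavProjection, m1@behavModeLoadings,
               tolerance = 1e-8, ignore_attr = TRUE)

  # sign convention: top behavioural |loading| is positive per mode
  vl <- m1@variableLoadings
  for (k in 1:2) {
    beh <- vl[vl$side == "behaviour" & vl$mode == k, ]
    expect_gt(beh$loading[which.max(abs(beh$loading))], 0)
  }
})

test_that("the rotation preserves the canonical-variate subspace", {
  sim <- tinySim(n = 200, pBrain = 15, pBehav = 15, seed = 40)
  pX <- fitPCA(blockValues(sim$imaging), 10)
  pY <- fitPCA(blockValues(sim$behaviour), 10)
  cc <- fitCCA(pX@scores, pY@scores, 2)
  m <- fitICARotation(cc, K = 2, seed = 1)
  # principal angles between span(U) and span(mode loadings) are ~0
  qU <- qr.Q(qr(cc@U))
  qM <- qr.Q(qr(m@brainModeLoadings))
  angles <- acos(pmin(svd(crossprod(qU, qM))$d, 1))
  expect_lt(max(angles), 1e-6)
})

test_that("mode correlations are invariant to variable order and scale", {
  sim <- tinySim(n = 200, pBrain = 15, pBehav = 18, seed = 41)
  base <- runFullDecomposition(sim$imaging, sim$behaviour, K = 2, seed = 7)
  set.seed(42)
  Xp <- blockValues(sim$imaging)[, sample(15)] * 3.7
  perm <- runFullDecomposition(DataBlock(Xp), sim$behaviour, K = 2, seed = 7)
  expect_equal(modeCorrs(perm), modeCorrs(base), tolerance = 1e-8)
})

test_that("an unrelated behaviour block yields no spurious mode", {
  sim <- tinySim(n = 500, pBrain = 20, pBehav = 20, seed = 43)
  set.seed(44)
  B <- matrix(rnorm(500 * 20), 500, 20,
              dimnames = list(participantIds(sim$imaging),
                              sprintf("b%02d", 1:20)))
  indep <- DataBlock(B)
  rep <- permutationTestModes(sim$imaging, indep, K = 2, nCompBrain = 15,
                              nCompBehav = 15, nPerm = 199, seed = 45)
  expect_true(all(rep@pFwe > 0.05))
})
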