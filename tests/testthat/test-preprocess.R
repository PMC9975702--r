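test_that("cleanBlock is an identity on well-behaved data", {
  set.seed(10)
  X <- namedMatrix(runif(100, -1, 1), 20, 5)
  out <- cleanBlock(DataBlock(X), zExtreme = 6)
  expect_equal(blockValues(out$block), X)
  expect_identical(out$report@cellsSetMissing, 0L)
  expect_identical(nrow(out$report@droppedVariables), 0L)
  expect_identical(nrow(out$report@droppedParticipants), 0L)
})

test_that("a single planted outlier is blanked and nothing else", {
  set.seed(11)
  X <- namedMatrix(runif(100, -1, 1), 20, 5)
  X[7, 3] <- 50 # enormous relative to the column's MAD
  out <- cleanBlock(DataBlock(X), zExtreme = 4)
  expect_identical(out$report@cellsSetMissing, 1L)
  expect_true(is.na(blockValues(out$block)[7, 3]))
  expect_equal(sum(is.na(blockValues(out$block))), 1)
})

test_that("variable/participant dropping matches a brute-force recount", {
  set.seed(12)
  X <- namedMatrix(rnorm(100), 20, 5)
  miss <- rbind(cbind(1:12, 2),   # variable v02: 12/20 = 60% missing
                cbind(3, 1:4),    # participant p03 heavily missing
                cbind(15:16, 4))
  X[miss] <- NA
  out <- cleanBlock(DataBlock(X), zExtreme = 100, maxVarMissing = 0.5,
                    maxParticipantMissing = 0.5)
  # oracle: recount fractions in the stated order
  keepVar <- colMeans(is.na(X)) <= 0.5
  Xv <- X[, keepVar, drop = FALSE]
  keepPart <- rowMeans(is.na(Xv)) <= 0.5
  expect_identical(variableNames(out$block), colnames(X)[keepVar])
  expect_identical(participantIds(out$block), rownames(X)[keepPart])
  Xall <- X
  Xall[1, ] <- NA # every variable now has some missingness
  expect_error(cleanBlock(DataBlock(Xall), zExtreme = 100, maxVarMissing = 1e-9),
               "all variables dropped")
})

test_that("imputation is an identity on dense data and exact for duplicates", {
  set.seed(13)
  X <- namedMatrix(rnorm(30), 6, 5)
  expect_identical(knnImpute(DataBlock(X), k = 1), DataBlock(X))
  # two identical variables, one missing entry, k = 1 -> exact copy
  X2 <- X
  X2[, 2] <- X2[, 1]
  X2[4, 2] <- NA
  filled <- knnImpute(DataBlock(X2), k = 1)
  expect_identical(blockValues(filled)[4, 2], X2[4, 1])
  # observed cells never altered
  obs <- !is.na(X2)
  expect_identical(blockValues(filled)[obs], X2[obs])
})

test_that("imputation matches the exhaustive pairwise-distance oracle", {
  set.seed(14)
  X <- namedMatrix(rnorm(30), 6, 5)
  X[2, 1] <- NA
  X[5, 4] <- NA
  for (k in 1:3) {
    got <- blockValues(knnImpute(DataBlock(X), k = k))
    expect_equal(got, knnImputeOracle(X, k))
  }
})

test_that("residualisation zeroes variables in the confound column space", {
  set.seed(15)
  n <- 40
  conf <- data.frame(participant_id = sprintf("p%02d", 1:n),
                     site = rep(c("A", "B"), n / 2),
                     age = runif(n, 5, 21))
  X <- cbind(inSpace = 2 * (conf$site == "B") + 0.5 * conf$age - 3,
             free = rnorm(n))
  rownames(X) <- conf$participant_id
  out <- residualise(DataBlock(X), conf, c("site", "age"))
  expect_lt(max(abs(blockValues(out)[, "inSpace"])), 1e-10)
  expect_equal(unname(colMeans(blockValues(out))), c(0, 0), tolerance = 1e-12)
})

test_that("empty confound spec reduces to column centering", {
  set.seed(16)
  X <- namedMatrix(rnorm(60), 12, 5)
  conf <- data.frame(participant_id = rownames(X))
  out <- residualise(DataBlock(X), conf, character())
  expect_equal(blockValues(out), scale(X, scale = FALSE),
               ignore_attr = TRUE)
})

test_that("residuals match an explicit normal-equations solve", {
  set.seed(17)
  n <- 8
  conf <- data.frame(participant_id = sprintf("p%02d", 1:n),
                     grp = rep(c("a", "b"), 4), age = rnorm(n))
  y <- rnorm(n)
  X <- matrix(y, n, 1, dimnames = list(conf$participant_id, "y"))
  out <- residualise(DataBlock(X), conf, c("grp", "age"))
  M <- cbind(1, conf$grp == "b", conf$age)
  beta <- solve(t(M) %*% M) %*% t(M) %*% y
  expect_equal(as.numeric(blockValues(out)), as.numeric(y - M %*% beta),
               tolerance = 1e-10)
})

test_that("residualisation is idempotent and flags rank deficiency", {
  set.seed(18)
  X <- namedMatrix(rnorm(200), 40, 5)
  conf <- data.frame(participant_id = rownames(X),
                     site = sample(c("A", "B", "C"), 40, replace = TRUE),
                     age = rnorm(40))
  once <- residualise(DataBlock(X), conf, c("site", "age"))
  twice <- residualise(once, conf, c("site", "age"))
  expect_equal(blockValues(once), blockValues(twice), tolerance = 1e-10)
  conf$dup <- conf$age # exactly collinear
  expect_error(residualise(DataBlock(X), conf, c("age", "dup")),
               "collinear")
})

test_that("volumetric variables additionally lose the global covariate", {
  set.seed(19)
  n <- 50
  conf <- data.frame(participant_id = sprintf("p%02d", 1:n),
                     site = rep(c("A", "B"), n / 2),
                     etiv = rnorm(n, 1500, 100))
  X <- cbind(vol = 0.01 * conf$etiv + rnorm(n, sd = 0.01),
             thick = rnorm(n))
  rownames(X) <- conf$participant_id
  out <- residualise(DataBlock(X), conf, "site", volumetricVars = "vol")
  # eTIV association removed from the volumetric variable only
  expect_lt(abs(cor(blockValues(out)[, "vol"], conf$etiv)), 0.05)
  plain <- residualise(DataBlock(X), conf, "site")
  expect_equal(blockValues(out)[, "thick"], blockValues(plain)[, "thick"])
})

test_that("the Blom transform matches its closed form and preserves order", {
  X <- matrix(c(10, 20, 30), 3, 1, dimnames = list(c("a", "b", "c"), "v"))
  out <- blockValues(rankInverseNormal(DataBlock(X)))
  expect_identical(out[2, 1], 0)
  expect_equal(out[1, 1], qnorm(0.625 / 3.25), tolerance = 1e-9)
  expect_equal(out[3, 1], -qnorm(0.625 / 3.25), tolerance = 1e-9)
  # monotonicity on arbitrary continuous input
  set.seed(20)
  for (i in 1:5) {
    x <- rexp(50) * sample(c(-1, 1), 1)
    z <- blockValues(rankInverseNormal(DataBlock(namedMatrix(x, 50, 1))))
    expect_identical(order(z), order(x))
  }
})

test_that("ties get average ranks and constant columns follow the config flag", {
  X <- namedMatrix(c(1, 1, 2, 3), 4, 1)
  out <- blockValues(rankInverseNormal(DataBlock(X)))
  expect_identical(out[1, 1], out[2, 1]) # tied values map identically
  C <- namedMatrix(rep(2, 6), 6, 1)
  expect_error(rankInverseNormal(DataBlock(C)), "constant")
  expect_warning(z <- rankInverseNormal(DataBlock(C), constantAction = "zero"),
                 "constant")
  expect_identical(unname(blockValues(z)[, 1]), rep(0, 6))
})

test_that("transformed columns are near-normal on tie-free input", {
  set.seed(21)
  X <- namedMatrix(rexp(300 * 3), 300, 3) # heavily skewed input
  z <- blockValues(rankInverseNormal(DataBlock(X)))
  g1 <- apply(z, 2, function(v) mean((v - mean(v))^3) / sd(v)^3)
  expect_true(all(abs(g1) < 0.2))
})

test_that("the preprocessing chain runs in order and reports counts", {
  sim <- tinySim(n = 120, pBrain = 15, pBehav = 15)
  conf <- generateConfoundTable(sim$imaging, seed = 3)
  raw <- injectConfoundsAndNoise(sim$imaging, conf,
                                 effects = list(site = c(siteB = 2)),
                                 missingRate = 0.05, extremeRate = 0.01,
                                 seed = 4)
  pr <- preprocessBlock(raw, conf, confoundSpec = c("site", "sequence"))
  expect_true(all(blockMask(pr$block)))
  expect_gt(pr$report@cellsSetMissing, 0)
  expect_gte(pr$report@cellsImputed, pr$report@cellsSetMissing)
  # site offset removed: site means indistinguishable after residualisation
  v <- blockValues(pr$block)
  cf <- pr$confounds
  d <- colMeans(v[cf$site == "siteB", , drop = FALSE]) -
    colMeans(v[cf$site != "siteB", , drop = FALSE])
  raw <- blockValues(knnImpute(cleanBlock(raw)$block))
  dRaw <- colMeans(raw[cf$site == "siteB", , drop = FALSE]) -
    colMeans(raw[cf$site != "siteB", , drop = FALSE])
  # residualisation removes the planted site offset (post-transform site
  # differences are sampling noise, far below the injected offset)
  expect_lt(max(abs(d)), 0.5 * max(abs(dRaw)))
})
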