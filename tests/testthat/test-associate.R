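confFixture <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(participant_id = sprintf("p%04d", seq_len(n)),
             age = runif(n, 5, 21),
             sex = sample(c("F", "M"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("the covariate model recovers exact and degenerate signals", {
  conf <- confFixture(60)
  fit <- fitCovariateModel(2 * conf$age, conf, terms = c("age", "sex"))
  expect_equal(unname(fit$coefficients["age"]), 2, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  # intercept-only model estimates the mean
  y <- rnorm(60)
  fit0 <- fitCovariateModel(y, conf, terms = character())
  expect_equal(unname(fit0$coefficients[1]), mean(y), tolerance = 1e-12)
})

test_that("covariate-model coefficients match a normal-equations solve", {
  conf <- confFixture(15, seed = 2)
  set.seed(3)
  y <- rnorm(15)
  fit <- fitCovariateModel(y, conf, terms = c("age", "age2", "sex"))
  ac <- conf$age - mean(conf$age)
  M <- cbind(1, ac, ac^2, conf$sex == "M")
  beta <- solve(t(M) %*% M) %*% t(M) %*% y
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-8)
})

test_that("with two balanced groups the Tukey contrast is the pooled t-test", {
  set.seed(4)
  n <- 40
  grp <- rep(c("no diagnosis", "case"), each = n / 2)
  y <- rnorm(n) + 0.8 * (grp == "case")
  conf <- data.frame(participant_id = sprintf("p%04d", 1:n))
  ct <- diagnosisContrasts(y, grp, conf, terms = character())
  tt <- t.test(y[grp == "case"], y[grp == "no diagnosis"], var.equal = TRUE)
  expect_equal(ct$pAdjusted, tt$p.value, tolerance = 1e-10)
  expect_equal(ct$beta, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
})

test_that("three-group contrasts match the studentized-range oracle", {
  set.seed(5)
  n <- 30
  grp <- rep(c("no diagnosis", "g1", "g2"), each = n / 3)
  y <- rnorm(n) + c(0, 0.5, -0.4)[match(grp, c("no diagnosis", "g1", "g2"))]
  conf <- data.frame(participant_id = sprintf("p%04d", 1:n))
  ct <- diagnosisContrasts(y, grp, conf, terms = character())
  # oracle: group means, pooled variance, ptukey at q = |beta| sqrt(2) / SE
  means <- tapply(y, grp, mean)
  s2 <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2))) / (n - 3)
  for (g in c("g1", "g2")) {
    beta <- means[[g]] - means[["no diagnosis"]]
    se <- sqrt(s2 * (2 / (n / 3)))
    q <- abs(beta) * sqrt(2) / se
    pOracle <- ptukey(q, nmeans = 3, df = n - 3, lower.tail = FALSE)
    row <- ct[ct$comparison == paste(g, "- no diagnosis"), ]
    expect_equal(row$beta, beta, tolerance = 1e-8)
    expect_equal(row$se, se, tolerance = 1e-8)
    expect_equal(row$pAdjusted, pOracle, tolerance = 1e-6)
  }
})

test_that("contrast tables are internally consistent and Tukey is conservative", {
  set.seed(6)
  n <- 150
  conf <- confFixture(n, seed = 7)
  grp <- sample(c("no diagnosis", "a", "b", "c"), n, replace = TRUE)
  y <- rnorm(n)
  ct <- diagnosisContrasts(y, grp, conf)
  expect_equal(ct$t, ct$beta / ct$se, tolerance = 1e-8)
  tcrit <- qt(0.975, ct$df)
  expect_equal(ct$upper - ct$beta, tcrit * ct$se, tolerance = 1e-8)
  expect_equal(ct$beta - ct$lower, tcrit * ct$se, tolerance = 1e-8)
  pRaw <- 2 * pt(-abs(ct$t), ct$df)
  expect_true(all(ct$pAdjusted >= pRaw - 1e-12))
  # all-pairwise option covers every pair once
  ctAll <- diagnosisContrasts(y, grp, conf, allPairwise = TRUE)
  expect_equal(nrow(ctAll), choose(4, 2))
})

test_that("contrasts agree with emmeans estimated marginal means", {
  skip_if_not_installed("emmeans")
  set.seed(8)
  n <- 120
  conf <- confFixture(n, seed = 9)
  grp <- sample(c("no diagnosis", "a", "b"), n, replace = TRUE)
  y <- rnorm(n) + 0.5 * (grp == "a") + 0.02 * conf$age
  ct <- diagnosisContrasts(y, grp, conf, terms = c("age", "sex"))
  df <- data.frame(y = y, diagnosis = factor(grp), age = conf$age,
                   sex = factor(conf$sex))
  emm <- emmeans::emmeans(lm(y ~ diagnosis + age + sex, data = df), "diagnosis")
  pairsTab <- as.data.frame(pairs(emm, adjust = "tukey"))
  for (g in c("a", "b")) {
    ours <- ct[ct$comparison == paste(g, "- no diagnosis"), ]
    theirs <- pairsTab[pairsTab$contrast == paste(g, "- no diagnosis"), ]
    expect_equal(ours$beta, theirs$estimate, tolerance = 1e-8)
    expect_equal(ours$se, theirs$SE, tolerance = 1e-8)
    expect_equal(ours$pAdjusted, theirs$p.value, tolerance = 1e-6)
  }
})

test_that("a planted one-SD group shift is estimated and detected", {
  set.seed(10)
  n <- 800
  grp <- rep(c("no diagnosis", "case"), each = 400)
  conf <- confFixture(n, seed = 11)
  y <- rnorm(n) + 1.0 * (grp == "case")
  ct <- diagnosisContrasts(y, grp, conf)
  expect_lt(ct$pAdjusted, 0.001)
  expect_equal(ct$beta, 1, tolerance = 0.15)
})

test_that("family-wise error of the adjusted contrasts is controlled", {
  set.seed(12)
  nSim <- 200
  anyHit <- vapply(seq_len(nSim), function(i) {
    n <- 150
    grp <- sample(c("no diagnosis", "a", "b", "c", "d"), n, replace = TRUE,
                  prob = c(0.4, 0.15, 0.15, 0.15, 0.15))
    y <- rnorm(n)
    conf <- data.frame(participant_id = sprintf("p%04d", 1:n))
    ct <- diagnosisContrasts(y, grp, conf, terms = character(),
                             allPairwise = TRUE)
    any(ct$pAdjusted < 0.05)
  }, logical(1))
  rate <- mean(anyHit)
  expect_gte(rate, 0.017)
  expect_lte(rate, 0.099)
})

test_that("the comorbidity trend is exact, subset-consistent, and powered", {
  conf <- confFixture(200, seed = 13)
  set.seed(14)
  nd <- rpois(200, 1.2)
  y <- -0.3 * nd
  tr <- suppressWarnings(comorbidityTrend(y, nd, conf, terms = character()))
  expect_equal(tr$slope, -0.3, tolerance = 1e-10) # noiseless: fit is exact
  # excluding zeros matches a brute-force refit on the subset
  y2 <- -0.3 * nd + rnorm(200, sd = 0.3)
  tr2 <- comorbidityTrend(y2, nd, conf, includeZero = FALSE,
                          terms = character())
  keep <- nd > 0
  ref <- lm(y2[keep] ~ nd[keep])
  expect_equal(tr2$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_identical(tr2$n, sum(keep))
  expect_error(comorbidityTrend(y, rep(2, 200), conf), "share one")
})

test_that("generator-driven diagnoses produce a negative loading trend", {
  sim <- tinySim(n = 2000, pBrain = 20, pBehav = 25, seed = 15)
  dg <- assignDiagnoses(sim$truth, modeEffect = 1, seed = 16)
  conf <- generateConfoundTable(sim$imaging, seed = 17)
  # regress the driving latent itself: the trend must be negative by design
  tr <- comorbidityTrend(sim$truth@latentFactors[, 2], dg$n_diagnoses, conf)
  expect_lt(tr$slope, 0)
  expect_lt(tr$p, 1e-6)
  trNoZero <- comorbidityTrend(sim$truth@latentFactors[, 2], dg$n_diagnoses,
                               conf, includeZero = FALSE)
  expect_lt(trNoZero$slope, 0)
})

test_that("robustness schemes leave independent-covariate results unchanged", {
  sim <- tinySim(n = 300, pBrain = 15, pBehav = 18, seed = 18)
  conf <- generateConfoundTable(sim$imaging, seed = 19)
  m <- runFullDecomposition(sim$imaging, sim$behaviour, K = 2, seed = 20)

  # covariate exactly orthogonal to data and loadings: partial = plain
  set.seed(21)
  B <- cbind(blockValues(sim$imaging), blockValues(sim$behaviour),
             m@brainModeLoadings, m@behavModeLoadings, 1)
  conf$orth <- qr.resid(qr(B), rnorm(300))
  r0 <- robustnessReruns(sim$imaging, sim$behaviour, conf, m,
                         scheme = "age-partial")
  # reuse the machinery with the orthogonal column under the "age" slot
  confOrth <- conf; confOrth$age <- conf$orth
  rOrth <- robustnessReruns(sim$imaging, sim$behaviour, confOrth, m,
                            scheme = "age-partial")
  expect_equal(unname(rOrth), c(1, 1), tolerance = 1e-8)

  # leave-out with an absent category drops nobody: concordance exactly 1
  dg <- rep("no diagnosis", 300)
  rLoo <- robustnessReruns(sim$imaging, sim$behaviour, conf, m,
                           scheme = "leave-out-category", diagnosis = dg,
                           leaveOut = "ADHD")
  expect_equal(unname(rLoo), c(1, 1), tolerance = 1e-10)

  # covariates independent of the planted modes: everything stays stable
  for (sch in c("age-partial", "income-partial", "medication-partial")) {
    r <- robustnessReruns(sim$imaging, sim$behaviour, conf, m, scheme = sch)
    expect_true(all(r > 0.95), label = sch)
  }
  rSex <- robustnessReruns(sim$imaging, sim$behaviour, conf, m,
                           scheme = "sex-residualised", seed = 22)
  expect_true(all(rSex > 0.95))
  dgMixed <- sample(c("ADHD", "no diagnosis"), 300, replace = TRUE)
  rDrop <- robustnessReruns(sim$imaging, sim$behaviour, conf, m,
                            scheme = "leave-out-category",
                            diagnosis = dgMixed, leaveOut = "ADHD")
  expect_true(all(rDrop > 0.95))
})
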