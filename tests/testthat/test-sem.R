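# a reliable 6-indicator measurement design for structural recovery
reliableLam <- function() {
  matrix(c(1, 0.95, 0.9, 0.9, 0.85, 0.95), 6, 1,
         dimnames = list(paste0("x", 1:6), "f"))
}

specTwoFactorSem <- function() {
  cfaSpec(list(f1 = paste0("x", 1:3), f2 = paste0("x", 4:6)))
}

genSemData <- function(n, beta, lam = reliableLam(), theta = 0.2) {
  eta <- rnorm(n)
  X <- eta %*% t(lam[, 1]) + matrix(rnorm(n * nrow(lam), 0, sqrt(theta)),
                                    n, nrow(lam))
  colnames(X) <- rownames(lam)
  y <- factor(ifelse(runif(n) < plogis(beta * eta), "case", "control"),
              levels = c("control", "case"))
  list(X = X, y = y, eta = eta)
}

test_that("two-stage structural model recovers a known odds ratio", {
  set.seed(30)
  spec <- cfaSpec(list(f = paste0("x", 1:6)))
  hits <- vapply(1:100, function(i) {
    d <- genSemData(2000, beta = log(2))
    fit <- semFit(spec, d$X, d$y, referenceLevel = "control")
    or <- fit@structural@coefficients$odds_ratio
    or >= 1.7 && or <= 2.35
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a null outcome gives odds ratios near 1 and non-significant p", {
  set.seed(31)
  spec <- cfaSpec(list(f = paste0("x", 1:6)))
  d <- genSemData(1500, beta = 0)
  fit <- semFit(spec, d$X, d$y, referenceLevel = "control")
  co <- fit@structural@coefficients
  expect_lt(abs(co$odds_ratio - 1), 0.2)
  # p roughly uniform under the null: repeated small sims
  ps <- vapply(1:20, function(i)
    semFit(spec, genSemData(400, 0)$X, genSemData(400, 0)$y[1:400],
           referenceLevel = "control")@structural@coefficients$p_value[1],
    numeric(1))
  expect_gt(mean(ps > 0.05), 0.7)
})

test_that("quadrature ML agrees with two-stage on sign and significance", {
  set.seed(32)
  spec <- cfaSpec(list(f = paste0("x", 1:6)))
  d <- genSemData(1000, beta = log(2.5))
  f1 <- semFit(spec, d$X, d$y, method = "two_stage",
               referenceLevel = "control")
  f2 <- semFit(spec, d$X, d$y, method = "quadrature_ml",
               referenceLevel = "control")
  c1 <- f1@structural@coefficients
  c2 <- f2@structural@coefficients
  expect_equal(sign(c1$coefficient), sign(c2$coefficient))
  expect_lt(c1$p_value, 0.01)
  expect_lt(c2$p_value, 0.01)
  expect_equal(c2$coefficient, log(2.5), tolerance = 0.3)
  # guard rails of the joint route
  expect_error(semFit(specTwoFactorSem(), d$X, d$y,
                      method = "quadrature_ml"), "single latent factor")
  expect_error(semFit(spec, d$X[1:4, ], d$y[1:4],
                      method = "quadrature_ml"),
               "more indicators than observations")
})

test_that("multinomial structural model finds both contrast factors", {
  set.seed(33)
  n <- 900
  lam <- matrix(0, 6, 2, dimnames = list(paste0("x", 1:6), c("f1", "f2")))
  lam[1:3, 1] <- c(1, 0.9, 0.9)
  lam[4:6, 2] <- c(1, 0.9, 0.9)
  eta <- matrix(rnorm(n * 2), n, 2)
  X <- eta %*% t(lam) + matrix(rnorm(n * 6, 0, sqrt(0.2)), n, 6)
  colnames(X) <- rownames(lam)
  # reference = middle group; each factor pushes toward one alternative
  lp2 <- 1.4 * eta[, 1]; lp3 <- 1.4 * eta[, 2]
  den <- 1 + exp(lp2) + exp(lp3)
  u <- runif(n)
  y <- ifelse(u < 1 / den, "single_tumor",
              ifelse(u < (1 + exp(lp2)) / den, "normal", "second_tumor"))
  fit <- semFit(specTwoFactorSem(), X, y, referenceLevel = "single_tumor")
  co <- fit@structural@coefficients
  expect_equal(fit@structural@referenceLevel, "single_tumor")
  f1norm <- co[co$outcome_level == "normal" & co$factor == "f1", ]
  f2sec <- co[co$outcome_level == "second_tumor" & co$factor == "f2", ]
  expect_lt(f1norm$p_value, 0.01)
  expect_lt(f2sec$p_value, 0.01)
  expect_gt(f1norm$coefficient, 0)
  expect_gt(f2sec$coefficient, 0)
})

test_that("second-order fit accepts a genuine common construct and rejects distinct factors", {
  set.seed(34)
  fl <- list(f1 = c("a1", "a2", "a3"), f2 = c("b1", "b2", "b3"))
  lam1 <- c(1, 0.8, 0.7); lam2 <- c(1, 0.9, 0.6)
  gen <- function(n, common) {
    if (common) {
      eta <- rnorm(n)
      xi <- cbind(0.9 * eta, 0.8 * eta)   # pure second-order structure
    } else {
      xi <- matrix(rnorm(n * 2), n, 2) %*% chol(matrix(c(1, .3, .3, 1), 2))
    }
    X <- cbind(xi[, 1] %*% t(lam1), xi[, 2] %*% t(lam2)) +
      matrix(rnorm(n * 6, 0, sqrt(0.4)), n, 6)
    colnames(X) <- c("a1", "a2", "a3", "b1", "b2", "b3")
    X
  }
  rGood <- vapply(1:50, function(i)
    secondOrderFit(fl, gen(500, TRUE))@fit@rmsea, numeric(1))
  rBad <- vapply(1:50, function(i)
    secondOrderFit(fl, gen(500, FALSE))@fit@rmsea, numeric(1))
  expect_lt(median(rGood), 0.08)
  expect_gt(median(rBad), 0.1)
  expect_error(secondOrderFit(list(f1 = c("a1", "a2")), gen(100, TRUE)),
               "at least two")
})

test_that("reference-panel CFA classification assigns held-out samples", {
  cfg <- syntheticConfig(groupSizes = c(gA = 8L, gB = 8L),
                         nPeptides = 300L, nEmptySpots = 30L,
                         factors = list(
                           list(name = "fA", shifts = c(gA = 3),
                                nLoadingPeptides = 40L,
                                loadingRange = c(0.3, 0.7), sign = 1),
                           list(name = "fB", shifts = c(gB = 3),
                                nLoadingPeptides = 40L,
                                loadingRange = c(0.3, 0.7), sign = 1)),
                         seed = 42L)
  sim <- simulateImmunosignature(cfg)
  x <- medianNormalizeLog10(sim$experiment)
  ids <- colnames(x)[c(1, 2, 9, 10)]
  cc <- cfaClassify(x, holdOut = ids, seed = 3)
  expect_equal(cc$accuracy, 100)
  expect_equal(cc$assignments$assigned_group,
               cc$assignments$known_group)
  # a pure-noise sample stays unclassified at the 0.3 threshold
  vals <- t(rfu(sim$experiment))
  noise <- matrix(10^rnorm(nrow(rfu(x)), 2.45, 0.35), 1)
  rownames(noise) <- "Snoise"
  colnames(noise) <- colnames(vals)
  x2 <- medianNormalizeLog10(PeptideArrayExperiment(
    rbind(vals, noise),
    groups = c(groupLabels(sim$experiment), NA),
    emptySpot = emptySpots(sim$experiment)))
  cc2 <- cfaClassify(x2, holdOut = "Snoise", seed = 3)
  expect_true(is.na(cc2$assignments$assigned_group))
  # threshold 0 forces an argmax assignment
  cc3 <- cfaClassify(x2, holdOut = "Snoise", threshold = 0, seed = 3)
  expect_false(is.na(cc3$assignments$assigned_group))
  # a held-out sample cannot be its own reference
  expect_error(cfaClassify(x, holdOut = ids[1], seed = 3,
                           references = setNames(ids[1], "gA")),
               "reference sample")
})
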