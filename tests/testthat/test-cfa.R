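specTwoFactor <- function() {
  cfaSpec(list(f1 = c("a1", "a2", "a3"), f2 = c("b1", "b2", "b3")))
}

popTwoFactor <- function() {
  lam <- matrix(0, 6, 2,
                dimnames = list(c("a1", "a2", "a3", "b1", "b2", "b3"),
                                c("f1", "f2")))
  lam[1:3, 1] <- c(1, 0.8, 0.7)
  lam[4:6, 2] <- c(1, 0.9, 0.6)
  list(lam = lam, Phi = matrix(c(1, 0.4, 0.4, 1.2), 2),
       theta = rep(0.5, 6))
}

test_that("model df counts moments minus free parameters", {
  # 1 factor, 3 indicators, marker scaling: just identified
  expect_equal(modelDf(cfaSpec(list(f = c("x1", "x2", "x3")))), 0L)
  # 2 correlated factors, 3 indicators each, marker per factor: df = 8
  expect_equal(modelDf(specTwoFactor()), 8L)
  # brute-force enumeration on randomized specs
  set.seed(20)
  for (i in 1:10) {
    m <- sample(2:3, 1)
    perFactor <- sample(3:5, m, replace = TRUE)
    ids <- paste0("v", seq_len(sum(perFactor)))
    fl <- split(ids, rep(seq_len(m), perFactor))
    names(fl) <- paste0("f", seq_len(m))
    covary <- sample(c("all", "none"), 1)
    spec <- cfaSpec(fl, covary = covary)
    v <- sum(perFactor)
    freeLoad <- sum(perFactor) - m          # one marker per factor
    freePhi <- m + if (covary == "all") m * (m - 1) / 2 else 0
    expect_equal(modelDf(spec),
                 as.integer(v * (v + 1) / 2 - (freeLoad + v + freePhi)))
  }
  # an under-identified spec errors
  expect_error(modelDf(cfaSpec(list(f1 = c("x1", "x2"), f2 = c("x1", "x2")))),
               "under-identified")
})

test_that("spec text grammar parses order-insensitively", {
  lines <- c("covary: f1 f2",
             "# comment",
             "factor: f2 b1 b2 b3",
             "fix: a1@f1 = 1",
             "factor: f1 a1 a2 a3",
             "outcome: disease ~ f1 f2 multinomial ref=single_tumor")
  spec <- parseCfaModel(lines)
  expect_setequal(spec@factors, c("f1", "f2"))
  expect_equal(sum(spec@lambdaFree), 4)
  expect_false(spec@lambdaFree["a1", "f1"])
  expect_equal(spec@lambdaValue["a1", "f1"], 1)
  expect_true(spec@phiFree["f1", "f2"])
  expect_equal(spec@structural$link, "multinomial")
  expect_equal(spec@structural$reference, "single_tumor")
  expect_error(parseCfaModel("nonsense line"), "unparseable")
})

test_that("a covariance equal to the implied structure yields zero discrepancy", {
  p <- popTwoFactor()
  Sig <- p$lam %*% p$Phi %*% t(p$lam) + diag(p$theta)
  fit <- cfaFit(specTwoFactor(), sampleCov = Sig, n = 200)
  expect_lt(fit@FML, 1e-6)
  expect_lt(fit@fit@chiSquare, 1e-4)
  expect_equal(unname(fit@lambda[2, 1]), 0.8, tolerance = 1e-3)
  expect_equal(unname(fit@phi[1, 2]), 0.4, tolerance = 1e-3)
  expect_true(fit@converged)
})

test_that("a just-identified model reports zero chi-square with indices suppressed", {
  set.seed(21)
  lam <- matrix(c(1, 0.8, 0.7), 3, 1,
                dimnames = list(c("x1", "x2", "x3"), "f"))
  X <- genCfaData(150, lam, theta = rep(0.5, 3), prefix = rownames(lam))
  fit <- cfaFit(cfaSpec(list(f = c("x1", "x2", "x3"))), X)
  expect_equal(fit@fit@df, 0L)
  expect_lt(fit@fit@chiSquare, 1e-4)
  expect_true(is.na(fit@fit@pValue))
  expect_true(is.na(fit@fit@rmsea))
  expect_false(is.na(fit@fit@srmr))
})

test_that("fit indices reproduce the chi-square tail and clamp the RMSEA", {
  fi <- computeFitIndices(14.054, 8, 191)
  expect_equal(fi@pValue, pchisq(14.054, 8, lower.tail = FALSE))
  # chi-square equal to df: zero non-centrality
  expect_equal(computeFitIndices(8, 8, 100)@rmsea, 0)
  # chi-square below df: clamped at zero
  expect_equal(computeFitIndices(3, 8, 100)@rmsea, 0)
  # SRMR of identical matrices is 0
  S <- diag(3) + 0.2
  expect_equal(computeFitIndices(10, 2, 50, S, S)@srmr, 0)
  expect_error(computeFitIndices(10, -1, 50), "df")
})

test_that("loadings are recovered within 0.1 in at least 95% of replicates", {
  # standardized design: loadings 0.7-0.9, factor variances fixed at 1
  set.seed(22)
  lam <- matrix(0, 6, 2,
                dimnames = list(c("a1", "a2", "a3", "b1", "b2", "b3"),
                                c("f1", "f2")))
  lam[1:3, 1] <- c(0.9, 0.8, 0.7)
  lam[4:6, 2] <- c(0.9, 0.8, 0.7)
  Phi <- matrix(c(1, 0.4, 0.4, 1), 2)
  theta <- 1 - rowSums(lam^2)
  spec <- cfaSpec(list(f1 = c("a1", "a2", "a3"), f2 = c("b1", "b2", "b3")),
                  fixedVariance = c("f1", "f2"))
  freeIdx <- which(spec@lambdaFree)
  hits <- vapply(1:100, function(i) {
    X <- genCfaData(500, lam, Phi, theta, prefix = rownames(lam))
    fit <- suppressWarnings(cfaFit(spec, X))
    mean(abs(abs(fit@lambda[freeIdx]) - lam[freeIdx]) <= 0.1)
  }, numeric(1))
  # estimate-level coverage across replicates
  expect_gte(mean(hits), 0.95)
  # and the typical replicate recovers every loading
  expect_gte(mean(hits == 1), 0.75)
})

test_that("swapping indicators between separated factors degrades fit", {
  set.seed(23)
  p <- popTwoFactor()
  X <- genCfaData(400, p$lam, matrix(c(1, 0.2, 0.2, 1), 2), p$theta,
                  prefix = rownames(p$lam))
  good <- cfaFit(specTwoFactor(), X)
  swapped <- cfaFit(cfaSpec(list(f1 = c("a1", "b2", "a3"),
                                 f2 = c("b1", "a2", "b3"))), X)
  expect_gt(swapped@fit@chiSquare, good@fit@chiSquare)
  expect_gt(swapped@fit@rmsea, good@fit@rmsea)
  expect_gt(swapped@fit@rmsea, 0.1)
})

test_that("robust (sandwich) standard errors are computed and finite", {
  set.seed(24)
  lam <- matrix(c(1, 0.8, 0.7, 0.9), 4, 1,
                dimnames = list(paste0("x", 1:4), "f"))
  X <- genCfaData(200, lam, theta = rep(0.4, 4), prefix = rownames(lam))
  fit <- cfaFit(cfaSpec(list(f = paste0("x", 1:4))), X, robust = TRUE)
  expect_true(all(is.finite(fit@paramTable$std_error)))
  expect_true(all(fit@paramTable$std_error > 0))
})

test_that("near-singular covariance and too-small samples are rejected", {
  set.seed(25)
  lam <- matrix(c(1, 0.8, 0.7), 3, 1,
                dimnames = list(paste0("x", 1:3), "f"))
  X <- genCfaData(60, lam, theta = rep(0.4, 3), prefix = rownames(lam))
  X2 <- cbind(X, x4 = X[, "x3"])        # exact duplicate column
  expect_error(cfaFit(cfaSpec(list(f = paste0("x", 1:4))), X2),
               "singular")
  expect_error(cfaFit(cfaSpec(list(f = paste0("x", 1:3))), X[1:5, ]),
               "sample size")
})
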