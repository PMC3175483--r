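test_that("correlation construction matches a direct oracle in both modes", {
  set.seed(8)
  obs <- matrix(rnorm(5 * 100), 100, 5, dimnames = list(NULL, paste0("v", 1:5)))
  R <- correlationMatrix(obs, mode = "peptides")
  # direct covariance / sd oracle
  C <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    xi <- obs[, i] - mean(obs[, i]); xj <- obs[, j] - mean(obs[, j])
    C[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_lt(max(abs(R@values - C)), 1e-12)
  expect_equal(R@nObservations, 100L)

  # identical samples correlate 1, negated samples -1 in samples mode
  v <- 10^rnorm(50, 2.5, 0.5)
  vals <- rbind(s1 = v, s2 = v, s3 = max(v) + min(v) - v)
  colnames(vals) <- paste0("p", 1:50)
  x <- medianNormalizeLog10(PeptideArrayExperiment(vals, c("a", "a", "b")))
  Rs <- correlationMatrix(x, mode = "samples")
  expect_equal(Rs@mode, "samples_as_variables")
  expect_equal(unname(Rs@values["s1", "s2"]), 1)
  # zero-variance variable is named
  vals2 <- vals; vals2[2, ] <- 7
  x2 <- suppressWarnings(
    medianNormalizeLog10(PeptideArrayExperiment(vals2, c("a", "a", "b"))))
  expect_error(correlationMatrix(x2, mode = "samples"), "s2")
})

test_that("eigen spectrum satisfies the trace identity and flags dominant structure", {
  expect_equal(eigenScree(diag(4))$eigenvalues, rep(1, 4))
  set.seed(9)
  lam <- runif(8, 0.5, 0.9)
  R <- oneFactorCor(lam)
  sc <- eigenScree(R)
  expect_equal(sum(sc$eigenvalues), 8, tolerance = 1e-9)
  expect_equal(sc$suggested, 1L)
  expect_gt(sc$eigenvalues[1], 2 * sc$eigenvalues[2])
  # three-block structure suggests three factors
  lam3 <- matrix(0, 12, 3)
  for (j in 1:3) lam3[(4 * j - 3):(4 * j), j] <- runif(4, 0.6, 0.8)
  R3 <- cov2cor(tcrossprod(lam3) + diag(1 - rowSums(lam3^2) + 0.2))
  dimnames(R3) <- list(paste0("v", 1:12), paste0("v", 1:12))
  expect_equal(eigenScree(R3)$suggested, 3L)
})

test_that("principal axis factoring recovers an exact one-factor structure", {
  R <- oneFactorCor(c(0.8, 0.7, 0.6))
  s <- pafFit(R, 1)
  expect_true(s@converged)
  expect_equal(unname(abs(loadings(s)[, 1])), c(0.8, 0.7, 0.6),
               tolerance = 1e-4)
  expect_equal(communalities(s) + uniquenesses(s), rep(1, 3),
               tolerance = 1e-6)
  # no common variance: identity input gives zero loadings
  I4 <- diag(4); dimnames(I4) <- list(paste0("v", 1:4), paste0("v", 1:4))
  s0 <- pafFit(I4, 1)
  expect_lt(max(abs(loadings(s0))), 1e-6)
  expect_error(pafFit(R, 3), "factor count")
})

test_that("an ultra-Heywood construction is clipped and flagged, not an error", {
  # v1 nearly duplicates a composite: drives its communality above 1
  R <- matrix(c(1, .95, .94, .2,
                .95, 1, .6, .2,
                .94, .6, 1, .2,
                .2, .2, .2, 1), 4, 4)
  dimnames(R) <- list(paste0("v", 1:4), paste0("v", 1:4))
  s <- expect_no_error(pafFit(R, 2))
  expect_true(any(s@heywood))
  expect_true(all(communalities(s) <= 1 + 1e-6))
})

test_that("PAF converges to PCA as uniquenesses vanish", {
  set.seed(10)
  lam <- matrix(0, 10, 2)
  lam[1:5, 1] <- runif(5, 0.98, 0.995)
  lam[6:10, 2] <- runif(5, 0.98, 0.995)
  h2 <- rowSums(lam^2)
  R <- cov2cor(tcrossprod(lam) + diag(pmax(1 - h2, 0.005)))
  dimnames(R) <- list(paste0("v", 1:10), paste0("v", 1:10))
  p1 <- pafFit(R, 2)
  p2 <- pafFit(R, 2, method = "pca")
  expect_lt(max(abs(abs(loadings(p1)) - abs(loadings(p2)))), 0.02)
  expect_equal(uniquenesses(p2), rep(0, 10))
})

test_that("rotations preserve communalities and the model reconstruction", {
  set.seed(12)
  lam <- matrix(0, 9, 3)
  for (j in 1:3) lam[(3 * j - 2):(3 * j), j] <- runif(3, 0.5, 0.8)
  lam[1, 2] <- 0.3  # a mild cross loading
  R <- cov2cor(tcrossprod(lam) + diag(1 - rowSums(lam^2)))
  dimnames(R) <- list(paste0("v", 1:9), paste0("v", 1:9))
  sol <- pafFit(R, 3)
  recon <- function(s) loadings(s) %*% factorCorrelation(s) %*% t(loadings(s))
  base <- recon(sol)
  for (meth in c("varimax", "promax", "geomin")) {
    r <- rotateSolution(sol, meth, nStarts = 10)
    expect_lt(max(abs(communalities(r) - communalities(sol))), 1e-6)
    expect_lt(max(abs(recon(r) - base)), 1e-6)
    if (meth == "varimax") {
      expect_equal(unname(factorCorrelation(r)), diag(3))
      expect_lt(max(abs(rowSums(loadings(r)^2) -
                        rowSums(loadings(sol)^2))), 1e-9)
    }
  }
})

test_that("varimax and promax agree with the stats-package references", {
  set.seed(13)
  lam <- matrix(0, 8, 2)
  lam[1:4, 1] <- runif(4, 0.5, 0.85)
  lam[5:8, 2] <- runif(4, 0.5, 0.85)
  lam[2, 2] <- 0.35
  R <- cov2cor(tcrossprod(lam) + diag(1 - rowSums(lam^2)))
  dimnames(R) <- list(paste0("v", 1:8), paste0("v", 1:8))
  sol <- pafFit(R, 2)
  vr <- rotateSolution(sol, "varimax")
  ref <- stats::varimax(loadings(sol), normalize = TRUE)
  expect_lt(max(abs(sort(abs(loadings(vr))) -
                    sort(abs(unclass(ref$loadings))))), 0.01)
  pr <- rotateSolution(sol, "promax", kappa = 4)
  refP <- stats::promax(loadings(sol), m = 4)
  expect_lt(max(abs(sort(abs(loadings(pr))) -
                    sort(abs(unclass(refP$loadings))))), 0.01)
})

test_that("a perfect simple structure is a varimax fixed point, and promax stays orthogonal when truth is", {
  L <- matrix(0, 6, 2)
  L[1:3, 1] <- c(0.8, 0.7, 0.6)
  L[4:6, 2] <- c(0.75, 0.65, 0.55)
  R <- cov2cor(tcrossprod(L) + diag(1 - rowSums(L^2)))
  dimnames(R) <- list(paste0("v", 1:6), paste0("v", 1:6))
  sol <- pafFit(R, 2)
  vr <- rotateSolution(sol, "varimax")
  A <- abs(loadings(vr))
  expect_lt(max(abs(sort(A[A > 0.1]) - sort(L[L > 0]))), 1e-3)
  # promax with kappa = 1 on an orthogonal solution reproduces it
  pr1 <- rotateSolution(sol, "promax", kappa = 1)
  expect_lt(max(abs(sort(abs(loadings(pr1))) - sort(abs(loadings(vr))))),
            1e-6)
  # orthogonal truth at large n: promax factor correlation stays near 0
  set.seed(14)
  X <- genCfaData(1000, L, Phi = diag(2), theta = 1 - rowSums(L^2))
  Rn <- correlationMatrix(X, mode = "peptides")
  prn <- rotateSolution(pafFit(Rn, 2), "promax")
  expect_lt(abs(factorCorrelation(prn)[1, 2]), 0.15)
  # m = 1 input is returned unchanged
  s1 <- pafFit(R, 1)
  expect_identical(rotateSolution(s1, "promax"), s1)
})

test_that("loading-threshold classification follows the 0.3 rule", {
  L <- rbind(s1 = c(0.9, 0.1), s2 = c(0.25, 0.28), s3 = c(0.05, 0.82),
             s4 = c(0.75, 0.4))
  colnames(L) <- c("F1", "F2")
  sol <- new("FactorSolution", loadings = L, factorCorrelation = diag(2),
             uniquenesses = rep(0.5, 4), communalities = rep(0.5, 4),
             eigenvalues = rep(1, 4), rotation = "promax",
             heywood = rep(FALSE, 4), converged = TRUE, nIterations = 1L,
             mode = "samples_as_variables", method = "paf")
  cls <- classifyByLoadings(sol, c(s1 = "a", s2 = "a", s3 = "b", s4 = "a"))
  asg <- cls@assignments
  expect_equal(asg$assigned_factor[asg$variable == "s1"], 1L)
  expect_true(is.na(asg$assigned_factor[asg$variable == "s2"]))
  expect_equal(asg$mapped_group[asg$variable == "s3"], "b")
  # s2 unclassified counts against accuracy: 3/4 correct
  expect_equal(cls@accuracy, 75)
  expect_equal(cls@crossLoadings$variable, "s4")
  expect_error(classifyByLoadings(sol, c(s1 = "a", s2 = "b", s3 = "c",
                                         s4 = "a")), "must equal")
})

test_that("classification succeeds under strong separation and is chance at null", {
  cfg <- syntheticConfig(groupSizes = c(g1 = 15L, g2 = 15L),
                         nPeptides = 600L, nEmptySpots = 60L,
                         factors = list(
                           list(name = "f1", shifts = c(g1 = 3),
                                nLoadingPeptides = 30L,
                                loadingRange = c(0.3, 0.7), sign = 1),
                           list(name = "f2", shifts = c(g2 = 3),
                                nLoadingPeptides = 30L,
                                loadingRange = c(0.3, 0.7), sign = 1)),
                         seed = 1L)
  accs <- vapply(1:5, function(s) {
    cfg$seed <- s
    sim <- simulateImmunosignature(cfg)
    x <- medianNormalizeLog10(sim$experiment)
    sol <- rotateSolution(pafFit(correlationMatrix(x, "samples"), 2),
                          "promax")
    classifyByLoadings(sol, setNames(groupLabels(x), colnames(x)))@accuracy
  }, numeric(1))
  expect_gte(mean(accs), 95)

  # zero separation: accuracy is chance over replicates
  accsNull <- vapply(1:50, function(s) {
    cfg$seed <- 1000L + s
    sim <- simulateNull(cfg)
    x <- medianNormalizeLog10(sim$experiment)
    sol <- rotateSolution(pafFit(correlationMatrix(x, "samples"), 2),
                          "promax")
    classifyByLoadings(sol, setNames(groupLabels(x), colnames(x)))@accuracy
  }, numeric(1))
  expect_lt(abs(mean(accsNull) - 50), 10)
})
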