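# Fixtures are generated in code; nothing is read from disk except
# files the tests themselves write to tempdir().

# small raw-intensity container
tinyExperiment <- function(values = NULL, groups = NULL) {
  if (is.null(values))
    values <- matrix(c(100, 200, 300, 400,
                       150, 250, 350, 450,
                       120, 220, 320, 420),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(c("s1", "s2", "s3"),
                                     c("p1", "p2", "p3", "p4")))
  if (is.null(groups)) groups <- c("a", "a", "b")
  PeptideArrayExperiment(values, groups = groups)
}

# population correlation matrix satisfying a 1-factor model exactly
oneFactorCor <- function(lam) {
  R <- tcrossprod(lam) + diag(1 - lam^2)
  dimnames(R) <- list(paste0("v", seq_along(lam)), paste0("v", seq_along(lam)))
  R
}

# draw data from a CFA model: X = eta Lam' + eps
genCfaData <- function(n, lam, Phi = NULL, theta = NULL, prefix = NULL) {
  v <- nrow(lam); m <- ncol(lam)
  if (is.null(Phi)) Phi <- diag(m)
  if (is.null(theta)) theta <- rep(0.4, v)
  eta <- matrix(rnorm(n * m), n, m) %*% chol(Phi)
  X <- eta %*% t(lam) + sweep(matrix(rnorm(n * v), n, v), 2,
                              sqrt(theta), `*`)
  colnames(X) <- if (is.null(prefix)) paste0("x", seq_len(v)) else prefix
  attr(X, "eta") <- eta
  X
}

# two-class data with a shared factor whose direction is not aligned
# with the class mean shift (alternating loading signs)
twoClassData <- function(n1 = 60, n2 = 60, v = 6, shift = 3,
                         lamAbs = 0.7, resSd = 0.5) {
  lam <- lamAbs * rep(c(1, -1), length.out = v)
  mk <- function(n, mu) {
    matrix(rnorm(n), n, 1) %*% t(lam) +
      matrix(rnorm(n * v, 0, resSd), n, v) +
      matrix(mu, n, v, byrow = TRUE)
  }
  X <- rbind(mk(n1, rep(0, v)), mk(n2, rep(shift, v)))
  colnames(X) <- paste0("y", seq_len(v))
  attr(X, "class_truth") <- rep(1:2, c(n1, n2))
  X
}

# a minimal GenePix-results file
writeDemoGPR <- function(path, ids, names, values,
                         signalColumn = "F635 Median") {
  header <- c("ATF\t1.0", "2\t6",
              '"Type=GenePix Results 3"',
              '"Wavelengths=635"')
  cols <- paste(c("Block", "Row", "Column", "Name", "ID",
                  signalColumn), collapse = "\t")
  body <- paste(1, 1, seq_along(ids), names, ids, values, sep = "\t")
  writeLines(c(header, cols, body), path)
  path
}

# independent EM oracle: 2-component Gaussian mixture with shared
# diagonal covariance (the m = 0 factor mixture), plain R loops
diagGmmOracle <- function(X, maxIter = 2000, tol = 1e-10,
                          mu0 = NULL, w0 = c(0.5, 0.5)) {
  n <- nrow(X); v <- ncol(X)
  if (is.null(mu0)) {
    o <- order(rowSums(X))
    mu0 <- rbind(colMeans(X[head(o, n %/% 2), , drop = FALSE]),
                 colMeans(X[tail(o, n %/% 2), , drop = FALSE]))
  }
  mu <- mu0; w <- w0; sig2 <- apply(X, 2, var)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    ld <- sapply(1:2, function(k)
      log(w[k]) + rowSums(dnorm(X, matrix(mu[k, ], n, v, byrow = TRUE),
                                matrix(sqrt(sig2), n, v, byrow = TRUE),
                                log = TRUE)))
    mx <- apply(ld, 1, max)
    llNew <- sum(mx + log(rowSums(exp(ld - mx))))
    post <- exp(ld - mx); post <- post / rowSums(post)
    if (abs(llNew - ll) < tol) break
    ll <- llNew
    nk <- colSums(post)
    w <- nk / n
    mu <- (t(post) %*% X) / nk
    S <- matrix(0, 1, v)
    for (k in 1:2) {
      R <- sweep(X, 2, mu[k, ])
      S <- S + colSums(R^2 * post[, k])
    }
    sig2 <- as.numeric(S) / n
  }
  list(ll = llNew, w = w, mu = mu, sig2 = sig2)
}
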