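#' Bayesian Information Criterion
#'
#' \code{BIC = -2 LL + p ln(n)} (natural log), used to enumerate the
#' number of latent classes: the model with the lowest BIC is preferred.
#'
#' @param LL maximized log-likelihood.
#' @param p number of free parameters (>= 0).
#' @param n number of observations (>= 1).
#' @return The BIC value.
#' @export
bic <- function(LL, p, n) {
  if (n < 1) stop("n must be >= 1")
  if (p < 0) stop("p must be >= 0")
  -2 * LL + p * log(n)
}

#' Average latent class probability matrix
#'
#' Entry (j, k) is the mean posterior probability of class k among the
#' observations whose modal (most likely) class is j. Diagonal entries
#' near 1 indicate crisp classification.
#'
#' @param posterior n x K matrix of posterior class probabilities (rows
#'   sum to 1).
#' @param modal optional integer vector of modal classes (default:
#'   row-wise argmax of \code{posterior}).
#' @return K x K matrix; rows for empty modal classes are NA.
#' @export
avgClassProb <- function(posterior, modal = NULL) {
  posterior <- as.matrix(posterior)
  if (any(abs(rowSums(posterior) - 1) > 1e-6))
    stop("posterior rows must sum to 1")
  K <- ncol(posterior)
  if (is.null(modal)) modal <- max.col(posterior, ties.method = "first")
  out <- matrix(NA_real_, K, K,
                dimnames = list(paste0("modal", seq_len(K)),
                                paste0("class", seq_len(K))))
  for (j in seq_len(K)) {
    sel <- modal == j
    if (any(sel)) out[j, ] <- colMeans(posterior[sel, , drop = FALSE])
  }
  out
}

#' Exploratory factor mixture model fit
#'
#' @slot K,m class and factor counts.
#' @slot weights class proportions (descending).
#' @slot means K x v class-specific intercepts.
#' @slot lambda loadings: v x m matrix (shared) or list of K matrices.
#' @slot theta residual variances: length-v vector or list of K.
#' @slot posterior n x K posterior class probabilities.
#' @slot modal integer modal class per observation.
#' @slot logLik,nParameters,n,bicValue fit summary.
#' @slot avgClassProbs K x K average posterior matrix.
#' @slot startLog best log-likelihood reached from each random start.
#' @slot llTrace log-likelihood per EM iteration of the winning start.
#' @slot rotatedLambda geomin- (or promax-)rotated copy of the loadings
#'   for reporting, when m >= 2.
#' @slot converged,flags diagnostics (e.g. near-empty classes).
#' @export
setClass("MixtureResult",
         representation(K = "integer", m = "integer", weights = "numeric",
                        means = "matrix", lambda = "ANY", theta = "ANY",
                        posterior = "matrix", modal = "integer",
                        logLik = "numeric", nParameters = "integer",
                        n = "integer", bicValue = "numeric",
                        avgClassProbs = "matrix", startLog = "numeric",
                        llTrace = "numeric", rotatedLambda = "ANY",
                        converged = "logical", flags = "character"))

setMethod("show", "MixtureResult", function(object) {
  cat(sprintf("MixtureResult: K = %d classes, m = %d factor(s), n = %d\n",
              object@K, object@m, object@n))
  cat(sprintf("  logLik = %.4f, parameters = %d, BIC = %.4f\n",
              object@logLik, object@nParameters, object@bicValue))
  cat("  class weights:", paste(sprintf("%.3f", object@weights),
                                collapse = ", "), "\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags,
                                                  collapse = "; "), "\n")
})

# log density of rows of X under N(mu, Sigma) via Cholesky
.mvnLogDens <- function(X, mu, chS) {
  R <- sweep(X, 2L, mu)
  z <- forwardsolve(t(chS), t(R))
  -0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(chS))) + colSums(z^2))
}

# one EM-for-FA (Rubin-Thayer) update of (Lambda, theta) given scatter W
.faStep <- function(W, L, th, m) {
  v <- nrow(W)
  if (m == 0L) return(list(L = L, th = pmax(diag(W), 1e-8)))
  Sigma <- tcrossprod(L) + diag(th, v)
  B <- solve(Sigma, L)                 # v x m: Sigma^-1 Lambda
  beta <- t(B)                         # m x v
  Ezz <- diag(m) - beta %*% L + beta %*% W %*% t(beta)
  Lnew <- W %*% t(beta) %*% solve((Ezz + t(Ezz)) / 2)
  thNew <- pmax(diag(W - Lnew %*% beta %*% W), 1e-8)
  list(L = Lnew, th = thNew)
}

.mixLL <- function(X, w, mu, covs) {
  n <- nrow(X); K <- length(w)
  Lg <- matrix(0, n, K)
  for (k in seq_len(K)) {
    ch <- tryCatch(chol(covs[[k]]), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Lg[, k] <- log(w[k]) + .mvnLogDens(X, mu[k, ], ch)
  }
  mx <- apply(Lg, 1L, max)
  ll <- sum(mx + log(rowSums(exp(Lg - mx))))
  post <- exp(Lg - mx)
  post <- post / rowSums(post)
  list(ll = ll, post = post)
}

#' Fit an exploratory factor mixture model
#'
#' EM estimation of a K-class mixture of factor-analysis models: within
#' class k the observations are multivariate normal with class-specific
#' intercepts \eqn{V_k} and covariance \eqn{\Lambda \Lambda' + \Theta}
#' (factor covariance fixed at identity for identification). By default
#' the loadings and residual variances are shared across classes -- the
#' minimal model in which classes differ by their intercept profiles --
#' with fully class-specific covariances available via
#' \code{classSpecific = TRUE}. \code{m = 0} gives a diagonal Gaussian
#' mixture. Estimation uses \code{nStarts} perturbed initializations
#' around a K-means partition (start seeds derived from \code{seed});
#' the best log-likelihood is kept and every start's final
#' log-likelihood is retained for local-solution inspection. Classes
#' are reported in order of descending weight, making output
#' deterministic given the seed. The log-likelihood is checked to be
#' non-decreasing at every EM iteration.
#'
#' @param x observations x variables numeric matrix.
#' @param K number of latent classes (>= 1).
#' @param m factors per class (0 <= m < variables).
#' @param nStarts random starts (default 20).
#' @param seed integer seed (default 1).
#' @param classSpecific logical: class-specific loadings/residuals.
#' @param maxIter,tol EM control.
#' @return A \linkS4class{MixtureResult}.
#' @export
fmmFit <- function(x, K, m = 1L, nStarts = 20L, seed = 1L,
                   classSpecific = FALSE, maxIter = 500L, tol = 1e-8) {
  X <- as.matrix(x)
  n <- nrow(X); v <- ncol(X)
  if (K < 1L) stop("K must be >= 1")
  if (m < 0L || m >= v) stop("m must satisfy 0 <= m < ", v)
  covPar <- v * m - m * (m - 1) / 2 + v
  nPar <- as.integer((K - 1) + K * v + (if (classSpecific) K else 1) * covPar)
  if (nPar >= n * v)
    stop(sprintf("parameter count (%d) reaches the data degrees of freedom (%d)",
                 nPar, n * v))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  S0 <- cov(X)
  sds <- sqrt(diag(S0))
  e0 <- eigen(S0, symmetric = TRUE)
  L0 <- if (m > 0)
    e0$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(e0$values[seq_len(m)] * 0.7, 1e-3)), m)
  else matrix(0, v, 0)
  runStart <- function(s) {
    set.seed(seed + s - 1L)
    km <- if (K > 1L) kmeans(X, centers = K, nstart = 1L)
          else list(centers = matrix(colMeans(X), 1L))
    mu <- matrix(km$centers, K, v)
    if (s > 1L) mu <- mu + matrix(rnorm(K * v, 0, 0.25 * sds), K, v,
                                  byrow = TRUE)
    w <- rep(1 / K, K)
    if (classSpecific) {
      L <- replicate(K, L0, simplify = FALSE)
      th <- replicate(K, pmax(0.5 * diag(S0), 1e-6), simplify = FALSE)
    } else {
      L <- L0
      th <- pmax(0.5 * diag(S0), 1e-6)
    }
    getCovs <- function(L, th) {
      if (classSpecific)
        lapply(seq_len(K), function(k) tcrossprod(L[[k]]) + diag(th[[k]], v))
      else rep(list(tcrossprod(L) + diag(th, v)), K)
    }
    llPrev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      es <- .mixLL(X, w, mu, getCovs(L, th))
      if (is.null(es)) return(NULL)
      if (es$ll < llPrev - 1e-6 * (1 + abs(llPrev)))
        stop("EM log-likelihood decreased; numerical failure")
      trace <- c(trace, es$ll)
      if (is.finite(llPrev) &&
          es$ll - llPrev < tol * (1 + abs(es$ll))) {
        converged <- TRUE
        break
      }
      llPrev <- es$ll
      post <- es$post
      nk <- colSums(post)
      w <- nk / n
      mu <- (t(post) %*% X) / nk
      if (classSpecific) {
        for (k in seq_len(K)) {
          R <- sweep(X, 2L, mu[k, ])
          Wk <- crossprod(R * post[, k], R) / nk[k]
          up <- .faStep(Wk, L[[k]], th[[k]], m)
          L[[k]] <- up$L; th[[k]] <- up$th
        }
      } else {
        W <- matrix(0, v, v)
        for (k in seq_len(K)) {
          R <- sweep(X, 2L, mu[k, ])
          W <- W + crossprod(R * post[, k], R)
        }
        W <- W / n
        up <- .faStep(W, L, th, m)
        L <- up$L; th <- up$th
      }
    }
    es <- .mixLL(X, w, mu, getCovs(L, th))
    list(ll = es$ll, post = es$post, w = w, mu = mu, L = L, th = th,
         trace = trace, converged = converged)
  }
  fits <- vector("list", nStarts)
  for (s in seq_len(nStarts)) fits[[s]] <- runStart(s)
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all EM starts failed (singular covariance)")
  startLog <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$ll,
                     numeric(1))
  best <- fits[[which.max(replace(startLog, is.na(startLog), -Inf))]]
  # normalize label order by descending weight
  ord <- order(best$w, decreasing = TRUE)
  w <- best$w[ord]
  mu <- best$mu[ord, , drop = FALSE]
  post <- best$post[, ord, drop = FALSE]
  if (classSpecific) {
    Lout <- best$L[ord]; thOut <- best$th[ord]
  } else {
    Lout <- best$L; thOut <- best$th
  }
  modal <- max.col(post, ties.method = "first")
  flags <- character()
  if (any(w < 1 / n))
    flags <- c(flags, sprintf("near-empty class(es): %s",
                              paste(which(w < 1 / n), collapse = ",")))
  if (any(tabulate(modal, K) == 0L))
    flags <- c(flags, sprintf("class(es) with no modal members: %s",
                              paste(which(tabulate(modal, K) == 0L),
                                    collapse = ",")))
  rotated <- NULL
  if (m >= 2L && !classSpecific) {
    rotated <- tryCatch({
      sol <- methods::new("FactorSolution", loadings = Lout,
                          factorCorrelation = diag(m),
                          uniquenesses = thOut,
                          communalities = rowSums(Lout^2),
                          eigenvalues = rep(1, v), rotation = "none",
                          heywood = rep(FALSE, v), converged = TRUE,
                          nIterations = 0L, mode = "unknown",
                          method = "paf")
      loadings(rotateSolution(sol, "geomin"))
    }, error = function(e) tryCatch({
      sol <- methods::new("FactorSolution", loadings = Lout,
                          factorCorrelation = diag(m),
                          uniquenesses = thOut,
                          communalities = rowSums(Lout^2),
                          eigenvalues = rep(1, v), rotation = "none",
                          heywood = rep(FALSE, v), converged = TRUE,
                          nIterations = 0L, mode = "unknown",
                          method = "paf")
      loadings(rotateSolution(sol, "promax"))
    }, error = function(e2) NULL))
  }
  ll <- best$ll
  dimnames(mu) <- list(paste0("class", seq_len(K)), colnames(X))
  methods::new("MixtureResult", K = as.integer(K), m = as.integer(m),
               weights = w, means = mu, lambda = Lout, theta = thOut,
               posterior = post, modal = modal, logLik = ll,
               nParameters = nPar, n = as.integer(n),
               bicValue = bic(ll, nPar, n),
               avgClassProbs = avgClassProb(post, modal),
               startLog = startLog, llTrace = best$trace,
               rotatedLambda = rotated,
               converged = best$converged, flags = flags)
}

#' Enumerate latent classes by BIC
#'
#' Fits \code{\link{fmmFit}} for each candidate class count and returns
#' the BIC table with the selected (minimum-BIC) model.
#'
#' @param x observations x variables matrix.
#' @param Ks integer vector of class counts to try (default 1:3).
#' @param ... passed to \code{\link{fmmFit}}.
#' @return list: \code{table} (data.frame K, logLik, parameters, BIC),
#'   \code{bestK}, \code{fits} (list of \linkS4class{MixtureResult}).
#' @export
enumerateClasses <- function(x, Ks = 1:3, ...) {
  fits <- lapply(Ks, function(K) fmmFit(x, K = K, ...))
  tab <- data.frame(K = Ks,
                    logLik = vapply(fits, function(f) f@logLik, numeric(1)),
                    parameters = vapply(fits, function(f) f@nParameters,
                                        integer(1)),
                    BIC = vapply(fits, function(f) f@bicValue, numeric(1)))
  list(table = tab, bestK = Ks[which.min(tab$BIC)], fits = fits)
}
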