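#' Confirmatory factor model specification
#'
#' Encodes the measurement equation \eqn{x = \Lambda \xi + \Delta}: a
#' pattern of free/fixed/zero loadings \eqn{\Lambda} over indicators and
#' factors, one free residual variance per indicator, and a free/fixed
#' factor covariance pattern. Each factor is scaled either by a marker
#' indicator with loading fixed at 1 or by fixing its variance, which is
#' required for identification. An optional second-order layer lets the
#' first-order factors load on a single higher factor, and an optional
#' structural part records the outcome to be regressed on the factors.
#'
#' @slot indicators,factors identifier vectors.
#' @slot lambdaFree logical v x m: free loading pattern.
#' @slot lambdaValue numeric v x m: values of non-free loadings.
#' @slot phiFree logical m x m: free factor (co)variances.
#' @slot phiValue numeric m x m: fixed values elsewhere.
#' @slot secondOrder logical flag.
#' @slot gammaFree,gammaValue second-order loadings of first-order
#'   factors.
#' @slot psiFree,psiValue first-order disturbance variances under the
#'   second-order layer.
#' @slot structural list: \code{outcome}, \code{link}, \code{reference}
#'   (empty when absent).
#' @export
setClass("CfaSpec",
         representation(indicators = "character", factors = "character",
                        lambdaFree = "matrix", lambdaValue = "matrix",
                        phiFree = "matrix", phiValue = "matrix",
                        secondOrder = "logical", gammaFree = "logical",
                        gammaValue = "numeric", psiFree = "logical",
                        psiValue = "numeric", structural = "list"))

setValidity("CfaSpec", function(object) {
  v <- length(object@indicators); m <- length(object@factors)
  msg <- character()
  if (!all(dim(object@lambdaFree) == c(v, m)))
    msg <- c(msg, "lambda pattern dimensions must match indicators x factors")
  loadsOn <- object@lambdaFree | object@lambdaValue != 0
  if (any(rowSums(loadsOn) == 0))
    msg <- c(msg, "every indicator must load on at least one factor")
  if (!object@secondOrder) {
    for (j in seq_len(m)) {
      marker <- any(!object@lambdaFree[, j] & object@lambdaValue[, j] != 0)
      fixedVar <- !object@phiFree[j, j]
      if (!marker && !fixedVar)
        msg <- c(msg, sprintf(
          "factor '%s' needs a fixed nonzero loading or a fixed variance",
          object@factors[j]))
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CfaSpec", function(object) {
  cat(sprintf("CfaSpec: %d indicators, %d factors%s\n",
              length(object@indicators), length(object@factors),
              if (object@secondOrder) " + second-order factor" else ""))
  if (length(object@structural))
    cat("  structural:", object@structural$outcome, "~",
        paste(object@factors, collapse = " + "),
        sprintf("(%s)", object@structural$link), "\n")
  cat("  free parameters:", .countFree(object), "\n")
})

#' Build a CFA specification
#'
#' @param factorList named list: each element the character vector of
#'   indicator ids loading on that factor (an indicator may appear under
#'   several factors).
#' @param fix named numeric vector of fixed loadings written as
#'   \code{"indicator@factor" = value}; when a factor has no fixed
#'   loading and its variance is not fixed, its first indicator is fixed
#'   at 1 (marker scaling).
#' @param covary \code{"all"} (default; every factor pair covaries
#'   freely), \code{"none"}, or a list of character pairs.
#' @param fixedVariance character vector of factors whose variance is
#'   fixed at 1 instead of marker scaling.
#' @param outcome,link,reference optional structural part: outcome
#'   variable name, \code{"logistic"} or \code{"multinomial"}, and the
#'   reference outcome level.
#' @return A \linkS4class{CfaSpec}.
#' @export
cfaSpec <- function(factorList, fix = NULL, covary = "all",
                    fixedVariance = NULL, outcome = NULL,
                    link = c("logistic", "multinomial"), reference = NULL) {
  link <- match.arg(link)
  if (is.null(names(factorList)) || any(names(factorList) == ""))
    stop("factorList must be a named list")
  factors <- names(factorList)
  indicators <- unique(unlist(factorList))
  v <- length(indicators); m <- length(factors)
  lf <- matrix(FALSE, v, m, dimnames = list(indicators, factors))
  lv <- matrix(0, v, m, dimnames = list(indicators, factors))
  for (j in factors) lf[factorList[[j]], j] <- TRUE
  for (nm in names(fix)) {
    parts <- strsplit(nm, "@", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[1] %in% indicators ||
        !parts[2] %in% factors)
      stop("bad fix entry: ", nm)
    lf[parts[1], parts[2]] <- FALSE
    lv[parts[1], parts[2]] <- fix[[nm]]
  }
  pf <- matrix(FALSE, m, m, dimnames = list(factors, factors))
  pv <- matrix(0, m, m, dimnames = list(factors, factors))
  diag(pf) <- TRUE
  if (!is.null(fixedVariance)) {
    pf[cbind(fixedVariance, fixedVariance)] <- FALSE
    pv[cbind(fixedVariance, fixedVariance)] <- 1
  }
  if (identical(covary, "all")) {
    pf[upper.tri(pf)] <- TRUE; pf[lower.tri(pf)] <- TRUE
  } else if (!identical(covary, "none")) {
    for (pair in covary) {
      pf[pair[1], pair[2]] <- TRUE; pf[pair[2], pair[1]] <- TRUE
    }
  }
  # ensure scaling: marker if no fixed loading and variance free
  for (j in seq_len(m)) {
    hasMarker <- any(!lf[, j] & lv[, j] != 0)
    if (!hasMarker && pf[j, j]) {
      first <- factorList[[factors[j]]][1]
      lf[first, j] <- FALSE
      lv[first, j] <- 1
    }
  }
  structural <- if (is.null(outcome)) list() else
    list(outcome = outcome, link = link, reference = reference)
  methods::new("CfaSpec", indicators = indicators, factors = factors,
               lambdaFree = lf, lambdaValue = lv, phiFree = pf,
               phiValue = pv, secondOrder = FALSE,
               gammaFree = logical(0), gammaValue = numeric(0),
               psiFree = logical(0), psiValue = numeric(0),
               structural = structural)
}

#' Parse a CFA/SEM model file
#'
#' Order-insensitive line grammar:
#' \preformatted{
#' factor: F1 V1 V2 V3
#' fix: V1@F1 = 1
#' fixvar: F1
#' covary: F1 F2
#' outcome: disease ~ F1 F2 multinomial ref=single_tumor
#' }
#' Lines starting with \code{#} are comments. When no \code{fix} or
#' \code{fixvar} applies to a factor, marker scaling is used
#' automatically. \code{covary} defaults to none when the file is used
#' (covariances must be declared).
#'
#' @param x path of the model file, or a character vector of lines.
#' @return A \linkS4class{CfaSpec}.
#' @export
parseCfaModel <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE)
           else x
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  factorList <- list(); fix <- numeric(); covary <- list()
  fixedVariance <- character()
  outcome <- NULL; link <- "logistic"; reference <- NULL
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("unparseable model line: ", ln)
    key <- trimws(kv[1])
    rest <- trimws(paste(kv[-1], collapse = ":"))
    toks <- strsplit(rest, "[[:space:]]+")[[1]]
    if (key == "factor") {
      if (length(toks) < 2L) stop("factor line needs a name + indicators: ", ln)
      factorList[[toks[1]]] <- c(factorList[[toks[1]]], toks[-1])
    } else if (key == "fix") {
      eq <- strsplit(rest, "=", fixed = TRUE)[[1]]
      if (length(eq) != 2L) stop("fix line must be 'indicator@factor = value'")
      fix[trimws(eq[1])] <- as.numeric(trimws(eq[2]))
    } else if (key == "fixvar") {
      fixedVariance <- c(fixedVariance, toks)
    } else if (key == "covary") {
      if (length(toks) != 2L) stop("covary line needs two factors: ", ln)
      covary[[length(covary) + 1L]] <- toks
    } else if (key == "outcome") {
      form <- strsplit(rest, "~", fixed = TRUE)[[1]]
      if (length(form) != 2L) stop("outcome line must contain '~'")
      outcome <- trimws(form[1])
      rhs <- strsplit(trimws(form[2]), "[[:space:]]+")[[1]]
      if ("multinomial" %in% rhs) link <- "multinomial"
      refTok <- grep("^ref=", rhs, value = TRUE)
      if (length(refTok)) reference <- sub("^ref=", "", refTok[1])
    } else stop("unknown model directive: ", key)
  }
  if (!length(factorList)) stop("model defines no factors")
  cfaSpec(factorList, fix = if (length(fix)) fix else NULL,
          covary = if (length(covary)) covary else "none",
          fixedVariance = if (length(fixedVariance)) fixedVariance else NULL,
          outcome = outcome, link = link, reference = reference)
}

.countFree <- function(spec) {
  m <- length(spec@factors)
  n <- sum(spec@lambdaFree) + length(spec@indicators)  # loadings + residuals
  if (spec@secondOrder) {
    n + sum(spec@gammaFree) + sum(spec@psiFree)
  } else {
    pf <- spec@phiFree
    n + sum(diag(pf)) + sum(pf[upper.tri(pf)])
  }
}

#' Degrees of freedom of a covariance-structure model
#'
#' \eqn{v(v+1)/2} unique covariance moments minus the number of free
#' parameters (free loadings, free residual variances, free factor
#' variances/covariances, and second-order parameters when present);
#' covariance structure only, no mean structure. A three-indicator
#' one-factor model is just identified (df = 0).
#'
#' @param spec a \linkS4class{CfaSpec}.
#' @return Integer df; error if negative (under-identified).
#' @export
modelDf <- function(spec) {
  v <- length(spec@indicators)
  df <- v * (v + 1) / 2 - .countFree(spec)
  if (df < 0)
    stop("model is under-identified: df = ", df)
  as.integer(df)
}

## ---- parameter packing ------------------------------------------------

# free parameter layout: [lambda raw] [log theta] [phi diag log] [phi off raw]
# or second-order: [lambda raw] [log theta] [gamma raw] [log psi free]
.parTemplate <- function(spec, S) {
  v <- length(spec@indicators); m <- length(spec@factors)
  idxL <- which(spec@lambdaFree)
  nL <- length(idxL)
  nTh <- v
  if (spec@secondOrder) {
    nG <- sum(spec@gammaFree); nPs <- sum(spec@psiFree)
    npar <- nL + nTh + nG + nPs
  } else {
    pd <- which(diag(spec@phiFree))
    po <- which(spec@phiFree & upper.tri(spec@phiFree))
    npar <- nL + nTh + length(pd) + length(po)
  }
  list(v = v, m = m, idxL = idxL, nL = nL, npar = npar)
}

.unpack <- function(par, spec, tpl) {
  v <- tpl$v; m <- tpl$m
  L <- spec@lambdaValue
  if (tpl$nL) L[tpl$idxL] <- par[seq_len(tpl$nL)]
  theta <- exp(par[tpl$nL + seq_len(v)])
  pos <- tpl$nL + v
  if (spec@secondOrder) {
    g <- spec@gammaValue
    ng <- sum(spec@gammaFree)
    if (ng) g[spec@gammaFree] <- par[pos + seq_len(ng)]
    pos <- pos + ng
    psi <- spec@psiValue
    nps <- sum(spec@psiFree)
    if (nps) psi[spec@psiFree] <- exp(par[pos + seq_len(nps)])
    Phi <- tcrossprod(g) + diag(psi, m)
    extra <- list(gamma = g, psi = psi)
  } else {
    Phi <- spec@phiValue
    pd <- which(diag(spec@phiFree))
    if (length(pd)) {
      dvals <- exp(par[pos + seq_along(pd)])
      diag(Phi)[pd] <- dvals
      pos <- pos + length(pd)
    }
    po <- which(spec@phiFree & upper.tri(spec@phiFree), arr.ind = TRUE)
    if (nrow(po)) {
      for (k in seq_len(nrow(po))) {
        val <- par[pos + k]
        Phi[po[k, 1], po[k, 2]] <- val
        Phi[po[k, 2], po[k, 1]] <- val
      }
    }
    extra <- list()
  }
  dimnames(Phi) <- list(spec@factors, spec@factors)
  c(list(L = L, theta = theta, Phi = Phi), extra)
}

.implied <- function(pars) {
  pars$L %*% pars$Phi %*% t(pars$L) + diag(pars$theta, nrow(pars$L))
}

.fml <- function(S, Sigma, logdetS) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  logdet + tr - logdetS - nrow(S)
}

.startValues <- function(spec, S, tpl) {
  v <- tpl$v; m <- tpl$m
  sds <- sqrt(diag(S))
  par <- numeric(tpl$npar)
  # loading starts: scale-aware 0.7 * sd relative to marker/unit factor
  markerSd <- vapply(seq_len(m), function(j) {
    mk <- which(!spec@lambdaFree[, j] & spec@lambdaValue[, j] != 0)
    if (length(mk)) sds[mk[1]] / abs(spec@lambdaValue[mk[1], j]) else 1
  }, numeric(1))
  if (tpl$nL) {
    lidx <- arrayInd(tpl$idxL, dim(spec@lambdaFree))
    par[seq_len(tpl$nL)] <- 0.7 * sds[lidx[, 1]] / markerSd[lidx[, 2]]
  }
  par[tpl$nL + seq_len(v)] <- log(pmax(0.5 * diag(S), 1e-4))
  pos <- tpl$nL + v
  if (spec@secondOrder) {
    ng <- sum(spec@gammaFree)
    if (ng) par[pos + seq_len(ng)] <- 0.7 * markerSd[spec@gammaFree]
    pos <- pos + ng
    nps <- sum(spec@psiFree)
    if (nps) par[pos + seq_len(nps)] <-
        log(pmax(0.3 * markerSd[spec@psiFree]^2, 1e-4))
  } else {
    pd <- which(diag(spec@phiFree))
    if (length(pd)) {
      par[pos + seq_along(pd)] <- log(pmax(0.5 * markerSd[pd]^2, 1e-4))
      pos <- pos + length(pd)
    }
    npo <- sum(spec@phiFree & upper.tri(spec@phiFree))
    if (npo) par[pos + seq_len(npo)] <- 0
  }
  par
}

#' Model fit indices for covariance-structure models
#'
#' @slot chiSquare likelihood-ratio statistic \eqn{(n-1) F_{ML}}.
#' @slot df model degrees of freedom.
#' @slot pValue chi-square tail probability (NA for df = 0).
#' @slot rmsea root mean square error of approximation,
#'   \eqn{\sqrt{\max(0, (\chi^2/df - 1)/(n-1))}} (NA for df = 0).
#' @slot srmr standardized root mean square residual over the unique
#'   elements of \eqn{S - \Sigma}, standardized by
#'   \eqn{\sqrt{S_{ii} S_{jj}}} (diagonal included).
#' @slot n sample size used.
#' @export
setClass("FitIndices",
         representation(chiSquare = "numeric", df = "integer",
                        pValue = "numeric", rmsea = "numeric",
                        srmr = "numeric", n = "integer"))

setMethod("show", "FitIndices", function(object) {
  if (object@df == 0L) {
    cat(sprintf("Chi-Sq = %.3f, df = 0 (just identified; p/RMSEA not applicable), SRMR = %.3f, n = %d\n",
                object@chiSquare, object@srmr, object@n))
  } else {
    cat(sprintf("Chi-Sq = %.3f, df = %d, p = %.4f, RMSEA = %.3f, SRMR = %.3f, n = %d\n",
                object@chiSquare, object@df, object@pValue, object@rmsea,
                object@srmr, object@n))
  }
})

#' Compute chi-square, RMSEA and SRMR fit indices
#'
#' RMSEA is based on the non-centrality \eqn{\chi^2 - df}, clamped at 0
#' when the statistic falls below its degrees of freedom; the p-value is
#' the chi-square survival probability. SRMR is the root mean squared
#' standardized residual between observed and implied covariances,
#' including diagonal elements. For just-identified models (df = 0) the
#' p-value and RMSEA are reported as NA while SRMR is still computed.
#'
#' @param chiSquare model chi-square (>= 0).
#' @param df model degrees of freedom (>= 0).
#' @param n sample size (> 1).
#' @param S,Sigma observed and model-implied covariance matrices (needed
#'   for SRMR; may be NULL, giving SRMR = NA).
#' @return A \linkS4class{FitIndices} object.
#' @export
computeFitIndices <- function(chiSquare, df, n, S = NULL, Sigma = NULL) {
  if (df < 0) stop("df must be >= 0")
  if (n <= 1) stop("n must be > 1")
  srmr <- NA_real_
  if (!is.null(S) && !is.null(Sigma)) {
    d <- sqrt(diag(S))
    res <- (S - Sigma) / tcrossprod(d)
    srmr <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))
  }
  if (df == 0L) {
    p <- NA_real_; rmsea <- NA_real_
  } else {
    p <- pchisq(chiSquare, df, lower.tail = FALSE)
    rmsea <- sqrt(max(0, (chiSquare / df - 1) / (n - 1)))
  }
  methods::new("FitIndices", chiSquare = as.numeric(chiSquare),
               df = as.integer(df), pValue = p, rmsea = rmsea,
               srmr = srmr, n = as.integer(n))
}

#' Fitted confirmatory factor model
#'
#' @slot spec the \linkS4class{CfaSpec} fitted.
#' @slot lambda,phi,theta estimated loadings, factor covariance, and
#'   residual variances.
#' @slot gamma,psi second-order estimates (length 0 otherwise).
#' @slot standardizedLoadings loadings on the correlation metric.
#' @slot scores Bartlett factor scores (0 rows when fitted from a
#'   covariance matrix only).
#' @slot paramTable data.frame of estimates and standard errors.
#' @slot fit \linkS4class{FitIndices}.
#' @slot S,Sigma observed and implied covariance matrices.
#' @slot FML,n discrepancy value and sample size.
#' @slot converged logical.
#' @slot boundWarnings character: parameters that hit their bounds.
#' @export
setClass("CfaResult",
         representation(spec = "CfaSpec", lambda = "matrix", phi = "matrix",
                        theta = "numeric", gamma = "numeric",
                        psi = "numeric", standardizedLoadings = "matrix",
                        scores = "matrix", paramTable = "data.frame",
                        fit = "FitIndices", S = "matrix", Sigma = "matrix",
                        FML = "numeric", n = "integer",
                        converged = "logical", boundWarnings = "character"))

#' @rdname immunosig-generics
#' @export
setMethod("fitIndices", "CfaResult", function(object) object@fit)
#' @rdname immunosig-generics
#' @export
setMethod("loadings", "CfaResult", function(object) object@lambda)

setMethod("show", "CfaResult", function(object) {
  cat(sprintf("CfaResult: %d indicators, %d factors%s; converged: %s\n",
              length(object@spec@indicators), length(object@spec@factors),
              if (object@spec@secondOrder) " (second-order)" else "",
              object@converged))
  show(object@fit)
  if (length(object@boundWarnings))
    cat("  at bound:", paste(object@boundWarnings, collapse = ", "), "\n")
})

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' \deqn{F_{ML} = \ln|\Sigma(\theta)| + tr(S \Sigma(\theta)^{-1}) -
#'   \ln|S| - v}
#' by quasi-Newton (BFGS) from moment-based starting values, with
#' variance parameters optimized on the log scale to enforce
#' positivity. The likelihood-ratio statistic is \eqn{(n-1) F_{ML}} at
#' the optimum; fit indices (\code{\link{computeFitIndices}}) are
#' attached. Standard errors come from the numerical Hessian of the
#' discrepancy; with \code{robust = TRUE}, Huber-White sandwich standard
#' errors computed from casewise score contributions are reported
#' instead (point estimates are unchanged; requires raw data).
#'
#' @param spec a \linkS4class{CfaSpec}.
#' @param data numeric matrix, observations x indicators (column names
#'   must cover the spec's indicators). Alternatively \code{NULL} with
#'   \code{sampleCov} and \code{n} supplied.
#' @param sampleCov optional observed covariance matrix.
#' @param n sample size (required with \code{sampleCov}).
#' @param robust logical: sandwich standard errors (default FALSE).
#' @param maxIter,tol optimizer control.
#' @return A \linkS4class{CfaResult}.
#' @export
cfaFit <- function(spec, data = NULL, sampleCov = NULL, n = NULL,
                   robust = FALSE, maxIter = 500L, tol = 1e-8) {
  if (is.null(data) && is.null(sampleCov))
    stop("supply data or sampleCov + n")
  if (!is.null(data)) {
    data <- as.matrix(data)
    miss <- setdiff(spec@indicators, colnames(data))
    if (length(miss))
      stop("data lacks indicator(s): ", paste(miss, collapse = ", "))
    X <- data[, spec@indicators, drop = FALSE]
    n <- nrow(X)
    S <- cov(X)
  } else {
    if (is.null(n)) stop("n is required with sampleCov")
    S <- as.matrix(sampleCov)[spec@indicators, spec@indicators]
    X <- NULL
  }
  v <- length(spec@indicators)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < max(ev) * 1e-10 || min(ev) <= 0)
    stop("sample covariance is (near-)singular; reduce the number of indicators")
  nfree <- .countFree(spec)
  if (n <= nfree)
    stop(sprintf("sample size (%d) must exceed the free parameter count (%d)",
                 n, nfree))
  df <- modelDf(spec)
  tpl <- .parTemplate(spec, S)
  logdetS <- as.numeric(determinant(S)$modulus)
  fn <- function(par) {
    pars <- .unpack(par, spec, tpl)
    f <- .fml(S, .implied(pars), logdetS)
    if (!is.finite(f)) 1e10 else f
  }
  start <- .startValues(spec, S, tpl)
  opt <- optim(start, fn, method = "BFGS", hessian = TRUE,
               control = list(maxit = maxIter, reltol = tol))
  pars <- .unpack(opt$par, spec, tpl)
  Sigma <- .implied(pars)
  FML <- max(0, opt$value)
  chi2 <- (n - 1) * FML
  fit <- computeFitIndices(chi2, df, n, S, Sigma)
  bound <- character()
  if (any(pars$theta < 1e-6))
    bound <- c(bound, paste0("theta:",
                             spec@indicators[pars$theta < 1e-6]))
  if (spec@secondOrder && any(pars$psi < 1e-6 & spec@psiFree))
    bound <- c(bound, paste0("psi:", spec@factors[pars$psi < 1e-6 &
                                                    spec@psiFree]))
  if (length(bound))
    warning("variance estimate(s) at lower bound: ",
            paste(bound, collapse = ", "))
  # standard errors
  se <- rep(NA_real_, tpl$npar)
  acov <- tryCatch({
    H <- (n - 1) / 2 * opt$hessian
    solve(H)
  }, error = function(e) NULL)
  if (!is.null(acov)) se <- sqrt(pmax(diag(acov), 0))
  if (robust && !is.null(X)) {
    se2 <- tryCatch(.sandwichSE(opt$par, spec, tpl, X),
                    error = function(e) NULL)
    if (!is.null(se2)) se <- se2
  }
  paramTable <- .paramTable(opt$par, se, spec, tpl)
  # standardized loadings
  stdL <- pars$L %*% diag(sqrt(diag(pars$Phi)), tpl$m) / sqrt(diag(Sigma))
  dimnames(stdL) <- dimnames(pars$L)
  scores <- matrix(numeric(0), 0, tpl$m)
  if (!is.null(X)) scores <- .bartlettScores(X, pars)
  methods::new("CfaResult", spec = spec, lambda = pars$L, phi = pars$Phi,
               theta = setNames(pars$theta, spec@indicators),
               gamma = if (spec@secondOrder) pars$gamma else numeric(0),
               psi = if (spec@secondOrder) pars$psi else numeric(0),
               standardizedLoadings = stdL, scores = scores,
               paramTable = paramTable, fit = fit, S = S, Sigma = Sigma,
               FML = FML, n = as.integer(n),
               converged = opt$convergence == 0L, boundWarnings = bound)
}

.paramTable <- function(par, se, spec, tpl) {
  nm <- character(tpl$npar)
  est <- numeric(tpl$npar)
  seOut <- se
  if (tpl$nL) {
    li <- arrayInd(tpl$idxL, dim(spec@lambdaFree))
    nm[seq_len(tpl$nL)] <- sprintf("lambda[%s,%s]",
                                   spec@indicators[li[, 1]],
                                   spec@factors[li[, 2]])
    est[seq_len(tpl$nL)] <- par[seq_len(tpl$nL)]
  }
  v <- tpl$v
  thIdx <- tpl$nL + seq_len(v)
  nm[thIdx] <- sprintf("theta[%s]", spec@indicators)
  est[thIdx] <- exp(par[thIdx])
  seOut[thIdx] <- se[thIdx] * est[thIdx]   # delta method for log scale
  pos <- tpl$nL + v
  if (spec@secondOrder) {
    ng <- sum(spec@gammaFree)
    if (ng) {
      nm[pos + seq_len(ng)] <- sprintf("gamma[%s]",
                                       spec@factors[spec@gammaFree])
      est[pos + seq_len(ng)] <- par[pos + seq_len(ng)]
      pos <- pos + ng
    }
    nps <- sum(spec@psiFree)
    if (nps) {
      idx <- pos + seq_len(nps)
      nm[idx] <- sprintf("psi[%s]", spec@factors[spec@psiFree])
      est[idx] <- exp(par[idx])
      seOut[idx] <- se[idx] * est[idx]
    }
  } else {
    pd <- which(diag(spec@phiFree))
    if (length(pd)) {
      idx <- pos + seq_along(pd)
      nm[idx] <- sprintf("phi[%s,%s]", spec@factors[pd], spec@factors[pd])
      est[idx] <- exp(par[idx])
      seOut[idx] <- se[idx] * est[idx]
      pos <- pos + length(pd)
    }
    po <- which(spec@phiFree & upper.tri(spec@phiFree), arr.ind = TRUE)
    if (nrow(po)) {
      idx <- pos + seq_len(nrow(po))
      nm[idx] <- sprintf("phi[%s,%s]", spec@factors[po[, 1]],
                         spec@factors[po[, 2]])
      est[idx] <- par[idx]
    }
  }
  data.frame(parameter = nm, estimate = est, std_error = seOut,
             stringsAsFactors = FALSE)
}

# casewise normal log-likelihood scores by central differences
.sandwichSE <- function(par, spec, tpl, X) {
  Xc <- sweep(X, 2L, colMeans(X))
  n <- nrow(Xc)
  caseLL <- function(p) {
    pars <- .unpack(p, spec, tpl)
    Sigma <- .implied(pars)
    ch <- chol(Sigma)
    Sinv <- chol2inv(ch)
    cst <- -0.5 * (2 * sum(log(diag(ch))) + ncol(Xc) * log(2 * pi))
    cst - 0.5 * rowSums((Xc %*% Sinv) * Xc)
  }
  h <- 1e-5
  G <- matrix(0, n, length(par))
  for (k in seq_along(par)) {
    pp <- par; pp[k] <- pp[k] + h
    pm <- par; pm[k] <- pm[k] - h
    G[, k] <- (caseLL(pp) - caseLL(pm)) / (2 * h)
  }
  # observed information via numerical Hessian of the summed loglik
  f <- function(p) sum(caseLL(p))
  A <- .numHess(f, par)
  B <- crossprod(G)
  Ainv <- solve(A)
  sqrt(pmax(diag(Ainv %*% B %*% t(Ainv)), 0))
}

.numHess <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  fp <- fm <- numeric(k)
  for (i in seq_len(k)) {
    xp <- x; xp[i] <- xp[i] + h; fp[i] <- f(xp)
    xm <- x; xm[i] <- xm[i] - h; fm[i] <- f(xm)
  }
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
      } else {
        xpp <- x; xpp[c(i, j)] <- xpp[c(i, j)] + h
        xmm <- x; xmm[c(i, j)] <- xmm[c(i, j)] - h
        H[i, j] <- H[j, i] <-
          (f(xpp) - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + f(xmm)) /
          (2 * h^2)
      }
    }
  }
  -H  # information = -Hessian of loglik
}

# Bartlett factor scores: (L' Th^-1 L)^-1 L' Th^-1 (x - xbar)
.bartlettScores <- function(X, pars) {
  Xc <- sweep(X, 2L, colMeans(X))
  W <- pars$L / pars$theta           # Th^-1 L
  M <- solve(crossprod(pars$L, W), t(W))
  sc <- Xc %*% t(M)
  colnames(sc) <- colnames(pars$L)
  sc
}

#' Bartlett factor scores from a fitted CFA
#'
#' @param object a \linkS4class{CfaResult} fitted from raw data.
#' @return Matrix of per-observation factor scores.
#' @export
factorScores <- function(object) {
  if (!nrow(object@scores))
    stop("no factor scores: model was fitted from a covariance matrix")
  object@scores
}
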