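#' Correlation matrix for factor analysis
#'
#' Pearson correlation matrix among the entities to be factored. S4
#' class \code{CorrelationMatrix} records the matrix, the mode
#' (\code{samples_as_variables} -- the Q-technique orientation used to
#' cluster sera samples -- or \code{peptides_as_variables}) and the
#' number of observations behind each correlation.
#'
#' @slot values symmetric correlation matrix with unit diagonal.
#' @slot mode character, orientation of the analysis.
#' @slot nObservations integer, observations per correlation.
#' @export
setClass("CorrelationMatrix",
         representation(values = "matrix", mode = "character",
                        nObservations = "integer"))

setValidity("CorrelationMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "must be square")
  else {
    if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "must be symmetric")
    if (max(abs(diag(v) - 1)) > 1e-8) msg <- c(msg, "diagonal must be 1")
    if (any(abs(v) > 1 + 1e-8)) msg <- c(msg, "entries must be in [-1, 1]")
    if (nrow(v) <= 500L && min(eigen(v, symmetric = TRUE,
                                     only.values = TRUE)$values) < -1e-6)
      msg <- c(msg, "matrix must be positive semi-definite")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat("CorrelationMatrix:", nrow(object@values), "variables (",
      object@mode, "),", object@nObservations, "observations\n")
})

#' Build a correlation matrix from normalized intensities
#'
#' In \code{samples} mode (the orientation used to classify sera), the
#' variables are samples and the observations are the non-empty-spot
#' peptides. The baseline binding profile shared by every sample makes
#' all samples correlate positively; under an oblique rotation this
#' common component is absorbed into the factor correlation, leaving
#' group structure in the pattern loadings, so ordinary Pearson
#' correlation is the default. \code{center = "double"} additionally
#' removes the per-peptide mean profile first (note that with only two
#' groups this forces the group deviation profiles to be antiparallel,
#' collapsing group structure into a single bipolar factor -- use with
#' care). In \code{peptides} mode the variables are peptides and
#' observations are samples (used to infer the factor structure of a
#' significant-peptide set). A plain numeric matrix (observations x
#' variables) can be given instead of a container.
#'
#' @param x a normalized \linkS4class{PeptideArrayExperiment} or a
#'   numeric observations x variables matrix.
#' @param mode \code{"samples"} or \code{"peptides"} (ignored for plain
#'   matrix input, which is taken as-is with mode recorded as given).
#' @param center \code{"variables"} (ordinary Pearson; default) or
#'   \code{"double"} (also remove per-observation means first).
#' @param peptides optional character vector restricting peptides used.
#' @return A \linkS4class{CorrelationMatrix}.
#' @export
correlationMatrix <- function(x, mode = c("samples", "peptides"),
                              center = NULL, peptides = NULL) {
  mode <- match.arg(mode)
  if (methods::is(x, "PeptideArrayExperiment")) {
    v <- normalizedValues(x)            # peptides x samples
    keep <- !emptySpots(x)
    if (!is.null(peptides)) keep <- keep & rownames(v) %in% peptides
    v <- v[keep, , drop = FALSE]
    obs <- if (mode == "samples") v else t(v)
  } else {
    obs <- as.matrix(x)                 # observations x variables
  }
  if (is.null(center)) center <- "variables"
  center <- match.arg(center, c("double", "variables"))
  if (nrow(obs) < 3L) stop("need at least 3 observations per correlation")
  if (center == "double")
    obs <- obs - rowMeans(obs)
  sds <- apply(obs, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(obs)[sds == 0], collapse = ", "))
  R <- cor(obs)
  # guard tiny asymmetries/overshoot from floating point
  R <- (R + t(R)) / 2
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- 1
  methods::new("CorrelationMatrix", values = R,
               mode = if (mode == "samples") "samples_as_variables"
                      else "peptides_as_variables",
               nObservations = nrow(obs))
}

.asCorMatrix <- function(R) {
  if (methods::is(R, "CorrelationMatrix")) return(R@values)
  as.matrix(R)
}

#' Eigenvalue spectrum and scree-based factor count suggestion
#'
#' Returns the full eigenvalue spectrum of a correlation matrix in
#' descending order, together with an advisory factor count: the index
#' of the largest relative eigenvalue drop among eigenvalues of at
#' least 1 (a stated convention standing in for visual scree
#' inspection; always user-overridable downstream).
#'
#' @param R a \linkS4class{CorrelationMatrix} or correlation matrix.
#' @return A list with \code{eigenvalues} (descending) and
#'   \code{suggested} (integer factor count).
#' @export
eigenScree <- function(R) {
  Rm <- .asCorMatrix(R)
  ev <- sort(eigen(Rm, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  v <- length(ev)
  cand <- which(ev[-v] >= 1)
  if (!length(cand)) {
    sug <- 1L
  } else {
    drop <- (ev[cand] - ev[cand + 1L]) / pmax(ev[cand + 1L], 1e-12)
    sug <- cand[which.max(drop)]
  }
  list(eigenvalues = ev, suggested = as.integer(sug))
}

#' Exploratory factor solution
#'
#' Result of principal axis factoring (or PCA) with optional rotation.
#' The common-factor decomposition is
#' \eqn{R = A R_f A' + D^2}: \code{loadings} is the v x m pattern matrix
#' A, \code{factorCorrelation} the m x m factor correlation
#' \eqn{R_f} (identity for unrotated/orthogonal solutions),
#' \code{uniquenesses} the diagonal of \eqn{D^2}, and
#' \code{communalities} the complement \eqn{1 - D^2} capturing the
#' variance each variable shares with the common factors.
#'
#' @slot loadings pattern matrix (variables x factors).
#' @slot factorCorrelation factor correlation matrix.
#' @slot uniquenesses,communalities per-variable variance split.
#' @slot eigenvalues spectrum of the input correlation matrix.
#' @slot rotation one of none/varimax/promax/geomin.
#' @slot heywood logical per variable: communality estimate reached 1.
#' @slot converged,nIterations iteration diagnostics.
#' @slot mode orientation tag propagated from the correlation matrix.
#' @slot method "paf" or "pca".
#' @export
setClass("FactorSolution",
         representation(loadings = "matrix", factorCorrelation = "matrix",
                        uniquenesses = "numeric", communalities = "numeric",
                        eigenvalues = "numeric", rotation = "character",
                        heywood = "logical", converged = "logical",
                        nIterations = "integer", mode = "character",
                        method = "character"))

#' @rdname immunosig-generics
#' @export
setMethod("loadings", "FactorSolution", function(object) object@loadings)
#' @rdname immunosig-generics
#' @export
setMethod("factorCorrelation", "FactorSolution",
          function(object) object@factorCorrelation)
#' @rdname immunosig-generics
#' @export
setMethod("uniquenesses", "FactorSolution",
          function(object) object@uniquenesses)
#' @rdname immunosig-generics
#' @export
setMethod("communalities", "FactorSolution",
          function(object) object@communalities)
#' @rdname immunosig-generics
#' @export
setMethod("eigenvalues", "FactorSolution",
          function(object) object@eigenvalues)

setMethod("show", "FactorSolution", function(object) {
  cat(sprintf("FactorSolution: %d variables, %d factors (%s, rotation: %s)\n",
              nrow(object@loadings), ncol(object@loadings),
              object@method, object@rotation))
  cat(sprintf("  converged: %s in %d iterations; Heywood variables: %d\n",
              object@converged, object@nIterations, sum(object@heywood)))
})

# flip each factor column so its largest-|loading| entry is positive;
# propagate sign flips into the factor correlation matrix.
.signFix <- function(L, Phi) {
  s <- vapply(seq_len(ncol(L)), function(j) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) -1 else 1
  }, numeric(1))
  L <- sweep(L, 2L, s, `*`)
  Phi <- diag(s, ncol(L)) %*% Phi %*% diag(s, ncol(L))
  dimnames(Phi) <- list(colnames(L), colnames(L))
  list(L = L, Phi = Phi)
}

#' Principal axis factoring with iterated communalities
#'
#' Ordinary least squares estimation of the common factor model: the
#' correlation diagonal is replaced by communality estimates
#' (initialized with squared multiple correlations), the reduced matrix
#' is eigendecomposed, loadings are the top-m scaled eigenvectors, and
#' the communalities are re-estimated until the largest change falls
#' below \code{tol}. Communality estimates exceeding 1 (Heywood cases)
#' are clipped to 1 - 1e-6 and flagged rather than raising an error.
#' With \code{method = "pca"} the diagonal is left at 1 and no
#' iteration occurs, giving principal components (zero uniquenesses) for
#' the PCA-versus-EFA comparison.
#'
#' @param R a \linkS4class{CorrelationMatrix} or correlation matrix.
#' @param m number of factors (1 <= m < number of variables).
#' @param maxIter,tol iteration control for the communality updates.
#' @param method \code{"paf"} (default) or \code{"pca"}.
#' @return An unrotated \linkS4class{FactorSolution}.
#' @export
pafFit <- function(R, m, maxIter = 200L, tol = 1e-6,
                   method = c("paf", "pca")) {
  method <- match.arg(method)
  mode <- if (methods::is(R, "CorrelationMatrix")) R@mode else "unknown"
  Rm <- .asCorMatrix(R)
  v <- nrow(Rm)
  if (m < 1L || m >= v) stop("factor count m must satisfy 1 <= m < ", v)
  evR <- sort(eigen(Rm, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  if (method == "pca") {
    e <- eigen(Rm, symmetric = TRUE)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
    dimnames(L) <- list(rownames(Rm), paste0("F", seq_len(m)))
    sf <- .signFix(L, diag(m))
    return(methods::new("FactorSolution", loadings = sf$L,
                        factorCorrelation = diag(m),
                        uniquenesses = rep(0, v),
                        communalities = rowSums(sf$L^2),
                        eigenvalues = evR, rotation = "none",
                        heywood = rep(FALSE, v), converged = TRUE,
                        nIterations = 0L, mode = mode, method = "pca"))
  }
  # squared multiple correlations; fall back to max |r| if R is singular
  h2 <- tryCatch(1 - 1 / diag(solve(Rm)),
                 error = function(e) {
                   Ro <- Rm; diag(Ro) <- 0
                   apply(abs(Ro), 1L, max)
                 })
  h2 <- pmin(pmax(h2, 0), 1 - 1e-6)
  heywood <- rep(FALSE, v)
  converged <- FALSE
  it <- 0L
  L <- NULL
  while (it < maxIter) {
    it <- it + 1L
    Rr <- Rm
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(m)], 0)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(lam), m)
    h2new <- rowSums(L^2)
    hey <- h2new > 1
    heywood <- heywood | hey
    h2new[hey] <- 1 - 1e-6
    delta <- max(abs(h2new - h2))
    h2 <- h2new
    if (delta < tol) { converged <- TRUE; break }
  }
  dimnames(L) <- list(rownames(Rm), paste0("F", seq_len(m)))
  sf <- .signFix(L, diag(m))
  methods::new("FactorSolution", loadings = sf$L,
               factorCorrelation = diag(m), uniquenesses = 1 - h2,
               communalities = h2, eigenvalues = evR, rotation = "none",
               heywood = heywood, converged = converged,
               nIterations = it, mode = mode, method = "paf")
}

## ---- gradient-projection rotation engine ------------------------------

# varimax criterion (to be minimized): -1/4 sum (L^2 - colmean(L^2))^2
.critVarimax <- function(L) {
  Q <- L^2
  Qc <- sweep(Q, 2L, colMeans(Q))
  list(f = -sum(Qc * Q) / 4, G = -L * Qc)
}

.critGeomin <- function(eps) {
  force(eps)
  function(L) {
    m <- ncol(L)
    L2 <- L^2 + eps
    pro <- exp(rowSums(log(L2)) / m)
    list(f = sum(pro), G = (2 / m) * (L / L2) * pro)
  }
}

# orthogonal gradient projection (minimizes crit over rotations T'T = I)
.gpForth <- function(A, crit, Tinit = NULL, maxit = 500L, tol = 1e-8) {
  m <- ncol(A)
  Tm <- if (is.null(Tinit)) diag(m) else Tinit
  al <- 1
  L <- A %*% Tm
  cv <- crit(L)
  G <- crossprod(A, cv$G)
  for (i in seq_len(maxit)) {
    M <- crossprod(Tm, G)
    S <- (M + t(M)) / 2
    Gp <- G - Tm %*% S
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    repeat {
      X <- Tm - al * Gp
      sv <- svd(X)
      Tt <- sv$u %*% t(sv$v)
      Lt <- A %*% Tt
      ct <- crit(Lt)
      if (ct$f < cv$f - 0.5 * s^2 * al || al < 1e-10) break
      al <- al / 2
    }
    Tm <- Tt; cv <- ct; L <- Lt
    G <- crossprod(A, cv$G)
  }
  list(L = L, T = Tm, f = cv$f)
}

# oblique gradient projection (columns of T have unit length);
# pattern L = A (T')^{-1}, factor correlation Phi = T'T
.gpFoblq <- function(A, crit, Tinit = NULL, maxit = 500L, tol = 1e-8) {
  m <- ncol(A)
  Tm <- if (is.null(Tinit)) diag(m) else Tinit
  al <- 1
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  cv <- crit(L)
  G <- -t(t(L) %*% cv$G %*% Ti)
  for (i in seq_len(maxit)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G), m)
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    repeat {
      X <- Tm - al * Gp
      v <- 1 / sqrt(colSums(X^2))
      Tt <- X %*% diag(v, m)
      Tti <- tryCatch(solve(Tt), error = function(e) NULL)
      if (!is.null(Tti)) {
        Lt <- A %*% t(Tti)
        ct <- crit(Lt)
        if (ct$f < cv$f - 0.5 * s^2 * al || al < 1e-10) break
      }
      al <- al / 2
      if (al < 1e-12) { Tt <- Tm; Tti <- solve(Tm); Lt <- L; ct <- cv; break }
    }
    Tm <- Tt; Ti <- Tti; L <- Lt; cv <- ct
    G <- -t(t(L) %*% cv$G %*% Ti)
  }
  list(L = L, T = Tm, Phi = crossprod(Tm), f = cv$f)
}

.randomOrthogonal <- function(m) {
  qr.Q(qr(matrix(rnorm(m * m), m, m)))
}

#' Rotate an exploratory factor solution
#'
#' Rotates the loading pattern for interpretability without changing the
#' solution's fit: the reconstruction \eqn{A R_f A' + D^2} and the
#' communalities are invariant. \code{varimax} is orthogonal
#' (Kaiser row-normalized, maximizing the variance of squared loadings
#' per factor, factor correlation fixed at identity); \code{promax}
#' raises the varimax loadings element-wise to the power \code{kappa}
#' (keeping signs) to form a simple-structure target and obliquely
#' Procrustes-rotates to it, returning a pattern matrix and a factor
#' correlation; \code{geomin} minimizes the geomin criterion (product of
#' squared loadings per row, smoothed by \code{geominEpsilon}) by
#' oblique gradient projection from \code{nStarts} random orthogonal
#' starts, keeping the best criterion value. Single-factor solutions
#' are returned unchanged.
#'
#' @param sol an unrotated (or orthogonally rotated)
#'   \linkS4class{FactorSolution}.
#' @param method \code{"varimax"}, \code{"promax"}, or \code{"geomin"}.
#' @param kappa promax target power (default 4, the classic choice).
#' @param geominEpsilon smoothing constant for geomin (default 0.01).
#' @param nStarts random orthogonal starts for geomin (default 30).
#' @param seed seed controlling the geomin starts (default 1, so output
#'   is deterministic).
#' @return A rotated \linkS4class{FactorSolution}.
#' @export
rotateSolution <- function(sol, method = c("varimax", "promax", "geomin"),
                           kappa = 4, geominEpsilon = 0.01, nStarts = 30L,
                           seed = 1L) {
  method <- match.arg(method)
  A <- sol@loadings
  m <- ncol(A)
  if (m < 2L) return(sol)
  if (method %in% c("varimax", "promax")) {
    # Kaiser normalization: rotate rows scaled to unit communality
    h <- sqrt(pmax(rowSums(A^2), 1e-12))
    An <- A / h
    rot <- .gpForth(An, .critVarimax)
    Lv <- rot$L * h
    if (method == "varimax") {
      L <- Lv; Phi <- diag(m)
    } else {
      # promax: oblique least-squares fit to the powered target
      Tgt <- sign(Lv) * abs(Lv)^kappa
      U <- qr.coef(qr(Lv), Tgt)
      d <- diag(solve(crossprod(U)))
      U <- U %*% diag(sqrt(d), m)
      L <- Lv %*% U
      Phi <- solve(crossprod(U))
      Phi <- (Phi + t(Phi)) / 2
    }
  } else {
    crit <- .critGeomin(geominEpsilon)
    best <- NULL
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    starts <- c(list(diag(m)),
                replicate(max(0L, nStarts - 1L), .randomOrthogonal(m),
                          simplify = FALSE))
    for (Tinit in starts) {
      r <- .gpFoblq(A, crit, Tinit = Tinit)
      if (is.null(best) || r$f < best$f) best <- r
    }
    L <- best$L
    Phi <- (best$Phi + t(best$Phi)) / 2
  }
  dimnames(L) <- dimnames(A)
  sf <- .signFix(L, Phi)
  out <- sol
  out@loadings <- sf$L
  out@factorCorrelation <- sf$Phi
  out@rotation <- method
  # communalities are rotation-invariant; recompute from the pattern
  out@communalities <- diag(sf$L %*% sf$Phi %*% t(sf$L))
  out@uniquenesses <- if (sol@method == "pca") rep(0, nrow(A)) else
    1 - out@communalities
  out
}

## ---- loading-threshold classification ---------------------------------

# all permutations of seq_len(n) as a matrix (n small: <= 5 groups)
.permMatrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permMatrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Classification result from loading thresholds
#'
#' @slot assignments data.frame: one row per variable with the assigned
#'   factor, the loading used, the known group, the group the factor
#'   maps to, and correctness.
#' @slot factorToGroup named character: group matched to each factor.
#' @slot accuracy percent correct among labeled variables (unclassified
#'   variables count as incorrect).
#' @slot crossLoadings data.frame of variables exceeding the threshold
#'   on more than one factor.
#' @slot threshold the |loading| cutoff used.
#' @export
setClass("FactorClassification",
         representation(assignments = "data.frame",
                        factorToGroup = "character", accuracy = "numeric",
                        crossLoadings = "data.frame", threshold = "numeric"))

setMethod("show", "FactorClassification", function(object) {
  cat(sprintf("FactorClassification: %.2f%% correct (threshold %.2f)\n",
              object@accuracy, object@threshold))
  cat("  factor -> group:",
      paste(names(object@factorToGroup), object@factorToGroup,
            sep = " -> ", collapse = ", "), "\n")
  cat("  unclassified:", sum(is.na(object@assignments$assigned_factor)),
      "; cross-loading:", nrow(object@crossLoadings), "\n")
})

#' Classify samples by their factor loadings
#'
#' Assigns each variable (sample, in the samples-as-variables
#' orientation) to the factor on which it has the largest absolute
#' pattern loading, provided that loading reaches \code{threshold};
#' samples below threshold on every factor are left unclassified and
#' count as incorrect. Factors are mapped to disease groups by the
#' permutation maximizing agreement with the known labels, and accuracy
#' is the percent of labeled samples assigned to their group's factor.
#'
#' @param sol a \linkS4class{FactorSolution} (pattern loadings are used).
#' @param labels known group label per variable (named by variable id or
#'   in row order); NA labels are ignored in the accuracy.
#' @param threshold minimum absolute loading (default 0.3).
#' @return A \linkS4class{FactorClassification}.
#' @export
classifyByLoadings <- function(sol, labels, threshold = 0.3) {
  L <- sol@loadings
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  if (!is.null(names(labels))) {
    if (is.null(rownames(L)))
      stop("solution has no variable names to match labels against")
    labels <- labels[rownames(L)]
  }
  if (length(labels) != nrow(L))
    stop("need one label per variable")
  labels <- as.character(labels)
  groups <- unique(labels[!is.na(labels)])
  m <- ncol(L)
  if (length(groups) != m)
    stop(sprintf("factor count (%d) must equal group count (%d)",
                 m, length(groups)))
  absL <- abs(L)
  top <- apply(absL, 1L, which.max)
  topLoad <- absL[cbind(seq_len(nrow(L)), top)]
  assigned <- ifelse(topLoad >= threshold, top, NA_integer_)
  over <- absL >= threshold
  cross <- which(rowSums(over) >= 2L)
  crossDf <- data.frame(variable = rownames(L)[cross],
                        n_factors = rowSums(over)[cross],
                        row.names = NULL, stringsAsFactors = FALSE)
  # factor -> group mapping by best permutation
  perms <- .permMatrix(m)
  scoreFor <- function(p) {
    mapped <- groups[p][assigned]
    sum(!is.na(mapped) & !is.na(labels) & mapped == labels)
  }
  sc <- apply(perms, 1L, scoreFor)
  bestPerm <- perms[which.max(sc), ]
  f2g <- setNames(groups[bestPerm], colnames(L))
  mapped <- groups[bestPerm][assigned]
  labeled <- !is.na(labels)
  correct <- labeled & !is.na(mapped) & mapped == labels
  acc <- 100 * sum(correct) / sum(labeled)
  assignments <- data.frame(
    variable = if (is.null(rownames(L))) seq_len(nrow(L)) else rownames(L),
    assigned_factor = assigned, loading_used = topLoad,
    known_group = labels, mapped_group = mapped,
    correct = ifelse(labeled, correct, NA),
    row.names = NULL, stringsAsFactors = FALSE)
  methods::new("FactorClassification", assignments = assignments,
               factorToGroup = f2g, accuracy = acc,
               crossLoadings = crossDf, threshold = threshold)
}
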