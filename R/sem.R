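#' Structural (latent regression) estimates
#'
#' Coefficients from regressing disease status on latent factors, with
#' odds ratios (\code{exp(coefficient)}, per unit of the factor on its
#' scaling metric) and a secondary per-SD odds ratio column rescaled by
#' the factor-score standard deviation. Multinomial outcomes produce
#' one coefficient block per non-reference level.
#'
#' @slot coefficients data.frame: \code{outcome_level}, \code{factor},
#'   \code{coefficient}, \code{odds_ratio}, \code{or_per_sd},
#'   \code{std_error}, \code{p_value}.
#' @slot outcomeLevels,referenceLevel outcome coding.
#' @slot method \code{"two_stage"} or \code{"quadrature_ml"}.
#' @slot converged logical.
#' @export
setClass("StructuralResult",
         representation(coefficients = "data.frame",
                        outcomeLevels = "character",
                        referenceLevel = "character", method = "character",
                        converged = "logical"))

setMethod("show", "StructuralResult", function(object) {
  cat(sprintf("StructuralResult (%s; reference: %s)\n", object@method,
              object@referenceLevel))
  print(object@coefficients, digits = 4)
  if (!object@converged) cat("warning: structural model did not converge\n")
})

#' Fitted structural equation model
#'
#' @slot measurement the \linkS4class{CfaResult} measurement part.
#' @slot structural the \linkS4class{StructuralResult} regression part.
#' @export
setClass("SemResult",
         representation(measurement = "CfaResult",
                        structural = "StructuralResult"))

setMethod("show", "SemResult", function(object) {
  cat("SemResult\n-- measurement --\n")
  show(object@measurement)
  cat("-- structural --\n")
  show(object@structural)
})

#' @rdname immunosig-generics
#' @export
setMethod("fitIndices", "SemResult",
          function(object) object@measurement@fit)

#' Fit a latent-factor structural model of disease status
#'
#' Combines a CFA measurement model over peptides with a regression of
#' disease status on the latent factor(s):
#' \code{method = "two_stage"} (default) fits the measurement model,
#' extracts Bartlett factor scores, and regresses the outcome on them by
#' logistic (2 outcome levels) or multinomial (>2 levels) regression;
#' \code{method = "quadrature_ml"} maximizes the joint likelihood of
#' indicators and a binary outcome, integrating a single latent factor
#' out by Gauss-Hermite quadrature. The joint route is only available
#' for one factor and a binary outcome; larger models use the two-stage
#' route, as does any model with more indicators than observations.
#'
#' @param spec a \linkS4class{CfaSpec} (its structural slot, if set,
#'   supplies link and reference level defaults).
#' @param data observations x indicators matrix (samples x peptides,
#'   typically log10 median-normalized intensities).
#' @param outcome factor/character of disease status per observation.
#' @param method \code{"two_stage"} or \code{"quadrature_ml"}.
#' @param referenceLevel outcome reference group (default: first level,
#'   or the spec's declared reference).
#' @param nodes Gauss-Hermite node count (default 15).
#' @return A \linkS4class{SemResult}.
#' @export
semFit <- function(spec, data, outcome,
                   method = c("two_stage", "quadrature_ml"),
                   referenceLevel = NULL, nodes = 15L) {
  method <- match.arg(method)
  data <- as.matrix(data)
  if (length(outcome) != nrow(data))
    stop("outcome must have one value per observation (row of data)")
  y <- as.factor(outcome)
  if (nlevels(y) < 2L) stop("outcome has a single level")
  if (is.null(referenceLevel) && length(spec@structural))
    referenceLevel <- spec@structural$reference
  if (!is.null(referenceLevel)) y <- stats::relevel(y, ref = referenceLevel)
  if (method == "quadrature_ml") {
    if (length(spec@factors) > 1L)
      stop("quadrature_ml supports a single latent factor; use two_stage")
    if (nlevels(y) > 2L)
      stop("quadrature_ml supports a binary outcome; use two_stage")
    if (length(spec@indicators) > nrow(data))
      stop("more indicators than observations: subset the peptides or use two_stage")
    return(.semQuadrature(spec, data, y, nodes))
  }
  meas <- cfaFit(spec, data)
  sc <- factorScores(meas)
  reg <- if (nlevels(y) == 2L) fitLogistic(y, sc)
         else fitMultinomial(y, sc, referenceLevel = levels(y)[1L])
  co <- reg$coefficients
  co <- co[co$term != "(Intercept)", , drop = FALSE]
  # glm/multinom mangle column names through make.names; map back
  tmap <- setNames(colnames(sc), make.names(colnames(sc)))
  co$term <- ifelse(co$term %in% names(tmap), tmap[co$term], co$term)
  sds <- apply(sc, 2L, sd)[co$term]
  co <- data.frame(outcome_level = co$outcome_level, factor = co$term,
                   coefficient = co$coefficient,
                   odds_ratio = co$odds_ratio,
                   or_per_sd = exp(co$coefficient * sds),
                   std_error = co$std_error, p_value = co$p_value,
                   stringsAsFactors = FALSE, row.names = NULL)
  str <- methods::new("StructuralResult", coefficients = co,
                      outcomeLevels = levels(y),
                      referenceLevel = levels(y)[1L],
                      method = "two_stage",
                      converged = meas@converged && reg$converged)
  methods::new("SemResult", measurement = meas, structural = str)
}

# Gauss-Hermite nodes/weights (weight function exp(-x^2)) via
# Golub-Welsch on the Jacobi matrix.
.gaussHermite <- function(k) {
  if (k < 2L) stop("need at least 2 quadrature nodes")
  off <- sqrt(seq_len(k - 1L) / 2)
  J <- matrix(0, k, k)
  J[cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L)] <- off
  J[cbind(seq_len(k - 1L) + 1L, seq_len(k - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = (e$vectors[1L, ord]^2) * sqrt(pi))
}

.semQuadrature <- function(spec, data, y, nodes) {
  X <- data[, spec@indicators, drop = FALSE]
  yy <- as.integer(y) - 1L      # 0 = reference
  v <- ncol(X)
  # start from the two-stage solution
  meas <- cfaFit(spec, X)
  sc <- factorScores(meas)
  reg0 <- fitLogistic(y, sc[, 1, drop = FALSE])
  lamFree <- spec@lambdaFree[, 1]
  lamFixed <- spec@lambdaValue[, 1]
  phiFree <- spec@phiFree[1, 1]
  Xc <- sweep(X, 2L, colMeans(X))
  gh <- .gaussHermite(nodes)
  pack <- c(meas@lambda[lamFree, 1],
            log(pmax(meas@theta, 1e-6)),
            if (phiFree) log(max(meas@phi[1, 1], 1e-6)),
            reg0$coefficients$coefficient)
  nl <- sum(lamFree)
  unpackQ <- function(p) {
    lam <- lamFixed
    if (nl) lam[lamFree] <- p[seq_len(nl)]
    th <- exp(p[nl + seq_len(v)])
    pos <- nl + v
    phi <- if (phiFree) exp(p[pos + 1L]) else spec@phiValue[1, 1]
    pos <- pos + as.integer(phiFree)
    a <- p[pos + 1L]; b <- p[pos + 2L]
    list(lam = lam, th = th, phi = phi, a = a, b = b)
  }
  negll <- function(p) {
    q <- unpackQ(p)
    eta <- sqrt(2 * q$phi) * gh$nodes            # quadrature abscissae
    # measurement loglik for each (obs, node)
    cst <- -0.5 * (sum(log(q$th)) + v * log(2 * pi))
    M <- matrix(0, nrow(Xc), length(eta))
    for (k in seq_along(eta)) {
      R <- sweep(Xc, 2L, q$lam * eta[k])
      M[, k] <- cst - 0.5 * colSums(t(R^2) / q$th) +
        ifelse(yy == 1L, plogis(q$a + q$b * eta[k], log.p = TRUE),
               plogis(q$a + q$b * eta[k], log.p = TRUE,
                      lower.tail = FALSE))
    }
    lw <- log(gh$weights / sqrt(pi))
    M <- sweep(M, 2L, lw, `+`)
    mx <- apply(M, 1L, max)
    -sum(mx + log(rowSums(exp(M - mx))))
  }
  opt <- optim(pack, negll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500))
  q <- unpackQ(opt$par)
  bIdx <- length(opt$par)
  seB <- tryCatch(sqrt(diag(solve(opt$hessian))[bIdx]),
                  error = function(e) NA_real_)
  p <- 2 * pnorm(-abs(q$b / seB))
  co <- data.frame(outcome_level = levels(y)[2L],
                   factor = spec@factors[1L], coefficient = q$b,
                   odds_ratio = exp(q$b),
                   or_per_sd = exp(q$b * sqrt(q$phi)),
                   std_error = seB, p_value = p,
                   stringsAsFactors = FALSE)
  str <- methods::new("StructuralResult", coefficients = co,
                      outcomeLevels = levels(y),
                      referenceLevel = levels(y)[1L],
                      method = "quadrature_ml",
                      converged = opt$convergence == 0L)
  methods::new("SemResult", measurement = meas, structural = str)
}

#' Second-order (hierarchical) confirmatory factor model
#'
#' Fits a model in which the first-order latent factors load on one
#' higher-order factor, testing whether they measure a single common
#' construct. The higher factor's variance is fixed at 1 and its
#' loadings are free. With three or more first-order factors the
#' first-order disturbances are free (the standard hierarchical CFA);
#' with exactly two they are fixed at 0 -- a free-disturbance two-factor
#' second-order model is covariance-equivalent to the correlated-factor
#' CFA and therefore untestable, whereas the zero-disturbance form
#' asserts that the higher factor fully accounts for both, which is the
#' falsifiable common-construct hypothesis (rejected by large RMSEA).
#'
#' @param factorList named list (>= 2 factors, each with >= 3 indicator
#'   ids).
#' @param data observations x indicators matrix.
#' @param ... passed to \code{\link{cfaFit}}.
#' @return A \linkS4class{CfaResult} (second-order parameters in
#'   \code{@gamma}, \code{@psi}).
#' @export
secondOrderFit <- function(factorList, data, ...) {
  if (length(factorList) < 2L)
    stop("need at least two first-order factors")
  if (any(lengths(factorList) < 3L))
    stop("each first-order factor needs at least 3 indicators")
  spec <- cfaSpec(factorList, covary = "none")
  m <- length(spec@factors)
  spec@secondOrder <- TRUE
  # first-order variances are implied by the second-order layer
  spec@phiFree <- matrix(FALSE, m, m,
                         dimnames = list(spec@factors, spec@factors))
  spec@gammaFree <- rep(TRUE, m)
  spec@gammaValue <- rep(0, m)
  if (m == 2L) {
    spec@psiFree <- rep(FALSE, m)
    spec@psiValue <- rep(0, m)
  } else {
    spec@psiFree <- rep(TRUE, m)
    spec@psiValue <- rep(0, m)
  }
  cfaFit(spec, data, ...)
}

#' Classify a sample by free loadings in a reference CFA
#'
#' Implements diagnostic screening with a reference panel: samples of
#' known disease status are the indicators of group factors (each
#' loading only on its group's factor, one randomly chosen reference
#' sample per factor fixed at 1 for scaling), observations are the
#' non-empty-spot peptides, and each held-out sample is given free
#' loadings on every factor. The held-out sample is assigned to the
#' factor with the largest absolute standardized loading when that
#' loading reaches \code{threshold} (with \code{threshold = 0} every
#' sample is assigned to its argmax factor).
#'
#' @param x a normalized \linkS4class{PeptideArrayExperiment}.
#' @param holdOut sample ids to classify (default: every labeled sample
#'   in turn, leave-one-out style).
#' @param threshold minimum |standardized loading| (default 0.3).
#' @param seed seed for the random choice of reference samples.
#' @param references optional named character: factor (group) ->
#'   reference sample id, overriding the random choice.
#' @return A list: \code{assignments} (data.frame with per-factor
#'   loadings, assigned group, known group, correct flag) and
#'   \code{accuracy} (percent correct among labeled held-out samples;
#'   unclassified counts as incorrect).
#' @export
cfaClassify <- function(x, holdOut = NULL, threshold = 0.3, seed = 1L,
                        references = NULL) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  v <- normalizedValues(x)[!emptySpots(x), , drop = FALSE]  # peptides x samples
  g <- setNames(groupLabels(x), colnames(v))
  groups <- unique(g[!is.na(g)])
  if (length(groups) < 2L) stop("need at least two groups")
  if (is.null(holdOut)) holdOut <- names(g)[!is.na(g)]
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  rows <- list()
  for (ho in holdOut) {
    if (!is.null(references) && ho %in% references)
      stop("reference sample cannot be the held-out sample: ", ho)
    members <- lapply(groups, function(gr)
      setdiff(names(g)[!is.na(g) & g == gr], ho))
    names(members) <- groups
    if (any(lengths(members) < 2L))
      stop("each group needs >= 2 samples besides the held-out one")
    refs <- vapply(groups, function(gr) {
      if (!is.null(references) && gr %in% names(references))
        references[[gr]]
      else sample(members[[gr]], 1L)
    }, character(1))
    factorList <- members
    for (gr in groups) factorList[[gr]] <- c(factorList[[gr]], ho)
    fixv <- setNames(rep(1, length(groups)), paste0(refs, "@", groups))
    spec <- cfaSpec(factorList, fix = as.list(fixv), covary = "all")
    fit <- suppressWarnings(cfaFit(spec, v))
    lo <- fit@standardizedLoadings[ho, ]
    best <- which.max(abs(lo))
    assigned <- if (abs(lo[best]) >= threshold || threshold == 0)
      groups[best] else NA_character_
    rows[[ho]] <- data.frame(sample = ho, t(lo),
                             assigned_group = assigned,
                             known_group = unname(g[ho]),
                             correct = identical(assigned, unname(g[ho])),
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  assignments <- do.call(rbind, rows)
  labeled <- !is.na(assignments$known_group)
  accuracy <- 100 * sum(assignments$correct[labeled]) / sum(labeled)
  list(assignments = assignments, accuracy = accuracy)
}
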