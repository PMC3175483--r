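#' Welch t-test with Satterthwaite degrees of freedom
#'
#' Two-sample t-test robust to unequal group variances (the
#' Behrens-Fisher situation typical of disease-group contrasts with
#' unequal sizes). With \eqn{w_1 = s_1^2/n_1} and \eqn{w_2 = s_2^2/n_2},
#' the statistic is \eqn{t = (\bar a - \bar b)/\sqrt{w_1 + w_2}} and the
#' effective degrees of freedom are
#' \deqn{df = (w_1+w_2)^2 / (w_1^2/(n_1-1) + w_2^2/(n_2-1)),}
#' which interpolates between \eqn{\min(n_1,n_2)-1} and
#' \eqn{n_1+n_2-2}. Two-tailed p-values come from the t survival
#' function. When both groups have zero variance and equal means the
#' statistic is taken as 0 with p = 1 by convention.
#'
#' @param a,b numeric vectors of the two groups (each of length >= 2,
#'   finite).
#' @return A one-row data.frame: \code{t_value}, \code{df},
#'   \code{p_value}, \code{mean_diff}, \code{n1}, \code{n2}.
#' @export
welchTTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("non-finite values in input")
  r <- .welchVec(matrix(a, ncol = 1), matrix(b, ncol = 1))
  data.frame(t_value = r$t, df = r$df, p_value = r$p,
             mean_diff = r$diff, n1 = length(a), n2 = length(b))
}

# Vectorized Welch test over columns of two observation x variable matrices.
.welchVec <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- colSums(sweep(A, 2L, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(B, 2L, m2)^2) / (n2 - 1)
  w1 <- v1 / n1; w2 <- v2 / n2
  se <- sqrt(w1 + w2)
  diff <- m1 - m2
  t <- diff / se
  df <- (w1 + w2)^2 / (w1^2 / (n1 - 1) + w2^2 / (n2 - 1))
  degen <- se == 0
  if (any(degen)) {
    t[degen] <- ifelse(diff[degen] == 0, 0, sign(diff[degen]) * Inf)
    df[degen] <- n1 + n2 - 2
  }
  p <- 2 * pt(-abs(t), df)
  p[degen & diff == 0] <- 1
  p[degen & diff != 0] <- 0
  list(t = unname(t), df = unname(df), p = unname(p), diff = unname(diff))
}

#' Two-tailed p-value from a t statistic
#'
#' @param t t statistic (sign is irrelevant).
#' @param df degrees of freedom, > 0 (possibly fractional, as produced
#'   by the Satterthwaite correction).
#' @return The two-tailed tail probability.
#' @export
pFromT <- function(t, df) {
  if (any(df <= 0)) stop("df must be > 0")
  2 * pt(-abs(t), df)
}

#' Bonferroni-corrected significance threshold
#'
#' Familywise error control for a screen of \code{m} peptides: the
#' per-test threshold is \code{alpha / m}.
#'
#' @param alpha nominal familywise alpha in (0, 1).
#' @param m number of tests (>= 1).
#' @return \code{alpha / m}.
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Screen all peptides for a two-group difference
#'
#' Runs the Welch-Satterthwaite test on every non-empty-spot peptide
#' using the log10 median-normalized intensities, ranks by ascending
#' p-value (ties broken by |t| descending, then peptide id), and flags
#' significance at the Bonferroni threshold \code{alpha / m} where
#' \code{m} is the number of peptides tested.
#'
#' @param x a normalized \linkS4class{PeptideArrayExperiment}.
#' @param group1,group2 group labels to contrast.
#' @param alpha familywise alpha (default 0.05).
#' @return A data.frame with columns \code{peptide_id}, \code{sequence},
#'   \code{t_value}, \code{df}, \code{p_value}, \code{mean_diff},
#'   \code{significant}; attributes \code{m} (tests run) and
#'   \code{threshold}.
#' @export
testAllPeptides <- function(x, group1, group2, alpha = 0.05) {
  g <- groupLabels(x)
  for (gg in c(group1, group2))
    if (!gg %in% g) stop("group not present in data: ", gg)
  v <- t(normalizedValues(x))           # samples x peptides
  keep <- !emptySpots(x)
  v <- v[, keep, drop = FALSE]
  seqs <- peptideSequences(x)[keep]
  A <- v[g == group1, , drop = FALSE]
  B <- v[g == group2, , drop = FALSE]
  if (nrow(A) < 2L || nrow(B) < 2L)
    stop("each group needs at least 2 samples")
  r <- .welchVec(A, B)
  m <- ncol(v)
  thr <- bonferroniThreshold(alpha, m)
  out <- data.frame(peptide_id = colnames(v), sequence = seqs,
                    t_value = r$t, df = r$df, p_value = r$p,
                    mean_diff = r$diff, significant = r$p < thr,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -abs(out$t_value), out$peptide_id), ]
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "threshold") <- thr
  out
}

#' Logistic and multinomial regression of an outcome on predictors
#'
#' Maximum-likelihood logit models (IRLS via \code{stats::glm}, and
#' \code{nnet::multinom} for >2 outcome levels) reported as
#' coefficients and odds ratios. Useful as an alternative per-peptide
#' screen or, downstream, to regress disease status on latent factor
#' scores. Complete or quasi-complete separation is reported through the
#' \code{converged} flag rather than an error.
#'
#' @param y outcome: binary (2 levels) for \code{fitLogistic}, L levels
#'   for \code{fitMultinomial}.
#' @param X numeric predictor matrix or data.frame (one row per sample).
#' @param referenceLevel outcome level used as the reference group
#'   (multinomial; default the first level).
#' @return A list of class \code{"immunosigRegression"}:
#'   \code{coefficients} (data.frame with \code{outcome_level},
#'   \code{term}, \code{coefficient}, \code{odds_ratio},
#'   \code{std_error}, \code{p_value}), \code{outcome_levels},
#'   \code{reference_level}, \code{converged}.
#' @export
fitLogistic <- function(y, X) {
  y <- as.factor(y)
  if (nlevels(y) != 2L)
    stop("fitLogistic needs a binary outcome; got ", nlevels(y), " level(s)")
  X <- as.data.frame(X)
  dat <- data.frame(.y = y, X, check.names = TRUE)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  co <- data.frame(outcome_level = levels(y)[2L], term = rownames(sm),
                   coefficient = sm[, 1], odds_ratio = exp(sm[, 1]),
                   std_error = sm[, 2], p_value = sm[, 4],
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = co, outcome_levels = levels(y),
                 reference_level = levels(y)[1L],
                 converged = fit$converged && !sep),
            class = "immunosigRegression")
}

#' @rdname fitLogistic
#' @export
fitMultinomial <- function(y, X, referenceLevel = NULL) {
  y <- as.factor(y)
  if (nlevels(y) < 2L) stop("outcome has a single level")
  if (!is.null(referenceLevel)) {
    if (!referenceLevel %in% levels(y))
      stop("reference level not an outcome level: ", referenceLevel)
    y <- stats::relevel(y, ref = referenceLevel)
  }
  if (nlevels(y) == 2L) {
    r <- fitLogistic(y, X)
    r$reference_level <- levels(y)[1L]
    return(r)
  }
  X <- as.data.frame(X)
  dat <- data.frame(.y = y, X, check.names = TRUE)
  fit <- nnet::multinom(.y ~ ., data = dat, trace = FALSE, maxit = 500)
  cf <- coef(fit)
  se <- summary(fit)$standard.errors
  z <- cf / se
  p <- 2 * pnorm(-abs(z))
  co <- do.call(rbind, lapply(rownames(cf), function(lv)
    data.frame(outcome_level = lv, term = colnames(cf),
               coefficient = cf[lv, ], odds_ratio = exp(cf[lv, ]),
               std_error = se[lv, ], p_value = p[lv, ],
               stringsAsFactors = FALSE, row.names = NULL)))
  structure(list(coefficients = co, outcome_levels = levels(y),
                 reference_level = levels(y)[1L],
                 converged = fit$convergence == 0),
            class = "immunosigRegression")
}

#' @export
print.immunosigRegression <- function(x, ...) {
  cat("Logit model (reference:", x$reference_level, ")\n")
  print(x$coefficients, digits = 4)
  if (!x$converged) cat("warning: model did not converge (separation?)\n")
  invisible(x)
}
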