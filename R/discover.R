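#' Latent-antibody discovery report
#'
#' Output of the multi-step discovery pipeline
#' (\code{\link{discoverAntibodies}}): exploratory classification
#' sanity check, significant-peptide screen, inferred factor structure,
#' confirmatory measurement fit, and the structural regression of
#' disease status on the latent factors, with per-factor peptide
#' membership and direction annotations.
#'
#' @slot contrast groups contrasted (length 2, or all groups).
#' @slot referenceGroup reference level for the structural model.
#' @slot efaAccuracy percent correct from the transposed-EFA sanity
#'   check.
#' @slot efaClassification the \linkS4class{FactorClassification}.
#' @slot scree eigenvalue spectrum of the significant-peptide
#'   correlation matrix (sample-mode spectrum before the screen).
#' @slot suggestedFactors inferred factor count (user-overridable
#'   upstream).
#' @slot testTable ranked per-peptide Welch test results.
#' @slot nSignificant Bonferroni-significant peptide count.
#' @slot factorMembership data.frame: peptide, factor, loading,
#'   direction (increased/decreased in the non-reference group), |t|.
#' @slot cfa \linkS4class{CfaResult} measurement model (or NULL).
#' @slot sem \linkS4class{SemResult} (or NULL).
#' @slot singleFactorSem list of per-factor \linkS4class{SemResult}s
#'   fitted when factors are collinear (score correlation > 0.9).
#' @slot warnings accumulated warnings (Heywood, non-convergence,
#'   collinearity, indicator subsetting).
#' @slot stoppedAt empty, or the stage at which the pipeline stopped.
#' @slot settings list of tuning parameters and the seed used.
#' @export
setClass("DiscoveryReport",
         representation(contrast = "character", referenceGroup = "character",
                        efaAccuracy = "numeric", efaClassification = "ANY",
                        scree = "numeric", suggestedFactors = "integer",
                        testTable = "data.frame", nSignificant = "integer",
                        factorMembership = "data.frame", cfa = "ANY",
                        sem = "ANY", singleFactorSem = "list",
                        warnings = "character", stoppedAt = "character",
                        settings = "list"))

setMethod("show", "DiscoveryReport", function(object) {
  cat("DiscoveryReport:", paste(object@contrast, collapse = " vs "), "\n")
  cat(sprintf("  EFA sanity classification: %.2f%%\n", object@efaAccuracy))
  cat(sprintf("  significant peptides: %d (threshold %.3g)\n",
              object@nSignificant, object@settings$bonferroni))
  if (length(object@stoppedAt)) {
    cat("  pipeline stopped at stage:", object@stoppedAt, "\n")
    return(invisible(NULL))
  }
  cat("  inferred factors:", object@suggestedFactors, "\n")
  if (!is.null(object@cfa)) show(object@cfa@fit)
  if (!is.null(object@sem)) print(object@sem@structural@coefficients,
                                  digits = 4)
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

#' Discover latent antibody factors from an immunosignature contrast
#'
#' Orchestrates the multi-step latent-factor discovery procedure:
#' (1) median-normalize on the log10 scale; (2) transposed (samples as
#' variables) EFA with rotation and loading-threshold classification as
#' a sanity check that the groups form separable constructs; (3)
#' Welch-Satterthwaite tests per peptide with Bonferroni control --
#' with zero significant peptides the pipeline stops here and reports
#' it; (4) EFA of the significant peptides, factor count from the
#' eigenvalue-drop rule unless overridden; (5) a CFA measurement model
#' over the per-factor peptide blocks (indicator sets are capped per
#' factor when peptides outnumber samples, mirroring the need to test
#' subsets in that regime); (6) a structural model regressing disease
#' status on the latent factors, with odds ratios; when two factors'
#' scores correlate above 0.9 the report flags multicollinearity and
#' also fits per-factor structural models; (7) per-peptide direction
#' annotation from group means. Cross-loading samples are reported,
#' never removed.
#'
#' @param x a \linkS4class{PeptideArrayExperiment} (raw; normalized if
#'   needed).
#' @param contrast character vector of 2 group labels, or
#'   \code{"multi"} for all groups (multinomial structural model).
#' @param alpha familywise alpha for the screen (default 0.05).
#' @param rotation rotation for the exploratory steps (default promax).
#' @param threshold loading threshold (default 0.3).
#' @param semMethod structural estimation route (default two_stage).
#' @param nFactors optional override of the inferred factor count.
#' @param referenceGroup reference disease level (default: first
#'   contrast group, or the largest group for multi).
#' @param maxIndicatorsPerFactor cap on CFA indicators per factor
#'   (default 8).
#' @param seed seed controlling the seeded sub-steps (default 1).
#' @return A \linkS4class{DiscoveryReport}.
#' @export
discoverAntibodies <- function(x, contrast, alpha = 0.05,
                               rotation = c("promax", "varimax", "geomin"),
                               threshold = 0.3,
                               semMethod = c("two_stage", "quadrature_ml"),
                               nFactors = NULL, referenceGroup = NULL,
                               maxIndicatorsPerFactor = 8L, seed = 1L) {
  rotation <- match.arg(rotation)
  semMethod <- match.arg(semMethod)
  if (!isNormalized(x)) x <- medianNormalizeLog10(x)
  g <- groupLabels(x)
  allGroups <- unique(g)
  multi <- identical(contrast, "multi")
  if (multi) {
    contrast <- allGroups
    if (length(contrast) < 2L) stop("need at least 2 groups")
  } else {
    if (length(contrast) != 2L || !all(contrast %in% g))
      stop("contrast must name two groups present in the data, or 'multi'")
  }
  if (is.null(referenceGroup))
    referenceGroup <- if (multi)
      contrast[which.max(tabulate(factor(g, contrast)))] else contrast[1]
  x <- x[, g %in% contrast]
  g <- groupLabels(x)
  warningsAcc <- character()
  settings <- list(alpha = alpha, rotation = rotation,
                   threshold = threshold, semMethod = semMethod,
                   referenceGroup = referenceGroup, seed = seed)

  ## stage 2: transposed EFA sanity check
  Rs <- correlationMatrix(x, mode = "samples")
  efaSol <- pafFit(Rs, m = length(contrast))
  efaSol <- rotateSolution(efaSol, rotation, seed = seed)
  cls <- classifyByLoadings(efaSol, setNames(g, colnames(x)),
                            threshold = threshold)
  if (nrow(cls@crossLoadings))
    warningsAcc <- c(warningsAcc,
                     sprintf("%d cross-loading sample(s) (reported, not removed)",
                             nrow(cls@crossLoadings)))

  ## stage 3: peptide screen
  pairs <- if (multi)
    lapply(setdiff(contrast, referenceGroup),
           function(gr) c(gr, referenceGroup))
  else list(contrast)
  tests <- lapply(pairs, function(pr)
    testAllPeptides(x, pr[1], pr[2], alpha = alpha))
  testTable <- tests[[1]]
  if (length(tests) > 1L) {
    merged <- do.call(rbind, tests)
    merged <- merged[order(merged$p_value, -abs(merged$t_value),
                           merged$peptide_id), ]
    testTable <- merged[!duplicated(merged$peptide_id), ]
  }
  settings$bonferroni <- attr(tests[[1]], "threshold")
  sig <- unique(unlist(lapply(tests, function(tt)
    tt$peptide_id[tt$significant])))
  nSig <- length(sig)
  if (nSig > 0L && nSig < 3L) {
    # too few peptides to support any factor structure
    warningsAcc <- c(warningsAcc,
                     sprintf("only %d significant peptide(s); factor modelling not attempted",
                             nSig))
    return(methods::new("DiscoveryReport", contrast = contrast,
                        referenceGroup = referenceGroup,
                        efaAccuracy = cls@accuracy, efaClassification = cls,
                        scree = eigenScree(Rs)$eigenvalues,
                        suggestedFactors = NA_integer_,
                        testTable = testTable, nSignificant = nSig,
                        factorMembership = data.frame(), cfa = NULL,
                        sem = NULL, singleFactorSem = list(),
                        warnings = warningsAcc,
                        stoppedAt = "factor_structure",
                        settings = settings))
  }
  if (nSig == 0L) {
    return(methods::new("DiscoveryReport", contrast = contrast,
                        referenceGroup = referenceGroup,
                        efaAccuracy = cls@accuracy, efaClassification = cls,
                        scree = eigenScree(Rs)$eigenvalues,
                        suggestedFactors = NA_integer_,
                        testTable = testTable, nSignificant = 0L,
                        factorMembership = data.frame(), cfa = NULL,
                        sem = NULL, singleFactorSem = list(),
                        warnings = warningsAcc,
                        stoppedAt = "significance_testing",
                        settings = settings))
  }

  ## stage 4: factor structure of the significant peptides
  Rp <- correlationMatrix(x, mode = "peptides", peptides = sig)
  scree <- eigenScree(Rp)
  m <- if (!is.null(nFactors)) as.integer(nFactors) else scree$suggested
  m <- max(1L, min(m, length(sig) - 1L))
  sol <- pafFit(Rp, m = m)
  if (any(sol@heywood))
    warningsAcc <- c(warningsAcc,
                     sprintf("%d Heywood communality estimate(s) in the peptide EFA",
                             sum(sol@heywood)))
  if (m >= 2L) sol <- rotateSolution(sol, rotation, seed = seed)
  L <- loadings(sol)
  absL <- abs(L)
  assigned <- apply(absL, 1L, which.max)
  keep <- absL[cbind(seq_len(nrow(L)), assigned)] >= threshold
  membership <- data.frame(peptide_id = rownames(L)[keep],
                           factor = paste0("F", assigned[keep]),
                           loading = L[cbind(which(keep), assigned[keep])],
                           stringsAsFactors = FALSE)
  # factors need >= 3 member peptides to be reportable
  tab <- table(membership$factor)
  dropF <- names(tab)[tab < 3L]
  if (length(dropF)) {
    warningsAcc <- c(warningsAcc,
                     sprintf("factor(s) dropped with < 3 member peptides: %s",
                             paste(dropF, collapse = ", ")))
    membership <- membership[!membership$factor %in% dropF, , drop = FALSE]
  }
  if (!nrow(membership)) {
    return(methods::new("DiscoveryReport", contrast = contrast,
                        referenceGroup = referenceGroup,
                        efaAccuracy = cls@accuracy, efaClassification = cls,
                        scree = scree$eigenvalues, suggestedFactors = m,
                        testTable = testTable, nSignificant = nSig,
                        factorMembership = membership, cfa = NULL,
                        sem = NULL, singleFactorSem = list(),
                        warnings = warningsAcc,
                        stoppedAt = "factor_structure",
                        settings = settings))
  }

  ## stage 5: CFA measurement model (top peptides per factor by |t|)
  tRank <- setNames(abs(testTable$t_value), testTable$peptide_id)
  factorsKept <- sort(unique(membership$factor))
  factorList <- lapply(factorsKept, function(f) {
    ids <- membership$peptide_id[membership$factor == f]
    ids[order(-tRank[ids])]
  })
  names(factorList) <- factorsKept
  nSamples <- ncol(x)
  cap <- maxIndicatorsPerFactor
  trimmed <- lapply(factorList, function(ids) head(ids, cap))
  if (any(lengths(factorList) > lengths(trimmed)))
    warningsAcc <- c(warningsAcc,
                     sprintf("indicator sets capped at %d peptides per factor for the CFA/SEM stage",
                             cap))
  vNorm <- t(normalizedValues(x))      # samples x peptides
  cfaRes <- tryCatch(
    suppressWarnings(cfaFit(cfaSpec(trimmed, covary = "all"), vNorm)),
    error = function(e) {
      warningsAcc <<- c(warningsAcc,
                        paste("CFA measurement model failed:",
                              conditionMessage(e)))
      NULL
    })
  if (!is.null(cfaRes) && !cfaRes@converged)
    warningsAcc <- c(warningsAcc, "CFA measurement model did not converge")

  ## stage 6: structural model
  semRes <- NULL
  singles <- list()
  if (!is.null(cfaRes)) {
    link <- if (multi && length(contrast) > 2L) "multinomial" else "logistic"
    spec <- cfaSpec(trimmed, covary = "all",
                    outcome = "disease", link = link,
                    reference = referenceGroup)
    outc <- factor(g, levels = c(referenceGroup,
                                 setdiff(contrast, referenceGroup)))
    semRes <- tryCatch(
      suppressWarnings(semFit(spec, vNorm, outc, method = semMethod,
                              referenceLevel = referenceGroup)),
      error = function(e) {
        warningsAcc <<- c(warningsAcc,
                          paste("structural model failed:",
                                conditionMessage(e)))
        NULL
      })
    if (!is.null(semRes) && !semRes@structural@converged)
      warningsAcc <- c(warningsAcc,
                       "structural regression did not converge (possible separation)")
    if (!is.null(semRes) && length(trimmed) > 1L) {
      sc <- factorScores(semRes@measurement)
      scCor <- cor(sc)
      high <- which(abs(scCor) > 0.9 & upper.tri(scCor), arr.ind = TRUE)
      if (nrow(high)) {
        warningsAcc <- c(warningsAcc,
                         sprintf("collinear factors (|r| > 0.9): %s",
                                 paste(apply(high, 1L, function(ij)
                                   paste(colnames(sc)[ij], collapse = "~")),
                                   collapse = ", ")))
        for (f in names(trimmed)) {
          sp1 <- cfaSpec(trimmed[f], covary = "none", outcome = "disease",
                         link = link, reference = referenceGroup)
          singles[[f]] <- tryCatch(
            suppressWarnings(semFit(sp1, vNorm, outc, method = semMethod,
                                    referenceLevel = referenceGroup)),
            error = function(e) NULL)
        }
      }
    }
  }

  ## stage 7: direction annotation from raw group means
  vAll <- t(normalizedValues(x))
  refMean <- colMeans(vAll[g == referenceGroup, membership$peptide_id,
                           drop = FALSE])
  otherMean <- colMeans(vAll[g != referenceGroup, membership$peptide_id,
                             drop = FALSE])
  membership$direction <- ifelse(otherMean > refMean, "increased",
                                 "decreased")
  membership$abs_t <- unname(tRank[membership$peptide_id])

  methods::new("DiscoveryReport", contrast = contrast,
               referenceGroup = referenceGroup,
               efaAccuracy = cls@accuracy, efaClassification = cls,
               scree = scree$eigenvalues, suggestedFactors = m,
               testTable = testTable, nSignificant = nSig,
               factorMembership = membership, cfa = cfaRes, sem = semRes,
               singleFactorSem = singles, warnings = warningsAcc,
               stoppedAt = character(0), settings = settings)
}

#' Write a discovery report to disk
#'
#' Writes plain-text and TSV artifacts with deterministic content and
#' ordering (re-running with the same inputs and seed reproduces the
#' files byte for byte): \code{summary.txt}, \code{tests.tsv} (ranked
#' peptide screen), \code{scree.tsv}, \code{classification.tsv},
#' \code{factor_membership.tsv}, \code{structural.tsv}, and a
#' machine-readable \code{summary.json}.
#'
#' @param report a \linkS4class{DiscoveryReport}.
#' @param outDir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outDir, 2) != 0)
    stop("output directory is not writable: ", outDir)
  paths <- character()
  wt <- function(df, name) {
    p <- file.path(outDir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(report@testTable, "tests.tsv")
  wt(data.frame(component = seq_along(report@scree),
                eigenvalue = report@scree), "scree.tsv")
  if (!is.null(report@efaClassification))
    wt(report@efaClassification@assignments, "classification.tsv")
  if (nrow(report@factorMembership))
    wt(report@factorMembership, "factor_membership.tsv")
  structuralTab <- if (!is.null(report@sem))
    report@sem@structural@coefficients else data.frame()
  if (nrow(structuralTab)) wt(structuralTab, "structural.tsv")

  sm <- file.path(outDir, "summary.txt")
  con <- file(sm, "w")
  cat("Latent-antibody discovery report\n", file = con)
  cat("contrast:", paste(report@contrast, collapse = " vs "), "\n",
      file = con)
  cat("reference group:", report@referenceGroup, "\n", file = con)
  cat(sprintf("EFA sanity classification: %.2f%%\n", report@efaAccuracy),
      file = con)
  cat(sprintf("significant peptides: %d (Bonferroni threshold %.4g)\n",
              report@nSignificant, report@settings$bonferroni), file = con)
  if (length(report@stoppedAt)) {
    cat("pipeline stopped at stage:", report@stoppedAt, "\n", file = con)
  } else {
    cat("inferred factors:", report@suggestedFactors, "\n", file = con)
    if (!is.null(report@cfa)) {
      f <- report@cfa@fit
      cat(sprintf("CFA fit: Chi-Sq = %.4f, df = %d, RMSEA = %s, SRMR = %.4f\n",
                  f@chiSquare, f@df,
                  if (is.na(f@rmsea)) "NA" else sprintf("%.4f", f@rmsea),
                  f@srmr), file = con)
    }
    if (nrow(structuralTab)) {
      cat("structural coefficients:\n", file = con)
      utils::write.table(format(structuralTab, digits = 6), con,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (length(report@warnings))
    cat("warnings:", paste(report@warnings, collapse = "; "), "\n",
        file = con)
  close(con)
  paths <- c(paths, sm)

  js <- list(contrast = report@contrast,
             reference_group = report@referenceGroup,
             efa_accuracy = report@efaAccuracy,
             n_significant = report@nSignificant,
             suggested_factors = report@suggestedFactors,
             stopped_at = if (length(report@stoppedAt)) report@stoppedAt
                          else NA,
             warnings = report@warnings,
             settings = report@settings[c("alpha", "rotation", "threshold",
                                          "semMethod", "seed")])
  if (nrow(structuralTab))
    js$odds_ratios <- setNames(as.list(structuralTab$odds_ratio),
                               paste(structuralTab$outcome_level,
                                     structuralTab$factor, sep = ":"))
  jp <- file.path(outDir, "summary.json")
  jsonlite::write_json(js, jp, auto_unbox = TRUE, digits = 10,
                       null = "null", na = "null", pretty = TRUE)
  paths <- c(paths, jp)
  invisible(paths)
}
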