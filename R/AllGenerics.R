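#' @import methods
#' @importFrom stats cor cov median optim pchisq pt qnorm rnorm runif sd var
#'   glm binomial coef kmeans quantile setNames pnorm dnorm plogis rbinom
#'   complete.cases
#' @importFrom utils read.delim write.table combn head
NULL

#' Generics for immunosig result objects
#'
#' Accessor generics shared by the factor-analytic result classes:
#' \code{loadings} returns a pattern matrix, \code{factorCorrelation} the
#' inter-factor correlation (identity for orthogonal solutions),
#' \code{uniquenesses} and \code{communalities} the variable-level variance
#' decomposition, \code{eigenvalues} the spectrum of the analyzed
#' correlation matrix, and \code{fitIndices} the chi-square/RMSEA/SRMR
#' summary of a fitted covariance-structure model.
#'
#' @param object an immunosig result object.
#' @return The corresponding component (matrix, numeric vector, or
#'   \linkS4class{FitIndices} object).
#' @name immunosig-generics
#' @aliases loadings factorCorrelation uniquenesses communalities
#'   eigenvalues fitIndices
NULL

#' @rdname immunosig-generics
#' @export
setGeneric("loadings", function(object) standardGeneric("loadings"))

#' @rdname immunosig-generics
#' @export
setGeneric("factorCorrelation",
           function(object) standardGeneric("factorCorrelation"))

#' @rdname immunosig-generics
#' @export
setGeneric("uniquenesses", function(object) standardGeneric("uniquenesses"))

#' @rdname immunosig-generics
#' @export
setGeneric("communalities", function(object) standardGeneric("communalities"))

#' @rdname immunosig-generics
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))

#' @rdname immunosig-generics
#' @export
setGeneric("fitIndices", function(object) standardGeneric("fitIndices"))
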