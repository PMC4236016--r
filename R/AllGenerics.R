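#' @include AllGenerics.R
NULL

#' Gene names of an object
#'
#' @param x an object carrying a gene axis.
#' @return Character vector of gene names.
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' Condition (time/stage) names of an object
#'
#' @param x an object carrying a condition axis.
#' @return Character vector of condition names.
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))

#' Numeric values stored in an object
#'
#' @param x an object with a numeric matrix payload.
#' @return A numeric matrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Surprisal decomposition of a log-expression matrix
#'
#' @param y an [ExpressionMatrix-class] or [LogExpressionMatrix-class].
#' @param ... passed to methods; see [surprisalDecompose,LogExpressionMatrix-method].
#' @export
setGeneric("surprisalDecompose",
           function(y, ...) standardGeneric("surprisalDecompose"))

#' Gene participation weights G of a decomposition
#'
#' @param x a [SurprisalDecomposition-class].
#' @return m x t matrix; column \eqn{\alpha + 1} holds the weights
#'   \eqn{G_{i\alpha}} of pattern \eqn{\alpha}.
#' @export
setGeneric("patternWeights", function(x) standardGeneric("patternWeights"))

#' Lagrange multipliers of a decomposition
#'
#' @param x a [SurprisalDecomposition-class].
#' @return t x t matrix; row \eqn{\alpha + 1} is the condition profile
#'   \eqn{\lambda_\alpha(T)}.
#' @export
setGeneric("multipliers", function(x) standardGeneric("multipliers"))

#' Singular values of a decomposition
#'
#' @param x a [SurprisalDecomposition-class].
#' @return Non-increasing numeric vector of length t.
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))
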