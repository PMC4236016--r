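#' @include AllGenerics.R
NULL

.checkAxisNames <- function(nm, what) {
  if (is.null(nm) || any(!nzchar(nm)))
    return(sprintf("all %s names must be non-empty", what))
  dup <- nm[duplicated(nm)]
  if (length(dup))
    return(sprintf("duplicate %s name(s): %s", what,
                   paste(unique(dup), collapse = ", ")))
  NULL
}

# ---------------------------------------------------------------------------
# ExpressionMatrix
# ---------------------------------------------------------------------------

#' Positive gene-expression matrix
#'
#' An m x t matrix of strictly positive expression signals (arbitrary
#' intensity units), genes on rows and conditions (time points or disease
#' stages) on columns. Row and column names are unique and m >= t >= 1; with
#' conditions as the short axis, its natural log is what the surprisal
#' decomposition factorizes.
#'
#' @slot values numeric matrix with gene row names and condition column names.
#' @seealso [readExpressionCSV()], [ExpressionMatrix()],
#'   [scaleToTargetIntensity()], [logTransform()]
#' @export
setClass("ExpressionMatrix", slots = c(values = "matrix"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  msg <- .checkAxisNames(rownames(v), "gene")
  if (!is.null(msg)) return(msg)
  msg <- .checkAxisNames(colnames(v), "condition")
  if (!is.null(msg)) return(msg)
  if (ncol(v) < 1L || nrow(v) < ncol(v))
    return(sprintf("need m >= t >= 1, got m=%d, t=%d", nrow(v), ncol(v)))
  if (anyNA(v) || any(v <= 0))
    return("all expression values must be strictly positive and non-missing")
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes x conditions, strictly positive.
#' @param geneNames,conditionNames optional axis names; taken from `dimnames`
#'   when omitted.
#' @return An [ExpressionMatrix-class].
#' @examples
#' x <- ExpressionMatrix(matrix(c(10, 20, 30, 40, 50, 60), 3, 2),
#'                       geneNames = c("A", "B", "C"),
#'                       conditionNames = c("T1", "T2"))
#' exprValues(x)
#' @export
ExpressionMatrix <- function(values, geneNames = rownames(values),
                             conditionNames = colnames(values)) {
  values <- as.matrix(values)
  dimnames(values) <- list(as.character(geneNames),
                           as.character(conditionNames))
  new("ExpressionMatrix", values = values)
}

# ---------------------------------------------------------------------------
# LogExpressionMatrix
# ---------------------------------------------------------------------------

#' Natural-log expression matrix
#'
#' Elementwise natural logarithm of an [ExpressionMatrix-class]; entries are
#' finite and dimensionless. This is the matrix the decomposition operates on.
#'
#' @slot values numeric matrix of finite log-expression values.
#' @seealso [logTransform()], [surprisalDecompose()]
#' @export
setClass("LogExpressionMatrix", slots = c(values = "matrix"))

setValidity("LogExpressionMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  msg <- .checkAxisNames(rownames(v), "gene")
  if (!is.null(msg)) return(msg)
  msg <- .checkAxisNames(colnames(v), "condition")
  if (!is.null(msg)) return(msg)
  if (any(!is.finite(v))) return("log-expression entries must all be finite")
  TRUE
})

# ---------------------------------------------------------------------------
# SurprisalDecomposition
# ---------------------------------------------------------------------------

#' Surprisal decomposition of log expression
#'
#' Holds the factorization \eqn{\ln X_i(T) = \sum_\alpha G_{i\alpha}
#' \lambda_\alpha(T)} obtained by SVD. Patterns are indexed \eqn{\alpha = 0,
#' \dots, t-1}; \eqn{\alpha = 0} is the steady state. Columns of `G` are
#' orthonormal gene participation weights; row \eqn{\alpha} of `lambda`
#' carries the Lagrange multipliers \eqn{\lambda_\alpha(T)} (singular value
#' folded in); `omega` are the non-increasing singular values.
#'
#' @slot G m x t numeric matrix of gene weights \eqn{G_{i\alpha}}.
#' @slot lambda t x t numeric matrix of multipliers \eqn{\lambda_\alpha(T)}.
#' @slot omega numeric vector of t singular values, non-increasing.
#' @seealso [surprisalDecompose()], [reconstruct()], [steadyStateResidual()],
#'   [sortPattern()]
#' @export
setClass("SurprisalDecomposition",
         slots = c(G = "matrix", lambda = "matrix", omega = "numeric"))

setValidity("SurprisalDecomposition", function(object) {
  G <- object@G; lam <- object@lambda; om <- object@omega
  t <- ncol(G)
  if (nrow(lam) != t || ncol(lam) != t)
    return("lambda must be t x t with t = ncol(G)")
  if (length(om) != t) return("omega must have one value per pattern")
  msg <- .checkAxisNames(rownames(G), "gene")
  if (!is.null(msg)) return(msg)
  msg <- .checkAxisNames(colnames(lam), "condition")
  if (!is.null(msg)) return(msg)
  if (anyNA(om) || any(om < 0)) return("singular values must be >= 0")
  if (is.unsorted(rev(om), strictly = FALSE) && any(diff(om) > 1e-8 * max(om, 1)))
    return("singular values must be non-increasing")
  TRUE
})

# ---------------------------------------------------------------------------
# Gene profiling containers
# ---------------------------------------------------------------------------

#' Sorted per-pattern gene profile
#'
#' All genes of a decomposition with their participation weights
#' \eqn{G_{i\alpha}} for one pattern, sorted in non-increasing order of
#' weight (ties broken by gene name).
#'
#' @slot pattern integer pattern index \eqn{\alpha} (0-based; 0 = steady state).
#' @slot genes character vector of gene names in sorted order.
#' @slot values numeric weights, non-increasing, aligned with `genes`.
#' @seealso [sortPattern()], [selectByBounds()]
#' @export
setClass("SortedProfile",
         slots = c(pattern = "integer", genes = "character",
                   values = "numeric"))

setValidity("SortedProfile", function(object) {
  if (length(object@genes) != length(object@values))
    return("genes and values must be aligned")
  if (is.unsorted(rev(object@values)))
    return("values must be non-increasing")
  if (anyDuplicated(object@genes)) return("duplicate gene names in profile")
  TRUE
})

#' Gene selection for one pattern
#'
#' An ordered subset of a [SortedProfile-class]: genes selected by weight
#' bounds or as the n most extreme, together with the parameters that
#' reproduce the subset.
#'
#' @slot pattern integer pattern index \eqn{\alpha} (0-based).
#' @slot role one of `"stable"`, `"deviating_high"`, `"deviating_low"`,
#'   `"bounds"`.
#' @slot genes,values the selected genes and their weights, in profile
#'   (non-increasing weight) order.
#' @slot group per-gene group label (`"high"`/`"low"` for bound selections,
#'   the role otherwise).
#' @slot params named list of selection parameters (`n`, `mode`, `upper`,
#'   `lower`, `inclusive` as applicable).
#' @seealso [selectByBounds()], [selectExtremes()], [writeGeneList()]
#' @export
setClass("GeneSelection",
         slots = c(pattern = "integer", role = "character",
                   genes = "character", values = "numeric",
                   group = "character", params = "list"))

setValidity("GeneSelection", function(object) {
  n <- length(object@genes)
  if (length(object@values) != n || length(object@group) != n)
    return("genes, values and group must be aligned")
  if (anyDuplicated(object@genes)) return("duplicate gene names in selection")
  if (!object@role %in% c("stable", "deviating_high", "deviating_low", "bounds"))
    return("invalid role tag")
  TRUE
})

# ---------------------------------------------------------------------------
# Connectivity containers
# ---------------------------------------------------------------------------

#' Table of functional-association links
#'
#' Canonicalized pairwise STRING combined scores between genes: one record
#' per unordered pair, scores expressed as probabilities in \[0, 1\]
#' (raw integer scores divided by 1000), no self links.
#'
#' @slot links data.frame with columns `gene_a`, `gene_b` (gene_a < gene_b)
#'   and `score`.
#' @seealso [parseStringLinks()], [buildScoreMatrix()]
#' @export
setClass("LinkTable", slots = c(links = "data.frame"))

setValidity("LinkTable", function(object) {
  lk <- object@links
  if (!all(c("gene_a", "gene_b", "score") %in% names(lk)))
    return("links must have columns gene_a, gene_b, score")
  if (nrow(lk) == 0L) return(TRUE)
  if (any(lk$gene_a == lk$gene_b)) return("self links are not allowed")
  if (any(lk$gene_a > lk$gene_b))
    return("pairs must be stored in canonical order (gene_a < gene_b)")
  if (anyDuplicated(paste(lk$gene_a, lk$gene_b, sep = "\r")))
    return("each unordered pair may appear once")
  if (any(lk$score < 0 | lk$score > 1))
    return("scores must be probabilities in [0, 1]")
  TRUE
})

#' Symmetric combined-score matrix over a gene list
#'
#' STRING combined scores arranged on an explicit ordered gene axis. Pairs
#' without database information carry `NA` (a missing marker distinct from a
#' zero score), as does the diagonal: STRING stores no self associations.
#'
#' @slot values symmetric numeric matrix with identical row/column gene
#'   names; probabilities in \[0, 1\] or `NA`.
#' @seealso [buildScoreMatrix()], [exportEdgeList()], [pairHeatmaps()]
#' @export
setClass("ConnectivityMatrix", slots = c(values = "matrix"))

.checkSquareSymmetric <- function(v) {
  if (nrow(v) != ncol(v)) return("matrix must be square")
  msg <- .checkAxisNames(rownames(v), "gene")
  if (!is.null(msg)) return(msg)
  if (!identical(rownames(v), colnames(v)))
    return("row and column gene axes must be identical")
  na <- is.na(v)
  if (!identical(na, t(na))) return("missingness must be symmetric")
  d <- abs(v - t(v))
  if (any(d[!is.na(d)] > 1e-12)) return("matrix must be symmetric")
  NULL
}

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  msg <- .checkSquareSymmetric(v)
  if (!is.null(msg)) return(msg)
  if (any(!is.na(diag(v)))) return("diagonal must carry the missing marker")
  ok <- v[!is.na(v)]
  if (any(ok < 0 | ok > 1)) return("scores must be probabilities in [0, 1]")
  TRUE
})

# ---------------------------------------------------------------------------
# Heatmap containers
# ---------------------------------------------------------------------------

#' Symmetric heatmap on a gene x gene axis
#'
#' Either a theoretical connectivity prediction (cell ij =
#' \eqn{G_{i\alpha} G_{j\alpha}}, dimensionless, signed) or an experimental
#' STRING combined-score matrix (probabilities, `NA` marks missing pairs).
#' Both axes carry the same genes in the same order.
#'
#' @slot values symmetric numeric matrix, identical row/column names.
#' @slot source `"theoretical"` or `"string_db"`.
#' @slot pattern integer pattern index for theoretical maps (`NA` otherwise).
#' @seealso [productHeatmap()], [pairHeatmaps()], [cellInfo()],
#'   [writeHeatmapTSV()]
#' @export
setClass("Heatmap",
         slots = c(values = "matrix", source = "character",
                   pattern = "integer"))

setValidity("Heatmap", function(object) {
  msg <- .checkSquareSymmetric(object@values)
  if (!is.null(msg)) return(msg)
  if (!object@source %in% c("theoretical", "string_db"))
    return("source must be 'theoretical' or 'string_db'")
  TRUE
})

#' Paired theoretical and experimental heatmaps
#'
#' A theoretical \eqn{G_{i\alpha} G_{j\alpha}} heatmap and a STRING
#' combined-score heatmap sharing an identical, identically ordered gene
#' axis, so the two can be compared cell by cell.
#'
#' @slot theoretical,experimental [Heatmap-class] members on the same axis.
#' @seealso [pairHeatmaps()], [correlateHeatmaps()]
#' @export
setClass("HeatmapPair",
         slots = c(theoretical = "Heatmap", experimental = "Heatmap"))

setValidity("HeatmapPair", function(object) {
  if (!identical(rownames(object@theoretical@values),
                 rownames(object@experimental@values)))
    return("both heatmaps must share the same ordered gene axis")
  TRUE
})

# ---------------------------------------------------------------------------
# Synthetic planted truth
# ---------------------------------------------------------------------------

#' Planted ground truth of a synthetic dataset
#'
#' Records what [generatePlantedDataset()] wrote into a synthetic expression
#' matrix: the true (orthonormal) gene weight columns, the true multiplier
#' profiles, the role of every gene and the noise level, so recovery can be
#' scored exactly.
#'
#' @slot trueG m x k matrix of planted gene weights (orthonormal columns;
#'   column 1 = steady state).
#' @slot trueLambda k x t matrix of planted multiplier profiles.
#' @slot roles per-gene labels: `"stable"`, `"deviating"` or `"background"`.
#' @slot noiseSd standard deviation of the additive log-scale noise.
#' @slot seed integer seed the dataset was generated from.
#' @seealso [generatePlantedDataset()], [generateLinksFixture()]
#' @export
setClass("PlantedTruth",
         slots = c(trueG = "matrix", trueLambda = "matrix",
                   roles = "character", noiseSd = "numeric",
                   seed = "integer"))

setValidity("PlantedTruth", function(object) {
  if (nrow(object@trueG) != length(object@roles))
    return("roles must label every gene")
  if (ncol(object@trueG) != nrow(object@trueLambda))
    return("trueG and trueLambda must agree on the number of components")
  if (!all(object@roles %in% c("stable", "deviating", "background")))
    return("roles must be stable/deviating/background")
  gram <- crossprod(object@trueG)
  if (max(abs(gram - diag(ncol(gram)))) > 1e-8)
    return("planted G columns must be orthonormal")
  TRUE
})

# ---------------------------------------------------------------------------
# Accessors and show methods
# ---------------------------------------------------------------------------

#' @describeIn ExpressionMatrix gene names.
#' @export
setMethod("geneNames", "ExpressionMatrix", function(x) rownames(x@values))

#' @describeIn ExpressionMatrix condition names.
#' @export
setMethod("conditionNames", "ExpressionMatrix", function(x) colnames(x@values))

#' @describeIn ExpressionMatrix the positive expression matrix.
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @describeIn LogExpressionMatrix gene names.
#' @export
setMethod("geneNames", "LogExpressionMatrix", function(x) rownames(x@values))

#' @describeIn LogExpressionMatrix condition names.
#' @export
setMethod("conditionNames", "LogExpressionMatrix",
          function(x) colnames(x@values))

#' @describeIn LogExpressionMatrix the log-expression matrix.
#' @export
setMethod("exprValues", "LogExpressionMatrix", function(x) x@values)

#' @describeIn SurprisalDecomposition gene names.
#' @export
setMethod("geneNames", "SurprisalDecomposition", function(x) rownames(x@G))

#' @describeIn SurprisalDecomposition condition names.
#' @export
setMethod("conditionNames", "SurprisalDecomposition",
          function(x) colnames(x@lambda))

#' @describeIn SurprisalDecomposition gene participation weights.
#' @export
setMethod("patternWeights", "SurprisalDecomposition", function(x) x@G)

#' @describeIn SurprisalDecomposition Lagrange multiplier matrix.
#' @export
setMethod("multipliers", "SurprisalDecomposition", function(x) x@lambda)

#' @describeIn SurprisalDecomposition singular values.
#' @export
setMethod("singularValues", "SurprisalDecomposition", function(x) x@omega)

#' @describeIn ConnectivityMatrix gene axis.
#' @export
setMethod("geneNames", "ConnectivityMatrix", function(x) rownames(x@values))

#' @describeIn ConnectivityMatrix score matrix (NA = missing pair).
#' @export
setMethod("exprValues", "ConnectivityMatrix", function(x) x@values)

#' @describeIn Heatmap gene axis.
#' @export
setMethod("geneNames", "Heatmap", function(x) rownames(x@values))

#' @describeIn Heatmap cell values.
#' @export
setMethod("exprValues", "Heatmap", function(x) x@values)

setMethod("show", "ExpressionMatrix", function(object) {
  v <- object@values
  cat(sprintf("ExpressionMatrix: %d genes x %d conditions\n", nrow(v), ncol(v)))
  cat("conditions:", paste(colnames(v), collapse = ", "), "\n")
  cat(sprintf("signal range: [%.4g, %.4g]\n", min(v), max(v)))
})

setMethod("show", "LogExpressionMatrix", function(object) {
  v <- object@values
  cat(sprintf("LogExpressionMatrix: %d genes x %d conditions (natural log)\n",
              nrow(v), ncol(v)))
})

setMethod("show", "SurprisalDecomposition", function(object) {
  t <- ncol(object@G)
  cat(sprintf("SurprisalDecomposition: %d genes, %d patterns (alpha = 0..%d)\n",
              nrow(object@G), t, t - 1L))
  cat("conditions:", paste(colnames(object@lambda), collapse = ", "), "\n")
  cat("singular values:", paste(signif(object@omega, 6), collapse = ", "), "\n")
  cat(sprintf("effective rank (omega > 1e-10 * omega0): %d\n",
              effectiveRank(object)))
})

setMethod("show", "SortedProfile", function(object) {
  cat(sprintf("SortedProfile: pattern alpha=%d, %d genes, weights in [%.4g, %.4g]\n",
              object@pattern, length(object@genes),
              min(object@values), max(object@values)))
})

setMethod("show", "GeneSelection", function(object) {
  cat(sprintf("GeneSelection: pattern alpha=%d, role '%s', %d genes\n",
              object@pattern, object@role, length(object@genes)))
  p <- object@params
  if (length(p))
    cat("params:", paste(names(p), unlist(lapply(p, format)),
                         sep = "=", collapse = ", "), "\n")
})

setMethod("show", "LinkTable", function(object) {
  cat(sprintf("LinkTable: %d canonical gene pairs\n", nrow(object@links)))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat(sprintf("ConnectivityMatrix: %d genes; %d/%d off-diagonal pairs scored\n",
              nrow(v), sum(!is.na(off)), length(off)))
})

setMethod("show", "Heatmap", function(object) {
  cat(sprintf("Heatmap (%s): %d x %d genes\n", object@source,
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "HeatmapPair", function(object) {
  cat(sprintf("HeatmapPair: %d shared genes (theoretical vs %s)\n",
              nrow(object@theoretical@values), object@experimental@source))
})

setMethod("show", "PlantedTruth", function(object) {
  cat(sprintf("PlantedTruth: %d genes (%d stable, %d deviating), noise sd %.3g, seed %d\n",
              length(object@roles), sum(object@roles == "stable"),
              sum(object@roles == "deviating"), object@noiseSd, object@seed))
})
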