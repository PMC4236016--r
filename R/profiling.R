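#' @include AllClasses.R
NULL

.checkAlpha <- function(d, alpha) {
  t <- ncol(d@G)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha != as.integer(alpha) ||
      alpha < 0L || alpha >= t)
    stop("pattern index alpha must be an integer in 0..", t - 1L)
  as.integer(alpha)
}

#' Sort the participation weights of one pattern
#'
#' Returns all genes with their weights \eqn{G_{i\alpha}} sorted in
#' non-increasing order (ties broken by gene name, ascending, in the C
#' locale) — the sorted eigenvector profile one scans before placing
#' selection bounds.
#'
#' @param d a [SurprisalDecomposition-class].
#' @param alpha pattern index, 0-based; 0 is the steady state.
#' @return A [SortedProfile-class].
#' @export
sortPattern <- function(d, alpha) {
  stopifnot(is(d, "SurprisalDecomposition"))
  alpha <- .checkAlpha(d, alpha)
  v <- d@G[, alpha + 1L]
  genes <- rownames(d@G)
  o <- order(-v, genes, method = "radix")
  new("SortedProfile", pattern = alpha, genes = genes[o], values = v[o])
}

#' Select genes by weight bounds
#'
#' Splits a sorted profile into a high group (weights above `upper`) and a
#' low group (weights below `lower`), both in profile order — the
#' two-horizontal-lines selection over the sorted eigenvector plot. Bounds
#' are strict by default; most weights sit near zero and are excluded.
#'
#' @param p a [SortedProfile-class].
#' @param upper,lower numeric bounds, `upper >= lower`. Use `Inf`/`-Inf` to
#'   disable a side.
#' @param inclusive if `TRUE`, use `>=`/`<=` instead of strict inequalities.
#' @return A [GeneSelection-class] with role `"bounds"`; slot `group` labels
#'   each gene `"high"` or `"low"`.
#' @examples
#' # see selectExtremes() for an end-to-end example
#' @export
selectByBounds <- function(p, upper, lower, inclusive = FALSE) {
  stopifnot(is(p, "SortedProfile"),
            is.numeric(upper), length(upper) == 1L,
            is.numeric(lower), length(lower) == 1L)
  if (upper < lower) stop("upper bound must be >= lower bound")
  hi <- if (inclusive) p@values >= upper else p@values > upper
  lo <- if (inclusive) p@values <= lower else p@values < lower
  keep <- hi | lo
  new("GeneSelection",
      pattern = p@pattern, role = "bounds",
      genes = p@genes[keep], values = p@values[keep],
      group = ifelse(hi, "high", "low")[keep],
      params = list(upper = upper, lower = lower, inclusive = inclusive))
}

#' Select the n most extreme genes of a pattern
#'
#' The field's standard subsets: the n "most stable" transcripts are the n
#' most negative \eqn{G_{i0}} (mode `"most_negative"` on the steady state),
#' and the n transcripts most contributing to a transformation pattern are
#' the n most positive (or largest-magnitude) \eqn{G_{i\alpha}}. Ties are
#' broken by gene name so the subset is deterministic; output keeps profile
#' (non-increasing weight) order.
#'
#' @param d a [SurprisalDecomposition-class].
#' @param alpha pattern index, 0-based.
#' @param n number of genes, 1 <= n <= m.
#' @param mode `"most_negative"`, `"most_positive"` or `"largest_magnitude"`.
#' @return A [GeneSelection-class]; role is `"stable"` for
#'   `most_negative` on the steady state, `"deviating_low"`/`"deviating_high"`
#'   otherwise.
#' @examples
#' x <- generatePlantedDataset(m = 200, nStable = 20, nDeviating = 20,
#'                             seed = 1L)
#' d <- surprisalDecompose(logTransform(x$expression))
#' sel <- selectExtremes(d, alpha = 0, n = 20, mode = "most_negative")
#' head(sel@genes)
#' @export
selectExtremes <- function(d, alpha, n,
                           mode = c("most_negative", "most_positive",
                                    "largest_magnitude")) {
  stopifnot(is(d, "SurprisalDecomposition"))
  mode <- match.arg(mode)
  alpha <- .checkAlpha(d, alpha)
  m <- nrow(d@G)
  if (!is.numeric(n) || length(n) != 1L || n != as.integer(n) ||
      n < 1L || n > m)
    stop("n must be an integer in 1..", m)
  n <- as.integer(n)
  v <- d@G[, alpha + 1L]
  genes <- rownames(d@G)
  key <- switch(mode,
                most_negative = v,
                most_positive = -v,
                largest_magnitude = -abs(v))
  picked <- genes[order(key, genes, method = "radix")[seq_len(n)]]
  keep <- genes %in% picked
  o <- order(-v[keep], genes[keep], method = "radix")
  role <- if (mode == "most_negative") {
    if (alpha == 0L) "stable" else "deviating_low"
  } else "deviating_high"
  new("GeneSelection",
      pattern = alpha, role = role,
      genes = genes[keep][o], values = v[keep][o],
      group = rep(role, n),
      params = list(n = n, mode = mode))
}

#' Write a selection as a plain gene list
#'
#' One gene name per line — the format the connectivity retrieval step
#' consumes.
#'
#' @param sel a [GeneSelection-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeneList <- function(sel, path) {
  stopifnot(is(sel, "GeneSelection"))
  writeLines(sel@genes, path)
  invisible(path)
}

#' Write a selection with weights and provenance
#'
#' TSV with the selection parameters in `#`-prefixed header lines, then
#' gene / weight / group columns, so the subset can be reproduced exactly.
#'
#' @param sel a [GeneSelection-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSelectionTSV <- function(sel, path) {
  stopifnot(is(sel, "GeneSelection"))
  hdr <- c(sprintf("# pattern\t%d", sel@pattern),
           sprintf("# role\t%s", sel@role),
           vapply(names(sel@params), function(k)
             sprintf("# %s\t%s", k, format(sel@params[[k]])), character(1)))
  body <- paste(sel@genes, sprintf("%.17g", sel@values), sel@group,
                sep = "\t")
  writeLines(c(hdr, "gene\tvalue\tgroup", body), path)
  invisible(path)
}
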