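#' @include AllClasses.R
NULL

#' Theoretical connectivity heatmap for one pattern
#'
#' Builds the symmetric matrix whose ij cell is the signed product
#' \eqn{G_{i\alpha} G_{j\alpha}} over a gene selection — the theoretical
#' prediction of functional connectivity within pattern \eqn{\alpha}. The
#' sign carries meaning: a positive product marks genes correlated within
#' the pattern (e.g. stable x stable, both weights negative), a negative
#' product marks anti-correlation. The matrix is the outer product of a
#' sub-vector with itself, hence exactly rank 1.
#'
#' @param d a [SurprisalDecomposition-class].
#' @param alpha pattern index, 0-based.
#' @param sel a [GeneSelection-class] or character vector of gene names; the
#'   axis order is the selection order.
#' @return A [Heatmap-class] with source `"theoretical"`.
#' @export
productHeatmap <- function(d, alpha, sel) {
  stopifnot(is(d, "SurprisalDecomposition"))
  alpha <- .checkAlpha(d, alpha)
  genes <- if (is(sel, "GeneSelection")) sel@genes else as.character(sel)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene(s) in selection: ", paste(dup, collapse = ", "))
  unknown <- setdiff(genes, rownames(d@G))
  if (length(unknown))
    stop("gene(s) not in decomposition: ", paste(unknown, collapse = ", "))
  g <- d@G[genes, alpha + 1L]
  v <- outer(g, g)
  dimnames(v) <- list(genes, genes)
  new("Heatmap", values = v, source = "theoretical", pattern = alpha)
}

#' Combined heatmap axis from a stable and a deviating selection
#'
#' The block layout used when a steady-state and a transformation selection
#' share one heatmap: the stable block first, ordered by ascending
#' \eqn{G_{i0}} (most stable, most negative first), then the deviating
#' block ordered by descending \eqn{G_{i1}}. Genes in both selections are
#' kept in the stable block.
#'
#' @param stable,deviating [GeneSelection-class] objects (typically pattern
#'   0 and pattern 1).
#' @return Character vector of gene names defining the axis order.
#' @export
combinedAxis <- function(stable, deviating) {
  stopifnot(is(stable, "GeneSelection"), is(deviating, "GeneSelection"))
  sBlock <- stable@genes[order(stable@values, stable@genes, method = "radix")]
  dBlock <- deviating@genes[order(-deviating@values, deviating@genes,
                                  method = "radix")]
  c(sBlock, setdiff(dBlock, sBlock))
}

#' Convert a connectivity matrix to a heatmap
#'
#' @param c a [ConnectivityMatrix-class].
#' @return A [Heatmap-class] with source `"string_db"`.
#' @export
asHeatmap <- function(c) {
  stopifnot(is(c, "ConnectivityMatrix"))
  new("Heatmap", values = c@values, source = "string_db",
      pattern = NA_integer_)
}

#' Pair a theoretical heatmap with a connectivity matrix
#'
#' Reindexes the connectivity matrix to the theoretical heatmap's gene order
#' so both members share an identical, identically ordered axis — the
#' precondition for cell-by-cell comparison. The gene sets must match
#' exactly.
#'
#' @param theory a [Heatmap-class] (source `"theoretical"`).
#' @param conn a [ConnectivityMatrix-class] or [Heatmap-class] over the same
#'   gene set, in any order.
#' @return A [HeatmapPair-class].
#' @export
pairHeatmaps <- function(theory, conn) {
  stopifnot(is(theory, "Heatmap"))
  cv <- if (is(conn, "ConnectivityMatrix")) conn@values
        else if (is(conn, "Heatmap")) conn@values
        else stop("conn must be a ConnectivityMatrix or Heatmap")
  axis <- rownames(theory@values)
  have <- rownames(cv)
  if (!setequal(axis, have)) {
    miss <- setdiff(axis, have)
    extra <- setdiff(have, axis)
    stop("gene sets differ; missing from connectivity: {",
         paste(miss, collapse = ", "), "}; absent from theory: {",
         paste(extra, collapse = ", "), "}")
  }
  cv <- cv[axis, axis, drop = FALSE]
  new("HeatmapPair",
      theoretical = theory,
      experimental = new("Heatmap", values = cv, source = "string_db",
                         pattern = NA_integer_))
}

#' Look up one heatmap cell
#'
#' The programmatic equivalent of zooming in on a heatmap cell: the two
#' crossing genes and the stored value (or the missing marker).
#'
#' @param h a [Heatmap-class].
#' @param i,j gene names on the axis.
#' @return A list with `gene_row`, `gene_col`, `value` (NA when missing) and
#'   `missing` (logical).
#' @export
cellInfo <- function(h, i, j) {
  stopifnot(is(h, "Heatmap"))
  axis <- rownames(h@values)
  for (g in c(i, j))
    if (!g %in% axis) stop("gene not on heatmap axis: ", g)
  val <- h@values[i, j]
  list(gene_row = i, gene_col = j, value = val, missing = is.na(val))
}

#' Steady-state vs transformation scatter coordinates
#'
#' One point per gene: \eqn{G_{i0}} against \eqn{G_{i1}}. Stable transcripts
#' sit at large negative \eqn{G_{i0}} with \eqn{G_{i1}} near zero; the
#' transcripts driving the transformation pattern show the opposite — the
#' homeostasis picture of the steady state.
#'
#' @param d a [SurprisalDecomposition-class] with at least two patterns.
#' @return data.frame with columns `gene`, `G0`, `G1`, in gene order.
#' @export
stabilityScatter <- function(d) {
  stopifnot(is(d, "SurprisalDecomposition"))
  if (ncol(d@G) < 2L)
    stop("stability scatter needs at least two patterns (t >= 2)")
  data.frame(gene = rownames(d@G), G0 = d@G[, 1L], G1 = d@G[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank correlation between paired heatmaps
#'
#' Spearman correlation over the upper-triangle off-diagonal cells where
#' both members carry a value; cells with a missing marker on either side
#' are excluded and the number of cells used is reported. Rank correlation
#' is the default because the two scales — signed weight products and
#' association probabilities — are not comparable linearly.
#'
#' @param p a [HeatmapPair-class].
#' @param method passed to [stats::cor()]; default `"spearman"`.
#' @return A list with `correlation` and `n_cells`.
#' @export
correlateHeatmaps <- function(p, method = "spearman") {
  stopifnot(is(p, "HeatmapPair"))
  a <- p@theoretical@values
  b <- p@experimental@values
  ut <- upper.tri(a)
  x <- a[ut]; y <- b[ut]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L)
    stop("need at least 3 mutually non-missing off-diagonal cells, have ",
         sum(ok))
  list(correlation = stats::cor(x[ok], y[ok], method = method),
       n_cells = sum(ok))
}

#' Write a heatmap as TSV
#'
#' Square matrix with gene names on both axes; missing cells carry the
#' reserved token `NA`. Values round-trip bit-exactly through
#' [readHeatmapTSV()].
#'
#' @param h a [Heatmap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHeatmapTSV <- function(h, path) {
  stopifnot(is(h, "Heatmap"))
  hdr <- sprintf("# source\t%s", h@source)
  if (!is.na(h@pattern))
    hdr <- c(hdr, sprintf("# pattern\t%d", h@pattern))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  .writeNamedMatrixTSV(h@values, tmp, corner = "gene")
  writeLines(c(hdr, readLines(tmp)), path)
  invisible(path)
}

#' Read a heatmap written by [writeHeatmapTSV()]
#'
#' @param path path to the TSV file.
#' @return A [Heatmap-class].
#' @export
readHeatmapTSV <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  src <- sub("^# source\t", "", grep("^# source\t", meta, value = TRUE))
  pat <- grep("^# pattern\t", meta, value = TRUE)
  pattern <- if (length(pat)) as.integer(sub("^# pattern\t", "", pat))
             else NA_integer_
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(body, tmp)
  v <- .readNamedMatrixTSV(tmp)
  new("Heatmap", values = v, source = src, pattern = pattern)
}
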