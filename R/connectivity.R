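#' @include AllClasses.R
NULL

#' Read a gene-name / protein-ID map
#'
#' Two-column TSV (header `gene`, `protein`, or any two columns in that
#' order) translating STRING protein identifiers to the gene names used in
#' the expression matrix. Both columns must be free of duplicates: a gene
#' mapped from two proteins (or vice versa) would make score assignment
#' ambiguous.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene` and `protein`.
#' @export
readIdMap <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("id map must have two columns (gene, protein)")
  if (!all(c("gene", "protein") %in% names(df))) {
    names(df)[1:2] <- c("gene", "protein")
  }
  df <- df[, c("gene", "protein")]
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup))
    stop("duplicate gene name(s) in id map: ", paste(dup, collapse = ", "))
  dup <- unique(df$protein[duplicated(df$protein)])
  if (length(dup))
    stop("duplicate protein id(s) in id map: ", paste(dup, collapse = ", "))
  df
}

#' Parse a STRING protein-links file
#'
#' Reads the whitespace-separated STRING flat-file dialect — a header line
#' naming (at least) `protein1`, `protein2` and `combined_score`, then one
#' record per protein pair with an integer combined score 0–999. Scores are
#' divided by 1000 into association probabilities; protein IDs are
#' translated to gene names through `idMap`; records with unmapped IDs are
#' dropped with a reported count; duplicate/self pairs are canonicalized
#' (unordered pair stored once; conflicting duplicate scores keep the
#' maximum — STRING's combined score reflects higher confidence when more
#' evidence supports an association — with a warning).
#'
#' @param path path to the links file. Extra columns (per-channel scores)
#'   are tolerated; columns are located by header name.
#' @param idMap data.frame from [readIdMap()] (columns `gene`, `protein`).
#' @return A [LinkTable-class].
#' @export
parseStringLinks <- function(path, idMap) {
  stopifnot(is.data.frame(idMap),
            all(c("gene", "protein") %in% names(idMap)))
  dup <- unique(idMap$gene[duplicated(idMap$gene)])
  if (length(dup))
    stop("duplicate gene name(s) in id map: ", paste(dup, collapse = ", "))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty links file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  header <- fields[[1L]]
  need <- c("protein1", "protein2", "combined_score")
  miss <- setdiff(need, header)
  if (length(miss))
    stop("links header lacks column(s): ", paste(miss, collapse = ", "))
  idx <- match(need, header)

  body <- fields[-1L]
  if (length(body) == 0L)
    return(new("LinkTable",
               links = data.frame(gene_a = character(), gene_b = character(),
                                  score = numeric())))
  nf <- lengths(body)
  bad <- which(nf != length(header))
  if (length(bad))
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 bad[1L] + 1L, length(header), nf[bad[1L]]))
  rec <- t(vapply(body, function(f) f[idx], character(3)))
  raw <- suppressWarnings(as.numeric(rec[, 3L]))
  bad <- which(is.na(raw) | raw != floor(raw) | raw < 0 | raw > 999)
  if (length(bad))
    stop(sprintf(
      "parse error at line %d: combined_score '%s' is not an integer in 0..999",
      bad[1L] + 1L, rec[bad[1L], 3L]))

  gene <- idMap$gene[match(rec[, 1L], idMap$protein)]
  geneB <- idMap$gene[match(rec[, 2L], idMap$protein)]
  unmapped <- is.na(gene) | is.na(geneB)
  if (any(unmapped))
    message(sum(unmapped), " record(s) dropped: protein id not in the map")
  a <- gene[!unmapped]; b <- geneB[!unmapped]
  score <- raw[!unmapped] / 1000

  self <- a == b
  if (any(self)) {
    message(sum(self), " self-link record(s) dropped")
    a <- a[!self]; b <- b[!self]; score <- score[!self]
  }
  ga <- pmin(a, b); gb <- pmax(a, b)
  key <- paste(ga, gb, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(score, key, max)
    rng <- tapply(score, key, function(s) diff(range(s)))
    if (any(rng > 0))
      warning(sum(rng > 0),
              " pair(s) had conflicting duplicate scores; keeping the maximum")
    first <- !duplicated(key)
    ord <- key[first]
    ga <- ga[first]; gb <- gb[first]
    score <- as.numeric(agg[ord])
  }
  new("LinkTable",
      links = data.frame(gene_a = ga, gene_b = gb, score = score,
                         stringsAsFactors = FALSE))
}

#' Build a combined-score matrix over an ordered gene list
#'
#' Arranges link scores into a symmetric matrix over exactly the given genes
#' in the given order. Pairs absent from the link table — and the diagonal —
#' carry `NA`, the explicit missing-data marker (the "white dots"): no
#' database information is not the same as a zero score.
#'
#' @param links a [LinkTable-class].
#' @param genes unique, non-empty character vector defining the axis.
#' @return A [ConnectivityMatrix-class].
#' @export
buildScoreMatrix <- function(links, genes) {
  stopifnot(is(links, "LinkTable"), is.character(genes))
  if (length(genes) == 0L) stop("gene list must be non-empty")
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene(s) in list: ", paste(dup, collapse = ", "))
  n <- length(genes)
  v <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  lk <- links@links
  keep <- lk$gene_a %in% genes & lk$gene_b %in% genes
  lk <- lk[keep, , drop = FALSE]
  if (nrow(lk)) {
    ia <- match(lk$gene_a, genes)
    ib <- match(lk$gene_b, genes)
    v[cbind(ia, ib)] <- lk$score
    v[cbind(ib, ia)] <- lk$score
  }
  new("ConnectivityMatrix", values = v)
}

#' Export a thresholded edge list
#'
#' One record per unordered gene pair with a non-missing score at or above
#' the threshold. The score is kept as the edge weight — downstream network
#' drawings scale line thickness by this functional-link probability.
#'
#' @param c a [ConnectivityMatrix-class].
#' @param threshold probability in \[0, 1\]; pairs with `score >= threshold`
#'   are exported.
#' @return data.frame with columns `gene_a`, `gene_b`, `score`, pairs in
#'   row-major upper-triangle order of the matrix axis.
#' @export
exportEdgeList <- function(c, threshold = 0) {
  stopifnot(is(c, "ConnectivityMatrix"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  v <- c@values
  genes <- rownames(v)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  s <- v[ut]
  keep <- !is.na(s) & s >= threshold
  data.frame(gene_a = genes[ut[keep, 1L]],
             gene_b = genes[ut[keep, 2L]],
             score = s[keep],
             stringsAsFactors = FALSE)
}

#' Write an edge list as TSV
#'
#' @param edges data.frame from [exportEdgeList()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
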