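#' @include AllClasses.R
NULL

#' Read an expression matrix from CSV
#'
#' Reads the tool's CSV contract: a title record `Gene,<cond1>,...,<condt>`
#' followed by one record per gene holding the gene name and t positive
#' expression signals. Gene and condition names must be unique; file order is
#' preserved. Cells that are empty or hold a non-positive signal are floored
#' at `floor` (a message reports the count), so the downstream log transform
#' is always defined.
#'
#' @param path path to a UTF-8, comma-separated file.
#' @param floor positive flooring constant for missing/non-positive signals
#'   (default 1.0 signal unit).
#' @return An [ExpressionMatrix-class] with names in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("Gene,K,E,L,BP", "ACTB,1200,1180,1210,1190",
#'              "MYC,80,160,420,460"), f)
#' readExpressionCSV(f)
#' @export
readExpressionCSV <- function(path, floor = 1.0) {
  stopifnot(is.numeric(floor), length(floor) == 1L, floor > 0)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!(seq_along(lines) > 1 & !nzchar(trimws(lines)))]
  if (length(lines) < 2L)
    stop("expected a title record plus at least one gene record in ", path)

  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop("parse error at line 1: title record must name at least one condition")
  conds <- trimws(header[-1L])
  dup <- unique(conds[duplicated(conds)])
  if (length(dup))
    stop("duplicate condition name(s): ", paste(dup, collapse = ", "))

  t <- length(conds)
  body <- strsplit(lines[-1L], ",", fixed = TRUE)
  nf <- lengths(body)
  # trailing empty field dropped by strsplit: "G,1," -> 2 fields; re-pad
  ends_comma <- endsWith(lines[-1L], ",")
  body[ends_comma] <- lapply(body[ends_comma], function(f) c(f, ""))
  nf <- lengths(body)
  bad <- which(nf != t + 1L)
  if (length(bad))
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 bad[1L] + 1L, t + 1L, nf[bad[1L]]))

  genes <- trimws(vapply(body, `[[`, character(1), 1L))
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene name(s): ", paste(dup, collapse = ", "))

  raw <- vapply(body, function(f) {
    cell <- trimws(f[-1L])
    out <- suppressWarnings(as.numeric(cell))
    out[cell == "" | toupper(cell) == "NA"] <- NA_real_
    out
  }, numeric(t))
  vals <- if (t == 1L) matrix(raw, ncol = 1L) else t(raw)

  # distinguish a truly non-numeric cell (error) from an empty one (floored)
  for (j in seq_len(t)) {
    cells <- trimws(vapply(body, `[[`, character(1), j + 1L))
    nonnum <- is.na(vals[, j]) & cells != "" & toupper(cells) != "NA"
    if (any(nonnum)) {
      i <- which(nonnum)[1L]
      stop(sprintf("parse error at line %d: non-numeric value '%s' for gene %s",
                   i + 1L, cells[i], genes[i]))
    }
  }

  low <- is.na(vals) | vals <= 0
  if (any(low)) {
    message(sum(low), " cell(s) floored at ", floor,
            " (missing or non-positive signal)")
    vals[low] <- floor
  }
  ExpressionMatrix(vals, geneNames = genes, conditionNames = conds)
}

#' Write an expression matrix to CSV
#'
#' Writes the same dialect [readExpressionCSV()] consumes. Values are
#' serialized with 17 significant digits so finite doubles round-trip
#' bit-exactly.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionCSV <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  v <- x@values
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(paste(c("Gene", colnames(v)), collapse = ","), rows), path)
  invisible(path)
}

#' Scale each array to a common target intensity
#'
#' Global per-array (per-condition) multiplicative scaling in the MAS5
#' tradition: every column is multiplied by `target / mean(column)` so all
#' column means equal `target`. With `trim > 0` the scaling factor uses a
#' trimmed column mean instead (the column mean after scaling then differs
#' from `target` by the trimming).
#'
#' @param x an [ExpressionMatrix-class].
#' @param target positive target intensity.
#' @param trim fraction (0 to 0.5) trimmed from each tail when computing the
#'   per-column reference mean; default 0 (plain arithmetic mean).
#' @return A rescaled [ExpressionMatrix-class]; names unchanged.
#' @examples
#' x <- ExpressionMatrix(matrix(c(50, 150, 200, 400), 2, 2),
#'                       geneNames = c("A", "B"),
#'                       conditionNames = c("T1", "T2"))
#' colMeans(exprValues(scaleToTargetIntensity(x, 500)))
#' @export
scaleToTargetIntensity <- function(x, target, trim = 0) {
  stopifnot(is(x, "ExpressionMatrix"),
            is.numeric(target), length(target) == 1L, target > 0,
            trim >= 0, trim < 0.5)
  v <- x@values
  ref <- apply(v, 2L, mean, trim = trim)
  if (any(ref <= 0))
    stop("non-positive column mean in condition(s): ",
         paste(colnames(v)[ref <= 0], collapse = ", "))
  ExpressionMatrix(sweep(v, 2L, target / ref, `*`),
                   geneNames = rownames(v), conditionNames = colnames(v))
}
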