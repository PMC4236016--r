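# Shared fixture builders; everything is generated in code at test time.

makeExpr <- function(values, genes = NULL, conds = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(conds)) conds <- paste0("T", seq_len(ncol(values)))
  ExpressionMatrix(values, geneNames = genes, conditionNames = conds)
}

randomExpr <- function(m, t, seed) {
  set.seed(seed)
  makeExpr(matrix(exp(rnorm(m * t, 6, 1)), m, t))
}

writeCSVFixture <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

writeLinksFile <- function(records,
                           header = "protein1 protein2 combined_score") {
  f <- tempfile(fileext = ".txt")
  writeLines(c(header, records), f)
  f
}

writeIdMapFile <- function(genes, proteins) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tprotein", paste(genes, proteins, sep = "\t")), f)
  f
}

# small planted dataset reused across files (cached per session)
smallPlanted <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generatePlantedDataset(m = 400, t = 4, nStable = 40,
                                       nDeviating = 40, seed = 11L)
    cache
  }
})
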