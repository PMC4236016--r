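decompPlanted <- function() {
  sim <- smallPlanted()
  list(sim = sim, d = surprisalDecompose(logTransform(sim$expression)))
}

twoGeneHeatmap <- function(gvals, genes = c("A", "B")) {
  v <- outer(gvals, gvals)
  dimnames(v) <- list(genes, genes)
  new("Heatmap", values = v, source = "theoretical", pattern = 0L)
}

test_that("product heatmaps are the signed outer product of the weight sub-vector", {
  d <- decompPlanted()$d
  genes <- geneNames(d)[1:6]
  h <- productHeatmap(d, 1, genes)
  g <- patternWeights(d)[genes, 2]
  expect_equal(exprValues(h), outer(g, g))
  expect_identical(geneNames(h), genes)
  expect_identical(h@source, "theoretical")

  # analytic 2 x 2 cases
  d2 <- d; d2@G[1:2, 2] <- c(1, -1)
  h2 <- productHeatmap(d2, 1, geneNames(d)[1:2])
  expect_equal(unname(exprValues(h2)), cbind(c(1, -1), c(-1, 1)))
  d2@G[1:2, 1] <- c(-2, -3)
  h3 <- productHeatmap(d2, 0, geneNames(d)[1:2])
  expect_equal(unname(exprValues(h3))[1, 2], 6)  # stable x stable > 0

  expect_error(productHeatmap(d, 0, c(genes, "NOPE")), "NOPE")
})

test_that("product heatmaps are symmetric and exactly rank 1", {
  d <- decompPlanted()$d
  sel <- selectExtremes(d, 0, 25, "most_negative")
  h <- productHeatmap(d, 0, sel)
  v <- exprValues(h)
  expect_identical(v, t(v))
  sv <- svd(v)$d
  expect_lt(sv[2], 1e-10 * sv[1])
})

test_that("pairing reindexes connectivity to the theoretical axis", {
  h <- twoGeneHeatmap(c(0.5, -0.25), genes = c("A", "B"))
  v <- matrix(c(NA, 0.7, 0.7, NA), 2, 2,
              dimnames = list(c("B", "A"), c("B", "A")))
  cm <- new("ConnectivityMatrix", values = v)
  p <- pairHeatmaps(h, cm)
  expect_identical(rownames(exprValues(p@experimental)), c("A", "B"))
  expect_equal(exprValues(p@experimental)["A", "B"], 0.7)

  # identical ordering passes through unchanged
  cm2 <- new("ConnectivityMatrix",
             values = matrix(c(NA, 0.4, 0.4, NA), 2, 2,
                             dimnames = list(c("A", "B"), c("A", "B"))))
  p2 <- pairHeatmaps(h, cm2)
  expect_identical(exprValues(p2@experimental), exprValues(cm2))

  # permutation oracle on a larger random matrix
  set.seed(3)
  genes <- paste0("g", 1:8)
  M <- matrix(runif(64), 8, 8); M <- (M + t(M)) / 2; diag(M) <- NA
  dimnames(M) <- list(genes, genes)
  perm <- sample(genes)
  cm3 <- new("ConnectivityMatrix", values = M[perm, perm])
  d <- decompPlanted()$d
  th <- productHeatmap(d, 0, geneNames(d)[1:8])
  th@values <- th@values[]; rownames(th@values) <- genes
  colnames(th@values) <- genes
  p3 <- pairHeatmaps(th, cm3)
  expect_equal(exprValues(p3@experimental), M)

  # gene-set mismatch names the difference
  cmMiss <- new("ConnectivityMatrix",
                values = M[perm[-1], perm[-1]])
  expect_error(pairHeatmaps(th, cmMiss), perm[1])
})

test_that("cell lookup returns the crossing genes and the stored value", {
  h <- twoGeneHeatmap(c(1, -1))
  ci <- cellInfo(h, "A", "B")
  expect_identical(ci$gene_row, "A")
  expect_equal(ci$value, -1)
  expect_false(ci$missing)

  cm <- new("ConnectivityMatrix",
            values = matrix(c(NA, 0.5, 0.5, NA), 2, 2,
                            dimnames = list(c("A", "B"), c("A", "B"))))
  hd <- asHeatmap(cm)
  diagCell <- cellInfo(hd, "A", "A")
  expect_true(diagCell$missing)

  set.seed(8)
  i <- sample(geneNames(h), 1); j <- sample(geneNames(h), 1)
  expect_equal(cellInfo(h, i, j)$value, exprValues(h)[i, j])
  expect_error(cellInfo(h, "A", "Z"), "Z")
})

test_that("the stability scatter separates planted stable from deviating genes", {
  x <- decompPlanted()
  sc <- stabilityScatter(x$d)
  expect_identical(nrow(sc), 400L)
  expect_identical(sc$gene, geneNames(x$d))
  roles <- x$sim$truth@roles
  stable <- sc[roles == "stable", ]
  dev <- sc[roles == "deviating", ]
  expect_gt(mean(abs(stable$G0)), mean(abs(dev$G0)))
  expect_gt(mean(abs(dev$G1)), 5 * mean(abs(stable$G1)))

  d1 <- x$d
  d1@G <- d1@G[, 1, drop = FALSE]
  d1@lambda <- d1@lambda[1, 1, drop = FALSE]
  d1@omega <- d1@omega[1]
  expect_error(stabilityScatter(d1), "t >= 2")
})

test_that("heatmap correlation is 1 on identity, -1 on negation, and matches a rank oracle", {
  set.seed(19)
  n <- 7
  genes <- paste0("g", 1:n)
  M <- matrix(rnorm(n * n), n, n); M <- M + t(M); diag(M) <- 0
  dimnames(M) <- list(genes, genes)
  hA <- new("Heatmap", values = M, source = "theoretical", pattern = 0L)

  same <- new("HeatmapPair", theoretical = hA,
              experimental = new("Heatmap", values = M, source = "string_db",
                                 pattern = NA_integer_))
  expect_equal(correlateHeatmaps(same)$correlation, 1.0)

  neg <- new("HeatmapPair", theoretical = hA,
             experimental = new("Heatmap", values = -M, source = "string_db",
                                pattern = NA_integer_))
  expect_equal(correlateHeatmaps(neg)$correlation, -1.0)

  # random pair with missing cells vs brute-force rank correlation
  B <- matrix(rnorm(n * n), n, n); B <- B + t(B)
  B[1, 3] <- B[3, 1] <- NA; diag(B) <- NA
  dimnames(B) <- list(genes, genes)
  pair <- new("HeatmapPair", theoretical = hA,
              experimental = new("Heatmap", values = B, source = "string_db",
                                 pattern = NA_integer_))
  got <- correlateHeatmaps(pair)
  ut <- upper.tri(M)
  x <- M[ut]; y <- B[ut]
  ok <- !is.na(x) & !is.na(y)
  oracle <- cor(rank(x[ok]), rank(y[ok]))   # Spearman from first principles
  expect_equal(got$correlation, oracle, tolerance = 1e-12)
  expect_identical(got$n_cells, sum(ok))

  # too few shared cells
  C <- B; C[] <- NA
  dimnames(C) <- list(genes, genes)
  sparse <- new("HeatmapPair", theoretical = hA,
                experimental = new("Heatmap", values = C, source = "string_db",
                                   pattern = NA_integer_))
  expect_error(correlateHeatmaps(sparse), "at least 3")
})

test_that("a planted stable connectivity block correlates positively with theory", {
  x <- decompPlanted()
  d <- x$d
  st <- selectExtremes(d, 0, 40, "most_negative")
  dv <- selectExtremes(d, 1, 40, "largest_magnitude")
  axis <- combinedAxis(st, dv)
  fx <- generateLinksFixture(x$sim$truth, withinStableScore = 0.9,
                             backgroundScore = 0.15, density = 0.8,
                             seed = 23L)
  cm <- buildScoreMatrix(parseStringLinks(fx$links, readIdMap(fx$id_map)),
                         axis)
  pair <- pairHeatmaps(productHeatmap(d, 0, axis), cm)
  r <- correlateHeatmaps(pair)
  expect_gt(r$correlation, 0)
  expect_gte(r$n_cells, 3L)
})

test_that("combined axes put the stable block first in the documented order", {
  x <- decompPlanted()
  st <- selectExtremes(x$d, 0, 10, "most_negative")
  dv <- selectExtremes(x$d, 1, 10, "most_positive")
  axis <- combinedAxis(st, dv)
  expect_length(axis, 20)
  expect_identical(axis[1], st@genes[which.min(st@values)])
  g1 <- patternWeights(x$d)[axis[11:20], 2]
  expect_false(is.unsorted(rev(g1)))
})

test_that("heatmap TSV serialization round-trips values and missing markers", {
  x <- decompPlanted()
  h <- productHeatmap(x$d, 1, geneNames(x$d)[3:8])
  f <- tempfile(fileext = ".tsv")
  writeHeatmapTSV(h, f)
  h2 <- readHeatmapTSV(f)
  expect_identical(exprValues(h2), exprValues(h))
  expect_identical(h2@source, "theoretical")
  expect_identical(h2@pattern, 1L)

  v <- matrix(c(NA, 0.5, 0.5, NA), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  hc <- new("Heatmap", values = v, source = "string_db",
            pattern = NA_integer_)
  f2 <- tempfile(fileext = ".tsv")
  writeHeatmapTSV(hc, f2)
  h3 <- readHeatmapTSV(f2)
  expect_identical(exprValues(h3), v)
  expect_identical(h3@source, "string_db")
})
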