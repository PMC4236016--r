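#' @include AllClasses.R
NULL

#' Generate an expression matrix with planted surprisal structure
#'
#' Builds a log-expression matrix as a rank-2 planted model plus noise,
#' \deqn{\ln X = u_0 p_0^\top + u_1 p_1^\top + \varepsilon,}
#' then exponentiates. The steady-state component \eqn{u_0 p_0^\top} is
#' large and positive for every gene: baselines are ~6 nat (signal ~400)
#' for background and deviating genes and ~9 nat for the planted stable
#' group, whose transcripts are the highly expressed, housekeeping-like
#' ones; the profile \eqn{p_0} is nearly constant across conditions — the
#' balanced state persists through all stages. The deviation component
#' touches only the planted deviating genes (half up-, half down-regulated,
#' `deviationAmplitude` nat each) along a monotone, mean-centered profile
#' \eqn{p_1} mimicking progressive transformation. Noise is additive
#' i.i.d. Gaussian on the log scale (multiplicative on signals), keeping
#' values positive. \eqn{u_1} is orthogonalized against \eqn{u_0} inside
#' the deviating support and \eqn{p_1} against \eqn{p_0}, so the normalized
#' planted components are exactly the noise-free SVD factors and recovery
#' can be scored by a plain cosine.
#'
#' @param m number of genes (default 2000).
#' @param t number of conditions (default 4), t >= 2.
#' @param nStable,nDeviating sizes of the planted groups (default 100 each);
#'   `nStable + nDeviating <= m`.
#' @param deviationAmplitude per-gene weight of the deviation component, in
#'   nat (default 4; peak-to-peak log change `deviationAmplitude` across the
#'   series, about a 7-fold shift at the extremes).
#' @param noiseSd log-scale noise standard deviation (default 0.05).
#' @param seed integer seed; the dataset is a pure function of the arguments.
#' @return A list with `expression` ([ExpressionMatrix-class]) and `truth`
#'   ([PlantedTruth-class]). Gene roles are assigned to shuffled positions.
#' @examples
#' sim <- generatePlantedDataset(m = 300, nStable = 30, nDeviating = 30,
#'                               seed = 7L)
#' sim$truth
#' @export
generatePlantedDataset <- function(m = 2000L, t = 4L, nStable = 100L,
                                   nDeviating = 100L,
                                   deviationAmplitude = 4,
                                   noiseSd = 0.05, seed) {
  stopifnot(m >= 1L, t >= 2L, nStable >= 0L, nDeviating >= 0L,
            nStable + nDeviating <= m,
            deviationAmplitude > 0, noiseSd >= 0,
            is.numeric(seed), length(seed) == 1L)
  if (nDeviating == 1L)
    stop("nDeviating must be 0 or at least 2 (one up- and one down-regulated ",
         "gene are needed for an orthogonal deviation component)")
  seed <- as.integer(seed)
  set.seed(seed)

  genes <- sprintf("GENE%05d", seq_len(m))
  conds <- sprintf("T%d", seq_len(t))
  roles <- rep("background", m)
  slots <- sample.int(m, nStable + nDeviating)
  stable <- slots[seq_len(nStable)]
  deviating <- slots[nStable + seq_len(nDeviating)]
  roles[stable] <- "stable"
  roles[deviating] <- "deviating"

  u0 <- stats::rnorm(m, 6, 0.6)
  u0[stable] <- stats::rnorm(nStable, 9, 0.2)
  u0 <- pmax(u0, 1)                       # keep every baseline well positive

  u1 <- numeric(m)
  if (nDeviating > 0L) {
    u1[deviating] <- rep_len(c(1, -1), nDeviating) * deviationAmplitude
    # exact orthogonality to u0 without touching non-deviating entries
    u1[deviating] <- u1[deviating] -
      sum(u0[deviating] * u1[deviating]) / sum(u0[deviating]^2) * u0[deviating]
  }

  p0 <- 1 + 0.01 * seq_len(t) / t         # near-constant balanced profile
  p1 <- seq(-0.5, 0.5, length.out = t)    # monotone transformation profile
  p1 <- p1 - sum(p1 * p0) / sum(p0^2) * p0

  L <- outer(u0, p0) + outer(u1, p1) +
    matrix(stats::rnorm(m * t, 0, noiseSd), m, t)
  dimnames(L) <- list(genes, conds)

  if (nDeviating > 0L) {
    trueG <- cbind(u0 / sqrt(sum(u0^2)), u1 / sqrt(sum(u1^2)))
    trueLambda <- rbind(sqrt(sum(u0^2)) * p0, sqrt(sum(u1^2)) * p1)
    patNames <- c("pattern0", "pattern1")
  } else {
    trueG <- cbind(u0 / sqrt(sum(u0^2)))
    trueLambda <- rbind(sqrt(sum(u0^2)) * p0)
    patNames <- "pattern0"
  }
  dimnames(trueG) <- list(genes, patNames)
  dimnames(trueLambda) <- list(patNames, conds)
  names(roles) <- genes

  list(expression = ExpressionMatrix(exp(L), geneNames = genes,
                                     conditionNames = conds),
       truth = new("PlantedTruth", trueG = trueG, trueLambda = trueLambda,
                   roles = roles, noiseSd = noiseSd, seed = seed))
}

#' Write a STRING-dialect links fixture for a planted dataset
#'
#' Emits a protein-links flat file (and a matching gene/protein id map) in
#' which planted stable–stable pairs carry a high combined score at the
#' requested density while a sparse background of other pairs (among the
#' labelled stable + deviating genes, at one tenth of `density`) carries a
#' low score — the structure in which the balanced-state transcripts form a
#' strongly interconnected functional network and the transformation
#' transcripts do not. Pairs not emitted end up as missing cells downstream.
#'
#' @param truth a [PlantedTruth-class].
#' @param withinStableScore probability for stable–stable links (default
#'   0.9; written as the raw integer `round(score * 1000)`).
#' @param backgroundScore probability for background links (default 0.15).
#' @param density fraction of stable–stable pairs emitted (default 1).
#' @param seed integer seed for the pair sampling.
#' @param linksPath,idMapPath output paths (defaults under `tempdir()`).
#' @return A list with `links` and `id_map` file paths.
#' @export
generateLinksFixture <- function(truth, withinStableScore = 0.9,
                                 backgroundScore = 0.15, density = 1,
                                 seed,
                                 linksPath = tempfile(fileext = ".txt"),
                                 idMapPath = tempfile(fileext = ".tsv")) {
  stopifnot(is(truth, "PlantedTruth"),
            withinStableScore >= 0, withinStableScore <= 1,
            backgroundScore >= 0, backgroundScore <= 1,
            density > 0, density <= 1,
            is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  genes <- names(truth@roles)
  labelled <- genes[truth@roles != "background"]
  stable <- genes[truth@roles == "stable"]

  prot <- function(g) paste0("PROT.", g)
  writeLines(c("gene\tprotein", paste(labelled, prot(labelled), sep = "\t")),
             idMapPath)

  pairRows <- function(gs) {
    if (length(gs) < 2L)
      return(data.frame(a = character(), b = character(),
                        stringsAsFactors = FALSE))
    idx <- utils::combn(length(gs), 2L)
    data.frame(a = gs[idx[1L, ]], b = gs[idx[2L, ]],
               stringsAsFactors = FALSE)
  }
  stablePairs <- pairRows(stable)
  keep <- stats::runif(nrow(stablePairs)) <= density
  stablePairs <- stablePairs[keep, , drop = FALSE]

  allPairs <- pairRows(labelled)
  isStable <- allPairs$a %in% stable & allPairs$b %in% stable
  bgPairs <- allPairs[!isStable, , drop = FALSE]
  keep <- stats::runif(nrow(bgPairs)) <= density / 10
  bgPairs <- bgPairs[keep, , drop = FALSE]

  rec <- rbind(
    if (nrow(stablePairs))
      cbind(stablePairs, score = round(withinStableScore * 1000)),
    if (nrow(bgPairs))
      cbind(bgPairs, score = round(backgroundScore * 1000)))
  lines <- "protein1 protein2 combined_score"
  if (!is.null(rec) && nrow(rec))
    lines <- c(lines, paste(prot(rec$a), prot(rec$b), rec$score))
  writeLines(lines, linksPath)
  list(links = linksPath, id_map = idMapPath)
}
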