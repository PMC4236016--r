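#' @include AllClasses.R
NULL

#' Natural-log transform of an expression matrix
#'
#' Elementwise natural logarithm; surprisal theory works in natural-log
#' (nat) units. The base is fixed; positivity is guaranteed upstream by the
#' read-time flooring.
#'
#' @param x an [ExpressionMatrix-class].
#' @return A [LogExpressionMatrix-class] with the same names.
#' @export
logTransform <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  v <- x@values
  if (any(v <= 0))
    stop("non-positive expression value reached logTransform; ",
         "read-time flooring was bypassed")
  new("LogExpressionMatrix", values = log(v))
}

# Deterministic sign convention, applied jointly to (G column, lambda row)
# so reconstruction is untouched:
#  * alpha = 0: steady-state weights predominantly negative (flip if the
#    column sum of G is positive), so lambda0 is negative and the product
#    G_i0 * lambda_0(T) reproduces positive log expression;
#  * alpha >= 1: the lambda entry of largest magnitude is positive, ties
#    broken toward the earliest condition.
.applySignConvention <- function(G, lam) {
  t <- ncol(G)
  if (t >= 1L && sum(G[, 1L]) > 0) {
    G[, 1L] <- -G[, 1L]
    lam[1L, ] <- -lam[1L, ]
  }
  if (t >= 2L) {
    for (a in 2:t) {
      row <- lam[a, ]
      if (all(row == 0)) next
      if (row[which.max(abs(row))] < 0) {
        G[, a] <- -G[, a]
        lam[a, ] <- -lam[a, ]
      }
    }
  }
  list(G = G, lambda = lam)
}

# Orthonormal completion of the columns of G (m x k, k < t) to t columns,
# deterministically, by Gram-Schmidt over the standard basis vectors.
.completeOrthonormal <- function(G, t) {
  m <- nrow(G)
  k <- ncol(G)
  e <- 1L
  while (k < t) {
    if (e > m) stop("cannot complete orthonormal basis")
    v <- numeric(m); v[e] <- 1
    if (k > 0L) v <- v - G %*% crossprod(G, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) {
      G <- cbind(G, as.numeric(v) / nv)
      k <- k + 1L
    }
    e <- e + 1L
  }
  G
}

.finishDecomposition <- function(G, lam, omega, genes, conds) {
  t <- length(omega)
  sgn <- .applySignConvention(G, lam)
  G <- sgn$G; lam <- sgn$lambda
  pat <- paste0("pattern", seq_len(t) - 1L)
  dimnames(G) <- list(genes, pat)
  dimnames(lam) <- list(pat, conds)
  names(omega) <- pat
  new("SurprisalDecomposition", G = G, lambda = lam, omega = omega)
}

#' @describeIn surprisalDecompose decompose a log-expression matrix.
#'
#' Factorizes the m x t natural-log expression matrix as \eqn{\ln X_i(T) =
#' \sum_{\alpha=0}^{t-1} G_{i\alpha} \lambda_\alpha(T)}. Two numerically
#' equivalent routes are provided:
#' \describe{
#'   \item{`small_matrix`}{eigendecomposes the t x t matrix \eqn{Y^\top Y}
#'     (rank at most t, the number of conditions) and back-projects to obtain
#'     the gene weights — the economical route when m is tens of thousands;}
#'   \item{`full_svd`}{thin SVD of the m x t matrix directly.}
#' }
#' Both return unit-norm orthonormal G columns, \eqn{\lambda_\alpha(T) =
#' \omega_\alpha V_{T\alpha}} with the singular value folded into lambda, and
#' a deterministic sign convention: steady-state weights \eqn{G_{i0}} sum
#' negative (stable transcripts carry the lowest, most negative \eqn{G_{i0}}),
#' and for \eqn{\alpha \ge 1} the largest-magnitude multiplier entry is
#' positive. All t patterns are retained; singular values below
#' `1e-10 * omega0` are reported as zero patterns by [effectiveRank()].
#'
#' @param method `"small_matrix"` (default) or `"full_svd"`.
#' @return A [SurprisalDecomposition-class].
#' @examples
#' x <- ExpressionMatrix(matrix(exp(rnorm(40, 6, 1)), 10, 4,
#'        dimnames = list(paste0("g", 1:10), c("K", "E", "L", "BP"))))
#' d <- surprisalDecompose(logTransform(x))
#' multipliers(d)              # 4 x 4 Lagrange multiplier matrix
#' singularValues(d)
#' @export
setMethod("surprisalDecompose", "LogExpressionMatrix",
          function(y, method = c("small_matrix", "full_svd")) {
  method <- match.arg(method)
  Y <- y@values
  m <- nrow(Y); t <- ncol(Y)
  if (t > m)
    stop("more conditions than genes (t = ", t, " > m = ", m,
         "); transpose the input so genes are rows")

  if (method == "full_svd") {
    s <- svd(Y, nu = t, nv = t)
    omega <- s$d
    G <- s$u
    lam <- t(s$v) * omega      # row alpha = omega_alpha * V[, alpha]
  } else {
    S <- crossprod(Y)                      # t x t, rank <= t
    e <- eigen(S, symmetric = TRUE)
    # eigenvalues of Y'Y that are zero in exact arithmetic surface as
    # roundoff of order eps * max; flush them so zero patterns are exact
    ev <- e$values
    nz <- ev > 1e-14 * max(ev, .Machine$double.xmin)
    omega <- sqrt(pmax(ev, 0))
    V <- e$vectors
    G <- matrix(0, m, 0L)
    if (any(nz))
      G <- sweep(Y %*% V[, nz, drop = FALSE], 2L, omega[nz], `/`)
    G <- .completeOrthonormal(G, t)
    omega[!nz] <- 0
    lam <- t(V) * omega
    lam[!nz, ] <- 0
  }
  .finishDecomposition(G, lam, omega, rownames(Y), colnames(Y))
})

#' @describeIn surprisalDecompose convenience method: log-transforms the
#'   positive expression matrix, then decomposes.
#' @export
setMethod("surprisalDecompose", "ExpressionMatrix",
          function(y, method = c("small_matrix", "full_svd")) {
  surprisalDecompose(logTransform(y), method = match.arg(method))
})

#' Number of non-negligible patterns
#'
#' Counts singular values above `tol * omega0`. The decomposition always
#' carries t patterns (a t x t multiplier matrix); this reports how many
#' rise above numerical noise — at most the rank of the input, hence at
#' most the number of conditions.
#'
#' @param d a [SurprisalDecomposition-class].
#' @param tol relative threshold (default 1e-10).
#' @return Integer count.
#' @export
effectiveRank <- function(d, tol = 1e-10) {
  stopifnot(is(d, "SurprisalDecomposition"))
  om <- d@omega
  if (max(om) == 0) return(0L)
  sum(om > tol * max(om))
}

#' Reconstruct log expression from the first k patterns
#'
#' Returns \eqn{\sum_{\alpha < k} G_{i\alpha} \lambda_\alpha(T)}. With
#' `k = 1` this is the steady-state term alone; with `k = t` it reproduces
#' the decomposed log matrix to machine precision (the factorization is
#' exact at full rank).
#'
#' @param d a [SurprisalDecomposition-class].
#' @param k number of leading patterns, 1 <= k <= t.
#' @return A [LogExpressionMatrix-class].
#' @export
reconstruct <- function(d, k) {
  stopifnot(is(d, "SurprisalDecomposition"))
  t <- ncol(d@G)
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) ||
      k < 1L || k > t)
    stop("k must be an integer in 1..", t)
  k <- as.integer(k)
  v <- d@G[, seq_len(k), drop = FALSE] %*% d@lambda[seq_len(k), , drop = FALSE]
  dimnames(v) <- list(rownames(d@G), colnames(d@lambda))
  new("LogExpressionMatrix", values = v)
}

#' Per-gene deviation from the steady-state term
#'
#' For each gene the maximum over conditions of \eqn{|\ln X_i(T) - G_{i0}
#' \lambda_0(T)|}: the largest log-fold-change left unexplained by the
#' steady state. Transcripts dominated by the balanced state — significant
#' negative \eqn{G_{i0}}, small deviation weights — have residuals near the
#' noise floor; transcripts driving the transformation patterns do not.
#'
#' @param d a [SurprisalDecomposition-class].
#' @return Named non-negative numeric vector, one value per gene, in gene
#'   order.
#' @export
steadyStateResidual <- function(d) {
  stopifnot(is(d, "SurprisalDecomposition"))
  t <- ncol(d@G)
  dev <- if (t == 1L) {
    matrix(0, nrow(d@G), ncol(d@lambda))
  } else {
    d@G[, -1L, drop = FALSE] %*% d@lambda[-1L, , drop = FALSE]
  }
  out <- apply(abs(dev), 1L, max)
  names(out) <- rownames(d@G)
  out
}

#' Write decomposition tables to a directory
#'
#' Emits three TSV tables: `G.tsv` (genes x patterns), `lambda.tsv`
#' (patterns x conditions) and `omega.tsv` (singular values). Values carry
#' 17 significant digits so [readDecomposition()] round-trips bit-exactly,
#' which is what lets a later pipeline stage be re-entered from saved
#' intermediates.
#'
#' @param d a [SurprisalDecomposition-class].
#' @param dir output directory (created if absent).
#' @return Character vector of the three file paths, invisibly.
#' @export
writeDecomposition <- function(d, dir) {
  stopifnot(is(d, "SurprisalDecomposition"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("G.tsv", "lambda.tsv", "omega.tsv"))
  .writeNamedMatrixTSV(d@G, paths[1L], corner = "gene")
  .writeNamedMatrixTSV(d@lambda, paths[2L], corner = "pattern")
  writeLines(c("pattern\tomega",
               paste(names(d@omega), sprintf("%.17g", d@omega), sep = "\t")),
             paths[3L])
  invisible(paths)
}

#' Read decomposition tables written by [writeDecomposition()]
#'
#' @param dir directory holding `G.tsv`, `lambda.tsv`, `omega.tsv`.
#' @return A [SurprisalDecomposition-class].
#' @export
readDecomposition <- function(dir) {
  G <- .readNamedMatrixTSV(file.path(dir, "G.tsv"))
  lam <- .readNamedMatrixTSV(file.path(dir, "lambda.tsv"))
  om <- utils::read.delim(file.path(dir, "omega.tsv"))
  omega <- om$omega
  names(omega) <- om$pattern
  new("SurprisalDecomposition", G = G, lambda = lam, omega = omega)
}

.writeNamedMatrixTSV <- function(v, path, corner = "gene", na = "NA") {
  rows <- vapply(seq_len(nrow(v)), function(i) {
    cells <- ifelse(is.na(v[i, ]), na, sprintf("%.17g", v[i, ]))
    paste(c(rownames(v)[i], cells), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c(corner, colnames(v)), collapse = "\t"), rows), path)
  invisible(path)
}

.readNamedMatrixTSV <- function(path, na = "NA") {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = na,
                          colClasses = c("character"))
  v <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- df[[1L]]
  v
}
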