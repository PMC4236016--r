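#' @include AllClasses.R
NULL

#' Draw a heatmap
#'
#' Theoretical maps use a diverging blue–white–red palette symmetric about
#' zero (sign encodes correlation vs anti-correlation within the pattern);
#' connectivity maps use a sequential palette on \[0, 1\]. Missing cells are
#' drawn in the reserved background colour (white), matching the
#' "no information" dots of a STRING heatmap.
#'
#' @param h a [Heatmap-class].
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return `h`, invisibly.
#' @export
plotHeatmap <- function(h, main = NULL, ...) {
  stopifnot(is(h, "Heatmap"))
  v <- h@values
  n <- nrow(v)
  if (is.null(main))
    main <- if (h@source == "theoretical")
      sprintf("G[i%d] x G[j%d] (theoretical)", h@pattern, h@pattern)
    else "STRING combined scores"
  if (h@source == "theoretical") {
    lim <- max(abs(v), na.rm = TRUE)
    if (lim == 0) lim <- 1
    brk <- seq(-lim, lim, length.out = 65L)
    col <- grDevices::hcl.colors(64L, "Blue-Red 2")
  } else {
    brk <- seq(0, 1, length.out = 65L)
    col <- grDevices::hcl.colors(64L, "YlOrRd", rev = TRUE)
  }
  graphics::image(seq_len(n), seq_len(n), t(v[n:1, , drop = FALSE]),
                  breaks = brk, col = col, axes = FALSE,
                  xlab = "", ylab = "", main = main, ...)
  graphics::box()
  invisible(h)
}

#' Draw a paired theoretical / connectivity heatmap
#'
#' Side-by-side rendering of the two members on their shared gene axis.
#'
#' @param p a [HeatmapPair-class].
#' @return `p`, invisibly.
#' @export
plotHeatmapPair <- function(p) {
  stopifnot(is(p, "HeatmapPair"))
  old <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 3, 1))
  on.exit(graphics::par(old))
  plotHeatmap(p@theoretical)
  plotHeatmap(p@experimental)
  invisible(p)
}

#' Draw the steady-state stability scatter
#'
#' \eqn{G_{i0}} against \eqn{G_{i1}} for every gene: the most stable
#' transcripts sit at the far negative end of the \eqn{G_{i0}} axis with
#' \eqn{G_{i1}} close to zero.
#'
#' @param d a [SurprisalDecomposition-class] (t >= 2).
#' @param ... passed to [graphics::plot()].
#' @return The scatter data.frame, invisibly.
#' @export
plotStabilityScatter <- function(d, ...) {
  sc <- stabilityScatter(d)
  graphics::plot(sc$G0, sc$G1, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("black", 0.5),
                 xlab = expression(G[i0]), ylab = expression(G[i1]), ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 2)
  invisible(sc)
}
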