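#' @include AllClasses.R
NULL

.pipelineDefaults <- function() {
  list(input = NA_character_, target = NA_real_,
       method = "small_matrix", pattern = 1L,
       top = 100L, bottom = 100L,
       upper = NA_real_, lower = NA_real_,
       links = NA_character_, id_map = NA_character_,
       outdir = "surprisal_out", seed = 1L,
       edge_threshold = 0.4, log_level = "info")
}

#' Read a flat key = value pipeline configuration
#'
#' One `key = value` pair per line; `#` starts a comment; unknown keys are
#' an error. Values are coerced to the type of the corresponding default.
#' Missing keys take defaults (see [runPipeline()]).
#'
#' @param path path to the config file.
#' @return Named list of pipeline settings.
#' @export
readPipelineConfig <- function(path) {
  defaults <- .pipelineDefaults()
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- defaults
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    proto <- defaults[[key]]
    cfg[[key]] <- if (is.integer(proto)) as.integer(val)
                  else if (is.numeric(proto)) as.numeric(val)
                  else val
  }
  cfg
}

#' Write a pipeline configuration
#'
#' Round-trips through [readPipelineConfig()]; `NA` entries are omitted.
#'
#' @param cfg named list as returned by [readPipelineConfig()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePipelineConfig <- function(cfg, path) {
  keep <- !vapply(cfg, function(v) length(v) == 1L && is.na(v), logical(1))
  writeLines(paste(names(cfg)[keep], "=",
                   vapply(cfg[keep], format, character(1))), path)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the sequential analysis pipeline
#'
#' Chains the four analysis stages — decomposition, gene profiling,
#' connectivity retrieval, heatmap comparison — writing every stage's output
#' under `outdir` so any later stage can be re-entered from saved
#' intermediates (the cyclical mode is simply re-invocation on those files).
#' Stages:
#' \enumerate{
#'   \item \strong{decompose}: read `input` (CSV contract; generated
#'     synthetically when `input` is `NA`), optionally scale each condition
#'     to `target` intensity, decompose by `method`, write `G.tsv`,
#'     `lambda.tsv`, `omega.tsv` and the scatter table `scatter.tsv`.
#'   \item \strong{profile}: select the `bottom` most-negative steady-state
#'     genes (the stable set) and the `top` most-positive genes of pattern
#'     `pattern` (or bound selection when `upper`/`lower` are set); write
#'     gene lists and provenance TSVs.
#'   \item \strong{connect} (when `links`/`id_map` are set): parse the
#'     STRING links file, build score matrices over both selections, export
#'     edge lists at `edge_threshold`.
#'   \item \strong{heatmap}: product heatmaps for the steady-state and
#'     deviation selections and for their combined block axis
#'     ([combinedAxis()]); when connectivity is available, paired heatmaps
#'     on identical axes plus their rank correlation (`correlation.tsv`).
#' }
#' A `manifest.tsv` of all written files with md5 checksums is produced
#' last. Any stage failure raises an error naming the stage; files already
#' written are preserved.
#'
#' @param cfg named list (see [readPipelineConfig()]) or path to a config
#'   file. Unset keys take the documented defaults.
#' @return data.frame manifest (file, md5), invisibly.
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  defaults <- .pipelineDefaults()
  miss <- setdiff(names(defaults), names(cfg))
  cfg[miss] <- defaults[miss]
  out <- cfg$outdir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  written <- character()
  note <- function(p) written <<- c(written, p)

  # -- stage: decompose ----------------------------------------------------
  d <- .stage("decompose", {
    x <- if (is.na(cfg$input)) {
      sim <- generatePlantedDataset(seed = cfg$seed)
      p <- file.path(out, "synthetic_input.csv")
      writeExpressionCSV(sim$expression, p)
      note(p)
      sim$expression
    } else {
      readExpressionCSV(cfg$input)
    }
    if (!is.na(cfg$target)) x <- scaleToTargetIntensity(x, cfg$target)
    dec <- surprisalDecompose(logTransform(x), method = cfg$method)
    for (p in writeDecomposition(dec, out)) note(p)
    if (ncol(dec@G) >= 2L) {
      p <- file.path(out, "scatter.tsv")
      utils::write.table(stabilityScatter(dec), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note(p)
    }
    dec
  })

  # -- stage: profile ------------------------------------------------------
  sels <- .stage("profile", {
    if (cfg$pattern >= ncol(d@G))
      stop("pattern ", cfg$pattern, " out of range (t = ", ncol(d@G), ")")
    stable <- selectExtremes(d, alpha = 0L, n = cfg$bottom,
                             mode = "most_negative")
    dev <- if (!is.na(cfg$upper) || !is.na(cfg$lower)) {
      selectByBounds(sortPattern(d, cfg$pattern),
                     upper = if (is.na(cfg$upper)) Inf else cfg$upper,
                     lower = if (is.na(cfg$lower)) -Inf else cfg$lower)
    } else {
      selectExtremes(d, alpha = cfg$pattern, n = cfg$top,
                     mode = "most_positive")
    }
    note(writeGeneList(stable, file.path(out, "stable_genes.txt")))
    note(writeSelectionTSV(stable, file.path(out, "stable_selection.tsv")))
    note(writeGeneList(dev, file.path(out, "deviating_genes.txt")))
    note(writeSelectionTSV(dev, file.path(out, "deviating_selection.tsv")))
    list(stable = stable, deviating = dev)
  })

  # -- stage: connect ------------------------------------------------------
  conn <- NULL
  if (!is.na(cfg$links) || !is.na(cfg$id_map)) {
    conn <- .stage("connect", {
      if (is.na(cfg$links) || !file.exists(cfg$links))
        stop("links file not found: ", cfg$links)
      if (is.na(cfg$id_map) || !file.exists(cfg$id_map))
        stop("id map not found: ", cfg$id_map)
      lk <- parseStringLinks(cfg$links, readIdMap(cfg$id_map))
      res <- lapply(sels, function(s) buildScoreMatrix(lk, s@genes))
      for (nm in names(res)) {
        e <- exportEdgeList(res[[nm]], cfg$edge_threshold)
        note(writeEdgeList(e, file.path(out, paste0(nm, "_edges.tsv"))))
      }
      res$linkTable <- lk
      res
    })
  }

  # -- stage: heatmap ------------------------------------------------------
  .stage("heatmap", {
    axis <- combinedAxis(sels$stable, sels$deviating)
    hs <- list(stable = productHeatmap(d, 0L, sels$stable),
               deviating = productHeatmap(d, cfg$pattern, sels$deviating),
               combined = productHeatmap(d, 0L, axis))
    for (nm in names(hs))
      note(writeHeatmapTSV(hs[[nm]],
                           file.path(out, paste0(nm, "_theory_heatmap.tsv"))))
    if (!is.null(conn)) {
      conn$combined <- buildScoreMatrix(conn$linkTable, axis)
      corr <- lapply(names(hs), function(nm) {
        pair <- pairHeatmaps(hs[[nm]], conn[[nm]])
        note(writeHeatmapTSV(pair@experimental,
                             file.path(out, paste0(nm, "_string_heatmap.tsv"))))
        # a block of identical scores has no rank correlation; record NA
        r <- tryCatch(suppressWarnings(correlateHeatmaps(pair)),
                      error = function(e) list(correlation = NA_real_,
                                               n_cells = 0L))
        data.frame(selection = nm, correlation = r$correlation,
                   n_cells = r$n_cells)
      })
      p <- file.path(out, "correlation.tsv")
      utils::write.table(do.call(rbind, corr), p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      note(p)
    }
    NULL
  })

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
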