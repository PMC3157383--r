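# Config-driven end-to-end runner: windowing, tilt/azimuth series,
# water RDFs and region metrics for a panel of variant trajectories,
# plus report writing.

.defaultRunConfig <- function() {
  list(
    variants = list(),
    tmResidues = c(490, 512),
    keyResidues = c(491, 505, 515),
    azimuthQuad = list(segment = "ICM", residues = 1:4,
                       atomName = "CA"),
    regions = list(list(label = "Box1", range = c(50, 53),
                        atomScope = "CA", segment = "ICD",
                        offset = 0)),
    window = "last 100 ns",
    strides = list(angles = 10, azimuth = 100),
    rdf = list(rMax = 15, binWidth = 0.1, normalization = "box"),
    waterCutoff = 4,
    geometryMode = "fixed-z",
    axisMethod = "curvature",
    dt = 10)
}

#' Build a run configuration
#'
#' Any field not supplied falls back to the documented default; every
#' applied default is logged by \code{\link{runAnalysis}}. Defaults
#' follow the conventional analysis choices for this system: TM
#' residues 490-512, key residues 491/505/515, analysis window = last
#' 100 ns, tilt stride 10 ps, azimuth stride 100 ps.
#'
#' @param variants list of \code{list(label=, topology=, trajectory=,
#'   dt=)} entries (dt optional, defaults to the global \code{dt}).
#' @param ... overrides of the default fields (\code{tmResidues},
#'   \code{keyResidues}, \code{azimuthQuad}, \code{regions},
#'   \code{window} (either \code{"last N ns"} or \code{c(start, end)}
#'   in ps), \code{strides}, \code{rdf}, \code{waterCutoff},
#'   \code{geometryMode}, \code{axisMethod}, \code{dt}).
#' @return a run-configuration list.
#' @export
runConfig <- function(variants, ...) {
  cfg <- .defaultRunConfig()
  cfg$variants <- variants
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ",
                        paste(bad, collapse = ", "))
  explicit <- names(dots)
  for (nm in explicit) cfg[[nm]] <- dots[[nm]]
  attr(cfg, "explicit") <- c("variants", explicit)
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of \code{\link{runConfig}}.
#' @return a run-configuration list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$variants)) stop("config must define variants")
  do.call(runConfig, c(list(variants = y$variants),
                       y[setdiff(names(y), "variants")]))
}

.resolveWindow <- function(window, trajectory) {
  if (is.character(window)) {
    m <- regmatches(window,
                    regexec("^last\\s+([0-9.]+)\\s*ns$", window))[[1]]
    if (length(m) != 2L)
      stop("window must be c(start, end) in ps or 'last N ns'")
    lastWindow(trajectory, as.numeric(m[2]))
  } else {
    if (length(window) != 2L) stop("window must have two elements")
    as.numeric(window)
  }
}

.logSelection <- function(label, what, n) {
  message(sprintf("[%s] selection '%s': %d atom(s)", label, what, n))
}

.analyzeVariant <- function(v, cfg) {
  label <- v$label
  dt <- if (!is.null(v$dt)) v$dt else cfg$dt
  topo <- readTopology(v$topology)
  traj <- readTrajectory(topo, v$trajectory, dt = dt)
  win <- .resolveWindow(cfg$window, traj)
  message(sprintf("[%s] window (%g, %g] ps; strides %g/%g ps",
                  label, win[1], win[2], cfg$strides$angles,
                  cfg$strides$azimuth))

  caIdx <- selectAtoms(topo, atomNames = "CA",
                       residues = seq(cfg$tmResidues[1],
                                      cfg$tmResidues[2]))
  .logSelection(label, "TM Calpha", length(caIdx))
  pIdx <- selectAtoms(topo, atomNames = "P")
  .logSelection(label, "phosphorus", length(pIdx))
  wIdx <- selectWaterOxygens(topo)
  .logSelection(label, "water oxygens", length(wIdx))
  quadIdx <- selectAtoms(topo, atomNames = cfg$azimuthQuad$atomName,
                         residues = cfg$azimuthQuad$residues,
                         segment = cfg$azimuthQuad$segment)
  .logSelection(label, "azimuth quad", length(quadIdx))
  if (length(quadIdx) != 4L)
    stop(sprintf("[%s] azimuth quad must resolve to 4 atoms, got %d",
                 label, length(quadIdx)))
  if (!length(caIdx)) stop(sprintf("[%s] empty TM Calpha selection", label))

  trajTilt <- selectFrames(traj, win[1], win[2], cfg$strides$angles)
  trajAz <- selectFrames(traj, win[1], win[2], cfg$strides$azimuth)

  tiltS <- summarizeAngles(angleSeries(
    trajTilt, "tilt", caIndices = caIdx, phosphorusIndices = pIdx,
    geometryMode = cfg$geometryMode, axisMethod = cfg$axisMethod))
  azSeries <- angleSeries(trajAz, "azimuthal", quadIndices = quadIdx)
  azS <- summarizeAngles(azSeries)
  azHist <- angleHistogram(azSeries, binWidth = 10)

  rdfs <- list()
  for (res in cfg$keyResidues) {
    cbIdx <- selectAtoms(topo, atomNames = "CB", residues = res)
    if (length(cbIdx) != 1L)
      stop(sprintf("[%s] residue %d: expected one CB atom, found %d",
                   label, res, length(cbIdx)))
    r <- waterRDF(trajTilt, cbIdx, wIdx, rMax = cfg$rdf$rMax,
                  binWidth = cfg$rdf$binWidth,
                  normalization = cfg$rdf$normalization,
                  centerLabel = sprintf("CB %d", res))
    mids <- r@binEdges[-1] - cfg$rdf$binWidth / 2
    rdfs[[as.character(res)]] <-
      data.frame(variant = label, residue = res, r = mids,
                 g = r@gValues)
  }

  regionRows <- list()
  for (rg in cfg$regions) {
    rd <- regionDefinition(rg$label, rg$range,
                           if (!is.null(rg$atomScope)) rg$atomScope
                           else "heavy")
    idx <- resolveRegion(topo, rd,
                         offset = if (!is.null(rg$offset)) rg$offset else 0,
                         segment = rg$segment)
    .logSelection(label, paste0("region ", rg$label), length(idx))
    ms <- regionMetricSeries(trajTilt, idx, pIdx,
                             waterIndices = if (length(wIdx)) wIdx
                                            else NULL,
                             cutoff = cfg$waterCutoff,
                             geometryMode = cfg$geometryMode)
    regionRows[[rg$label]] <- data.frame(
      variant = label, region = rg$label,
      meanMinDistance = mean(ms$minMembraneDistance),
      meanExposure = mean(ms$hydrationCount),
      n = nrow(ms))
  }

  list(
    tilt = data.frame(variant = label, mean = tiltS@linearMean,
                      sd = tiltS@linearSD, n = tiltS@n),
    azimuth = data.frame(variant = label,
                         circularMean = azS@circularMean,
                         linearMean = azS@linearMean,
                         circularSD = azS@circularSD,
                         resultantLength = azS@resultantLength,
                         weaklyConcentrated = azS@weaklyConcentrated,
                         n = azS@n),
    azimuthHistogram = cbind(variant = label, azHist),
    rdf = do.call(rbind, rdfs),
    regions = if (length(regionRows)) do.call(rbind, regionRows)
              else NULL)
}

#' Run the full analysis over a panel of variants
#'
#' Deterministic given its inputs (the analysis draws no random
#' numbers). Each variant's trajectory is windowed and strided, then
#' the tilt table, azimuth table and histograms, water RDF curves for
#' the key residues, and region membrane-contact/exposure metrics are
#' computed. Every applied default and resolved selection size is
#' logged via \code{message()}.
#'
#' @param config a run configuration (\code{\link{runConfig}}, a YAML
#'   path, or a bare list with the same fields).
#' @param keepGoing when TRUE, a failing variant is reported as a
#'   warning and skipped instead of aborting the run.
#' @return a report list with elements \code{tiltTable},
#'   \code{azimuthTable}, \code{azimuthHistograms}, \code{rdfCurves},
#'   \code{regionMetrics} (data.frames), and \code{config}.
#' @export
runAnalysis <- function(config, keepGoing = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- .defaultRunConfig()
  cfg[names(config)] <- config
  explicit <- attr(config, "explicit")
  if (!is.null(explicit)) {
    defaulted <- setdiff(names(cfg), explicit)
    if (length(defaulted))
      message("defaults applied: ", paste(defaulted, collapse = ", "))
  }
  if (!length(cfg$variants)) stop("config defines no variants")
  labels <- vapply(cfg$variants, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicate variant labels in config")
  results <- list()
  for (v in cfg$variants) {
    res <- if (keepGoing)
      tryCatch(.analyzeVariant(v, cfg), error = function(e) {
        warning(sprintf("variant '%s' failed: %s", v$label,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    else .analyzeVariant(v, cfg)
    if (!is.null(res)) results[[v$label]] <- res
  }
  if (!length(results)) stop("no variant could be analysed")
  rbindField <- function(field)
    do.call(rbind, c(lapply(results, `[[`, field),
                     list(make.row.names = FALSE)))
  list(tiltTable = rbindField("tilt"),
       azimuthTable = rbindField("azimuth"),
       azimuthHistograms = rbindField("azimuthHistogram"),
       rdfCurves = rbindField("rdf"),
       regionMetrics = rbindField("regions"),
       config = cfg)
}

#' Write a report to disk
#'
#' One TSV per table (angles printed with 1 decimal, g(r) with 4) plus
#' a full-precision JSON mirror and a manifest listing every written
#' file with its MD5 checksum.
#'
#' @param report the list returned by \code{\link{runAnalysis}}.
#' @param outDir output directory (created if needed).
#' @param formats subset of \code{c("tsv", "json")}.
#' @return data.frame manifest (file, md5), invisibly; also written as
#'   \code{manifest.tsv}.
#' @export
writeReport <- function(report, outDir, formats = c("tsv", "json")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  fmt <- function(df, cols, digits) {
    for (cl in intersect(cols, names(df)))
      df[[cl]] <- formatC(df[[cl]], format = "f", digits = digits)
    df
  }
  if ("tsv" %in% formats) {
    tables <- list(
      tilt_table.tsv = fmt(report$tiltTable, c("mean", "sd"), 1),
      azimuth_table.tsv = fmt(report$azimuthTable,
                              c("circularMean", "linearMean",
                                "circularSD"), 1),
      azimuth_histograms.tsv = report$azimuthHistograms,
      rdf_curves.tsv = fmt(report$rdfCurves, "g", 4),
      region_metrics.tsv = report$regionMetrics)
    for (nm in names(tables)) {
      if (is.null(tables[[nm]])) next
      p <- file.path(outDir, nm)
      utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, p)
    }
  }
  if ("json" %in% formats) {
    p <- file.path(outDir, "report.json")
    jsonlite::write_json(
      report[c("tiltTable", "azimuthTable", "azimuthHistograms",
               "rdfCurves", "regionMetrics")],
      p, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    written <- c(written, p)
  }
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
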