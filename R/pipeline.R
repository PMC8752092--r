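# End-to-end orchestration: simulate -> drift-correct -> segment ->
# calibrate -> count -> report, with optional on-disk artifacts.

#' Run the full counting pipeline on a synthetic field
#'
#' Generates a ground-truth synapse population and a PALM acquisition from
#' it, estimates and corrects lateral drift, segments synaptic clusters
#' and extrasynaptic calibration complexes, calibrates the photophysics,
#' converts detections to receptor numbers and densities, and summarizes
#' the population. With \code{outDir} set, all tabular artifacts (CSV),
#' structured results (JSON) and a run manifest (configuration echo, seed,
#' package version) are written there; re-running with the same seed
#' produces byte-identical outputs.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param counting a \linkS4class{CountingConfig}.
#' @param segmentationArgs named list of overrides passed to
#'   \code{\link{segmentSynapticClusters}} (its calibrated defaults are
#'   used otherwise).
#' @param drift logical: estimate and correct drift (default TRUE).
#' @param outDir optional output directory.
#' @param verbose logical progress messages.
#' @return list with field, trace, corrected (table), clusters (counted
#'   \linkS4class{SynapticClusterSet}), complexes, calibration, summary
#'   (of receptor numbers) and densityReport.
#' @examples
#' \donttest{
#' res <- runPipeline(simulationConfig("dorsal-2mo", nSynapses = 50,
#'                                     seed = 2))
#' res$summary$median
#' }
#' @export
runPipeline <- function(config, counting = countingConfig(),
                        segmentationArgs = list(), drift = TRUE,
                        outDir = NULL, verbose = FALSE) {
    say <- function(...) if (verbose) message(...)
    say("simulating ", config@nSynapses, " synapses (preset ",
        config@preset, ")")
    pop <- makeSynapsePopulation(config)
    field <- simulateLocalizations(pop)
    tab <- field@locs
    trace <- NULL
    if (drift) {
        say("estimating drift")
        trace <- estimateDrift(tab)
        tab <- correctDrift(tab, trace)
    }
    say("segmenting ", nDetections(tab), " detections")
    clusters <- do.call(segmentSynapticClusters,
                        c(list(tab), segmentationArgs))
    complexes <- detectExtrasynapticComplexes(tab, clusters)
    say(nrow(clusters@clusters), " synaptic clusters, ",
        nrow(complexes@complexes), " extrasynaptic complexes")
    calib <- calibratePhotophysics(complexes, tab, counting,
                                   nFrames = config@nFrames)
    clusters <- countReceptors(clusters, calib, counting)
    cl <- clusterTable(clusters)
    summary <- if (nrow(cl)) summarizePopulation(cl$receptors) else NULL
    densityReport <- if (nrow(cl) >= 3)
        densityVsArea(cl) else NULL
    res <- list(field = field, trace = trace, corrected = tab,
                clusters = clusters, complexes = complexes,
                calibration = calib, summary = summary,
                densityReport = densityReport)
    if (!is.null(outDir)) writePipelineArtifacts(res, config, outDir)
    res
}

writePipelineArtifacts <- function(res, config, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeLocalizations(res$corrected,
                       file.path(outDir, "localizations.csv"))
    writeClusters(res$clusters, file.path(outDir, "clusters.csv"))
    writeCalibration(res$calibration,
                     file.path(outDir, "calibration.json"))
    if (!is.null(res$trace)) {
        tr <- driftTrace(res$trace)
        data.table::fwrite(
            data.frame(frame = tr$frame, dx_nm = tr$dx, dy_nm = tr$dy),
            file.path(outDir, "drift.csv"))
    }
    if (!is.null(res$summary)) {
        s <- res$summary
        jsonlite::write_json(
            list(n = s$n, median = s$median, q1 = s$q1, q3 = s$q3,
                 mean = s$mean, sd = s$sd, cv = s$cv,
                 density = if (!is.null(res$densityReport)) list(
                     spearman = res$densityReport$spearman,
                     slope = res$densityReport$regression$slope,
                     mean = mean(clusterTable(res$clusters)$density))
                 else NULL),
            file.path(outDir, "summary.json"), auto_unbox = TRUE,
            digits = NA, null = "null")
    }
    cfg <- configAsList(config)
    manifest <- list(
        package = "glyrPALM",
        version = as.character(utils::packageVersion("glyrPALM")),
        seed = config@seed, config = cfg)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(outDir)
}

configAsList <- function(config) {
    sn <- slotNames(config)
    out <- lapply(sn, function(s) {
        v <- slot(config, s)
        if (is.data.frame(v)) as.list(v) else v
    })
    names(out) <- sn
    out
}
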