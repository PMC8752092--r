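# Accessors and show methods.

#' Localization data as a data.frame
#' @param object a \linkS4class{LocalizationTable}.
#' @return data.frame with columns frame, x, y, intensity, sigma.
#' @export
locData <- function(object) {
    stopifnot(is(object, "LocalizationTable"))
    object@data
}

#' Number of detections
#' @param object a \linkS4class{LocalizationTable}.
#' @return integer count of rows.
#' @export
nDetections <- function(object) nrow(locData(object))

#' Field size in nm
#' @param object a \linkS4class{LocalizationTable} or
#'   \linkS4class{SynapsePopulation}.
#' @return numeric(2), field extent in nm.
#' @export
fieldSize <- function(object) object@fieldSize

#' Per-cluster table of a segmentation result
#' @param object a \linkS4class{SynapticClusterSet} or
#'   \linkS4class{ExtrasynapticComplexSet}.
#' @return data.frame, one row per cluster/complex.
#' @export
clusterTable <- function(object) {
    if (is(object, "SynapticClusterSet")) object@clusters
    else if (is(object, "ExtrasynapticComplexSet")) object@complexes
    else stop("no cluster table for this class")
}

#' Ground-truth synapse records
#' @param object a \linkS4class{SynapsePopulation} or
#'   \linkS4class{SyntheticField}.
#' @return list of per-synapse records.
#' @export
synapses <- function(object) {
    if (is(object, "SyntheticField")) object@population@synapses
    else object@synapses
}

#' Detection probability of a calibration
#' @param object a \linkS4class{PhotophysicsCalibration}.
#' @param corrected if TRUE (default) the blink-model corrected functional
#'   fraction, else the raw estimator 2*N2/(N1+2*N2).
#' @return numeric probability.
#' @export
pDet <- function(object, corrected = TRUE) {
    stopifnot(is(object, "PhotophysicsCalibration"))
    if (corrected) object@pDet else object@pdetRaw
}

#' Mean detections per fluorophore of a calibration
#' @param object a \linkS4class{PhotophysicsCalibration}.
#' @param corrected if TRUE (default) the blink-model corrected mean
#'   detections per fluorophore, else the raw mean detections per burst.
#' @return numeric mean.
#' @export
detectionsPerFluor <- function(object, corrected = TRUE) {
    stopifnot(is(object, "PhotophysicsCalibration"))
    if (corrected) object@detectionsPerFluor
    else object@meanDetectionsPerBurst
}

#' Per-frame drift of a trace
#' @param object a \linkS4class{DriftTrace}.
#' @return data.frame frame, dx, dy (nm).
#' @export
driftTrace <- function(object) {
    stopifnot(is(object, "DriftTrace"))
    data.frame(frame = object@frame, dx = object@dx, dy = object@dy)
}

setMethod("show", "LocalizationTable", function(object) {
    cat("LocalizationTable:", nrow(object@data), "detections,",
        object@nFrames, "frames, field",
        paste(round(object@fieldSize / 1000, 2), collapse = " x "),
        "um\n")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig preset '", object@preset, "': ",
        object@nSynapses, " synapses, median ", object@copyNumberMedian,
        " receptors, packing ", object@packingDensity, " / um^2\n",
        sep = "")
})

setMethod("show", "SynapsePopulation", function(object) {
    n <- length(object@synapses)
    cts <- vapply(object@synapses, `[[`, numeric(1), "trueCount")
    cat("SynapsePopulation:", n, "synapses")
    if (n) cat(", median true count", stats::median(cts))
    cat("\n")
})

setMethod("show", "SyntheticField", function(object) {
    cat("SyntheticField:", nrow(object@locs@data), "detections from",
        length(object@population@synapses), "synapses and",
        length(object@complexes), "extrasynaptic complexes\n")
})

setMethod("show", "DriftTrace", function(object) {
    cat("DriftTrace over", length(object@frame), "frames (",
        object@nAnchors, "anchors, window", object@window, "); max |d| =",
        round(max(abs(c(object@dx, object@dy))), 1), "nm\n")
})

setMethod("show", "SynapticClusterSet", function(object) {
    cat("SynapticClusterSet:", nrow(object@clusters), "clusters")
    if (nrow(object@clusters)) {
        cat(", median area",
            round(stats::median(object@clusters$area), 4), "um^2")
        if ("receptors" %in% names(object@clusters))
            cat(", median receptors",
                round(stats::median(object@clusters$receptors), 1))
    }
    cat("\n")
})

setMethod("show", "ExtrasynapticComplexSet", function(object) {
    cat("ExtrasynapticComplexSet:", nrow(object@complexes), "complexes\n")
})

setMethod("show", "PhotophysicsCalibration", function(object) {
    cat("PhotophysicsCalibration (", object@model, " model): N1 = ",
        object@N1, ", N2 = ", object@N2, ", excluded = ", object@nExcluded,
        "\n  raw: P_det = ", round(object@pdetRaw, 3),
        ", detections/burst = ", round(object@meanDetectionsPerBurst, 2),
        "\n  corrected: P_det = ", round(object@pDet, 3),
        ", detections/fluorophore = ",
        round(object@detectionsPerFluor, 2), "\n", sep = "")
})

setMethod("show", "SerialSectionStack", function(object) {
    nseg <- vapply(object@sections, length, integer(1))
    cat("SerialSectionStack:", length(object@sections), "sections (",
        sum(nseg > 0), "non-empty ), thickness", object@thickness, "nm\n")
})

setMethod("show", "FRCCurve", function(object) {
    cat("FRCCurve:", length(object@freq), "rings, threshold",
        round(object@threshold, 3), "; resolution:",
        if (object@limited) "beyond grid Nyquist (no crossing)"
        else paste0(round(object@resolution, 1), " nm"), "\n")
})
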