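#' @import methods
#' @importFrom stats approx cor fft lm coef confint median predict quantile
#'   rbinom rgeom rlnorm rnorm rpois runif sd setNames
#' @importFrom utils head tail read.csv write.csv
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' Rendering configuration for pointillist density maps
#'
#' Controls how localization tables are converted to images: the pixel size in
#' nm and the Gaussian rendering kernel. Pixels are 0-based, half-open bins
#' \code{[k*px, (k+1)*px)}. Each localization deposits unit mass, so the image
#' sum equals the number of localizations.
#'
#' The kernel sigma is expressed in pixels by default (\code{kernelUnits =
#' "px"}); the conventional value 0.01 px is effectively a delta kernel, i.e.
#' plain 2D histogramming at the pixel grid. Set \code{kernelUnits = "nm"} to
#' specify it in nanometres instead.
#'
#' @slot pixelSize numeric, pixel edge in nm (default 10).
#' @slot kernelSigma numeric, Gaussian kernel sigma (default 0.01).
#' @slot kernelUnits character, "px" or "nm".
#' @export
setClass("RenderConfig", representation(
    pixelSize = "numeric", kernelSigma = "numeric", kernelUnits = "character"
), prototype(pixelSize = 10, kernelSigma = 0.01, kernelUnits = "px"))

setValidity("RenderConfig", function(object) {
    if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
        return("pixelSize must be a single positive number")
    if (length(object@kernelSigma) != 1 || object@kernelSigma < 0)
        return("kernelSigma must be a single non-negative number")
    if (!object@kernelUnits %in% c("px", "nm"))
        return("kernelUnits must be 'px' or 'nm'")
    TRUE
})

#' Construct a RenderConfig
#'
#' @param pixelSize pixel edge in nm.
#' @param kernelSigma rendering kernel sigma.
#' @param kernelUnits units of \code{kernelSigma}: "px" or "nm".
#' @return A \linkS4class{RenderConfig} object.
#' @examples
#' renderConfig(pixelSize = 10)
#' @export
renderConfig <- function(pixelSize = 10, kernelSigma = 0.01,
                         kernelUnits = "px") {
    new("RenderConfig", pixelSize = pixelSize, kernelSigma = kernelSigma,
        kernelUnits = kernelUnits)
}

#' Simulation configuration for synthetic PALM fields
#'
#' Bundles every parameter of the synthetic-data generator: the synapse
#' population (copy-number distribution, packing density, shapes), the
#' photophysics (functional-fluorophore probability, blink-train length,
#' conversion schedule), acquisition (frames, localization precision, drift)
#' and the extrasynaptic calibration complexes.
#'
#' Presets fix the population parameters to the study conditions:
#' \describe{
#'   \item{dorsal-2mo}{median 114 receptors/synapse, packing 2000 per um^2}
#'   \item{ventral-2mo}{median 228 (= 2 x 114), packing 2000 per um^2}
#'   \item{oscillator-ventral}{median 160, packing 2000 per um^2 (reduced
#'     copy numbers at constant density)}
#'   \item{custom}{all parameters as given}
#' }
#'
#' @slot preset character preset name.
#' @slot nSynapses integer number of synapses.
#' @slot copyNumberMedian numeric median receptors per synapse.
#' @slot copyNumberCV numeric coefficient of variation of the log-normal
#'   copy-number distribution.
#' @slot packingDensity numeric receptors per um^2.
#' @slot hetTagFraction numeric probability that a beta subunit carries a
#'   functional tag (1 homozygous, 0.5 heterozygous).
#' @slot extrasynapticDensity numeric calibration complexes per um^2.
#' @slot nFrames integer movie length in frames.
#' @slot pDet numeric probability that a tagged fluorophore is functional.
#' @slot meanDetectionsPerBurst numeric mean of the (shifted-geometric)
#'   detections-per-burst distribution; one burst per fluorophore.
#' @slot burstSizeModel character "geometric" or "constant".
#' @slot localizationSigma numeric localization precision in nm.
#' @slot driftPath data.frame or NULL; piecewise-linear drift nodes with
#'   columns frame, dx, dy (nm).
#' @slot gridPitch numeric synapse placement pitch in nm.
#' @slot nBeta integer tagged beta subunits per receptor pentamer.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig", representation(
    preset = "character", nSynapses = "integer",
    copyNumberMedian = "numeric", copyNumberCV = "numeric",
    packingDensity = "numeric", hetTagFraction = "numeric",
    extrasynapticDensity = "numeric", nFrames = "integer",
    pDet = "numeric", meanDetectionsPerBurst = "numeric",
    burstSizeModel = "character", localizationSigma = "numeric",
    driftPath = "dfOrNULL", gridPitch = "numeric", nBeta = "integer",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    if (object@pDet < 0 || object@pDet > 1)
        msg <- c(msg, "pDet must be in [0, 1]")
    if (object@packingDensity <= 0)
        msg <- c(msg, "packingDensity must be > 0")
    if (object@copyNumberMedian <= 0)
        msg <- c(msg, "copyNumberMedian must be > 0")
    if (object@meanDetectionsPerBurst < 1)
        msg <- c(msg, "meanDetectionsPerBurst must be >= 1")
    if (object@nFrames < 1L)
        msg <- c(msg, "nFrames must be >= 1")
    if (object@hetTagFraction < 0 || object@hetTagFraction > 1)
        msg <- c(msg, "hetTagFraction must be in [0, 1]")
    if (!object@burstSizeModel %in% c("geometric", "constant"))
        msg <- c(msg, "burstSizeModel must be 'geometric' or 'constant'")
    if (is.null(msg)) TRUE else msg
})

#' Table of single-molecule localizations
#'
#' The pipeline's universal currency: one row per detection with the frame
#' index (1-based), coordinates in nm (origin at the field corner), the fitted
#' intensity and the localization precision in nm.
#'
#' @slot data data.frame with columns frame, x, y, intensity, sigma.
#' @slot fieldSize numeric(2), field extent in nm.
#' @slot nFrames integer, movie length in frames.
#' @export
setClass("LocalizationTable", representation(
    data = "data.frame", fieldSize = "numeric", nFrames = "integer"
))

setValidity("LocalizationTable", function(object) {
    need <- c("frame", "x", "y", "intensity", "sigma")
    if (!all(need %in% names(object@data)))
        return(paste("data must have columns:", paste(need, collapse = ", ")))
    if (length(object@fieldSize) != 2 || any(object@fieldSize <= 0))
        return("fieldSize must be two positive numbers (nm)")
    if (nrow(object@data) && any(object@data$frame < 1))
        return("frames must be >= 1")
    TRUE
})

#' Ground-truth synapse population
#'
#' A list of simulated synapses, each a list with elements \code{id},
#' \code{trueArea} (um^2), \code{outline} (list of rings, each an n x 2 matrix
#' in nm; first ring is the outer boundary, further rings are perforations),
#' \code{trueCount} (receptors), \code{positions} (receptor coordinates, nm),
#' \code{tilt} (degrees) and \code{centroid} (nm).
#'
#' @slot synapses list of per-synapse records.
#' @slot config the generating \linkS4class{SimulationConfig}.
#' @slot fieldSize numeric(2) field extent in nm.
#' @export
setClass("SynapsePopulation", representation(
    synapses = "list", config = "SimulationConfig", fieldSize = "numeric"
))

#' Synthetic PALM field with ground-truth linkage
#'
#' Output of \code{\link{simulateLocalizations}}: the localization table plus
#' full ground truth - the generating population, the extrasynaptic complexes
#' (each with position and per-fluorophore burst records), a per-detection
#' linkage table (source type, source id, fluorophore id) and the injected
#' drift truth, if any.
#'
#' @slot locs \linkS4class{LocalizationTable}.
#' @slot population \linkS4class{SynapsePopulation}.
#' @slot complexes list of ground-truth complex records.
#' @slot linkage data.frame, one row per detection: source ("synapse" or
#'   "complex"), sourceId, fluorId.
#' @slot driftTruth data.frame or NULL: frame, dx, dy actually applied.
#' @export
setClass("SyntheticField", representation(
    locs = "LocalizationTable", population = "SynapsePopulation",
    complexes = "list", linkage = "data.frame", driftTruth = "dfOrNULL"
))

#' Per-frame lateral drift trace
#'
#' Displacement (dx, dy, nm) for every frame in \code{[1, nFrames]}, obtained
#' by anchor-based estimation (\code{\link{estimateDrift}}) or supplied
#' directly. The trace is defined up to a global offset; by convention the
#' first window is the reference.
#'
#' @slot frame integer vector 1..nFrames.
#' @slot dx,dy numeric per-frame displacement in nm.
#' @slot window integer window length in frames.
#' @slot nAnchors integer number of anchor clusters used.
#' @export
setClass("DriftTrace", representation(
    frame = "integer", dx = "numeric", dy = "numeric",
    window = "integer", nAnchors = "integer"
))

setValidity("DriftTrace", function(object) {
    n <- length(object@frame)
    if (length(object@dx) != n || length(object@dy) != n)
        return("frame, dx, dy must have equal length")
    if (n && !identical(object@frame, seq_len(n)))
        return("frame must be the contiguous sequence 1..nFrames")
    TRUE
})

#' Segmented synaptic clusters
#'
#' Result of \code{\link{segmentSynapticClusters}}: a per-cluster table
#' (detections, extent, area, centroid, and - once counted - receptors and
#' density), a per-detection assignment vector and the cluster footprints as
#' 0-based pixel index matrices on the rendering grid.
#'
#' @slot clusters data.frame with one row per retained cluster.
#' @slot assignment integer vector, cluster id per detection (NA outside).
#' @slot footprints list of integer matrices (columns ix, iy; 0-based pixels).
#' @slot pixelSize numeric rendering pixel size in nm.
#' @export
setClass("SynapticClusterSet", representation(
    clusters = "data.frame", assignment = "integer", footprints = "list",
    pixelSize = "numeric"
))

#' Extrasynaptic calibration complexes
#'
#' Result of \code{\link{detectExtrasynapticComplexes}}: small clusters of
#' detections outside all synapse footprints, used to calibrate the
#' photophysics (bursts per complex, detections per burst).
#'
#' @slot complexes data.frame: id, nDetections, extent, centroid.
#' @slot detectionIndices list of integer vectors into the source table.
#' @export
setClass("ExtrasynapticComplexSet", representation(
    complexes = "data.frame", detectionIndices = "list"
))

#' Photophysics calibration
#'
#' Converts detections to molecules. Stores the raw burst statistics of the
#' calibration complexes (N1 one-burst, N2 two-burst counts, the raw burst
#' mean and the raw estimator 2*N2/(N1+2*N2)) together with the blink-model
#' corrected quantities actually used for counting: \code{detectionsPerFluor}
#' (mean detections per fluorophore including singleton blinks) and
#' \code{pDet} (fraction of functional fluorophores).
#'
#' @slot N1,N2 integer counts of complexes with exactly 1 / 2 bursts.
#' @slot nExcluded integer complexes with > 2 bursts (excluded, reported).
#' @slot nComplexes integer complexes used.
#' @slot pdetRaw numeric raw estimator 2*N2/(N1+2*N2).
#' @slot meanDetectionsPerBurst numeric raw mean detections per burst.
#' @slot detectionsPerFluor numeric model-corrected detections/fluorophore.
#' @slot pDet numeric model-corrected functional fraction.
#' @slot q numeric probability that a site yields an observable burst.
#' @slot pCollision numeric estimated burst-collision probability.
#' @slot model character blink model used ("geometric" or "none").
#' @export
setClass("PhotophysicsCalibration", representation(
    N1 = "integer", N2 = "integer", nExcluded = "integer",
    nComplexes = "integer", pdetRaw = "numeric",
    meanDetectionsPerBurst = "numeric", detectionsPerFluor = "numeric",
    pDet = "numeric", q = "numeric", pCollision = "numeric",
    model = "character"
))

setValidity("PhotophysicsCalibration", function(object) {
    if (object@N1 < 0 || object@N2 < 0) return("N1, N2 must be >= 0")
    if (object@N1 + object@N2 < 1) return("N1 + N2 must be >= 1")
    if (object@pDet <= 0 || object@pDet > 1)
        return("pDet must be in (0, 1]")
    TRUE
})

#' Counting configuration
#'
#' Parameters of burst grouping and molecular conversion: the temporal gap
#' (frames) beyond which detections belong to different bursts, the minimum
#' detections per burst, the number of tagged beta subunits per receptor
#' pentamer, and which blink-model corrections the calibration applies.
#'
#' @slot gapMax integer frames (default 1000).
#' @slot minDetPerBurst integer (default 2).
#' @slot nBeta integer tagged subunits per receptor (default 2).
#' @slot blinkModel character "geometric" (default) or "none".
#' @slot collisionCorrection logical correct burst collisions (default TRUE).
#' @slot filterCorrection logical correct the minimum-detection complex
#'   filter censoring (default TRUE).
#' @slot minDetComplex integer the detection filter the complexes passed
#'   (default 5, as in segmentation).
#' @export
setClass("CountingConfig", representation(
    gapMax = "integer", minDetPerBurst = "integer", nBeta = "integer",
    blinkModel = "character", collisionCorrection = "logical",
    filterCorrection = "logical", minDetComplex = "integer"
), prototype(gapMax = 1000L, minDetPerBurst = 2L, nBeta = 2L,
    blinkModel = "geometric", collisionCorrection = TRUE,
    filterCorrection = TRUE, minDetComplex = 5L))

setValidity("CountingConfig", function(object) {
    if (object@gapMax < 1L) return("gapMax must be >= 1")
    if (object@nBeta < 1L) return("nBeta must be >= 1")
    if (!object@blinkModel %in% c("geometric", "none"))
        return("blinkModel must be 'geometric' or 'none'")
    TRUE
})

#' Construct a CountingConfig
#'
#' @param gapMax burst-splitting gap in frames.
#' @param minDetPerBurst minimum detections per burst.
#' @param nBeta tagged beta subunits per receptor.
#' @param blinkModel "geometric" or "none".
#' @param collisionCorrection logical.
#' @param filterCorrection logical.
#' @param minDetComplex the minimum-detection filter applied to complexes.
#' @return A \linkS4class{CountingConfig}.
#' @examples
#' countingConfig(gapMax = 1000)
#' @export
countingConfig <- function(gapMax = 1000, minDetPerBurst = 2, nBeta = 2,
                           blinkModel = "geometric",
                           collisionCorrection = TRUE,
                           filterCorrection = TRUE, minDetComplex = 5) {
    new("CountingConfig", gapMax = as.integer(gapMax),
        minDetPerBurst = as.integer(minDetPerBurst),
        nBeta = as.integer(nBeta), blinkModel = blinkModel,
        collisionCorrection = collisionCorrection,
        filterCorrection = filterCorrection,
        minDetComplex = as.integer(minDetComplex))
}

#' Serial-section stack of postsynaptic profiles
#'
#' Ordered EM sections; each section holds the lengths (nm) of the
#' postsynaptic membrane profile segments seen in that section (an empty
#' section has none). Postsynaptic area follows as cumulative length times
#' section thickness; the segmentation index counts in-plane and z-axis
#' interruptions.
#'
#' @slot sections list of numeric vectors (segment lengths in nm).
#' @slot thickness numeric section thickness in nm (default 70).
#' @slot tilt numeric tilt of the synapse relative to the imaging plane
#'   (degrees) or NA.
#' @slot palmArea numeric projected (PALM-like) area in um^2 or NA.
#' @export
setClass("SerialSectionStack", representation(
    sections = "list", thickness = "numeric", tilt = "numeric",
    palmArea = "numeric"
), prototype(thickness = 70, tilt = NA_real_, palmArea = NA_real_))

setValidity("SerialSectionStack", function(object) {
    if (object@thickness <= 0) return("thickness must be > 0")
    bad <- vapply(object@sections,
                  function(s) length(s) && any(s < 0), logical(1))
    if (any(bad)) return("segment lengths must be >= 0")
    TRUE
})

#' Construct a SerialSectionStack
#'
#' @param sections list of numeric vectors of profile segment lengths (nm),
#'   one element per section in z order; use \code{numeric(0)} for an empty
#'   section.
#' @param thickness section thickness in nm.
#' @param tilt synapse tilt in degrees, if known.
#' @param palmArea projected PALM area in um^2, if known.
#' @return A \linkS4class{SerialSectionStack}.
#' @examples
#' serialSectionStack(list(400, 500, 600))
#' @export
serialSectionStack <- function(sections, thickness = 70, tilt = NA_real_,
                               palmArea = NA_real_) {
    sections <- lapply(sections, as.numeric)
    new("SerialSectionStack", sections = sections, thickness = thickness,
        tilt = as.numeric(tilt), palmArea = as.numeric(palmArea))
}

#' Fourier ring correlation curve
#'
#' Correlation between two half-data reconstructions per spatial-frequency
#' ring, with the first crossing below the threshold converted to a
#' resolution in nm. If the curve never crosses the threshold the resolution
#' is NA and \code{limited} is TRUE (better than the grid's Nyquist limit).
#'
#' @slot freq numeric spatial frequencies (1/nm) at ring centers.
#' @slot frc numeric correlation per ring.
#' @slot threshold numeric crossing threshold (default 1/7).
#' @slot resolution numeric resolution in nm or NA.
#' @slot limited logical TRUE if no crossing (resolution beyond Nyquist).
#' @export
setClass("FRCCurve", representation(
    freq = "numeric", frc = "numeric", threshold = "numeric",
    resolution = "numeric", limited = "logical"
))
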