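# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (!exists(key, envir = .fixtures)) {
        assign(key, force(expr), envir = .fixtures)
    }
    get(key, envir = .fixtures)
}

# Bare localization table from coordinates.
makeTable <- function(x, y, frame = seq_along(x), fieldSize = NULL,
                      nFrames = max(frame), sigma = 9) {
    if (is.null(fieldSize)) fieldSize <- c(max(x) + 500, max(y) + 500)
    new("LocalizationTable",
        data = data.frame(frame = as.integer(frame), x = x, y = y,
                          intensity = rep(1000, length(x)),
                          sigma = rep(sigma[1], length(x))),
        fieldSize = fieldSize, nFrames = as.integer(nFrames))
}

# Standard mid-sized population run through the full pipeline.
stdRun <- function() {
    cached("stdRun", {
        cfg <- simulationConfig("dorsal-2mo", nSynapses = 500, seed = 3,
                                driftPath = linearDriftPath(80, 60, 25000))
        res <- runPipeline(cfg)
        res$match <- matchClustersToSynapses(res$clusters, res$field)
        res
    })
}

# Full acceptance-scale dorsal run.
accRun <- function() {
    cached("accRun", {
        cfg <- simulationConfig("dorsal-2mo", nSynapses = 1000, seed = 1,
                                driftPath = linearDriftPath(80, 60, 25000))
        runPipeline(cfg)
    })
}

# Field whose five brightest structures are compact, point-like dense
# clusters (fluorophore aggregates), the geometry the window-centroid CLT
# bound assumes; plus ordinary synapses as background.
pointAnchorField <- function(driftPath = NULL, seed = 9) {
    cfg <- simulationConfig("custom", nSynapses = 40, seed = seed,
                            driftPath = driftPath)
    pop <- makeSynapsePopulation(cfg)
    th <- seq(0, 2 * pi, length.out = 17)[-17]
    set.seed(seed + 500)
    for (i in 1:5) {
        cx <- 1500 + ((i - 1) %% 3) * 4000
        cy <- 1500 + ((i - 1) %/% 3) * 4000
        ring <- cbind(cx + 6 * cos(th), cy + 6 * sin(th))
        pop@synapses[[length(pop@synapses) + 1L]] <-
            groundTruthSynapse(ring, trueCount = 600, tilt = 0,
                               id = length(pop@synapses) + 1L)
    }
    simulateLocalizations(pop)
}

# Small dense field for resolution estimation at a given localization
# precision.
frcField <- function(sigma, seed = 4) {
    cfg <- simulationConfig("dorsal-2mo", nSynapses = 25,
                            gridPitch = 2000, localizationSigma = sigma,
                            seed = seed)
    simulateLocalizations(makeSynapsePopulation(cfg))
}

# RMS difference of two per-frame traces after removing the constant
# offset (drift is estimable only up to a gauge constant).
alignedRMS <- function(trace, truth) {
    ex <- trace$dx - truth$dx
    ey <- trace$dy - truth$dy
    sqrt(mean((ex - mean(ex))^2 + (ey - mean(ey))^2))
}

# Toy complex set: list of per-complex detection frame vectors, all
# detections of one complex at the same position.
complexSetFromFrames <- function(frameList, spacing = 2000) {
    n <- length(frameList)
    x <- rep(spacing * seq_len(n), lengths(frameList))
    y <- rep(500, length(x))
    tab <- makeTable(x, y, frame = unlist(frameList),
                     nFrames = max(unlist(frameList)))
    idx <- split(seq_along(x), rep(seq_len(n), lengths(frameList)))
    cs <- new("ExtrasynapticComplexSet",
              complexes = data.frame(id = seq_len(n),
                                     nDetections = lengths(frameList),
                                     extent = 0,
                                     centroidX = spacing * seq_len(n),
                                     centroidY = 500),
              detectionIndices = unname(idx))
    list(table = tab, complexes = cs)
}
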