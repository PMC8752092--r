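# Synthetic PALM data generator: synapse populations with log-normal copy
# numbers at fixed packing density, photoconvertible-fluorophore blink
# bursts over the movie, localization noise, lateral drift, extrasynaptic
# two-fluorophore calibration complexes and serial EM sections - all with
# retained ground truth so the analysis can be tested by parameter recovery.

presetDefaults <- function(preset) {
    switch(preset,
        "dorsal-2mo" = list(copyNumberMedian = 114, packingDensity = 2000),
        "ventral-2mo" = list(copyNumberMedian = 228, packingDensity = 2000),
        "oscillator-ventral" = list(copyNumberMedian = 160,
                                    packingDensity = 2000),
        "custom" = list(),
        stop("unknown preset '", preset, "'"))
}

#' Construct a SimulationConfig
#'
#' Presets fix the population parameters (see
#' \linkS4class{SimulationConfig}); all other arguments can be overridden.
#' The defaults describe a 25,000-frame acquisition with 9 nm localization
#' precision, a 60\% functional-fluorophore fraction and a mean of 6
#' detections per fluorophore blink train.
#'
#' @param preset one of "dorsal-2mo", "ventral-2mo", "oscillator-ventral",
#'   "custom".
#' @param nSynapses number of synapses.
#' @param copyNumberMedian median receptors per synapse (custom preset).
#' @param copyNumberCV coefficient of variation of the log-normal copy
#'   number distribution.
#' @param packingDensity receptors per um^2 (custom preset).
#' @param hetTagFraction probability a beta subunit carries a functional
#'   tag (1 homozygous, 0.5 heterozygous).
#' @param extrasynapticDensity calibration complexes per um^2.
#' @param nFrames movie length in frames.
#' @param pDet probability a tagged fluorophore is functional.
#' @param meanDetectionsPerBurst mean blink-train length (detections).
#' @param burstSizeModel "geometric" (shifted geometric, support >= 1) or
#'   "constant".
#' @param localizationSigma localization precision in nm.
#' @param driftPath data.frame(frame, dx, dy) of piecewise-linear drift
#'   nodes in nm, or NULL for no drift.
#' @param gridPitch synapse placement pitch in nm.
#' @param nBeta tagged beta subunits per receptor pentamer.
#' @param seed RNG seed.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' simulationConfig("dorsal-2mo", nSynapses = 100, seed = 1)
#' @export
simulationConfig <- function(preset = "custom", nSynapses = 100,
                             copyNumberMedian = 114, copyNumberCV = 0.6,
                             packingDensity = 2000, hetTagFraction = 1,
                             extrasynapticDensity = 2, nFrames = 25000,
                             pDet = 0.6, meanDetectionsPerBurst = 6,
                             burstSizeModel = "geometric",
                             localizationSigma = 9, driftPath = NULL,
                             gridPitch = 2000, nBeta = 2, seed = 1) {
    pd <- presetDefaults(preset)
    if (!is.null(pd$copyNumberMedian)) copyNumberMedian <- pd$copyNumberMedian
    if (!is.null(pd$packingDensity)) packingDensity <- pd$packingDensity
    new("SimulationConfig", preset = preset,
        nSynapses = as.integer(nSynapses),
        copyNumberMedian = copyNumberMedian, copyNumberCV = copyNumberCV,
        packingDensity = packingDensity, hetTagFraction = hetTagFraction,
        extrasynapticDensity = extrasynapticDensity,
        nFrames = as.integer(nFrames), pDet = pDet,
        meanDetectionsPerBurst = meanDetectionsPerBurst,
        burstSizeModel = burstSizeModel,
        localizationSigma = localizationSigma, driftPath = driftPath,
        gridPitch = gridPitch, nBeta = as.integer(nBeta),
        seed = as.integer(seed))
}

# One synapse outline: ellipse of the requested interior area, perforated
# with small elliptical holes with probability increasing with area
# (larger synapses are more convoluted). Holes stay strictly interior so
# the 2D projection remains singly connected.
makeOutline <- function(cx, cy, areaNm2, rng = NULL) {
    ar <- runif(1, 1, 1.6)                     # axis ratio
    th <- runif(1, 0, pi)
    areaUm2 <- areaNm2 / 1e6
    nHoles <- 0L
    pPerf <- 1 - exp(-areaUm2 / 0.15)
    if (runif(1) < pPerf) nHoles <- 1L + rpois(1, areaUm2 / 0.06)
    holeA <- if (nHoles) runif(nHoles, 25, 55) else numeric(0)  # hole radii
    holeB <- holeA * runif(max(nHoles, 1), 0.7, 1)[seq_len(nHoles)]
    holeArea <- sum(pi * holeA * holeB)
    outerArea <- areaNm2 + holeArea
    a <- sqrt(outerArea * ar / pi)
    b <- outerArea / (pi * a)
    outer <- ellipseRing(cx, cy, a, b, th)
    # discretization shrinks the polygon slightly; rescale to exact area
    sc <- sqrt(outerArea / ringArea(outer))
    outer <- cbind(cx + (outer[, 1] - cx) * sc, cy + (outer[, 2] - cy) * sc)
    rings <- list(outer)
    if (nHoles) {
        for (h in seq_len(nHoles)) {
            # place hole center well inside the outer ellipse
            repeat {
                r <- sqrt(runif(1)) * 0.6
                phi <- runif(1, 0, 2 * pi)
                hx <- r * a * cos(phi); hy <- r * b * sin(phi)
                hcx <- cx + hx * cos(th) - hy * sin(th)
                hcy <- cy + hx * sin(th) + hy * cos(th)
                margin <- max(holeA[h], holeB[h]) + 15
                if (r * min(a, b) + margin < 0.95 * min(a, b)) break
            }
            rings <- c(rings, list(
                ellipseRing(hcx, hcy, holeA[h], holeB[h],
                            runif(1, 0, pi), 24L)))
        }
    }
    rings
}

#' Generate a ground-truth synapse population
#'
#' Copy numbers are drawn log-normal with the configured median and CV;
#' each synapse's area follows from the constant packing density
#' (area = expected count / density) and the realized receptor count is
#' Poisson around that expectation. Shapes are macular (elliptical) for
#' small synapses and perforated with probability increasing with area.
#' Synapses are laid out on a jittered grid so that they never overlap.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param counts optional integer vector of forced receptor counts; when
#'   given, areas are exactly count / packingDensity and no Poisson noise
#'   is applied.
#' @return A \linkS4class{SynapsePopulation}.
#' @examples
#' pop <- makeSynapsePopulation(
#'     simulationConfig("dorsal-2mo", nSynapses = 20, seed = 1))
#' pop
#' @export
makeSynapsePopulation <- function(config, counts = NULL) {
    validObject(config)
    set.seed(config@seed)
    n <- config@nSynapses
    pitch <- config@gridPitch
    if (n <= 0) {
        return(new("SynapsePopulation", synapses = list(), config = config,
                   fieldSize = c(pitch, pitch)))
    }
    ngrid <- ceiling(sqrt(n))
    field <- c(ngrid, ceiling(n / ngrid)) * pitch
    forced <- !is.null(counts)
    if (forced) {
        stopifnot(length(counts) == n)
        lambda <- as.numeric(counts)
        cts <- as.integer(counts)
    } else {
        sdlog <- sqrt(log(1 + config@copyNumberCV^2))
        lambda <- rlnorm(n, meanlog = log(config@copyNumberMedian),
                         sdlog = sdlog)
        cts <- rpois(n, lambda)
    }
    areaNm2 <- lambda / config@packingDensity * 1e6
    cells <- sample.int(ngrid * ceiling(n / ngrid), n)
    syn <- vector("list", n)
    for (i in seq_len(n)) {
        cellx <- (cells[i] - 1) %% ngrid
        celly <- (cells[i] - 1) %/% ngrid
        cx <- cellx * pitch + pitch / 2 + runif(1, -150, 150)
        cy <- celly * pitch + pitch / 2 + runif(1, -150, 150)
        rings <- makeOutline(cx, cy, areaNm2[i])
        pos <- samplePointsInRings(cts[i], rings)
        syn[[i]] <- list(
            id = i, trueArea = ringsArea(rings) / 1e6,
            outline = rings, trueCount = cts[i], positions = pos,
            tilt = runif(1, 0, 60), centroid = c(cx, cy))
    }
    new("SynapsePopulation", synapses = syn, config = config,
        fieldSize = field)
}

#' Construct a single ground-truth synapse from an explicit outline
#'
#' Mainly for tests and worked examples where an exact geometry is needed
#' (e.g. a rectangle for serial-section arithmetic).
#'
#' @param outline a single n x 2 matrix (nm) or a list of rings (first ring
#'   the outer boundary, further rings perforations).
#' @param trueCount receptor count; default fills the outline at
#'   \code{packingDensity}.
#' @param packingDensity receptors per um^2.
#' @param tilt tilt angle in degrees.
#' @param id synapse id.
#' @return A synapse record (list) as stored in
#'   \linkS4class{SynapsePopulation}.
#' @examples
#' rect <- cbind(c(0, 1000, 1000, 0), c(0, 0, 700, 700))
#' syn <- groundTruthSynapse(rect, trueCount = 100)
#' @export
groundTruthSynapse <- function(outline, trueCount = NULL,
                               packingDensity = 2000, tilt = 0, id = 1L) {
    rings <- if (is.matrix(outline)) list(outline) else outline
    areaUm2 <- ringsArea(rings) / 1e6
    if (is.null(trueCount)) trueCount <- round(areaUm2 * packingDensity)
    pos <- samplePointsInRings(trueCount, rings)
    bb <- ringsBBox(rings)
    list(id = as.integer(id), trueArea = areaUm2, outline = rings,
         trueCount = as.integer(trueCount), positions = pos, tilt = tilt,
         centroid = c(mean(bb[1:2]), mean(bb[3:4])))
}

# Draw blink-train lengths (detections per fluorophore).
drawBurstSizes <- function(n, config) {
    m <- config@meanDetectionsPerBurst
    if (config@burstSizeModel == "constant") rep(round(m), n)
    else 1L + rgeom(n, prob = 1 / m)
}

# Emit localizations for fluorophore sites at given positions.
emitDetections <- function(pos, source, sourceId, fluorId, config) {
    nf <- nrow(pos)
    if (nf == 0) {
        return(list(det = NULL,
                    fates = data.frame(conversionFrame = integer(0),
                                       burstSize = integer(0))))
    }
    sizes <- drawBurstSizes(nf, config)
    tmax <- pmax(config@nFrames - sizes + 1L, 1L)
    t0 <- 1L + as.integer(floor(runif(nf) * tmax))
    idx <- rep.int(seq_len(nf), sizes)
    off <- sequence(sizes) - 1L
    frame <- t0[idx] + off
    det <- data.frame(
        frame = frame,
        x = pos[idx, 1] + rnorm(length(idx), 0, config@localizationSigma),
        y = pos[idx, 2] + rnorm(length(idx), 0, config@localizationSigma),
        intensity = rlnorm(length(idx), log(1000), 0.3),
        sigma = config@localizationSigma,
        source = source, sourceId = sourceId[idx], fluorId = fluorId[idx])
    list(det = det,
         fates = data.frame(conversionFrame = t0, burstSize = sizes))
}

#' Simulate a PALM acquisition from a ground-truth population
#'
#' Each receptor contributes \code{nBeta} fluorophore sites at its position;
#' each site is tagged with probability \code{hetTagFraction} and functional
#' with probability \code{pDet}. A functional fluorophore converts at a
#' frame uniform over the movie and emits exactly one blink train of
#' consecutive-frame detections whose length follows the configured
#' distribution; every detection is displaced by isotropic Gaussian
#' localization noise. Extrasynaptic two-fluorophore calibration complexes
#' are scattered uniformly outside the synapses (100 nm clearance). If the
#' configuration carries a drift path it is injected into the coordinates
#' and the per-frame truth stored.
#'
#' @param population a \linkS4class{SynapsePopulation}.
#' @param config simulation parameters; defaults to the population's own.
#' @param hetTagFraction optional override of the tag fraction.
#' @param seed optional override of the RNG seed for the acquisition
#'   (the population seed plus one by default, so that repeated
#'   acquisitions of one population are independent but reproducible).
#' @return A \linkS4class{SyntheticField}.
#' @examples
#' pop <- makeSynapsePopulation(
#'     simulationConfig("dorsal-2mo", nSynapses = 5, seed = 1))
#' fld <- simulateLocalizations(pop)
#' fld
#' @export
simulateLocalizations <- function(population, config = population@config,
                                  hetTagFraction = NULL, seed = NULL) {
    validObject(config)
    if (config@nFrames < 1) stop("nFrames must be >= 1")
    if (!is.null(hetTagFraction)) config@hetTagFraction <- hetTagFraction
    if (is.null(seed)) seed <- config@seed + 1L
    set.seed(seed)
    field <- population@fieldSize
    syn <- population@synapses
    if (!length(syn) && config@extrasynapticDensity <= 0)
        stop("population is empty and extrasynaptic density is 0")

    parts <- vector("list", 2L)
    # --- synaptic fluorophores
    if (length(syn)) {
        pos <- do.call(rbind, lapply(syn, `[[`, "positions"))
        sid <- rep.int(vapply(syn, `[[`, integer(1), "id"),
                       vapply(syn, `[[`, integer(1), "trueCount"))
        nrec <- nrow(pos)
        pos <- pos[rep(seq_len(nrec), each = config@nBeta), , drop = FALSE]
        sid <- rep(sid, each = config@nBeta)
        tagged <- runif(nrow(pos)) < config@hetTagFraction
        functional <- tagged & (runif(nrow(pos)) < config@pDet)
        keep <- which(functional)
        em <- emitDetections(pos[keep, , drop = FALSE], "synapse",
                             sid[keep], keep, config)
        parts[[1L]] <- em$det
    }
    # --- extrasynaptic complexes
    complexes <- list()
    if (config@extrasynapticDensity > 0) {
        fieldUm2 <- prod(field) / 1e6
        nCplx <- rpois(1, config@extrasynapticDensity * fieldUm2)
        if (nCplx > 0) {
            cx <- runif(3 * nCplx + 50, 0, field[1])
            cy <- runif(3 * nCplx + 50, 0, field[2])
            ok <- rep(TRUE, length(cx))
            for (s in syn) {
                bb <- ringsBBox(s$outline)
                ok <- ok & !(cx > bb["xmin"] - 100 & cx < bb["xmax"] + 100 &
                             cy > bb["ymin"] - 100 & cy < bb["ymax"] + 100)
            }
            keep <- which(ok)[seq_len(min(nCplx, sum(ok)))]
            cpos <- cbind(cx[keep], cy[keep])
            nCplx <- nrow(cpos)
            spos <- cpos[rep(seq_len(nCplx), each = config@nBeta), ,
                         drop = FALSE]
            csid <- rep(seq_len(nCplx), each = config@nBeta)
            tagged <- runif(nrow(spos)) < config@hetTagFraction
            functional <- tagged & (runif(nrow(spos)) < config@pDet)
            keepf <- which(functional)
            em <- emitDetections(spos[keepf, , drop = FALSE], "complex",
                                 csid[keepf], keepf, config)
            parts[[2L]] <- em$det
            nf <- tabulate(csid[keepf], nbins = nCplx)
            complexes <- lapply(seq_len(nCplx), function(i) {
                list(id = i, position = cpos[i, ],
                     nFluorophores = config@nBeta, nFunctional = nf[i])
            })
        }
    }
    det <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    if (is.null(det)) {
        det <- data.frame(frame = integer(0), x = numeric(0),
                          y = numeric(0), intensity = numeric(0),
                          sigma = numeric(0), source = character(0),
                          sourceId = integer(0), fluorId = integer(0))
    }
    ord <- order(det$frame)
    det <- det[ord, , drop = FALSE]
    rownames(det) <- NULL
    locs <- new("LocalizationTable",
                data = det[, c("frame", "x", "y", "intensity", "sigma")],
                fieldSize = field, nFrames = config@nFrames)
    linkage <- det[, c("source", "sourceId", "fluorId")]
    driftTruth <- NULL
    if (!is.null(config@driftPath)) {
        locs <- injectDrift(locs, config@driftPath)
        driftTruth <- pathToPerFrame(config@driftPath, config@nFrames)
    }
    new("SyntheticField", locs = locs, population = population,
        complexes = complexes, linkage = linkage, driftTruth = driftTruth)
}

# Piecewise-linear drift path -> per-frame displacement.
pathToPerFrame <- function(path, nFrames) {
    stopifnot(all(c("frame", "dx", "dy") %in% names(path)))
    if (max(path$frame) < nFrames)
        stop("drift path ends at frame ", max(path$frame),
             " but the movie has ", nFrames, " frames")
    f <- seq_len(nFrames)
    data.frame(frame = f,
               dx = approx(path$frame, path$dx, xout = f, rule = 2)$y,
               dy = approx(path$frame, path$dy, xout = f, rule = 2)$y)
}

#' Linear drift path helper
#'
#' @param dxTotal,dyTotal total displacement in nm reached at the last frame.
#' @param nFrames movie length.
#' @return data.frame(frame, dx, dy) with two nodes (zero at frame 1).
#' @examples
#' linearDriftPath(100, 60, 25000)
#' @export
linearDriftPath <- function(dxTotal, dyTotal, nFrames) {
    data.frame(frame = c(1, nFrames), dx = c(0, dxTotal),
               dy = c(0, dyTotal))
}

#' Inject lateral drift into a localization table
#'
#' Shifts every detection by the path displacement at its frame
#' (piecewise-linear interpolation between nodes). The path must cover the
#' last frame of the table.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param driftPath data.frame(frame, dx, dy) of nodes in nm.
#' @return A drifted \linkS4class{LocalizationTable}.
#' @examples
#' tab <- new("LocalizationTable",
#'     data = data.frame(frame = 1:2, x = 0, y = 0, intensity = 1,
#'                       sigma = 9),
#'     fieldSize = c(1000, 1000), nFrames = 10L)
#' injectDrift(tab, linearDriftPath(100, 0, 10))
#' @export
injectDrift <- function(table, driftPath) {
    d <- locData(table)
    if (!nrow(d)) return(table)
    pf <- pathToPerFrame(driftPath, max(table@nFrames, max(d$frame)))
    d$x <- d$x + pf$dx[d$frame]
    d$y <- d$y + pf$dy[d$frame]
    initialize(table, data = d)
}

#' Render the registered scaffold reference channel
#'
#' Produces the second-channel image (e.g. a scaffold-protein render) on the
#' same grid as \code{\link{renderDensityMap}}: each synapse's integrated
#' intensity is \code{gain} times its scaffold quantity (by default the
#' receptor count divided by \code{occupancyRatio}), spread uniformly over
#' the pixels inside its outline, plus Gaussian read noise.
#'
#' @param population a \linkS4class{SynapsePopulation}.
#' @param gain intensity per scaffold unit.
#' @param noiseSd Gaussian read-noise sd (counts/pixel).
#' @param occupancyRatio receptor/scaffold ratio linking the scaffold
#'   quantity to the receptor count.
#' @param scaffold optional explicit per-synapse scaffold quantities.
#' @param config a \linkS4class{RenderConfig}.
#' @return numeric matrix; rows index x pixels, columns y pixels (0-based
#'   pixel k covers [k*px, (k+1)*px)).
#' @examples
#' pop <- makeSynapsePopulation(
#'     simulationConfig("dorsal-2mo", nSynapses = 4, seed = 1))
#' img <- renderReferenceChannel(pop, gain = 2)
#' @export
renderReferenceChannel <- function(population, gain = 1, noiseSd = 0,
                                   occupancyRatio = 1, scaffold = NULL,
                                   config = renderConfig()) {
    if (gain <= 0) stop("gain must be > 0")
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    px <- config@pixelSize
    field <- population@fieldSize
    dims <- pmax(ceiling(field / px), 1)
    img <- matrix(0, dims[1], dims[2])
    syn <- population@synapses
    if (length(syn)) {
        if (is.null(scaffold)) {
            scaffold <- vapply(syn, `[[`, numeric(1), "trueCount") /
                occupancyRatio
        }
        for (i in seq_along(syn)) {
            rings <- syn[[i]]$outline
            bb <- ringsBBox(rings)
            ix <- seq(max(0, floor(bb["xmin"] / px)),
                      min(dims[1] - 1, ceiling(bb["xmax"] / px)))
            iy <- seq(max(0, floor(bb["ymin"] / px)),
                      min(dims[2] - 1, ceiling(bb["ymax"] / px)))
            cc <- expand.grid(ix = ix, iy = iy)
            inside <- pointInRings((cc$ix + 0.5) * px, (cc$iy + 0.5) * px,
                                   rings)
            if (!any(inside)) { # degenerate: all mass on nearest pixel
                cen <- pmin(pmax(floor(syn[[i]]$centroid / px), 0), dims - 1)
                img[cen[1] + 1, cen[2] + 1] <-
                    img[cen[1] + 1, cen[2] + 1] + gain * scaffold[i]
                next
            }
            w <- gain * scaffold[i] / sum(inside)
            sel <- cbind(cc$ix[inside] + 1, cc$iy[inside] + 1)
            img[sel] <- img[sel] + w
        }
    }
    if (noiseSd > 0) img <- img + rnorm(length(img), 0, noiseSd)
    img
}

#' Slice a synapse into serial EM sections
#'
#' The outline is cut perpendicular to its y axis into bands of width equal
#' to the section thickness; each section's profile segments are the
#' scanline intersections at the band midline (perforations split the
#' profile into several segments). The projected (PALM-like) area,
#' \code{trueArea * cos(tilt)}, is stored alongside for PALM-EM comparison.
#'
#' @param synapse a synapse record (from \code{\link{makeSynapsePopulation}}
#'   or \code{\link{groundTruthSynapse}}).
#' @param thickness section thickness in nm (default 70).
#' @param tilt tilt in degrees; defaults to the synapse's own.
#' @return A \linkS4class{SerialSectionStack}.
#' @examples
#' rect <- cbind(c(0, 1000, 1000, 0), c(0, 0, 700, 700))
#' stk <- makeSerialSections(groundTruthSynapse(rect), thickness = 70,
#'                           tilt = 0)
#' emArea(stk)
#' @export
makeSerialSections <- function(synapse, thickness = 70,
                               tilt = synapse$tilt) {
    if (thickness <= 0) stop("thickness must be > 0")
    if (is.null(tilt) || is.na(tilt)) tilt <- 0
    if (tilt < 0 || tilt >= 90) stop("tilt must be in [0, 90) degrees")
    rings <- synapse$outline
    bb <- ringsBBox(rings)
    nSec <- max(1L, ceiling((bb["ymax"] - bb["ymin"]) / thickness - 1e-9))
    sections <- lapply(seq_len(nSec), function(k) {
        ymid <- bb["ymin"] + (k - 0.5) * thickness
        scanlineSegments(rings, ymid)
    })
    new("SerialSectionStack", sections = sections, thickness = thickness,
        tilt = tilt,
        palmArea = synapse$trueArea * cos(tilt * pi / 180))
}
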