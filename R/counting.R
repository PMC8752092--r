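# Molecular counting: burst grouping, photophysics calibration from
# extrasynaptic two-fluorophore complexes, and conversion of synaptic
# detections into receptor copy numbers and packing densities.
#
# Blink model: each functional fluorophore emits one burst whose length
# (detections) is shifted-geometric, X = 1 + Geom(theta), E[X] = 1/theta.
# A burst is observable only if X >= 2, so the probability that a
# fluorophore site yields an observable burst is q = P_det * (1 - theta).
# The memorylessness of the geometric gives E[X | X >= k] = k - 1 + 1/theta,
# which makes the calibration corrections closed-form (see the vignette).

#' Group detections of one complex into bursts
#'
#' Detections are split wherever consecutive frames are more than
#' \code{gapMax} apart ("one burst per 1,000 frames" as a binning-offset
#' invariant gap rule); runs with fewer than \code{minDetPerBurst}
#' detections are discarded (a burst needs at least two detections).
#'
#' @param frames integer vector of detection frames (one complex).
#' @param config a \linkS4class{CountingConfig}.
#' @return data.frame with one row per burst: nDetections, firstFrame,
#'   lastFrame, ordered by firstFrame.
#' @examples
#' groupBursts(c(10, 11, 12, 1500, 1501))   # two bursts (gap 1488 > 1000)
#' @export
groupBursts <- function(frames, config = countingConfig()) {
    frames <- sort(as.integer(frames))
    if (!length(frames)) {
        return(data.frame(nDetections = integer(0),
                          firstFrame = integer(0),
                          lastFrame = integer(0)))
    }
    newBurst <- c(TRUE, diff(frames) > config@gapMax)
    id <- cumsum(newBurst)
    n <- tabulate(id)
    first <- frames[newBurst]
    last <- frames[c(newBurst[-1], TRUE)]
    keep <- n >= config@minDetPerBurst
    data.frame(nDetections = n[keep], firstFrame = first[keep],
               lastFrame = last[keep])
}

#' Detection-probability estimator from 1- vs 2-burst complex counts
#'
#' For two-fluorophore complexes in which each fluorophore independently
#' yields an observable burst with probability p, the numbers of observable
#' complexes showing exactly one and exactly two bursts have expectations
#' proportional to 2p(1-p) and p^2. The maximum-likelihood estimate of p
#' given N1 and N2 is \code{2*N2 / (N1 + 2*N2)}.
#'
#' @param N1 complexes with exactly one burst.
#' @param N2 complexes with exactly two bursts.
#' @return probability in (0, 1].
#' @examples
#' estimatePdet(0, 40)    # 1: both fluorophores always seen
#' estimatePdet(50, 50)   # 2/3
#' @export
estimatePdet <- function(N1, N2) {
    if (N1 < 0 || N2 < 0) stop("N1 and N2 must be non-negative")
    if (N1 + N2 == 0) stop("no observable complexes (N1 = N2 = 0)")
    2 * N2 / (N1 + 2 * N2)
}

# P(G1 + G2 <= j) for G ~ Geom(theta) on 0,1,2,... (negative binomial r=2)
pGeomSumLE <- function(j, theta) {
    if (j < 0) return(0)
    i <- 0:j
    sum((i + 1) * theta^2 * (1 - theta)^i)
}

#' Calibrate photophysics from extrasynaptic complexes
#'
#' Groups each complex's detections into bursts and tallies complexes with
#' one (N1) and two (N2) bursts; complexes with more are excluded and
#' counted. On top of the raw statistics (burst-count ratio estimator and
#' raw mean detections per burst) the calibration fits the geometric blink
#' model, correcting three selection effects that bias the raw plug-in
#' conversion:
#' \itemize{
#'  \item singleton censoring - fluorophores emitting a single detection
#'    produce no burst, so the raw burst mean is E[X | X >= 2] while
#'    synaptic detections include singletons;
#'  \item burst collisions - two fluorophores converting within
#'    \code{gapMax} of each other merge into one apparent burst, moving
#'    complexes from N2 to N1;
#'  \item the minimum-detection filter - complexes below
#'    \code{minDetComplex} detections are never segmented, censoring
#'    preferentially the single-burst complexes with short bursts.
#' }
#' The corrected outputs are \code{detectionsPerFluor} (mean detections per
#' fluorophore including singletons) and \code{pDet} (fraction of
#' functional fluorophores); with \code{blinkModel = "none"} the raw
#' quantities are passed through unchanged.
#'
#' @param complexSet an \linkS4class{ExtrasynapticComplexSet}.
#' @param table the \linkS4class{LocalizationTable} the complexes index.
#' @param config a \linkS4class{CountingConfig}.
#' @param nFrames movie length (for the collision probability); defaults
#'   to the table's.
#' @param maxBurstSeparation nm; a "2-burst complex" whose burst centroids
#'   are further apart than this is two accidentally linked neighboring
#'   complexes, not one pentamer (burst centroids of a true complex agree
#'   to a few nm), and is excluded from N1/N2.
#' @return A \linkS4class{PhotophysicsCalibration}.
#' @export
calibratePhotophysics <- function(complexSet, table,
                                  config = countingConfig(),
                                  nFrames = table@nFrames,
                                  maxBurstSeparation = 40) {
    idxList <- complexSet@detectionIndices
    if (!length(idxList)) stop("no usable calibration complexes")
    d <- locData(table)
    frames <- d$frame
    burstList <- lapply(idxList, function(i) groupBursts(frames[i], config))
    nb <- vapply(burstList, nrow, integer(1))
    # spatial consistency of 2-burst complexes
    for (ci in which(nb == 2L)) {
        b <- burstList[[ci]]
        i <- idxList[[ci]]
        f <- frames[i]
        cen <- vapply(1:2, function(k) {
            sel <- i[f >= b$firstFrame[k] & f <= b$lastFrame[k]]
            c(mean(d$x[sel]), mean(d$y[sel]))
        }, numeric(2))
        if (sqrt(sum((cen[, 1] - cen[, 2])^2)) > maxBurstSeparation)
            nb[ci] <- 99L   # flag as excluded (linked neighbors)
    }
    N1 <- sum(nb == 1L); N2 <- sum(nb == 2L)
    nExcluded <- sum(nb > 2L)
    if (N1 + N2 == 0) stop("no complexes with 1 or 2 bursts; cannot ",
                           "calibrate photophysics")
    included <- nb %in% c(1L, 2L)
    sizes1 <- unlist(lapply(burstList[nb == 1L], `[[`, "nDetections"))
    sizes2 <- unlist(lapply(burstList[nb == 2L], `[[`, "nDetections"))
    allSizes <- c(sizes1, sizes2)
    dbarRaw <- mean(allSizes)
    pdetRaw <- estimatePdet(N1, N2)

    if (config@blinkModel == "none") {
        return(new("PhotophysicsCalibration", N1 = as.integer(N1),
                   N2 = as.integer(N2), nExcluded = as.integer(nExcluded),
                   nComplexes = as.integer(sum(included)),
                   pdetRaw = pdetRaw, meanDetectionsPerBurst = dbarRaw,
                   detectionsPerFluor = dbarRaw, pDet = pdetRaw,
                   q = pdetRaw, pCollision = 0, model = "none"))
    }
    k0 <- if (config@filterCorrection) config@minDetComplex else 2L
    # theta from the burst sizes of two-burst complexes, whose joint
    # filter condition distorts them least:
    # E[X_i | X1 + X2 >= k0] = 2 + E[G]/(1 - P(G1+G2 <= k0-5))
    theta <- if (length(sizes2) >= 10) {
        u2 <- mean(sizes2)
        solveThetaTwoBurst(u2, k0)
    } else {
        # fallback: one-burst sizes are X | X >= k0, E = k0 - 1 + 1/theta
        u1 <- mean(sizes1)
        min(max(1 / max(u1 - k0 + 1, 1.05), 1e-4), 0.95)
    }
    # collision probability: conversions uniform over the movie merge when
    # they fall within gapMax (plus a burst length) of each other
    pm <- 0
    if (config@collisionCorrection) {
        delta <- min(config@gapMax + 1 / theta, nFrames)
        pm <- 2 * delta / nFrames - (delta / nFrames)^2
    }
    # filter pass probabilities given the burst count; for single-burst
    # complexes the second site may contribute a lone singleton detection
    # (probability w among non-observable sites), relaxing the filter by
    # one detection -- solved by fixed-point iteration in rho
    s2 <- 1 - pGeomSumLE(k0 - 5L, theta)
    r <- N2 / max(N1, 1L)
    q <- 2 * r / (1 + 2 * r)   # starting value (uncorrected)
    for (it in 1:4) {
        rho <- min(q / (1 - theta), 1)
        w <- rho * theta / max(1 - rho * (1 - theta), 1e-9)
        s1 <- (1 - w) * (1 - theta)^max(k0 - 2L, 0L) +
            w * (1 - theta)^max(k0 - 3L, 0L)
        q <- if (N1 == 0L) 1 else {
            2 * r * s1 / ((1 - pm) * s2 + r * (2 * s1 - pm * s2))
        }
        q <- min(max(q, 1e-6), 1)
    }
    m <- 1 / theta
    pdet <- min(q / (1 - theta), 1)
    new("PhotophysicsCalibration", N1 = as.integer(N1),
        N2 = as.integer(N2), nExcluded = as.integer(nExcluded),
        nComplexes = as.integer(sum(included)), pdetRaw = pdetRaw,
        meanDetectionsPerBurst = dbarRaw, detectionsPerFluor = m,
        pDet = pdet, q = q, pCollision = pm, model = "geometric")
}

# Solve E[X_i | X1 + X2 >= k0] = u for theta of the shifted geometric.
# E[G | G1 + G2 >= k0 - 4] = E[G] / (1 - P(sum <= k0 - 5)) since
# E[G1; sum >= j] = E[G1] - E[G1; sum < j] and the omitted term vanishes
# for j <= 1 (G1 = 0 contributes nothing); for k0 = 5 this is exact:
# u = 2 + 1/(theta (1 + theta)).
solveThetaTwoBurst <- function(u, k0) {
    if (u <= 2.05) return(0.95)
    if (k0 <= 4L) return(min(max(1 / (u - 1), 1e-4), 0.95))
    f <- function(th) {
        sel <- 1 - pGeomSumLE(k0 - 5L, th)
        2 + ((1 - th) / th) / sel - u
    }
    stats::uniroot(f, c(1e-4, 0.95), tol = 1e-10)$root
}

#' Build a PhotophysicsCalibration from explicit values
#'
#' Convenience constructor for worked examples and tests where the
#' conversion factors are known rather than estimated.
#'
#' @param detectionsPerFluor mean detections per fluorophore.
#' @param pDet functional-fluorophore fraction.
#' @param N1,N2 burst-count tallies (defaults give the same pDet).
#' @return A \linkS4class{PhotophysicsCalibration}.
#' @examples
#' photophysicsCalibration(2.5, 1)
#' @export
photophysicsCalibration <- function(detectionsPerFluor, pDet,
                                    N1 = 0L, N2 = 100L) {
    new("PhotophysicsCalibration", N1 = as.integer(N1),
        N2 = as.integer(N2), nExcluded = 0L,
        nComplexes = as.integer(N1 + N2),
        pdetRaw = estimatePdet(N1, N2),
        meanDetectionsPerBurst = detectionsPerFluor,
        detectionsPerFluor = detectionsPerFluor, pDet = pDet, q = pDet,
        pCollision = 0, model = "none")
}

#' Convert synaptic detections to receptor numbers and densities
#'
#' For each cluster, detected fluorophores = D / detectionsPerFluor,
#' molecules (tagged beta subunits) = fluorophores / P_det, receptors =
#' molecules / nBeta, density = receptors / area. Receptor numbers are
#' real-valued; rounding is left to presentation.
#'
#' @param clusterSet a \linkS4class{SynapticClusterSet}.
#' @param calib a \linkS4class{PhotophysicsCalibration}.
#' @param config a \linkS4class{CountingConfig} (supplies nBeta).
#' @return The cluster set with \code{receptors} and \code{density}
#'   columns added to its table.
#' @export
countReceptors <- function(clusterSet, calib, config = countingConfig()) {
    validObject(calib)
    dpf <- calib@detectionsPerFluor
    p <- calib@pDet
    if (dpf <= 0 || p <= 0)
        stop("calibration has non-positive detections/fluorophore or P_det")
    cl <- clusterSet@clusters
    cl$receptors <- cl$nDetections / dpf / p / config@nBeta
    cl$density <- cl$receptors / cl$area
    initialize(clusterSet, clusters = cl)
}
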