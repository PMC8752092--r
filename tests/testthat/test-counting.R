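# Burst grouping, detection-probability estimation, photophysics
# calibration, and molecular conversion.

test_that("burst grouping applies the gap rule and the two-detection
          minimum", {
    b <- groupBursts(c(10, 11, 12, 1500, 1501))
    expect_identical(nrow(b), 2L)
    expect_identical(b$nDetections, c(3L, 2L))
    expect_identical(b$firstFrame, c(10L, 1500L))

    expect_identical(nrow(groupBursts(42)), 0L)      # singletons discarded
    b2 <- groupBursts(c(5, 6))
    expect_identical(b2$nDetections, 2L)

    # gap of exactly 1000 frames stays one burst; 1001 splits
    expect_identical(nrow(groupBursts(c(1, 1001))), 1L)
    expect_identical(nrow(groupBursts(c(1, 2, 1003, 1004))), 2L)
})

test_that("estimatePdet matches its closed forms and is monotone", {
    expect_equal(estimatePdet(0, 40), 1)
    expect_equal(estimatePdet(50, 50), 2 / 3)
    expect_error(estimatePdet(0, 0), "observable")
    for (N1 in c(1, 10, 100)) {
        vals <- vapply(c(1, 5, 25, 125), function(N2)
            estimatePdet(N1, N2), numeric(1))
        expect_true(all(diff(vals) > 0))
        expect_true(all(vals > 0 & vals <= 1))
    }
})

test_that("estimatePdet recovers the truth on simulated two-fluorophore
          complexes", {
    # independent oracle: direct binomial simulation of observability
    set.seed(42)
    for (p in c(0.3, 0.5, 0.8)) {
        nf <- rbinom(1e4, 2, p)
        N1 <- sum(nf == 1); N2 <- sum(nf == 2)
        est <- estimatePdet(N1, N2)
        pi2 <- p / (2 - p)            # P(2 bursts | observable)
        nObs <- N1 + N2
        se <- 2 / (1 + pi2)^2 * sqrt(pi2 * (1 - pi2) / nObs)
        expect_lt(abs(est - p), 3 * se)
    }
})

test_that("calibration tallies N1/N2 and raw statistics as specified", {
    frames <- c(replicate(50, list(c(100, 101, 102)), simplify = FALSE),
                replicate(50, list(c(100, 101, 5000, 5001)),
                          simplify = FALSE))
    fx <- complexSetFromFrames(lapply(frames, `[[`, 1))
    cal <- calibratePhotophysics(fx$complexes, fx$table, nFrames = 25000L)
    expect_identical(cal@N1, 50L)
    expect_identical(cal@N2, 50L)
    expect_equal(cal@pdetRaw, 2 / 3)

    # every complex shows 2 bursts -> raw P_det = 1
    fx2 <- complexSetFromFrames(replicate(30, c(10, 11, 3000, 3001),
                                          simplify = FALSE))
    cal2 <- calibratePhotophysics(fx2$complexes, fx2$table,
                                  nFrames = 25000L)
    expect_equal(cal2@pdetRaw, 1)
    expect_equal(pDet(cal2), 1)

    # bursts of sizes 3, 2, 4 -> raw mean detections/burst = 3
    fx3 <- complexSetFromFrames(list(c(1, 2, 3), c(10, 11),
                                     c(20, 21, 22, 23)))
    cal3 <- calibratePhotophysics(fx3$complexes, fx3$table,
                                  nFrames = 25000L)
    expect_equal(cal3@meanDetectionsPerBurst, 3)
    expect_identical(cal3@N1, 3L)

    empty <- new("ExtrasynapticComplexSet",
                 complexes = data.frame(), detectionIndices = list())
    expect_error(calibratePhotophysics(empty, fx$table), "complex")
})

test_that("model-corrected calibration recovers the generating
          photophysics", {
    cfg <- simulationConfig("custom", nSynapses = 0,
                            extrasynapticDensity = 3, gridPitch = 50000,
                            seed = 11)
    fld <- simulateLocalizations(makeSynapsePopulation(cfg))
    cs <- detectExtrasynapticComplexes(fld@locs)
    cal <- calibratePhotophysics(cs, fld@locs, nFrames = cfg@nFrames)
    expect_lt(abs(cal@detectionsPerFluor / 6 - 1), 0.03)
    expect_lt(abs(pDet(cal) / 0.6 - 1), 0.04)
    # the raw plug-in quantities are visibly biased in comparison
    expect_gt(cal@meanDetectionsPerBurst, 7)
})

test_that("countReceptors applies the conversion arithmetic", {
    mkSet <- function(D) new("SynapticClusterSet",
        clusters = data.frame(id = 1L, nDetections = D, extent = 400,
                              area = 0.05, centroidX = 0, centroidY = 0),
        assignment = integer(0), footprints = list(), pixelSize = 10)
    calib <- photophysicsCalibration(2.5, 1)
    out <- clusterTable(countReceptors(mkSet(570L), calib))
    expect_equal(out$receptors, 114)        # 570 / 2.5 / 1 / 2
    expect_equal(out$density, 114 / 0.05)

    calib2 <- photophysicsCalibration(2, 0.5)
    expect_equal(clusterTable(countReceptors(mkSet(400L),
                                             calib2))$receptors, 200)
    expect_equal(clusterTable(countReceptors(mkSet(0L),
                                             calib))$receptors, 0)
})

test_that("end-to-end counting is unbiased and density is
          size-independent", {
    res <- stdRun()
    tab <- clusterTable(res$clusters)
    m <- res$match
    ratio <- tab$receptors / m$trueCount
    expect_gt(median(ratio), 0.95)
    expect_lt(median(ratio), 1.05)
    expect_lt(abs(cor(tab$density, tab$area, method = "spearman")), 0.1)
})

test_that("receptor counts are stable under temporal subsampling only
          with re-calibration", {
    res <- stdRun()
    tab <- res$corrected
    d <- locData(tab)
    half <- initialize(tab, data = d[d$frame <= 12500, , drop = FALSE],
                       nFrames = 12500L)
    clH <- segmentSynapticClusters(half)
    csH <- detectExtrasynapticComplexes(half, clH)
    calH <- calibratePhotophysics(csH, half, nFrames = 12500L)
    clH <- countReceptors(clH, calH)
    mH <- matchClustersToSynapses(clH, res$field)
    ratioH <- median(clusterTable(clH)$receptors / mH$trueCount)
    # half the movie quarters the two-burst complex count (q is halved),
    # so the re-calibrated conversion carries ~4x the calibration
    # variance of the full run
    expect_gt(ratioH, 0.85)
    expect_lt(ratioH, 1.15)
    # re-calibration halves P_det (half the fluorophores convert)...
    expect_lt(pDet(calH) / pDet(res$calibration), 0.6)
    # ...so counting the half-movie with the full-movie calibration
    # would halve the answer
    clWrong <- countReceptors(segmentSynapticClusters(half),
                              res$calibration)
    mW <- matchClustersToSynapses(clWrong, res$field)
    ratioW <- median(clusterTable(clWrong)$receptors / mW$trueCount)
    expect_lt(ratioW, 0.65)
})
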