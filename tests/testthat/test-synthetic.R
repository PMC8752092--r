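# Synthetic-data generator: population statistics, photophysics,
# drift injection, reference channel, serial sections.

test_that("population copy numbers and packing density match the preset", {
    cfg <- simulationConfig("dorsal-2mo", nSynapses = 1000, seed = 7)
    pop <- makeSynapsePopulation(cfg)
    cts <- vapply(synapses(pop), `[[`, numeric(1), "trueCount")
    ars <- vapply(synapses(pop), `[[`, numeric(1), "trueArea")
    expect_length(cts, 1000)
    expect_lt(abs(median(cts) / 114 - 1), 0.05)
    # population mean of count/area converges to the packing density
    expect_lt(abs(mean(cts / ars) / 2000 - 1), 0.02)

    vcfg <- simulationConfig("ventral-2mo", nSynapses = 1000, seed = 8)
    vct <- vapply(synapses(makeSynapsePopulation(vcfg)), `[[`,
                  numeric(1), "trueCount")
    expect_lt(abs(median(vct) / 228 - 1), 0.05)
})

test_that("empty and forced-count populations behave as specified", {
    cfg <- simulationConfig("custom", nSynapses = 0, seed = 1)
    expect_length(synapses(makeSynapsePopulation(cfg)), 0)
    expect_error(simulationConfig("made-up-preset"), "preset")

    cfg <- simulationConfig("custom", nSynapses = 1, packingDensity = 2000,
                            seed = 2)
    pop <- makeSynapsePopulation(cfg, counts = 200L)
    expect_equal(synapses(pop)[[1]]$trueArea, 0.1, tolerance = 1e-12)
    expect_identical(synapses(pop)[[1]]$trueCount, 200L)
})

test_that("one receptor with certain detection and fixed burst length
          yields two three-detection bursts", {
    rect <- cbind(c(0, 200, 200, 0), c(0, 0, 200, 200)) + 400
    syn <- groundTruthSynapse(rect, trueCount = 1)
    cfg <- simulationConfig("custom", nSynapses = 1, pDet = 1,
                            meanDetectionsPerBurst = 3,
                            burstSizeModel = "constant",
                            extrasynapticDensity = 0, seed = 5)
    pop <- new("SynapsePopulation", synapses = list(syn), config = cfg,
               fieldSize = c(1000, 1000))
    fld <- simulateLocalizations(pop)
    expect_identical(nDetections(fld@locs), 6L)   # 2 fluorophores x 3
    b <- groupBursts(locData(fld@locs)$frame)
    expect_identical(nrow(b), 2L)
    expect_identical(b$nDetections, c(3L, 3L))
})

test_that("pDet = 0 yields an empty table", {
    cfg <- simulationConfig("custom", nSynapses = 3, pDet = 0,
                            extrasynapticDensity = 0, seed = 5)
    fld <- simulateLocalizations(makeSynapsePopulation(cfg))
    expect_identical(nDetections(fld@locs), 0L)
})

test_that("burst sizes follow the configured mean (law of large numbers)", {
    rect <- cbind(c(0, 4000, 4000, 0), c(0, 0, 4000, 4000)) + 200
    syn <- groundTruthSynapse(rect, trueCount = 9000)   # ~1e4 fluorophores
    cfg <- simulationConfig("custom", nSynapses = 1, pDet = 0.6,
                            meanDetectionsPerBurst = 2.5,
                            extrasynapticDensity = 0, seed = 11)
    pop <- new("SynapsePopulation", synapses = list(syn), config = cfg,
               fieldSize = c(5000, 5000))
    fld <- simulateLocalizations(pop)
    sizes <- as.integer(table(fld@linkage$fluorId))
    expect_gt(length(sizes), 1e4 * 0.9)
    se <- sd(sizes) / sqrt(length(sizes))
    expect_lt(abs(mean(sizes) - 2.5), 3 * se)
})

test_that("heterozygous tagging halves the expected synaptic signal", {
    cfg <- simulationConfig("dorsal-2mo", nSynapses = 150, seed = 13)
    pop <- makeSynapsePopulation(cfg)
    fHom <- simulateLocalizations(pop, hetTagFraction = 1, seed = 100)
    fHet <- simulateLocalizations(pop, hetTagFraction = 0.5, seed = 200)
    nHom <- sum(fHom@linkage$source == "synapse")
    nHet <- sum(fHet@linkage$source == "synapse")
    ratio <- nHom / nHet
    # 3 SE on the ratio of two Poisson-like totals
    se <- ratio * sqrt(1 / nHom + 1 / nHet) * 2   # burst clumping factor
    expect_lt(abs(ratio - 2), max(3 * se, 0.1))
})

test_that("two-burst fraction among observable complexes matches
          p^2 / (1 - (1-p)^2)", {
    cfg <- simulationConfig("custom", nSynapses = 0,
                            extrasynapticDensity = 4, gridPitch = 60000,
                            pDet = 0.6, burstSizeModel = "constant",
                            meanDetectionsPerBurst = 3, seed = 17)
    fld <- simulateLocalizations(makeSynapsePopulation(cfg))
    nf <- vapply(fld@complexes, `[[`, numeric(1), "nFunctional")
    obs <- nf[nf >= 1]
    expect_gt(length(obs), 1e4)
    p <- 0.6
    expected <- p^2 / (1 - (1 - p)^2)
    frac <- mean(obs == 2)
    se <- sqrt(expected * (1 - expected) / length(obs))
    expect_lt(abs(frac - expected), 3 * se)
})

test_that("simulation is reproducible bit for bit under a fixed seed", {
    cfg <- simulationConfig("dorsal-2mo", nSynapses = 20, seed = 23,
                            driftPath = linearDriftPath(50, -30, 25000))
    f1 <- simulateLocalizations(makeSynapsePopulation(cfg))
    f2 <- simulateLocalizations(makeSynapsePopulation(cfg))
    expect_identical(locData(f1@locs), locData(f2@locs))
    expect_identical(f1@linkage, f2@linkage)
})

test_that("drift injection shifts, inverts and validates as specified", {
    tab <- makeTable(c(100, 200), c(100, 200), frame = c(1L, 25000L),
                     nFrames = 25000L)
    zero <- data.frame(frame = c(1, 25000), dx = 0, dy = 0)
    expect_identical(locData(injectDrift(tab, zero)), locData(tab))

    lin <- linearDriftPath(250, 0, 25000)   # 0.01 nm/frame
    shifted <- injectDrift(tab, lin)
    expect_equal(locData(shifted)$x[2] - locData(tab)$x[2], 250)

    back <- correctDrift(shifted, driftTraceFromPath(lin, 25000))
    expect_identical(locData(back)$x, locData(tab)$x)
    expect_identical(locData(back)$y, locData(tab)$y)

    short <- data.frame(frame = c(1, 1000), dx = c(0, 5), dy = 0)
    expect_error(injectDrift(tab, short), "drift path ends")
})

test_that("reference channel integrates to gain times the scaffold", {
    cfg <- simulationConfig("dorsal-2mo", nSynapses = 9, seed = 31)
    pop <- makeSynapsePopulation(cfg)
    cts <- vapply(synapses(pop), `[[`, numeric(1), "trueCount")
    img <- renderReferenceChannel(pop, gain = 3, noiseSd = 0)
    expect_equal(sum(img), 3 * sum(cts), tolerance = 1e-9)

    empty <- makeSynapsePopulation(
        simulationConfig("custom", nSynapses = 0, seed = 1))
    expect_true(all(renderReferenceChannel(empty) == 0))
    expect_error(renderReferenceChannel(pop, noiseSd = -1), "noiseSd")

    # identical noise-free channel pair: maximal intensity correlation
    icq <- computeICQ(img, img, mask = img > 0)
    expect_equal(icq$value, 0.5)
})

test_that("serial sectioning slices geometry as specified", {
    rect <- cbind(c(0, 1000, 1000, 0), c(0, 0, 700, 700))
    syn <- groundTruthSynapse(rect, trueCount = 100)
    stk <- makeSerialSections(syn, thickness = 70, tilt = 0)
    expect_length(stk@sections, 10)
    expect_true(all(vapply(stk@sections, length, integer(1)) == 1))
    expect_equal(unlist(stk@sections), rep(1000, 10), tolerance = 1e-9)

    stk60 <- makeSerialSections(syn, thickness = 70, tilt = 60)
    expect_equal(stk60@palmArea / syn$trueArea, 0.5, tolerance = 1e-9)

    # one perforation crossing k consecutive sections -> 2 segments there
    hole <- cbind(c(400, 600, 600, 400), c(200, 200, 480, 480))
    perf <- groundTruthSynapse(list(rect, hole[4:1, ]), trueCount = 100)
    stkP <- makeSerialSections(perf, thickness = 70, tilt = 0)
    nseg <- vapply(stkP@sections, length, integer(1))
    # hole spans y in [200, 480): section midlines 245...455 -> sections 4-7
    expect_identical(nseg, c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 1L, 1L, 1L))

    expect_error(makeSerialSections(syn, tilt = 95), "tilt")
    expect_error(makeSerialSections(syn, thickness = 0), "thickness")
})
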