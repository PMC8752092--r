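# Serial-section EM morphometry.

test_that("EM area is cumulative profile length times thickness", {
    expect_equal(emArea(serialSectionStack(list(400, 500, 600))), 0.105)
    expect_equal(emArea(serialSectionStack(list(1000))), 0.07)
    s <- list(c(300, 200), 450, numeric(0), 700)
    expect_equal(emArea(serialSectionStack(s, thickness = 140)),
                 2 * emArea(serialSectionStack(s, thickness = 70)))
    expect_error(emArea(serialSectionStack(list(numeric(0)))),
                 "non-empty")
})

test_that("EM area is additive over sub-stacks and reversal-invariant", {
    a <- list(c(300, 200), 450); b <- list(700, 100, 250)
    ab <- serialSectionStack(c(a, b))
    expect_equal(emArea(ab),
                 emArea(serialSectionStack(a)) +
                 emArea(serialSectionStack(b)))
    expect_equal(emArea(serialSectionStack(rev(c(a, b)))), emArea(ab))
})

test_that("segmentation index counts in-plane and z interruptions", {
    expect_identical(
        segmentationIndex(serialSectionStack(list(500, 600, 550))), 0L)
    expect_identical(
        segmentationIndex(serialSectionStack(list(500, c(200, 250),
                                                  500))), 1L)
    expect_identical(
        segmentationIndex(serialSectionStack(
            list(500, numeric(0), numeric(0), 400))), 1L)
    # mixed: two in-plane gaps in one section + one z gap
    stk <- serialSectionStack(list(500, c(100, 100, 100), numeric(0),
                                   300))
    expect_identical(segmentationIndex(stk), 3L)
    # reversal invariance; emptying one interior section adds exactly 1
    expect_identical(segmentationIndex(serialSectionStack(
        rev(stk@sections))), 3L)
    base <- serialSectionStack(list(500, 500, 500, 500))
    hollowed <- serialSectionStack(list(500, numeric(0), 500, 500))
    expect_identical(segmentationIndex(hollowed),
                     segmentationIndex(base) + 1L)
    # persisted perforation counted per section or once per run
    pers <- serialSectionStack(list(500, c(200, 200), c(200, 200), 500))
    expect_identical(segmentationIndex(pers), 2L)
    expect_identical(segmentationIndex(pers, mergePersistent = TRUE), 1L)
})

test_that("PALM-EM comparison reflects projection geometry", {
    stk <- serialSectionStack(list(1000), tilt = 0)
    cmp <- comparePalmEm(0.07, stk)
    expect_equal(cmp$ratio, 1)
    expect_equal(cmp$correctedRatio, 1)

    stk60 <- serialSectionStack(list(1000), tilt = 60)
    cmp60 <- comparePalmEm(0.07 * cos(pi / 3), stk60)
    expect_equal(cmp60$ratio, 0.5, tolerance = 1e-9)
    expect_equal(cmp60$correctedRatio, 1, tolerance = 1e-9)

    expect_error(comparePalmEm(0, stk), "palmArea")
})

test_that("sectioned synthetic synapses reproduce their true area and
          the projection inequality", {
    cfg <- simulationConfig("ventral-2mo", nSynapses = 30, seed = 19)
    pop <- makeSynapsePopulation(cfg)
    for (syn in synapses(pop)) {
        stk <- makeSerialSections(syn)
        expect_lt(abs(emArea(stk) / syn$trueArea - 1), 0.12)
        cmp <- comparePalmEm(stk@palmArea, stk)
        expect_lte(cmp$ratio, 1.12)   # projection can only shrink
    }
})

test_that("segmentation index correlates with synapse area", {
    cfg <- simulationConfig("ventral-2mo", nSynapses = 200, seed = 29)
    pop <- makeSynapsePopulation(cfg)
    idx <- vapply(synapses(pop), function(s)
        segmentationIndex(makeSerialSections(s)), integer(1))
    area <- vapply(synapses(pop), `[[`, numeric(1), "trueArea")
    expect_gt(cor(idx, area, method = "spearman"), 0.5)
})
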