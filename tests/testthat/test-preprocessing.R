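# Rendering and drift estimation / correction.

test_that("rendering follows the pixel convention and conserves mass", {
    tab <- makeTable(105, 55, fieldSize = c(200, 100))
    m <- renderDensityMap(tab)
    expect_equal(dim(m), c(20L, 10L))
    # 0-based pixel (10, 5): column index 10 for x = 105 nm at 10 nm pixels
    expect_equal(m[11, 6], 1)
    expect_equal(sum(m), 1)

    set.seed(1)
    n <- 5000
    tab2 <- makeTable(runif(n, 0, 2000), runif(n, 0, 1000),
                      fieldSize = c(2000, 1000))
    expect_equal(sum(renderDensityMap(tab2)), n, tolerance = 1e-6)
    blurred <- renderDensityMap(tab2, renderConfig(kernelSigma = 2))
    expect_equal(sum(blurred), n, tolerance = 1e-6)

    emptyTab <- makeTable(numeric(0), numeric(0), frame = integer(0),
                          fieldSize = c(100, 100), nFrames = 1L)
    expect_warning(m0 <- renderDensityMap(emptyTab), "empty")
    expect_true(all(m0 == 0))
})

test_that("rendering is translation-covariant at pixel granularity", {
    set.seed(2)
    x <- runif(300, 100, 900); y <- runif(300, 100, 900)
    tab <- makeTable(x, y, fieldSize = c(2000, 2000))
    shifted <- makeTable(x + 30, y, fieldSize = c(2000, 2000))
    m1 <- renderDensityMap(tab)
    m2 <- renderDensityMap(shifted)
    expect_equal(m2[4:200, ], m1[1:197, ])
})

test_that("injected piecewise-linear drift is recovered to < 5 nm RMS", {
    path <- data.frame(frame = c(1, 8000, 16000, 25000),
                       dx = c(0, 45, 70, 100), dy = c(0, -25, 10, 60))
    fld <- pointAnchorField(driftPath = path, seed = 9)
    tr <- estimateDrift(fld@locs)
    expect_lt(alignedRMS(driftTrace(tr), fld@driftTruth), 5)
})

test_that("drift-free fields give a trace within the centroid CLT bound", {
    fld <- pointAnchorField(driftPath = NULL, seed = 10)
    tr <- estimateDrift(fld@locs)
    # detections per anchor per window (window/movie fraction of the
    # anchor's total), most conservative anchor
    nAnchor <- 600 * 2 * 0.6 * 6
    nPerWin <- nAnchor * 2000 / 25000
    bound <- 3 * 9 / sqrt(nPerWin)
    t <- driftTrace(tr)
    expect_lt(max(abs(c(t$dx - mean(t$dx), t$dy - mean(t$dy)))), bound)
})

test_that("drift estimation reports its failure modes", {
    short <- makeTable(runif(500, 0, 500), runif(500, 0, 500),
                       frame = rep(1:500, 1), nFrames = 1000L)
    expect_error(estimateDrift(short), "window")
    sparse <- makeTable(runif(2000, 0, 20000), runif(2000, 0, 20000),
                        frame = sample.int(25000, 2000, replace = TRUE),
                        nFrames = 25000L)
    expect_error(estimateDrift(sparse), "anchor")
})

test_that("drift correction is the exact inverse of injection and a
          fixed point of estimation", {
    set.seed(4)
    paths <- list(
        data.frame(frame = c(1, 12000, 25000), dx = c(0, 200, 380),
                   dy = c(0, -150, -90)),
        data.frame(frame = c(1, 25000), dx = c(0, -300), dy = c(0, 450)),
        data.frame(frame = c(1, 10000, 25000),
                   dx = c(0, 90, 20), dy = c(0, 60, 200)))
    for (path in paths) {
        fld <- pointAnchorField(driftPath = path, seed = 12)
        # narrower smoothing bandwidth for curvier traces
        tr <- estimateDrift(fld@locs, smoothWindows = 2)
        expect_lt(alignedRMS(driftTrace(tr), fld@driftTruth), 5)
        corrected <- correctDrift(fld@locs, tr)
        re <- estimateDrift(corrected, smoothWindows = 2)
        t2 <- driftTrace(re)
        amp <- max(abs(c(t2$dx - mean(t2$dx), t2$dy - mean(t2$dy))))
        expect_lt(amp, 5)
    }

    tab <- makeTable(c(10, 20), c(30, 40), frame = c(1L, 2L))
    zero <- new("DriftTrace", frame = 1:2, dx = c(0, 0), dy = c(0, 0),
                window = 0L, nAnchors = 0L)
    expect_identical(locData(correctDrift(tab, zero)), locData(tab))
    expect_error(correctDrift(makeTable(1, 1, frame = 5L), zero),
                 "frame")
})
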