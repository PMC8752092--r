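# Cluster segmentation: printed-threshold conformance and recovery of
# ground truth on synthetic fields.

# n detections spread uniformly in a disc at (cx, cy)
discCloud <- function(n, cx, cy, radius, seed = 1) {
    set.seed(seed)
    r <- radius * sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
    cbind(cx + r * cos(a), cy + r * sin(a))
}

test_that("synaptic cluster filters accept and reject by construction", {
    # 300 detections over ~400 nm extent: passes all three filters
    pts <- discCloud(300, 1000, 1000, 200)
    tab <- makeTable(pts[, 1], pts[, 2],
                     frame = sample.int(25000, 300, replace = TRUE),
                     fieldSize = c(2000, 2000), nFrames = 25000L)
    cl <- segmentSynapticClusters(tab)
    expect_identical(nrow(clusterTable(cl)), 1L)
    expect_gte(clusterTable(cl)$nDetections, 250)

    # 100 detections: below the 250-detection minimum
    pts <- discCloud(100, 1000, 1000, 200)
    tab <- makeTable(pts[, 1], pts[, 2], fieldSize = c(2000, 2000))
    expect_identical(nrow(clusterTable(segmentSynapticClusters(tab))), 0L)

    # elongated cluster of 4000 nm extent: above the 3000 nm maximum
    x <- seq(500, 4500, length.out = 400)
    set.seed(3)
    tab <- makeTable(x, 1000 + rnorm(400, 0, 40),
                     fieldSize = c(5000, 2000))
    expect_identical(nrow(clusterTable(segmentSynapticClusters(tab))), 0L)
})

test_that("extrasynaptic complex filters follow the printed thresholds", {
    mk <- function(pts) makeTable(pts[, 1], pts[, 2],
                                  fieldSize = c(3000, 3000))
    # 6 detections within 50 nm: accepted
    pts <- discCloud(6, 500, 500, 25, seed = 4)
    cs <- detectExtrasynapticComplexes(mk(pts))
    expect_identical(nrow(clusterTable(cs)), 1L)

    # 4 detections: below the 5-detection minimum
    pts <- discCloud(4, 500, 500, 25, seed = 5)
    expect_identical(
        nrow(clusterTable(detectExtrasynapticComplexes(mk(pts)))), 0L)

    # 9 linked detections spanning 200 nm: above the 120 nm maximum
    pts <- cbind(500 + seq(0, 200, by = 25), 500)
    expect_identical(
        nrow(clusterTable(detectExtrasynapticComplexes(mk(pts)))), 0L)

    # detections inside synapse footprints are excluded
    big <- discCloud(400, 1000, 1000, 180, seed = 6)
    tab <- makeTable(big[, 1], big[, 2], fieldSize = c(3000, 3000))
    cl <- segmentSynapticClusters(tab)
    cs2 <- detectExtrasynapticComplexes(tab, cl)
    expect_identical(nrow(clusterTable(cs2)), 0L)
})

test_that("retained clusters satisfy their invariants on a synthetic
          field", {
    res <- stdRun()
    tab <- clusterTable(res$clusters)
    expect_gt(nrow(tab), 400)
    expect_true(all(tab$nDetections >= 250))
    expect_true(all(tab$extent >= 200 & tab$extent <= 3000))
    expect_true(all(tab$area > 0))
})

test_that("bright ground-truth synapses are recovered one-to-one", {
    res <- stdRun()
    m <- res$match
    pop <- synapses(res$field@population)
    cts <- vapply(pop, `[[`, numeric(1), "trueCount")
    # expected detections = count x nBeta x pDet x mean burst length
    eligible <- which(cts * 2 * 0.6 * 6 >= 300)
    hits <- table(factor(m$synapseId, levels = seq_along(pop)))
    oneToOne <- sum(hits[eligible] == 1)
    expect_gte(oneToOne / length(eligible), 0.95)
    expect_gt(mean(m$purity), 0.99)
})

test_that("measured cluster areas track true areas", {
    res <- stdRun()
    tab <- clusterTable(res$clusters)
    m <- res$match
    expect_gt(cor(tab$area, m$trueArea, method = "spearman"), 0.9)
    # calibrated area estimator: unbiased to a few percent on average
    expect_lt(abs(mean(tab$area / m$trueArea) - 1), 0.06)
})
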