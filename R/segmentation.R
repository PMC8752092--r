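# Segmentation of synaptic clusters and extrasynaptic calibration
# complexes from drift-corrected localization tables.

#' Segment synaptic clusters from a localization table
#'
#' Renders the table to a density map, binarizes each candidate region at
#' \code{intensityThreshold} times its local maximum, labels connected
#' components (8-connectivity), fills enclosed holes, assigns detections to
#' the component containing their pixel, and filters components by
#' detection count and spatial extent (maximum pairwise span, i.e. Feret
#' diameter). Cluster area is the footprint pixel count, minus a boundary
#' correction that compensates the one-pixel rim the thresholded mask adds
#' around a blurred point cluster, times the squared pixel size.
#'
#' Candidate regions are connected blobs of occupied pixels found on a
#' coarse (200 nm) grid, so the local-maximum normalization is
#' per-structure rather than per-image and a single bright synapse cannot
#' suppress the others.
#'
#' @param table a drift-corrected \linkS4class{LocalizationTable}.
#' @param minDet minimum detections per cluster (default 250).
#' @param minSize,maxSize extent bounds in nm (defaults 200 and 3000).
#' @param intensityThreshold fraction of the local density-map maximum
#'   (default 0.1).
#' @param config a \linkS4class{RenderConfig}; the default smooths the
#'   10 nm histogram with a 1.5-pixel Gaussian so the suprathreshold mask
#'   is contiguous rather than porous (Poisson pixel occupancy at typical
#'   synaptic densities is far from saturating); together with
#'   \code{boundaryCorrection} this pair is calibrated on uniform-density
#'   synthetic populations so that measured areas are unbiased (vignette).
#' @param boundaryCorrection boundary pixels counted as this fraction of an
#'   interior pixel when measuring area (0 disables; see the package
#'   vignette for the calibration).
#' @return A \linkS4class{SynapticClusterSet}.
#' @export
segmentSynapticClusters <- function(table, minDet = 250, minSize = 200,
                                    maxSize = 3000,
                                    intensityThreshold = 0.1,
                                    config = renderConfig(kernelSigma = 1.5),
                                    boundaryCorrection = 0.7) {
    px <- config@pixelSize
    d <- locData(table)
    empty <- new("SynapticClusterSet",
                 clusters = data.frame(id = integer(0),
                                       nDetections = integer(0),
                                       extent = numeric(0),
                                       area = numeric(0),
                                       centroidX = numeric(0),
                                       centroidY = numeric(0)),
                 assignment = integer(0), footprints = list(),
                 pixelSize = px)
    if (!nrow(d)) return(empty)
    ix <- pmax(floor(d$x / px), 0)
    iy <- pmax(floor(d$y / px), 0)
    # ---- candidate regions on a coarse grid
    cgrid <- 200
    cxi <- floor(d$x / cgrid) + 1L
    cyi <- floor(d$y / cgrid) + 1L
    cxi <- pmax(cxi, 1L); cyi <- pmax(cyi, 1L)
    cocc <- matrix(FALSE, max(cxi), max(cyi))
    cocc[cbind(cxi, cyi)] <- TRUE
    clab <- labelComponents(cocc, connectivity = 8)
    candOf <- clab[cbind(cxi, cyi)]
    sig <- config@kernelSigma
    if (config@kernelUnits == "nm") sig <- sig / px

    clusters <- list(); footprints <- list()
    assignment <- rep(NA_integer_, nrow(d))
    nextId <- 0L
    for (cand in which(tabulate(candOf) >= minDet)) {
        sel <- which(candOf == cand)
        x0 <- min(ix[sel]) - 2L; y0 <- min(iy[sel]) - 2L
        nx <- max(ix[sel]) - x0 + 3L; ny <- max(iy[sel]) - y0 + 3L
        li <- ix[sel] - x0 + 1L; lj <- iy[sel] - y0 + 1L
        img <- matrix(0, nx, ny)
        cnt <- table(factor(li + nx * (lj - 1L),
                            levels = seq_len(nx * ny)))
        img[] <- as.numeric(cnt)
        if (sig >= 0.3) img <- gaussianBlur(img, sig)
        mask <- img >= intensityThreshold * max(img)
        lab <- fillHoles(labelComponents(mask, connectivity = 8),
                         maxPx = 12)
        nLab <- max(lab)
        if (nLab == 0L) next
        detLab <- lab[cbind(li, lj)]
        npix <- tabulate(lab[lab > 0L], nbins = nLab)
        nbnd <- boundaryCounts(lab, nLab)
        for (l in seq_len(nLab)) {
            mem <- sel[detLab == l]
            D <- length(mem)
            if (D < minDet) next
            extent <- feretDiameter(cbind(d$x[mem], d$y[mem]))
            if (extent < minSize || extent > maxSize) next
            areaPx <- npix[l] - boundaryCorrection * nbnd[l]
            area <- max(areaPx, 1) * px^2 / 1e6
            nextId <- nextId + 1L
            assignment[mem] <- nextId
            fp <- which(lab == l, arr.ind = TRUE)
            footprints[[nextId]] <- cbind(ix = fp[, 1] + x0 - 1L,
                                          iy = fp[, 2] + y0 - 1L)
            clusters[[nextId]] <- data.frame(
                id = nextId, nDetections = D, extent = extent,
                area = area, centroidX = mean(d$x[mem]),
                centroidY = mean(d$y[mem]))
        }
    }
    if (!length(clusters)) return(empty)
    new("SynapticClusterSet", clusters = do.call(rbind, clusters),
        assignment = assignment, footprints = footprints, pixelSize = px)
}

#' Detect extrasynaptic calibration complexes
#'
#' Single-linkage clustering (within \code{linkRadius}) of the detections
#' lying outside every synaptic-cluster footprint, filtered by detection
#' count and extent. These small clusters are the two-fluorophore receptor
#' complexes used to calibrate the photophysics.
#'
#' @param table the same drift-corrected \linkS4class{LocalizationTable}
#'   used for synapse segmentation.
#' @param synapseFootprints a \linkS4class{SynapticClusterSet} (its
#'   footprints are excluded) or NULL if there are none.
#' @param minDet minimum detections (default 5).
#' @param minSize,maxSize extent bounds in nm (defaults 10 and 120).
#' @param linkRadius linkage radius in nm (about 3x the localization
#'   precision).
#' @param exclusionMargin nm added around each synapse footprint's
#'   bounding box when excluding detections, so that stray rim detections
#'   of a synapse are not mistaken for small complexes.
#' @return An \linkS4class{ExtrasynapticComplexSet}; the
#'   \code{detectionIndices} slot maps each complex back to table rows.
#' @export
detectExtrasynapticComplexes <- function(table, synapseFootprints = NULL,
                                         minDet = 5, minSize = 10,
                                         maxSize = 120, linkRadius = 30,
                                         exclusionMargin = 75) {
    d <- locData(table)
    out <- new("ExtrasynapticComplexSet",
               complexes = data.frame(id = integer(0),
                                      nDetections = integer(0),
                                      extent = numeric(0),
                                      centroidX = numeric(0),
                                      centroidY = numeric(0)),
               detectionIndices = list())
    if (!nrow(d)) return(out)
    keep <- rep(TRUE, nrow(d))
    if (!is.null(synapseFootprints) &&
        length(synapseFootprints@footprints)) {
        px <- synapseFootprints@pixelSize
        for (fp in synapseFootprints@footprints) {
            x0 <- min(fp[, 1]) * px - exclusionMargin
            x1 <- (max(fp[, 1]) + 1) * px + exclusionMargin
            y0 <- min(fp[, 2]) * px - exclusionMargin
            y1 <- (max(fp[, 2]) + 1) * px + exclusionMargin
            keep <- keep & !(d$x >= x0 & d$x < x1 & d$y >= y0 & d$y < y1)
        }
    }
    idx <- which(keep)
    if (!length(idx)) return(out)
    x <- d$x[idx]; y <- d$y[idx]
    cellx <- floor(x / linkRadius); celly <- floor(y / linkRadius)
    cellKey <- paste(cellx, celly)
    byCell <- split(seq_along(idx), cellKey)
    cellXY <- do.call(rbind, strsplit(names(byCell), " "))
    cellXY <- matrix(as.integer(cellXY), ncol = 2)
    cellIndex <- setNames(seq_along(byCell), names(byCell))
    pairs <- list()
    for (ci in seq_along(byCell)) {
        pts <- byCell[[ci]]
        neigh <- pts
        for (sx in -1:1) for (sy in -1:1) {
            if (sx == 0 && sy == 0) next
            key <- paste(cellXY[ci, 1] + sx, cellXY[ci, 2] + sy)
            cj <- cellIndex[key]
            if (!is.na(cj) && cj > ci) neigh <- c(neigh, byCell[[cj]])
        }
        if (length(neigh) < 2) next
        dd <- as.matrix(stats::dist(cbind(x[neigh], y[neigh])))
        hit <- which(dd <= linkRadius & upper.tri(dd), arr.ind = TRUE)
        if (nrow(hit)) {
            pairs[[length(pairs) + 1L]] <-
                cbind(neigh[hit[, 1]], neigh[hit[, 2]])
        }
    }
    comp <- unionFind(length(idx), do.call(rbind, pairs))
    res <- list(); dlist <- list(); nid <- 0L
    for (g in split(seq_along(idx), comp)) {
        if (length(g) < minDet) next
        extent <- feretDiameter(cbind(x[g], y[g]))
        if (extent < minSize || extent > maxSize) next
        nid <- nid + 1L
        res[[nid]] <- data.frame(
            id = nid, nDetections = length(g), extent = extent,
            centroidX = mean(x[g]), centroidY = mean(y[g]))
        dlist[[nid]] <- idx[g]
    }
    if (!nid) return(out)
    new("ExtrasynapticComplexSet", complexes = do.call(rbind, res),
        detectionIndices = dlist)
}
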