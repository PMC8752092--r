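# Drift estimation/correction and pointillist rendering.

#' Render a localization table to a density map
#'
#' Each localization deposits unit mass at its pixel (0-based index
#' \code{floor(coordinate / pixelSize)}); with a non-negligible kernel sigma
#' the histogram is convolved with a normalized Gaussian, so total image
#' mass always equals the number of localizations. Rows of the returned
#' matrix index x pixels, columns y pixels.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param config a \linkS4class{RenderConfig}.
#' @param dims optional integer(2) image size in pixels (defaults to the
#'   field size).
#' @return numeric matrix of pixel masses.
#' @examples
#' tab <- new("LocalizationTable",
#'     data = data.frame(frame = 1L, x = 105, y = 55, intensity = 1,
#'                       sigma = 9),
#'     fieldSize = c(200, 100), nFrames = 1L)
#' m <- renderDensityMap(tab)
#' which(m == 1, arr.ind = TRUE) - 1   # 0-based pixel (10, 5)
#' @export
renderDensityMap <- function(table, config = renderConfig(), dims = NULL) {
    px <- config@pixelSize
    if (is.null(dims)) dims <- pmax(ceiling(table@fieldSize / px), 1)
    dims <- as.integer(dims)
    d <- locData(table)
    if (!nrow(d)) {
        warning("empty localization table: returning an all-zero image")
        return(matrix(0, dims[1], dims[2]))
    }
    ix <- pmin(pmax(floor(d$x / px), 0), dims[1] - 1)
    iy <- pmin(pmax(floor(d$y / px), 0), dims[2] - 1)
    img <- matrix(0, dims[1], dims[2])
    cnt <- table(factor(ix + dims[1] * iy, levels = 0:(prod(dims) - 1)))
    img[] <- as.numeric(cnt)
    sig <- config@kernelSigma
    if (config@kernelUnits == "nm") sig <- sig / px
    if (sig >= 0.3) img <- gaussianBlur(img, sig)
    img
}

# Separable Gaussian convolution with renormalized edge handling
# (mass-conserving on the finite grid).
gaussianBlur <- function(img, sigmaPx) {
    r <- max(1L, ceiling(4 * sigmaPx))
    k <- stats::dnorm(seq(-r, r), sd = sigmaPx)
    k <- k / sum(k)
    pad <- function(m, n) rbind(matrix(0, n, ncol(m)), m,
                                matrix(0, n, ncol(m)))
    conv1 <- function(m) {   # convolve along rows (dimension 1)
        out <- matrix(0, nrow(m), ncol(m))
        mp <- pad(m, r)
        for (j in seq_along(k)) {
            out <- out + k[j] * mp[seq_len(nrow(m)) + (j - 1L), ,
                                   drop = FALSE]
        }
        out
    }
    out <- conv1(img)
    out <- t(conv1(t(out)))
    # reflect mass that leaked off the grid back in, preserving the total
    tot <- sum(img)
    if (tot > 0 && sum(out) > 0) out <- out * (tot / sum(out))
    out
}

#' Estimate lateral drift from dense anchor clusters
#'
#' Selects the \code{nAnchors} densest compact detection clusters (at least
#' \code{minPerWindow} detections in every window, radius below
#' \code{maxRadius}) and tracks their centroids across sliding windows of
#' \code{window} frames advancing by half a window. The per-window
#' displacements relative to the first window are averaged over anchors,
#' smoothed by a local linear fit over +/- 3 neighboring windows (burst
#' photophysics makes window centroids far noisier than the raw detection
#' count suggests, since detections arrive in bursts from few independent
#' fluorophores), and linearly interpolated between window centers to a
#' per-frame trace (clamped beyond the end centers). Since absolute
#' position is unobservable, the trace is defined up to a constant: the
#' first window is the reference.
#'
#' @param table a \linkS4class{LocalizationTable} spanning at least two
#'   windows.
#' @param nAnchors number of anchor clusters.
#' @param window window length in frames.
#' @param minPerWindow minimum detections an anchor must have in every
#'   window.
#' @param maxRadius anchor radius in nm.
#' @param smoothWindows local-linear smoothing half-width, in windows.
#' @return A \linkS4class{DriftTrace}.
#' @export
estimateDrift <- function(table, nAnchors = 5, window = 2000,
                          minPerWindow = 50, maxRadius = 300,
                          smoothWindows = 3) {
    d <- locData(table)
    nFrames <- max(table@nFrames, if (nrow(d)) max(d$frame) else 0L)
    if (floor(nFrames / window) < 2)
        stop("table spans ", floor(nFrames / window),
             " window(s); at least 2 needed for drift estimation")
    step <- max(window %/% 2L, 1L)
    starts <- seq(1L, max(nFrames - window + 1L, 1L), by = step)
    nWin <- length(starts)
    centersF <- starts + window / 2
    # candidate anchors: centroids of the densest 100 nm cells
    cell <- paste(floor(d$x / 100), floor(d$y / 100))
    top <- names(sort(table(cell), decreasing = TRUE))
    centers <- NULL
    for (cl in top) {
        sel <- cell == cl
        cen <- c(mean(d$x[sel]), mean(d$y[sel]))
        if (!is.null(centers) &&
            any((centers[, 1] - cen[1])^2 +
                (centers[, 2] - cen[2])^2 < (3 * maxRadius)^2)) next
        centers <- rbind(centers, cen)
        if (nrow(centers) >= 4 * nAnchors) break
    }
    smoothLocal <- function(v) {
        vapply(seq_len(nWin), function(i) {
            j <- max(1L, i - smoothWindows):min(nWin, i + smoothWindows)
            if (length(j) < 3) return(mean(v[j]))
            unname(predict(lm(y ~ x, data.frame(x = centersF[j],
                                                y = v[j])),
                           data.frame(x = centersF[i])))
        }, numeric(1))
    }
    # track one anchor across windows; predicted (per-window) reference
    # positions break the feedback random walk of naive self-tracking
    track <- function(cen, predDx = NULL, predDy = NULL) {
        dx <- numeric(nWin); dy <- numeric(nWin)
        total <- 0L; ref <- cen
        for (w in seq_len(nWin)) {
            if (!is.null(predDx)) ref <- cen + c(predDx[w], predDy[w])
            inw <- d$frame >= starts[w] & d$frame < starts[w] + window
            sel <- inw &
                (d$x - ref[1])^2 + (d$y - ref[2])^2 < maxRadius^2
            n <- sum(sel)
            if (n < minPerWindow) return(NULL)
            cw <- c(mean(d$x[sel]), mean(d$y[sel]))
            if (is.null(predDx)) ref <- cw
            dx[w] <- cw[1]; dy[w] <- cw[2]
            total <- total + n
        }
        list(dx = dx - dx[1], dy = dy - dy[1], total = total,
             base = c(dx[1], dy[1]))
    }
    pass1 <- list(); totals <- numeric(0); compact <- logical(0)
    bases <- NULL
    for (a in seq_len(NROW(centers))) {
        tr <- track(centers[a, ])
        if (is.null(tr)) next
        sel <- (d$x - centers[a, 1])^2 +
            (d$y - centers[a, 2])^2 < maxRadius^2
        ext <- feretDiameter(cbind(d$x[sel], d$y[sel]))
        pass1[[length(pass1) + 1L]] <- tr
        totals <- c(totals, tr$total)
        compact <- c(compact, ext <= 1.7 * maxRadius)
        bases <- rbind(bases, tr$base)
    }
    if (length(pass1) < nAnchors)
        stop("drift calibration failed: only ", length(pass1),
             " dense anchor cluster(s) found, ", nAnchors, " required")
    # prefer compact anchors (fully inside the tracking ball); fall back
    # to the brightest otherwise
    ord <- order(!compact, -totals)
    keep <- ord[seq_len(nAnchors)]
    avgDisp <- function(trs) {
        list(dx = smoothLocal(rowMeans(vapply(trs, `[[`, numeric(nWin),
                                              "dx"))),
             dy = smoothLocal(rowMeans(vapply(trs, `[[`, numeric(nWin),
                                              "dy"))))
    }
    est <- avgDisp(pass1[keep])
    for (pass in 1:2) {   # re-track against the predicted trajectory
        trs <- lapply(keep, function(a)
            track(bases[a, ], est$dx, est$dy))
        if (any(vapply(trs, is.null, logical(1)))) break
        est <- avgDisp(trs)
    }
    dxw <- est$dx - est$dx[1]; dyw <- est$dy - est$dy[1]
    f <- seq_len(nFrames)
    new("DriftTrace", frame = as.integer(f),
        dx = approx(centersF, dxw, xout = f, rule = 2)$y,
        dy = approx(centersF, dyw, xout = f, rule = 2)$y,
        window = as.integer(window), nAnchors = as.integer(nAnchors))
}

#' Subtract a drift trace from a localization table
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param trace a \linkS4class{DriftTrace} covering every frame present.
#' @return The corrected \linkS4class{LocalizationTable}; row order and all
#'   other columns unchanged.
#' @export
correctDrift <- function(table, trace) {
    d <- locData(table)
    if (!nrow(d)) return(table)
    if (max(d$frame) > length(trace@frame))
        stop("drift trace covers frames up to ", length(trace@frame),
             " but the table contains frame ", max(d$frame))
    d$x <- d$x - trace@dx[d$frame]
    d$y <- d$y - trace@dy[d$frame]
    initialize(table, data = d)
}

#' Convert a piecewise-linear drift path to a per-frame trace
#'
#' Useful to correct with a known (e.g. injected) path: correcting with the
#' exact injected path restores the original coordinates bit for bit.
#'
#' @param path data.frame(frame, dx, dy) of nodes in nm.
#' @param nFrames movie length in frames.
#' @return A \linkS4class{DriftTrace}.
#' @export
driftTraceFromPath <- function(path, nFrames) {
    pf <- pathToPerFrame(path, nFrames)
    new("DriftTrace", frame = pf$frame, dx = pf$dx, dy = pf$dy,
        window = 0L, nAnchors = 0L)
}
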