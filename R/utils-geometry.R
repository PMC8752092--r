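# Planar geometry helpers for synapse outlines: polygons with holes are
# represented as lists of rings (n x 2 matrices, nm); the first ring is the
# outer boundary, subsequent rings are perforations. Interior membership uses
# the even-odd rule, so holes are excluded automatically.

ringArea <- function(ring) {
    x <- ring[, 1]; y <- ring[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Net area (outer minus holes), nm^2.
ringsArea <- function(rings) {
    a <- vapply(rings, ringArea, numeric(1))
    a[1] - sum(a[-1])
}

ringsBBox <- function(rings) {
    xs <- unlist(lapply(rings, function(r) r[, 1]))
    ys <- unlist(lapply(rings, function(r) r[, 2]))
    c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

# Even-odd membership test, vectorized over query points.
pointInRings <- function(px, py, rings) {
    inside <- rep(FALSE, length(px))
    for (ring in rings) {
        x1 <- ring[, 1]; y1 <- ring[, 2]
        x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
        for (e in seq_along(x1)) {
            crosses <- (y1[e] > py) != (y2[e] > py)
            if (any(crosses)) {
                xint <- x1[e] + (py[crosses] - y1[e]) / (y2[e] - y1[e]) *
                    (x2[e] - x1[e])
                hit <- which(crosses)[px[crosses] < xint]
                inside[hit] <- !inside[hit]
            }
        }
    }
    inside
}

# Uniform sample of n points in the polygon interior (rejection sampling).
samplePointsInRings <- function(n, rings) {
    if (n == 0) return(matrix(numeric(0), 0, 2))
    bb <- ringsBBox(rings)
    out <- matrix(NA_real_, n, 2)
    got <- 0L
    area <- ringsArea(rings)
    boxArea <- (bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"])
    accept <- max(area / boxArea, 0.05)
    while (got < n) {
        m <- ceiling((n - got) / accept) + 16L
        px <- runif(m, bb["xmin"], bb["xmax"])
        py <- runif(m, bb["ymin"], bb["ymax"])
        ok <- pointInRings(px, py, rings)
        k <- min(sum(ok), n - got)
        if (k > 0) {
            idx <- which(ok)[seq_len(k)]
            out[got + seq_len(k), ] <- cbind(px[idx], py[idx])
            got <- got + k
        }
    }
    out
}

# Closed ellipse ring (counter-clockwise), rotated by theta.
ellipseRing <- function(cx, cy, a, b, theta = 0, n = 64L) {
    t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    x <- a * cos(t); y <- b * sin(t)
    cbind(cx + x * cos(theta) - y * sin(theta),
          cy + x * sin(theta) + y * cos(theta))
}

# Horizontal scanline at height y: sorted x-crossings paired into segments
# (even-odd rule; holes split segments).
scanlineSegments <- function(rings, y) {
    xs <- numeric(0)
    for (ring in rings) {
        x1 <- ring[, 1]; y1 <- ring[, 2]
        x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
        crosses <- (y1 > y) != (y2 > y)
        if (any(crosses)) {
            xs <- c(xs, x1[crosses] + (y - y1[crosses]) /
                        (y2[crosses] - y1[crosses]) *
                        (x2[crosses] - x1[crosses]))
        }
    }
    xs <- sort(xs)
    if (length(xs) < 2) return(numeric(0))
    n <- length(xs) %/% 2
    xs[2 * seq_len(n)] - xs[2 * seq_len(n) - 1]
}

# Max pairwise distance (Feret diameter) of a point set; uses the convex
# hull to stay O(h^2).
feretDiameter <- function(xy) {
    if (nrow(xy) < 2) return(0)
    h <- grDevices::chull(xy)
    pts <- xy[h, , drop = FALSE]
    if (nrow(pts) < 2) return(0)
    d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
    sqrt(max(d2))
}
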