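# Connected-component labeling (run-based union-find) and hole filling for
# binary masks. 8-connectivity for objects, 4-connectivity for background,
# the standard complementary pair.

labelComponents <- function(mask, connectivity = 8) {
    nr <- nrow(mask); nc <- ncol(mask)
    runs <- list(); nRuns <- 0L
    colRuns <- vector("list", nc)
    for (j in seq_len(nc)) {
        v <- mask[, j]
        if (!any(v)) { colRuns[[j]] <- integer(0); next }
        r <- rle(v)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        sel <- which(r$values)
        ids <- nRuns + seq_along(sel)
        nRuns <- nRuns + length(sel)
        colRuns[[j]] <- ids
        for (k in seq_along(sel)) {
            runs[[ids[k]]] <- c(j, starts[sel[k]], ends[sel[k]])
        }
    }
    if (nRuns == 0L) return(matrix(0L, nr, nc))
    parent <- seq_len(nRuns)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    slack <- if (connectivity == 8) 1L else 0L
    for (j in 2:max(nc, 2)) {
        if (j > nc) break
        a <- colRuns[[j - 1L]]; b <- colRuns[[j]]
        if (!length(a) || !length(b)) next
        for (ib in b) {
            rb <- runs[[ib]]
            for (ia in a) {
                ra <- runs[[ia]]
                if (ra[2] <= rb[3] + slack && rb[2] <= ra[3] + slack) {
                    pa <- find(ia); pb <- find(ib)
                    if (pa != pb) parent[pa] <- pb
                }
            }
        }
    }
    roots <- vapply(seq_len(nRuns), find, integer(1))
    lab <- match(roots, unique(roots))
    out <- matrix(0L, nr, nc)
    for (i in seq_len(nRuns)) {
        r <- runs[[i]]
        out[r[2]:r[3], r[1]] <- lab[i]
    }
    out
}

# Fill enclosed background holes of a labeled image with the enclosing
# object's label. Background components (4-connected) not touching the
# image border are holes; holes larger than maxPx pixels are kept open
# (genuine perforations rather than sampling speckle).
fillHoles <- function(lab, maxPx = Inf) {
    mask <- lab > 0L
    bg <- labelComponents(!mask, connectivity = 4)
    if (!any(bg > 0L)) return(lab)
    border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    holes <- setdiff(unique(bg[bg > 0L]), border)
    for (h in holes) {
        px <- which(bg == h, arr.ind = TRUE)
        if (nrow(px) > maxPx) next
        # label of any 4-neighbour object pixel
        cand <- integer(0)
        for (s in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
            ii <- px[, 1] + s[1]; jj <- px[, 2] + s[2]
            ok <- ii >= 1 & ii <= nrow(lab) & jj >= 1 & jj <= ncol(lab)
            cand <- c(cand, lab[cbind(ii[ok], jj[ok])])
        }
        cand <- cand[cand > 0L]
        if (length(cand)) lab[px] <- as.integer(names(
            sort(table(cand), decreasing = TRUE))[1])
    }
    lab
}

# Count boundary pixels of each label (pixels with a 4-neighbour outside
# their own label, or on the image edge).
boundaryCounts <- function(lab, nLabels) {
    nr <- nrow(lab); nc <- ncol(lab)
    padded <- matrix(0L, nr + 2L, nc + 2L)
    padded[2:(nr + 1L), 2:(nc + 1L)] <- lab
    core <- padded[2:(nr + 1L), 2:(nc + 1L)]
    isB <- core > 0L &
        (padded[1:nr, 2:(nc + 1L)] != core |
         padded[3:(nr + 2L), 2:(nc + 1L)] != core |
         padded[2:(nr + 1L), 1:nc] != core |
         padded[2:(nr + 1L), 3:(nc + 2L)] != core)
    tabulate(core[isB], nbins = nLabels)
}

# Disjoint-set union over point pairs (used for complex linkage).
unionFind <- function(n, pairs) {
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    if (NROW(pairs)) {
        for (k in seq_len(nrow(pairs))) {
            a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
            if (a != b) parent[a] <- b
        }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    match(roots, unique(roots))
}
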