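# Fourier ring correlation resolution estimation from two half-data
# reconstructions.

#' Fourier ring correlation and resolution estimate
#'
#' Splits a localization table into two halves (odd vs even frames by
#' default, mirroring the acquisition-level split; optionally a random
#' half-split), renders both halves on a common square grid, and computes
#' the correlation of their Fourier transforms per frequency ring:
#' \deqn{FRC(q) = Re \sum_q F_1 F_2^* / \sqrt{\sum_q |F_1|^2 \sum_q
#'   |F_2|^2}.}
#' The resolution is the reciprocal of the first frequency where the curve
#' (median-smoothed over 3 rings for crossing detection only) drops below
#' the threshold (1/7 by convention). If the curve never crosses, the
#' resolution is beyond the grid's Nyquist limit and reported as NA with
#' \code{limited = TRUE}. A pair of pre-rendered images can be supplied
#' instead of a table.
#'
#' @param x a \linkS4class{LocalizationTable}, or a list of two equal-size
#'   numeric matrices.
#' @param split "odd-even" (default) or "random".
#' @param config a \linkS4class{RenderConfig} used to render table halves.
#' @param threshold crossing threshold (default 1/7).
#' @param seed RNG seed for the random split.
#' @return An \linkS4class{FRCCurve}.
#' @export
computeFRC <- function(x, split = c("odd-even", "random"),
                       config = renderConfig(), threshold = 1 / 7,
                       seed = 1L) {
    split <- match.arg(split)
    px <- config@pixelSize
    if (is(x, "LocalizationTable")) {
        d <- locData(x)
        if (!nrow(d)) stop("empty localization table")
        sel <- if (split == "odd-even") d$frame %% 2 == 1 else {
            set.seed(seed)
            sample(c(TRUE, FALSE), nrow(d), replace = TRUE)
        }
        if (!any(sel) || all(sel))
            stop("one half of the split is empty")
        mk <- function(rows) {
            initialize(x, data = d[rows, , drop = FALSE])
        }
        dims <- pmax(ceiling(x@fieldSize / px), 1)
        n <- 2^ceiling(log2(max(dims)))
        img1 <- renderDensityMap(mk(sel), config, dims = c(n, n))
        img2 <- renderDensityMap(mk(!sel), config, dims = c(n, n))
    } else if (is.list(x) && length(x) == 2) {
        img1 <- x[[1]]; img2 <- x[[2]]
        if (!all(dim(img1) == dim(img2)))
            stop("the two images must have identical dimensions")
        if (sum(img1) == 0 || sum(img2) == 0)
            stop("one half-image is empty")
        n <- 2^ceiling(log2(max(dim(img1))))
        pad <- function(m) {
            out <- matrix(0, n, n)
            out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
            out
        }
        img1 <- pad(img1); img2 <- pad(img2)
    } else {
        stop("x must be a LocalizationTable or a list of two images")
    }
    n <- nrow(img1)
    f1 <- fft(img1); f2 <- fft(img2)
    k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    if (length(k) != n) k <- ifelse(seq_len(n) - 1 <= n / 2,
                                    seq_len(n) - 1, seq_len(n) - 1 - n)
    kr <- sqrt(outer(k^2, k^2, "+"))
    ring <- pmin(round(kr), n %/% 2) + 1L
    num <- Re(f1 * Conj(f2))
    d11 <- Mod(f1)^2
    d22 <- Mod(f2)^2
    sNum <- tapply(num, ring, sum)
    s11 <- tapply(d11, ring, sum)
    s22 <- tapply(d22, ring, sum)
    nr <- n %/% 2
    frc <- as.numeric(sNum[seq_len(nr)]) /
        sqrt(as.numeric(s11[seq_len(nr)]) * as.numeric(s22[seq_len(nr)]))
    frc[!is.finite(frc)] <- 0
    freq <- (seq_len(nr) - 1) / (n * px)
    sm <- if (nr >= 3) stats::runmed(frc, 3) else frc
    below <- which(sm < threshold & seq_len(nr) > 1)
    if (length(below)) {
        i <- below[1]
        # linear interpolation between the bracketing rings
        q0 <- freq[i - 1]; q1 <- freq[i]
        v0 <- sm[i - 1]; v1 <- sm[i]
        qc <- if (v0 != v1) q0 + (v0 - threshold) * (q1 - q0) / (v0 - v1)
              else q1
        res <- 1 / qc
        limited <- FALSE
    } else {
        res <- NA_real_
        limited <- TRUE
    }
    new("FRCCurve", freq = freq, frc = frc, threshold = threshold,
        resolution = res, limited = limited)
}
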