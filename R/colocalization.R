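# Two-channel co-localization: intensity correlation quotient (ICQ),
# per-synapse receptor-scaffold occupancy, and binding-site occupancy.

#' Intensity correlation quotient of two images
#'
#' The ICQ is the fraction of pixels whose mean-centered intensities in the
#' two channels covary positively, minus 0.5; it lies in [-0.5, +0.5], is
#' insensitive to absolute intensity scaling, and values around +0.3
#' indicate tight spatial correlation of two synaptic components. Pixels
#' with an exactly zero product are excluded from both numerator and
#' denominator so the bounds are attained exactly.
#'
#' @param imageA,imageB numeric matrices of identical dimensions.
#' @param mask optional logical matrix selecting the pixels to use
#'   (at least 2).
#' @return list with elements \code{value}, \code{nPixelsUsed} (pixels
#'   with non-zero product) and \code{nMasked} (pixels in the mask).
#' @examples
#' a <- matrix(runif(100), 10)
#' computeICQ(a, a)$value   # +0.5
#' @export
computeICQ <- function(imageA, imageB, mask = NULL) {
    if (!all(dim(imageA) == dim(imageB)))
        stop("images must have identical dimensions")
    if (is.null(mask)) mask <- matrix(TRUE, nrow(imageA), ncol(imageA))
    a <- imageA[mask]; b <- imageB[mask]
    if (length(a) < 2) stop("mask must select at least 2 pixels")
    if (max(a) == min(a) || max(b) == min(b))
        stop("ICQ undefined: an image is constant on the mask ",
             "(no intensity fluctuations to correlate)")
    prod <- (a - mean(a)) * (b - mean(b))
    used <- prod != 0
    if (!any(used)) stop("ICQ undefined: all centered products are zero")
    list(value = mean(prod[used] > 0) - 0.5,
         nPixelsUsed = sum(used), nMasked = length(a))
}

#' Per-synapse receptor-scaffold occupancy
#'
#' Integrates both channels over each synaptic cluster footprint and
#' reports the per-synapse intensity pair, their ratio, and the Spearman
#' rank correlation across synapses (equal receptor-scaffold occupancy
#' shows as a tight positive correlation independent of synapse size).
#'
#' @param clusterSet a \linkS4class{SynapticClusterSet} defining the
#'   footprints (from the receptor channel).
#' @param imageA,imageB registered channel images on the cluster set's
#'   pixel grid (e.g. receptor density map and scaffold reference).
#' @return list with \code{table} (id, intensityA, intensityB, ratio) and
#'   \code{spearman} (NA with a warning for fewer than 3 synapses).
#' @export
synapseOccupancy <- function(clusterSet, imageA, imageB) {
    if (!all(dim(imageA) == dim(imageB)))
        stop("images must have identical dimensions")
    fps <- clusterSet@footprints
    rows <- lapply(seq_along(fps), function(i) {
        fp <- fps[[i]]
        sel <- cbind(fp[, 1] + 1L, fp[, 2] + 1L)
        ok <- sel[, 1] >= 1 & sel[, 1] <= nrow(imageA) &
            sel[, 2] >= 1 & sel[, 2] <= ncol(imageA)
        ia <- sum(imageA[sel[ok, , drop = FALSE]])
        ib <- sum(imageB[sel[ok, , drop = FALSE]])
        data.frame(id = clusterSet@clusters$id[i], intensityA = ia,
                   intensityB = ib,
                   ratio = if (ib != 0) ia / ib else NA_real_)
    })
    tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(id = integer(0), intensityA = numeric(0),
                   intensityB = numeric(0), ratio = numeric(0))
    rho <- NA_real_
    if (nrow(tab) >= 3) {
        rho <- cor(tab$intensityA, tab$intensityB, method = "spearman")
    } else {
        warning("fewer than 3 synapses: correlation omitted")
    }
    list(table = tab, spearman = rho)
}

#' Binding-site occupancy from receptor and scaffold densities
#'
#' Each receptor engages \code{nBeta} scaffold binding sites, so the
#' occupied fraction is \code{nBeta * receptorDensity / scaffoldDensity};
#' with about 2000 receptors/um^2 against scaffold sites at up to
#' 9000/um^2 this is 4/9, i.e. close to half the binding sites.
#'
#' @param receptorDensity receptors per um^2.
#' @param scaffoldDensity scaffold molecules (binding sites) per um^2.
#' @param nBeta scaffold-binding subunits per receptor.
#' @return occupied fraction.
#' @examples
#' bindingSiteOccupancy(2000, 9000, 2)   # 4/9
#' @export
bindingSiteOccupancy <- function(receptorDensity, scaffoldDensity,
                                 nBeta = 2) {
    if (scaffoldDensity <= 0) stop("scaffoldDensity must be > 0")
    nBeta * receptorDensity / scaffoldDensity
}
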