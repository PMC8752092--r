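# Serial-section EM morphometry: postsynaptic area, segmentation index,
# and PALM-EM area correspondence.

sectionSegmentCounts <- function(stack) {
    vapply(stack@sections, function(s) sum(s > 0), integer(1))
}

#' Postsynaptic area from a serial-section stack
#'
#' The cumulative length of the postsynaptic profile over all sections
#' multiplied by the section thickness.
#'
#' @param stack a \linkS4class{SerialSectionStack}.
#' @return area in um^2.
#' @examples
#' emArea(serialSectionStack(list(400, 500, 600), thickness = 70))  # 0.105
#' @export
emArea <- function(stack) {
    validObject(stack)
    total <- sum(unlist(stack@sections))
    if (!length(stack@sections) || total <= 0)
        stop("stack has no non-empty sections; EM area undefined")
    total * stack@thickness / 1e6
}

#' Segmentation index of a postsynaptic specialization
#'
#' Counts interruptions of the postsynaptic site: in-plane gaps (a section
#' showing k profile segments contributes k - 1) plus z-axis interruptions
#' (each maximal run of empty sections strictly between non-empty sections
#' counts once, however many sections it spans). A macular synapse scores
#' 0. With \code{mergePersistent = TRUE}, a perforation persisting over
#' consecutive sections is counted once per run instead of once per
#' section.
#'
#' @param stack a \linkS4class{SerialSectionStack}.
#' @param mergePersistent logical (default FALSE).
#' @return integer index.
#' @examples
#' segmentationIndex(serialSectionStack(list(500, c(200, 250), 500)))  # 1
#' @export
segmentationIndex <- function(stack, mergePersistent = FALSE) {
    validObject(stack)
    nseg <- sectionSegmentCounts(stack)
    nonEmpty <- which(nseg > 0)
    if (!length(nonEmpty)) return(0L)
    core <- nseg[min(nonEmpty):max(nonEmpty)]
    extra <- pmax(core - 1L, 0L)
    inPlane <- if (mergePersistent) {
        r <- rle(extra > 0L)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        sum(vapply(which(r$values), function(i)
            max(extra[starts[i]:ends[i]]), integer(1)))
    } else {
        sum(extra)
    }
    zr <- rle(core == 0L)
    zGaps <- sum(zr$values)
    as.integer(inPlane + zGaps)
}

#' Compare a PALM area with the serial-section EM area
#'
#' PALM measures the 2D projection of the (often tilted) postsynaptic
#' surface, so the PALM/EM area ratio is at most 1 and equals cos(tilt)
#' for a planar synapse; when the tilt is known the corrected ratio
#' divides it out.
#'
#' @param palmArea PALM-measured area in um^2.
#' @param stack a \linkS4class{SerialSectionStack}.
#' @param tilt tilt in degrees; defaults to the stack's.
#' @return list with emArea, ratio, and correctedRatio (NA without tilt).
#' @examples
#' stk <- serialSectionStack(list(1000), tilt = 60)
#' comparePalmEm(0.07 * cos(pi / 3), stk)
#' @export
comparePalmEm <- function(palmArea, stack, tilt = stack@tilt) {
    if (palmArea <= 0) stop("palmArea must be > 0")
    ea <- emArea(stack)
    ratio <- palmArea / ea
    corrected <- if (!is.na(tilt)) ratio / cos(tilt * pi / 180)
                 else NA_real_
    list(emArea = ea, ratio = ratio, correctedRatio = corrected)
}
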