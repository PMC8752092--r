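# Population statistics and density-vs-area reports.

#' Summarize a population of values
#'
#' Order statistics use R's default linear-interpolation quantile
#' convention (type 7). The coefficient of variation is SD/mean.
#'
#' @param values numeric vector (n >= 1).
#' @param bins number of histogram bins.
#' @return list with n, median, q1, q3, mean, sd, cv, and histogram
#'   (breaks, counts).
#' @examples
#' summarizePopulation(c(1, 2, 3))
#' @export
summarizePopulation <- function(values, bins = 20) {
    values <- values[is.finite(values)]
    if (!length(values)) stop("no values to summarize")
    qs <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    m <- mean(values)
    s <- if (length(values) > 1) sd(values) else 0
    h <- graphics::hist(values, breaks = bins, plot = FALSE)
    list(n = length(values), median = qs[2], q1 = qs[1], q3 = qs[3],
         mean = m, sd = s, cv = if (m != 0) s / m else NA_real_,
         histogram = list(breaks = h$breaks, counts = h$counts))
}

#' Receptor density versus synapse area report
#'
#' Linear regression of density on area (with its 95\% confidence
#' interval), the Spearman rank correlation, and the coefficient of
#' variation of density within quantile-based area bins. On populations
#' with constant packing density, the slope is indistinguishable from zero
#' and |Spearman rho| is small: density is independent of synapse size.
#'
#' @param clusters data.frame with columns \code{area} and \code{density}
#'   (e.g. \code{clusterTable(countReceptors(...))}).
#' @param nBins number of quantile area bins for the CV profile.
#' @return list with regression (slope, intercept, slope CI), spearman,
#'   and a per-bin data.frame (areaMid, n, cv).
#' @export
densityVsArea <- function(clusters, nBins = 5) {
    if (nrow(clusters) < 3)
        stop("at least 3 clusters are required")
    fit <- lm(density ~ area, data = clusters)
    ci <- confint(fit)["area", ]
    rho <- cor(clusters$area, clusters$density, method = "spearman")
    br <- unique(quantile(clusters$area, seq(0, 1, length.out = nBins + 1)))
    bin <- cut(clusters$area, br, include.lowest = TRUE)
    cvs <- vapply(split(clusters$density, bin), function(v) {
        if (length(v) > 1 && mean(v) != 0) sd(v) / mean(v) else NA_real_
    }, numeric(1))
    mids <- vapply(split(clusters$area, bin), mean, numeric(1))
    ns <- vapply(split(clusters$area, bin), length, integer(1))
    list(regression = list(slope = unname(coef(fit)[2]),
                           intercept = unname(coef(fit)[1]),
                           slopeCI = unname(ci)),
         spearman = rho,
         bins = data.frame(areaMid = mids, n = ns, cv = cvs,
                           row.names = NULL))
}

#' Match segmented clusters to ground-truth synapses
#'
#' Uses the per-detection ground-truth linkage of a synthetic field:
#' each cluster is attributed to the synapse contributing the majority of
#' its member detections. Reports the match, its purity, and the truth for
#' parameter-recovery analysis.
#'
#' @param clusterSet a \linkS4class{SynapticClusterSet} segmented from the
#'   field's (possibly drift-corrected) table.
#' @param field the \linkS4class{SyntheticField} the table came from.
#' @return data.frame: clusterId, synapseId, purity, trueCount, trueArea.
#' @export
matchClustersToSynapses <- function(clusterSet, field) {
    link <- field@linkage
    syn <- field@population@synapses
    ids <- vapply(syn, `[[`, integer(1), "id")
    rows <- lapply(seq_len(nrow(clusterSet@clusters)), function(i) {
        mem <- which(clusterSet@assignment == clusterSet@clusters$id[i])
        src <- link$sourceId[mem][link$source[mem] == "synapse"]
        if (!length(src)) {
            return(data.frame(clusterId = clusterSet@clusters$id[i],
                              synapseId = NA_integer_, purity = 0,
                              trueCount = NA_real_, trueArea = NA_real_))
        }
        tab <- sort(table(src), decreasing = TRUE)
        sid <- as.integer(names(tab)[1])
        j <- match(sid, ids)
        data.frame(clusterId = clusterSet@clusters$id[i], synapseId = sid,
                   purity = as.numeric(tab[1]) / length(mem),
                   trueCount = syn[[j]]$trueCount,
                   trueArea = syn[[j]]$trueArea)
    })
    do.call(rbind, rows)
}
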