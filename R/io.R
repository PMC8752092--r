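# Plain-text interchange: localization CSV, cluster CSV, calibration and
# serial-section JSON, TIFF images.

#' Write / read a localization table as CSV
#'
#' Dialect: header \code{frame,x_nm,y_nm,intensity,sigma_nm}, frame
#' 1-based, coordinates in nm with origin at the field corner.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param path file path.
#' @return \code{writeLocalizations} returns the path invisibly;
#'   \code{readLocalizations} returns a \linkS4class{LocalizationTable}.
#' @export
writeLocalizations <- function(table, path) {
    d <- locData(table)
    out <- data.frame(frame = d$frame, x_nm = d$x, y_nm = d$y,
                      intensity = d$intensity, sigma_nm = d$sigma)
    data.table::fwrite(out, path)
    invisible(path)
}

#' @rdname writeLocalizations
#' @param fieldSize field extent in nm; inferred from the data if NULL.
#' @param nFrames movie length; inferred if NULL.
#' @export
readLocalizations <- function(path, fieldSize = NULL, nFrames = NULL) {
    d <- as.data.frame(data.table::fread(path))
    need <- c("frame", "x_nm", "y_nm", "intensity", "sigma_nm")
    if (!all(need %in% names(d)))
        stop("localization CSV must have columns: ",
             paste(need, collapse = ", "))
    if (is.null(fieldSize)) fieldSize <- c(max(d$x_nm), max(d$y_nm))
    if (is.null(nFrames)) nFrames <- max(d$frame)
    new("LocalizationTable",
        data = data.frame(frame = as.integer(d$frame), x = d$x_nm,
                          y = d$y_nm, intensity = d$intensity,
                          sigma = d$sigma_nm),
        fieldSize = as.numeric(fieldSize), nFrames = as.integer(nFrames))
}

#' Write a cluster table as CSV
#'
#' Columns: id, n_detections, extent_nm, area_um2, centroid_x_nm,
#' centroid_y_nm, plus receptors and density_per_um2 once counted.
#'
#' @param clusterSet a \linkS4class{SynapticClusterSet}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeClusters <- function(clusterSet, path) {
    cl <- clusterSet@clusters
    out <- data.frame(id = cl$id, n_detections = cl$nDetections,
                      extent_nm = cl$extent, area_um2 = cl$area,
                      centroid_x_nm = cl$centroidX,
                      centroid_y_nm = cl$centroidY)
    if ("receptors" %in% names(cl)) {
        out$receptors <- cl$receptors
        out$density_per_um2 <- cl$density
    }
    data.table::fwrite(out, path)
    invisible(path)
}

#' Write a photophysics calibration as JSON
#'
#' @param calib a \linkS4class{PhotophysicsCalibration}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeCalibration <- function(calib, path) {
    jsonlite::write_json(list(
        N1 = calib@N1, N2 = calib@N2, n_excluded = calib@nExcluded,
        n_complexes = calib@nComplexes, pdet_raw = calib@pdetRaw,
        mean_detections_per_burst = calib@meanDetectionsPerBurst,
        detections_per_fluorophore = calib@detectionsPerFluor,
        pdet = calib@pDet, q = calib@q, p_collision = calib@pCollision,
        model = calib@model), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Write / read a serial-section stack as JSON
#'
#' @param stack a \linkS4class{SerialSectionStack}.
#' @param path file path.
#' @return \code{writeSerialSectionStack} returns the path invisibly;
#'   \code{readSerialSectionStack} returns the stack.
#' @export
writeSerialSectionStack <- function(stack, path) {
    jsonlite::write_json(list(
        thickness_nm = stack@thickness, tilt_deg = stack@tilt,
        palm_area_um2 = stack@palmArea,
        sections = lapply(stack@sections, as.numeric)),
        path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    invisible(path)
}

#' @rdname writeSerialSectionStack
#' @export
readSerialSectionStack <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = FALSE)
    sections <- lapply(j$sections, function(s) unlist(s, use.names = FALSE))
    sections <- lapply(sections, function(s) if (is.null(s)) numeric(0)
                       else as.numeric(s))
    serialSectionStack(sections, thickness = j$thickness_nm,
                       tilt = if (is.null(j$tilt_deg)) NA_real_
                              else j$tilt_deg,
                       palmArea = if (is.null(j$palm_area_um2)) NA_real_
                                  else j$palm_area_um2)
}

#' Write an image matrix as TIFF
#'
#' Density maps are written as 32-bit float TIFF with a fixed storage
#' scale of 1/65536 (counts up to 2^24 round-trip exactly in the float32
#' mantissa); \code{readImageTIFF} multiplies the scale back. Reference
#' channels are written as 16-bit unsigned integer (values clipped to
#' [0, 65535]).
#'
#' @param img numeric matrix.
#' @param path file path.
#' @param bits 32 (float) or 16 (unsigned integer).
#' @return the path, invisibly.
#' @export
writeImageTIFF <- function(img, path, bits = 32) {
    if (bits == 32) {
        tiff::writeTIFF(pmax(img, 0) / 65536, path,
                        bits.per.sample = 32L, reduce = FALSE)
    } else {
        tiff::writeTIFF(pmax(pmin(img / 65535, 1), 0), path,
                        bits.per.sample = 16L)
    }
    invisible(path)
}

#' @rdname writeImageTIFF
#' @param scaled if TRUE (default) undo the fixed 1/65536 storage scale
#'   used for 32-bit images.
#' @export
readImageTIFF <- function(path, scaled = TRUE) {
    img <- tiff::readTIFF(path, as.is = FALSE, info = TRUE)
    bps <- attr(img, "bits.per.sample")
    if (length(dim(img)) > 2) img <- img[, , 1]
    img <- matrix(as.numeric(img), nrow(img), ncol(img))
    if (scaled && !is.null(bps) && bps == 32L) img <- img * 65536
    img
}
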