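MAX_DN <- 65535

#' Read a time-lapse movie from TIFF
#'
#' Accepts a multi-page TIFF or a directory of numbered single-page
#' TIFFs. Pixel values are returned on the 16-bit digital-number scale
#' (0..65535). Calibration precedence is explicit arguments first, then
#' TIFF resolution metadata (for the pixel size), then an error: frame
#' interval is never stored in plain TIFF, so it must always be supplied.
#' When an explicit argument overrides conflicting metadata a warning is
#' emitted.
#'
#' @param path file or directory path.
#' @param frameInterval seconds per frame (required).
#' @param pixelSize micrometres per pixel; if `NULL`, taken from TIFF
#'   x-resolution metadata when present (assumed dots per centimetre).
#' @return a [MovieStack-class].
#' @seealso [writeMovie()]
#' @export
readMovie <- function(path, frameInterval = NULL, pixelSize = NULL) {
    if (is.null(frameInterval))
        stop("frameInterval must be supplied (not stored in TIFF)")
    if (dir.exists(path)) {
        files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
        if (length(files) < 2L) stop("need >= 2 frames")
        pages <- lapply(files, function(f) tiff::readTIFF(f, info = TRUE))
    } else {
        pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
        if (!is.list(pages)) pages <- list(pages)
    }
    if (length(pages) < 2L) stop("need >= 2 frames")
    dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
        stop("mixed frame shapes in ", path)
    metaPx <- NA_real_
    xres <- attr(pages[[1L]], "x.resolution")
    if (!is.null(xres) && is.finite(xres) && xres > 0)
        metaPx <- 1e4 / xres   # dots/cm -> um/pixel
    if (is.null(pixelSize)) {
        if (!is.finite(metaPx))
            stop("pixelSize not supplied and absent from TIFF metadata")
        pixelSize <- metaPx
    } else if (is.finite(metaPx) && abs(metaPx - pixelSize) > 1e-6 * pixelSize) {
        warning(sprintf(
            "explicit pixelSize %.6g um overrides TIFF metadata %.6g um",
            pixelSize, metaPx))
    }
    a <- array(0, dim = c(dims[1, 1], dims[2, 1], length(pages)))
    for (i in seq_along(pages)) a[, , i] <- round(pages[[i]] * MAX_DN)
    MovieStack(a, frameInterval, pixelSize)
}

#' Write a movie as 16-bit multi-page TIFF
#'
#' Intensities are rounded and clamped to 0..65535; a stack whose values
#' already lie on that integer grid round-trips losslessly through
#' [readMovie()]. The pixel size is embedded as TIFF resolution metadata.
#'
#' @param movie a [MovieStack-class].
#' @param path output file path.
#' @param overwrite allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
writeMovie <- function(movie, path, overwrite = FALSE) {
    stopifnot(is(movie, "MovieStack"))
    if (file.exists(path) && !overwrite)
        stop("refusing to overwrite ", path, " (set overwrite = TRUE)")
    a <- pmin(pmax(round(movie@frames), 0), MAX_DN) / MAX_DN
    pages <- lapply(seq_len(dim(a)[3L]), function(i) a[, , i])
    tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                    reduce = TRUE,
                    compression = "none")
    invisible(path)
}

#' Write / read a boolean mask as 8-bit TIFF
#'
#' @param mask logical matrix.
#' @param path file path.
#' @param overwrite allow replacing an existing file.
#' @return `writeMask`: `path` invisibly; `readMask`: a logical matrix.
#' @export
writeMask <- function(mask, path, overwrite = FALSE) {
    if (file.exists(path) && !overwrite)
        stop("refusing to overwrite ", path, " (set overwrite = TRUE)")
    tiff::writeTIFF((mask * 1) + 0, path, bits.per.sample = 8L)
    invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
    m <- tiff::readTIFF(path)
    m > 0.5
}

#' Export a flow field as CSV
#'
#' One row per interrogation window with columns `x`, `y` (window centre,
#' pixels), `u`, `v` (pixels per frame pair), `speed_um_s`, `quality`,
#' `n_pairs`.
#'
#' @param field a [FlowField-class].
#' @param path file path (`NULL` returns the data.frame only).
#' @param overwrite allow replacing an existing file.
#' @return the exported data.frame, invisibly when written.
#' @export
writeFlowFieldCSV <- function(field, path = NULL, overwrite = FALSE) {
    stopifnot(is(field, "FlowField"))
    df <- data.frame(
        x = rep(field@x, each = length(field@y)),
        y = rep(field@y, times = length(field@x)),
        u = as.vector(field@u), v = as.vector(field@v),
        speed_um_s = as.vector(field@speed),
        quality = as.vector(field@quality),
        n_pairs = as.vector(field@nValidPairs))
    if (is.null(path)) return(df)
    if (file.exists(path) && !overwrite)
        stop("refusing to overwrite ", path, " (set overwrite = TRUE)")
    utils::write.csv(df, path, row.names = FALSE)
    invisible(df)
}

#' Export / import tracks as CSV
#'
#' Columns `track_id`, `frame`, `x_px`, `y_px`; an empty track set yields
#' a header-only file.
#'
#' @param x a [TrackSet-class] or a ground-truth tracks data.frame.
#' @param path file path.
#' @param overwrite allow replacing an existing file.
#' @return `writeTracksCSV`: the data.frame invisibly; `readTracksCSV`:
#'   a tracks data.frame with columns `track_id`, `frame`, `x`, `y`.
#' @export
writeTracksCSV <- function(x, path, overwrite = FALSE) {
    if (file.exists(path) && !overwrite)
        stop("refusing to overwrite ", path, " (set overwrite = TRUE)")
    tr <- if (is(x, "TrackSet")) x@tracks else x
    df <- data.frame(track_id = tr$track_id, frame = tr$frame,
                     x_px = tr$x, y_px = tr$y)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(df)
}

#' @rdname writeTracksCSV
#' @export
readTracksCSV <- function(path) {
    df <- utils::read.csv(path)
    data.frame(track_id = df$track_id, frame = df$frame,
               x = df$x_px, y = df$y_px)
}

#' Tidy per-movie metric rows
#'
#' Builds rows of the package-wide long metrics table: one row per
#' (movie, metric) with columns `movie_id`, `group`, `pipeline`,
#' `metric`, `value`.
#'
#' @param movieId specimen or movie identifier.
#' @param group experimental group label.
#' @param pipeline pipeline name.
#' @param metrics named numeric vector of metric values.
#' @return data.frame in long form.
#' @export
metricsRows <- function(movieId, group, pipeline, metrics) {
    data.frame(movie_id = movieId, group = group, pipeline = pipeline,
               metric = names(metrics), value = as.numeric(metrics),
               row.names = NULL)
}

#' Build a run manifest
#'
#' Records input paths, pipeline name and package version, all parameter
#' values, the seed, and md5 checksums of the output files, so every
#' reported metric is traceable to exactly one manifest.
#'
#' @param inputs character vector of input paths.
#' @param pipeline pipeline name.
#' @param params named list of parameter values.
#' @param seed integer seed (or `NA`).
#' @param outputs character vector of output file paths to checksum.
#' @return a list with class `ciliaflow_manifest`.
#' @export
runManifest <- function(inputs, pipeline, params = list(), seed = NA_integer_,
                        outputs = character()) {
    sums <- if (length(outputs)) as.list(tools::md5sum(outputs)) else list()
    structure(list(
        inputs = as.character(inputs),
        pipeline = pipeline,
        version = as.character(utils::packageVersion("ciliaflow")),
        params = params,
        seed = seed,
        output_checksums = sums), class = "ciliaflow_manifest")
}

#' Write pipeline outputs to a directory
#'
#' Dispatches on the classes of `results` entries: [FlowField-class] and
#' tracks become CSV, logical masks become TIFF, data.frames become CSV,
#' and the manifest is written as JSON. Existing files are never
#' overwritten unless `overwrite = TRUE`.
#'
#' @param results named list of result objects.
#' @param outDir output directory (created if needed).
#' @param manifest optional [runManifest()] list; output checksums are
#'   filled in after writing.
#' @param overwrite allow replacing existing files.
#' @return character vector of files written, invisibly.
#' @export
writeOutputs <- function(results, outDir, manifest = NULL, overwrite = FALSE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    written <- character()
    for (nm in names(results)) {
        obj <- results[[nm]]
        if (is(obj, "FlowField")) {
            p <- file.path(outDir, paste0(nm, ".csv"))
            writeFlowFieldCSV(obj, p, overwrite = overwrite)
        } else if (is(obj, "TrackSet")) {
            p <- file.path(outDir, paste0(nm, ".csv"))
            writeTracksCSV(obj, p, overwrite = overwrite)
        } else if (is.matrix(obj) && is.logical(obj)) {
            p <- file.path(outDir, paste0(nm, ".tif"))
            writeMask(obj, p, overwrite = overwrite)
        } else if (is.data.frame(obj)) {
            p <- file.path(outDir, paste0(nm, ".csv"))
            if (file.exists(p) && !overwrite)
                stop("refusing to overwrite ", p, " (set overwrite = TRUE)")
            utils::write.csv(obj, p, row.names = FALSE)
        } else if (is(obj, "MovieStack")) {
            p <- file.path(outDir, paste0(nm, ".tif"))
            writeMovie(obj, p, overwrite = overwrite)
        } else {
            stop("no writer for result '", nm, "' of class ", class(obj)[1L])
        }
        written <- c(written, p)
    }
    if (!is.null(manifest)) {
        manifest$output_checksums <- as.list(tools::md5sum(written))
        p <- file.path(outDir, "manifest.json")
        if (file.exists(p) && !overwrite)
            stop("refusing to overwrite ", p, " (set overwrite = TRUE)")
        jsonlite::write_json(unclass(manifest), p, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
        written <- c(written, p)
    }
    invisible(written)
}
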