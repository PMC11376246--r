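#' Construct a MovieStack
#'
#' @param frames numeric H x W x T array of nonnegative intensities.
#' @param frameInterval seconds per frame step.
#' @param pixelSize micrometres per pixel.
#' @return a [MovieStack-class].
#' @examples
#' mv <- MovieStack(array(runif(32 * 32 * 3), c(32, 32, 3)),
#'                  frameInterval = 0.1, pixelSize = 0.5)
#' @rdname MovieStack-class
#' @export
MovieStack <- function(frames, frameInterval, pixelSize) {
    new("MovieStack", frames = frames,
        frameInterval = as.numeric(frameInterval),
        pixelSize = as.numeric(pixelSize))
}

#' @rdname MovieStack-class
#' @export
setMethod("frames", "MovieStack", function(x) x@frames)

#' @rdname MovieStack-class
#' @export
setMethod("nFrames", "MovieStack", function(x) dim(x@frames)[3L])

#' @rdname MovieStack-class
#' @export
setMethod("frameInterval", "MovieStack", function(x) x@frameInterval)

#' @rdname MovieStack-class
#' @export
setMethod("pixelSize", "MovieStack", function(x) x@pixelSize)

#' @rdname MovieStack-class
#' @export
setMethod("dim", "MovieStack", function(x) dim(x@frames))

#' Extract one frame as a matrix
#'
#' @param x a [MovieStack-class].
#' @param i frame index.
#' @return numeric H x W matrix.
#' @export
getFrame <- function(x, i) {
    stopifnot(is(x, "MovieStack"), i >= 1L, i <= nFrames(x))
    x@frames[, , i]
}

setMethod("show", "MovieStack", function(object) {
    d <- dim(object@frames)
    cat("MovieStack:", d[3L], "frames of", d[1L], "x", d[2L], "px\n")
    cat(sprintf("  frame interval %.4g s (%.3g s total), pixel size %.4g um\n",
                object@frameInterval, object@frameInterval * (d[3L] - 1L),
                object@pixelSize))
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(object@frames), max(object@frames)))
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@imageSize[1L], "x", object@imageSize[2L], "px,",
        object@nFrames, "frames,", object@nBeads, "beads\n")
    cat(sprintf("  patches %d x %d, active %.2f, coherence %.2f, mean speed %.3g um/s\n",
                object@patchGrid[1L], object@patchGrid[2L],
                object@activeFraction, object@coherence, object@meanSpeed))
    cat(sprintf("  drift (%.3g, %.3g) um/s, noise SD %.3g, seed %d\n",
                object@driftVelocity[1L], object@driftVelocity[2L],
                object@noiseSD, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", sum(object@activeMask), "of",
        length(object@activeMask), "patches active;",
        length(unique(object@tracks$track_id)), "true tracks\n")
})
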