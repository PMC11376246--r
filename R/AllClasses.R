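#' @import methods
NULL

#' Simulation configuration for synthetic bead movies
#'
#' A validated parameter container describing one synthetic acquisition:
#' geometry and calibration of the camera, the bead population, the
#' piecewise-constant flow field driving the beads, and the sensor model.
#' Defaults mirror a typical transport-assay acquisition (30 s at 10
#' frames per second) on a circular culture insert.
#'
#' @slot imageSize integer(2), frame height and width in pixels.
#' @slot nFrames integer(1), number of frames (>= 2).
#' @slot frameInterval numeric(1), seconds between frames.
#' @slot pixelSize numeric(1), micrometres per pixel.
#' @slot nBeads integer(1), number of tracer beads seeded.
#' @slot beadSigma numeric(1), Gaussian spot width (pixels).
#' @slot beadAmplitude numeric(1), peak intensity added by one bead.
#' @slot patchGrid integer(2), rows x columns of flow-field patches; the
#'   image size must be divisible by the grid.
#' @slot activeFraction numeric(1) in \[0, 1\], fraction of patches with
#'   nonzero flow.
#' @slot meanSpeed numeric(1), mean bead speed in active patches (um/s).
#' @slot speedCV numeric(1), coefficient of variation of per-patch speed.
#' @slot coherence numeric(1) in \[0, 1\]; with this probability an active
#'   patch takes the shared global direction, otherwise an independent
#'   uniform direction on \[0, 2*pi).
#' @slot flowDirection numeric(1), the shared global direction in radians,
#'   or `NA` to draw it at random.
#' @slot driftVelocity numeric(2), whole-frame translation (um/s), x then y.
#' @slot backgroundLevel numeric(1), constant background intensity.
#' @slot noiseSD numeric(1), additive Gaussian sensor noise SD.
#' @slot diffusionSD numeric(1), per-frame Brownian jitter SD in pixels
#'   (0 by default so kinematic oracles are exact).
#' @slot minSeparation numeric(1), minimum initial distance between beads
#'   in pixels (0 disables the constraint).
#' @slot fovRadiusFraction numeric(1) in \[0, 1\], circular field-of-view
#'   radius relative to half the shorter image side.
#' @slot seed integer(1), RNG seed; equal configurations give bit-identical
#'   movies and ground truth.
#' @seealso [simConfig()], [simulateBeadMovie()]
#' @export
setClass("SimConfig", representation(
    imageSize = "integer",
    nFrames = "integer",
    frameInterval = "numeric",
    pixelSize = "numeric",
    nBeads = "integer",
    beadSigma = "numeric",
    beadAmplitude = "numeric",
    patchGrid = "integer",
    activeFraction = "numeric",
    meanSpeed = "numeric",
    speedCV = "numeric",
    coherence = "numeric",
    flowDirection = "numeric",
    driftVelocity = "numeric",
    backgroundLevel = "numeric",
    noiseSD = "numeric",
    diffusionSD = "numeric",
    minSeparation = "numeric",
    fovRadiusFraction = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    in01 <- function(x) is.finite(x) && x >= 0 && x <= 1
    if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
        msg <- c(msg, "imageSize must be two integers >= 8")
    if (object@nFrames < 2L)
        msg <- c(msg, "nFrames must be >= 2")
    if (!(object@frameInterval > 0) || !(object@pixelSize > 0))
        msg <- c(msg, "frameInterval and pixelSize must be > 0")
    if (object@nBeads < 0L) msg <- c(msg, "nBeads must be >= 0")
    if (!(object@beadSigma > 0)) msg <- c(msg, "beadSigma must be > 0")
    if (length(object@patchGrid) != 2L || any(object@patchGrid < 1L))
        msg <- c(msg, "patchGrid must be two positive integers")
    else if (any(object@patchGrid > object@imageSize))
        msg <- c(msg, "patchGrid cannot exceed imageSize")
    else if (any(object@imageSize %% object@patchGrid != 0L))
        msg <- c(msg, "imageSize must be divisible by patchGrid")
    if (!in01(object@activeFraction)) msg <- c(msg, "activeFraction must lie in [0, 1]")
    if (!in01(object@coherence)) msg <- c(msg, "coherence must lie in [0, 1]")
    if (!in01(object@fovRadiusFraction)) msg <- c(msg, "fovRadiusFraction must lie in [0, 1]")
    if (!(object@meanSpeed >= 0)) msg <- c(msg, "meanSpeed must be >= 0")
    if (object@speedCV < 0 || object@noiseSD < 0 || object@diffusionSD < 0 ||
        object@minSeparation < 0)
        msg <- c(msg, "speedCV, noiseSD, diffusionSD, minSeparation must be >= 0")
    if (length(object@driftVelocity) != 2L || any(!is.finite(object@driftVelocity)))
        msg <- c(msg, "driftVelocity must be a finite 2-vector")
    if (length(msg)) msg else TRUE
})

#' Ground truth emitted alongside a simulated movie
#'
#' @slot activeMask logical matrix at patch resolution (rows x cols of
#'   the patch grid); `TRUE` where the patch carries flow.
#' @slot directionField numeric matrix of flow directions (radians),
#'   `NA` where the patch is inactive.
#' @slot speedField numeric matrix of patch speeds (um/s), 0 where inactive.
#' @slot tracks data.frame with columns `track_id`, `frame`, `x`, `y`
#'   (pixel coordinates, 1-based, x = column, y = row). A bead that wraps
#'   within its patch or leaves the frame ends its track; a wrap starts a
#'   new track id.
#' @slot driftVelocity numeric(2), um/s.
#' @slot coherence numeric(1), as configured.
#' @export
setClass("GroundTruth", representation(
    activeMask = "matrix",
    directionField = "matrix",
    speedField = "matrix",
    tracks = "data.frame",
    driftVelocity = "numeric",
    coherence = "numeric"
))

setValidity("GroundTruth", function(object) {
    msg <- character()
    if (!identical(dim(object@activeMask), dim(object@directionField)))
        msg <- c(msg, "activeMask and directionField must share dimensions")
    if (any(object@activeMask != is.finite(object@directionField)))
        msg <- c(msg, "directionField must be defined exactly where activeMask is TRUE")
    if (nrow(object@tracks)) {
        sp <- split(object@tracks$frame, object@tracks$track_id)
        if (any(vapply(sp, function(f) any(diff(f) != 1L), logical(1))))
            msg <- c(msg, "track frames must strictly increase with no gaps")
    }
    if (length(msg)) msg else TRUE
})

#' A calibrated time-lapse intensity stack
#'
#' The common input of all pipelines: a height x width x frames array of
#' nonnegative intensities with its physical calibration. Pixel
#' coordinates are 1-based throughout the package, with x indexing
#' columns and y indexing rows (top-left origin), matching R's native
#' matrix convention.
#'
#' @slot frames numeric array, dim = c(height, width, nFrames).
#' @slot frameInterval numeric(1), seconds per frame step.
#' @slot pixelSize numeric(1), micrometres per pixel.
#' @seealso [readMovie()], [writeMovie()]
#' @export
setClass("MovieStack", representation(
    frames = "array",
    frameInterval = "numeric",
    pixelSize = "numeric"
))

setValidity("MovieStack", function(object) {
    d <- dim(object@frames)
    msg <- character()
    if (length(d) != 3L) msg <- c(msg, "frames must be a 3D array (H x W x T)")
    else if (d[3L] < 2L) msg <- c(msg, "need >= 2 frames")
    if (!(object@frameInterval > 0)) msg <- c(msg, "frameInterval must be > 0")
    if (!(object@pixelSize > 0)) msg <- c(msg, "pixelSize must be > 0")
    if (anyNA(object@frames) || any(object@frames < 0))
        msg <- c(msg, "frame intensities must be nonnegative and finite")
    if (length(msg)) msg else TRUE
})

#' A per-window flow velocity field
#'
#' One displacement vector per interrogation window, obtained by
#' normalized cross-correlation between frame pairs and averaged over
#' time as a vector mean, so incoherent jitter cancels while directed
#' transport survives.
#'
#' @slot x,y numeric vectors of window-centre coordinates (pixels;
#'   x = column centres, y = row centres).
#' @slot u,v numeric matrices (length(y) x length(x)) of mean displacement
#'   per frame pair (pixels), along +x and +y (downwards).
#' @slot speed numeric matrix, time-averaged window speed in um/s:
#'   `sqrt(u^2+v^2) * pixelSize / (frameInterval * pairSpacing)`.
#' @slot quality numeric matrix, median first-to-second correlation peak
#'   ratio across frame pairs; `NA` where no pair yielded a valid peak.
#' @slot nullSpeed numeric matrix, um/s: magnitude of the alternating-sign
#'   (Nyquist) mean of the same per-pair displacements. Coherent transport
#'   cancels in this statistic while frame-to-frame jitter survives, so it
#'   samples the no-transport null used for the noise floor.
#' @slot nValidPairs integer matrix, frame pairs contributing per window.
#' @slot windowSize,overlap,pairSpacing PIV geometry parameters.
#' @slot pixelSize,frameInterval calibration copied from the movie.
#' @export
setClass("FlowField", representation(
    x = "numeric", y = "numeric",
    u = "matrix", v = "matrix",
    speed = "matrix", quality = "matrix",
    nullSpeed = "matrix",
    nValidPairs = "matrix",
    windowSize = "integer", overlap = "numeric", pairSpacing = "integer",
    pixelSize = "numeric", frameInterval = "numeric"
))

setValidity("FlowField", function(object) {
    d <- c(length(object@y), length(object@x))
    ok <- identical(dim(object@u), d) && identical(dim(object@v), d) &&
        identical(dim(object@speed), d) && identical(dim(object@quality), d)
    if (!ok) return("u, v, speed, quality must be length(y) x length(x) matrices")
    if (any(object@speed < 0, na.rm = TRUE)) return("speeds must be >= 0")
    TRUE
})

#' Result of the PIV (flow-field) quantification pipeline
#'
#' @slot field the [FlowField-class] the classification is based on.
#' @slot fovMask logical H x W raster, circular field of view.
#' @slot activeMask logical window matrix: in-FOV, valid correlation, and
#'   time-averaged speed above the noise floor.
#' @slot aboveThresholdMask logical window matrix, subset of `activeMask`
#'   with speed above the control-derived threshold.
#' @slot percentActive numeric(1), percent of scoreable in-FOV windows active.
#' @slot percentAboveThreshold numeric(1), percent above the speed threshold.
#' @slot thresholdSpeed numeric(1), um/s (`NA` if none applied).
#' @slot noiseFloor numeric(1), um/s speed floor used for "active".
#' @export
setClass("CambridgeResult", representation(
    field = "FlowField",
    fovMask = "matrix",
    activeMask = "matrix",
    aboveThresholdMask = "matrix",
    percentActive = "numeric",
    percentAboveThreshold = "numeric",
    thresholdSpeed = "numeric",
    noiseFloor = "numeric"
))

setValidity("CambridgeResult", function(object) {
    msg <- character()
    if (any(object@aboveThresholdMask & !object@activeMask))
        msg <- c(msg, "aboveThresholdMask must be a subset of activeMask")
    pa <- object@percentActive; pt <- object@percentAboveThreshold
    if (is.finite(pa) && (pa < 0 || pa > 100)) msg <- c(msg, "percentActive out of [0, 100]")
    if (is.finite(pt) && is.finite(pa) && pt > pa + 1e-9)
        msg <- c(msg, "percentAboveThreshold cannot exceed percentActive")
    if (length(msg)) msg else TRUE
})

#' Result of the moving/coordinated region pipeline
#'
#' @slot movingMask logical H x W raster of pixels whose intensity changes
#'   over the movie above a data-driven threshold.
#' @slot fovMask logical H x W raster.
#' @slot blockSize integer(1), region block size in pixels.
#' @slot blockMoving logical block matrix (>= 50 percent of block pixels moving).
#' @slot blockDirections numeric block matrix of flow directions (radians),
#'   `NA` where not moving or correlation invalid.
#' @slot blockAlignment numeric block matrix of local mean resultant length.
#' @slot coordinatedBlocks logical block matrix.
#' @slot movingFraction numeric(1), percent of in-FOV area moving.
#' @slot coordinatedFraction numeric(1), percent of in-FOV area moving and
#'   coordinated.
#' @slot coordinatedOfMoving numeric(1), percent of moving area coordinated.
#' @export
setClass("RegionMasks", representation(
    movingMask = "matrix",
    fovMask = "matrix",
    blockSize = "integer",
    blockMoving = "matrix",
    blockDirections = "matrix",
    blockAlignment = "matrix",
    coordinatedBlocks = "matrix",
    movingFraction = "numeric",
    coordinatedFraction = "numeric",
    coordinatedOfMoving = "numeric"
))

setValidity("RegionMasks", function(object) {
    msg <- character()
    if (any(object@coordinatedBlocks & !object@blockMoving))
        msg <- c(msg, "coordinated blocks must be moving blocks")
    fr <- c(object@movingFraction, object@coordinatedFraction)
    if (any(is.finite(fr) & (fr < 0 | fr > 100)))
        msg <- c(msg, "fractions must lie in [0, 100]")
    if (is.finite(object@coordinatedFraction) && is.finite(object@movingFraction) &&
        object@coordinatedFraction > object@movingFraction + 1e-9)
        msg <- c(msg, "coordinatedFraction cannot exceed movingFraction")
    if (length(msg)) msg else TRUE
})

#' Linked bead trajectories
#'
#' @slot tracks data.frame with columns `track_id`, `frame`, `x`, `y`
#'   (pixels). Frames strictly increase within a track; a closed gap
#'   appears as a frame step > 1.
#' @slot maxDisplacement numeric(1), linking cutoff (pixels per frame step).
#' @slot minTrackLength integer(1), minimum detections per reported track.
#' @slot maxGap integer(1), maximum frames bridged by gap closing.
#' @export
setClass("TrackSet", representation(
    tracks = "data.frame",
    maxDisplacement = "numeric",
    minTrackLength = "integer",
    maxGap = "integer"
))

setValidity("TrackSet", function(object) {
    tr <- object@tracks
    need <- c("track_id", "frame", "x", "y")
    if (!all(need %in% names(tr)))
        return("tracks needs columns track_id, frame, x, y")
    if (nrow(tr)) {
        sp <- split(tr$frame, tr$track_id)
        if (any(vapply(sp, function(f) any(diff(f) <= 0L), logical(1))))
            return("frames must strictly increase within each track")
    }
    TRUE
})

#' Whole-specimen drift quantification
#'
#' @slot centroids data.frame with columns `frame`, `x`, `y` (pixels).
#' @slot driftSpeed numeric(1), net displacement / elapsed time (um/s).
#' @slot driftPathRatio numeric(1) in \[0, 1\], net / total path length.
#' @slot pixelSize,frameInterval calibration used for the conversion.
#' @export
setClass("DriftResult", representation(
    centroids = "data.frame",
    driftSpeed = "numeric",
    driftPathRatio = "numeric",
    pixelSize = "numeric",
    frameInterval = "numeric"
))

setValidity("DriftResult", function(object) {
    if (object@driftSpeed < 0) return("driftSpeed must be >= 0")
    r <- object@driftPathRatio
    if (is.finite(r) && (r < -1e-9 || r > 1 + 1e-9))
        return("driftPathRatio must lie in [0, 1]")
    TRUE
})
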