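#' Build a simulation configuration
#'
#' Constructs a validated [SimConfig-class]. The defaults emulate a
#' 30-second, 10 frames-per-second acquisition of 1-um fluorescent tracer
#' beads on a circular epithelial culture, imaged at 0.5 um/pixel. Flow is
#' piecewise constant over a patch grid: a patch is either active (beads
#' advect at its speed along its direction) or static. Directions of
#' active patches follow a mixture: with probability `coherence` the
#' shared global direction, otherwise an independent uniform draw.
#'
#' @param imageSize frame height and width in pixels (length-2, or a
#'   scalar for square frames).
#' @param nFrames number of frames.
#' @param frameInterval seconds between frames.
#' @param pixelSize micrometres per pixel.
#' @param nBeads number of beads.
#' @param beadSigma Gaussian spot width, pixels.
#' @param beadAmplitude peak intensity of one bead above background.
#' @param patchGrid rows x columns of flow patches (scalar for square
#'   grids); must divide `imageSize`.
#' @param activeFraction fraction of patches carrying flow, in \[0, 1\].
#' @param meanSpeed mean active-patch speed, um/s.
#' @param speedCV per-patch speed coefficient of variation.
#' @param coherence probability that an active patch takes the global
#'   direction, in \[0, 1\].
#' @param flowDirection global flow direction in radians (`NA` = random).
#' @param driftVelocity whole-frame translation, um/s (x, y).
#' @param backgroundLevel constant background intensity.
#' @param noiseSD additive Gaussian sensor noise SD.
#' @param diffusionSD per-frame Brownian bead jitter SD, pixels.
#' @param minSeparation minimum initial bead spacing, pixels (0 = none).
#' @param fovRadiusFraction circular field-of-view radius relative to
#'   half the shorter image side.
#' @param seed integer RNG seed.
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(imageSize = 128, nFrames = 10, nBeads = 50, seed = 1)
#' @export
simConfig <- function(imageSize = c(256L, 256L), nFrames = 300L,
                      frameInterval = 0.1, pixelSize = 0.5,
                      nBeads = 1200L, beadSigma = 1.5, beadAmplitude = 400,
                      patchGrid = c(8L, 8L), activeFraction = 0.5,
                      meanSpeed = 5, speedCV = 0.2, coherence = 0.8,
                      flowDirection = NA_real_, driftVelocity = c(0, 0),
                      backgroundLevel = 100, noiseSD = 5,
                      diffusionSD = 0, minSeparation = 0,
                      fovRadiusFraction = 0.95, seed = 1L) {
    if (length(imageSize) == 1L) imageSize <- rep(imageSize, 2L)
    if (length(patchGrid) == 1L) patchGrid <- rep(patchGrid, 2L)
    new("SimConfig",
        imageSize = as.integer(imageSize), nFrames = as.integer(nFrames),
        frameInterval = as.numeric(frameInterval),
        pixelSize = as.numeric(pixelSize),
        nBeads = as.integer(nBeads), beadSigma = as.numeric(beadSigma),
        beadAmplitude = as.numeric(beadAmplitude),
        patchGrid = as.integer(patchGrid),
        activeFraction = as.numeric(activeFraction),
        meanSpeed = as.numeric(meanSpeed), speedCV = as.numeric(speedCV),
        coherence = as.numeric(coherence),
        flowDirection = as.numeric(flowDirection),
        driftVelocity = as.numeric(driftVelocity),
        backgroundLevel = as.numeric(backgroundLevel),
        noiseSD = as.numeric(noiseSD), diffusionSD = as.numeric(diffusionSD),
        minSeparation = as.numeric(minSeparation),
        fovRadiusFraction = as.numeric(fovRadiusFraction),
        seed = as.integer(seed))
}

#' Draw the patchwise flow field of a simulation
#'
#' Selects `round(activeFraction * nPatches)` patches uniformly at random
#' as active (an exact, deterministic count), assigns each active patch a
#' direction from the coherence mixture and a speed
#' `meanSpeed * (1 + speedCV * eps)` with standard-normal `eps`, clamped
#' at zero.
#'
#' @param config a [SimConfig-class].
#' @return list with `activeMask` (logical patch matrix), `directionField`
#'   (radians, `NA` where inactive), `speedField` (um/s, 0 where inactive),
#'   and `globalDirection` (radians).
#' @export
buildFlowField <- function(config) {
    validObject(config)
    withSeed(config@seed, {
        npr <- config@patchGrid[1L]; npc <- config@patchGrid[2L]
        n <- npr * npc
        nActive <- as.integer(round(config@activeFraction * n))
        active <- matrix(FALSE, npr, npc)
        if (nActive > 0L) active[sample.int(n, nActive)] <- TRUE
        globalDir <- if (is.finite(config@flowDirection)) config@flowDirection
                     else stats::runif(1, 0, 2 * pi)
        dir <- matrix(NA_real_, npr, npc)
        spd <- matrix(0, npr, npc)
        if (nActive > 0L) {
            coh <- stats::runif(nActive) < config@coherence
            th <- ifelse(coh, globalDir, stats::runif(nActive, 0, 2 * pi))
            dir[active] <- th
            spd[active] <- pmax(0, config@meanSpeed *
                (1 + config@speedCV * stats::rnorm(nActive)))
        }
        list(activeMask = active, directionField = dir, speedField = spd,
             globalDirection = globalDir)
    })
}

# Add one Gaussian spot to `img` in place semantics (returns new matrix).
addSpot <- function(img, x, y, amplitude, sigma) {
    h <- nrow(img); w <- ncol(img)
    r <- stampRadius(sigma)
    rows <- max(1L, floor(y - r)):min(h, ceiling(y + r))
    cols <- max(1L, floor(x - r)):min(w, ceiling(x + r))
    if (!length(rows) || !length(cols)) return(img)
    ey <- exp(-((rows - y)^2) / (2 * sigma^2))
    ex <- exp(-((cols - x)^2) / (2 * sigma^2))
    img[rows, cols] <- img[rows, cols] + amplitude * (ey %o% ex)
    img
}

# Patch index (row, col) of continuous pixel coordinates; coordinates are
# 1-based with pixel centres on integers, so patch k covers
# (0.5 + (k-1)*pw, 0.5 + k*pw].
patchIndex <- function(x, n, size) {
    pmin(pmax(ceiling((x - 0.5) / size), 1L), n)
}

#' Advect beads through a flow field and render the movie
#'
#' Beads are seeded uniformly (optionally with a minimum spacing), then
#' advance each frame by the velocity of the patch they currently occupy
#' plus the global drift, expressed in pixels per frame. A bead crossing
#' the boundary of an active patch re-enters that patch from the opposite
#' side (toroidal wrap), keeping bead density and per-patch speed
#' stationary over arbitrarily long movies; the wrap ends the bead's
#' current ground-truth track and starts a new one. Beads in static
#' patches move only with drift and are removed once they leave the
#' frame. Each bead is rendered as a constant-amplitude Gaussian spot on
#' a constant background with additive Gaussian sensor noise. The same
#' configuration (including seed) always yields a bit-identical stack.
#'
#' @param config a [SimConfig-class].
#' @param flow output of [buildFlowField()]; drawn from `config` if `NULL`.
#' @return list with `movie` (a [MovieStack-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @export
advectAndRender <- function(config, flow = NULL) {
    validObject(config)
    if (is.null(flow)) flow <- buildFlowField(config)
    h <- config@imageSize[1L]; w <- config@imageSize[2L]
    npr <- config@patchGrid[1L]; npc <- config@patchGrid[2L]
    ph <- h / npr; pw <- w / npc
    stepPx <- config@frameInterval / config@pixelSize       # um/s -> px/frame
    driftPx <- config@driftVelocity * stepPx
    # per-patch velocity in px/frame (x = col, y = row; y positive down)
    vxPatch <- flow$speedField * cos(flow$directionField) * stepPx
    vyPatch <- flow$speedField * sin(flow$directionField) * stepPx
    vxPatch[!flow$activeMask] <- 0
    vyPatch[!flow$activeMask] <- 0

    withSeed(config@seed + 1L, {
        n <- config@nBeads
        if (n > 0L) {
            if (config@minSeparation > 0) {
                xs <- ys <- numeric(0)
                tries <- 0L
                while (length(xs) < n && tries < 200L * n) {
                    cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
                    if (!length(xs) ||
                        min((xs - cx)^2 + (ys - cy)^2) >= config@minSeparation^2) {
                        xs <- c(xs, cx); ys <- c(ys, cy)
                    }
                    tries <- tries + 1L
                }
                if (length(xs) < n)
                    stop("could not place ", n, " beads at minSeparation = ",
                         config@minSeparation)
                x <- xs; y <- ys
            } else {
                x <- stats::runif(n, 1, w)
                y <- stats::runif(n, 1, h)
            }
            trackId <- seq_len(n)
            alive <- rep(TRUE, n)
        } else {
            x <- y <- numeric(0); trackId <- integer(0); alive <- logical(0)
        }
        nextId <- n + 1L

        frames <- array(0, dim = c(h, w, config@nFrames))
        rows <- vector("list", config@nFrames)
        for (t in seq_len(config@nFrames)) {
            live <- which(alive)
            if (length(live))
                rows[[t]] <- data.frame(track_id = trackId[live], frame = t,
                                        x = x[live], y = y[live])
            img <- matrix(config@backgroundLevel, h, w)
            # spot rendering is inlined: modifying `img` in place here
            # avoids a full-frame copy per bead
            sg2 <- 2 * config@beadSigma^2
            srad <- stampRadius(config@beadSigma)
            for (i in live) {
                sy <- max(1L, floor(y[i] - srad)):min(h, ceiling(y[i] + srad))
                sx <- max(1L, floor(x[i] - srad)):min(w, ceiling(x[i] + srad))
                img[sy, sx] <- img[sy, sx] + config@beadAmplitude *
                    (exp(-((sy - y[i])^2) / sg2) %o%
                     exp(-((sx - x[i])^2) / sg2))
            }
            if (config@noiseSD > 0)
                img <- img + matrix(stats::rnorm(h * w, 0, config@noiseSD), h, w)
            frames[, , t] <- pmax(img, 0)

            if (t == config@nFrames) break
            for (i in live) {
                pr <- patchIndex(y[i], npr, ph)
                pc <- patchIndex(x[i], npc, pw)
                dx <- vxPatch[pr, pc] + driftPx[1L]
                dy <- vyPatch[pr, pc] + driftPx[2L]
                if (config@diffusionSD > 0) {
                    dx <- dx + stats::rnorm(1, 0, config@diffusionSD)
                    dy <- dy + stats::rnorm(1, 0, config@diffusionSD)
                }
                nx <- x[i] + dx; ny <- y[i] + dy
                if (flow$activeMask[pr, pc]) {
                    lox <- 0.5 + (pc - 1L) * pw
                    loy <- 0.5 + (pr - 1L) * ph
                    wx <- ((nx - lox) %% pw) + lox
                    wy <- ((ny - loy) %% ph) + loy
                    if (abs(wx - nx) > 1e-9 || abs(wy - ny) > 1e-9) {
                        nx <- wx; ny <- wy
                        trackId[i] <- nextId; nextId <- nextId + 1L
                    }
                } else if (nx < 0.5 || nx > w + 0.5 || ny < 0.5 || ny > h + 0.5) {
                    alive[i] <- FALSE
                }
                x[i] <- nx; y[i] <- ny
            }
        }
        tracksDf <- if (any(lengths(rows))) do.call(rbind, rows[lengths(rows) > 0])
                    else data.frame(track_id = integer(0), frame = integer(0),
                                    x = numeric(0), y = numeric(0))
        tracksDf <- tracksDf[order(tracksDf$track_id, tracksDf$frame), ,
                             drop = FALSE]
        rownames(tracksDf) <- NULL
        movie <- new("MovieStack", frames = frames,
                     frameInterval = config@frameInterval,
                     pixelSize = config@pixelSize)
        truth <- new("GroundTruth", activeMask = flow$activeMask,
                     directionField = flow$directionField,
                     speedField = flow$speedField,
                     tracks = tracksDf,
                     driftVelocity = config@driftVelocity,
                     coherence = config@coherence)
        list(movie = movie, truth = truth)
    })
}

#' Simulate a bead transport movie with ground truth
#'
#' Convenience wrapper: [buildFlowField()] followed by
#' [advectAndRender()].
#'
#' @inheritParams advectAndRender
#' @return list with `movie` and `truth` (see [advectAndRender()]).
#' @examples
#' sim <- simulateBeadMovie(simConfig(imageSize = 96, nFrames = 6,
#'                                    nBeads = 40, patchGrid = 2, seed = 7))
#' nFrames(sim$movie)
#' @export
simulateBeadMovie <- function(config) {
    advectAndRender(config, buildFlowField(config))
}

#' Simulate a drifting-specimen brightfield movie
#'
#' Renders a single dark, internally textured ellipse (a stand-in for a
#' whole embryo under brightfield illumination) translating across a
#' bright background at `driftVelocity`. The texture is an analytic
#' function of object-local coordinates, so it translates rigidly with
#' subpixel accuracy. The drift path is centred on the frame, and a
#' configuration whose path would clip the specimen against the frame
#' edge (which would bias the centroid) is rejected. The true centroid
#' series is recorded as a single-track ground truth.
#'
#' @param config a [SimConfig-class]; `driftVelocity` (um/s) sets the
#'   motion and `imageSize`, `backgroundLevel`, `noiseSD` the rendering.
#' @return list with `movie` (a [MovieStack-class]) and `truth`
#'   (a [GroundTruth-class] whose `tracks` slot holds the centroid series).
#' @export
simulateEmbryoDrift <- function(config) {
    validObject(config)
    h <- config@imageSize[1L]; w <- config@imageSize[2L]
    a <- 0.30 * min(h, w)   # semi-axis along x
    b <- 0.22 * min(h, w)   # semi-axis along y
    stepPx <- config@frameInterval / config@pixelSize
    driftPx <- config@driftVelocity * stepPx
    # centre the drift path on the frame so the specimen stays visible
    # for as long as possible
    mid <- c((w + 1) / 2, (h + 1) / 2)
    c0 <- mid - driftPx * (config@nFrames - 1L) / 2
    cT <- mid + driftPx * (config@nFrames - 1L) / 2
    margin <- c(a, b)
    if (any(c(c0, cT) < 1 + margin[c(1, 2, 1, 2)]) ||
        any(c(c0[1L], cT[1L]) > w - a) || any(c(c0[2L], cT[2L]) > h - b))
        stop("driftVelocity carries the specimen out of frame before nFrames")

    withSeed(config@seed + 2L, {
        xs <- seq_len(w); ys <- seq_len(h)
        frames <- array(0, dim = c(h, w, config@nFrames))
        cent <- matrix(0, config@nFrames, 2L)
        for (t in seq_len(config@nFrames)) {
            cx <- c0[1L] + driftPx[1L] * (t - 1L)
            cy <- c0[2L] + driftPx[2L] * (t - 1L)
            cent[t, ] <- c(cx, cy)
            qx <- ((xs - cx) / a)^2
            qy <- ((ys - cy) / b)^2
            q <- outer(qy, qx, `+`)
            inside <- pmin(1, pmax(0, (1 - q) * 8))    # antialiased edge
            u <- outer(rep(1, h), xs - cx)
            v <- outer(ys - cy, rep(1, w))
            tex <- 1 + 0.25 * sin(u / 6) + 0.25 * cos(v / 9)
            obj <- 0.3 * config@backgroundLevel * tex
            img <- config@backgroundLevel * (1 - inside) + obj * inside
            if (config@noiseSD > 0)
                img <- img + matrix(stats::rnorm(h * w, 0, config@noiseSD), h, w)
            frames[, , t] <- pmax(img, 0)
        }
        movie <- new("MovieStack", frames = frames,
                     frameInterval = config@frameInterval,
                     pixelSize = config@pixelSize)
        empty <- matrix(FALSE, config@patchGrid[1L], config@patchGrid[2L])
        truth <- new("GroundTruth", activeMask = empty,
                     directionField = matrix(NA_real_, nrow(empty), ncol(empty)),
                     speedField = matrix(0, nrow(empty), ncol(empty)),
                     tracks = data.frame(track_id = 1L,
                                         frame = seq_len(config@nFrames),
                                         x = cent[, 1L], y = cent[, 2L]),
                     driftVelocity = config@driftVelocity,
                     coherence = config@coherence)
        list(movie = movie, truth = truth)
    })
}
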