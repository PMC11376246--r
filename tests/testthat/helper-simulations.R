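# Shared fixture builders. All fixtures are generated in code at test
# time; sizes are kept small so the whole suite runs in minutes.

# Uniform noise-free translation: one active patch covering the frame,
# fixed direction, exact per-patch speed (speedCV = 0).
uniformFlowConfig <- function(pxPerFrame = 2, direction = 0, imageSize = 128,
                              nFrames = 8, nBeads = 250, noiseSD = 0,
                              seed = 42, ...) {
    # meanSpeed chosen so that speed * interval / pixelSize = pxPerFrame
    simConfig(imageSize = imageSize, nFrames = nFrames, nBeads = nBeads,
              patchGrid = 1, activeFraction = 1, coherence = 1,
              flowDirection = direction,
              meanSpeed = pxPerFrame * 0.5 / 0.1, speedCV = 0,
              noiseSD = noiseSD, seed = seed, ...)
}

# Static movie: beads present but no flow.
staticConfig <- function(imageSize = 128, nFrames = 8, nBeads = 150,
                         noiseSD = 5, seed = 7, ...) {
    simConfig(imageSize = imageSize, nFrames = nFrames, nBeads = nBeads,
              patchGrid = 1, activeFraction = 0, noiseSD = noiseSD,
              seed = seed, ...)
}

# Rotate a movie stack by 90 degrees (counter-clockwise in matrix terms).
rotateMovie90 <- function(movie) {
    a <- frames(movie)
    d <- dim(a)
    b <- array(0, c(d[2L], d[1L], d[3L]))
    for (t in seq_len(d[3L]))
        b[, , t] <- t(a[, , t])[d[2L]:1, ]
    MovieStack(b, frameInterval(movie), pixelSize(movie))
}

# Intensity-weighted centroid of a background-subtracted frame.
frameCentroid <- function(frame, background) {
    f <- pmax(frame - background, 0)
    c(x = sum(f * col(f)) / sum(f), y = sum(f * row(f)) / sum(f))
}
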