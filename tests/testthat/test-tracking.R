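test_that("bead detection finds isolated spots with subpixel accuracy", {
    cfg <- simConfig(imageSize = 128, nFrames = 3, nBeads = 20, patchGrid = 1,
                     activeFraction = 0, noiseSD = 0, minSeparation = 12,
                     seed = 2)
    sim <- simulateBeadMovie(cfg)
    det <- detectBeads(sim$movie, spotSigma = 1.5, snrMin = 5)
    tr1 <- sim$truth@tracks[sim$truth@tracks$frame == 1L, ]
    expect_identical(nrow(det[[1]]), nrow(tr1))
    err <- vapply(seq_len(nrow(tr1)), function(i)
        min(sqrt((det[[1]]$x - tr1$x[i])^2 + (det[[1]]$y - tr1$y[i])^2)),
        numeric(1))
    expect_lt(max(err), 0.5)

    # blank frames yield empty detection lists
    blank <- MovieStack(array(100, c(64, 64, 2)), 0.1, 0.5)
    expect_identical(nrow(detectBeads(blank)[[1]]), 0L)
})

test_that("two nearly merged beads give at most two flagged detections", {
    img <- matrix(100, 64, 64)
    for (cx in c(32, 33)) {
        img <- img + 400 * (exp(-((1:64 - 30)^2) / 4.5) %o%
                            exp(-((1:64 - cx)^2) / 4.5))
    }
    mv <- MovieStack(array(rep(img, 2), c(64, 64, 2)), 0.1, 0.5)
    d <- detectBeads(mv, spotSigma = 1.5, snrMin = 3)[[1]]
    expect_lte(nrow(d), 2L)
    if (nrow(d) == 2L) expect_true(all(d$crowded))
})

test_that("linking reproduces simple motion and respects separations", {
    # single bead, uniform motion: one track matching the truth
    cfg <- uniformFlowConfig(pxPerFrame = 2, imageSize = 96, nFrames = 10,
                             nBeads = 1, seed = 5)
    sim <- simulateBeadMovie(cfg)
    ts <- linkTracks(detectBeads(sim$movie), maxDisplacement = 5,
                     minTrackLength = 3, maxGap = 0)
    expect_identical(nTracks(ts), 1L)
    got <- tracks(ts)
    tru <- sim$truth@tracks
    expect_identical(nrow(got), nrow(tru))
    expect_lt(max(abs(got$x - tru$x)), 0.1)

    # two well-separated parallel beads: two tracks, no identity swap
    d2 <- lapply(1:8, function(f) data.frame(x = c(10 + f, 10 + f),
                                             y = c(10, 60)))
    ts2 <- linkTracks(d2, maxDisplacement = 3, minTrackLength = 3,
                      maxGap = 0)
    expect_identical(nTracks(ts2), 2L)
    ys <- tapply(tracks(ts2)$y, tracks(ts2)$track_id,
                 function(v) length(unique(v)))
    expect_true(all(ys == 1L))
})

test_that("a bead leaving the frame ends its track at the last visible frame", {
    # drift carries beads in a static patch out of the frame
    cfg <- simConfig(imageSize = 96, nFrames = 30, nBeads = 8, patchGrid = 1,
                     activeFraction = 0, driftVelocity = c(10, 0),
                     noiseSD = 0, minSeparation = 15, seed = 12)
    sim <- simulateBeadMovie(cfg)
    tru <- sim$truth@tracks
    lastFrames <- tapply(tru$frame, tru$track_id, max)
    expect_true(any(lastFrames < 30))
    ts <- linkTracks(detectBeads(sim$movie), maxDisplacement = 5,
                     minTrackLength = 3, maxGap = 0)
    gotLast <- tapply(tracks(ts)$frame, tracks(ts)$track_id, max)
    expect_true(any(gotLast < 30))
})

test_that("gap closing bridges short dropouts without inventing steps", {
    det <- lapply(1:9, function(f)
        if (f == 5) data.frame(x = numeric(0), y = numeric(0))
        else data.frame(x = 10 + 2 * f, y = 20))
    bridged <- linkTracks(det, maxDisplacement = 5, minTrackLength = 3,
                          maxGap = 2)
    expect_identical(nTracks(bridged), 1L)
    expect_identical(sum(diff(tracks(bridged)$frame) == 2L), 1L)
    broken <- linkTracks(det, maxDisplacement = 5, minTrackLength = 3,
                         maxGap = 0)
    expect_identical(nTracks(broken), 2L)
})

test_that("specimen speed is the mean of per-track path speeds", {
    mk <- function(id, step, n = 11) data.frame(track_id = id,
                                                frame = seq_len(n),
                                                x = step * seq_len(n),
                                                y = 0)
    ts <- new("TrackSet", tracks = rbind(mk(1L, 2)),
              maxDisplacement = 5, minTrackLength = 3L, maxGap = 0L)
    # 2 px/frame at 1 um/px and 0.1 s -> 20 um/s
    expect_equal(specimenSpeed(ts, 1, 0.1)$specimenSpeed, 20)

    ts2 <- new("TrackSet", tracks = rbind(mk(1L, 1), mk(2L, 3)),
               maxDisplacement = 5, minTrackLength = 3L, maxGap = 0L)
    expect_equal(specimenSpeed(ts2, 1, 0.1)$specimenSpeed, 20)

    empty <- new("TrackSet",
                 tracks = data.frame(track_id = integer(0),
                                     frame = integer(0), x = numeric(0),
                                     y = numeric(0)),
                 maxDisplacement = 5, minTrackLength = 3L, maxGap = 0L)
    expect_error(specimenSpeed(empty, 1, 0.1), "empty")
})

test_that("embryo drift is recovered and a circular path has ratio near 0", {
    sim <- simulateEmbryoDrift(simConfig(imageSize = 224, nFrames = 40,
                                         driftVelocity = c(4, 0),
                                         noiseSD = 2, seed = 6))
    dr <- embryoDrift(sim$movie)
    expect_equal(dr@driftSpeed, 4, tolerance = 0.05)
    expect_gt(dr@driftPathRatio, 0.95)

    # stationary specimen, noise-free rendering: exactly zero drift
    dr0 <- embryoDrift(simulateEmbryoDrift(
        simConfig(imageSize = 224, nFrames = 12, driftVelocity = c(0, 0),
                  noiseSD = 0, seed = 6))$movie)
    expect_identical(dr0@driftSpeed, 0)
    expect_identical(dr0@driftPathRatio, 0)

    # circular motion returning to start: net ~ 0, total large
    h <- 96; t <- 24
    a <- array(0, c(h, h, t))
    for (k in seq_len(t)) {
        cx <- 48 + 12 * cos(2 * pi * (k - 1) / (t - 1))
        cy <- 48 + 12 * sin(2 * pi * (k - 1) / (t - 1))
        disk <- (outer((seq_len(h) - cy)^2, (seq_len(h) - cx)^2, `+`) <= 100)
        a[, , k] <- 200 - 150 * disk
    }
    drc <- embryoDrift(MovieStack(a, 0.1, 0.5))
    expect_lt(drc@driftPathRatio, 0.1)
    path <- sum(sqrt(rowSums(diff(as.matrix(drc@centroids[, c("x", "y")]))^2)))
    expect_gt(path, 50)
})
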