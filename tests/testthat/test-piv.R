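test_that("cross-correlation recovers known integer and fractional shifts", {
    # oracle: two windows rendered from the same spots, the second offset
    # by a known displacement, so the correlation peak must sit there
    renderSpots <- function(n, xs, ys, sigma = 1.5) {
        img <- matrix(0, n, n)
        for (k in seq_along(xs)) {
            img <- img + exp(-(outer((seq_len(n) - ys[k])^2,
                                     (seq_len(n) - xs[k])^2, `+`)) /
                             (2 * sigma^2))
        }
        img
    }
    # well-separated spots on a jittered grid keep correlation peaks of
    # different beads from overlapping, isolating the estimator's error
    set.seed(1)
    g <- expand.grid(x = seq(6, 27, by = 7), y = seq(6, 27, by = 7))
    xs <- g$x + runif(nrow(g), -1.5, 1.5)
    ys <- g$y + runif(nrow(g), -1.5, 1.5)
    for (sh in list(c(2, 0), c(-3, 1), c(0.5, 0), c(1.25, -0.75))) {
        A <- renderSpots(32, xs, ys)
        B <- renderSpots(32, xs + sh[1], ys + sh[2])
        r <- ciliaflow:::xcorrDisp(A, B, maxShift = 8)
        expect_true(r$valid)
        expect_lt(abs(r$dx - sh[1]), 0.06)
        expect_lt(abs(r$dy - sh[2]), 0.06)
    }
    # zero-variance windows are flagged invalid with zero displacement
    z <- ciliaflow:::xcorrDisp(matrix(5, 16, 16), matrix(5, 16, 16), 4)
    expect_false(z$valid)
    expect_identical(c(z$dx, z$dy), c(0, 0))
})

test_that("uniform translation yields a uniform flow field", {
    sim <- simulateBeadMovie(uniformFlowConfig(pxPerFrame = 2))
    ff <- computePivField(sim$movie, windowSize = 32, overlap = 0.5)
    ok <- is.finite(ff@u)
    expect_true(all(abs(ff@u[ok] - 2) < 0.1))
    expect_true(all(abs(ff@v[ok]) < 0.1))
    # speed conversion: 2 px/frame * 0.5 um/px / 0.1 s = 10 um/s
    expect_equal(mean(ff@speed[ok]), 10, tolerance = 0.02)
})

test_that("a static movie gives zero displacements and speeds", {
    sim <- simulateBeadMovie(staticConfig(noiseSD = 0))
    ff <- computePivField(sim$movie, windowSize = 32, overlap = 0.5)
    ok <- is.finite(ff@u)
    expect_true(any(ok))
    expect_true(all(abs(ff@u[ok]) < 1e-6))
    expect_true(all(ff@speed[ok] < 1e-5))
})

test_that("the flow field is equivariant under 90-degree rotation", {
    sim <- simulateBeadMovie(uniformFlowConfig(pxPerFrame = 1.5,
                                               direction = 0.4,
                                               noiseSD = 2, seed = 21))
    ff <- computePivField(sim$movie, windowSize = 32, overlap = 0)
    ffr <- computePivField(rotateMovie90(sim$movie), windowSize = 32,
                           overlap = 0)
    s1 <- mean(ff@speed[is.finite(ff@speed)])
    s2 <- mean(ffr@speed[is.finite(ffr@speed)])
    expect_equal(s2, s1, tolerance = 0.01)
    # transpose + row flip maps (u, v) -> (v, -u)
    expect_equal(mean(ffr@u[is.finite(ffr@u)]),
                 mean(ff@v[is.finite(ff@v)]), tolerance = 0.05)
    expect_equal(mean(ffr@v[is.finite(ffr@v)]),
                 -mean(ff@u[is.finite(ff@u)]), tolerance = 0.05)
})

test_that("circular masks have the right geometry", {
    mv <- MovieStack(array(runif(64 * 64 * 2), c(64, 64, 2)), 0.1, 0.5)
    m <- fitCircularMask(mv, 1.0)
    expect_equal(sum(m) / length(m), pi / 4, tolerance = 0.01)
    expect_false(any(fitCircularMask(mv, 0)))
    expect_error(fitCircularMask(mv, 1.5), "radiusFraction")

    # auto mode: fit a vignetted culture disk off the frame centre
    h <- 96; w <- 96
    dy <- (seq_len(h) - 45)^2; dx <- (seq_len(w) - 52)^2
    disk <- (outer(dy, dx, `+`) <= 30^2) * 200
    a <- array(rep(disk, 3) + rnorm(h * w * 3, 0, 2) + 10, c(h, w, 3))
    auto <- fitCircularMask(MovieStack(pmax(a, 0), 0.1, 0.5), "auto")
    ij <- which(auto, arr.ind = TRUE)
    expect_lt(abs(mean(ij[, 1]) - 45), 2)
    expect_lt(abs(mean(ij[, 2]) - 52), 2)
})

test_that("active classification recovers the simulated active fraction", {
    cfg <- simConfig(imageSize = 256, nFrames = 20, nBeads = 900,
                     patchGrid = 4, activeFraction = 0.5, coherence = 0.8,
                     meanSpeed = 5, noiseSD = 5, seed = 31)
    sim <- simulateBeadMovie(cfg)
    ff <- computePivField(sim$movie, windowSize = 32, overlap = 0)
    act <- classifyActive(ff)
    expect_lt(abs(act$percentActive - 50), 5)

    # fully static movie: nothing active
    simS <- simulateBeadMovie(staticConfig(imageSize = 128, nBeads = 300))
    ffS <- computePivField(simS$movie, windowSize = 32, overlap = 0)
    expect_identical(classifyActive(ffS)$percentActive, 0)
})

test_that("speed scale equivariance: doubling speed doubles the field", {
    runAt <- function(mu) {
        cfg <- simConfig(imageSize = 192, nFrames = 16, nBeads = 500,
                         patchGrid = 3, activeFraction = 1, coherence = 1,
                         flowDirection = 1, meanSpeed = mu, speedCV = 0,
                         noiseSD = 3, seed = 17)
        sim <- simulateBeadMovie(cfg)
        ff <- computePivField(sim$movie, windowSize = 32, overlap = 0)
        act <- classifyActive(ff)
        c(speed = mean(ff@speed[act$activeMask]), pct = act$percentActive)
    }
    a <- runAt(2.5); b <- runAt(5)
    expect_equal(unname(b["speed"] / a["speed"]), 2, tolerance = 0.05)
    expect_lt(abs(unname(a["pct"]) - unname(b["pct"])), 2)
})

test_that("threshold metrics nest inside the active percentage", {
    cfg <- simConfig(imageSize = 192, nFrames = 16, nBeads = 500,
                     patchGrid = 3, activeFraction = 1, coherence = 0.7,
                     meanSpeed = 5, noiseSD = 5, seed = 13)
    sim <- simulateBeadMovie(cfg)
    res <- cambridgePipeline(sim$movie, windowSize = 32, overlap = 0,
                             fov = 1.0, thresholdSpeed = 4)
    expect_true(validObject(res))
    expect_lte(res@percentAboveThreshold, res@percentActive)
    # a threshold above every speed yields 0%
    hi <- cambridgePipeline(sim$movie, windowSize = 32, overlap = 0,
                            fov = 1.0, thresholdSpeed = 1e6)
    expect_identical(hi@percentAboveThreshold, 0)
})

test_that("the control threshold is the mean active control speed", {
    fakeField <- function(speed) {
        n <- 4L
        m <- matrix(speed, n, n)
        new("FlowField", x = seq(16, by = 32, length.out = n),
            y = seq(16, by = 32, length.out = n),
            u = m / 5, v = m * 0, speed = m,
            quality = matrix(2, n, n), nullSpeed = matrix(0, n, n),
            nValidPairs = matrix(5L, n, n), windowSize = 32L,
            overlap = 0, pairSpacing = 1L, pixelSize = 0.5,
            frameInterval = 0.1)
    }
    act <- function(f) classifyActive(f, noiseFloor = 0.1)
    f1 <- fakeField(2); f2 <- fakeField(6)
    expect_equal(computeControlThreshold(list(f1), list(act(f1))), 2)
    expect_equal(computeControlThreshold(list(f1, f2),
                                         list(act(f1), act(f2))), 4)
    # all windows below the floor: no active controls, no threshold
    f0 <- fakeField(0.01)
    expect_error(computeControlThreshold(list(f0),
                                         list(list(activeMask = matrix(FALSE, 4, 4),
                                                   scoreable = matrix(TRUE, 4, 4)))),
                 "active control")
})
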