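test_that("moving mask is empty for constant and static-noise movies", {
    # perfectly constant movie
    mv <- MovieStack(array(50, c(64, 64, 5)), 0.1, 0.5)
    mm <- computeMovingMask(mv)
    expect_identical(mm$movingFraction, 0)

    # static beads plus sensor noise stay below the threshold
    simS <- simulateBeadMovie(staticConfig(imageSize = 128, nFrames = 12,
                                           nBeads = 300, noiseSD = 5))
    mmS <- computeMovingMask(simS$movie)
    expect_lt(mmS$movingFraction, 5)
})

test_that("moving mask tracks the spatial extent of motion", {
    # beads everywhere, flow confined to the left half of the frame
    cfg <- simConfig(imageSize = c(128, 128), nFrames = 40, nBeads = 260,
                     patchGrid = c(1, 2), activeFraction = 0.5,
                     coherence = 1, flowDirection = pi / 2, meanSpeed = 5,
                     noiseSD = 4, seed = 15)
    flow <- buildFlowField(cfg)
    # force the left column of patches active for a known geometry
    flow$activeMask <- matrix(c(TRUE, FALSE), 1, 2)
    flow$directionField <- matrix(c(pi / 2, NA), 1, 2)
    flow$speedField <- matrix(c(5, 0), 1, 2)
    sim <- advectAndRender(cfg, flow)
    mm <- computeMovingMask(sim$movie)
    leftFrac <- mean(mm$movingMask[, 1:64])
    rightFrac <- mean(mm$movingMask[, 65:128])
    expect_gt(leftFrac, 0.5)
    expect_lt(rightFrac, 0.1)
})

test_that("block directions recover uniform and opposing flows", {
    sim <- simulateBeadMovie(uniformFlowConfig(pxPerFrame = 1.5,
                                               imageSize = 128,
                                               nFrames = 30, nBeads = 220,
                                               noiseSD = 3, seed = 23))
    mm <- computeMovingMask(sim$movie)
    rd <- computeRegionDirections(sim$movie, mm$movingMask, blockSize = 32)
    dirs <- rd$blockDirections[is.finite(rd$blockDirections)]
    expect_gt(length(dirs), 4)
    expect_true(all(abs(dirs) < 0.1))

    # two halves flowing +x and -x give a bimodal direction field
    right <- simulateBeadMovie(uniformFlowConfig(pxPerFrame = 1.5,
                                                 direction = pi,
                                                 imageSize = 128,
                                                 nFrames = 30, nBeads = 220,
                                                 noiseSD = 3, seed = 24))
    a <- array(0, c(128, 256, 30))
    a[, 1:128, ] <- frames(sim$movie)
    a[, 129:256, ] <- frames(right$movie)
    glued <- MovieStack(a, 0.1, 0.5)
    mm2 <- computeMovingMask(glued)
    rd2 <- computeRegionDirections(glued, mm2$movingMask, blockSize = 32)
    dl <- rd2$blockDirections[, 1:4]; dl <- dl[is.finite(dl)]
    dr <- rd2$blockDirections[, 5:8]; dr <- dr[is.finite(dr)]
    expect_true(all(abs(dl) < 0.15))
    expect_true(all(abs(abs(dr) - pi) < 0.15))

    # a static movie yields an empty direction field
    simS <- simulateBeadMovie(staticConfig(imageSize = 128, nBeads = 300,
                                           noiseSD = 4))
    mmS <- computeMovingMask(simS$movie)
    rdS <- computeRegionDirections(simS$movie, mmS$movingMask, blockSize = 32)
    expect_identical(sum(is.finite(rdS$blockDirections)), 0L)
})

test_that("coordination scoring has the correct alignment limits", {
    # identical directions: R = 1 everywhere, all blocks coordinated
    d <- matrix(0.7, 6, 6)
    cm <- computeCoordinatedMask(d, radius = 2, rMin = 0.8)
    expect_true(all(cm$coordinatedBlocks))
    expect_equal(unique(as.vector(cm$alignment)), 1)

    # uniform random directions on a large grid: alignment follows the
    # Rayleigh null, so almost nothing clears rMin = 0.8
    dr <- matrix(ciliaflow:::withSeed(2, runif(400, 0, 2 * pi)), 20, 20)
    cmr <- computeCoordinatedMask(dr, radius = 2, rMin = 0.8)
    expect_lt(mean(cmr$coordinatedBlocks), 0.15)

    # isolated blocks (< minNeighbors) are unscored and uncoordinated
    iso <- matrix(NA_real_, 5, 5); iso[3, 3] <- 1; iso[1, 1] <- 2
    cmi <- computeCoordinatedMask(iso, radius = 1, rMin = 0.1)
    expect_false(any(cmi$coordinatedBlocks))
})

test_that("coordinated area is monotone in the alignment threshold", {
    cfg <- simConfig(imageSize = 256, nFrames = 24, nBeads = 1000,
                     patchGrid = 8, activeFraction = 1, coherence = 0.6,
                     meanSpeed = 5, noiseSD = 5, seed = 41)
    sim <- simulateBeadMovie(cfg)
    fr <- vapply(c(0.3, 0.6, 0.9), function(rmin)
        stevenagePipeline(sim$movie, fov = matrix(TRUE, 256, 256),
                          rMin = rmin)@coordinatedFraction, numeric(1))
    expect_true(all(diff(fr) <= 0))
})

test_that("region metrics satisfy their containment invariants", {
    cfg <- simConfig(imageSize = 192, nFrames = 20, nBeads = 600,
                     patchGrid = 6, activeFraction = 0.6, coherence = 0.8,
                     meanSpeed = 5, noiseSD = 5, seed = 8)
    sim <- simulateBeadMovie(cfg)
    rm <- stevenagePipeline(sim$movie, fov = 0.95)
    expect_true(validObject(rm))
    expect_lte(rm@coordinatedFraction, rm@movingFraction)
    expect_equal(rm@coordinatedOfMoving,
                 100 * rm@coordinatedFraction / rm@movingFraction,
                 tolerance = 1e-9)
})

test_that("moving and coordinated fractions are rotation invariant", {
    cfg <- simConfig(imageSize = 192, nFrames = 24, nBeads = 500,
                     patchGrid = 6, activeFraction = 0.7, coherence = 0.9,
                     meanSpeed = 5, noiseSD = 5, seed = 19)
    sim <- simulateBeadMovie(cfg)
    a <- stevenagePipeline(sim$movie, fov = matrix(TRUE, 192, 192))
    b <- stevenagePipeline(rotateMovie90(sim$movie),
                           fov = matrix(TRUE, 192, 192))
    expect_lt(abs(a@movingFraction - b@movingFraction), 2)
    expect_lt(abs(a@coordinatedFraction - b@coordinatedFraction), 2)
})
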