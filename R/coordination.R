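# "Stevenage" pipeline: moving mask from temporal intensity variability,
# per-block flow directionality, and a coordinated mask from circular
# alignment of nearby blocks.

#' Segment moving pixels from temporal intensity change
#'
#' The per-pixel temporal standard deviation `s` summarizes how much
#' each pixel's intensity changes over the movie. The sensor-noise
#' scale is estimated from the median absolute frame-to-frame
#' difference over all in-FOV pixel-frame samples
#' (`sigma = MAD(diff) / sqrt(2)`): a static pixel differs between
#' consecutive frames by pure noise, and even a pixel lying on a bead
#' path is quiet in most frames, so this estimate stays robust however
#' large the cumulative moving area is, as long as the instantaneous
#' bead coverage of single frames stays below about half the field of
#' view. A pixel is moving when `s > kSigma * sigma`; the mask is
#' illumination-invariant and is cleaned by a morphological opening
#' and removal of small components.
#'
#' @param movie a [MovieStack-class].
#' @param fovMask logical raster (or `NULL` for the whole frame).
#' @param kSigma threshold multiplier on the background noise scale
#'   (default 3).
#' @param openRadius radius of the opening brush in pixels (0 disables).
#' @param minArea smallest component kept, pixels.
#' @return list with `movingMask` (logical raster), `movingFraction`
#'   (percent of in-FOV area), and `threshold`.
#' @export
computeMovingMask <- function(movie, fovMask = NULL, kSigma = 3,
                              openRadius = 2L, minArea = 25L) {
    stopifnot(is(movie, "MovieStack"))
    d <- dim(movie@frames)
    if (is.null(fovMask)) fovMask <- matrix(TRUE, d[1L], d[2L])
    if (!any(fovMask)) stop("empty field-of-view mask")
    s <- temporalSD(movie@frames)
    tN <- d[3L]
    flat <- matrix(movie@frames, d[1L] * d[2L], tN)
    dif <- flat[, -1L, drop = FALSE] - flat[, -tN, drop = FALSE]
    sigmaBg <- stats::median(abs(dif[as.vector(fovMask), ])) /
        (0.6744898 * sqrt(2))
    thr <- kSigma * sigmaBg
    mask <- s > thr & fovMask
    if (openRadius > 0L && any(mask)) {
        brushSize <- 2L * as.integer(openRadius) + 1L
        mask <- EBImage::opening(mask * 1,
                                 EBImage::makeBrush(brushSize, "disc")) > 0.5
    }
    if (minArea > 0L && any(mask)) {
        lab <- EBImage::bwlabel(mask)
        if (max(lab) > 0L) {
            sizes <- tabulate(lab[lab > 0L])
            keep <- which(sizes >= minArea)
            mask <- matrix(lab %in% keep, d[1L], d[2L]) & mask
        }
    }
    list(movingMask = mask,
         movingFraction = 100 * sum(mask) / sum(fovMask),
         threshold = thr)
}

#' Flow direction of moving blocks
#'
#' Divides the frame into square blocks; a block is counted as moving
#' when at least half of its pixels belong to the moving mask. For each
#' moving block, the time-averaged displacement vector is estimated with
#' the same normalized cross-correlation estimator used by
#' [computePivField()] (one interrogation window per block), and its
#' angle is the block direction. Blocks with invalid or low-quality
#' correlation are dropped from the direction field.
#'
#' @param movie a [MovieStack-class].
#' @param movingMask logical raster from [computeMovingMask()].
#' @param blockSize block side in pixels.
#' @param pairSpacing frame separation of correlated pairs.
#' @param qualityMin minimum correlation peak ratio.
#' @param minFractionMoving fraction of block pixels that must be moving.
#' @param maxPairs optional cap on frame pairs (see [computePivField()]).
#' @return list with `blockMoving` (logical block matrix),
#'   `blockDirections` (radians, `NA` where undefined), `blockSpeed`
#'   (um/s), and `blockSize`.
#' @export
computeRegionDirections <- function(movie, movingMask, blockSize = 32L,
                                    pairSpacing = 1L, qualityMin = 1.1,
                                    minFractionMoving = 0.5,
                                    maxPairs = Inf) {
    stopifnot(is(movie, "MovieStack"))
    blockSize <- as.integer(blockSize)
    ff <- computePivField(movie, windowSize = blockSize, overlap = 0,
                          pairSpacing = pairSpacing, maxPairs = maxPairs)
    ny <- length(ff@y); nx <- length(ff@x)
    moving <- matrix(FALSE, ny, nx)
    y0 <- as.integer(ff@y - (blockSize - 1) / 2)
    x0 <- as.integer(ff@x - (blockSize - 1) / 2)
    for (j in seq_len(nx)) for (i in seq_len(ny)) {
        blk <- movingMask[y0[i]:(y0[i] + blockSize - 1L),
                          x0[j]:(x0[j] + blockSize - 1L)]
        moving[i, j] <- mean(blk) >= minFractionMoving
    }
    ok <- moving & ff@nValidPairs > 0L & is.finite(ff@quality) &
        ff@quality >= qualityMin & is.finite(ff@u)
    dirs <- matrix(NA_real_, ny, nx)
    dirs[ok] <- atan2(ff@v[ok], ff@u[ok])
    list(blockMoving = moving, blockDirections = dirs,
         blockSpeed = ff@speed, blockSize = blockSize,
         x = ff@x, y = ff@y)
}

#' Coordinated blocks from local direction alignment
#'
#' For each block with a defined direction, the alignment score is the
#' mean resultant length R of the unit direction vectors of all
#' direction-bearing blocks within `radius` (block units, Euclidean,
#' including the block itself). Blocks with fewer than `minNeighbors`
#' direction-bearing blocks in their neighbourhood are unscored and
#' counted as uncoordinated. A block is coordinated when its alignment
#' reaches `rMin`. Under fully random directions R follows the Rayleigh
#' null (expectation about `0.886/sqrt(n)`), so coordinated area
#' vanishes; under a single shared direction R = 1 everywhere.
#'
#' @param directions block matrix of angles (radians, `NA` = undefined).
#' @param radius neighbourhood radius in blocks (default 2).
#' @param rMin alignment threshold in \[0, 1\] (default 0.8).
#' @param minNeighbors minimum direction-bearing blocks per
#'   neighbourhood, self included (default 3).
#' @return list with `coordinatedBlocks` (logical block matrix) and
#'   `alignment` (numeric block matrix of R values, `NA` where unscored).
#' @export
computeCoordinatedMask <- function(directions, radius = 2, rMin = 0.8,
                                   minNeighbors = 3L) {
    ny <- nrow(directions); nx <- ncol(directions)
    coord <- matrix(FALSE, ny, nx)
    align <- matrix(NA_real_, ny, nx)
    has <- is.finite(directions)
    if (!any(has)) return(list(coordinatedBlocks = coord, alignment = align))
    idx <- which(has, arr.ind = TRUE)
    z <- exp(1i * directions[has])
    for (k in seq_len(nrow(idx))) {
        i <- idx[k, 1L]; j <- idx[k, 2L]
        d2 <- (idx[, 1L] - i)^2 + (idx[, 2L] - j)^2
        nb <- d2 <= radius^2
        if (sum(nb) < minNeighbors) next
        r <- Mod(mean(z[nb]))
        align[i, j] <- r
        coord[i, j] <- r >= rMin
    }
    list(coordinatedBlocks = coord, alignment = align)
}

#' Run the full moving/coordination pipeline on one movie
#'
#' Chains [computeMovingMask()], [computeRegionDirections()] and
#' [computeCoordinatedMask()] and reports the three area metrics:
#' percent of the field of view moving, percent moving and coordinated,
#' and percent of the moving area that is coordinated. Coordinated area
#' is measured as the moving pixels inside coordinated blocks, so it is
#' a subset of the moving area by construction.
#'
#' @inheritParams computeMovingMask
#' @inheritParams computeRegionDirections
#' @inheritParams computeCoordinatedMask
#' @param fov `"auto"`, a radius fraction in \[0, 1\], or a logical mask.
#' @return a [RegionMasks-class].
#' @export
stevenagePipeline <- function(movie, fov = 0.95, kSigma = 3,
                              blockSize = 32L, radius = 2, rMin = 0.8,
                              pairSpacing = 1L, qualityMin = 1.1,
                              openRadius = 2L, minArea = 25L,
                              minNeighbors = 3L, maxPairs = Inf) {
    fovMask <- if (is.matrix(fov)) fov else fitCircularMask(movie, fov)
    if (!any(fovMask)) stop("empty field-of-view mask")
    mv <- computeMovingMask(movie, fovMask, kSigma = kSigma,
                            openRadius = openRadius, minArea = minArea)
    rd <- computeRegionDirections(movie, mv$movingMask,
                                  blockSize = blockSize,
                                  pairSpacing = pairSpacing,
                                  qualityMin = qualityMin,
                                  maxPairs = maxPairs)
    cm <- computeCoordinatedMask(rd$blockDirections, radius = radius,
                                 rMin = rMin, minNeighbors = minNeighbors)
    fovArea <- sum(fovMask)
    movingArea <- sum(mv$movingMask)
    coordArea <- 0L
    if (any(cm$coordinatedBlocks)) {
        y0 <- as.integer(rd$y - (rd$blockSize - 1) / 2)
        x0 <- as.integer(rd$x - (rd$blockSize - 1) / 2)
        ij <- which(cm$coordinatedBlocks, arr.ind = TRUE)
        for (k in seq_len(nrow(ij))) {
            i <- ij[k, 1L]; j <- ij[k, 2L]
            coordArea <- coordArea +
                sum(mv$movingMask[y0[i]:(y0[i] + rd$blockSize - 1L),
                                  x0[j]:(x0[j] + rd$blockSize - 1L)])
        }
    }
    movingFraction <- 100 * movingArea / fovArea
    coordFraction <- 100 * coordArea / fovArea
    coordOfMoving <- if (movingArea > 0) 100 * coordArea / movingArea else 0
    new("RegionMasks", movingMask = mv$movingMask, fovMask = fovMask,
        blockSize = rd$blockSize, blockMoving = rd$blockMoving,
        blockDirections = rd$blockDirections,
        blockAlignment = cm$alignment,
        coordinatedBlocks = cm$coordinatedBlocks,
        movingFraction = movingFraction,
        coordinatedFraction = coordFraction,
        coordinatedOfMoving = coordOfMoving)
}

setMethod("show", "RegionMasks", function(object) {
    cat("RegionMasks (block size", object@blockSize, "px)\n")
    cat(sprintf("  moving area:            %.1f %% of FOV\n",
                object@movingFraction))
    cat(sprintf("  coordinated area:       %.1f %% of FOV\n",
                object@coordinatedFraction))
    cat(sprintf("  coordinated of moving:  %.1f %%\n",
                object@coordinatedOfMoving))
})
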