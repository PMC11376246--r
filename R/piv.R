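# "Cambridge" pipeline: per-window PIV flow fields, circular field-of-view
# masking, active-window classification against a noise floor, and the
# fraction of the culture moving above a control-derived speed threshold.

# Displacement of window B relative to window A by zero-padded normalized
# cross-correlation with triangular-overlap correction and a 3-point
# Gaussian subpixel peak fit. Positive dx means content moved towards
# larger x (columns), positive dy towards larger y (rows, i.e. down).
xcorrDisp <- function(A, B, maxShift) {
    n1 <- nrow(A); n2 <- ncol(A)
    A <- A - mean(A); B <- B - mean(B)
    sA <- sqrt(sum(A^2)); sB <- sqrt(sum(B^2))
    if (sA < 1e-12 || sB < 1e-12)
        return(list(dx = 0, dy = 0, quality = NA_real_, valid = FALSE))
    P1 <- 2L * n1; P2 <- 2L * n2
    pa <- matrix(0, P1, P2); pa[1:n1, 1:n2] <- A
    pb <- matrix(0, P1, P2); pb[1:n1, 1:n2] <- B
    cc <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb),
                        inverse = TRUE)) / (P1 * P2)
    m <- as.integer(maxShift)
    sh <- (-m):m
    idx1 <- ((sh) %% P1) + 1L
    idx2 <- ((sh) %% P2) + 1L
    reg <- cc[idx1, idx2, drop = FALSE]
    # correct the triangular overlap taper of linear correlation, then
    # normalize to a correlation coefficient
    taper <- ((1 - abs(sh) / n1) %o% (1 - abs(sh) / n2))
    reg <- reg / (taper * sA * sB)
    pk <- which(reg == max(reg), arr.ind = TRUE)[1L, ]
    iy <- pk[1L]; ix <- pk[2L]
    peak <- reg[iy, ix]
    # first-to-second peak ratio outside a 3x3 exclusion zone
    excl <- reg
    excl[max(1L, iy - 1L):min(nrow(reg), iy + 1L),
         max(1L, ix - 1L):min(ncol(reg), ix + 1L)] <- -Inf
    second <- max(excl)
    quality <- if (is.finite(second) && second > 0) peak / second else Inf

    subpix <- function(cm, c0, cp) {
        if (cm > 0 && c0 > 0 && cp > 0) {
            den <- 2 * (log(cm) - 2 * log(c0) + log(cp))
            if (abs(den) > 1e-12) return((log(cm) - log(cp)) / den)
        }
        den <- 2 * (cm - 2 * c0 + cp)
        if (abs(den) > 1e-12) (cm - cp) / den else 0
    }
    dy <- sh[iy]; dx <- sh[ix]
    if (iy > 1L && iy < nrow(reg)) {
        d <- subpix(reg[iy - 1L, ix], peak, reg[iy + 1L, ix])
        if (is.finite(d) && abs(d) < 1) dy <- dy + d
    }
    if (ix > 1L && ix < ncol(reg)) {
        d <- subpix(reg[iy, ix - 1L], peak, reg[iy, ix + 1L])
        if (is.finite(d) && abs(d) < 1) dx <- dx + d
    }
    list(dx = dx, dy = dy, quality = quality, valid = TRUE)
}

#' Compute a PIV flow velocity field
#'
#' Tiles the frame with interrogation windows (`windowSize` pixels, a
#' fractional `overlap` between neighbours) and, for every frame pair
#' `(t, t + pairSpacing)`, estimates the window displacement as the
#' subpixel-refined peak of the normalized cross-correlation of the two
#' windows. Per-window velocity is the vector mean of displacements over
#' all frame pairs, so incoherent jitter cancels while directed
#' transport survives; its magnitude, converted with the movie
#' calibration, is the window speed in um/s. Windows with zero intensity
#' variance contribute no displacement and are flagged invalid.
#'
#' @param movie a [MovieStack-class].
#' @param windowSize interrogation window side, pixels (>= 8).
#' @param overlap fractional overlap between neighbouring windows in
#'   \[0, 1).
#' @param pairSpacing frame separation of correlated pairs.
#' @param maxShift largest displacement searched, pixels (default
#'   `windowSize / 4`).
#' @param maxPairs optional cap on the number of frame pairs used
#'   (evenly subsampled); `Inf` uses all.
#' @return a [FlowField-class].
#' @examples
#' sim <- simulateBeadMovie(simConfig(imageSize = 64, nFrames = 5,
#'     nBeads = 60, patchGrid = 1, activeFraction = 1, coherence = 1,
#'     flowDirection = 0, noiseSD = 0, speedCV = 0, seed = 3))
#' ff <- computePivField(sim$movie, windowSize = 32, overlap = 0)
#' @export
computePivField <- function(movie, windowSize = 32L, overlap = 0.5,
                            pairSpacing = 1L, maxShift = NULL,
                            maxPairs = Inf) {
    stopifnot(is(movie, "MovieStack"))
    windowSize <- as.integer(windowSize)
    pairSpacing <- as.integer(pairSpacing)
    if (windowSize < 8L) stop("windowSize must be >= 8 px")
    if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
    d <- dim(movie@frames)
    if (d[3L] < pairSpacing + 1L)
        stop("movie needs at least pairSpacing + 1 frames")
    if (is.null(maxShift)) maxShift <- max(2L, windowSize %/% 4L)
    step <- max(1L, as.integer(round(windowSize * (1 - overlap))))
    y0 <- seq(1L, d[1L] - windowSize + 1L, by = step)
    x0 <- seq(1L, d[2L] - windowSize + 1L, by = step)
    ny <- length(y0); nx <- length(x0)
    if (!ny || !nx) stop("windowSize larger than the frame")

    starts <- seq_len(d[3L] - pairSpacing)
    if (is.finite(maxPairs) && length(starts) > maxPairs)
        starts <- starts[unique(as.integer(round(
            seq(1L, length(starts), length.out = maxPairs))))]

    sumU <- matrix(0, ny, nx); sumV <- matrix(0, ny, nx)
    altU <- matrix(0, ny, nx); altV <- matrix(0, ny, nx)
    lastU <- matrix(0, ny, nx); lastV <- matrix(0, ny, nx)
    lastSign <- matrix(1, ny, nx)
    cnt <- matrix(0L, ny, nx)
    qual <- array(NA_real_, c(ny, nx, length(starts)))
    for (k in seq_along(starts)) {
        t <- starts[k]
        fa <- movie@frames[, , t]
        fb <- movie@frames[, , t + pairSpacing]
        for (j in seq_len(nx)) for (i in seq_len(ny)) {
            ry <- y0[i]:(y0[i] + windowSize - 1L)
            rx <- x0[j]:(x0[j] + windowSize - 1L)
            r <- xcorrDisp(fa[ry, rx], fb[ry, rx], maxShift)
            if (r$valid) {
                sgn <- if (cnt[i, j] %% 2L == 0L) 1 else -1
                sumU[i, j] <- sumU[i, j] + r$dx
                sumV[i, j] <- sumV[i, j] + r$dy
                altU[i, j] <- altU[i, j] + sgn * r$dx
                altV[i, j] <- altV[i, j] + sgn * r$dy
                lastU[i, j] <- r$dx; lastV[i, j] <- r$dy
                lastSign[i, j] <- sgn
                cnt[i, j] <- cnt[i, j] + 1L
                qual[i, j, k] <- r$quality
            }
        }
    }
    u <- ifelse(cnt > 0L, sumU / cnt, NA_real_)
    v <- ifelse(cnt > 0L, sumV / cnt, NA_real_)
    toSpeed <- movie@pixelSize / (movie@frameInterval * pairSpacing)
    spd <- sqrt(u^2 + v^2) * toSpeed
    # alternating-sign null over an even number of pairs (drop the last
    # pair where the count is odd so equal-and-opposite terms pair up)
    odd <- cnt %% 2L == 1L
    aU <- ifelse(odd, altU - lastSign * lastU, altU)
    aV <- ifelse(odd, altV - lastSign * lastV, altV)
    nEven <- cnt - (cnt %% 2L)
    nullSpd <- ifelse(nEven > 0L, sqrt(aU^2 + aV^2) / pmax(nEven, 1L), NA_real_) *
        toSpeed
    nullSpd[cnt > 0L & nEven == 0L] <- 0
    q <- apply(qual, c(1, 2), function(z) {
        z <- z[is.finite(z)]
        if (length(z)) stats::median(z) else NA_real_
    })
    new("FlowField", x = x0 + (windowSize - 1) / 2,
        y = y0 + (windowSize - 1) / 2,
        u = u, v = v, speed = spd, quality = q,
        nullSpeed = nullSpd,
        nValidPairs = cnt,
        windowSize = windowSize, overlap = overlap,
        pairSpacing = pairSpacing,
        pixelSize = movie@pixelSize, frameInterval = movie@frameInterval)
}

#' @rdname FlowField-class
#' @export
setMethod("speeds", "FlowField", function(x) x@speed)

#' @rdname FlowField-class
#' @export
setMethod("displacements", "FlowField", function(x) list(u = x@u, v = x@v))

setMethod("show", "FlowField", function(object) {
    cat("FlowField:", length(object@y), "x", length(object@x),
        "windows of", object@windowSize, "px (overlap",
        object@overlap, ")\n")
    sp <- object@speed[is.finite(object@speed)]
    if (length(sp))
        cat(sprintf("  speed median %.3g um/s, max %.3g um/s\n",
                    stats::median(sp), max(sp)))
})

#' Fit the circular field-of-view mask
#'
#' With a numeric `radiusFraction` the circle is centred on the frame
#' with radius `radiusFraction * min(H, W) / 2`. In `"auto"` mode the
#' bright culture area of the temporal-mean image is segmented (Otsu
#' threshold, largest connected component) and the circle is centred on
#' its centroid with the component's 99th-percentile centroid distance
#' as radius.
#'
#' @param movie a [MovieStack-class].
#' @param radiusFraction numeric in \[0, 1\], or `"auto"`.
#' @return logical H x W matrix.
#' @export
fitCircularMask <- function(movie, radiusFraction = 0.95) {
    stopifnot(is(movie, "MovieStack"))
    d <- dim(movie@frames)
    if (identical(radiusFraction, "auto")) {
        avg <- apply(movie@frames, c(1, 2), mean)
        rng <- range(avg)
        if (diff(rng) < 1e-12) stop("auto FOV: no foreground component")
        nrm <- (avg - rng[1L]) / diff(rng)
        fg <- nrm > EBImage::otsu(nrm, range = c(0, 1))
        comp <- largestComponent(fg)
        if (is.null(comp)) stop("auto FOV: no foreground component")
        ij <- which(comp, arr.ind = TRUE)
        cy <- mean(ij[, 1L]); cx <- mean(ij[, 2L])
        rad <- stats::quantile(sqrt((ij[, 1L] - cy)^2 + (ij[, 2L] - cx)^2),
                               0.99, names = FALSE)
        dy <- (seq_len(d[1L]) - cy)^2
        dx <- (seq_len(d[2L]) - cx)^2
        return(outer(dy, dx, `+`) <= rad^2)
    }
    if (!is.numeric(radiusFraction) || radiusFraction < 0 || radiusFraction > 1)
        stop("radiusFraction must be in [0, 1] or \"auto\"")
    circularRaster(d[1L], d[2L], radiusFraction)
}

# TRUE for windows whose centre lies inside the (optional) FOV mask.
windowInFov <- function(field, fovMask) {
    if (is.null(fovMask))
        return(matrix(TRUE, length(field@y), length(field@x)))
    iy <- pmin(pmax(round(field@y), 1L), nrow(fovMask))
    ix <- pmin(pmax(round(field@x), 1L), ncol(fovMask))
    matrix(fovMask[cbind(rep(iy, times = length(ix)),
                         rep(ix, each = length(iy)))],
           length(iy), length(ix))
}

#' Estimate the speed noise floor of a flow field
#'
#' Self-calibrating no-transport null: for every window the
#' alternating-sign mean of its per-pair displacements cancels
#' temporally coherent transport exactly while preserving the
#' white frame-to-frame jitter that also drives the ordinary vector
#' mean. The floor is `k` times a high quantile of that null speed over
#' the in-FOV windows, so genuinely static windows sit comfortably
#' below it. The statistic is a deterministic function of the movie (no
#' resampling involved).
#'
#' @param field a [FlowField-class].
#' @param fovMask optional logical raster restricting the windows used.
#' @param k multiplier on the null quantile (default 3).
#' @param quantile quantile of the null speed distribution (default 0.95).
#' @return numeric(1), speed floor in um/s.
#' @export
estimateNoiseFloor <- function(field, fovMask = NULL, k = 3,
                               quantile = 0.95) {
    stopifnot(is(field, "FlowField"))
    inFov <- windowInFov(field, fovMask)
    sp <- field@nullSpeed[inFov & is.finite(field@nullSpeed)]
    if (!length(sp)) return(0)
    k * stats::quantile(sp, quantile, names = FALSE)
}

#' Classify active windows and report the active percentage
#'
#' A window counts as active when its centre lies in the field of view,
#' its correlation is scoreable (valid pairs and a first-to-second peak
#' ratio of at least `qualityMin`), and its time-averaged speed exceeds
#' the noise floor. Unscoreable windows are excluded from both numerator
#' and denominator so correlation artifacts are not mistaken for static
#' regions.
#'
#' @param field a [FlowField-class].
#' @param fovMask logical raster (or `NULL` for the whole frame).
#' @param noiseFloor speed floor in um/s; if `NULL`, estimated with
#'   [estimateNoiseFloor()] from the field's own null statistic.
#' @param qualityMin minimum correlation peak ratio (default 1.1).
#' @return list with `activeMask`, `scoreable` (logical window matrices),
#'   `percentActive`, and `noiseFloor`.
#' @export
classifyActive <- function(field, fovMask = NULL, noiseFloor = NULL,
                           qualityMin = 1.1) {
    stopifnot(is(field, "FlowField"))
    if (is.null(noiseFloor))
        noiseFloor <- estimateNoiseFloor(field, fovMask)
    inFov <- windowInFov(field, fovMask)
    scoreable <- inFov & field@nValidPairs > 0L &
        is.finite(field@speed) & is.finite(field@quality) &
        field@quality >= qualityMin
    if (!any(scoreable))
        stop("no scoreable in-FOV windows")
    active <- scoreable & field@speed > noiseFloor
    list(activeMask = active, scoreable = scoreable,
         percentActive = 100 * sum(active) / sum(scoreable),
         noiseFloor = noiseFloor)
}

#' Percentage of the field of view moving above a speed threshold
#'
#' Counts, among scoreable in-FOV windows, those that are active and
#' whose time-averaged speed exceeds `thresholdSpeed` (typically the
#' mean control speed from [computeControlThreshold()]). By
#' construction the above-threshold windows are a subset of the active
#' windows, so the returned percentage never exceeds the active
#' percentage.
#'
#' @param field a [FlowField-class].
#' @param active output of [classifyActive()] for the same field.
#' @param thresholdSpeed speed threshold, um/s (> 0).
#' @return list with `aboveMask` and `percentAboveThreshold`.
#' @export
fractionAboveThreshold <- function(field, active, thresholdSpeed) {
    stopifnot(is(field, "FlowField"), thresholdSpeed >= 0)
    above <- active$activeMask & field@speed > thresholdSpeed
    above[!is.finite(field@speed)] <- FALSE
    list(aboveMask = above,
         percentAboveThreshold = 100 * sum(above) / sum(active$scoreable))
}

#' Mean control speed as the group threshold
#'
#' Pools the time-averaged speeds of all active in-FOV windows across
#' the control movies of a batch and returns their arithmetic mean — the
#' "mean control speed" against which treated cultures are scored.
#' Inactive windows are excluded so the threshold reflects transport
#' speed, not the fraction of static culture.
#'
#' @param fields list of [FlowField-class] objects (one per control movie).
#' @param actives list of matching [classifyActive()] outputs.
#' @return numeric(1), threshold speed in um/s.
#' @export
computeControlThreshold <- function(fields, actives) {
    stopifnot(length(fields) == length(actives), length(fields) >= 1L)
    sp <- unlist(lapply(seq_along(fields), function(i) {
        f <- fields[[i]]; a <- actives[[i]]
        f@speed[a$activeMask & is.finite(f@speed)]
    }))
    if (!length(sp)) stop("no active control windows; cannot define threshold")
    mean(sp)
}

#' Run the full PIV quantification pipeline on one movie
#'
#' Computes the flow field, the circular field-of-view mask, the active
#' classification, and (when a threshold is supplied) the
#' above-threshold fraction, returning a [CambridgeResult-class].
#'
#' @inheritParams computePivField
#' @param fov `"auto"`, a radius fraction in \[0, 1\], or a logical mask.
#' @param noiseFloor speed floor in um/s, or `NULL` to self-calibrate.
#' @param thresholdSpeed control-derived threshold in um/s, or `NA` to
#'   skip the above-threshold metric.
#' @param qualityMin minimum correlation peak ratio.
#' @return a [CambridgeResult-class].
#' @export
cambridgePipeline <- function(movie, windowSize = 32L, overlap = 0.5,
                              pairSpacing = 1L, fov = 0.95,
                              noiseFloor = NULL, thresholdSpeed = NA_real_,
                              qualityMin = 1.1, maxPairs = Inf) {
    field <- computePivField(movie, windowSize = windowSize,
                             overlap = overlap, pairSpacing = pairSpacing,
                             maxPairs = maxPairs)
    fovMask <- if (is.matrix(fov)) fov else fitCircularMask(movie, fov)
    if (!any(fovMask)) stop("empty field-of-view mask")
    act <- classifyActive(field, fovMask, noiseFloor = noiseFloor,
                          qualityMin = qualityMin)
    if (is.finite(thresholdSpeed)) {
        ab <- fractionAboveThreshold(field, act, thresholdSpeed)
        aboveMask <- ab$aboveMask
        pctAbove <- ab$percentAboveThreshold
    } else {
        aboveMask <- act$activeMask & FALSE
        pctAbove <- NA_real_
    }
    new("CambridgeResult", field = field, fovMask = fovMask,
        activeMask = act$activeMask, aboveThresholdMask = aboveMask,
        percentActive = act$percentActive,
        percentAboveThreshold = pctAbove,
        thresholdSpeed = thresholdSpeed, noiseFloor = act$noiseFloor)
}

setMethod("show", "CambridgeResult", function(object) {
    cat("CambridgeResult\n")
    cat(sprintf("  percent active:          %.1f %%\n", object@percentActive))
    if (is.finite(object@percentAboveThreshold))
        cat(sprintf("  percent above threshold: %.1f %% (threshold %.3g um/s)\n",
                    object@percentAboveThreshold, object@thresholdSpeed))
    cat(sprintf("  noise floor:             %.3g um/s\n", object@noiseFloor))
})
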