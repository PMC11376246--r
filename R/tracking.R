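# Bead detection, track linking, per-specimen speeds, and whole-specimen
# drift quantification.

# Scale-normalized negative Laplacian-of-Gaussian kernel: positive
# response at bright blobs of width ~ sigma.
logKernel <- function(sigma) {
    r <- stampRadius(sigma)
    xs <- (-r):r
    g <- exp(-xs^2 / (2 * sigma^2))
    G <- g %o% g
    r2 <- outer(xs^2, xs^2, `+`)
    k <- -(r2 / sigma^2 - 2) * G      # -sigma^2 * LoG, up to a constant
    k - mean(k)
}

#' Detect bead spots in every frame
#'
#' Spot candidates are strict local maxima of the Laplacian-of-Gaussian
#' response at scale `spotSigma` whose response exceeds `snrMin` times
#' the robust spread (MAD) of the frame's response. Candidate positions
#' are refined to subpixel accuracy by a separable 3-point Gaussian fit
#' on the background-subtracted intensity, which is exact for an
#' isolated Gaussian spot. Detections closer than `3 * spotSigma` to
#' another detection are flagged as crowded (possible merges).
#'
#' @param movie a [MovieStack-class].
#' @param spotSigma expected spot width, pixels.
#' @param snrMin detection threshold in MAD units of the LoG response.
#' @return list of per-frame data.frames with columns `x`, `y`,
#'   `response`, `crowded`.
#' @export
detectBeads <- function(movie, spotSigma = 1.5, snrMin = 5) {
    stopifnot(is(movie, "MovieStack"))
    kern <- logKernel(spotSigma)
    d <- dim(movie@frames)
    out <- vector("list", d[3L])
    for (t in seq_len(d[3L])) {
        img <- movie@frames[, , t]
        if (diff(range(img)) < 1e-12) {
            out[[t]] <- data.frame(x = numeric(0), y = numeric(0),
                                   response = numeric(0), crowded = logical(0))
            next
        }
        resp <- EBImage::filter2(img, kern, boundary = "replicate")
        # floor the threshold above FFT round-off so featureless frames
        # cannot produce spurious maxima
        thr <- max(snrMin * stats::mad(as.vector(resp)),
                   1e-6 * diff(range(img)))
        # strict local maxima over the 8-neighbourhood
        h <- d[1L]; w <- d[2L]
        core <- resp[2:(h - 1), 2:(w - 1)]
        isMax <- core > thr
        for (dy in -1:1) for (dx in -1:1) {
            if (dy == 0L && dx == 0L) next
            isMax <- isMax &
                core > resp[(2:(h - 1)) + dy, (2:(w - 1)) + dx]
        }
        ij <- which(isMax, arr.ind = TRUE)
        if (!nrow(ij)) {
            out[[t]] <- data.frame(x = numeric(0), y = numeric(0),
                                   response = numeric(0), crowded = logical(0))
            next
        }
        py <- ij[, 1L] + 1L; px <- ij[, 2L] + 1L
        bg <- stats::median(img)
        sub <- function(cm, c0, cp) {
            if (cm > 0 && c0 > 0 && cp > 0) {
                den <- 2 * (log(cm) - 2 * log(c0) + log(cp))
                if (abs(den) > 1e-12) {
                    v <- (log(cm) - log(cp)) / den
                    if (is.finite(v) && abs(v) < 1) return(v)
                }
            }
            den <- 2 * (cm - 2 * c0 + cp)
            v <- if (abs(den) > 1e-12) (cm - cp) / den else 0
            if (is.finite(v) && abs(v) < 1) v else 0
        }
        xs <- ys <- numeric(length(py))
        for (k in seq_along(py)) {
            i <- py[k]; j <- px[k]
            ys[k] <- i + sub(img[i - 1L, j] - bg, img[i, j] - bg,
                             img[i + 1L, j] - bg)
            xs[k] <- j + sub(img[i, j - 1L] - bg, img[i, j] - bg,
                             img[i, j + 1L] - bg)
        }
        crowded <- rep(FALSE, length(xs))
        if (length(xs) > 1L) {
            dd <- as.matrix(stats::dist(cbind(xs, ys)))
            diag(dd) <- Inf
            crowded <- apply(dd, 1L, min) < 3 * spotSigma
        }
        out[[t]] <- data.frame(x = xs, y = ys,
                               response = resp[cbind(py, px)],
                               crowded = crowded)
    }
    out
}

#' Link detections into bead trajectories
#'
#' Frame-to-frame assignment by greedy globally-nearest pairing (each
#' accepted pair is a mutual nearest neighbour) with a hard distance
#' cutoff, TrackMate-style. A track missing detections may be bridged
#' across up to `maxGap` frames, with the cutoff scaled by the number of
#' frames spanned. Tracks with fewer than `minTrackLength` detections
#' are discarded.
#'
#' @param detections list of per-frame data.frames with columns `x`, `y`
#'   (as from [detectBeads()]).
#' @param maxDisplacement linking cutoff in pixels per frame step.
#' @param minTrackLength minimum detections per reported track.
#' @param maxGap maximum frames bridged by gap closing (0 = none).
#' @return a [TrackSet-class].
#' @export
linkTracks <- function(detections, maxDisplacement, minTrackLength = 3L,
                       maxGap = 2L) {
    minTrackLength <- as.integer(minTrackLength)
    maxGap <- as.integer(maxGap)
    open <- list()     # each: list(rows = data.frame(frame, x, y))
    closed <- list()
    for (f in seq_along(detections)) {
        det <- detections[[f]]
        nd <- if (is.null(det)) 0L else nrow(det)
        # retire tracks whose gap can no longer be bridged
        if (length(open)) {
            last <- vapply(open, function(tr) tr$last, numeric(1))
            expired <- f - last - 1L > maxGap
            closed <- c(closed, open[expired])
            open <- open[!expired]
        }
        if (nd == 0L) next
        assigned <- rep(FALSE, nd)
        if (length(open)) {
            tx <- vapply(open, function(tr) tr$x, numeric(1))
            ty <- vapply(open, function(tr) tr$y, numeric(1))
            tl <- vapply(open, function(tr) tr$last, numeric(1))
            cutoff <- maxDisplacement * (f - tl)
            dd <- sqrt(outer(tx, det$x, `-`)^2 + outer(ty, det$y, `-`)^2)
            dd[dd > cutoff] <- Inf
            trackFree <- rep(TRUE, length(open))
            while (any(is.finite(dd))) {
                k <- arrayInd(which.min(dd), dim(dd))
                i <- k[1L]; j <- k[2L]
                tr <- open[[i]]
                tr$rows <- rbind(tr$rows,
                                 data.frame(frame = f, x = det$x[j],
                                            y = det$y[j]))
                tr$last <- f; tr$x <- det$x[j]; tr$y <- det$y[j]
                open[[i]] <- tr
                trackFree[i] <- FALSE
                assigned[j] <- TRUE
                dd[i, ] <- Inf
                dd[, j] <- Inf
            }
        }
        for (j in which(!assigned)) {
            open[[length(open) + 1L]] <- list(
                rows = data.frame(frame = f, x = det$x[j], y = det$y[j]),
                last = f, x = det$x[j], y = det$y[j])
        }
    }
    closed <- c(closed, open)
    keep <- vapply(closed, function(tr) nrow(tr$rows) >= minTrackLength,
                   logical(1))
    closed <- closed[keep]
    if (length(closed)) {
        ord <- order(vapply(closed, function(tr) tr$rows$frame[1L], numeric(1)),
                     vapply(closed, function(tr) tr$rows$x[1L], numeric(1)),
                     vapply(closed, function(tr) tr$rows$y[1L], numeric(1)))
        closed <- closed[ord]
        df <- do.call(rbind, lapply(seq_along(closed), function(i) {
            r <- closed[[i]]$rows
            data.frame(track_id = i, frame = r$frame, x = r$x, y = r$y)
        }))
    } else {
        df <- data.frame(track_id = integer(0), frame = integer(0),
                         x = numeric(0), y = numeric(0))
    }
    rownames(df) <- NULL
    new("TrackSet", tracks = df, maxDisplacement = maxDisplacement,
        minTrackLength = minTrackLength, maxGap = maxGap)
}

#' @rdname TrackSet-class
#' @export
setMethod("tracks", "TrackSet", function(x) x@tracks)

#' @rdname TrackSet-class
#' @export
setMethod("nTracks", "TrackSet", function(x)
    length(unique(x@tracks$track_id)))

setMethod("show", "TrackSet", function(object) {
    n <- nTracks(object)
    cat("TrackSet:", n, "tracks,", nrow(object@tracks), "localizations\n")
    if (n) {
        len <- table(object@tracks$track_id)
        cat(sprintf("  track length median %d, range %d-%d frames\n",
                    as.integer(stats::median(len)), min(len), max(len)))
    }
})

#' Per-track and per-specimen speeds
#'
#' The speed of one track is its total path length (sum of step
#' distances, in micrometres) divided by its duration; the specimen
#' speed is the unweighted arithmetic mean over its tracks, matching the
#' "tracks averaged across each specimen" convention. A net-displacement
#' speed (straight-line distance over duration) is reported alongside.
#'
#' @param trackset a [TrackSet-class] with at least one track.
#' @param pixelSize micrometres per pixel.
#' @param frameInterval seconds per frame step.
#' @return list with `perTrack` (data.frame: `track_id`, `n_frames`,
#'   `path_speed_um_s`, `net_speed_um_s`) and `specimenSpeed` (um/s,
#'   mean of per-track path speeds).
#' @export
specimenSpeed <- function(trackset, pixelSize, frameInterval) {
    stopifnot(is(trackset, "TrackSet"))
    tr <- trackset@tracks
    if (!nrow(tr)) stop("empty TrackSet: specimen speed undefined")
    sp <- lapply(split(tr, tr$track_id), function(g) {
        g <- g[order(g$frame), ]
        steps <- sqrt(diff(g$x)^2 + diff(g$y)^2)
        dur <- (g$frame[nrow(g)] - g$frame[1L]) * frameInterval
        if (dur <= 0) return(NULL)
        data.frame(track_id = g$track_id[1L], n_frames = nrow(g),
                   path_speed_um_s = sum(steps) * pixelSize / dur,
                   net_speed_um_s = sqrt((g$x[nrow(g)] - g$x[1L])^2 +
                                         (g$y[nrow(g)] - g$y[1L])^2) *
                       pixelSize / dur)
    })
    perTrack <- do.call(rbind, sp)
    if (is.null(perTrack) || !nrow(perTrack))
        stop("no track with positive duration")
    rownames(perTrack) <- NULL
    list(perTrack = perTrack,
         specimenSpeed = mean(perTrack$path_speed_um_s))
}

#' Quantify whole-specimen drift from a brightfield movie
#'
#' Each frame is segmented by Otsu's threshold; the minority intensity
#' class (the specimen against its background, whichever side of the
#' threshold covers less area) is labelled and the largest connected
#' component's centroid is recorded. Drift speed is the net centroid
#' displacement over the elapsed time; the path ratio is net over total
#' path length (1 for straight drift, near 0 for wandering that returns
#' to the start, and 0 by convention for a stationary specimen).
#'
#' @param movie a [MovieStack-class].
#' @return a [DriftResult-class].
#' @export
embryoDrift <- function(movie) {
    stopifnot(is(movie, "MovieStack"))
    d <- dim(movie@frames)
    cent <- matrix(NA_real_, d[3L], 2L)
    for (t in seq_len(d[3L])) {
        img <- movie@frames[, , t]
        rng <- range(img)
        if (diff(rng) < 1e-12)
            stop("no object found in frame ", t)
        nrm <- (img - rng[1L]) / diff(rng)
        thr <- EBImage::otsu(nrm, range = c(0, 1))
        dark <- nrm < thr
        obj <- if (sum(dark) <= length(dark) / 2) dark else !dark
        comp <- largestComponent(obj)
        if (is.null(comp)) stop("no object found in frame ", t)
        ij <- which(comp, arr.ind = TRUE)
        cent[t, ] <- c(mean(ij[, 2L]), mean(ij[, 1L]))   # (x, y)
    }
    net <- sqrt(sum((cent[d[3L], ] - cent[1L, ])^2))
    total <- sum(sqrt(rowSums(diff(cent)^2)))
    elapsed <- (d[3L] - 1L) * movie@frameInterval
    new("DriftResult",
        centroids = data.frame(frame = seq_len(d[3L]),
                               x = cent[, 1L], y = cent[, 2L]),
        driftSpeed = net * movie@pixelSize / elapsed,
        driftPathRatio = if (total > 1e-9) min(net / total, 1) else 0,
        pixelSize = movie@pixelSize,
        frameInterval = movie@frameInterval)
}

setMethod("show", "DriftResult", function(object) {
    cat(sprintf("DriftResult: %.4g um/s over %d frames, path ratio %.2f\n",
                object@driftSpeed, nrow(object@centroids),
                object@driftPathRatio))
})
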