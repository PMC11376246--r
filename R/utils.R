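# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else {
            assign(".Random.seed", old, envir = globalenv())
        }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    force(code)
}

#' Mean resultant length of a set of angles
#'
#' The standard circular-statistics coherence measure: 1 when all angles
#' coincide, approaching 0 for many independent uniform angles (Rayleigh
#' expectation about `0.886/sqrt(n)`).
#'
#' @param theta numeric vector of angles in radians; `NA` values dropped.
#' @return numeric(1) in \[0, 1\]; `NA` if no finite angle remains.
#' @export
meanResultantLength <- function(theta) {
    theta <- theta[is.finite(theta)]
    if (!length(theta)) return(NA_real_)
    Mod(mean(exp(1i * theta)))
}

# Circular variance, 1 - R.
circularVariance <- function(theta) 1 - meanResultantLength(theta)

# Per-pixel temporal standard deviation of a H x W x T array.
temporalSD <- function(a) {
    d <- dim(a)
    m <- matrix(a, d[1L] * d[2L], d[3L])
    mu <- rowMeans(m)
    s2 <- rowSums((m - mu)^2) / (d[3L] - 1L)
    matrix(sqrt(pmax(s2, 0)), d[1L], d[2L])
}

# Circular boolean raster centred on the frame.
circularRaster <- function(h, w, radiusFraction) {
    cy <- (h + 1) / 2
    cx <- (w + 1) / 2
    r <- radiusFraction * min(h, w) / 2
    dy <- (seq_len(h) - cy)^2
    dx <- (seq_len(w) - cx)^2
    outer(dy, dx, `+`) <= r^2
}

# Largest connected component of a logical matrix (8-connectivity).
largestComponent <- function(mask) {
    lab <- EBImage::bwlabel(mask)
    if (max(lab) == 0L) return(NULL)
    tab <- tabulate(lab[lab > 0L])
    lab == which.max(tab)
}

stampRadius <- function(sigma) max(2L, ceiling(4 * sigma))
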