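# Aggregation of per-movie metrics into group summaries, and a
# distribution-free two-group comparison.

#' Summarize metrics by group
#'
#' Aggregates a long metrics table (as produced by [metricsRows()],
#' optionally with a `batch` column) to mean, SD and n per
#' (batch, group, metric).
#'
#' @param table data.frame with columns `group`, `metric`, `value`, and
#'   optionally `batch`.
#' @param groups optional character vector of expected group labels; any
#'   label in the table outside this set is an error.
#' @return data.frame with columns `batch` (if present), `group`,
#'   `metric`, `mean`, `sd`, `n`.
#' @export
summarizeGroups <- function(table, groups = NULL) {
    stopifnot(all(c("group", "metric", "value") %in% names(table)))
    if (!is.null(groups)) {
        bad <- setdiff(unique(table$group), groups)
        if (length(bad))
            stop("unknown group label(s): ", paste(bad, collapse = ", "))
    }
    if (any(!is.finite(table$value)))
        stop("metric values must be finite")
    keys <- c(if ("batch" %in% names(table)) "batch", "group", "metric")
    agg <- stats::aggregate(table$value, table[keys], function(v)
        c(mean = mean(v), sd = stats::sd(v), n = length(v)))
    out <- cbind(agg[keys],
                 mean = agg$x[, "mean"],
                 sd = agg$x[, "sd"],
                 n = as.integer(agg$x[, "n"]))
    out[do.call(order, out[keys]), , drop = FALSE]
}

#' Permutation test for a two-group difference in means
#'
#' A distribution-free, self-contained check of group separation:
#' the observed absolute difference of group means is compared with its
#' distribution under `nPerm` random relabelings of specimens. The
#' two-sided p-value uses the add-one convention
#' `(1 + #{perm >= obs}) / (nPerm + 1)` and is deterministic for a fixed
#' seed.
#'
#' @param table long metrics data.frame (columns `group`, `metric`,
#'   `value`), or `NULL` when `values` and `labels` are given directly.
#' @param metric metric name to test (when `table` is given).
#' @param nPerm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @param values,labels alternative direct interface: numeric values and
#'   a two-level group labelling.
#' @return list with `p.value`, `observed` (difference of means,
#'   group1 - group2 in label sort order), and `nPerm`.
#' @export
permutationGroupTest <- function(table = NULL, metric = NULL, nPerm = 1000L,
                                 seed = 1L, values = NULL, labels = NULL) {
    if (!is.null(table)) {
        stopifnot(!is.null(metric))
        sub <- table[table$metric == metric, ]
        values <- sub$value
        labels <- sub$group
    }
    nPerm <- as.integer(nPerm)
    if (nPerm < 100L) stop("nPerm must be >= 100")
    labels <- as.character(labels)
    lev <- sort(unique(labels))
    if (length(lev) != 2L) stop("exactly two groups required")
    g1 <- values[labels == lev[1L]]
    g2 <- values[labels == lev[2L]]
    if (length(g1) < 3L || length(g2) < 3L)
        stop("need >= 3 specimens per group")
    obs <- mean(g1) - mean(g2)
    pooled <- c(g1, g2)
    n1 <- length(g1)
    exceed <- withSeed(seed, {
        sum(vapply(seq_len(nPerm), function(i) {
            idx <- sample.int(length(pooled), n1)
            abs(mean(pooled[idx]) - mean(pooled[-idx])) >= abs(obs) - 1e-12
        }, logical(1)))
    })
    list(p.value = (1 + exceed) / (nPerm + 1), observed = obs, nPerm = nPerm)
}
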