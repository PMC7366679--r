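#' Two-sided unpaired Student's t-test (pooled variance)
#'
#' Equal-variance two-sample t-test as used for all differential comparisons
#' in the pipeline. Degenerate inputs follow a documented convention: if the
#' pooled variance is zero the p-value is 1 when the group means are equal
#' and 0 when they differ (an infinitely precise difference).
#'
#' @param group_a,group_b numeric vectors, each of length >= 2, finite.
#' @return list with elements `statistic` (t) and `p.value`.
#' @examples
#' studentTTwoSided(c(1, 2, 3), c(4, 5, 6))
#' @export
studentTTwoSided <- function(group_a, group_b) {
    if (length(group_a) < 2 || length(group_b) < 2)
        stop("each group needs at least 2 observations")
    if (!all(is.finite(group_a)) || !all(is.finite(group_b)))
        stop("groups must be finite numeric vectors")
    na <- length(group_a); nb <- length(group_b)
    ma <- mean(group_a); mb <- mean(group_b)
    df <- na + nb - 2
    pooled <- (sum((group_a - ma)^2) + sum((group_b - mb)^2)) / df
    stderr <- sqrt(pooled * (1 / na + 1 / nb))
    # degenerate (essentially constant) groups: documented convention
    if (stderr < 10 * .Machine$double.eps * max(abs(ma), abs(mb), 1)) {
        eq <- abs(ma - mb) <= stderr
        return(list(statistic = if (eq) 0 else sign(ma - mb) * Inf,
                    p.value = if (eq) 1.0 else 0.0))
    }
    tstat <- (ma - mb) / stderr
    list(statistic = tstat,
         p.value = 2 * stats::pt(-abs(tstat), df))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around the standard step-up false discovery rate
#' adjustment; output order matches input order and values are capped at 1.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return numeric vector of BH-adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(pvalues) {
    if (!is.numeric(pvalues) || anyNA(pvalues) ||
        any(pvalues < 0 | pvalues > 1))
        stop("pvalues must be numeric in [0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value sums hypergeometric probabilities, over all tables
#' with the observed margins, that do not exceed the observed table's
#' probability (ties resolved with a relative tolerance of 1e-7). Any zero
#' margin makes the table degenerate and returns p = 1.
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return the two-sided p-value.
#' @examples
#' fisherTwoSided(matrix(c(8, 62, 150, 4000), nrow = 2))
#' @export
fisherTwoSided <- function(table) {
    table <- as.matrix(table)
    if (!all(dim(table) == c(2, 2)))
        stop("table must be 2x2")
    if (any(table < 0) || any(table != round(table)))
        stop("table entries must be non-negative integers")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        return(1.0)
    stats::fisher.test(table, alternative = "two.sided")$p.value
}

## Run a computation with a private RNG stream, restoring the caller's state.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}
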