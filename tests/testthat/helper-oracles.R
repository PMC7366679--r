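# Independent oracles, deliberately written from first principles so they
# share no code path with the package implementations they check.

# Step-up false discovery rate adjustment, direct from the definition:
# q_(i) = min_{j >= i} ( p_(j) * n / j ), capped at 1, in input order.
bhStepUpOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    ranked <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(ranked)))
    adj <- pmin(adj, 1)
    out <- numeric(n)
    out[o] <- adj
    out
}

# Two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins; tables with probability <= observed (relative
# tolerance 1e-7) contribute.
fisherEnumOracle <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1])
    if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1.0)
    n <- r1 + r2
    a_vals <- max(0, c1 - r2):min(r1, c1)
    probs <- vapply(a_vals, function(a)
        exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)),
        numeric(1))
    p_obs <- probs[a_vals == tab[1, 1]]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided pooled-variance t-test p-value with the t CDF obtained by
# numerical integration of the density (no call to pt).
tTestOracle <- function(a, b) {
    na <- length(a); nb <- length(b)
    df <- na + nb - 2
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
    tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    dens <- function(x)
        gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
        (1 + x^2 / df)^(-(df + 1) / 2)
    upper <- stats::integrate(dens, abs(tstat), Inf,
                              rel.tol = 1e-12)$value
    2 * upper
}

# Regular-language motif oracle: R/K at -3 or -4, phosphoacceptor S/T,
# proline at +1 — expressed as explicit regex alternatives anchored to the
# site position.
motifRegexOracle <- function(sequence, site_index) {
    n <- nchar(sequence)
    if (site_index + 1 > n) return(FALSE)
    site_ok <- grepl("^[ST]P", substr(sequence, site_index, n))
    if (!site_ok) return(FALSE)
    for (off in c(3, 4)) {
        i <- site_index - off
        if (i >= 1 && substr(sequence, i, i) %in% c("R", "K"))
            return(TRUE)
    }
    FALSE
}

# Sample covariance eigendecomposition for the PCA cross-check.
pcaEigenOracle <- function(abundances) {
    x <- t(log2(abundances))
    x <- sweep(x, 2, colMeans(x))
    ev <- eigen(stats::cov(x), symmetric = TRUE)
    scores <- x %*% ev$vectors
    list(scores = scores, values = ev$values)
}
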