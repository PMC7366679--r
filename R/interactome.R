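## Differential AP-MS/BioID interactomics: high-confidence interactor
## filtering, bait normalization, low-quantile (MNAR) imputation,
## equal-variance t-testing with BH adjustment per mutant-vs-reference
## contrast, regulation calls, cancer-driver enrichment and replicate QC.

#' Filter interactor records to the high-confidence set
#'
#' AP-MS preys are kept iff their SAINT score is strictly above the AP-MS
#' cutoff; BioID preys require a score at or above the (by default perfect)
#' BioID cutoff. Survivors are then removed if seen in more than the
#' allowed fraction of contaminant-control runs or in the GFP control
#' pulldowns.
#'
#' @param records interactor data.frame (see [readInteractorTable]).
#' @param thresholds an [InteractomeThresholds-class].
#' @return the filtered data.frame.
#' @export
filterHighConfidence <- function(records,
                                 thresholds = interactomeThresholds()) {
    unknown <- setdiff(unique(records$method), c("APMS", "BioID"))
    if (length(unknown))
        stop("unknown method value(s): ", paste(unknown, collapse = ", "))
    keep <- ifelse(records$method == "APMS",
                   records$saint_score > thresholds@saint_apms,
                   records$saint_score >= thresholds@saint_bioid)
    keep <- keep &
        records$control_frequency <= thresholds@control_freq_max &
        !records$in_gfp_control
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Normalize prey intensities to the bait intensity of the same run
#'
#' Every intensity is divided by the bait intensity of its (condition,
#' replicate); the bait itself maps to exactly 1. Per-run global scale
#' factors (injection amount, instrument response) cancel.
#'
#' @param records long quant data.frame.
#' @param bait_id identifier of the bait analyte; must be quantified and
#'   positive in every run.
#' @return the normalized data.frame.
#' @export
baitNormalize <- function(records, bait_id) {
    bait <- records[records$analyte_id == bait_id, , drop = FALSE]
    runs <- unique(records[, c("condition", "replicate")])
    key <- paste(bait$condition, bait$replicate)
    run_key <- paste(runs$condition, runs$replicate)
    miss <- !run_key %in% key[!is.na(bait$intensity) & bait$intensity > 0]
    if (any(miss))
        stop("bait not quantified in ",
             paste(runs$condition[miss], runs$replicate[miss], sep = "/",
                   collapse = ", "))
    denom <- bait$intensity[match(paste(records$condition,
                                        records$replicate), key)]
    records$intensity <- records$intensity / denom
    records
}

#' Impute missing intensities from a low-quantile distribution
#'
#' Missing log2 intensities are replaced by seeded draws from a Normal
#' centred at the 5th percentile of the observed log2 intensities with
#' standard deviation `width_factor` times the observed log2 sd, truncated
#' below at the observed minimum minus 3 sd — the classic down-shifted
#' imputation for values missing because they fell below the detection
#' limit. Imputation is applied only to analytes observed in at least half
#' of the runs of at least one condition; analytes absent everywhere (or
#' below that support) are left missing and flagged in the
#' `imputation_skipped` attribute.
#'
#' @param records long quant data.frame (raw or normalized intensities).
#' @param q quantile defining the centre of the imputation distribution.
#' @param width_factor multiplier of the observed sd.
#' @param seed integer seed for the draws.
#' @return the data.frame with missing intensities filled in; attribute
#'   `imputation_skipped` lists analytes left untouched.
#' @export
imputeLowQuantile <- function(records, q = 0.05, width_factor = 0.3,
                              seed = 1L) {
    obs <- records$intensity[!is.na(records$intensity)]
    if (length(obs) < 20)
        stop("need at least 20 observed values for a stable low quantile")
    l2 <- log2(obs)
    centre <- stats::quantile(l2, q, names = FALSE)
    sdev <- width_factor * stats::sd(l2)
    lower <- min(l2) - 3 * sdev

    n_runs_per_cond <- tapply(records$replicate, records$condition,
                              function(x) length(unique(x)))
    obs_tab <- tapply(!is.na(records$intensity),
                      list(records$analyte_id, records$condition), sum)
    eligible <- rownames(obs_tab)[apply(obs_tab, 1, function(x)
        any(x >= n_runs_per_cond[colnames(obs_tab)] / 2, na.rm = TRUE))]
    skipped <- setdiff(unique(records$analyte_id), eligible)

    fill <- which(is.na(records$intensity) &
                  records$analyte_id %in% eligible)
    if (length(fill)) {
        draws <- withSeed(seed,
                          pmax(stats::rnorm(length(fill), centre, sdev),
                               lower))
        records$intensity[fill] <- 2^draws
    }
    attr(records, "imputation_skipped") <- skipped
    records
}

#' Differential interaction analysis against the reference condition
#'
#' For every prey and every non-reference condition: log2FC is the mean
#' log2 intensity difference to the reference, the p-value comes from the
#' two-sided equal-variance t-test on log2 intensities, and adjustment is
#' BH within the mutant-vs-reference contrast. A prey is called up/down iff
#' |log2FC| exceeds the fold-change threshold strictly and the adjusted p
#' is at or below the significance threshold. Analytes without at least
#' two observations in both groups of a contrast are excluded from it.
#'
#' @param records long quant data.frame of (normalized, imputed)
#'   intensities.
#' @param reference name of the reference condition.
#' @param thresholds an [InteractomeThresholds-class] (fold-change and
#'   adjusted-p thresholds are used).
#' @return data.frame with analyte_id, condition, log2fc, pvalue,
#'   adj_pvalue, regulated.
#' @export
differentialInteractome <- function(records, reference,
                                    thresholds = interactomeThresholds()) {
    differentialByCondition(records, reference,
                            fc_thresh = thresholds@fc_thresh,
                            adj_p_thresh = thresholds@adj_p_thresh)
}

## Shared engine for all per-contrast differential layers.
differentialByCondition <- function(records, reference, fc_thresh,
                                    adj_p_thresh, strict_p = FALSE) {
    if (!reference %in% records$condition)
        stop("reference condition '", reference, "' absent from the data")
    conds <- setdiff(unique(records$condition), reference)
    ref_df <- records[records$condition == reference, , drop = FALSE]
    out <- list()
    excluded <- character()
    for (cond in conds) {
        mut_df <- records[records$condition == cond, , drop = FALSE]
        ids <- union(unique(mut_df$analyte_id), unique(ref_df$analyte_id))
        res <- lapply(ids, function(id) {
            a <- mut_df$intensity[mut_df$analyte_id == id]
            b <- ref_df$intensity[ref_df$analyte_id == id]
            a <- log2(a[!is.na(a)])
            b <- log2(b[!is.na(b)])
            if (length(a) < 2 || length(b) < 2) return(NULL)
            ht <- studentTTwoSided(a, b)
            data.frame(analyte_id = id, condition = cond,
                       log2fc = mean(a) - mean(b), pvalue = ht$p.value,
                       stringsAsFactors = FALSE)
        })
        dropped <- ids[vapply(res, is.null, logical(1))]
        if (length(dropped))
            excluded <- union(excluded, dropped)
        res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
        if (is.null(res)) next
        res$adj_pvalue <- bhAdjust(res$pvalue)
        sig <- if (strict_p) res$adj_pvalue < adj_p_thresh
               else res$adj_pvalue <= adj_p_thresh
        res$regulated <- ifelse(sig & res$log2fc > fc_thresh, "up",
                         ifelse(sig & res$log2fc < -fc_thresh, "down",
                                "none"))
        out[[cond]] <- res
    }
    if (length(excluded))
        message("excluded from testing (insufficient observations): ",
                length(excluded), " analyte-contrast combinations")
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(analyte_id = character(), condition = character(),
                          log2fc = numeric(), pvalue = numeric(),
                          adj_pvalue = numeric(), regulated = character(),
                          stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
}

#' Count regulated analytes in one condition
#'
#' @param results differential results data.frame.
#' @param condition the condition to count in.
#' @return named numeric vector: n_up, n_down, n_total (= up + down).
#' @export
countRegulated <- function(results, condition) {
    r <- results$regulated[results$condition == condition]
    c(n_up = sum(r == "up"), n_down = sum(r == "down"),
      n_total = sum(r != "none"))
}

#' Cancer-driver enrichment in an interactor set
#'
#' Fraction of cancer-driver proteins among the interactors and the
#' two-sided Fisher p-value of the 2x2 table (driver vs non-driver) x
#' (interactor vs background-only).
#'
#' @param interactors character set of interactor ids (subset of
#'   `background`).
#' @param cdp_list character set of cancer-driver ids.
#' @param background character background universe (e.g. the measured
#'   proteome).
#' @return list with `fraction_cdp`, `n_cdp`, `n_interactors`, `p.value`.
#' @export
cdpEnrichment <- function(interactors, cdp_list, background) {
    interactors <- unique(interactors)
    if (!length(interactors)) stop("empty interactor set")
    if (!all(interactors %in% background))
        stop("interactors must be a subset of the background")
    rest <- setdiff(background, interactors)
    a <- sum(interactors %in% cdp_list)
    tab <- matrix(c(a, length(interactors) - a,
                    sum(rest %in% cdp_list),
                    length(rest) - sum(rest %in% cdp_list)),
                  nrow = 2, byrow = TRUE)
    list(fraction_cdp = a / length(interactors), n_cdp = a,
         n_interactors = length(interactors),
         p.value = fisherTwoSided(tab))
}

#' Per-analyte replicate coefficient of variation
#'
#' CV = sd/mean of the raw intensities across replicates, per analyte and
#' condition (observed values only; at least two required). The summary
#' reports the median CV and the fraction exceeding a QC bound.
#'
#' @param records long quant data.frame of raw intensities.
#' @param qc_bound CV bound used in the summary.
#' @return list with `per_analyte` (analyte_id, condition, cv) and
#'   `summary` (median_cv, fraction_above_bound, qc_bound).
#' @export
replicateCV <- function(records, qc_bound = 0.21) {
    grp <- split(records$intensity,
                 list(records$analyte_id, records$condition), drop = TRUE)
    cv <- vapply(grp, function(x) {
        x <- x[!is.na(x)]
        if (length(x) < 2) return(NA_real_)
        stats::sd(x) / mean(x)
    }, numeric(1))
    keys <- strsplit(names(cv), ".", fixed = TRUE)
    per <- data.frame(
        analyte_id = vapply(keys, `[`, character(1), 1),
        condition = vapply(keys, `[`, character(1), 2),
        cv = unname(cv), stringsAsFactors = FALSE)
    per <- per[!is.na(per$cv), , drop = FALSE]
    rownames(per) <- NULL
    list(per_analyte = per,
         summary = c(median_cv = stats::median(per$cv),
                     fraction_above_bound = mean(per$cv > qc_bound),
                     qc_bound = qc_bound))
}
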