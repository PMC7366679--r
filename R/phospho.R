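## DIA phospho- and total-proteome layer: feature quality filtering,
## decoy-based FDR with FFT scaling, total-ion normalization, fragment
## selection and peptide roll-up, differential testing, kinase-motif
## matching and enrichment, and per-condition regulation summaries.

#' Filter DIA features on m-score and detection rate
#'
#' A feature (analyte) is kept iff its best (smallest) m-score over all
#' runs is at or below the cutoff AND it is detected (non-missing) in at
#' least the required fraction of all runs, the denominator being every
#' (condition, replicate) present in the table.
#'
#' @param records long quant data.frame with an `mscore` column.
#' @param mscore_max m-score cutoff (0.01 for the phospho layer, the
#'   global proteome cutoff for the total-proteome layer).
#' @param detection_rate_min minimum detected fraction of all runs
#'   (inclusive).
#' @return the filtered data.frame.
#' @export
filterDiaFeatures <- function(records, mscore_max = 0.01,
                              detection_rate_min = 0.30) {
    n_runs <- nrow(unique(records[, c("condition", "replicate")]))
    best <- tapply(records$mscore, records$analyte_id, min, na.rm = TRUE)
    det <- tapply(!is.na(records$intensity), records$analyte_id, sum)
    keep_ids <- names(best)[best <= mscore_max &
                            det[names(best)] / n_runs >= detection_rate_min]
    out <- records[records$analyte_id %in% keep_ids, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Decoy-based FDR estimate scaled by the fraction of false targets
#'
#' FDR = fft * n_decoy / n_target. The FFT scaling accounts for targets
#' that are genuinely absent, making the raw decoy/target ratio an
#' overestimate.
#'
#' @param n_decoy,n_target non-negative integer counts; n_target > 0.
#' @param fft fraction of false targets in (0, 1].
#' @return the estimated FDR.
#' @examples
#' fdrFromFft(100, 1000, 0.46)  # 0.046
#' @export
fdrFromFft <- function(n_decoy, n_target, fft = 0.46) {
    if (n_target <= 0) stop("n_target must be positive")
    if (n_decoy < 0) stop("n_decoy must be non-negative")
    if (fft <= 0 || fft > 1) stop("fft must be in (0, 1]")
    fft * n_decoy / n_target
}

#' Total ion signal normalization
#'
#' Scales every run so its total intensity equals the mean of all run
#' totals; the grand total is conserved exactly.
#'
#' @param records long quant data.frame.
#' @return the normalized data.frame.
#' @export
tisNormalize <- function(records) {
    run <- paste(records$condition, records$replicate, sep = ".")
    totals <- tapply(records$intensity, run, sum, na.rm = TRUE)
    target <- mean(totals)
    records$intensity <- as.numeric(records$intensity *
                                    (target / totals[run]))
    records
}

#' Select fragments per peptide for roll-up
#'
#' Per peptide, each fragment's log2 profile across runs is correlated with
#' the mean fragment profile of the peptide; fragments below the minimum
#' correlation are dropped, the top `frag_max` by total intensity are kept,
#' and the peptide is retained only if at least `frag_min` fragments
#' survive. A protein is retained only if at least one of its peptides
#' survives.
#'
#' @param fragments long fragment data.frame with columns analyte_id
#'   (fragment), peptide_id, protein_id, condition, replicate, intensity.
#' @param thresholds a [DiaThresholds-class].
#' @return the fragment rows that survive selection.
#' @export
selectFragments <- function(fragments, thresholds = diaThresholds()) {
    runs <- unique(fragments[, c("condition", "replicate")])
    run_key <- paste(runs$condition, runs$replicate, sep = ".")
    keep_rows <- logical(nrow(fragments))
    for (pep in unique(fragments$peptide_id)) {
        ix <- which(fragments$peptide_id == pep)
        sub <- fragments[ix, , drop = FALSE]
        frag_ids <- unique(sub$analyte_id)
        m <- matrix(NA_real_, nrow = length(frag_ids),
                    ncol = length(run_key),
                    dimnames = list(frag_ids, run_key))
        m[cbind(match(sub$analyte_id, frag_ids),
                match(paste(sub$condition, sub$replicate, sep = "."),
                      run_key))] <- log2(sub$intensity)
        mean_profile <- colMeans(m, na.rm = TRUE)
        r <- apply(m, 1, function(v)
            suppressWarnings(stats::cor(v, mean_profile,
                                        use = "pairwise.complete.obs")))
        r[is.na(r)] <- 1  # constant profiles carry no shape evidence
        surv <- frag_ids[r >= thresholds@frag_corr_min]
        if (length(surv) > thresholds@frag_max) {
            tot <- rowSums(2^m[surv, , drop = FALSE], na.rm = TRUE)
            surv <- surv[order(-tot)][seq_len(thresholds@frag_max)]
        }
        if (length(surv) >= thresholds@frag_min)
            keep_rows[ix[sub$analyte_id %in% surv]] <- TRUE
    }
    out <- fragments[keep_rows, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Roll fragments up to peptide intensities
#'
#' Peptide intensity per run = sum of the kept fragment intensities of that
#' run. Peptides with no surviving fragment are absent from the output.
#'
#' @param fragments fragment rows surviving [selectFragments].
#' @param analyte_kind kind stamped on the rolled-up rows ("protein" for
#'   the total-proteome layer, "phosphopeptide" for the phospho layer).
#' @return long quant data.frame at peptide level (analyte_id =
#'   peptide_id; protein_id carried through).
#' @export
rollupPeptide <- function(fragments, analyte_kind = "protein") {
    key <- paste(fragments$peptide_id, fragments$condition,
                 fragments$replicate, sep = "\r")
    sums <- tapply(fragments$intensity, key, function(x)
        if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE))
    parts <- strsplit(names(sums), "\r", fixed = TRUE)
    out <- data.frame(
        analyte_id = vapply(parts, `[`, character(1), 1),
        analyte_kind = analyte_kind,
        condition = vapply(parts, `[`, character(1), 2),
        replicate = as.integer(vapply(parts, `[`, character(1), 3)),
        intensity = unname(sums), stringsAsFactors = FALSE)
    out$protein_id <- fragments$protein_id[
        match(out$analyte_id, fragments$peptide_id)]
    rownames(out) <- NULL
    out
}

#' Differential phospho/protein analysis against the reference condition
#'
#' Peptide-level log2 t-test with BH adjustment within each
#' mutant-vs-reference contrast, and regulation calls at the standard
#' thresholds. This is the package's documented surrogate for upstream
#' Bayesian group-comparison tooling: the thresholds and directions match,
#' the model internals do not.
#'
#' @param records long quant data.frame at peptide or protein level.
#' @param reference reference condition name.
#' @param thresholds a [DiaThresholds-class].
#' @return differential results data.frame; attribute `method` documents
#'   the surrogate test used.
#' @export
differentialPhospho <- function(records, reference,
                                thresholds = diaThresholds()) {
    res <- differentialByCondition(records, reference,
                                   fc_thresh = thresholds@fc_thresh,
                                   adj_p_thresh = thresholds@adj_p_thresh)
    attr(res, "method") <-
        "equal-variance t-test on log2 intensities, BH per contrast"
    res
}

#' Apply the stricter heatmap-inclusion profile
#'
#' Flags analytes significant under the stricter profile (smaller adjusted
#' p, smaller fold-change bound) used to decide display inclusion.
#'
#' @param results differential results data.frame.
#' @param thresholds a [DiaThresholds-class] (`strong_fc`,
#'   `strong_p_thresh`).
#' @return logical vector parallel to `results` rows.
#' @export
strongRegulation <- function(results, thresholds = diaThresholds()) {
    abs(results$log2fc) > thresholds@strong_fc &
        results$adj_pvalue <= thresholds@strong_p_thresh
}

#' Summarize regulation per condition
#'
#' Among analytes with adjusted p at or below the significance threshold in
#' a condition, reports the counts and fractions called up and down.
#'
#' @param results differential results data.frame.
#' @param adj_p_thresh significance cutoff defining the denominator.
#' @return data.frame condition, n_significant, n_up, n_down, frac_up,
#'   frac_down.
#' @export
summarizeRegulation <- function(results, adj_p_thresh = 0.05) {
    conds <- unique(results$condition)
    if (!length(conds))
        return(data.frame(condition = character(),
                          n_significant = integer(), n_up = integer(),
                          n_down = integer(), frac_up = numeric(),
                          frac_down = numeric(), stringsAsFactors = FALSE))
    rows <- lapply(conds, function(cd) {
        r <- results[results$condition == cd, , drop = FALSE]
        sig <- r[r$adj_pvalue <= adj_p_thresh, , drop = FALSE]
        n_up <- sum(sig$regulated == "up")
        n_down <- sum(sig$regulated == "down")
        data.frame(condition = cd, n_significant = nrow(sig),
                   n_up = n_up, n_down = n_down,
                   frac_up = if (nrow(sig)) n_up / nrow(sig) else 0,
                   frac_down = if (nrow(sig)) n_down / nrow(sig) else 0,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Match a phosphosite against the kinase recognition motif
#'
#' TRUE iff the site residue is an allowed phosphoacceptor, the residue
#' immediately after the site is the required +1 residue, and a basic
#' residue (R/K) sits at one of the allowed upstream offsets. Positions
#' beyond either terminus never match.
#'
#' @param sequence amino-acid string.
#' @param site_index 1-based position of the phosphosite within
#'   `sequence`.
#' @param motif a [MotifSpec-class].
#' @return logical.
#' @examples
#' motifMatch("RAASPK", 4)   # TRUE: R at -3, P at +1
#' motifMatch("AAASAA", 4)   # FALSE
#' @export
motifMatch <- function(sequence, site_index, motif = motifSpec()) {
    chars <- strsplit(sequence, "")[[1]]
    n <- length(chars)
    if (site_index < 1 || site_index > n)
        stop("site_index outside the sequence")
    if (!chars[site_index] %in% motif@site_residues) return(FALSE)
    p1 <- site_index + 1L
    if (p1 > n || chars[p1] != motif@plus_one) return(FALSE)
    for (o in motif@basic_offsets) {
        i <- site_index + o
        if (i >= 1 && i <= n && chars[i] %in% c("R", "K")) return(TRUE)
    }
    FALSE
}

#' Motif enrichment among downregulated phosphopeptides
#'
#' Fraction of motif-bearing peptides among the regulated-down set, with a
#' two-sided Fisher p-value on the 2x2 table motif x (down vs not-down)
#' over all quantified peptides.
#'
#' @param regulated_down data.frame of downregulated peptides with
#'   `sequence` and `site_index` columns (subset of `all_quantified` by
#'   peptide_id).
#' @param all_quantified data.frame of all quantified peptides with the
#'   same columns plus `peptide_id`.
#' @param motif a [MotifSpec-class].
#' @return list with `fraction_with_motif`, `n_down`, `p.value`.
#' @export
motifEnrichment <- function(regulated_down, all_quantified,
                            motif = motifSpec()) {
    hit <- function(df) vapply(seq_len(nrow(df)), function(i)
        motifMatch(df$sequence[i], df$site_index[i], motif), logical(1))
    down_ids <- regulated_down$peptide_id
    all_hit <- hit(all_quantified)
    is_down <- all_quantified$peptide_id %in% down_ids
    a <- sum(all_hit & is_down)
    tab <- matrix(c(a, sum(is_down) - a,
                    sum(all_hit & !is_down),
                    sum(!all_hit & !is_down)), nrow = 2, byrow = TRUE)
    list(fraction_with_motif = if (sum(is_down)) a / sum(is_down) else 0,
         n_down = sum(is_down), p.value = fisherTwoSided(tab))
}

#' Correlation between phosphopeptide and protein fold changes
#'
#' Squared Pearson correlation of matched log2 fold changes after joining
#' the phospho results to the protein results on protein id (and condition
#' when present in both). Requires at least three matched pairs.
#'
#' @param phospho_results differential results with a `protein_id` column.
#' @param protein_results protein-level differential results whose
#'   `analyte_id` is the protein id.
#' @return list with `r_squared` and `n_pairs`.
#' @export
phosphoProteinCorrelation <- function(phospho_results, protein_results) {
    key_p <- paste(phospho_results$protein_id, phospho_results$condition)
    key_q <- paste(protein_results$analyte_id, protein_results$condition)
    m <- match(key_p, key_q)
    ok <- !is.na(m)
    if (sum(ok) < 3)
        stop("need at least 3 matched phospho/protein pairs")
    r <- stats::cor(phospho_results$log2fc[ok],
                    protein_results$log2fc[m[ok]])
    list(r_squared = r^2, n_pairs = sum(ok))
}
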