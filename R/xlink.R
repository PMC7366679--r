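## Quantitative cross-linking layer: identification filtering, an automated
## surrogate of the manual chromatogram acceptance review, transition-level
## quantification, reference-peptide normalization, minimum-value
## imputation, replicate correlation, PCA and differential cross-links, and
## mapping of cross-links onto a structure as distance restraints.

#' Filter cross-link identifications
#'
#' Kept iff the ld (linear discriminant) score is strictly above the cutoff
#' and both linked peptides reach the minimum length.
#'
#' @param xls cross-link identification data.frame with columns xl_id,
#'   pos_a, pos_b, ld_score, peptide_len_a, peptide_len_b, library_rt.
#' @param thresholds an [XlThresholds-class].
#' @return the filtered data.frame.
#' @export
filterIdentifications <- function(xls, thresholds = xlThresholds()) {
    keep <- xls$ld_score > thresholds@ld_min &
        xls$peptide_len_a >= thresholds@min_pep_len &
        xls$peptide_len_b >= thresholds@min_pep_len
    out <- xls[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Automated peak acceptance for one cross-link in one run
#'
#' Surrogate for the manual targeted-chromatogram review. A peak is
#' accepted iff (1) the median apex retention time is within the tolerance
#' of the library retention time of the identification, (2) the light and
#' heavy channel apexes co-elute within the co-elution tolerance, and (3)
#' the Pearson correlation of the six paired (light, heavy) transition
#' areas reaches the shape threshold. Fewer than three transition pairs
#' with finite areas reject the peak outright.
#'
#' @param measurements data.frame of transition rows for one (xl_id,
#'   condition, replicate), both channels present; columns channel,
#'   transition_index, area, snr, apex_rt.
#' @param library_rt library retention time (minutes) of the
#'   identification.
#' @param thresholds an [XlThresholds-class].
#' @return list with `accepted` (logical) and `reasons` (character vector
#'   of failed criteria: "rt", "coelution", "shape", or
#'   "insufficient transitions").
#' @export
acceptPeak <- function(measurements, library_rt,
                       thresholds = xlThresholds()) {
    light <- measurements[measurements$channel == "light", , drop = FALSE]
    heavy <- measurements[measurements$channel == "heavy", , drop = FALSE]
    if (!nrow(light) || !nrow(heavy))
        stop("both channels must be present")
    la <- light$area[match(1:6, light$transition_index)]
    ha <- heavy$area[match(1:6, heavy$transition_index)]
    paired <- is.finite(la) & is.finite(ha)
    if (sum(paired) < 3)
        return(list(accepted = FALSE,
                    reasons = "insufficient transitions"))
    reasons <- character()
    apex <- stats::median(measurements$apex_rt, na.rm = TRUE)
    if (abs(apex - library_rt) > thresholds@rt_tolerance_min)
        reasons <- c(reasons, "rt")
    if (abs(stats::median(light$apex_rt, na.rm = TRUE) -
            stats::median(heavy$apex_rt, na.rm = TRUE)) >
        thresholds@coelution_tol_min)
        reasons <- c(reasons, "coelution")
    shape <- if (stats::sd(la[paired]) == 0 || stats::sd(ha[paired]) == 0)
        1.0 else stats::cor(la[paired], ha[paired])
    if (shape < thresholds@shape_corr_min)
        reasons <- c(reasons, "shape")
    list(accepted = length(reasons) == 0, reasons = reasons)
}

#' Quantify one cross-link in one run from its transition areas
#'
#' The abundance is the sum of the integrated areas over both channels (at
#' most twelve terms: six light plus six heavy), keeping only transitions
#' whose signal-to-noise ratio is at or above the cutoff. If no transition
#' survives the abundance is missing (`NA`), never 0.
#'
#' @param measurements transition rows for one (xl_id, condition,
#'   replicate).
#' @param thresholds an [XlThresholds-class].
#' @return the summed abundance, or `NA_real_`.
#' @export
quantifyCrosslink <- function(measurements, thresholds = xlThresholds()) {
    keep <- is.finite(measurements$area) &
        measurements$snr >= thresholds@snr_min
    if (!any(keep)) return(NA_real_)
    sum(measurements$area[keep])
}

#' Build the cross-link abundance matrix from transition data
#'
#' Runs peak acceptance and transition-level quantification for every
#' (cross-link, condition, replicate) and assembles a cross-link by run
#' abundance matrix. Rejected peaks yield missing abundances.
#'
#' @param transitions long transition data.frame.
#' @param xls identification data.frame (for library retention times).
#' @param thresholds an [XlThresholds-class].
#' @return numeric matrix, rows = cross-links, columns = runs named
#'   "condition.replicate"; attribute `rejections` records rejected peaks
#'   with reasons.
#' @export
quantifyAllCrosslinks <- function(transitions, xls,
                                  thresholds = xlThresholds()) {
    runs <- unique(transitions[, c("condition", "replicate")])
    run_names <- paste(runs$condition, runs$replicate, sep = ".")
    ids <- unique(transitions$xl_id)
    m <- matrix(NA_real_, nrow = length(ids), ncol = nrow(runs),
                dimnames = list(ids, run_names))
    rej <- list()
    for (i in seq_along(ids)) {
        lib_rt <- xls$library_rt[match(ids[i], xls$xl_id)]
        for (r in seq_len(nrow(runs))) {
            mm <- transitions[transitions$xl_id == ids[i] &
                              transitions$condition == runs$condition[r] &
                              transitions$replicate == runs$replicate[r], ,
                              drop = FALSE]
            if (!nrow(mm)) next
            acc <- acceptPeak(mm, lib_rt, thresholds)
            if (!acc$accepted) {
                rej[[length(rej) + 1L]] <- data.frame(
                    xl_id = ids[i], condition = runs$condition[r],
                    replicate = runs$replicate[r],
                    reasons = paste(acc$reasons, collapse = ";"),
                    stringsAsFactors = FALSE)
                next
            }
            m[i, r] <- quantifyCrosslink(mm, thresholds)
        }
    }
    attr(m, "rejections") <- if (length(rej)) do.call(rbind, rej) else
        data.frame(xl_id = character(), condition = character(),
                   replicate = integer(), reasons = character())
    m
}

#' Normalize cross-link abundances to two reference peptides
#'
#' Each run's abundances are divided by the mean intensity of the two
#' non-cross-linked reference peptides of that run, cancelling per-run
#' loading and response differences.
#'
#' @param abundances cross-link x run matrix (columns "condition.replicate").
#' @param reference_peptides data.frame with peptide_id, condition,
#'   replicate, intensity; exactly two peptides, present and positive in
#'   every run.
#' @return the normalized matrix.
#' @export
normalizeToReference <- function(abundances, reference_peptides) {
    run_names <- colnames(abundances)
    ref_key <- paste(reference_peptides$condition,
                     reference_peptides$replicate, sep = ".")
    for (rn in run_names) {
        v <- reference_peptides$intensity[ref_key == rn]
        if (length(v) != 2 || any(is.na(v)) || any(v <= 0))
            stop("reference peptides missing or non-positive in run ", rn)
        abundances[, rn] <- abundances[, rn] / mean(v)
    }
    abundances
}

#' Impute missing abundances with the global observed minimum
#'
#' @param abundances numeric matrix with possible `NA` cells.
#' @return the matrix with every missing cell set to the minimum observed
#'   value; an all-missing matrix is an error.
#' @export
imputeMinimum <- function(abundances) {
    obs <- abundances[is.finite(abundances)]
    if (!length(obs)) stop("all abundances missing; nothing to impute from")
    abundances[!is.finite(abundances)] <- min(obs)
    abundances
}

#' Pairwise replicate Pearson correlation
#'
#' Pearson correlation of cross-link abundances for every pair of runs,
#' plus the average correlation among replicates of each condition.
#'
#' @param abundances cross-link x run matrix (columns
#'   "condition.replicate").
#' @return list with `pairwise` (run x run correlation matrix) and
#'   `per_condition` (named vector of mean within-condition correlations).
#' @export
replicatePearson <- function(abundances) {
    cc <- stats::cor(abundances, use = "pairwise.complete.obs")
    conds <- sub("\\.[^.]*$", "", colnames(abundances))
    per <- vapply(unique(conds), function(cd) {
        ix <- which(conds == cd)
        if (length(ix) < 2) return(NA_real_)
        mean(cc[ix, ix][upper.tri(cc[ix, ix])])
    }, numeric(1))
    list(pairwise = cc, per_condition = per)
}

#' PCA of log2 cross-link abundances
#'
#' Principal components of the samples (runs) computed from the
#' feature-centred log2 abundance matrix via singular value decomposition.
#' Component signs follow the convention that the largest-magnitude loading
#' of each component is positive.
#'
#' @param abundances cross-link x run matrix of positive abundances (no
#'   missing values; impute first).
#' @return list with `scores` (runs x components), `loadings`,
#'   `explained` (variance fractions summing to 1).
#' @export
pcaScores <- function(abundances) {
    if (ncol(abundances) < 2 || nrow(abundances) < 2)
        stop("need at least 2 samples and 2 features")
    x <- t(log2(abundances))          # samples x features
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
    flip[flip == 0] <- 1
    scores <- sweep(pc$x, 2, flip, `*`)
    loadings <- sweep(pc$rotation, 2, flip, `*`)
    expl <- pc$sdev^2 / sum(pc$sdev^2)
    list(scores = scores, loadings = loadings, explained = expl)
}

#' Differential cross-link analysis against the reference condition
#'
#' Two-sided equal-variance t-test and BH adjustment on log2 abundances per
#' cross-link and mutant-vs-reference contrast, with the same regulation
#' thresholds as the interaction layer.
#'
#' @param abundances cross-link x run matrix (columns
#'   "condition.replicate") of positive abundances.
#' @param reference reference condition name.
#' @param fc_thresh,adj_p_thresh regulation thresholds.
#' @return differential results data.frame (analyte_id, condition, log2fc,
#'   pvalue, adj_pvalue, regulated).
#' @export
differentialCrosslinks <- function(abundances, reference, fc_thresh = 1.0,
                                   adj_p_thresh = 0.05) {
    conds <- sub("\\.[^.]*$", "", colnames(abundances))
    reps <- sub("^.*\\.", "", colnames(abundances))
    long <- data.frame(
        analyte_id = rep(rownames(abundances), ncol(abundances)),
        condition = rep(conds, each = nrow(abundances)),
        replicate = as.integer(rep(reps, each = nrow(abundances))),
        intensity = as.vector(abundances), stringsAsFactors = FALSE)
    differentialByCondition(long, reference, fc_thresh, adj_p_thresh)
}

#' Classify a cross-link as a structural distance restraint
#'
#' If both linked residues fall inside the covered range of the structure
#' and carry a Calpha, the Euclidean Calpha-Calpha distance is computed and
#' the restraint is satisfied iff the distance is at most the cross-linker
#' maximum (inclusive). Otherwise the cross-link is unmappable — it lies in
#' a region for which structural information is missing.
#'
#' @param pos_a,pos_b 1-based residue indices of the linked residues.
#' @param structure a [StructureModel-class].
#' @param thresholds an [XlThresholds-class] (`distance_max_A` is used).
#' @param offset integer added to cross-link residue numbering to align it
#'   with the structure's author numbering.
#' @return list with `status` ("satisfied", "violated" or "unmappable") and
#'   `distance` (Angstrom, `NA` if unmappable).
#' @export
checkDistanceRestraint <- function(pos_a, pos_b, structure,
                                   thresholds = xlThresholds(),
                                   offset = 0L) {
    a <- pos_a + offset
    b <- pos_b + offset
    idx <- residueIndices(structure)
    rng <- coveredRange(structure)
    ok <- function(p) p >= rng[1] && p <= rng[2] && p %in% idx
    if (!ok(a) || !ok(b))
        return(list(status = "unmappable", distance = NA_real_))
    d <- sqrt(sum((structure@coords[as.character(a), ] -
                   structure@coords[as.character(b), ])^2))
    list(status = if (d <= thresholds@distance_max_A) "satisfied"
         else "violated", distance = d)
}

#' Map all cross-links onto a structure
#'
#' @param xls identification data.frame.
#' @param structure a [StructureModel-class].
#' @param thresholds an [XlThresholds-class].
#' @param offset residue numbering offset (see [checkDistanceRestraint]).
#' @return data.frame xl_id, pos_a, pos_b, status, distance.
#' @export
mapRestraints <- function(xls, structure, thresholds = xlThresholds(),
                          offset = 0L) {
    res <- lapply(seq_len(nrow(xls)), function(i) {
        r <- checkDistanceRestraint(xls$pos_a[i], xls$pos_b[i], structure,
                                    thresholds, offset)
        data.frame(xl_id = xls$xl_id[i], pos_a = xls$pos_a[i],
                   pos_b = xls$pos_b[i], status = r$status,
                   distance = r$distance, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}
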