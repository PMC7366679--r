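## Seeded generators for every input layer of the pipeline. Each generator
## draws from its own RNG stream (master seed plus a fixed stage offset) so
## the layers are independently reproducible, and each returns the tables
## in the pipeline's input schemas together with a ground-truth table that
## the recovery tests recount against.

.STAGE_OFFSETS <- c(interactome = 101L, crosslink = 202L, phospho = 303L,
                    proteome = 404L, annotations = 505L)

.runGrid <- function(conditions, n_replicates) {
    expand.grid(condition = conditions,
                replicate = seq_len(n_replicates),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

.plantedLookup <- function(cfg) {
    pe <- cfg@planted_effects
    if (!nrow(pe)) return(function(id, cond) 0)
    key <- paste(pe$analyte_id, pe$condition)
    function(id, cond) {
        i <- match(paste(id, cond), key)
        if (is.na(i)) 0 else pe$log2fc[i]
    }
}

#' Simulate a differential AP-MS/BioID interactomics experiment
#'
#' Generates bait-prey MS1 intensity records with planted per-condition
#' log2 fold changes, a bait analyte present in every run, per-run scale
#' factors (cancelled by bait normalization), logistic intensity-dependent
#' (MNAR) missingness on prey intensities, and an interactor-score table in
#' which true interactors carry high SAINT scores and low control
#' frequencies while contaminants show the opposite pattern.
#'
#' @param cfg a [SimConfig-class].
#' @param bait_id identifier of the bait analyte (present in every run).
#' @param contaminant_fraction fraction of preys generated as contaminants.
#' @return list with elements `quant` (long quant table, bait-normalized
#'   ratios are NOT yet applied), `interactors` (SAINT/control-frequency
#'   table), and `truth` (per prey: base log2 intensity, contaminant flag,
#'   and planted effects).
#' @export
simInteractome <- function(cfg, bait_id = "BAIT",
                           contaminant_fraction = 0.2) {
    stopifnot(is(cfg, "SimConfig"))
    withSeed(cfg@seed + .STAGE_OFFSETS[["interactome"]], {
        preys <- sprintf("prey%03d", seq_len(cfg@n_preys))
        base <- stats::runif(cfg@n_preys, 18, 24)
        names(base) <- preys
        contaminant <- stats::runif(cfg@n_preys) < contaminant_fraction
        planted <- .plantedLookup(cfg)
        runs <- .runGrid(cfg@conditions, cfg@n_replicates)
        run_scale <- 2^stats::runif(nrow(runs), -0.5, 0.5)
        bait_log2 <- 26

        rows <- vector("list", nrow(runs))
        for (r in seq_len(nrow(runs))) {
            cond <- runs$condition[r]
            mu <- base + vapply(preys, planted, numeric(1), cond = cond)
            l2 <- mu + stats::rnorm(cfg@n_preys, 0, cfg@noise_sd_log2)
            p_miss <- if (cfg@mnar_slope <= 0) 0 else
                stats::plogis(-cfg@mnar_slope * (l2 - cfg@mnar_midpoint))
            miss <- stats::runif(cfg@n_preys) < p_miss
            inten <- 2^l2 * run_scale[r]
            inten[miss] <- NA_real_
            rows[[r]] <- data.frame(
                analyte_id = c(bait_id, preys),
                analyte_kind = "prey",
                condition = cond,
                replicate = runs$replicate[r],
                intensity = c(2^bait_log2 * run_scale[r], inten),
                mscore = NA_real_, decoy = NA,
                stringsAsFactors = FALSE)
        }
        quant <- do.call(rbind, rows)
        rownames(quant) <- NULL

        method <- rep(c("APMS", "BioID"), length.out = cfg@n_preys)
        saint <- ifelse(contaminant,
                        stats::runif(cfg@n_preys, 0, 0.95),
                        ifelse(method == "BioID", 1,
                               stats::runif(cfg@n_preys, 0.96, 1)))
        ctrl <- ifelse(contaminant,
                       stats::runif(cfg@n_preys, 0.2, 0.9),
                       stats::runif(cfg@n_preys, 0, 0.1))
        interactors <- data.frame(
            bait_id = bait_id, prey_id = preys, method = method,
            saint_score = saint, control_frequency = ctrl,
            in_gfp_control = contaminant & stats::runif(cfg@n_preys) < 0.5,
            stringsAsFactors = FALSE)

        pe <- cfg@planted_effects
        truth <- data.frame(prey_id = preys, base_log2 = base,
                            contaminant = contaminant,
                            stringsAsFactors = FALSE)
        list(quant = quant, interactors = interactors, truth = truth,
             planted = pe, bait_id = bait_id)
    })
}

#' Simulate a toy structure with cross-links and PRM transition data
#'
#' Places lysine pairs at controlled Calpha distances: a declared subset
#' violates the cross-linker restraint and a declared subset falls outside
#' the covered residue range (unmappable). PRM transition areas (six per
#' channel) carry planted per-condition fold changes, per-run scale factors
#' cancelled by reference-peptide normalization, and a declared set of
#' low signal-to-noise transitions. Two non-cross-linked reference peptides
#' are emitted per run.
#'
#' @param cfg a [SimConfig-class]; only the first `xl_conditions` of
#'   `cfg@conditions` are used if supplied.
#' @param xl_conditions conditions measured in the cross-linking layer
#'   (default the reference plus the next two conditions, mirroring a
#'   purification-limited design).
#' @param n_violating number of cross-link pairs planted beyond the
#'   restraint distance.
#' @param n_unmappable number of cross-links with a residue outside the
#'   covered range.
#' @param n_low_snr number of transition traces planted below the
#'   signal-to-noise cutoff.
#' @return list with `structure` ([StructureModel-class]), `xls`
#'   (identification table), `transitions` (long PRM transition table),
#'   `reference_peptides` (two per run), and `truth`.
#' @export
simStructureCrosslinks <- function(cfg,
                                   xl_conditions = cfg@conditions[
                                       seq_len(min(3, length(cfg@conditions)))],
                                   n_violating = 2L,
                                   n_unmappable = 3L,
                                   n_low_snr = 4L) {
    stopifnot(is(cfg, "SimConfig"))
    n_xl <- cfg@n_crosslinks
    stopifnot(n_violating + n_unmappable <= n_xl)
    withSeed(cfg@seed + .STAGE_OFFSETS[["crosslink"]], {
        ## toy chain: mappable residues 10..(10+2*n_mapped-1); each mappable
        ## cross-link gets its own residue pair on its own y-offset row so
        ## pairwise distances are controlled independently.
        n_mapped <- n_xl - n_unmappable
        status <- c(rep("satisfied", n_mapped - n_violating),
                    rep("violated", n_violating),
                    rep("unmappable", n_unmappable))
        dist_target <- c(stats::runif(n_mapped - n_violating, 8, 28),
                         stats::runif(n_violating, 32, 60))
        res_idx <- 10L + seq_len(2L * n_mapped) - 1L
        pos_a <- res_idx[seq(1, 2 * n_mapped, by = 2)]
        pos_b <- res_idx[seq(2, 2 * n_mapped, by = 2)]
        coords <- matrix(0, nrow = 2 * n_mapped, ncol = 3,
                         dimnames = list(res_idx, c("x", "y", "z")))
        for (i in seq_len(n_mapped)) {
            coords[2 * i - 1, ] <- c(0, 100 * i, 0)
            coords[2 * i, ] <- c(dist_target[i], 100 * i, 0)
        }
        covered <- as.integer(range(res_idx))
        structure <- new("StructureModel", chain = "A", coords = coords,
                         resnames = rep("LYS", nrow(coords)),
                         covered_range = covered)
        ## unmappable cross-links sit beyond the covered range
        un_a <- covered[2] + 50L + seq_len(n_unmappable)
        un_b <- un_a + 5L
        xls <- data.frame(
            xl_id = sprintf("XL%02d", seq_len(n_xl)),
            pos_a = c(pos_a, un_a), pos_b = c(pos_b, un_b),
            ld_score = stats::runif(n_xl, 26, 45),
            peptide_len_a = sample(5:15, n_xl, replace = TRUE),
            peptide_len_b = sample(5:15, n_xl, replace = TRUE),
            library_rt = stats::runif(n_xl, 20, 80),
            stringsAsFactors = FALSE)

        planted <- .plantedLookup(cfg)
        runs <- .runGrid(xl_conditions, cfg@n_replicates)
        run_scale <- 2^stats::runif(nrow(runs), -0.3, 0.3)
        base_area <- matrix(stats::runif(n_xl * 6, 2e4, 2e5),
                            nrow = n_xl)
        tr_rows <- list()
        low_snr_budget <- n_low_snr
        low_snr_ids <- character()
        for (r in seq_len(nrow(runs))) {
            cond <- runs$condition[r]
            rep_i <- runs$replicate[r]
            for (i in seq_len(n_xl)) {
                fc <- planted(xls$xl_id[i], cond)
                noise <- 2^stats::rnorm(6, 0, cfg@noise_sd_log2)
                apex <- xls$library_rt[i] + stats::rnorm(1, 0, 0.05)
                for (ch in c("light", "heavy")) {
                    areas <- base_area[i, ] * 2^fc * noise * run_scale[r]
                    snr <- stats::runif(6, 10, 50)
                    tr_rows[[length(tr_rows) + 1L]] <- data.frame(
                        xl_id = xls$xl_id[i], condition = cond,
                        replicate = rep_i, channel = ch,
                        transition_index = 1:6, area = areas, snr = snr,
                        apex_rt = apex + stats::rnorm(1, 0, 0.02),
                        stringsAsFactors = FALSE)
                }
            }
        }
        transitions <- do.call(rbind, tr_rows)
        rownames(transitions) <- NULL
        ## plant the declared low-snr transitions in the first run
        if (n_low_snr > 0) {
            first_run <- which(transitions$condition == runs$condition[1] &
                               transitions$replicate == runs$replicate[1])
            pick <- first_run[seq_len(min(n_low_snr, length(first_run)))]
            transitions$snr[pick] <- stats::runif(length(pick), 0.5, 4.9)
            low_snr_ids <- paste(transitions$xl_id[pick],
                                 transitions$condition[pick],
                                 transitions$replicate[pick],
                                 transitions$channel[pick],
                                 transitions$transition_index[pick])
        }
        refs <- data.frame(
            peptide_id = rep(c("ref1", "ref2"), each = nrow(runs)),
            condition = rep(runs$condition, 2),
            replicate = rep(runs$replicate, 2),
            intensity = rep(c(5e5, 7e5), each = nrow(runs)) *
                rep(run_scale, 2),
            stringsAsFactors = FALSE)
        truth <- data.frame(xl_id = xls$xl_id, status = status,
            distance = c(dist_target, rep(NA_real_, n_unmappable)),
            stringsAsFactors = FALSE)
        list(structure = structure, xls = xls, transitions = transitions,
             reference_peptides = refs, truth = truth,
             low_snr_keys = low_snr_ids, planted = cfg@planted_effects)
    })
}

#' Simulate DIA phosphoproteomics records with planted motif-bearing sites
#'
#' Generates phosphopeptide windows (site-centred amino-acid sequences): a
#' fraction `motif_fraction_down` of planted-down peptides carry the
#' kinase recognition motif R/K-x-x(-x)-S/T-P around the phosphosite, all
#' other peptides are built motif-free. Intensities carry planted effects,
#' log-normal noise and MNAR missingness; decoys are flagged at
#' `fraction_decoy` and a declared noise set receives large m-scores.
#'
#' @param cfg a [SimConfig-class].
#' @param down_conditions conditions in which the planted-down peptides are
#'   reduced (defaults to the catalytically impaired set present in
#'   `cfg@conditions`).
#' @param n_down number of planted-down phosphopeptides.
#' @param down_log2fc planted fold change of the down set (log2).
#' @return list with `quant` (long table with m-scores and decoy flags),
#'   `peptides` (sequence/site table), `truth`.
#' @export
simPhospho <- function(cfg,
                       down_conditions = intersect(c("KR", "SX", "KO"),
                                                   cfg@conditions),
                       n_down = max(1L, round(cfg@n_phosphopeptides * 0.2)),
                       down_log2fc = -2) {
    stopifnot(is(cfg, "SimConfig"))
    withSeed(cfg@seed + .STAGE_OFFSETS[["phospho"]], {
        n <- cfg@n_phosphopeptides
        ids <- sprintf("ppep%04d", seq_len(n))
        prot <- sprintf("prot%03d",
                        sample.int(cfg@n_proteins, n, replace = TRUE))
        is_down <- seq_len(n) <= n_down
        has_motif <- is_down & stats::runif(n) < cfg@motif_fraction_down
        win <- 11L; site <- 6L
        alphabet_neutral <- c("A", "G", "L", "V", "E", "D", "Q", "N")
        seqs <- vapply(seq_len(n), function(i) {
            s <- sample(alphabet_neutral, win, replace = TRUE)
            s[site] <- sample(c("S", "T"), 1)
            if (has_motif[i]) {
                s[site + 1] <- "P"
                s[site + sample(c(-3L, -4L), 1)] <- sample(c("R", "K"), 1)
            } else {
                # no +1 proline => cannot match the motif
                s[site + 1] <- sample(alphabet_neutral, 1)
            }
            paste(s, collapse = "")
        }, character(1))
        ## most sites confidently localized; a tail above the FLR cutoff
        flr <- ifelse(stats::runif(n) < 0.9, stats::runif(n, 0, 0.01),
                      stats::runif(n, 0.02, 0.5))
        peptides <- data.frame(
            peptide_id = ids, protein_id = prot, sequence = seqs,
            site_index = site, flr = flr, localized = flr <= 0.01,
            stringsAsFactors = FALSE)

        base <- stats::runif(n, 16, 22)
        decoy <- stats::runif(n) < cfg@fraction_decoy
        noisy_mscore <- stats::runif(n) < 0.1
        planted <- .plantedLookup(cfg)
        runs <- .runGrid(cfg@conditions, cfg@n_replicates)
        rows <- vector("list", nrow(runs))
        for (r in seq_len(nrow(runs))) {
            cond <- runs$condition[r]
            eff <- ifelse(is_down & cond %in% down_conditions,
                          down_log2fc, 0) +
                vapply(ids, planted, numeric(1), cond = cond)
            l2 <- base + eff + stats::rnorm(n, 0, cfg@noise_sd_log2)
            p_miss <- if (cfg@mnar_slope <= 0) 0 else
                stats::plogis(-cfg@mnar_slope * (l2 - cfg@mnar_midpoint))
            inten <- 2^l2
            inten[stats::runif(n) < p_miss] <- NA_real_
            rows[[r]] <- data.frame(
                analyte_id = ids, analyte_kind = "phosphopeptide",
                condition = cond, replicate = runs$replicate[r],
                intensity = inten,
                mscore = ifelse(noisy_mscore,
                                stats::runif(n, 0.02, 0.5),
                                stats::runif(n, 1e-6, 0.005)),
                decoy = decoy, stringsAsFactors = FALSE)
        }
        quant <- do.call(rbind, rows)
        rownames(quant) <- NULL
        truth <- data.frame(
            peptide_id = ids, protein_id = prot, planted_down = is_down,
            down_log2fc = ifelse(is_down, down_log2fc, 0),
            has_motif = has_motif, decoy = decoy,
            noisy_mscore = noisy_mscore, stringsAsFactors = FALSE)
        list(quant = quant, peptides = peptides, truth = truth,
             down_conditions = down_conditions)
    })
}

#' Simulate total-proteome fragment-level DIA records
#'
#' Fragment-level records (3-8 fragments per peptide, one peptide per
#' protein here) suitable for the fragment-selection and roll-up rules;
#' planted per-condition protein effects propagate to all fragments, and a
#' declared subset of fragments is anti-correlated with its peptide
#' profile to exercise fragment rejection.
#'
#' @param cfg a [SimConfig-class].
#' @param n_bad_fragments number of planted anti-correlated fragments.
#' @return list with `fragments` (long table; analyte_id is the fragment,
#'   `peptide_id` and `protein_id` carried alongside), `truth`.
#' @export
simProteome <- function(cfg, n_bad_fragments = 5L) {
    stopifnot(is(cfg, "SimConfig"))
    withSeed(cfg@seed + .STAGE_OFFSETS[["proteome"]], {
        n <- cfg@n_proteins
        prot <- sprintf("prot%03d", seq_len(n))
        n_frag <- sample(3:8, n, replace = TRUE)
        planted <- .plantedLookup(cfg)
        runs <- .runGrid(cfg@conditions, cfg@n_replicates)
        base <- stats::runif(n, 17, 23)
        rows <- list()
        bad <- character()
        for (i in seq_len(n)) {
            pep <- paste0(prot[i], "_pep1")
            frag_base <- stats::runif(n_frag[i], -2, 0)
            for (r in seq_len(nrow(runs))) {
                cond <- runs$condition[r]
                run_shift <- stats::rnorm(1, 0, cfg@noise_sd_log2)
                l2 <- base[i] + planted(prot[i], cond) + run_shift +
                    frag_base + stats::rnorm(n_frag[i], 0,
                                             cfg@noise_sd_log2 / 2)
                rows[[length(rows) + 1L]] <- data.frame(
                    analyte_id = paste0(pep, "_f", seq_len(n_frag[i])),
                    analyte_kind = "fragment",
                    peptide_id = pep, protein_id = prot[i],
                    condition = cond, replicate = runs$replicate[r],
                    intensity = 2^l2,
                    mscore = stats::runif(n_frag[i], 1e-7, 3e-5),
                    decoy = FALSE, stringsAsFactors = FALSE)
            }
        }
        fragments <- do.call(rbind, rows)
        rownames(fragments) <- NULL
        ## plant anti-correlated fragments: invert their profile across runs
        if (n_bad_fragments > 0) {
            cand <- unique(fragments$analyte_id)
            bad <- cand[seq_len(min(n_bad_fragments, length(cand)))]
            for (b in bad) {
                ix <- which(fragments$analyte_id == b)
                l2 <- log2(fragments$intensity[ix])
                fragments$intensity[ix] <-
                    2^(2 * mean(l2) - l2 + stats::rnorm(length(ix), 0, 0.01))
            }
        }
        truth <- data.frame(protein_id = prot, base_log2 = base,
                            n_fragments = n_frag, stringsAsFactors = FALSE)
        list(fragments = fragments, truth = truth, bad_fragments = bad)
    })
}

#' Simulate annotation sets for network integration
#'
#' Draws a cancer-driver list covering a configured fraction of the protein
#' universe, reference interaction edges among them with mixed evidence
#' (some experimentally validated with PubMed ids, some not), and term sets
#' of configured sizes.
#'
#' @param cfg a [SimConfig-class].
#' @param cdp_rate fraction of the protein universe on the driver list.
#' @param n_edges number of reference edges.
#' @param n_terms,term_size term-set count and size.
#' @param experimental_fraction fraction of edges annotated as
#'   experimentally validated with PubMed ids.
#' @return an [AnnotationSets-class] object.
#' @export
simAnnotations <- function(cfg, cdp_rate = 0.1, n_edges = 60L,
                           n_terms = 8L, term_size = 15L,
                           experimental_fraction = 0.7) {
    stopifnot(is(cfg, "SimConfig"))
    withSeed(cfg@seed + .STAGE_OFFSETS[["annotations"]], {
        universe <- sprintf("prot%03d", seq_len(cfg@n_proteins))
        n_cdp <- round(cdp_rate * cfg@n_proteins)
        cdp <- sample(universe, n_cdp)
        a <- sample(universe, n_edges, replace = TRUE)
        b <- sample(universe, n_edges, replace = TRUE)
        keep <- a != b
        a <- a[keep]; b <- b[keep]
        experimental <- stats::runif(length(a)) < experimental_fraction
        edges <- data.frame(
            idA = a, idB = b,
            evidence_kind = ifelse(experimental, "experimental",
                                   "predicted"),
            pubmed_ids = ifelse(experimental,
                                as.character(sample(1e6:2e6, length(a))),
                                ""),
            stringsAsFactors = FALSE)
        term_sets <- lapply(seq_len(n_terms), function(i)
            sample(universe, term_size))
        names(term_sets) <- sprintf("TERM%03d", seq_len(n_terms))
        annotationSets(cdp_list = cdp, ppi_edges = edges,
                       term_sets = term_sets, background = universe)
    })
}
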