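#' @import methods
NULL

## ---------------------------------------------------------------------------
## Threshold / criteria profiles
## ---------------------------------------------------------------------------

#' Thresholds for high-confidence interactor filtering and regulation calls
#'
#' Holds the cutoffs applied to the AP-MS/BioID interaction layer: SAINT
#' score thresholds (strict `>` for AP-MS, equality for BioID), the maximum
#' tolerated contaminant-control frequency, and the fold-change /
#' adjusted-p thresholds used for regulation calls.
#'
#' @slot saint_apms numeric, AP-MS SAINT cutoff (kept iff score strictly
#'   greater).
#' @slot saint_bioid numeric, BioID SAINT cutoff (kept iff score >= cutoff;
#'   the default 1 means only perfect scores pass).
#' @slot control_freq_max numeric, preys seen in more than this fraction of
#'   contaminant-control runs are removed.
#' @slot fc_thresh numeric, regulation requires |log2FC| strictly above this.
#' @slot adj_p_thresh numeric, regulation requires BH-adjusted p <= this.
#' @export
setClass("InteractomeThresholds", representation(
    saint_apms = "numeric",
    saint_bioid = "numeric",
    control_freq_max = "numeric",
    fc_thresh = "numeric",
    adj_p_thresh = "numeric"
))

setValidity("InteractomeThresholds", function(object) {
    msgs <- character()
    for (s in c("saint_apms", "saint_bioid", "control_freq_max",
                "adj_p_thresh")) {
        v <- slot(object, s)
        if (length(v) != 1 || !is.finite(v) || v < 0 || v > 1)
            msgs <- c(msgs, sprintf("%s must be a single value in [0, 1]", s))
    }
    if (length(object@fc_thresh) != 1 || !is.finite(object@fc_thresh) ||
        object@fc_thresh <= 0)
        msgs <- c(msgs, "fc_thresh must be a single positive value")
    if (length(msgs)) msgs else TRUE
})

#' @param saint_apms,saint_bioid,control_freq_max,fc_thresh,adj_p_thresh see
#'   the corresponding slots.
#' @rdname InteractomeThresholds-class
#' @export
interactomeThresholds <- function(saint_apms = 0.95, saint_bioid = 1.0,
                                  control_freq_max = 0.15, fc_thresh = 1.0,
                                  adj_p_thresh = 0.05) {
    new("InteractomeThresholds", saint_apms = saint_apms,
        saint_bioid = saint_bioid, control_freq_max = control_freq_max,
        fc_thresh = fc_thresh, adj_p_thresh = adj_p_thresh)
}

#' Thresholds for the quantitative cross-linking layer
#'
#' Identification filtering (xQuest ld score, minimum peptide length), the
#' automated peak-acceptance surrogate for the manual chromatogram review
#' (retention-time match to the identification library, light/heavy
#' co-elution, transition peak-shape correlation), the per-transition
#' signal-to-noise cutoff, and the cross-linker distance restraint.
#'
#' @slot ld_min numeric, identifications kept iff ld score strictly greater.
#' @slot min_pep_len integer, both linked peptides must be at least this long.
#' @slot snr_min numeric, transitions with signal-to-noise below this are
#'   dropped from quantification.
#' @slot rt_tolerance_min numeric minutes, allowed deviation of the apex from
#'   the library retention time.
#' @slot coelution_tol_min numeric minutes, allowed apex offset between the
#'   light and heavy channel.
#' @slot shape_corr_min numeric, minimum Pearson correlation of the paired
#'   light/heavy transition areas.
#' @slot distance_max_A numeric Angstrom, maximum Calpha-Calpha distance a
#'   cross-link may span (DSS spacer geometry implies roughly 30 A).
#' @export
setClass("XlThresholds", representation(
    ld_min = "numeric",
    min_pep_len = "integer",
    snr_min = "numeric",
    rt_tolerance_min = "numeric",
    coelution_tol_min = "numeric",
    shape_corr_min = "numeric",
    distance_max_A = "numeric"
))

setValidity("XlThresholds", function(object) {
    msgs <- character()
    if (object@min_pep_len < 1L) msgs <- c(msgs, "min_pep_len must be >= 1")
    for (s in c("snr_min", "rt_tolerance_min", "coelution_tol_min",
                "distance_max_A"))
        if (slot(object, s) < 0)
            msgs <- c(msgs, sprintf("%s must be non-negative", s))
    if (abs(object@shape_corr_min) > 1)
        msgs <- c(msgs, "shape_corr_min must be in [-1, 1]")
    if (length(msgs)) msgs else TRUE
})

#' @param ld_min,min_pep_len,snr_min,rt_tolerance_min,coelution_tol_min,shape_corr_min,distance_max_A
#'   see the corresponding slots.
#' @rdname XlThresholds-class
#' @export
xlThresholds <- function(ld_min = 25, min_pep_len = 5L, snr_min = 5,
                         rt_tolerance_min = 2, coelution_tol_min = 0.2,
                         shape_corr_min = 0.8, distance_max_A = 30) {
    new("XlThresholds", ld_min = ld_min,
        min_pep_len = as.integer(min_pep_len), snr_min = snr_min,
        rt_tolerance_min = rt_tolerance_min,
        coelution_tol_min = coelution_tol_min,
        shape_corr_min = shape_corr_min, distance_max_A = distance_max_A)
}

#' Thresholds for the DIA phospho- and total-proteome layer
#'
#' Feature-quality filters (m-score, detection-rate), the decoy scaling
#' factor used for FDR estimation, the fragment-selection rules for
#' peptide roll-up, and the two regulation-call profiles (the standard one
#' and the stricter profile used for heatmap inclusion).
#'
#' @slot mscore_max_phospho numeric, phosphopeptide features kept iff best
#'   m-score <= this.
#' @slot detection_rate_min numeric, features must be detected in at least
#'   this fraction of all runs.
#' @slot mscore_max_proteome numeric, global m-score cutoff for the total
#'   proteome layer.
#' @slot fft numeric in (0, 1], estimated fraction of false targets scaling
#'   decoy counts into an FDR.
#' @slot frag_corr_min numeric, fragments below this correlation with the
#'   peptide mean profile are dropped.
#' @slot frag_min,frag_max integer, peptides must retain between frag_min and
#'   frag_max fragments.
#' @slot fc_thresh,adj_p_thresh numeric, standard regulation thresholds.
#' @slot strong_fc,strong_p_thresh numeric, stricter profile for heatmap
#'   inclusion.
#' @export
setClass("DiaThresholds", representation(
    mscore_max_phospho = "numeric",
    detection_rate_min = "numeric",
    mscore_max_proteome = "numeric",
    fft = "numeric",
    frag_corr_min = "numeric",
    frag_min = "integer",
    frag_max = "integer",
    fc_thresh = "numeric",
    adj_p_thresh = "numeric",
    strong_fc = "numeric",
    strong_p_thresh = "numeric"
))

setValidity("DiaThresholds", function(object) {
    msgs <- character()
    if (object@fft <= 0 || object@fft > 1)
        msgs <- c(msgs, "fft must be in (0, 1]")
    if (object@detection_rate_min < 0 || object@detection_rate_min > 1)
        msgs <- c(msgs, "detection_rate_min must be in [0, 1]")
    if (object@frag_min < 1L || object@frag_max < object@frag_min)
        msgs <- c(msgs, "need 1 <= frag_min <= frag_max")
    if (length(msgs)) msgs else TRUE
})

#' @param mscore_max_phospho,detection_rate_min,mscore_max_proteome,fft,frag_corr_min,frag_min,frag_max,fc_thresh,adj_p_thresh,strong_fc,strong_p_thresh
#'   see the corresponding slots.
#' @rdname DiaThresholds-class
#' @export
diaThresholds <- function(mscore_max_phospho = 0.01, detection_rate_min = 0.30,
                          mscore_max_proteome = 3.9811e-5, fft = 0.46,
                          frag_corr_min = 0.1, frag_min = 3L, frag_max = 6L,
                          fc_thresh = 1.0, adj_p_thresh = 0.05,
                          strong_fc = 0.5, strong_p_thresh = 0.01) {
    new("DiaThresholds", mscore_max_phospho = mscore_max_phospho,
        detection_rate_min = detection_rate_min,
        mscore_max_proteome = mscore_max_proteome, fft = fft,
        frag_corr_min = frag_corr_min, frag_min = as.integer(frag_min),
        frag_max = as.integer(frag_max), fc_thresh = fc_thresh,
        adj_p_thresh = adj_p_thresh, strong_fc = strong_fc,
        strong_p_thresh = strong_p_thresh)
}

#' Kinase substrate phosphorylation motif
#'
#' A proline-directed basic motif of the form R/K-x-x(-x)-S/T-P: the
#' phosphoacceptor (S or T by default), a required residue at +1 (P), and a
#' basic residue (R or K) at one of a set of upstream offsets (-3 or -4 by
#' default).
#'
#' @slot basic_offsets integer vector of negative offsets at which R/K may sit.
#' @slot plus_one character, required residue immediately after the site.
#' @slot site_residues character vector of allowed phosphoacceptor residues.
#' @export
setClass("MotifSpec", representation(
    basic_offsets = "integer",
    plus_one = "character",
    site_residues = "character"
))

setValidity("MotifSpec", function(object) {
    if (any(object@basic_offsets >= 0))
        return("basic_offsets must be negative (upstream of the site)")
    TRUE
})

#' @param basic_offsets,plus_one,site_residues see the corresponding slots.
#' @rdname MotifSpec-class
#' @export
motifSpec <- function(basic_offsets = c(-3L, -4L), plus_one = "P",
                      site_residues = c("S", "T")) {
    new("MotifSpec", basic_offsets = as.integer(basic_offsets),
        plus_one = plus_one, site_residues = site_residues)
}

#' Criteria for selecting regulated cancer-driver proteins
#'
#' A protein enters the integrated network iff it is on the cancer-driver
#' list and is regulated at the phospho level and/or the interaction level
#' in at least one mutant condition. Methods-style strict `<` comparisons on
#' the adjusted p-values are the default; both can be relaxed to `<=`.
#'
#' @slot phospho_fc,phospho_fdr numeric, phospho-layer thresholds.
#' @slot interaction_fc,interaction_adj_p numeric, interaction-layer
#'   thresholds.
#' @slot strict_p logical, if TRUE the p criteria use strict `<`.
#' @slot evidence_required character, either "experimental_with_pubmed"
#'   (reference edges must be experimentally validated and carry PubMed ids)
#'   or "any".
#' @export
setClass("IntegrationCriteria", representation(
    phospho_fc = "numeric",
    phospho_fdr = "numeric",
    interaction_fc = "numeric",
    interaction_adj_p = "numeric",
    strict_p = "logical",
    evidence_required = "character"
))

setValidity("IntegrationCriteria", function(object) {
    if (!object@evidence_required %in% c("experimental_with_pubmed", "any"))
        return("evidence_required must be 'experimental_with_pubmed' or 'any'")
    TRUE
})

#' @param phospho_fc,phospho_fdr,interaction_fc,interaction_adj_p,strict_p,evidence_required
#'   see the corresponding slots.
#' @rdname IntegrationCriteria-class
#' @export
integrationCriteria <- function(phospho_fc = 1.0, phospho_fdr = 0.05,
                                interaction_fc = 1.0,
                                interaction_adj_p = 0.05,
                                strict_p = TRUE,
                                evidence_required = "experimental_with_pubmed") {
    new("IntegrationCriteria", phospho_fc = phospho_fc,
        phospho_fdr = phospho_fdr, interaction_fc = interaction_fc,
        interaction_adj_p = interaction_adj_p, strict_p = strict_p,
        evidence_required = evidence_required)
}

## ---------------------------------------------------------------------------
## Structure model
## ---------------------------------------------------------------------------

#' Residue-indexed Calpha coordinates for distance-restraint checks
#'
#' One Calpha coordinate per covered residue of one chain, indexed by the
#' author residue numbering of the source PDB. The covered range records the
#' span of the structure; cross-links outside it are classified unmappable.
#'
#' @slot chain character, chain identifier.
#' @slot coords numeric matrix (n x 3, Angstrom) with residue indices as
#'   rownames, in strictly increasing order.
#' @slot resnames character vector of residue names parallel to coords rows.
#' @slot covered_range integer length-2, first and last covered residue index.
#' @export
setClass("StructureModel", representation(
    chain = "character",
    coords = "matrix",
    resnames = "character",
    covered_range = "integer"
))

setValidity("StructureModel", function(object) {
    msgs <- character()
    if (!is.numeric(object@coords) || ncol(object@coords) != 3)
        msgs <- c(msgs, "coords must be a numeric n x 3 matrix")
    if (any(!is.finite(object@coords)))
        msgs <- c(msgs, "coordinates must be finite")
    idx <- suppressWarnings(as.integer(rownames(object@coords)))
    if (anyNA(idx) || any(diff(idx) <= 0))
        msgs <- c(msgs, "residue indices must be strictly increasing integers")
    if (length(object@resnames) != nrow(object@coords))
        msgs <- c(msgs, "resnames must parallel the coordinate rows")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn StructureModel-class residue indices with a Calpha present.
#' @param object,x a `StructureModel`.
#' @export
residueIndices <- function(x) as.integer(rownames(x@coords))

#' @describeIn StructureModel-class the `[min, max]` covered residue range.
#' @export
coveredRange <- function(x) x@covered_range

setMethod("show", "StructureModel", function(object) {
    cat(sprintf(
        "StructureModel: chain %s, %d residues with Calpha, covering %d-%d\n",
        object@chain, nrow(object@coords),
        object@covered_range[1], object@covered_range[2]))
})

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' Configuration of the synthetic multi-layer study
#'
#' Defines the simulated study design: conditions (the first is the
#' reference), replicate count, analyte counts per layer, log2 noise,
#' planted per-condition effects, the intensity-dependent (MNAR)
#' missingness model, and the planted motif/decoy fractions. The defaults
#' mirror the emulated study: seven mutant conditions plus wild type,
#' three biological replicates, and effect magnitudes of a few log2 units.
#'
#' @slot seed integer, master seed; each generator derives its own stream
#'   from it plus a fixed stage offset.
#' @slot n_preys,n_phosphopeptides,n_proteins,n_crosslinks integer counts.
#' @slot conditions character vector; the first entry is the reference.
#' @slot n_replicates integer >= 2.
#' @slot noise_sd_log2 numeric >= 0, replicate noise on the log2 scale.
#' @slot planted_effects data.frame with columns analyte_id, condition,
#'   log2fc giving the planted true effects.
#' @slot mnar_midpoint,mnar_slope numeric, logistic missingness model:
#'   P(missing) = plogis(-slope * (log2 intensity - midpoint)).
#' @slot motif_fraction_down numeric in [0, 1], fraction of planted-down
#'   phosphopeptides that carry the kinase motif.
#' @slot fraction_decoy numeric in [0, 1], fraction of decoy analytes.
#' @export
setClass("SimConfig", representation(
    seed = "integer",
    n_preys = "integer",
    n_phosphopeptides = "integer",
    n_proteins = "integer",
    n_crosslinks = "integer",
    conditions = "character",
    n_replicates = "integer",
    noise_sd_log2 = "numeric",
    planted_effects = "data.frame",
    mnar_midpoint = "numeric",
    mnar_slope = "numeric",
    motif_fraction_down = "numeric",
    fraction_decoy = "numeric"
))

setValidity("SimConfig", function(object) {
    msgs <- character()
    for (s in c("n_preys", "n_phosphopeptides", "n_proteins", "n_crosslinks"))
        if (slot(object, s) < 1L)
            msgs <- c(msgs, sprintf("%s must be >= 1", s))
    if (object@n_replicates < 2L)
        msgs <- c(msgs, "n_replicates must be >= 2")
    if (length(object@conditions) < 2L ||
        anyDuplicated(object@conditions))
        msgs <- c(msgs, "need >= 2 distinct conditions (first is reference)")
    if (object@noise_sd_log2 < 0)
        msgs <- c(msgs, "noise_sd_log2 must be >= 0")
    for (s in c("motif_fraction_down", "fraction_decoy")) {
        v <- slot(object, s)
        if (v < 0 || v > 1)
            msgs <- c(msgs, sprintf("%s must be in [0, 1]", s))
    }
    pe <- object@planted_effects
    if (nrow(pe) && !all(c("analyte_id", "condition", "log2fc") %in%
                         colnames(pe)))
        msgs <- c(msgs,
                  "planted_effects needs analyte_id, condition, log2fc")
    if (length(msgs)) msgs else TRUE
})

#' @param seed,n_preys,n_phosphopeptides,n_proteins,n_crosslinks,conditions,n_replicates,noise_sd_log2,planted_effects,mnar_midpoint,mnar_slope,motif_fraction_down,fraction_decoy
#'   see the corresponding slots.
#' @rdname SimConfig-class
#' @export
simConfig <- function(seed = 1L,
                      n_preys = 60L,
                      n_phosphopeptides = 120L,
                      n_proteins = 200L,
                      n_crosslinks = 14L,
                      conditions = c("WT", "KR", "RL", "SX",
                                     "SL", "SP", "PL", "KO"),
                      n_replicates = 3L,
                      noise_sd_log2 = 0.3,
                      planted_effects = data.frame(
                          analyte_id = character(),
                          condition = character(),
                          log2fc = numeric()),
                      mnar_midpoint = 16,
                      mnar_slope = 1.5,
                      motif_fraction_down = 0.5,
                      fraction_decoy = 0.1) {
    new("SimConfig", seed = as.integer(seed), n_preys = as.integer(n_preys),
        n_phosphopeptides = as.integer(n_phosphopeptides),
        n_proteins = as.integer(n_proteins),
        n_crosslinks = as.integer(n_crosslinks), conditions = conditions,
        n_replicates = as.integer(n_replicates),
        noise_sd_log2 = noise_sd_log2, planted_effects = planted_effects,
        mnar_midpoint = mnar_midpoint, mnar_slope = mnar_slope,
        motif_fraction_down = motif_fraction_down,
        fraction_decoy = fraction_decoy)
}

#' @describeIn SimConfig-class the declared reference condition.
#' @param x a `SimConfig`.
#' @export
referenceCondition <- function(x) x@conditions[1]

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        paste0("SimConfig: seed %d, %d conditions (ref %s), %d replicates,",
               " noise sd %.2f log2\n"),
        object@seed, length(object@conditions), object@conditions[1],
        object@n_replicates, object@noise_sd_log2))
    cat(sprintf("  preys %d, phosphopeptides %d, proteins %d, crosslinks %d, planted effects %d\n",
                object@n_preys, object@n_phosphopeptides, object@n_proteins,
                object@n_crosslinks, nrow(object@planted_effects)))
})

## ---------------------------------------------------------------------------
## Annotation sets and the regulated network
## ---------------------------------------------------------------------------

#' Annotation inputs for network integration
#'
#' User-supplied prior knowledge: the cancer-driver list, an undirected
#' deduplicated reference edge list with evidence fields, term-to-gene sets
#' for over-representation analysis, and the background universe.
#'
#' @slot cdp_list character, cancer-driver protein ids.
#' @slot ppi_edges data.frame with columns idA, idB, evidence_kind,
#'   pubmed_ids (semicolon-separated, possibly empty); canonically ordered
#'   (idA <= idB) and deduplicated.
#' @slot term_sets named list of character vectors.
#' @slot background character, background protein universe.
#' @export
setClass("AnnotationSets", representation(
    cdp_list = "character",
    ppi_edges = "data.frame",
    term_sets = "list",
    background = "character"
))

setValidity("AnnotationSets", function(object) {
    e <- object@ppi_edges
    msgs <- character()
    if (nrow(e)) {
        if (!all(c("idA", "idB", "evidence_kind", "pubmed_ids") %in%
                 colnames(e)))
            msgs <- c(msgs,
                "ppi_edges needs idA, idB, evidence_kind, pubmed_ids")
        else {
            if (any(e$idA > e$idB))
                msgs <- c(msgs, "ppi_edges must be canonically ordered")
            if (anyDuplicated(paste(e$idA, e$idB)))
                msgs <- c(msgs, "ppi_edges must be deduplicated")
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct an AnnotationSets object, canonicalizing the edge list
#'
#' Edge endpoints are sorted within each pair and symmetric/repeated pairs
#' collapsed (first occurrence kept), so the stored edge list is undirected
#' and deduplicated.
#'
#' @param cdp_list,term_sets,background see the corresponding slots.
#' @param ppi_edges data.frame with idA, idB, evidence_kind, pubmed_ids in
#'   any order/orientation.
#' @rdname AnnotationSets-class
#' @export
annotationSets <- function(cdp_list = character(),
                           ppi_edges = data.frame(
                               idA = character(), idB = character(),
                               evidence_kind = character(),
                               pubmed_ids = character()),
                           term_sets = list(),
                           background = character()) {
    if (nrow(ppi_edges)) {
        a <- pmin(ppi_edges$idA, ppi_edges$idB)
        b <- pmax(ppi_edges$idA, ppi_edges$idB)
        ppi_edges$idA <- a
        ppi_edges$idB <- b
        ppi_edges <- ppi_edges[!duplicated(paste(a, b)), , drop = FALSE]
        rownames(ppi_edges) <- NULL
    }
    new("AnnotationSets", cdp_list = unique(cdp_list), ppi_edges = ppi_edges,
        term_sets = term_sets, background = unique(background))
}

setMethod("show", "AnnotationSets", function(object) {
    cat(sprintf(
        "AnnotationSets: %d CDPs, %d reference edges, %d term sets, background %d\n",
        length(object@cdp_list), nrow(object@ppi_edges),
        length(object@term_sets), length(object@background)))
})

#' Integrated network of regulated cancer-driver proteins
#'
#' Nodes are the selected regulated cancer-driver proteins with per-layer,
#' per-condition regulation flags; edges are the evidence-filtered reference
#' interactions among them. Nodes without any retrieved interaction are
#' retained and marked isolated.
#'
#' @slot nodes character, node protein ids.
#' @slot flags data.frame (protein_id, layer, condition, direction), one row
#'   per regulation event supporting a node's inclusion.
#' @slot edges data.frame (idA, idB, evidence_kind, pubmed_ids), canonical
#'   order, both endpoints nodes.
#' @slot isolated named logical, TRUE iff the node has degree 0.
#' @export
setClass("RegulatedNetwork", representation(
    nodes = "character",
    flags = "data.frame",
    edges = "data.frame",
    isolated = "logical"
))

setValidity("RegulatedNetwork", function(object) {
    msgs <- character()
    e <- object@edges
    if (nrow(e) && !all(c(e$idA, e$idB) %in% object@nodes))
        msgs <- c(msgs, "every edge endpoint must be a node")
    if (!identical(sort(names(object@isolated)), sort(object@nodes)))
        msgs <- c(msgs, "isolated must be named by the nodes")
    deg <- table(factor(c(e$idA, e$idB), levels = object@nodes))
    bad <- names(object@isolated)[object@isolated !=
                                  (deg[names(object@isolated)] == 0)]
    if (length(bad))
        msgs <- c(msgs, paste("isolated flag inconsistent with degree for:",
                              paste(bad, collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "RegulatedNetwork", function(object) {
    cat(sprintf(
        "RegulatedNetwork: %d nodes (%d isolated), %d edges, %d regulation flags\n",
        length(object@nodes), sum(object@isolated), nrow(object@edges),
        nrow(object@flags)))
})

#' @describeIn RegulatedNetwork-class node ids.
#' @param x a `RegulatedNetwork`.
#' @export
networkNodes <- function(x) x@nodes

#' @describeIn RegulatedNetwork-class evidence-filtered edges.
#' @export
networkEdges <- function(x) x@edges

#' @describeIn RegulatedNetwork-class per-node regulation flags.
#' @export
regulationFlags <- function(x) x@flags

#' @describeIn RegulatedNetwork-class named logical of isolated nodes.
#' @export
isolatedNodes <- function(x) x@isolated

#' Convert a RegulatedNetwork to an igraph graph
#'
#' @param x a `RegulatedNetwork`.
#' @return an undirected `igraph` graph with isolated nodes retained.
#' @export
asIgraph <- function(x) {
    stopifnot(is(x, "RegulatedNetwork"))
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(x@nodes), name = x@nodes)
    if (nrow(x@edges))
        g <- igraph::add_edges(g, rbind(x@edges$idA, x@edges$idB))
    g
}
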