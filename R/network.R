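## Cross-layer integration: selection of regulated cancer-driver proteins
## from the interaction and phospho layers, evidence-filtered mapping of
## reference edges among them, overlap/novelty against a reference
## interactome, and EASE-style over-representation analysis.

#' Select regulated cancer-driver proteins across layers
#'
#' A protein is selected iff it is on the cancer-driver list AND it is
#' regulated — at the phospho level and/or the interaction level, under the
#' integration criteria — in at least one mutant condition. The returned
#' flags record which layer, condition and direction supported each node.
#'
#' @param phospho_results phospho differential results with a `protein_id`
#'   column.
#' @param interaction_results interaction differential results
#'   (`analyte_id` is the prey protein id).
#' @param annotations an [AnnotationSets-class].
#' @param criteria an [IntegrationCriteria-class].
#' @return list with `nodes` (character) and `flags` (data.frame
#'   protein_id, layer, condition, direction).
#' @export
selectRegulatedCdps <- function(phospho_results, interaction_results,
                                annotations,
                                criteria = integrationCriteria()) {
    cmp <- if (criteria@strict_p) `<` else `<=`
    ph <- phospho_results[
        abs(phospho_results$log2fc) > criteria@phospho_fc &
        cmp(phospho_results$adj_pvalue, criteria@phospho_fdr), ,
        drop = FALSE]
    it <- interaction_results[
        abs(interaction_results$log2fc) > criteria@interaction_fc &
        cmp(interaction_results$adj_pvalue, criteria@interaction_adj_p), ,
        drop = FALSE]
    flags <- rbind(
        if (nrow(ph)) data.frame(
            protein_id = ph$protein_id, layer = "phospho",
            condition = ph$condition,
            direction = ifelse(ph$log2fc > 0, "up", "down"),
            stringsAsFactors = FALSE),
        if (nrow(it)) data.frame(
            protein_id = it$analyte_id, layer = "interaction",
            condition = it$condition,
            direction = ifelse(it$log2fc > 0, "up", "down"),
            stringsAsFactors = FALSE))
    if (is.null(flags))
        flags <- data.frame(protein_id = character(), layer = character(),
                            condition = character(),
                            direction = character())
    flags <- flags[flags$protein_id %in% annotations@cdp_list, ,
                   drop = FALSE]
    rownames(flags) <- NULL
    list(nodes = sort(unique(flags$protein_id)), flags = flags)
}

#' Build the regulated cancer-driver network
#'
#' Maps the reference edges with both endpoints among the selected nodes
#' and evidence passing the criteria (experimentally validated with PubMed
#' ids by default); symmetric duplicates are collapsed and nodes without
#' any retrieved interaction are retained as isolated.
#'
#' @param selection output of [selectRegulatedCdps] (or a character vector
#'   of node ids, in which case flags are empty).
#' @param annotations an [AnnotationSets-class].
#' @param criteria an [IntegrationCriteria-class].
#' @return a [RegulatedNetwork-class].
#' @export
buildNetwork <- function(selection, annotations,
                         criteria = integrationCriteria()) {
    if (is.character(selection))
        selection <- list(nodes = sort(unique(selection)),
                          flags = data.frame(protein_id = character(),
                                             layer = character(),
                                             condition = character(),
                                             direction = character()))
    nodes <- selection$nodes
    e <- annotations@ppi_edges
    keep <- e$idA %in% nodes & e$idB %in% nodes
    if (criteria@evidence_required == "experimental_with_pubmed")
        keep <- keep & e$evidence_kind == "experimental" &
            !is.na(e$pubmed_ids) & nzchar(e$pubmed_ids)
    edges <- e[keep, , drop = FALSE]
    rownames(edges) <- NULL
    deg <- table(factor(c(edges$idA, edges$idB), levels = nodes))
    isolated <- stats::setNames(as.vector(deg) == 0, nodes)
    new("RegulatedNetwork", nodes = nodes, flags = selection$flags,
        edges = edges, isolated = isolated)
}

#' Per-node, per-condition dual regulation table
#'
#' Long-format export pairing each node and mutant condition with its
#' interaction-layer and phospho-layer regulation call, suitable for the
#' two-color-code rendering of integrated networks.
#'
#' @param network a [RegulatedNetwork-class].
#' @param conditions conditions to tabulate (default: all conditions seen
#'   in the flags).
#' @return data.frame protein_id, condition, interaction_regulation,
#'   phospho_regulation; one row per node x condition.
#' @export
dualRegulationTable <- function(network,
                                conditions = sort(unique(
                                    network@flags$condition))) {
    nodes <- networkNodes(network)
    if (!length(nodes) || !length(conditions))
        return(data.frame(protein_id = character(),
                          condition = character(),
                          interaction_regulation = character(),
                          phospho_regulation = character()))
    fl <- network@flags
    grid <- expand.grid(protein_id = nodes, condition = conditions,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    lookup <- function(layer, id, cond) {
        d <- fl$direction[fl$protein_id == id & fl$condition == cond &
                          fl$layer == layer]
        if (length(d)) d[1] else "none"
    }
    grid$interaction_regulation <- mapply(lookup, "interaction",
                                          grid$protein_id, grid$condition)
    grid$phospho_regulation <- mapply(lookup, "phospho",
                                      grid$protein_id, grid$condition)
    grid
}

#' Overlap of detected interactors with a reference interactome
#'
#' Per bait: recall = fraction of detected interactors already among the
#' bait's reference neighbours; novel fraction = 1 - recall. Also reports
#' the number of preys shared by every bait.
#'
#' @param interactors_by_bait named list of character vectors (detected
#'   interactors per bait).
#' @param reference_edges data.frame with idA, idB (undirected reference
#'   edge list).
#' @return list with `per_bait` (data.frame bait, n_detected, recall,
#'   novel_fraction), `mean_recall`, `mean_novel_fraction`,
#'   `shared_all_count`.
#' @export
referenceOverlap <- function(interactors_by_bait, reference_edges) {
    neighbours <- function(bait)
        unique(c(reference_edges$idB[reference_edges$idA == bait],
                 reference_edges$idA[reference_edges$idB == bait]))
    rows <- lapply(names(interactors_by_bait), function(bait) {
        det <- unique(interactors_by_bait[[bait]])
        if (!length(det)) stop("empty interactor set for bait ", bait)
        rec <- mean(det %in% neighbours(bait))
        data.frame(bait = bait, n_detected = length(det), recall = rec,
                   novel_fraction = 1 - rec, stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, rows)
    shared <- Reduce(intersect, interactors_by_bait)
    list(per_bait = per, mean_recall = mean(per$recall),
         mean_novel_fraction = mean(per$novel_fraction),
         shared_all_count = length(shared))
}

#' Over-representation analysis of term sets (Fisher or EASE variant)
#'
#' Per term, a 2x2 table (in-term vs not) x (hit vs background-only) is
#' tested. The `fisher` variant uses the two-sided exact test; the `ease`
#' variant is the conservative one-sided upper-tail test with the in-term
#' hit count reduced by one (floored at 0), matching the "modified Fisher
#' exact test" semantics of common annotation servers. P-values are BH
#' adjusted across terms.
#'
#' @param hit_set character vector of hit ids (subset of `background`).
#' @param term_sets named list of character vectors (subsets of
#'   `background`).
#' @param background character background universe.
#' @param variant "fisher" or "ease".
#' @return data.frame term_id, n_term, n_hit_in_term, p.value, adj_pvalue,
#'   ordered as `term_sets`.
#' @export
easeOra <- function(hit_set, term_sets, background,
                    variant = c("fisher", "ease")) {
    variant <- match.arg(variant)
    hit_set <- unique(hit_set)
    if (!length(hit_set)) stop("empty hit set")
    if (!all(hit_set %in% background))
        stop("hit_set must be a subset of the background")
    N <- length(unique(background))
    n_hit <- length(hit_set)
    ps <- vapply(names(term_sets), function(tm) {
        term <- unique(term_sets[[tm]])
        K <- length(term)
        a <- sum(hit_set %in% term)
        if (variant == "fisher") {
            tab <- matrix(c(a, n_hit - a, K - a, N - n_hit - (K - a)),
                          nrow = 2, byrow = TRUE)
            fisherTwoSided(tab)
        } else {
            a_ease <- max(a - 1L, 0L)
            # upper tail P(X >= a_ease), X ~ Hypergeom(N, K, n_hit)
            stats::phyper(a_ease - 1, K, N - K, n_hit, lower.tail = FALSE)
        }
    }, numeric(1))
    out <- data.frame(
        term_id = names(term_sets),
        n_term = vapply(term_sets, function(x) length(unique(x)),
                        integer(1)),
        n_hit_in_term = vapply(term_sets, function(x)
            sum(hit_set %in% unique(x)), integer(1)),
        p.value = unname(ps), stringsAsFactors = FALSE)
    out$adj_pvalue <- bhAdjust(out$p.value)
    rownames(out) <- NULL
    out
}
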