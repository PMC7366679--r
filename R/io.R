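## Readers and writers for the long-format quantitative tables, PDB
## structures and FASTA sequences consumed by the pipeline. All tables are
## UTF-8, tab-separated, long format, with a documented canonical column
## order so that write(read(x)) round-trips byte-identically.

.QUANT_COLS <- c("analyte_id", "analyte_kind", "condition", "replicate",
                 "intensity", "mscore", "decoy")
.ANALYTE_KINDS <- c("prey", "phosphopeptide", "protein", "crosslink",
                    "fragment")

#' Read a long-format quantitative table
#'
#' One row per measured intensity of one analyte in one condition/replicate.
#' Missing intensities are encoded as an empty cell or "NA" and are kept as
#' `NA` — never as 0, so downstream intensity-dependent imputation can
#' distinguish absence from low abundance. Optional columns `mscore` and
#' `decoy` are filled with `NA` when absent from the file.
#'
#' @param path path to a tab-separated file with header columns
#'   `analyte_id`, `condition`, `replicate`, `intensity` and optionally
#'   `analyte_kind`, `mscore`, `decoy`.
#' @param schema the analyte kind to stamp on rows when the file carries no
#'   `analyte_kind` column; one of prey, phosphopeptide, protein, crosslink,
#'   fragment.
#' @return data.frame in canonical column order.
#' @export
readQuantTable <- function(path, schema = c("prey", "phosphopeptide",
                                            "protein", "crosslink",
                                            "fragment")) {
    schema <- match.arg(schema)
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            na.strings = c("NA", ""),
                            colClasses = NA, check.names = TRUE)
    required <- c("analyte_id", "condition", "replicate", "intensity")
    missing_cols <- setdiff(required, colnames(df))
    if (length(missing_cols))
        stop("malformed header: missing column(s) ",
             paste(missing_cols, collapse = ", "))
    if (!"analyte_kind" %in% colnames(df))
        df$analyte_kind <- rep(schema, nrow(df))
    if (!"mscore" %in% colnames(df)) df$mscore <- rep(NA_real_, nrow(df))
    if (!"decoy" %in% colnames(df)) df$decoy <- rep(NA, nrow(df))
    df$replicate <- as.integer(df$replicate)
    df$intensity <- as.numeric(df$intensity)
    df$mscore <- as.numeric(df$mscore)
    df$decoy <- as.logical(df$decoy)
    validateQuantRecords(df)
    df[, .QUANT_COLS]
}

#' Validate a collection of quantitative records
#'
#' Enforces the row-level invariants: intensity missing or strictly
#' positive, replicates positive integers, known analyte kinds, m-scores in
#' (0, 1], and unique (analyte_id, condition, replicate) keys. Row numbers
#' (1-based over the data body) are named in every error.
#'
#' @param df data.frame of quantitative records.
#' @return invisibly, the validated data.frame.
#' @export
validateQuantRecords <- function(df) {
    bad <- which(!is.na(df$intensity) & df$intensity <= 0)
    if (length(bad))
        stop("non-positive intensity at row(s): ",
             paste(bad, collapse = ", "),
             " (missing values must be empty or NA, never 0)")
    bad <- which(is.na(df$replicate) | df$replicate < 1)
    if (length(bad))
        stop("replicate must be a positive integer at row(s): ",
             paste(bad, collapse = ", "))
    bad <- which(!df$analyte_kind %in% .ANALYTE_KINDS)
    if (length(bad))
        stop("unknown analyte_kind at row(s): ", paste(bad, collapse = ", "))
    bad <- which(!is.na(df$mscore) & (df$mscore <= 0 | df$mscore > 1))
    if (length(bad))
        stop("mscore must lie in (0, 1] at row(s): ",
             paste(bad, collapse = ", "))
    key <- paste(df$analyte_id, df$condition, df$replicate)
    if (anyDuplicated(key))
        stop("duplicated (analyte_id, condition, replicate) at row(s): ",
             paste(which(duplicated(key)), collapse = ", "))
    invisible(df)
}

#' Write a quantitative table in canonical form
#'
#' Columns are emitted in the canonical order with missing values written as
#' "NA", so reading the file back reproduces the body byte-identically.
#'
#' @param df data.frame of quantitative records.
#' @param path output path.
#' @export
writeQuantTable <- function(df, path) {
    validateQuantRecords(df)
    utils::write.table(df[, .QUANT_COLS], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a bait-prey interactor table
#'
#' @param path tab-separated file with columns `bait_id`, `prey_id`,
#'   `method` (APMS or BioID), `saint_score`, `control_frequency`,
#'   `in_gfp_control`.
#' @return data.frame of interactor records.
#' @export
readInteractorTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    req <- c("bait_id", "prey_id", "method", "saint_score",
             "control_frequency", "in_gfp_control")
    if (!all(req %in% colnames(df)))
        stop("malformed header: need ", paste(req, collapse = ", "))
    if (any(df$saint_score < 0 | df$saint_score > 1))
        stop("saint_score must lie in [0, 1]")
    if (any(df$control_frequency < 0 | df$control_frequency > 1))
        stop("control_frequency must lie in [0, 1]")
    df$in_gfp_control <- as.logical(df$in_gfp_control)
    df
}

#' Parse Calpha coordinates of one chain from a PDB file
#'
#' Keeps one Calpha per residue using the author residue numbering. When
#' alternate locations are present the highest-occupancy altloc is kept,
#' ties going to the first in file order. Residues lacking a Calpha are
#' skipped with a warning.
#'
#' @param path PDB file.
#' @param chain chain identifier to extract.
#' @return a [StructureModel-class] object.
#' @export
readStructure <- function(path, chain) {
    if (!file.exists(path)) stop("file not found: ", path)
    pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                            rm.alt = FALSE))
    at <- pdb$atom
    chains <- unique(at$chain)
    if (!chain %in% chains)
        stop("chain '", chain, "' not present; available chains: ",
             paste(chains, collapse = ", "))
    sel <- at[at$chain == chain & at$elety == "CA" & at$type == "ATOM", ,
              drop = FALSE]
    all_res <- unique(at$resno[at$chain == chain & at$type == "ATOM"])
    no_ca <- setdiff(all_res, sel$resno)
    if (length(no_ca))
        warning("skipping residue(s) without Calpha: ",
                paste(no_ca, collapse = ", "))
    if (!nrow(sel)) stop("no Calpha atoms found in chain ", chain)
    # altloc resolution: highest occupancy wins, ties to first in file
    occ <- ifelse(is.na(sel$o), 1, sel$o)
    ord <- order(sel$resno, -occ, seq_len(nrow(sel)))
    sel <- sel[ord, , drop = FALSE]
    sel <- sel[!duplicated(sel$resno), , drop = FALSE]
    sel <- sel[order(sel$resno), , drop = FALSE]
    coords <- as.matrix(sel[, c("x", "y", "z")])
    rownames(coords) <- sel$resno
    colnames(coords) <- c("x", "y", "z")
    new("StructureModel", chain = chain, coords = coords,
        resnames = sel$resid,
        covered_range = as.integer(range(sel$resno)))
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector of uppercased sequences; duplicate
#'   identifiers are an error.
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    ss <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(ids))
        stop("duplicate sequence id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    seqs <- toupper(as.character(ss))
    names(seqs) <- ids
    seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
writeFasta <- function(seqs, path) {
    ss <- Biostrings::AAStringSet(seqs)
    Biostrings::writeXStringSet(ss, path)
    invisible(path)
}
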