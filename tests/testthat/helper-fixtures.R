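# Small programmatic fixtures shared across test files.

quantFixture <- function() {
    data.frame(
        analyte_id = rep(c("BAIT", "preyA", "preyB"), times = 4),
        analyte_kind = "prey",
        condition = rep(c("WT", "WT", "KR", "KR"), each = 3),
        replicate = rep(c(1L, 2L, 1L, 2L), each = 3),
        intensity = c(4e6, 2e6, 1e6,
                      4e6, 2e6, NA,
                      8e6, 1e6, 2e6,
                      8e6, 1e6, 2e6),
        mscore = NA_real_, decoy = NA,
        stringsAsFactors = FALSE)
}

writeQuantFixture <- function(df = quantFixture()) {
    path <- withr::local_tempfile(fileext = ".tsv",
                                  .local_envir = parent.frame())
    mutlayers::writeQuantTable(df, path)
    path
}

# A minimal PDB with two chains; chain A residues 146 and 147, the second
# with two altlocs (B has the higher occupancy and different coordinates).
pdbFixture <- function() {
    path <- withr::local_tempfile(fileext = ".pdb",
                                  .local_envir = parent.frame())
    lines <- c(
        "ATOM      1  N   LYS A 146       0.000   0.000   0.000  1.00 10.00           N",
        "ATOM      2  CA  LYS A 146       1.000   2.000   3.000  1.00 10.00           C",
        "ATOM      3  CA ALYS A 147       9.000   9.000   9.000  0.40 10.00           C",
        "ATOM      4  CA BLYS A 147       4.000   5.000   6.000  0.60 10.00           C",
        "ATOM      5  CA  GLY B  10       7.000   8.000   9.000  1.00 10.00           C",
        "END")
    writeLines(lines, path)
    path
}

fastaFixture <- function(dup = FALSE) {
    path <- withr::local_tempfile(fileext = ".fasta",
                                  .local_envir = parent.frame())
    lines <- c(">protA", "MKTAYIAKQR", ">protB", "mvhltpeeks")
    if (dup) lines <- c(lines, ">protA", "AAAA")
    writeLines(lines, path)
    path
}

# Transition rows for one cross-link in one run, both channels, areas
# 1..6 (light) and 7..12 (heavy), co-eluting at the library RT.
transitionFixture <- function(library_rt = 50) {
    data.frame(
        xl_id = "XL1", condition = "WT", replicate = 1L,
        channel = rep(c("light", "heavy"), each = 6),
        transition_index = rep(1:6, 2),
        area = as.numeric(1:12),
        snr = 20,
        apex_rt = library_rt,
        stringsAsFactors = FALSE)
}

# Random rigid motion (rotation + translation) of a StructureModel.
rigidMotion <- function(structure) {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    shift <- stats::rnorm(3, 0, 50)
    coords <- structure@coords %*% q +
        matrix(shift, nrow(structure@coords), 3, byrow = TRUE)
    dimnames(coords) <- dimnames(structure@coords)
    methods::new("StructureModel", chain = structure@chain,
                 coords = coords, resnames = structure@resnames,
                 covered_range = structure@covered_range)
}
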