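test_that("DIA feature filtering applies m-score and detection rules", {
    mk <- function(id, mscore, n_detected, n_runs = 10) data.frame(
        analyte_id = id, analyte_kind = "phosphopeptide",
        condition = "C", replicate = seq_len(n_runs),
        intensity = c(rep(100, n_detected),
                      rep(NA_real_, n_runs - n_detected)),
        mscore = mscore, decoy = FALSE, stringsAsFactors = FALSE)
    df <- rbind(mk("good", 0.005, 5), mk("badscore", 0.02, 10),
                mk("rare", 0.005, 2), mk("edge", 0.005, 3))
    out <- filterDiaFeatures(df, mscore_max = 0.01,
                             detection_rate_min = 0.30)
    # "edge" detected in exactly 3 of 10 runs passes the inclusive >= 30%
    expect_setequal(unique(out$analyte_id), c("good", "edge"))
})

test_that("FFT-scaled FDR is exact and linear", {
    expect_identical(fdrFromFft(0, 1000, 0.46), 0)
    expect_identical(fdrFromFft(100, 1000, 0.46), 0.046)
    expect_identical(fdrFromFft(100, 1000, 1.0), 0.1)
    # linear in both n_decoy and fft
    expect_identical(fdrFromFft(200, 1000, 0.46),
                     2 * fdrFromFft(100, 1000, 0.46))
    expect_identical(fdrFromFft(100, 1000, 0.23),
                     0.5 * fdrFromFft(100, 1000, 0.46))
    expect_error(fdrFromFft(10, 0, 0.46), "positive")
})

test_that("TIS normalization equalizes run totals, conserving the sum", {
    df <- data.frame(
        analyte_id = rep(c("a", "b"), 2), analyte_kind = "protein",
        condition = rep(c("WT", "KR"), each = 2),
        replicate = 1L,
        intensity = c(40, 60, 120, 80),   # totals 100 and 200
        mscore = NA_real_, decoy = NA, stringsAsFactors = FALSE)
    out <- tisNormalize(df)
    # scale factors 1.5 and 0.75
    expect_equal(out$intensity, c(60, 90, 90, 60))
    tot <- tapply(out$intensity, out$condition, sum)
    expect_lt(diff(range(tot)) / mean(tot), 1e-9)
    expect_equal(sum(out$intensity), sum(df$intensity))
    one <- df[df$condition == "WT", ]
    expect_equal(tisNormalize(one)$intensity, one$intensity)
})

test_that("fragment selection keeps coherent fragments and drops peptides", {
    runs <- expand.grid(condition = c("WT", "KR"), replicate = 1:3,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    profile <- c(10, 11, 12, 13, 14, 15)
    mkpep <- function(pep, n_frag, invert = integer()) {
        do.call(rbind, lapply(seq_len(n_frag), function(f) {
            l2 <- if (f %in% invert) rev(profile) else profile
            data.frame(analyte_id = paste0(pep, "_f", f),
                       analyte_kind = "fragment",
                       peptide_id = pep, protein_id = paste0(pep, "_prot"),
                       condition = runs$condition,
                       replicate = runs$replicate,
                       intensity = 2^(l2 - f * 0.1),
                       mscore = 1e-6, decoy = FALSE,
                       stringsAsFactors = FALSE)
        }))
    }
    df <- rbind(mkpep("pepA", 6), mkpep("pepB", 2), mkpep("pepC", 4,
                                                          invert = 4))
    out <- selectFragments(df)
    # 6 identical-profile fragments all kept
    expect_length(unique(out$analyte_id[out$peptide_id == "pepA"]), 6)
    # 2 surviving fragments < frag_min: peptide dropped
    expect_false("pepB" %in% out$peptide_id)
    # anti-correlated fragment (r = -1 against the mean profile) dropped
    expect_false("pepC_f4" %in% out$analyte_id)
    expect_length(unique(out$analyte_id[out$peptide_id == "pepC"]), 3)

    roll <- rollupPeptide(out)
    wt1 <- df[df$peptide_id == "pepA" & df$condition == "WT" &
              df$replicate == 1, ]
    expect_equal(roll$intensity[roll$analyte_id == "pepA" &
                                roll$condition == "WT" &
                                roll$replicate == 1],
                 sum(wt1$intensity))
    # roll-up is order invariant
    set.seed(3)
    roll2 <- rollupPeptide(out[sample(nrow(out)), ])
    roll2 <- roll2[order(roll2$analyte_id, roll2$condition,
                         roll2$replicate), ]
    rolls <- roll[order(roll$analyte_id, roll$condition,
                        roll$replicate), ]
    expect_equal(roll2$intensity, rolls$intensity)
})

test_that("phospho differential recovers planted effects; type-I holds", {
    cfg <- simConfig(seed = 5, noise_sd_log2 = 0, mnar_slope = 0,
                     planted_effects = data.frame(
                         analyte_id = "ppep0001", condition = "KO",
                         log2fc = -2.2))
    sp <- simPhospho(cfg, n_down = 0L)
    res <- differentialPhospho(sp$quant, "WT")
    ko <- res[res$condition == "KO", ]
    expect_equal(ko$log2fc[ko$analyte_id == "ppep0001"], -2.2,
                 tolerance = 1e-9)
    expect_identical(ko$regulated[ko$analyte_id == "ppep0001"], "down")
    expect_true(all(ko$regulated[ko$analyte_id != "ppep0001"] == "none"))

    # type-I calibration on 1000 planted nulls
    cfg2 <- simConfig(seed = 301, n_phosphopeptides = 1000L,
                      noise_sd_log2 = 0.3, mnar_slope = 0,
                      conditions = c("WT", "KR"))
    sp2 <- simPhospho(cfg2, n_down = 0L)
    res2 <- differentialPhospho(sp2$quant, "WT")
    frac <- mean(res2$pvalue <= 0.05)
    expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(res2)))
})

test_that("regulation summaries report per-condition fractions", {
    res <- data.frame(
        analyte_id = sprintf("p%03d", 1:145),
        condition = "KR",
        log2fc = c(rep(-2, 68), rep(0.2, 77)),
        pvalue = 0.001, adj_pvalue = 0.01,
        regulated = c(rep("down", 68), rep("none", 77)),
        stringsAsFactors = FALSE)
    s <- summarizeRegulation(res)
    expect_equal(s$n_significant, 145)
    expect_equal(s$n_down, 68)
    expect_equal(round(100 * s$frac_down, 1), 46.9)
    expect_true(all(s$n_up + s$n_down <= s$n_significant))
    empty <- summarizeRegulation(res[0, ])
    expect_equal(nrow(empty), 0)
})

test_that("motif matching agrees with the regular-language oracle", {
    expect_true(motifMatch("RAASPK", 4))
    expect_true(motifMatch("KAAATPG", 5))
    expect_false(motifMatch("AAASAA", 4))
    # exhaustive over all sequences of length <= 6 on {A,R,K,S,T,P}
    alphabet <- c("A", "R", "K", "S", "T", "P")
    for (len in 2:6) {
        grid <- do.call(expand.grid,
                        c(rep(list(alphabet), len),
                          list(KEEP.OUT.ATTRS = FALSE,
                               stringsAsFactors = FALSE)))
        seqs <- do.call(paste0, grid)
        for (site in seq_len(len)) {
            got <- vapply(seqs, function(s) motifMatch(s, site),
                          logical(1), USE.NAMES = FALSE)
            want <- vapply(seqs, function(s) motifRegexOracle(s, site),
                           logical(1), USE.NAMES = FALSE)
            expect_identical(got, want)
        }
    }
    # sampled at lengths 7-8
    set.seed(6)
    for (i in 1:500) {
        len <- sample(7:8, 1)
        s <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
        site <- sample(len, 1)
        expect_identical(motifMatch(s, site), motifRegexOracle(s, site))
    }
})

test_that("motif enrichment: degenerate and extreme cases, recovery", {
    peps <- data.frame(
        peptide_id = sprintf("p%d", 1:10),
        sequence = rep("AAASAA", 10), site_index = 4,
        stringsAsFactors = FALSE)
    none <- motifEnrichment(peps[1:3, ], peps)
    expect_equal(none$fraction_with_motif, 0)
    expect_equal(none$p.value, 1.0)

    # all-and-only down peptides carry the motif
    peps$sequence[1:3] <- "RAASPK"
    only <- motifEnrichment(peps[1:3, ], peps)
    expect_equal(only$fraction_with_motif, 1)
    a <- matrix(c(3, 0, 0, 7), 2, byrow = TRUE)
    expect_equal(only$p.value, fisherEnumOracle(a), tolerance = 1e-12)

    # synthetic recovery of the planted motif fraction among true downs
    cfg <- simConfig(seed = 19, n_phosphopeptides = 400L,
                     motif_fraction_down = 0.5)
    sp <- simPhospho(cfg, n_down = 120L)
    down <- sp$peptides[sp$truth$planted_down, ]
    enr <- motifEnrichment(down, sp$peptides)
    expect_lt(abs(enr$fraction_with_motif - 0.5), 3 * sqrt(0.25 / 120))
})

test_that("phospho/protein fold-change correlation behaves", {
    ph <- data.frame(analyte_id = sprintf("p%d", 1:6),
                     protein_id = sprintf("prot%d", 1:6),
                     condition = "KO", log2fc = c(1, 2, 3, 4, 5, 6),
                     stringsAsFactors = FALSE)
    pr <- data.frame(analyte_id = sprintf("prot%d", 1:6),
                     condition = "KO", log2fc = c(1, 2, 3, 4, 5, 6),
                     stringsAsFactors = FALSE)
    expect_equal(phosphoProteinCorrelation(ph, pr)$r_squared, 1)
    expect_error(phosphoProteinCorrelation(ph[1:2, ], pr), "at least 3")

    # independent layers: R^2 near zero (median over 100 seeds)
    ph50 <- data.frame(analyte_id = sprintf("p%d", 1:50),
                       protein_id = sprintf("prot%d", 1:50),
                       condition = "KO", log2fc = 0,
                       stringsAsFactors = FALSE)
    pr50 <- data.frame(analyte_id = sprintf("prot%d", 1:50),
                       condition = "KO", log2fc = 0,
                       stringsAsFactors = FALSE)
    r2 <- vapply(1:100, function(s) {
        set.seed(s)
        ph50$log2fc <- rnorm(50)
        pr50$log2fc <- rnorm(50)
        phosphoProteinCorrelation(ph50, pr50)$r_squared
    }, numeric(1))
    expect_lt(median(r2), 0.05)
})
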