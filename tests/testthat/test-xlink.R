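test_that("identification filtering is strict on ld and length", {
    xls <- data.frame(
        xl_id = c("x1", "x2", "x3"),
        pos_a = 1L, pos_b = 2L,
        ld_score = c(25.0, 25.1, 40),
        peptide_len_a = c(9L, 5L, 4L),
        peptide_len_b = c(9L, 9L, 9L),
        library_rt = 50, stringsAsFactors = FALSE)
    kept <- filterIdentifications(xls)
    expect_identical(kept$xl_id, "x2")
})

test_that("peak acceptance applies rt, coelution and shape criteria", {
    tr <- transitionFixture(library_rt = 50)
    ok <- acceptPeak(tr, 50)
    expect_true(ok$accepted)

    late <- tr
    late$apex_rt <- 52.5
    r <- acceptPeak(late, 50)
    expect_false(r$accepted)
    expect_identical(r$reasons, "rt")

    apart <- tr
    apart$apex_rt[apart$channel == "heavy"] <- 50.5
    r <- acceptPeak(apart, 50)
    expect_false(r$accepted)
    expect_true("coelution" %in% r$reasons)

    # anti-correlated shapes: light pattern reversed in heavy channel;
    # cor(c(1:6), c(6:1)) = -1 by the hand covariance formula
    anti <- tr
    anti$area[anti$channel == "heavy"] <- rev(anti$area[anti$channel ==
                                                        "heavy"])
    r <- acceptPeak(anti, 50)
    expect_false(r$accepted)
    expect_identical(r$reasons, "shape")

    few <- tr[c(1, 2, 7, 8), ]
    r <- acceptPeak(few, 50)
    expect_false(r$accepted)
    expect_identical(r$reasons, "insufficient transitions")
})

test_that("transition quantification sums areas above the snr cutoff", {
    tr <- transitionFixture()
    expect_equal(quantifyCrosslink(tr), 78)       # 1 + ... + 12
    tr$snr[tr$area == 12] <- 4
    expect_equal(quantifyCrosslink(tr), 66)       # drops the area-12 trace
    tr$snr <- 4
    expect_true(is.na(quantifyCrosslink(tr)))
    # permutation invariance
    tr2 <- transitionFixture()
    set.seed(1)
    perm <- tr2[sample(nrow(tr2)), ]
    expect_equal(quantifyCrosslink(perm), 78)
    # additivity: splitting one transition's area into two with the same
    # snr leaves the sum unchanged
    half_a <- within(tr2[1, ], area <- 0.4)
    half_b <- within(tr2[1, ], area <- 0.6)
    expect_equal(quantifyCrosslink(rbind(tr2[-1, ], half_a, half_b)), 78)
})

test_that("reference normalization divides by the mean of two peptides", {
    m <- matrix(c(6, 10), nrow = 2, dimnames = list(c("x1", "x2"), "WT.1"))
    refs <- data.frame(peptide_id = c("r1", "r2"), condition = "WT",
                       replicate = 1L, intensity = c(2, 4),
                       stringsAsFactors = FALSE)
    out <- normalizeToReference(m, refs)
    expect_equal(out["x1", "WT.1"], 2.0)
    refs1 <- refs
    refs1$intensity <- c(1, 1)
    expect_equal(normalizeToReference(m, refs1), m)
    refs0 <- refs
    refs0$intensity[1] <- 0
    expect_error(normalizeToReference(m, refs0), "WT.1")
})

test_that("minimum imputation fills with the global observed minimum", {
    m <- matrix(c(4, 2, 8, NA), nrow = 2)
    out <- imputeMinimum(m)
    expect_equal(out[2, 2], 2)
    expect_equal(imputeMinimum(m * 1), out)     # idempotent on complete
    expect_error(imputeMinimum(matrix(NA_real_, 2, 2)), "all abundances")
})

test_that("replicate correlation is exact and affine invariant", {
    m <- matrix(2^c(1, 2, 3, 4, 5,
                    1, 2, 3, 4, 5,
                    5, 1, 4, 2, 3), ncol = 3,
                dimnames = list(sprintf("x%d", 1:5),
                                c("WT.1", "WT.2", "KR.1")))
    rp <- replicatePearson(m)
    expect_equal(rp$pairwise["WT.1", "WT.2"], 1)
    expect_equal(rp$per_condition[["WT"]], 1)
    # hand covariance formula on the 5-point pair
    x <- m[, "WT.1"]; y <- m[, "KR.1"]
    hand <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(rp$pairwise["WT.1", "KR.1"], hand)
    m2 <- m
    m2[, "KR.1"] <- 3 * m2[, "KR.1"] + 7
    expect_equal(replicatePearson(m2)$pairwise["WT.1", "KR.1"],
                 rp$pairwise["WT.1", "KR.1"])
})

test_that("PCA matches an eigendecomposition oracle up to sign", {
    set.seed(2)
    m <- matrix(2^runif(12, 4, 8), nrow = 4,
                dimnames = list(sprintf("x%d", 1:4),
                                c("A.1", "A.2", "B.1")))
    pc <- pcaScores(m)
    expect_equal(sum(pc$explained), 1, tolerance = 1e-10)
    oracle <- pcaEigenOracle(m)
    for (k in seq_len(ncol(pc$scores))) {
        if (oracle$values[k] < 1e-12) next
        expect_equal(abs(unname(pc$scores[, k])),
                     abs(unname(oracle$scores[, k])), tolerance = 1e-8)
    }
    # two identical samples collapse on the leading component
    m2 <- cbind(m[, c(1, 1)], m[, 3])
    colnames(m2) <- colnames(m)
    pc2 <- pcaScores(m2)
    expect_equal(pc2$scores[1, 1], pc2$scores[2, 1], tolerance = 1e-9)
    # sample reordering permutes scores but preserves them (sign-fixed)
    perm <- c(3, 1, 2)
    pc3 <- pcaScores(m[, perm])
    expect_equal(unname(pc3$scores[match(colnames(m),
                                         colnames(m)[perm]), ]),
                 unname(pc$scores), tolerance = 1e-8)
})

test_that("differential cross-links recover planted changes", {
    cfg <- simConfig(seed = 5, noise_sd_log2 = 0, mnar_slope = 0,
                     planted_effects = data.frame(
                         analyte_id = "XL01", condition = "KR",
                         log2fc = -2.8))
    sx <- simStructureCrosslinks(cfg, n_low_snr = 0)
    m <- quantifyAllCrosslinks(sx$transitions, sx$xls)
    mn <- normalizeToReference(m, sx$reference_peptides)
    res <- differentialCrosslinks(imputeMinimum(mn), "WT")
    kr <- res[res$condition == "KR", ]
    expect_equal(kr$log2fc[kr$analyte_id == "XL01"], -2.8,
                 tolerance = 1e-9)
    expect_identical(kr$regulated[kr$analyte_id == "XL01"], "down")
    expect_true(all(kr$regulated[kr$analyte_id != "XL01"] == "none"))
})

test_that("cross-link fold changes are recovered within 0.1 at noise 0.1", {
    cfg <- simConfig(seed = 77, noise_sd_log2 = 0.1,
                     planted_effects = data.frame(
                         analyte_id = c("XL01", "XL02"),
                         condition = c("KR", "RL"),
                         log2fc = c(-2, 1.5)))
    sx <- simStructureCrosslinks(cfg, n_low_snr = 0)
    m <- quantifyAllCrosslinks(sx$transitions, sx$xls)
    res <- differentialCrosslinks(
        imputeMinimum(normalizeToReference(m, sx$reference_peptides)),
        "WT")
    got1 <- res$log2fc[res$analyte_id == "XL01" & res$condition == "KR"]
    got2 <- res$log2fc[res$analyte_id == "XL02" & res$condition == "RL"]
    expect_lt(abs(got1 - (-2)), 0.1 + 3 * 0.1 * sqrt(2 / 3))
    expect_lt(abs(got2 - 1.5), 0.1 + 3 * 0.1 * sqrt(2 / 3))
})

test_that("distance restraints: hand geometry, symmetry, rigid invariance", {
    coords <- matrix(c(0, 0, 0, 10, 0, 0, 30.1, 0, 0), nrow = 3,
                     byrow = TRUE,
                     dimnames = list(c(146, 200, 300), c("x", "y", "z")))
    s <- new("StructureModel", chain = "A", coords = coords,
             resnames = rep("LYS", 3), covered_range = c(146L, 552L))
    r <- checkDistanceRestraint(146, 200, s)
    expect_equal(r$distance, 10)
    expect_identical(r$status, "satisfied")
    expect_identical(checkDistanceRestraint(146, 300, s)$status,
                     "violated")   # 30.1 > 30, strict boundary
    expect_identical(checkDistanceRestraint(5, 200, s)$status,
                     "unmappable") # residue 5 outside 146-552
    # symmetry
    expect_equal(checkDistanceRestraint(200, 146, s)$distance,
                 r$distance)
    # invariance under 100 random rigid motions
    set.seed(4)
    for (i in 1:100) {
        s2 <- rigidMotion(s)
        expect_identical(checkDistanceRestraint(146, 300, s2)$status,
                         "violated")
        expect_equal(checkDistanceRestraint(146, 200, s2)$distance, 10,
                     tolerance = 1e-9)
    }
    # numbering offset maps construct numbering onto author numbering
    expect_identical(checkDistanceRestraint(46, 100, s,
                                            offset = 100L)$status,
                     "satisfied")
})
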