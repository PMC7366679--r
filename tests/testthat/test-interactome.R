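test_that("high-confidence filtering applies the asymmetric score rules", {
    recs <- data.frame(
        bait_id = "B",
        prey_id = c("p1", "p2", "p3", "p4", "p5"),
        method = c("APMS", "APMS", "BioID", "BioID", "APMS"),
        saint_score = c(0.96, 0.96, 0.99, 1.0, 0.95),
        control_frequency = c(0.10, 0.16, 0, 0.10, 0.05),
        in_gfp_control = c(FALSE, FALSE, FALSE, FALSE, FALSE),
        stringsAsFactors = FALSE)
    kept <- filterHighConfidence(recs)
    # p1 kept; p2 removed (control freq > 15%); p3 removed (BioID needs
    # score = 1); p4 kept; p5 removed (AP-MS needs score strictly > 0.95)
    expect_setequal(kept$prey_id, c("p1", "p4"))

    recs$in_gfp_control[1] <- TRUE
    expect_false("p1" %in% filterHighConfidence(recs)$prey_id)
    recs$method[1] <- "SPEC"
    expect_error(filterHighConfidence(recs), "unknown method")
})

test_that("bait normalization divides by the bait of the same run", {
    df <- quantFixture()
    out <- baitNormalize(df, "BAIT")
    expect_equal(out$intensity[out$analyte_id == "BAIT"], rep(1, 4))
    expect_equal(out$intensity[out$analyte_id == "preyA" &
                               out$condition == "WT" &
                               out$replicate == 1], 0.5)
    # bait missing in one run names the run
    df2 <- df[!(df$analyte_id == "BAIT" & df$condition == "KR" &
                df$replicate == 2), ]
    expect_error(baitNormalize(df2, "BAIT"), "KR/2")
    # pipeline invariance: scaling one run cancels out
    df3 <- df
    ix <- df3$condition == "KR" & df3$replicate == 1
    df3$intensity[ix] <- df3$intensity[ix] * 7
    expect_equal(baitNormalize(df3, "BAIT")$intensity, out$intensity)
})

test_that("low-quantile imputation is seeded and leaves observed alone", {
    set.seed(8)
    n <- 300
    df <- data.frame(
        analyte_id = rep(sprintf("a%03d", 1:n), each = 2),
        analyte_kind = "prey",
        condition = rep(c("WT", "WT"), n),
        replicate = rep(1:2, n),
        intensity = 2^rnorm(2 * n, 20, 2),
        mscore = NA_real_, decoy = NA, stringsAsFactors = FALSE)
    df$intensity[seq(1, 2 * n, by = 17)] <- NA

    out1 <- imputeLowQuantile(df, seed = 4)
    out2 <- imputeLowQuantile(df, seed = 4)
    expect_identical(out1, out2)
    obs <- !is.na(df$intensity)
    expect_identical(out1$intensity[obs], df$intensity[obs])
    expect_false(anyNA(out1$intensity))
    # no missing values: identity
    full <- df[obs, ]
    expect_identical(imputeLowQuantile(full, seed = 4)$intensity,
                     full$intensity)
    expect_error(imputeLowQuantile(df[1:10, ]), "at least 20")
})

test_that("imputation draws centre on the observed 5th percentile", {
    set.seed(31)
    obs_log2 <- rnorm(5000, 20, 2)
    n_miss <- 10000
    df <- data.frame(
        analyte_id = c(sprintf("o%04d", 1:5000),
                       rep(sprintf("m%04d", 1:(n_miss / 2)), each = 2)),
        analyte_kind = "prey",
        condition = "WT",
        replicate = c(rep(1L, 5000), rep(1:2, n_miss / 2)),
        intensity = c(2^obs_log2, rep(NA_real_, n_miss)),
        mscore = NA_real_, decoy = NA, stringsAsFactors = FALSE)
    # give the missing analytes one observed run in a second condition so
    # they are eligible for imputation
    anchor <- data.frame(
        analyte_id = sprintf("m%04d", 1:(n_miss / 2)),
        analyte_kind = "prey", condition = "KR", replicate = 1L,
        intensity = 2^rnorm(n_miss / 2, 20, 2),
        mscore = NA_real_, decoy = NA, stringsAsFactors = FALSE)
    df2 <- rbind(df, anchor)
    out <- imputeLowQuantile(df2, seed = 99, width_factor = 0.3)
    filled <- log2(out$intensity[is.na(df2$intensity)])
    all_obs <- log2(df2$intensity[!is.na(df2$intensity)])
    centre <- quantile(all_obs, 0.05, names = FALSE)
    sdev <- 0.3 * sd(all_obs)
    expect_lt(abs(mean(filled) - centre), 3 * sdev / sqrt(length(filled)))
    expect_length(filled, n_miss)
})

test_that("differential calls recover planted effects and count correctly", {
    cfg <- simConfig(seed = 5, noise_sd_log2 = 0, mnar_slope = 0,
                     planted_effects = data.frame(
                         analyte_id = c("prey001", "prey002"),
                         condition = c("KR", "KR"),
                         log2fc = c(-3, 2)))
    si <- simInteractome(cfg)
    qn <- baitNormalize(si$quant, "BAIT")
    res <- suppressMessages(differentialInteractome(qn, "WT"))
    kr <- res[res$condition == "KR", ]
    expect_equal(kr$log2fc[kr$analyte_id == "prey001"], -3,
                 tolerance = 1e-9)
    expect_identical(kr$regulated[kr$analyte_id == "prey001"], "down")
    expect_identical(kr$regulated[kr$analyte_id == "prey002"], "up")
    nulls <- kr[!kr$analyte_id %in% c("prey001", "prey002"), ]
    expect_true(all(abs(nulls$log2fc) < 1e-9))
    expect_true(all(nulls$regulated == "none"))

    expect_equal(countRegulated(res, "KR"),
                 c(n_up = 1, n_down = 1, n_total = 2))
    expect_equal(countRegulated(res, "RL"),
                 c(n_up = 0, n_down = 0, n_total = 0))
    # counts invariant to row order
    shuf <- res[sample(nrow(res)), ]
    expect_equal(countRegulated(shuf, "KR"), countRegulated(res, "KR"))
    expect_equal(countRegulated(res[0, ], "KR"),
                 c(n_up = 0, n_down = 0, n_total = 0))
})

test_that("type-I error of the interactome stage is calibrated", {
    # 1000 planted nulls, 3 replicates, log2 noise sd 0.3
    cfg <- simConfig(seed = 101, n_preys = 1000L, noise_sd_log2 = 0.3,
                     mnar_slope = 0, conditions = c("WT", "KR"))
    si <- simInteractome(cfg)
    qn <- baitNormalize(si$quant, "BAIT")
    res <- suppressMessages(differentialInteractome(qn, "WT"))
    frac <- mean(res$pvalue <= 0.05)
    se <- sqrt(0.05 * 0.95 / nrow(res))
    expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("cancer-driver enrichment reproduces the printed fraction", {
    interactors <- sprintf("i%02d", 1:70)
    cdp <- c(interactors[1:8], sprintf("c%03d", 1:150))
    background <- unique(c(interactors, cdp, sprintf("b%04d", 1:4000)))
    enr <- cdpEnrichment(interactors, cdp, background)
    expect_equal(round(100 * enr$fraction_cdp, 1), 11.4)
    expect_equal(enr$n_cdp, 8)
    expect_true(enr$p.value >= 0 && enr$p.value <= 1)
    all_cdp <- cdpEnrichment(interactors[1:8], cdp, background)
    expect_equal(all_cdp$fraction_cdp, 1)
    expect_error(cdpEnrichment(character(), cdp, background), "empty")
})

test_that("null cancer-driver enrichment keeps p near 1 across seeds", {
    ps <- vapply(1:100, function(s) {
        set.seed(s)
        background <- sprintf("g%04d", 1:400)
        cdp <- sample(background, 40)          # 10% drivers overall
        interactors <- sample(background, 60)  # random, same 10% rate
        cdpEnrichment(interactors, cdp, background)$p.value
    }, numeric(1))
    expect_gt(median(ps), 0.5)
})

test_that("replicate CV is exact on toy data and scale invariant", {
    df <- data.frame(
        analyte_id = rep(c("a", "b"), each = 3),
        analyte_kind = "prey",
        condition = "WT", replicate = rep(1:3, 2),
        intensity = c(5, 5, 5, 1, 2, 3),
        mscore = NA_real_, decoy = NA, stringsAsFactors = FALSE)
    cv <- replicateCV(df)
    expect_equal(cv$per_analyte$cv[cv$per_analyte$analyte_id == "a"], 0)
    expect_equal(cv$per_analyte$cv[cv$per_analyte$analyte_id == "b"],
                 sd(1:3) / 2)
    df10 <- df
    df10$intensity <- df10$intensity * 10
    expect_equal(replicateCV(df10)$per_analyte$cv, cv$per_analyte$cv)
})
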