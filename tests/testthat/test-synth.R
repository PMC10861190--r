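test_that("cohort generation is deterministic and dimensioned correctly", {
    cfg <- synthConfig(n_participants = 100, n_proteins = 20, seed = 42)
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(proteinMatrix(a), proteinMatrix(b))
    expect_identical(cohortData(a), cohortData(b))
    expect_equal(dim(proteinMatrix(a)), c(300L, 20L))
    expect_equal(length(participants(a)), 100L)
    cd <- cohortData(a)
    expect_setequal(unique(cd$batch), c("discovery", "validation"))
})

test_that("invalid configurations are rejected", {
    expect_error(synthConfig(n_participants = 5), "n_participants")
    expect_error(synthConfig(n_visits = 1), "n_visits")
    expect_error(synthConfig(n_proteins = 15, n_bmd_proteins = 10,
                             n_age_proteins = 10), "exceeds")
    expect_error(synthConfig(frac_female = 1.2), "proportions")
    expect_error(synthConfig(age_sd = 0), "positive")
})

test_that("left-censoring removes exactly the lowest quantile per protein", {
    coh <- simulateCohort(synthConfig(n_participants = 120, n_proteins = 12,
                                      n_bmd_proteins = 4, n_age_proteins = 4,
                                      missing_rate = 0.15, seed = 9))
    m <- proteinMatrix(coh)
    n_expected <- round(0.15 * nrow(m))
    for (j in seq_len(ncol(m))) {
        n_miss <- sum(is.na(m[, j]))
        expect_lte(abs(n_miss - n_expected), 1)
    }
    coh0 <- simulateCohort(synthConfig(n_participants = 120,
                                       n_proteins = 12,
                                       n_bmd_proteins = 4,
                                       n_age_proteins = 4,
                                       missing_rate = 0, seed = 9))
    expect_false(anyNA(proteinMatrix(coh0)))
})

test_that("ground truth is coherent with the generated matrix", {
    coh <- default_cohort()
    gt <- groundTruth(coh)
    m <- proteinMatrix(coh)
    expect_true(all(gt$bmd_proteins$protein %in% colnames(m)))
    expect_true(all(gt$age_proteins$protein %in% colnames(m)))
    expect_equal(mean(gt$delta), 0, tolerance = 1e-12)
    # age proteins follow x = q + k * BA + noise(s)
    cd <- cohortData(coh)
    base <- cd$visit == 1
    ap <- gt$age_proteins[1, ]
    ba <- gt$ba_true[as.character(cd$participant[base])]
    x <- m[base, ap$protein]
    ok <- !is.na(x)
    resid <- x[ok] - (ap$q + ap$k * ba[ok])
    expect_lt(abs(mean(resid)), 4 * ap$s / sqrt(sum(ok)) + 0.05 * ap$s)
    expect_equal(sd(resid), ap$s, tolerance = 0.25)
})

test_that("batches are exchangeable when shift and censoring are off", {
    hits <- 0L
    for (r in 1:100) {
        coh <- simulateCohort(synthConfig(n_participants = 80,
                                          n_proteins = 3,
                                          n_bmd_proteins = 1,
                                          n_age_proteins = 1,
                                          missing_rate = 0,
                                          batch_shift_sd = 0,
                                          seed = 1000 + r))
        cd <- cohortData(coh)
        m <- proteinMatrix(coh)
        base <- cd$visit == 1
        pv <- t.test(m[base & cd$batch == "discovery", 3],
                     m[base & cd$batch == "validation", 3])$p.value
        hits <- hits + (pv >= 0.05)
    }
    expect_gte(hits, 90L)
})

test_that("a causal protein's planted BMD effect is recovered by OLS", {
    coh <- simulateCohort(synthConfig(n_participants = 2000,
                                      n_proteins = 20,
                                      missing_rate = 0,
                                      bmd_effect_sd_per_sd = 0.3,
                                      seed = 77))
    gt <- groundTruth(coh)
    cd <- cohortData(coh)
    md <- S4Vectors::metadata(coh)
    m <- proteinMatrix(coh)
    base <- cd$visit == 1
    last <- cd$visit == max(cd$visit)
    tsc <- (cd$bmd_ls[last] - md$tscore_ref_mean[["ls"]]) /
        md$tscore_ref_sd[["ls"]]
    for (i in c(1, 4)) {
        z <- as.vector(scale(m[base, gt$bmd_proteins$protein[i]]))
        f <- summary(lm(tsc ~ z))$coefficients
        expect_lt(abs(f["z", 1] - gt$bmd_proteins$beta_ls[i]),
                  3 * f["z", 2])
    }
})

test_that("MR summary generator matches its stated construction", {
    expect_error(simulateMrSummary(0, 0.5, 0), "n_snps")
    expect_error(simulateMrSummary(10, 0.5, -1), "pleiotropy_sd")
    one <- simulateMrSummary(1, 0.5, 0, seed = 3)
    expect_equal(nrow(one$instruments), 1L)

    # null effect, no pleiotropy: IVW within 3 SE of 0
    null <- simulateMrSummary(50, 0, 0, seed = 4)
    iv <- mrIvw(null$instruments)
    expect_lt(abs(iv$beta), 3 * iv$se)

    # Wald ratios concentrate on theta as instruments strengthen
    strong <- simulateMrSummary(200, 0.5, 0, seed = 5,
                                se_x_range = c(1e-4, 2e-4),
                                se_y_range = c(1e-4, 2e-4))
    ratios <- strong$instruments$beta_y / strong$instruments$beta_x
    expect_equal(mean(ratios), 0.5, tolerance = 0.005)

    # determinism
    expect_identical(simulateMrSummary(20, 0.3, 0.1, seed = 6),
                     simulateMrSummary(20, 0.3, 0.1, seed = 6))
})

test_that("survival calibration generator is seeded and proportional", {
    a <- simulateSurvival(500, 0.3, seed = 11)
    expect_identical(a, simulateSurvival(500, 0.3, seed = 11))
    expect_true(all(a$time > 0))
    fit <- fitCoxModel(a, a$exposure)
    expect_lt(abs(fit$beta - 0.3), 3 * fit$se)
})
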