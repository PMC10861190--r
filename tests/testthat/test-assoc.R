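test_that("the mixed model is exact on noise-free linear data", {
    id <- rep(1:60, each = 3)
    x <- rnorm(60)[id]
    y <- 0.5 * x
    fit <- fitLmm(y, x, id)
    expect_equal(fit$beta, 0.5, tolerance = 1e-6)
    expect_equal(fit$n_participants, 60L)
})

test_that("the mixed model reduces to OLS with one visit per person", {
    set.seed(21)
    n <- 300
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n, 0, 0.8)
    lmm <- fitLmm(y, x, seq_len(n))
    ols <- summary(lm(y ~ x))$coefficients
    expect_equal(lmm$beta, ols["x", 1], tolerance = 0.01)
    expect_equal(lmm$se, ols["x", 2], tolerance = 0.02)
})

test_that("collinear covariates are reported by name", {
    set.seed(3)
    id <- rep(1:40, each = 2)
    x <- rnorm(40)[id]
    cov <- data.frame(a = rnorm(80))
    cov$b <- 2 * cov$a
    expect_error(fitLmm(rnorm(80), x, id, cov), "collinear")
})

test_that("the generator's BMD effect is recovered within 3 SE", {
    coh <- std_cohort(calib_cohort())
    gt <- groundTruth(coh)
    hits <- 0L
    for (i in seq_len(4)) {
        est <- runAssociation(coh, "ls", batch = NULL,
                              covariates = covariateTiers()$model1,
                              proteins = gt$bmd_proteins$protein[i])
        hits <- hits +
            (abs(est$beta - gt$bmd_proteins$beta_ls[i]) < 3 * est$se)
    }
    expect_gte(hits, 3L)
})

test_that("permuted exposures are rejected at the nominal 5% rate", {
    coh <- std_cohort(simulateCohort(
        synthConfig(n_participants = 120, n_proteins = 10,
                    n_bmd_proteins = 2, n_age_proteins = 2,
                    missing_rate = 0, seed = 31)))
    cd <- cohortData(coh)
    z <- proteinMatrix(coh)
    base <- which(cd$visit == 1)
    fu <- cd$visit > 1
    base_idx <- match(cd$participant, cd$participant[base])
    bmd_z <- as.vector(scale(cd$bmd_ls))
    rejections <- 0L
    set.seed(99)
    for (r in 1:100) {
        perm <- sample(length(base))
        expo <- z[base[perm], 5][base_idx]
        est <- fitLmm(bmd_z[fu], expo[fu], cd$participant[fu])
        rejections <- rejections + (abs(est$beta) > 1.96 * est$se)
    }
    expect_lte(rejections, 12L)
})

test_that("DerSimonian-Laird pooling matches hand-computed cases", {
    m1 <- metaRandomEffects(c(0.3, 0.3), c(0.1, 0.1))
    expect_equal(m1$beta_pooled, 0.3)
    expect_equal(m1$se_pooled, 0.1 / sqrt(2), tolerance = 1e-6)
    expect_equal(m1$Q, 0)
    expect_equal(m1$tau2, 0)
    expect_equal(m1$I2, 0)

    m2 <- metaRandomEffects(c(0.2, 0.4), c(0.1, 0.1))
    expect_equal(m2$beta_fixed, 0.3)
    expect_equal(m2$Q, 2.0)
    expect_equal(m2$tau2, 0.01)
    expect_equal(m2$beta_pooled, 0.3)
    expect_equal(m2$se_pooled, 0.1)
    expect_equal(m2$I2, 50)

    # an infinitely imprecise study carries no weight
    m3 <- metaRandomEffects(c(0.25, 5), c(0.1, 1e6))
    expect_equal(m3$beta_pooled, 0.25, tolerance = 1e-6)
    expect_error(metaRandomEffects(0.3, 0.1), "at least 2")
    expect_error(metaRandomEffects(c(0.1, 0.2), c(0.1, 0)), "> 0")
})

test_that("DL pooling agrees with the metafor reference implementation", {
    skip_if_not_installed("metafor")
    set.seed(7)
    for (r in 1:100) {
        k <- sample(2:5, 1)
        beta <- rnorm(k, 0.2, 0.3)
        se <- runif(k, 0.05, 0.3)
        mine <- metaRandomEffects(beta, se)
        ref <- metafor::rma(yi = beta, sei = se, method = "DL")
        expect_equal(mine$beta_pooled, unname(ref$beta[, 1]),
                     tolerance = 1e-8)
        expect_equal(mine$se_pooled, unname(ref$se), tolerance = 1e-8)
        expect_equal(mine$tau2, unname(ref$tau2), tolerance = 1e-8)
        expect_equal(mine$Q, unname(ref$QE), tolerance = 1e-8)
    }
})

test_that("with tau2 = 0 the pooled estimate is inverse-variance fixed", {
    set.seed(11)
    for (r in 1:500) {
        se <- runif(2, 0.05, 0.3)
        # draw homogeneous studies so tau2 is frequently truncated to 0
        beta <- rnorm(2, 0.1, se / 4)
        m <- metaRandomEffects(beta, se)
        if (m$tau2 == 0) {
            w <- 1 / se^2
            expect_equal(m$beta_pooled, sum(w * beta) / sum(w),
                         tolerance = 1e-10)
            expect_equal(m$se_pooled, 1 / sqrt(sum(w)), tolerance = 1e-10)
        }
    }
})

test_that("Cochran's Q is calibrated under homogeneity", {
    set.seed(13)
    exceed <- 0L
    for (r in 1:1000) {
        se <- c(0.1, 0.12)
        beta <- rnorm(2, 0.3, se)
        m <- metaRandomEffects(beta, se)
        exceed <- exceed + (m$Q > qchisq(0.95, df = 1))
    }
    expect_gt(exceed, 25L)
    expect_lt(exceed, 80L)
})

test_that("significance flag applies p < 0.05 and I2 < 30 strictly", {
    meta <- data.frame(p = c(0.04, 0.04, 0.05, 0.01),
                       I2 = c(25, 45, 10, 30))
    out <- flagSignificant(meta)
    expect_equal(out$flagged, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("metaAnalyze pools per protein and attaches BH q-values", {
    est <- data.frame(
        protein = rep(c("P1", "P2"), 2),
        site = "ls",
        cohort = rep(c("discovery", "validation"), each = 2),
        beta = c(0.30, 0.0, 0.32, 0.01),
        se = c(0.1, 0.1, 0.1, 0.1),
        p = NA, n_obs = 100, n_participants = 50)
    out <- metaAnalyze(est)
    expect_equal(out$protein, c("P1", "P2"))
    expect_equal(out$beta_pooled[1], 0.31)
    expect_equal(out$q, bhAdjust(out$p))
    expect_true(out$flagged[1])
    expect_false(out$flagged[2])
})
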