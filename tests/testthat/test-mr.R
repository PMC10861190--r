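mk_inst <- function(beta_x, beta_y, se_y, se_x = 0.01) {
    data.frame(snp = sprintf("rs%03d", seq_along(beta_x)),
               effect_allele = "A", other_allele = "G",
               eaf = 0.3, beta_x = beta_x, se_x = se_x,
               p_x = 2 * pnorm(-abs(beta_x / se_x)),
               beta_y = beta_y, se_y = se_y)
}

test_that("the genome-wide threshold is applied with its boundary", {
    d <- mk_inst(c(0.1, 0.1, 0.1), c(0, 0, 0), 0.01)
    d$p_x <- c(4e-8, 5e-8, 6e-8)
    out <- filterInstruments(d)
    expect_equal(out$p_x, c(4e-8, 5e-8))
    expect_equal(attr(out, "n_dropped"), 1L)
    d$p_x <- rep(1e-6, 3)
    expect_error(filterInstruments(d), "no instrument")
})

test_that("harmonization aligns alleles and is idempotent", {
    ex <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4"),
                     effect_allele = c("A", "A", "A", "A"),
                     other_allele = c("G", "T", "G", "C"),
                     eaf = c(0.3, 0.5, 0.3, 0.3),
                     beta = c(0.1, 0.1, 0.1, 0.1), se = 0.01,
                     pval = 1e-10)
    oy <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4"),
                     effect_allele = c("G", "A", "A", "C"),
                     other_allele = c("A", "T", "G", "G"),
                     eaf = c(0.7, 0.5, 0.3, 0.3),
                     beta = c(0.05, 0.02, 0.03, 0.04), se = 0.01,
                     pval = 0.5)
    h <- harmonizeInstruments(ex, oy)
    lg <- attr(h, "log")
    # swapped alleles: outcome effect flips
    expect_equal(h$beta_y[h$snp == "rs1"], -0.05)
    # ambiguous palindromic SNP dropped
    expect_false("rs2" %in% h$snp)
    expect_equal(lg$action[lg$snp == "rs2"], "dropped_palindromic")
    # identical alleles: unchanged
    expect_equal(h$beta_y[h$snp == "rs3"], 0.03)
    # incompatible allele pair dropped
    expect_false("rs4" %in% h$snp)
    # harmonizing the harmonized set changes nothing
    h2 <- harmonizeInstruments(
        data.frame(snp = h$snp, effect_allele = h$effect_allele,
                   other_allele = h$other_allele, eaf = h$eaf,
                   beta = h$beta_x, se = h$se_x, pval = h$p_x),
        data.frame(snp = h$snp, effect_allele = h$effect_allele,
                   other_allele = h$other_allele, eaf = h$eaf,
                   beta = h$beta_y, se = h$se_y, pval = 0.5))
    expect_equal(h2$beta_y, h$beta_y)
    expect_equal(h2$snp, h$snp)
})

test_that("Wald ratio follows its formula including signs", {
    w <- waldRatio(0.1, 0.01, 0.05, 0.02)
    expect_equal(w$beta, 0.5)
    expect_equal(w$se, 0.2)
    expect_equal(waldRatio(0.1, 0.01, 0, 0.02)$beta, 0)
    expect_equal(waldRatio(-0.1, 0.01, 0.05, 0.02)$beta, -0.5)
    expect_error(waldRatio(0, 0.01, 0.05, 0.02), "nonzero")
})

test_that("IVW matches the hand-computed two-SNP example", {
    d <- mk_inst(c(0.1, 0.2), c(0.02, 0.05), c(0.01, 0.01))
    iv <- mrIvw(d)
    expect_equal(iv$beta, 0.24, tolerance = 1e-10)
    expect_equal(iv$se, sqrt(1 / 500), tolerance = 1e-6)
    expect_false(iv$random_effects)
    # duplicated SNP pools to the single-SNP Wald ratio
    d2 <- mk_inst(c(0.1, 0.1), c(0.05, 0.05), c(0.02, 0.02))
    expect_equal(mrIvw(d2)$beta,
                 waldRatio(0.1, 0.01, 0.05, 0.02)$beta)
    expect_error(mrIvw(d2[1, ]), ">= 2")
})

test_that("Egger recovers an exact affine relation", {
    bx <- c(0.05, 0.1, 0.15, 0.2)
    d <- mk_inst(bx, 0.1 + 0.3 * bx, 0.01)
    eg <- mrEgger(d)
    expect_equal(eg$beta[eg$method == "egger_slope"], 0.3,
                 tolerance = 1e-10)
    expect_equal(eg$beta[eg$method == "egger_intercept"], 0.1,
                 tolerance = 1e-10)
    expect_error(mrEgger(mk_inst(rep(0.1, 4), rnorm(4), 0.01)),
                 "leverage")
    expect_error(mrEgger(d[1:2, ]), ">= 3")
})

test_that("weighted median interpolates the 50% weight point", {
    d <- mk_inst(c(0.1, 0.1, 0.1), c(0.01, 0.02, 0.09), 0.01)
    wm <- mrWeightedMedian(d, n_boot = 200, seed = 1)
    expect_equal(wm$beta, 0.2, tolerance = 1e-10)
    expect_gt(wm$se, 0)
    # a dominant SNP pulls the median to its ratio
    dd <- mk_inst(c(0.1, 0.1, 0.1), c(0.01, 0.02, 0.09),
                  c(0.2, 0.2, 0.002))
    wmd <- mrWeightedMedian(dd, n_boot = 200, seed = 1)
    expect_equal(wmd$beta, 0.9, tolerance = 0.02)
    expect_error(mrWeightedMedian(d[1:2, ]), ">= 3")
})

test_that("mode estimators locate the ratio density peak", {
    d <- mk_inst(rep(0.1, 5), rep(0.03, 5), 0.01)
    sm <- mrMode(d, "simple", n_boot = 100, seed = 2)
    expect_equal(sm$beta, 0.3, tolerance = 1e-10)
    # majority cluster with outliers
    set.seed(3)
    bx <- rep(0.1, 10)
    by <- c(0.03 + rnorm(7, 0, 0.002), rep(0.2, 3))
    d2 <- mk_inst(bx, by, 0.01)
    m2 <- mrMode(d2, "simple", n_boot = 100, seed = 3)
    expect_equal(m2$beta, 0.3, tolerance = 0.05)
    # grid oracle: weighted kernel density argmax
    wr <- d2$beta_y / d2$beta_x
    se_r <- d2$se_y / abs(d2$beta_x)
    w <- (1 / se_r^2) / sum(1 / se_r^2)
    h <- 0.9 * min(sd(wr), mad(wr)) * length(wr)^(-0.2)
    grid <- seq(min(wr) - 3 * h, max(wr) + 3 * h, length.out = 4000)
    dens <- vapply(grid, function(g)
        sum(w * dnorm((g - wr) / h)), numeric(1))
    mw <- mrMode(d2, "weighted", n_boot = 100, seed = 3)
    expect_equal(mw$beta, grid[which.max(dens)], tolerance = 0.01)
    # a precise outlier moves the weighted but not the simple mode
    d3 <- mk_inst(rep(0.1, 7),
                  c(0.03 + c(-0.002, 0, 0.002, -0.001, 0.001), 0.2, 0.2),
                  c(rep(0.02, 5), 1e-4, 1e-4))
    s3 <- mrMode(d3, "simple", n_boot = 50, seed = 4)$beta
    w3 <- mrMode(d3, "weighted", n_boot = 50, seed = 4)$beta
    expect_lt(abs(s3 - 0.3), 0.1)
    expect_lt(abs(w3 - 2.0), 0.1)
})

test_that("all estimators agree under valid instruments", {
    for (r in 1:8) {
        sim <- simulateMrSummary(50, 0.5, 0, seed = 400 + r)
        est <- mrAll(sim$instruments, seed = r, n_boot = 200)
        betas <- est$beta[est$method != "egger_intercept"]
        ses <- est$se[est$method != "egger_intercept"]
        expect_lt(max(betas) - min(betas), 2 * max(ses))
        expect_lt(abs(est$beta[est$method == "ivw"] - 0.5),
                  3 * est$se[est$method == "ivw"])
    }
})

test_that("single-instrument input falls back to the Wald ratio", {
    sim <- simulateMrSummary(1, 0.4, 0, seed = 9)
    est <- mrAll(sim$instruments)
    expect_equal(est$method, "wald")
    expect_equal(nrow(est), 1L)
})
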