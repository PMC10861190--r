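# direct construction of an age-coupled panel with known truth
make_age_panel <- function(n = 500, m = 12, p_noise = 20, accel_sd = 5,
                           r_target = 0.3, seed = 1) {
    set.seed(seed)
    ca <- rnorm(n, 57.5, 5.1)
    delta <- rnorm(n, 0, accel_sd)
    ba <- ca + delta
    k <- sample(c(-1, 1), m, TRUE) * runif(m, 0.06, 0.12)
    q <- runif(m, 4, 7) - k * 57.5
    s <- abs(k) * 5.1 * sqrt(1 / r_target^2 - 1)
    x_age <- sapply(seq_len(m), function(j)
        q[j] + k[j] * ba + rnorm(n, 0, s[j]))
    colnames(x_age) <- sprintf("A%02d", seq_len(m))
    x_noise <- matrix(rnorm(n * p_noise), n,
                      dimnames = list(NULL, sprintf("N%02d",
                                                    seq_len(p_noise))))
    list(x = cbind(x_age, x_noise), ca = ca, ba = ba, delta = delta,
         age_ids = colnames(x_age))
}

test_that("age-protein screening keeps true correlates, drops redundancy", {
    set.seed(2)
    ca <- rnorm(300, 57, 5)
    z <- cbind(exact = ca,
               dup = ca,
               noise = rnorm(300))
    z <- scale(z)
    sel <- selectAgeProteins(z, ca, max_pairwise_r = 0.7, min_abs_r = 0.1)
    expect_true("exact" %in% sel || "dup" %in% sel)
    expect_length(intersect(c("exact", "dup"), sel), 1L)  # one of the pair
    expect_false("noise" %in% sel)
    expect_equal(unname(attr(sel, "r")[1]), 1, tolerance = 1e-12)
    expect_error(selectAgeProteins(scale(matrix(rnorm(600), 300)), ca,
                                   min_abs_r = 0.9), "screen")
})

test_that("planted age proteins are recovered from a large noise panel", {
    hits <- fps <- c()
    for (r in 1:10) {
        pan <- make_age_panel(n = 2000, m = 12, p_noise = 100,
                              seed = 100 + r)
        sel <- selectAgeProteins(scale(pan$x), pan$ca)
        hits <- c(hits, mean(pan$age_ids %in% sel))
        fps <- c(fps, sum(!sel %in% pan$age_ids))
    }
    expect_gte(mean(hits == 1), 0.9)
    expect_gte(mean(fps <= 1), 0.9)
})

test_that("a noise-free single-protein model returns chronological age", {
    ca <- runif(80, 45, 75)
    x <- cbind(p1 = 10 + 0.5 * ca)
    mod <- fitKdm(x, ca)
    ba <- predictBioage(mod, x, ca)
    expect_equal(ba$ba_e, ca, tolerance = 1e-8)
    expect_equal(mod@proteins$q, 10, tolerance = 1e-8)
    expect_equal(mod@proteins$k, 0.5, tolerance = 1e-8)
    expect_gt(mod@sBA, 0)
})

test_that("corrected age interpolates between the estimate and CA", {
    pan <- make_age_panel(n = 400, seed = 3)
    mod <- fitKdm(pan$x[, pan$age_ids], pan$ca)
    ba <- predictBioage(mod, pan$x[, pan$age_ids], pan$ca)
    expect_true(all(ba$ba_ec >= pmin(ba$ba_e, ba$ca) - 1e-9))
    expect_true(all(ba$ba_ec <= pmax(ba$ba_e, ba$ca) + 1e-9))
    # s_BA limits
    hi <- predictBioage(mod, pan$x[, pan$age_ids], pan$ca, s_ba = 1e9)
    expect_equal(hi$ba_ec, ba$ba_e, tolerance = 1e-4)
    lo <- predictBioage(mod, pan$x[, pan$age_ids], pan$ca, s_ba = 1e-9)
    expect_equal(lo$ba_ec, pan$ca, tolerance = 1e-4)
    # acceleration is a residual: mean exactly 0, uncorrelated with CA
    expect_equal(mean(ba$accel), 0, tolerance = 1e-8)
    expect_equal(abs(cor(ba$accel, ba$ca)), 0, tolerance = 1e-8)
    expect_error(predictBioage(mod, pan$x[, pan$age_ids[-1]], pan$ca),
                 "missing")
})

test_that("the uncorrected estimate is invariant to protein rescaling", {
    pan <- make_age_panel(n = 300, m = 5, p_noise = 0, seed = 4)
    mod1 <- fitKdm(pan$x, pan$ca)
    x2 <- sweep(pan$x, 2, c(3, 0.2, 10, 1, 5), `*`)
    mod2 <- fitKdm(x2, pan$ca)
    expect_equal(predictBioage(mod1, pan$x, pan$ca)$ba_e,
                 predictBioage(mod2, x2, pan$ca)$ba_e, tolerance = 1e-8)
})

test_that("two proteins with identical information average their estimates", {
    set.seed(5)
    ca <- rnorm(400, 57, 5)
    x1 <- 2 + 0.1 * ca + rnorm(400, 0, 1)
    x2 <- 5 + 0.1 * ca + rnorm(400, 0, 1)
    both <- cbind(a = x1, b = x2)
    mod <- fitKdm(both, ca)
    single_a <- fitKdm(cbind(a = x1), ca)
    single_b <- fitKdm(cbind(b = x2), ca)
    ba_a <- predictBioage(single_a, cbind(a = x1), ca, s_ba = 1e9)$ba_ec
    ba_b <- predictBioage(single_b, cbind(b = x2), ca, s_ba = 1e9)$ba_ec
    ba_ab <- predictBioage(mod, both, ca, s_ba = 1e9)$ba_ec
    # estimated weights (k/s)^2 are near-identical, so the pooled estimate
    # tracks the equal-weight average of the single-protein estimates
    avg <- (ba_a + ba_b) / 2
    expect_gt(cor(ba_ab, avg), 0.99)
    expect_equal(mean(ba_ab - avg), 0, tolerance = 0.2)
    # and with mathematically identical information it is exact
    mod_dup <- fitKdm(cbind(a = x1, b = x1 + 3), ca)
    ba_dup <- predictBioage(mod_dup, cbind(a = x1, b = x1 + 3), ca,
                            s_ba = 1e9)$ba_ec
    expect_equal(ba_dup, ba_a, tolerance = 1e-6)
})

test_that("training-set mean of BA_E - CA vanishes with centred residuals", {
    pan <- make_age_panel(n = 1000, seed = 6)
    mod <- fitKdm(pan$x[, pan$age_ids], pan$ca)
    ba <- predictBioage(mod, pan$x[, pan$age_ids], pan$ca)
    expect_lt(abs(mean(ba$ba_e - pan$ca)), 0.5)
})

test_that("biological age tracks true age better than CA alone", {
    wins <- 0L
    for (r in 1:20) {
        pan <- make_age_panel(n = 1000, m = 12, p_noise = 0,
                              accel_sd = 5, seed = 200 + r)
        mod <- fitKdm(pan$x, pan$ca)
        ba <- predictBioage(mod, pan$x, pan$ca)
        wins <- wins + (cor(ba$ba_ec, pan$ba) > cor(pan$ca, pan$ba))
    }
    expect_gte(wins, 19L)
})

test_that("degenerate slopes are dropped with a warning", {
    set.seed(7)
    ca <- rnorm(100, 57, 5)
    x <- cbind(good = 1 + 0.2 * ca + rnorm(100, 0, 1),
               flat = rep(2, 100))
    expect_warning(mod <- fitKdm(x, ca), "zero age slope")
    expect_equal(mod@proteins$protein, "good")
})
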