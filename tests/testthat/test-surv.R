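test_that("survival records implement incident-event timing", {
    d <- data.frame(
        participant = rep(c("a", "b", "c"), each = 3),
        time_years = rep(c(0, 3.3, 6.6), 3),
        status = c("normal", "osteopenia", "osteoporosis",   # incident
                   "normal", "normal", "normal",             # censored
                   "osteoporosis", "normal", "normal"))      # prevalent
    rec <- makeSurvivalRecords(d)
    expect_equal(nrow(rec), 2L)
    expect_equal(rec$time[rec$participant == "a"], 6.6)
    expect_equal(rec$event[rec$participant == "a"], 1L)
    expect_equal(rec$time[rec$participant == "b"], 6.6)
    expect_equal(rec$event[rec$participant == "b"], 0L)
    expect_equal(attr(rec, "excluded"), "c")
})

test_that("the Cox fit maximizes the written partial likelihood", {
    rec <- data.frame(time = c(1, 2, 3, 4), event = 1L)
    x <- c(1, 0, 1, 0)
    fit <- fitCoxModel(rec, x)
    # grid-search oracle on the explicit partial likelihood
    pl <- function(b) (exp(b) / (2 * exp(b) + 2)) *
        (1 / (exp(b) + 2)) * (exp(b) / (exp(b) + 1))
    grid <- seq(-3, 3, by = 1e-4)
    b_star <- grid[which.max(pl(grid))]
    expect_equal(fit$beta, b_star, tolerance = 1e-3)
    # and the fitted maximum dominates random probes
    set.seed(1)
    probes <- runif(200, -3, 3)
    expect_true(all(cox_logpl(fit$beta, rec$time, rec$event, x) + 1e-9 >=
                    vapply(probes, cox_logpl, numeric(1),
                           time = rec$time, event = rec$event, x = x)))
})

test_that("Efron and Breslow agree on tie-free data", {
    d <- simulateSurvival(150, 0.4, seed = 5)
    expect_equal(length(unique(d$time[d$event == 1])), sum(d$event))
    fe <- fitCoxModel(d, d$exposure, ties = "efron")
    fb <- fitCoxModel(d, d$exposure, ties = "breslow")
    expect_equal(fe$beta, fb$beta, tolerance = 1e-10)
})

test_that("the planted log hazard ratio is recovered", {
    d <- simulateSurvival(2000, 0.3, seed = 6)
    fit <- fitCoxModel(d, d$exposure)
    expect_lt(abs(fit$beta - 0.3), 3 * fit$se)
    expect_true(fit$ci[1] < fit$hr & fit$hr < fit$ci[2])
    expect_error(fitCoxModel(data.frame(time = 1:3, event = 0L), 1:3),
                 "no events")
    expect_error(fitCoxModel(data.frame(time = 1:3, event = 1L),
                             rep(1, 3)), "vary")
})

test_that("permuted exposures give nominal Cox coverage", {
    d <- simulateSurvival(300, 0.5, seed = 7)
    set.seed(8)
    cover <- 0L
    for (r in 1:100) {
        f <- fitCoxModel(d, sample(d$exposure))
        cover <- cover + (f$ci[1] < 1 & 1 < f$ci[2])
    }
    expect_gte(cover, 88L)
})

test_that("the spline basis is restricted, smooth and matches the formula", {
    set.seed(9)
    x <- runif(500, 0, 10)
    b <- rcsExpand(x, 4)
    kn <- attr(b, "knots")
    expect_equal(ncol(b), 3L)
    expect_equal(kn, quantile(x, c(0.05, 0.35, 0.65, 0.95), names = FALSE))
    # pure linear region below the first knot
    expect_true(all(b[x < kn[1], -1] == 0))
    # independently coded textbook formula at probe points
    k <- length(kn)
    oracle <- function(xx, j) {
        pp <- function(u) pmax(u, 0)^3
        (pp(xx - kn[j]) -
         pp(xx - kn[k - 1]) * (kn[k] - kn[j]) / (kn[k] - kn[k - 1]) +
         pp(xx - kn[k]) * (kn[k - 1] - kn[j]) / (kn[k] - kn[k - 1])) /
            (kn[k] - kn[1])^2
    }
    probes <- seq(0.5, 9.5, length.out = 10)
    pb <- rcsExpand(probes, knots = kn)
    for (j in 1:2)
        expect_equal(pb[, j + 1], oracle(probes, j), tolerance = 1e-10)
    # continuous second derivative at each knot (numerical)
    h <- 1e-4
    for (kk in kn) {
        for (j in 2:3) {
            f <- function(v) rcsExpand(v, knots = kn)[, j]
            d2 <- function(v) (f(v + h) - 2 * f(v) + f(v - h)) / h^2
            expect_equal(d2(kk - 10 * h), d2(kk + 10 * h),
                         tolerance = 1e-3)
        }
    }
    # linearity beyond the boundary knots: second differences vanish
    far <- c(12, 13, 14)
    fb <- rcsExpand(far, knots = kn)
    expect_equal(fb[3, ] - 2 * fb[2, ] + fb[1, ], rep(0, 3),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_error(rcsExpand(x, knots = c(1, 1, 2)), "duplicate")
    expect_error(rcsExpand(x, 7), "n_knots")
})

test_that("an exactly linear effect needs no nonlinear spline terms", {
    set.seed(10)
    x <- runif(300, -2, 2)
    y <- 2 * x + 1
    b <- rcsExpand(x, 4)
    fit <- lm(y ~ b)
    expect_lt(max(abs(residuals(fit))), 1e-8)
    expect_equal(unname(coef(fit)[3:4]), c(0, 0), tolerance = 1e-6)
})

test_that("spline dose-response is monotone for a log-linear hazard", {
    d <- simulateSurvival(1500, 0.5, seed = 11)
    curve <- rcsDoseResponse(d, d$exposure, n_knots = 4)
    expect_equal(curve$loghr[which.min(abs(curve$exposure -
                                           median(d$exposure)))], 0,
                 tolerance = 0.05)
    expect_gt(cor(curve$exposure, curve$loghr), 0.98)
})

test_that("quartile hazard ratios order with a monotone risk", {
    d <- simulateSurvival(1200, 0.6, seed = 12)
    q <- prsQuartiles(d$exposure)
    res <- quartileHr(d, q)
    expect_equal(res$hr$quartile, c("Q2", "Q3", "Q4"))
    expect_gt(res$hr$hr[3], res$hr$hr[1])
    expect_lt(res$p_trend, 1e-6)
    # free of exposure effect: CIs cover 1
    set.seed(13)
    dn <- simulateSurvival(800, 0, seed = 13)
    resn <- quartileHr(dn, prsQuartiles(rnorm(800)))
    expect_true(all(resn$hr$lo < 1 & 1 < resn$hr$hi))
    expect_error(quartileHr(d, factor(rep("Q1", nrow(d)),
                                      levels = paste0("Q", 1:4))),
                 "empty quartile|variation")
})
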