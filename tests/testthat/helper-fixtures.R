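# Shared fixtures, memoised so expensive cohorts are built once per run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (!exists(name, envir = .fixture_cache))
        assign(name, builder(), envir = .fixture_cache)
    get(name, envir = .fixture_cache)
}

# mid-sized cohort with default study conditions (left-censoring on)
default_cohort <- function() fixture("default_cohort", function() {
    simulateCohort(synthConfig(n_participants = 400, n_proteins = 40,
                               seed = 101))
})

# calibration cohort: no missingness, used for parameter-recovery checks
calib_cohort <- function() fixture("calib_cohort", function() {
    simulateCohort(synthConfig(n_participants = 1000, n_proteins = 25,
                               missing_rate = 0, seed = 202))
})

std_cohort <- function(coh) standardizeProteins(imputeHalfMin(coh))

# brute-force BH step-up oracle: q(i) = min_{j >= i} min(1, m p(j)/j)
bh_bruteforce <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
        rank_i <- which(o == i)
        cand <- vapply(rank_i:m, function(j) min(1, m * p[o[j]] / j),
                       numeric(1))
        q[i] <- min(cand)
    }
    q
}

# brute-force AUC by pair counting
auc_bruteforce <- function(labels, scores) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (a in pos) for (b in neg)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
}

# adjusted Rand index (independent of any clustering package)
ari <- function(a, b) {
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sum_ij <- sum(comb2(tab))
    sum_a <- sum(comb2(rowSums(tab)))
    sum_b <- sum(comb2(colSums(tab)))
    n <- sum(tab)
    expected <- sum_a * sum_b / comb2(n)
    (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# longitudinal mixture data with planted linear-growth classes
make_traj_data <- function(n, intercepts, slopes = NULL, sigma = 0.2,
                           times = c(0, 3.3, 6.6), seed = 1) {
    set.seed(seed)
    K <- length(intercepts)
    if (is.null(slopes)) slopes <- rep(-0.05, K)
    cls <- sample(rep_len(seq_len(K), n))
    id <- rep(sprintf("i%04d", seq_len(n)), each = length(times))
    tt <- rep(times, n)
    y <- intercepts[cls][rep(seq_len(n), each = length(times))] +
        slopes[cls][rep(seq_len(n), each = length(times))] * tt +
        rnorm(length(tt), 0, sigma)
    list(data = data.frame(participant = id, time = tt, y = y),
         class = cls)
}

# Breslow partial log-likelihood for tie-free data (oracle for Cox fits)
cox_logpl <- function(beta, time, event, x) {
    ord <- order(time)
    time <- time[ord]; event <- event[ord]; x <- x[ord]
    eta <- beta * x
    ll <- 0
    for (i in which(event == 1)) {
        risk <- time >= time[i]
        ll <- ll + eta[i] - log(sum(exp(eta[risk])))
    }
    ll
}
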