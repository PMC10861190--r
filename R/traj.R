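#' Latent-class linear growth trajectories fitted by EM
#'
#' Fits the K-class mixture of linear growth curves
#' `y_it = a_k + b_k * t_it + e_it`, `e ~ N(0, sigma^2)` (shared residual
#' SD), to longitudinal outcome data by EM with multiple restarts. The
#' first restart initializes responsibilities from k-means on per-person
#' OLS (intercept, slope) pairs; further restarts perturb that solution.
#' The best log-likelihood is kept and class labels are canonicalized by
#' ascending intercept. The EM log-likelihood is checked to be
#' non-decreasing at every iteration.
#'
#' @param data data.frame with columns `participant`, `time` (years) and
#'   `y` (the outcome, typically standardized BMD).
#' @param K number of latent classes (>= 1).
#' @param seed integer seed (restart jitter).
#' @param n_restarts number of EM restarts (K >= 2).
#' @param tol EM convergence tolerance on the log-likelihood increase.
#' @param max_iter maximum EM iterations per restart.
#' @return list of class `TrajectoryFit`: `K`, `intercept`, `slope`, `pi`,
#'   `sigma`, `posterior` (participants x K), `assignment` (named integer),
#'   `loglik`, `bic` (`-2 loglik + n_params log(N)`), `appa` (per-class
#'   mean of max posterior among assigned members), `appa_min`,
#'   `n_params`, `converged`, `degenerate` (any class weight < 1e-6),
#'   `loglik_trace`.
#' @export
fitLctm <- function(data, K, seed = 1L, n_restarts = 20L, tol = 1e-8,
                    max_iter = 500L) {
    stopifnot(all(c("participant", "time", "y") %in% colnames(data)))
    if (K < 1L) stop("K must be >= 1")
    data <- data[stats::complete.cases(data[c("participant", "time", "y")]), ]
    pid <- as.character(data$participant)
    ids <- unique(pid)
    n <- length(ids)
    if (n < K) stop("need at least K participants")
    idx <- match(pid, ids)
    tt <- data$time
    yy <- data$y

    if (K == 1L) {            # single-class limit: pooled OLS
        fit <- lm(yy ~ tt)
        sig <- sqrt(mean(residuals(fit)^2))
        ll <- sum(dnorm(yy, fitted(fit), sig, log = TRUE))
        n_params <- 3L
        post <- matrix(1, n, 1, dimnames = list(ids, NULL))
        return(structure(list(
            K = 1L, intercept = unname(coef(fit)[1]),
            slope = unname(coef(fit)[2]), pi = 1, sigma = sig,
            posterior = post,
            assignment = setNames(rep(1L, n), ids),
            loglik = ll, bic = -2 * ll + n_params * log(n),
            appa = 1, appa_min = 1, n_params = n_params,
            converged = TRUE, degenerate = FALSE, loglik_trace = ll),
            class = "TrajectoryFit"))
    }

    # per-person OLS (intercept, slope) for the k-means initialization
    pp <- t(vapply(seq_len(n), function(i) {
        r <- idx == i
        if (sum(r) >= 2L && length(unique(tt[r])) >= 2L)
            coef(lm(yy[r] ~ tt[r]))
        else c(mean(yy[r]), 0)
    }, numeric(2)))

    set.seed(seed)
    best <- NULL
    for (rs in seq_len(n_restarts)) {
        resp0 <- .lctmInit(pp, K, first = rs == 1L)
        fit <- .lctmEm(yy, tt, idx, n, K, resp0, tol, max_iter)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }

    ord <- order(best$a)
    resp <- best$resp[, ord, drop = FALSE]
    rownames(resp) <- ids
    assign_k <- max.col(resp)
    appa <- vapply(seq_len(K), function(k) {
        mem <- assign_k == k
        if (!any(mem)) NA_real_ else mean(resp[mem, k])
    }, numeric(1))
    n_params <- 2L * K + (K - 1L) + 1L
    ll <- best$loglik
    structure(list(
        K = as.integer(K), intercept = best$a[ord], slope = best$b[ord],
        pi = best$pi[ord], sigma = best$sigma, posterior = resp,
        assignment = setNames(assign_k, ids),
        loglik = ll, bic = -2 * ll + n_params * log(n),
        appa = appa, appa_min = min(appa, na.rm = TRUE),
        n_params = n_params, converged = best$converged,
        degenerate = any(best$pi < 1e-6) || anyNA(appa),
        loglik_trace = best$trace),
        class = "TrajectoryFit")
}

.lctmInit <- function(pp, K, first) {
    n <- nrow(pp)
    km <- tryCatch(
        kmeans(pp, centers = K, nstart = if (first) 5L else 1L),
        error = function(e) NULL)
    cl <- if (is.null(km)) sample.int(K, n, TRUE) else km$cluster
    resp <- matrix(0, n, K)
    resp[cbind(seq_len(n), cl)] <- 1
    if (!first) {             # soften + jitter for restart diversity
        resp <- resp + matrix(runif(n * K, 0, 0.5), n, K)
        resp <- resp / rowSums(resp)
    }
    resp
}

.lctmEm <- function(yy, tt, idx, n, K, resp, tol, max_iter) {
    ll_old <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    a <- b <- pi_k <- numeric(K)
    sigma <- 1
    for (iter in seq_len(max_iter)) {
        # M-step: per-class WLS of y on t with row weights resp[person, k]
        for (k in seq_len(K)) {
            w <- resp[idx, k]
            sw <- sum(w); swt <- sum(w * tt); swt2 <- sum(w * tt^2)
            swy <- sum(w * yy); swty <- sum(w * tt * yy)
            det <- sw * swt2 - swt^2
            if (det < 1e-12 || sw < 1e-10) {   # empty/degenerate class
                a[k] <- mean(yy); b[k] <- 0
            } else {
                b[k] <- (sw * swty - swt * swy) / det
                a[k] <- (swy - b[k] * swt) / sw
            }
        }
        res2 <- vapply(seq_len(K), function(k)
            sum(resp[idx, k] * (yy - a[k] - b[k] * tt)^2), numeric(1))
        sigma <- sqrt(max(sum(res2) / length(yy), 1e-12))
        pi_k <- pmax(colMeans(resp), 1e-12)
        pi_k <- pi_k / sum(pi_k)

        # E-step: per-person class log-likelihoods
        lmat <- matrix(0, n, K)
        for (k in seq_len(K)) {
            lr <- dnorm(yy, a[k] + b[k] * tt, sigma, log = TRUE)
            lmat[, k] <- rowsum(lr, idx)[, 1] + log(pi_k[k])
        }
        mx <- apply(lmat, 1, max)
        lse <- mx + log(rowSums(exp(lmat - mx)))
        resp <- exp(lmat - lse)
        ll <- sum(lse)
        trace <- c(trace, ll)
        if (ll < ll_old - 1e-6)
            stop("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
        if (is.finite(ll_old) && ll - ll_old < tol) {
            converged <- TRUE
            break
        }
        ll_old <- ll
    }
    list(a = a, b = b, pi = pi_k, sigma = sigma, resp = resp,
         loglik = ll, converged = converged, trace = trace)
}

#' @export
print.TrajectoryFit <- function(x, ...) {
    cat("TrajectoryFit: K =", x$K, " BIC =", round(x$bic, 1),
        " APPA(min) =", round(x$appa_min, 3), "\n")
    print(data.frame(class = seq_len(x$K),
                     intercept = round(x$intercept, 3),
                     slope = round(x$slope, 4),
                     pi = round(x$pi, 3)))
    invisible(x)
}

#' Select the number of trajectory classes
#'
#' Among converged fits (typically K = 1..5), picks the lowest BIC among
#' those whose minimum per-class average posterior probability of
#' assignment (APPA) meets the threshold; if none qualifies, the lowest
#' BIC overall with a warning. Equal BIC ties break toward the smaller K.
#'
#' @param fits list of `TrajectoryFit` objects.
#' @param appa_threshold minimum acceptable APPA (default 0.7).
#' @return the selected `TrajectoryFit`.
#' @export
selectClasses <- function(fits, appa_threshold = 0.7) {
    if (!length(fits)) stop("no fits supplied")
    bic <- vapply(fits, `[[`, numeric(1), "bic")
    appa <- vapply(fits, `[[`, numeric(1), "appa_min")
    K <- vapply(fits, `[[`, integer(1), "K")
    ok <- appa >= appa_threshold
    pool <- if (any(ok)) which(ok) else {
        warning("no fit meets the APPA threshold; selecting on BIC alone")
        seq_along(fits)
    }
    ord <- pool[order(bic[pool], K[pool])]
    fits[[ord[1]]]
}

#' One-way ANOVA of a protein across trajectory classes
#'
#' Fixed-effects one-way ANOVA of baseline protein values by assigned
#' trajectory class.
#'
#' @param x numeric vector (e.g. baseline standardized protein).
#' @param assignment class labels aligned with `x`.
#' @return list: `F`, `df1`, `df2`, `p`.
#' @export
anovaAcrossClasses <- function(x, assignment) {
    g <- factor(assignment)
    if (nlevels(g) < 2L) stop("need at least 2 classes")
    if (any(table(g) < 2L)) stop("every class needs at least 2 members")
    av <- anova(aov(x ~ g))
    list(F = av[1, "F value"], df1 = av[1, "Df"], df2 = av[2, "Df"],
         p = av[1, "Pr(>F)"])
}
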