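#' Incident-osteoporosis survival records from visit-level statuses
#'
#' Builds one record per participant: event time = years from the first
#' BMD visit to the first visit classified osteoporosis; participants
#' without an event are censored at their last attended visit. Participants
#' already osteoporotic at their first visit are prevalent cases and are
#' excluded (listed in the `excluded` attribute).
#'
#' @param statuses data.frame with columns `participant`, `time_years` and
#'   `status` (factor/character with level `"osteoporosis"`).
#' @return data.frame `participant`, `time`, `event` (0/1); attribute
#'   `excluded` holds prevalent participant ids.
#' @export
makeSurvivalRecords <- function(statuses) {
    stopifnot(all(c("participant", "time_years", "status") %in%
                  colnames(statuses)))
    statuses <- statuses[order(statuses$participant, statuses$time_years), ]
    out <- lapply(split(statuses, statuses$participant), function(d) {
        if (nrow(d) == 0L) return(NULL)
        op <- d$status == "osteoporosis"
        if (op[1])                     # prevalent at first visit
            return(data.frame(participant = d$participant[1],
                              time = NA_real_, event = NA_integer_))
        t0 <- d$time_years[1]
        if (any(op)) {
            data.frame(participant = d$participant[1],
                       time = d$time_years[which(op)[1]] - t0, event = 1L)
        } else {
            data.frame(participant = d$participant[1],
                       time = d$time_years[nrow(d)] - t0, event = 0L)
        }
    })
    out <- do.call(rbind, out)
    excluded <- out$participant[is.na(out$event)]
    out <- out[!is.na(out$event) & out$time > 0, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "excluded") <- as.character(excluded)
    out
}

#' Cox proportional-hazards fit for a continuous exposure
#'
#' Maximizes the Cox partial likelihood with Efron handling of tied event
#' times (visit-grouped events are heavily tied) and returns the Wald
#' estimate for the exposure coefficient.
#'
#' @param records data.frame with `time` and `event`.
#' @param exposure numeric vector aligned with `records`.
#' @param covariates optional data.frame aligned with `records`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level Wald confidence level.
#' @return list of class `CoxResult`: `beta` (log-HR per exposure unit),
#'   `hr`, `se`, `ci` (on the HR scale), `p`, `n`, `n_events`, `ties`.
#' @export
fitCoxModel <- function(records, exposure, covariates = NULL,
                        ties = c("efron", "breslow"), conf_level = 0.95) {
    ties <- match.arg(ties)
    if (sum(records$event) < 1L) stop("no events in the records")
    if (length(unique(exposure)) < 2L)
        stop("exposure does not vary")
    dat <- data.frame(.time = records$time, .event = records$event,
                      .x = exposure)
    if (!is.null(covariates)) {
        stopifnot(nrow(covariates) == nrow(records))
        dat <- cbind(dat, .prepCovariates(covariates))
    }
    dat <- dat[complete.cases(dat), , drop = FALSE]
    fit <- survival::coxph(survival::Surv(.time, .event) ~ .,
                           data = dat, ties = ties)
    cf <- summary(fit)$coefficients
    beta <- cf[".x", "coef"]; se <- cf[".x", "se(coef)"]
    if (!is.finite(beta) || abs(beta) > 15)
        stop("monotone partial likelihood (perfect separation?)")
    zq <- qnorm(1 - (1 - conf_level) / 2)
    structure(list(beta = beta, hr = exp(beta), se = se,
                   ci = exp(c(beta - zq * se, beta + zq * se)),
                   p = 2 * pnorm(-abs(beta / se)),
                   n = nrow(dat), n_events = sum(dat$.event),
                   ties = ties),
              class = "CoxResult")
}

#' @export
print.CoxResult <- function(x, ...) {
    cat(sprintf("CoxResult: HR %.3f (%.3f-%.3f), p = %.3g, %d events/%d\n",
                x$hr, x$ci[1], x$ci[2], x$p, x$n_events, x$n))
    invisible(x)
}

#' Restricted cubic spline basis (natural spline, Harrell knots)
#'
#' Expands a continuous exposure into `n_knots - 1` columns (the linear
#' term plus `n_knots - 2` restricted cubic terms), linear beyond the
#' boundary knots with continuous first and second derivatives at every
#' knot. Default knot placement follows Harrell's quantiles: (0.10, 0.50,
#' 0.90) for 3 knots, (0.05, 0.35, 0.65, 0.95) for 4, (0.05, 0.275, 0.50,
#' 0.725, 0.95) for 5. Nonlinear terms are scaled by
#' `(t_K - t_1)^2` so all columns share the exposure's units.
#'
#' @param x numeric vector.
#' @param n_knots 3, 4 or 5.
#' @param knots optional explicit knot locations (overrides `n_knots`).
#' @return matrix `length(x)` x `(k - 1)` with attribute `knots`.
#' @export
rcsExpand <- function(x, n_knots = 4L, knots = NULL) {
    if (is.null(knots)) {
        if (!n_knots %in% 3:5) stop("n_knots must be 3, 4 or 5")
        probs <- switch(as.character(n_knots),
                        "3" = c(0.10, 0.50, 0.90),
                        "4" = c(0.05, 0.35, 0.65, 0.95),
                        "5" = c(0.05, 0.275, 0.50, 0.725, 0.95))
        knots <- quantile(x, probs, names = FALSE)
    }
    knots <- sort(knots)
    if (any(duplicated(knots)))
        stop("duplicate knots; supply distinct locations or fewer knots")
    k <- length(knots)
    tk <- knots[k]; tk1 <- knots[k - 1]
    scale2 <- (knots[k] - knots[1])^2
    cub <- function(u) pmax(u, 0)^3
    basis <- matrix(0, length(x), k - 1)
    basis[, 1] <- x
    for (j in seq_len(k - 2)) {
        tj <- knots[j]
        basis[, j + 1] <- (cub(x - tj) -
            cub(x - tk1) * (tk - tj) / (tk - tk1) +
            cub(x - tk) * (tk1 - tj) / (tk - tk1)) / scale2
    }
    colnames(basis) <- paste0("rcs", seq_len(k - 1))
    attr(basis, "knots") <- knots
    basis
}

#' Spline dose-response curve for osteoporosis hazard
#'
#' Fits a Cox model on the restricted cubic spline expansion of the
#' exposure (plus covariates) and evaluates the log hazard ratio relative
#' to a reference exposure value over a grid.
#'
#' @param records data.frame with `time`, `event`.
#' @param exposure numeric vector aligned with `records`.
#' @param covariates optional data.frame.
#' @param n_knots number of spline knots.
#' @param ref reference exposure (default: median).
#' @param grid evaluation grid (default: 100 points spanning the exposure).
#' @return data.frame `exposure`, `loghr`, `se`, `lo`, `hi`; attribute
#'   `fit` carries the coxph object.
#' @export
rcsDoseResponse <- function(records, exposure, covariates = NULL,
                            n_knots = 4L, ref = NULL, grid = NULL) {
    basis <- rcsExpand(exposure, n_knots)
    dat <- data.frame(.time = records$time, .event = records$event, basis)
    if (!is.null(covariates))
        dat <- cbind(dat, .prepCovariates(covariates))
    dat <- dat[complete.cases(dat), , drop = FALSE]
    fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = dat)
    if (is.null(ref)) ref <- median(exposure)
    if (is.null(grid))
        grid <- seq(min(exposure), max(exposure), length.out = 100L)
    kn <- attr(basis, "knots")
    bg <- rcsExpand(grid, knots = kn)
    br <- rcsExpand(ref, knots = kn)
    D <- sweep(bg, 2, as.vector(br))
    cf <- coef(fit)[colnames(basis)]
    V <- vcov(fit)[colnames(basis), colnames(basis)]
    loghr <- as.vector(D %*% cf)
    se <- sqrt(rowSums((D %*% V) * D))
    out <- data.frame(exposure = grid, loghr = loghr, se = se,
                      lo = loghr - 1.96 * se, hi = loghr + 1.96 * se)
    attr(out, "fit") <- fit
    out
}

#' Quartile hazard ratios and trend test
#'
#' Cox regression with indicator-coded exposure quartiles (Q1 reference)
#' plus a separate model entering the quartile rank as a single ordinal
#' covariate for the Wald p-trend.
#'
#' @param records data.frame with `time`, `event`.
#' @param quartiles factor Q1-Q4 aligned with `records` (see
#'   [prsQuartiles()]).
#' @param covariates optional data.frame.
#' @return list: `hr` (data.frame for Q2-Q4: HR, lo, hi, p), `p_trend`,
#'   `n_events`.
#' @export
quartileHr <- function(records, quartiles, covariates = NULL) {
    quartiles <- factor(quartiles)
    if (any(table(quartiles) == 0L)) stop("empty quartile")
    if (nlevels(quartiles) < 2L) stop("no variation across quartiles")
    ev <- tapply(records$event, quartiles, sum)
    if (sum(ev > 0) < 2L) stop("events present in fewer than 2 quartiles")
    dat <- data.frame(.time = records$time, .event = records$event,
                      .q = quartiles)
    if (!is.null(covariates))
        dat <- cbind(dat, .prepCovariates(covariates))
    dat <- dat[complete.cases(dat), , drop = FALSE]
    fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = dat)
    cf <- summary(fit)$coefficients
    qrows <- grep("^\\.q", rownames(cf))
    hr <- data.frame(quartile = sub("^\\.q", "", rownames(cf)[qrows]),
                     hr = exp(cf[qrows, "coef"]),
                     lo = exp(cf[qrows, "coef"] - 1.96 * cf[qrows, "se(coef)"]),
                     hi = exp(cf[qrows, "coef"] + 1.96 * cf[qrows, "se(coef)"]),
                     p = cf[qrows, "Pr(>|z|)"], row.names = NULL)
    dat$.q <- as.numeric(dat$.q)
    fit_tr <- survival::coxph(survival::Surv(.time, .event) ~ ., data = dat)
    cft <- summary(fit_tr)$coefficients
    list(hr = hr, p_trend = cft[".q", "Pr(>|z|)"],
         n_events = sum(dat$.event))
}

#' Visit-level osteoporosis statuses for a cohort
#'
#' Applies [tscoreClassify()] to the stored BMD of a [ProteoCohort-class]
#' at one site, using the cohort's T-score reference values.
#'
#' @param cohort a [ProteoCohort-class].
#' @param site `"ls"` or `"fn"`.
#' @return data.frame `participant`, `visit`, `time_years`, `bmd`,
#'   `tscore`, `status`.
#' @export
cohortStatuses <- function(cohort, site = c("ls", "fn")) {
    site <- match.arg(site)
    cd <- cohortData(cohort)
    md <- S4Vectors::metadata(cohort)
    ts <- tscoreClassify(cd[[paste0("bmd_", site)]],
                         md$tscore_ref_mean[[site]],
                         md$tscore_ref_sd[[site]])
    data.frame(participant = cd$participant, visit = cd$visit,
               time_years = cd$time_years, bmd = ts$bmd,
               tscore = ts$tscore, status = ts$status,
               stringsAsFactors = FALSE)
}
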