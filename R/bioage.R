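#' Select age-coupled proteins with redundancy removal
#'
#' Keeps proteins whose absolute Pearson correlation with chronological age
#' is at least `min_abs_r` with BH q < 0.05, then greedily removes the
#' weaker member of any pair correlated beyond `max_pairwise_r` (the
#' stronger CA-correlate survives). Deterministic: candidates are processed
#' in decreasing |r| order with ties broken by column order.
#'
#' @param z numeric matrix (samples x proteins), standardized.
#' @param ca chronological age (years), aligned with rows of `z`.
#' @param max_pairwise_r redundancy threshold on |pairwise r|.
#' @param min_abs_r minimum |correlation| with CA.
#' @return character vector of retained protein names, with attribute `r`
#'   (their CA correlations).
#' @export
selectAgeProteins <- function(z, ca, max_pairwise_r = 0.7,
                              min_abs_r = 0.1) {
    r <- as.vector(cor(z, ca))
    n <- nrow(z)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    p <- 2 * pt(-abs(tstat), n - 2)
    q <- bhAdjust(p)
    cand <- which(abs(r) >= min_abs_r & q < 0.05)
    if (!length(cand))
        stop("no protein passes the age-correlation screen; ",
             "lower min_abs_r or check standardization")
    cand <- cand[order(-abs(r[cand]), cand)]
    kept <- integer(0)
    for (j in cand) {
        if (!length(kept) ||
            all(abs(cor(z[, j], z[, kept, drop = FALSE])) <= max_pairwise_r))
            kept <- c(kept, j)
    }
    out <- colnames(z)[kept]
    attr(out, "r") <- setNames(r[kept], out)
    out
}

#' Fit a Klemera-Doubal biological-age model
#'
#' Step 1 regresses every protein on chronological age (OLS), storing the
#' intercept q_j, slope k_j, residual SD s_j and age correlation r_j; each
#' protein then yields an age estimate `(x_j - q_j)/k_j` in years. Step 2
#' aggregates them with precision weights `(k_j/s_j)^2` into the
#' uncorrected estimate
#' `BA_E = sum_j (x_j - q_j) k_j / s_j^2 / sum_j k_j^2 / s_j^2`.
#' The chronological-age weight for the corrected estimator comes from
#' `s_BA^2 = Var(BA_E - CA) - ((1 - r_char^2)/r_char^2) *`
#' `(CA_max - CA_min)^2 / (12 m)`, with the characteristic correlation
#' `r_char` the `(k_j^2/s_j^2)`-weighted mean of |r_j|. A non-positive
#' correction falls back to `Var(BA_E - CA)` (floored), which keeps the
#' corrected estimator defined for weakly age-correlated panels.
#'
#' @param x numeric matrix (samples x proteins) restricted to the selected
#'   proteins; raw or standardized abundances both work.
#' @param ca chronological age (years).
#' @param s_floor lower bound on residual SDs (keeps weights finite in
#'   noise-free degenerate cases).
#' @return a [KdmModel-class].
#' @export
fitKdm <- function(x, ca, s_floor = 1e-6) {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
    if (var(ca) <= 0) stop("chronological age must vary")
    n <- nrow(x)
    fits <- lapply(seq_len(ncol(x)), function(j) {
        f <- lm(x[, j] ~ ca)
        s <- sqrt(sum(residuals(f)^2) / max(n - 2, 1))
        c(q = unname(coef(f)[1]), k = unname(coef(f)[2]),
          s = max(s, s_floor),
          r = suppressWarnings(cor(x[, j], ca)))
    })
    pr <- as.data.frame(do.call(rbind, fits))
    pr$protein <- colnames(x)
    drop <- abs(pr$k) < 1e-12
    if (any(drop)) {
        warning("dropping protein(s) with zero age slope: ",
                paste(pr$protein[drop], collapse = ", "))
        pr <- pr[!drop, , drop = FALSE]
        x <- x[, !drop, drop = FALSE]
    }
    if (!nrow(pr)) stop("no protein retains a nonzero age slope")
    m <- nrow(pr)

    ba_e <- .kdmBaE(x, pr)
    wj <- pr$k^2 / pr$s^2
    r_char <- sum(wj * abs(pr$r)) / sum(wj)
    ca_range <- range(ca)
    var_diff <- var(ba_e - ca)
    corr_term <- ((1 - r_char^2) / r_char^2) *
        (diff(ca_range)^2 / (12 * m))
    s_ba2 <- var_diff - corr_term
    floored <- FALSE
    if (!is.finite(s_ba2) || s_ba2 <= 0) {
        s_ba2 <- var_diff
        floored <- TRUE
    }
    if (s_ba2 <= 1e-8) {      # noise-free degenerate panel
        s_ba2 <- 1e-4
        floored <- TRUE
    }
    new("KdmModel",
        proteins = pr[, c("protein", "q", "k", "s", "r")],
        sBA = sqrt(s_ba2), rChar = r_char, caRange = ca_range,
        sBAFloored = floored)
}

.kdmBaE <- function(x, pr) {
    num <- sweep(x, 2, pr$q, `-`) %*% (pr$k / pr$s^2)
    as.vector(num) / sum(pr$k^2 / pr$s^2)
}

#' Predict biological age and age acceleration
#'
#' Computes the uncorrected estimate BA_E, the CA-corrected biological age
#' `BA_EC = (sum_j (x_j - q_j) k_j/s_j^2 + CA/s_BA^2) /`
#' `(sum_j k_j^2/s_j^2 + 1/s_BA^2)` — a precision-weighted compromise
#' between the proteomic estimate and chronological age — and the age
#' acceleration, defined as the residual from the OLS regression of BA_EC
#' on CA over the scoring set (sample mean 0 by construction).
#'
#' @param model a [KdmModel-class].
#' @param x numeric matrix (samples x proteins) containing every model
#'   protein, on the scale used at fit time.
#' @param ca chronological age (years).
#' @param s_ba optional override of the model's s_BA (used for limit
#'   checks).
#' @return data.frame: `sample`, `ca`, `ba_e`, `ba_ec`, `accel`,
#'   `accel_z`.
#' @export
predictBioage <- function(model, x, ca, s_ba = NULL) {
    x <- as.matrix(x)
    pr <- model@proteins
    miss <- setdiff(pr$protein, colnames(x))
    if (length(miss))
        stop("model protein(s) missing from the matrix: ",
             paste(miss, collapse = ", "))
    x <- x[, pr$protein, drop = FALSE]
    if (is.null(s_ba)) s_ba <- model@sBA
    ba_e <- .kdmBaE(x, pr)
    wsum <- sum(pr$k^2 / pr$s^2)
    num <- as.vector(sweep(x, 2, pr$q, `-`) %*% (pr$k / pr$s^2))
    ba_ec <- (num + ca / s_ba^2) / (wsum + 1 / s_ba^2)
    acc_fit <- lm(ba_ec ~ ca)
    accel <- as.vector(residuals(acc_fit))
    accel_z <- if (sd(accel) > 0) as.vector(scale(accel)) else accel
    data.frame(sample = if (is.null(rownames(x)))
                   seq_len(nrow(x)) else rownames(x),
               ca = ca, ba_e = ba_e, ba_ec = ba_ec,
               accel = accel, accel_z = accel_z,
               stringsAsFactors = FALSE)
}

#' Cox models of osteoporosis on proteomic biological age
#'
#' Standardizes the chosen biological-age measure (corrected biological age
#' or its acceleration) and delegates to [fitCoxModel()] for each covariate
#' tier.
#'
#' @param bioage data.frame from [predictBioage()] with a `participant`
#'   column (or `sample` holding participant ids).
#' @param records survival records from [makeSurvivalRecords()].
#' @param covariate_data data.frame of baseline covariates keyed by
#'   `participant`.
#' @param measure `"ba_ec"` (KDM biological age) or `"accel"`.
#' @param tiers named list of covariate column sets (see
#'   [covariateTiers()]).
#' @return named list of `CoxResult`, one per tier.
#' @export
bioageSurvival <- function(bioage, records, covariate_data,
                           measure = c("ba_ec", "accel"),
                           tiers = covariateTiers()) {
    measure <- match.arg(measure)
    key <- if ("participant" %in% colnames(bioage)) "participant" else
        "sample"
    dat <- merge(records, bioage, by.x = "participant", by.y = key)
    dat <- merge(dat, covariate_data, by = "participant")
    expo <- as.vector(scale(dat[[measure]]))
    lapply(tiers, function(cv) {
        fitCoxModel(dat, expo, dat[, cv, drop = FALSE])
    })
}
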