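#' Build a protein risk score from meta-analysis weights
#'
#' PRS_i = sum_j w_j * z_ij over the flagged proteins, with weights taken
#' from pooled association betas and sign-flipped to a risk scale (positive
#' weight = BMD-lowering), so hazard ratios above 1 are expected for higher
#' scores. The raw score is then z-standardized over the scoring set.
#'
#' @param weights named numeric vector of pooled betas (protein effect on
#'   BMD, SD/SD) or a data.frame with columns `protein` and `beta_pooled`.
#' @param z numeric matrix of standardized abundances (samples x proteins).
#' @param orient if `TRUE` (default) weights are negated so that a positive
#'   score means higher risk (lower BMD).
#' @return data.frame with `sample`, `raw` and `score` (standardized);
#'   attribute `weights` holds the oriented weights used.
#' @export
buildPrs <- function(weights, z, orient = TRUE) {
    if (is.data.frame(weights))
        weights <- setNames(weights$beta_pooled, weights$protein)
    if (!length(weights) || all(weights == 0))
        stop("degenerate score: no nonzero weights")
    miss <- setdiff(names(weights), colnames(z))
    if (length(miss))
        stop("weighted protein(s) absent from the matrix: ",
             paste(miss, collapse = ", "))
    w <- if (orient) -weights else weights
    raw <- as.vector(z[, names(w), drop = FALSE] %*% w)
    out <- data.frame(sample = if (is.null(rownames(z)))
                          as.character(seq_len(nrow(z))) else rownames(z),
                      raw = raw,
                      score = as.vector(scale(raw)),
                      stringsAsFactors = FALSE)
    attr(out, "weights") <- w
    out
}

#' Quartile labels for a risk score
#'
#' Cuts at the 25/50/75 sample percentiles (type-7 quantiles); values at or
#' below a cutpoint fall in the lower quartile. A constant score vector is
#' degenerate: all observations land in Q1 and the `degenerate` attribute
#' is set.
#'
#' @param scores numeric vector, length >= 4.
#' @return factor with levels Q1-Q4 (attribute `degenerate` flags ties
#'   collapsing the cutpoints).
#' @export
prsQuartiles <- function(scores) {
    if (length(scores) < 4L) stop("need at least 4 scores")
    cuts <- quantile(scores, c(0.25, 0.5, 0.75), names = FALSE)
    degenerate <- any(duplicated(cuts))
    q <- factor(paste0("Q", findInterval(scores, cuts, left.open = TRUE) + 1L),
                levels = paste0("Q", 1:4))
    attr(q, "degenerate") <- degenerate
    q
}

#' Cross-sectional generalized linear model for a risk score
#'
#' Covariate-adjusted linear (BMD outcome) or logistic (osteoporosis
#' outcome) regression of the outcome on a standardized score, with Wald
#' confidence interval. Logistic fits showing signs of separation
#' (|coefficient| > 10 on the SD scale) are flagged.
#'
#' @param outcome numeric (linear) or 0/1 (logistic) vector.
#' @param score numeric exposure (per-SD scale recommended).
#' @param covariates optional data.frame aligned with `outcome`.
#' @param family `"linear"` or `"logistic"`.
#' @param conf_level confidence level for the Wald interval.
#' @return list: `beta` (log-odds for logistic), `or` (odds ratio, logistic
#'   only), `se`, `ci` (on the beta scale), `p`, `n`, `separation_flag`.
#' @export
fitGlmCross <- function(outcome, score, covariates = NULL,
                        family = c("linear", "logistic"),
                        conf_level = 0.95) {
    family <- match.arg(family)
    dat <- data.frame(.y = outcome, .score = score)
    if (!is.null(covariates)) {
        stopifnot(nrow(covariates) == length(outcome))
        dat <- cbind(dat, .prepCovariates(covariates))
    }
    dat <- dat[complete.cases(dat), , drop = FALSE]
    if (family == "logistic" && !all(dat$.y %in% c(0, 1)))
        stop("logistic family requires a 0/1 outcome")
    fam <- if (family == "linear") gaussian() else binomial()
    fit <- glm(.y ~ ., data = dat, family = fam)
    cf <- summary(fit)$coefficients
    beta <- cf[".score", 1]; se <- cf[".score", 2]
    zq <- qnorm(1 - (1 - conf_level) / 2)
    sep <- family == "logistic" && (abs(beta) > 10 || !fit$converged)
    list(beta = beta,
         or = if (family == "logistic") exp(beta) else NA_real_,
         se = se, ci = c(beta - zq * se, beta + zq * se),
         p = 2 * pnorm(-abs(beta / se)), n = nrow(dat),
         separation_flag = sep)
}
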