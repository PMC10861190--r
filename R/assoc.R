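#' Random-intercept mixed-model association of a protein with BMD
#'
#' Fits, by REML, the linear mixed model
#' `bmd_it = beta * protein_i + gamma' covariates_i + u_i + e_it`
#' with a per-participant random intercept, where the exposure is the
#' baseline (standardized) protein value and the outcome the standardized
#' BMD at the follow-up visits. Returns the Wald estimate for the protein
#' coefficient.
#'
#' @param bmd numeric outcome vector (standardized BMD), one entry per
#'   person-visit row.
#' @param protein numeric exposure vector aligned with `bmd` (baseline
#'   value repeated across a participant's rows).
#' @param participant participant identifier aligned with `bmd`.
#' @param covariates optional data.frame of baseline covariates aligned
#'   with `bmd`; rows with missing values are dropped (complete-case).
#' @return list of class `AssocEstimate`: `beta` (BMD-SD per protein-SD),
#'   `se`, `p` (two-sided Wald, normal reference), `n_obs`,
#'   `n_participants`.
#' @export
fitLmm <- function(bmd, protein, participant, covariates = NULL) {
    dat <- data.frame(.bmd = bmd, .protein = protein,
                      .id = as.factor(participant))
    if (!is.null(covariates)) {
        stopifnot(nrow(covariates) == length(bmd))
        dat <- cbind(dat, .prepCovariates(covariates))
    }
    dat <- dat[complete.cases(dat), , drop = FALSE]
    if (length(unique(dat$.id)) < 2L)
        stop("need >= 2 participants with observed BMD")
    rhs <- c(".protein", setdiff(colnames(dat), c(".bmd", ".protein", ".id")))
    X <- stats::model.matrix(
        stats::reformulate(rhs), dat)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
        stop("singular covariate design; collinear column(s): ",
             paste(bad, collapse = ", "))
    }
    fml <- stats::reformulate(c(rhs, "(1 | .id)"), response = ".bmd")
    fit <- withCallingHandlers(
        lme4::lmer(fml, data = dat, REML = TRUE,
                   control = lme4::lmerControl(
                       check.conv.singular = "ignore",
                       check.nobs.vs.nlev = "ignore",
                       check.nobs.vs.nRE = "ignore",
                       calc.derivs = FALSE)),
        message = function(m) invokeRestart("muffleMessage"),
        warning = function(w) {
            if (grepl("singular|converge", conditionMessage(w),
                      ignore.case = TRUE))
                invokeRestart("muffleWarning")
        })
    beta <- lme4::fixef(fit)[[".protein"]]
    se <- tryCatch({
        V <- suppressWarnings(as.matrix(vcov(fit)))
        sqrt(V[".protein", ".protein"])
    }, error = function(e) NA_real_)
    if (!is.finite(se)) {
        # degenerate fit (e.g. exactly linear, zero-residual data): fall
        # back to the fixed-effects OLS standard error
        ols <- lm(.bmd ~ X - 1, data = dat)
        se <- max(suppressWarnings(
            summary(ols)$coefficients["X.protein", 2]), 1e-12)
    }
    structure(list(beta = beta, se = se,
                   p = 2 * pnorm(-abs(beta / se)),
                   n_obs = nrow(dat),
                   n_participants = length(unique(dat$.id))),
              class = "AssocEstimate")
}

#' Per-cohort protein-BMD association scan
#'
#' Runs [fitLmm()] for every protein: exposure = baseline standardized
#' protein, outcome = standardized follow-up BMD at the requested site,
#' within one cohort batch.
#'
#' @param cohort a standardized, imputed [ProteoCohort-class].
#' @param site `"ls"` or `"fn"`.
#' @param batch `"discovery"` or `"validation"` (or `NULL` for all).
#' @param covariates character vector of colData covariate columns to
#'   adjust for (baseline values); `NULL` for unadjusted.
#' @param proteins character vector of proteins to scan (default all).
#' @return data.frame, one row per protein: `protein`, `site`, `cohort`,
#'   `beta`, `se`, `p`, `n_obs`, `n_participants`.
#' @export
runAssociation <- function(cohort, site = c("ls", "fn"), batch = NULL,
                           covariates = covariateTiers()$model1,
                           proteins = NULL) {
    site <- match.arg(site)
    cd <- cohortData(cohort)
    z <- proteinMatrix(cohort)
    if (is.null(proteins)) proteins <- colnames(z)
    keep <- if (is.null(batch)) rep(TRUE, nrow(cd)) else cd$batch == batch
    cdk <- cd[keep, , drop = FALSE]
    zk <- z[keep, , drop = FALSE]

    base_visit <- min(cdk$visit)
    is_base <- cdk$visit == base_visit
    base_idx <- match(cdk$participant, cdk$participant[is_base])
    bmd_col <- paste0("bmd_", site)
    bmd_z <- as.vector(scale(cdk[[bmd_col]]))

    covdf <- NULL
    if (length(covariates))
        covdf <- cdk[which(is_base)[base_idx], covariates, drop = FALSE]
    fu <- !is_base   # outcome = follow-up BMD visits
    res <- lapply(proteins, function(pr) {
        expo <- zk[which(is_base)[base_idx], pr]
        est <- fitLmm(bmd_z[fu], expo[fu], cdk$participant[fu],
                      if (is.null(covdf)) NULL else
                          covdf[fu, , drop = FALSE])
        data.frame(protein = pr, site = site,
                   cohort = if (is.null(batch)) "all" else batch,
                   beta = est$beta, se = est$se, p = est$p,
                   n_obs = est$n_obs, n_participants = est$n_participants,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Covariate adjustment tiers
#'
#' Tiered covariate sets mirroring the usual epidemiological build-up:
#' model1 = age + sex; model2 adds anthropometry, lifestyle, diet and
#' supplement use; model3 adds clinical biochemistry and blood pressure.
#'
#' @return named list of character vectors of colData column names.
#' @export
covariateTiers <- function() {
    m1 <- c("age", "sex")
    m2 <- c(m1, "bmi", "whr", "smoking", "alcohol", "tea",
            "physical_activity", "energy", "carbohydrate", "fiber",
            "calcium_supp", "multivit")
    m3 <- c(m2, "sbp", "dbp", "glucose", "tc", "tg", "ldl", "hdl",
            "uric_acid")
    list(model1 = m1, model2 = m2, model3 = m3)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools k >= 2 independent estimates: fixed-effect weights `w_i = 1/se_i^2`
#' give `beta_fixed` and Cochran's `Q = sum w_i (beta_i - beta_fixed)^2`;
#' the between-study variance is
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random-effects
#' weights `1/(se_i^2 + tau2)` give the pooled estimate and its SE;
#' `I2 = max(0, (Q - (k-1))/Q) * 100`. Two-sided normal p-value.
#'
#' @param beta,se numeric vectors of per-study estimates and standard
#'   errors (all `se > 0`).
#' @return list: `beta_pooled`, `se_pooled`, `p`, `Q`, `df`, `tau2`, `I2`,
#'   `beta_fixed`, `k`.
#' @export
metaRandomEffects <- function(beta, se) {
    k <- length(beta)
    if (k < 2L) stop("need at least 2 estimates to pool")
    if (length(se) != k || any(se <= 0)) stop("all SEs must be > 0")
    w <- 1 / se^2
    beta_fixed <- sum(w * beta) / sum(w)
    Q <- sum(w * (beta - beta_fixed)^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (se^2 + tau2)
    beta_pooled <- sum(ws * beta) / sum(ws)
    se_pooled <- sqrt(1 / sum(ws))
    I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
    list(beta_pooled = beta_pooled, se_pooled = se_pooled,
         p = 2 * pnorm(-abs(beta_pooled / se_pooled)),
         Q = Q, df = k - 1L, tau2 = tau2, I2 = I2,
         beta_fixed = beta_fixed, k = k)
}

#' Meta-analyze per-cohort association scans
#'
#' Pools discovery and validation estimates per protein with
#' [metaRandomEffects()], attaches Benjamini-Hochberg q-values within the
#' site family, and applies the significance flag.
#'
#' @param estimates data.frame from [runAssociation()] stacked over
#'   cohorts (one site).
#' @return data.frame, one row per protein: pooled beta/se/p, Q, tau2, I2,
#'   `q` and `flagged`.
#' @export
metaAnalyze <- function(estimates) {
    stopifnot(length(unique(estimates$site)) == 1L)
    out <- lapply(split(estimates, estimates$protein), function(d) {
        m <- metaRandomEffects(d$beta, d$se)
        data.frame(protein = d$protein[1], site = d$site[1],
                   beta_pooled = m$beta_pooled, se_pooled = m$se_pooled,
                   p = m$p, Q = m$Q, tau2 = m$tau2, I2 = m$I2,
                   k = m$k, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out <- out[match(unique(estimates$protein), out$protein), ]
    out$q <- bhAdjust(out$p)
    flagSignificant(out)
}

#' Flag significant pooled associations
#'
#' A pooled estimate is flagged when p < 0.05 and I-squared < 30%
#' (strict inequalities). BH q-values are reported alongside but do not
#' enter the flag.
#'
#' @param meta data.frame with columns `p` and `I2`.
#' @return the input with a logical `flagged` column.
#' @export
flagSignificant <- function(meta) {
    meta$flagged <- meta$p < 0.05 & meta$I2 < 30
    meta
}
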