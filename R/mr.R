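#' Genome-wide-significance instrument filter
#'
#' Keeps SNPs whose exposure association reaches p <= 5e-8 (boundary
#' included).
#'
#' @param instruments data.frame with a `p_x` column.
#' @param p_threshold significance threshold.
#' @return the filtered data.frame; attribute `n_dropped` records the
#'   count removed.
#' @export
filterInstruments <- function(instruments, p_threshold = 5e-8) {
    if (!"p_x" %in% colnames(instruments))
        stop("instruments need a p_x column")
    keep <- instruments$p_x <= p_threshold
    if (!any(keep))
        stop("no instrument passes p <= ", format(p_threshold))
    out <- instruments[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_dropped") <- sum(!keep)
    out
}

.palindromic <- function(a1, a2) {
    (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
        (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure effect allele: matching alleles
#' pass through, swapped alleles flip the outcome effect sign (and reflect
#' the outcome EAF), incompatible allele pairs are dropped, and
#' strand-ambiguous (palindromic) SNPs are dropped when the exposure EAF
#' lies in (0.42, 0.58) or is unknown (otherwise EAF concordance decides
#' the alignment). Harmonizing an already harmonized set is a no-op.
#'
#' @param exposure data.frame: `snp`, `effect_allele`, `other_allele`,
#'   `beta` , `se`, `pval` and optional `eaf` (columns may equally be named
#'   `beta_x`/`se_x`/`p_x`).
#' @param outcome data.frame with the same scheme for the outcome GWAS.
#' @param eaf_window palindromic ambiguity window around 0.5.
#' @return data.frame `snp`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta_x`, `se_x`, `p_x`, `beta_y`, `se_y`, with attribute `log`
#'   (per-SNP action taken).
#' @export
harmonizeInstruments <- function(exposure, outcome,
                                 eaf_window = c(0.42, 0.58)) {
    ex <- .mrNormalize(exposure, "x")
    oy <- .mrNormalize(outcome, "y")
    shared <- intersect(ex$snp, oy$snp)
    if (!length(shared)) stop("no shared SNPs between exposure and outcome")
    ex <- ex[match(shared, ex$snp), ]
    oy <- oy[match(shared, oy$snp), ]

    action <- character(length(shared))
    beta_y <- oy$beta_y
    keep <- rep(TRUE, length(shared))
    same <- ex$effect_allele == oy$effect_allele &
        ex$other_allele == oy$other_allele
    swapped <- ex$effect_allele == oy$other_allele &
        ex$other_allele == oy$effect_allele
    pal <- .palindromic(ex$effect_allele, ex$other_allele)

    action[same] <- "kept"
    beta_y[swapped] <- -beta_y[swapped]
    action[swapped] <- "flipped"
    bad <- !same & !swapped
    keep[bad] <- FALSE
    action[bad] <- "dropped_incompatible"

    amb <- pal & (is.na(ex$eaf) | (ex$eaf > eaf_window[1] &
                                   ex$eaf < eaf_window[2]))
    keep[amb] <- FALSE
    action[amb] <- "dropped_palindromic"
    # unambiguous palindromic SNPs: EAF discordance implies strand flip,
    # which for palindromic alleles is equivalent to an effect-allele swap
    fix <- pal & !amb & keep & !is.na(oy$eaf) &
        ((ex$eaf > 0.5) != (oy$eaf > 0.5))
    beta_y[fix] <- -beta_y[fix]
    action[fix] <- "flipped_palindromic_eaf"

    out <- data.frame(snp = shared,
                      effect_allele = ex$effect_allele,
                      other_allele = ex$other_allele,
                      eaf = ex$eaf,
                      beta_x = ex$beta_x, se_x = ex$se_x, p_x = ex$p_x,
                      beta_y = beta_y, se_y = oy$se_y,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
    if (!nrow(out)) stop("no SNP survived harmonization")
    rownames(out) <- NULL
    attr(out, "log") <- data.frame(snp = shared, action = action,
                                   stringsAsFactors = FALSE)
    out
}

.mrNormalize <- function(d, which) {
    d <- as.data.frame(d)
    pick <- function(cands) {
        hit <- cands[cands %in% colnames(d)]
        if (!length(hit)) NULL else d[[hit[1]]]
    }
    sfx <- paste0("_", which)
    out <- data.frame(
        snp = d$snp,
        effect_allele = toupper(pick(c("effect_allele", "ea"))),
        other_allele = toupper(pick(c("other_allele", "oa"))),
        stringsAsFactors = FALSE)
    eaf <- pick(c("eaf", paste0("eaf", sfx)))
    out$eaf <- if (is.null(eaf)) NA_real_ else eaf
    out[[paste0("beta", sfx)]] <- pick(c("beta", paste0("beta", sfx)))
    out[[paste0("se", sfx)]] <- pick(c("se", paste0("se", sfx)))
    pv <- pick(c("pval", "p", paste0("p", sfx)))
    out[[paste0("p", sfx)]] <- if (is.null(pv)) NA_real_ else pv
    bad <- !out$effect_allele %in% c("A", "C", "G", "T") |
        !out$other_allele %in% c("A", "C", "G", "T")
    if (any(bad)) stop("non-ACGT allele codes in row(s): ",
                       paste(which(bad), collapse = ", "))
    out
}

.mrEstimate <- function(method, beta, se, n_snps, p = NULL) {
    if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
    data.frame(method = method, beta = beta, se = se, p = p,
               n_snps = n_snps, stringsAsFactors = FALSE)
}

#' Wald ratio for a single instrument
#'
#' beta = beta_y / beta_x with first-order standard error se_y / |beta_x|.
#'
#' @param beta_x,se_x exposure effect and SE.
#' @param beta_y,se_y outcome effect and SE.
#' @return one-row data.frame (`method`, `beta`, `se`, `p`, `n_snps`).
#' @export
waldRatio <- function(beta_x, se_x, beta_y, se_y) {
    if (beta_x == 0) stop("beta_x must be nonzero for a Wald ratio")
    .mrEstimate("wald", beta_y / beta_x, se_y / abs(beta_x), 1L)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of outcome on exposure effects through the origin
#' with weights 1/se_y^2:
#' `beta = sum(b_x b_y / se_y^2) / sum(b_x^2 / se_y^2)`, fixed-effect
#' `se = (sum b_x^2/se_y^2)^{-1/2}`, inflated multiplicatively by the
#' residual overdispersion when it exceeds 1.
#'
#' @param instruments harmonized data.frame (`beta_x`, `beta_y`, `se_y`),
#'   >= 2 SNPs.
#' @return one-row data.frame; extra columns `overdispersion` and
#'   `random_effects` record whether inflation applied.
#' @export
mrIvw <- function(instruments) {
    k <- nrow(instruments)
    if (k < 2L) stop("IVW needs >= 2 SNPs; use waldRatio for one")
    bx <- instruments$beta_x; by <- instruments$beta_y
    w <- 1 / instruments$se_y^2
    beta <- sum(w * bx * by) / sum(w * bx^2)
    se_fixed <- sqrt(1 / sum(w * bx^2))
    phi <- sum(w * (by - beta * bx)^2) / (k - 1)
    se <- se_fixed * sqrt(max(1, phi))
    out <- .mrEstimate("ivw", beta, se, k)
    out$overdispersion <- phi
    out$random_effects <- phi > 1
    out
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with an intercept
#' (weights 1/se_y^2). The slope is the causal estimate; the intercept
#' tests directional pleiotropy. Standard errors use multiplicative
#' overdispersion scaling floored at 1.
#'
#' @param instruments harmonized data.frame, >= 3 SNPs with spread in
#'   `beta_x`.
#' @return two-row data.frame (`egger_slope`, `egger_intercept`).
#' @export
mrEgger <- function(instruments) {
    k <- nrow(instruments)
    if (k < 3L) stop("MR-Egger needs >= 3 SNPs")
    bx <- instruments$beta_x; by <- instruments$beta_y
    if (sd(bx) == 0) stop("no spread in exposure effects (no leverage)")
    w <- 1 / instruments$se_y^2
    X <- cbind(1, bx)
    XtWX <- crossprod(X, X * w)
    cf <- solve(XtWX, crossprod(X, by * w))
    res <- by - X %*% cf
    phi <- sum(w * res^2) / (k - 2)
    V <- solve(XtWX) * max(1, phi)
    rbind(.mrEstimate("egger_slope", cf[2], sqrt(V[2, 2]), k),
          .mrEstimate("egger_intercept", cf[1], sqrt(V[1, 1]), k))
}

.waldRatios <- function(instruments) {
    r <- instruments$beta_y / instruments$beta_x
    se <- instruments$se_y / abs(instruments$beta_x)
    list(ratio = r, se = se, w = 1 / se^2)
}

#' Weighted-median MR estimate
#'
#' Orders per-SNP Wald ratios and takes the value at cumulative inverse-
#' variance weight 0.5 (linear interpolation between bracketing ratios);
#' consistent when at least half the weight comes from valid instruments.
#' The standard error comes from a seeded parametric bootstrap.
#'
#' @param instruments harmonized data.frame, >= 3 SNPs.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return one-row data.frame.
#' @export
mrWeightedMedian <- function(instruments, n_boot = 1000L, seed = 1L) {
    k <- nrow(instruments)
    if (k < 3L) stop("weighted median needs >= 3 SNPs")
    est <- .weightedMedianPoint(instruments)
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(b) {
        d <- instruments
        d$beta_x <- rnorm(k, instruments$beta_x, instruments$se_x)
        d$beta_y <- rnorm(k, instruments$beta_y, instruments$se_y)
        .weightedMedianPoint(d)
    }, numeric(1))
    .mrEstimate("weighted_median", est, sd(boot), k)
}

.weightedMedianPoint <- function(instruments) {
    wr <- .waldRatios(instruments)
    ord <- order(wr$ratio)
    r <- wr$ratio[ord]
    w <- wr$w[ord] / sum(wr$w)
    s <- cumsum(w) - w / 2
    if (!any(s < 0.5)) return(r[1])
    below <- max(which(s < 0.5))
    if (below == length(r)) return(r[length(r)])
    r[below] + (r[below + 1] - r[below]) *
        (0.5 - s[below]) / (s[below + 1] - s[below])
}

#' Mode-based MR estimates
#'
#' Kernel-smoothed density of the per-SNP Wald ratios (Gaussian kernel,
#' modified Silverman bandwidth `0.9 min(sd, mad) n^{-1/5}` times
#' `bandwidth_factor`); the estimate is the density argmax. The weighted
#' variant weights each ratio by its inverse variance. Standard errors by
#' seeded parametric bootstrap.
#'
#' @param instruments harmonized data.frame, >= 3 SNPs.
#' @param mode `"simple"` or `"weighted"`.
#' @param bandwidth_factor multiplier on the Silverman bandwidth.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return one-row data.frame.
#' @export
mrMode <- function(instruments, mode = c("simple", "weighted"),
                   bandwidth_factor = 1, n_boot = 1000L, seed = 1L) {
    mode <- match.arg(mode)
    k <- nrow(instruments)
    if (k < 3L) stop("mode estimators need >= 3 SNPs")
    est <- .modePoint(instruments, mode, bandwidth_factor)
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(b) {
        d <- instruments
        d$beta_x <- rnorm(k, instruments$beta_x, instruments$se_x)
        d$beta_y <- rnorm(k, instruments$beta_y, instruments$se_y)
        .modePoint(d, mode, bandwidth_factor)
    }, numeric(1))
    .mrEstimate(paste0(mode, "_mode"), est, sd(boot), k)
}

.modePoint <- function(instruments, mode, bandwidth_factor) {
    wr <- .waldRatios(instruments)
    r <- wr$ratio
    if (length(unique(r)) == 1L) return(r[1])
    w <- if (mode == "weighted") wr$w / sum(wr$w) else
        rep(1 / length(r), length(r))
    h <- bandwidth_factor * 0.9 *
        min(sd(r), mad(r)) * length(r)^(-1 / 5)
    if (h <= 0) h <- bandwidth_factor * 0.9 * sd(r) * length(r)^(-1 / 5)
    d <- density(r, weights = w, bw = h, n = 1024)
    d$x[which.max(d$y)]
}

#' Run the full MR estimator panel
#'
#' Wald ratio when a single SNP is supplied; otherwise IVW, MR-Egger
#' (slope + intercept), weighted median and both mode estimators.
#'
#' @param instruments harmonized data.frame.
#' @param seed integer seed for the bootstrap-based estimators.
#' @param n_boot bootstrap replicates.
#' @return data.frame, one row per estimate.
#' @export
mrAll <- function(instruments, seed = 1L, n_boot = 1000L) {
    if (nrow(instruments) == 1L)
        return(waldRatio(instruments$beta_x, instruments$se_x,
                         instruments$beta_y, instruments$se_y))
    out <- mrIvw(instruments)[, c("method", "beta", "se", "p", "n_snps")]
    if (nrow(instruments) >= 3L) {
        out <- rbind(out, mrEgger(instruments),
                     mrWeightedMedian(instruments, n_boot, seed),
                     mrMode(instruments, "simple", 1, n_boot, seed),
                     mrMode(instruments, "weighted", 1, n_boot, seed))
    }
    rownames(out) <- NULL
    out
}
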