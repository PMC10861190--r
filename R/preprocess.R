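#' Half-minimum imputation of left-censored protein values
#'
#' Replaces every missing value of protein j by half of the lowest observed
#' value of that protein across all analysed samples (visits pooled),
#' the standard substitution for below-detection-limit abundances.
#'
#' @param x a [ProteoCohort-class] or a numeric matrix (samples x proteins).
#' @return same class as `x`, with no missing abundances.
#' @export
setGeneric("imputeHalfMin", function(x) standardGeneric("imputeHalfMin"))

#' @rdname imputeHalfMin
#' @export
setMethod("imputeHalfMin", "matrix", function(x) {
    all_missing <- colSums(!is.na(x)) == 0
    if (any(all_missing))
        stop("protein column(s) fully missing: ",
             paste(colnames(x)[all_missing], collapse = ", "))
    halfmin <- apply(x, 2, function(col) min(col, na.rm = TRUE) / 2)
    idx <- which(is.na(x), arr.ind = TRUE)
    if (nrow(idx)) x[idx] <- halfmin[idx[, 2]]
    x
})

#' @rdname imputeHalfMin
#' @export
setMethod("imputeHalfMin", "ProteoCohort", function(x) {
    filled <- t(imputeHalfMin(proteinMatrix(x)))
    SummarizedExperiment::assay(x, "abundance") <- filled
    S4Vectors::metadata(x)$imputed <- TRUE
    x
})

#' Column-wise z-standardization with reusable parameters
#'
#' Computes per-protein mean and sample SD (n - 1 denominator) on the
#' fitting rows and applies them to all rows, returning the parameters so
#' downstream scoring can reuse them without leakage.
#'
#' For a `ProteoCohort`, parameters are fitted on the baseline rows of each
#' batch separately and applied to that batch's follow-up rows, so the
#' discovery/validation split stays leakage-free.
#'
#' @param x numeric matrix (samples x proteins) or [ProteoCohort-class].
#' @param fit_on integer or logical row index defining the fitting set
#'   (matrix method; default all rows).
#' @return matrix method: the standardized matrix with attribute `params`
#'   (data.frame of mean, sd per column). Cohort method: the cohort with
#'   standardized abundances and parameters in `metadata()$standardization`.
#' @export
setGeneric("standardizeProteins", function(x, fit_on = NULL)
    standardGeneric("standardizeProteins"))

#' @rdname standardizeProteins
#' @export
setMethod("standardizeProteins", "matrix", function(x, fit_on = NULL) {
    if (anyNA(x)) stop("standardization expects an imputed (complete) matrix")
    if (is.null(fit_on)) fit_on <- seq_len(nrow(x))
    fit <- x[fit_on, , drop = FALSE]
    mu <- colMeans(fit)
    sdv <- apply(fit, 2, sd)
    zero_var <- sdv <= .Machine$double.eps^0.5
    if (any(zero_var))
        stop("zero-variance protein column(s) on the fitting rows: ",
             paste(colnames(x)[zero_var], collapse = ", "))
    z <- sweep(sweep(x, 2, mu, `-`), 2, sdv, `/`)
    attr(z, "params") <- data.frame(protein = colnames(x), mean = mu,
                                    sd = sdv, row.names = NULL,
                                    stringsAsFactors = FALSE)
    z
})

#' @rdname standardizeProteins
#' @export
setMethod("standardizeProteins", "ProteoCohort", function(x, fit_on = NULL) {
    m <- proteinMatrix(x)
    cd <- cohortData(x)
    out <- m
    params <- list()
    batches <- if ("batch" %in% colnames(cd)) unique(cd$batch) else "all"
    for (b in batches) {
        rows <- if (identical(b, "all")) seq_len(nrow(m)) else
            which(cd$batch == b)
        base_rows <- rows[cd$visit[rows] == min(cd$visit[rows])]
        zb <- standardizeProteins(m[rows, , drop = FALSE],
                                  fit_on = match(base_rows, rows))
        out[rows, ] <- zb
        params[[as.character(b)]] <- attr(zb, "params")
    }
    SummarizedExperiment::assay(x, "abundance") <- t(out)
    S4Vectors::metadata(x)$standardization <- params
    x
})

#' T-score computation and osteoporosis classification
#'
#' T = (BMD - ref_mean) / ref_sd against a young-adult reference.
#' Classification partitions the real line: osteoporosis for T < -2.5,
#' osteopenia for -2.5 <= T < -1, normal for T >= -1. A treated-flag
#' override classifies participants under osteoporosis treatment as
#' osteoporosis regardless of T.
#'
#' @param bmd numeric vector of BMD values (g/cm^2).
#' @param ref_mean,ref_sd young-adult reference mean and SD (g/cm^2).
#' @param treated logical vector (recycled); `TRUE` forces osteoporosis.
#' @return data.frame with `bmd`, `tscore` and `status` (factor with levels
#'   normal, osteopenia, osteoporosis).
#' @export
tscoreClassify <- function(bmd, ref_mean, ref_sd, treated = FALSE) {
    if (ref_sd <= 0) stop("ref_sd must be > 0")
    tsc <- (bmd - ref_mean) / ref_sd
    status <- ifelse(tsc < -2.5, "osteoporosis",
                     ifelse(tsc < -1, "osteopenia", "normal"))
    status[rep_len(as.logical(treated), length(bmd))] <- "osteoporosis"
    data.frame(bmd = bmd, tscore = tsc,
               status = factor(status, levels = c("normal", "osteopenia",
                                                  "osteoporosis")))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone-enforced, capped at 1,
#' order preserved).
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(pvals) {
    if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
        stop("p-values must lie in [0, 1] and be non-missing")
    p.adjust(pvals, method = "BH")
}

#' Case-control fold change per protein with FDR control
#'
#' Fold change = (mean_case - mean_control) / mean_control on imputed,
#' unstandardized abundances (a standardized matrix would put control means
#' near 0 and leave FC undefined). p-values from a two-sided Welch two-sample
#' t-test (or Wilcoxon rank-sum), adjusted by Benjamini-Hochberg within the
#' protein family passed in.
#'
#' @param x numeric matrix (samples x proteins), imputed abundances.
#' @param case_rows,control_rows row indices of the two groups.
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @return data.frame with `protein`, `fc`, `p`, `q`.
#' @export
foldChange <- function(x, case_rows, control_rows,
                       test = c("welch", "wilcoxon")) {
    test <- match.arg(test)
    if (!length(case_rows) || !length(control_rows))
        stop("both groups must be non-empty")
    if (anyNA(x)) stop("foldChange expects an imputed matrix")
    res <- vapply(seq_len(ncol(x)), function(j) {
        a <- x[case_rows, j]; b <- x[control_rows, j]
        mc <- mean(a); mn <- mean(b)
        if (abs(mn) < .Machine$double.eps)
            stop("control mean is 0 for protein ", colnames(x)[j],
                 "; compute fold change on pre-standardization abundances")
        pv <- if (identical(a, b) || (sd(a) == 0 && sd(b) == 0 &&
                                      mc == mn)) 1 else
            if (test == "welch") t.test(a, b)$p.value else
                stats::wilcox.test(a, b, exact = FALSE)$p.value
        c(fc = (mc - mn) / mn, p = pv)
    }, numeric(2))
    data.frame(protein = colnames(x), fc = res["fc", ], p = res["p", ],
               q = bhAdjust(res["p", ]), row.names = NULL,
               stringsAsFactors = FALSE)
}

#' PCA inspection of batch structure
#'
#' Principal components of a standardized matrix; reports per-component and
#' cumulative variance explained and, with two batches, the absolute
#' difference of batch means on PC1 in PC1-SD units.
#'
#' @param x numeric matrix (samples x proteins), standardized.
#' @param batch batch labels (one per row); `NULL` or a single level skips
#'   the separation summary.
#' @param n_components number of components to report.
#' @return list with `var_explained`, `cum_var_explained`, `scores`
#'   (first components) and `pc1_separation` (NA when undefined).
#' @export
pcaBatchCheck <- function(x, batch = NULL, n_components = 10L) {
    if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 rows and 2 columns")
    pc <- prcomp(x, center = TRUE, scale. = FALSE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    k <- min(n_components, ncol(pc$x))
    sep <- NA_real_
    if (!is.null(batch) && length(unique(batch)) == 2L) {
        lv <- unique(batch)
        pc1 <- pc$x[, 1]
        gap <- abs(mean(pc1[batch == lv[1]]) - mean(pc1[batch == lv[2]]))
        sep <- if (sd(pc1) > 0) gap / sd(pc1) else 0
    }
    list(var_explained = ve, cum_var_explained = cumsum(ve),
         scores = pc$x[, seq_len(k), drop = FALSE], pc1_separation = sep)
}

#' Paired t-test of within-person change
#'
#' One-sample t-test on the paired differences `x - y`, two-sided. A
#' zero-variance nonzero-mean difference vector is degenerate: p is
#' reported as 0 with a `degenerate` flag instead of erroring.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return list with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
pairedT <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 2L) stop("need at least 2 pairs")
    d <- x - y
    if (sd(d) == 0) {
        if (mean(d) == 0)
            return(list(t = 0, df = length(d) - 1L, p = 1,
                        mean_diff = 0, degenerate = FALSE))
        return(list(t = Inf * sign(mean(d)), df = length(d) - 1L, p = 0,
                    mean_diff = mean(d), degenerate = TRUE))
    }
    tt <- t.test(d)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}
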