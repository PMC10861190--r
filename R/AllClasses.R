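#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata
#' @importFrom stats aov anova approx coef cor cor.test density dnorm glm
#'   binomial gaussian kmeans lm mad median na.omit p.adjust pchisq pf pnorm
#'   prcomp pt qnorm quantile rbinom residuals rnorm runif sd t.test var vcov
#'   setNames complete.cases rexp predict qt
#' @importFrom utils head read.delim write.table
NULL

#' Longitudinal proteomic cohort container
#'
#' `ProteoCohort` extends
#' [SummarizedExperiment::SummarizedExperiment-class] for person-visit
#' proteomic cohorts. Rows are proteins, columns are person-visit samples.
#' The single assay `"abundance"` holds protein abundances (arbitrary
#' intensity units) with `NA` marking values missing below the detection
#' limit. Column data carries, per person-visit: `participant`, `visit`
#' (1-based visit index), `time_years` (years since baseline), `age`
#' (chronological age at the visit, years), `sex` (`"female"`/`"male"`),
#' `batch` (`"discovery"`/`"validation"`) plus bone mineral density columns
#' (`bmd_ls`, `bmd_fn`, g/cm^2) and covariates.
#'
#' Ground truth of synthetic cohorts, T-score reference values and
#' standardization parameters live in `metadata()`.
#'
#' @export
setClass("ProteoCohort", contains = "SummarizedExperiment")

.required_coldata <- c("participant", "visit", "time_years", "age", "sex")

setValidity("ProteoCohort", function(object) {
    msg <- character()
    if (!"abundance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'abundance' is required")
    missing_cols <- setdiff(.required_coldata,
                            colnames(SummarizedExperiment::colData(object)))
    if (length(missing_cols))
        msg <- c(msg, paste0("colData lacks required column(s): ",
                             paste(missing_cols, collapse = ", ")))
    if (is.null(rownames(object)))
        msg <- c(msg, "protein (row) names are required")
    if (length(msg)) msg else TRUE
})

#' Construct a ProteoCohort
#'
#' @param abundance numeric matrix, proteins x person-visit samples; `NA`
#'   marks left-censored missing values.
#' @param colData data.frame (one row per person-visit) with at least
#'   `participant`, `visit`, `time_years`, `age`, `sex`.
#' @param metadata list of cohort-level metadata (ground truth, T-score
#'   references, ...).
#' @return a [ProteoCohort-class] object.
#' @export
ProteoCohort <- function(abundance, colData, metadata = list()) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = abundance),
        colData = S4Vectors::DataFrame(colData, check.names = FALSE),
        metadata = metadata)
    new("ProteoCohort", se)
}

#' Klemera-Doubal biological-age model
#'
#' Calibration of the Klemera-Doubal estimator on age-coupled proteins.
#' For each protein j the slots store the age regression
#' x_j = q_j + k_j * CA + e, e ~ N(0, s_j^2), and its age correlation r_j.
#' `sBA` (years) is the uncertainty attached to chronological age in the
#' corrected estimator, `rChar` the characteristic biomarker-age
#' correlation, `caRange` the chronological-age range of the training set.
#'
#' @slot proteins data.frame with columns `protein`, `q`, `k`, `s`, `r`.
#' @slot sBA numeric(1), years.
#' @slot rChar numeric(1), dimensionless.
#' @slot caRange numeric(2), years.
#' @slot sBAFloored logical(1), whether the variance correction was floored.
#' @export
setClass("KdmModel", representation(
    proteins = "data.frame",
    sBA = "numeric",
    rChar = "numeric",
    caRange = "numeric",
    sBAFloored = "logical"))

setValidity("KdmModel", function(object) {
    p <- object@proteins
    msg <- character()
    if (!all(c("protein", "q", "k", "s", "r") %in% colnames(p)))
        msg <- c(msg, "proteins slot needs columns protein, q, k, s, r")
    if (nrow(p) < 1L) msg <- c(msg, "at least one protein required")
    if (any(p$s <= 0)) msg <- c(msg, "residual SDs must be positive")
    if (any(p$k == 0)) msg <- c(msg, "zero slopes are not allowed")
    if (length(object@sBA) != 1L || object@sBA <= 0)
        msg <- c(msg, "sBA must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' @describeIn KdmModel number of proteins in the model
#' @param object,x a `KdmModel`
#' @export
setMethod("length", "KdmModel", function(x) nrow(x@proteins))

setMethod("show", "KdmModel", function(object) {
    cat("KdmModel with", nrow(object@proteins), "protein(s)\n")
    cat(sprintf("  s_BA   : %.3f years%s\n", object@sBA,
                if (object@sBAFloored) " (floored)" else ""))
    cat(sprintf("  r_char : %.3f\n", object@rChar))
    cat(sprintf("  CA range: [%.1f, %.1f] years\n",
                object@caRange[1], object@caRange[2]))
})

setMethod("show", "ProteoCohort", function(object) {
    callNextMethod()
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf("ProteoCohort: %d participants, %d visit rows, %d proteins\n",
                length(unique(cd$participant)), ncol(object), nrow(object)))
    miss <- mean(is.na(SummarizedExperiment::assay(object, "abundance")))
    cat(sprintf("  missing abundance fraction: %.3f\n", miss))
})
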