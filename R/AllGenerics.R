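#' Accessors for ProteoCohort
#'
#' `proteinMatrix` returns the abundance matrix oriented person-visit rows x
#' protein columns (the orientation most statistical code here consumes);
#' `cohortData` the per person-visit table as a plain data.frame;
#' `groundTruth` the generator ground truth (or `NULL` for real data);
#' `participants` the unique participant identifiers.
#'
#' @param x a [ProteoCohort-class]
#' @return `proteinMatrix`: numeric matrix (samples x proteins);
#'   `cohortData`: data.frame; `groundTruth`: list or `NULL`;
#'   `participants`: character vector.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("proteinMatrix", function(x) standardGeneric("proteinMatrix"))

#' @rdname cohort-accessors
#' @export
setMethod("proteinMatrix", "ProteoCohort", function(x)
    t(SummarizedExperiment::assay(x, "abundance")))

#' @rdname cohort-accessors
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' @rdname cohort-accessors
#' @export
setMethod("cohortData", "ProteoCohort", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname cohort-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname cohort-accessors
#' @export
setMethod("groundTruth", "ProteoCohort", function(x)
    S4Vectors::metadata(x)$ground_truth)

#' @rdname cohort-accessors
#' @export
setGeneric("participants", function(x) standardGeneric("participants"))

#' @rdname cohort-accessors
#' @export
setMethod("participants", "ProteoCohort", function(x)
    unique(as.character(SummarizedExperiment::colData(x)$participant)))
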