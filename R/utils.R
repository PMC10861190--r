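# Shared covariate preparation: encode sex numerically and put continuous
# covariates on the SD scale (does not change exposure coefficients, keeps
# optimizers well conditioned).
.prepCovariates <- function(covariates) {
    if (is.null(covariates)) return(NULL)
    covariates <- as.data.frame(covariates)
    for (nm in colnames(covariates)) {
        v <- covariates[[nm]]
        if (!is.numeric(v)) {
            if (nm == "sex") v <- as.numeric(v == "male")
            else v <- as.numeric(factor(v))
        }
        u <- unique(v[!is.na(v)])
        if (length(u) > 2L && sd(v, na.rm = TRUE) > 0)
            v <- (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
        covariates[[nm]] <- v
    }
    covariates
}
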