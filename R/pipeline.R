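.writeTsv <- function(df, path) {
    fmt <- df
    for (j in seq_along(fmt)) {
        if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]])) {
            v <- sprintf("%.17g", fmt[[j]])
            v[is.na(fmt[[j]])] <- ""
            fmt[[j]] <- v
        } else {
            v <- as.character(fmt[[j]])
            v[is.na(fmt[[j]])] <- ""
            fmt[[j]] <- v
        }
    }
    write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.cohort_known_cols <- function() {
    c(.required_coldata, "batch", "bmd_ls", "bmd_fn",
      colnames(.simulateCovariates(1, 0, 0)))
}

#' Write a cohort to plain-text files
#'
#' Writes `cohort.tsv` (person-visit table), `proteins.tsv` (sample id
#' column + one column per protein; empty cell = missing) and, when
#' present, `ground_truth.json`. Floats are serialized with 17 significant
#' digits so a read-back reproduces the in-memory values exactly.
#'
#' @param cohort a [ProteoCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cd <- cohortData(cohort)
    cd <- data.frame(sample = rownames(cd), cd, row.names = NULL,
                     check.names = FALSE)
    p_cohort <- file.path(dir, "cohort.tsv")
    .writeTsv(cd, p_cohort)
    pm <- proteinMatrix(cohort)
    pdf <- data.frame(sample = rownames(pm), as.data.frame(pm),
                      row.names = NULL, check.names = FALSE)
    p_prot <- file.path(dir, "proteins.tsv")
    .writeTsv(pdf, p_prot)
    paths <- c(cohort = p_cohort, proteins = p_prot)
    gt <- groundTruth(cohort)
    if (!is.null(gt)) {
        gt$config <- unclass(gt$config)
        p_gt <- file.path(dir, "ground_truth.json")
        jsonlite::write_json(gt, p_gt, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        paths <- c(paths, ground_truth = p_gt)
    }
    invisible(paths)
}

#' Read a cohort from plain-text files
#'
#' Reads the person-visit table and the protein abundance table written by
#' [writeCohort()] (or prepared externally with the same schema). Unknown
#' cohort columns trigger a warning and are ignored; non-numeric abundance
#' cells are collected into a row-level error report.
#'
#' @param cohort_path path to the person-visit TSV (requires columns
#'   `sample`, `participant`, `visit`, `time_years`, `age`, `sex`).
#' @param protein_path path to the protein TSV (`sample` + one numeric
#'   column per protein; empty cells are missing).
#' @param tscore_ref_mean,tscore_ref_sd named per-site T-score references
#'   attached to the cohort metadata.
#' @return a [ProteoCohort-class].
#' @export
readCohort <- function(cohort_path, protein_path,
                       tscore_ref_mean = c(ls = 1.047, fn = 0.858),
                       tscore_ref_sd = c(ls = 0.110, fn = 0.120)) {
    cd <- read.delim(cohort_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
    mandatory <- c("sample", .required_coldata)
    miss <- setdiff(mandatory, colnames(cd))
    if (length(miss))
        stop("cohort file lacks mandatory column(s): ",
             paste(miss, collapse = ", "))
    unknown <- setdiff(colnames(cd), c("sample", .cohort_known_cols()))
    if (length(unknown)) {
        warning("ignoring unknown cohort column(s): ",
                paste(unknown, collapse = ", "))
        cd <- cd[, setdiff(colnames(cd), unknown), drop = FALSE]
    }
    rownames(cd) <- cd$sample
    cd$sample <- NULL

    praw <- read.delim(protein_path, check.names = FALSE,
                       colClasses = "character",
                       stringsAsFactors = FALSE)
    if (!"sample" %in% colnames(praw))
        stop("protein file lacks the mandatory 'sample' column")
    samp <- praw$sample
    praw$sample <- NULL
    bad <- list()
    pm <- matrix(NA_real_, nrow(praw), ncol(praw),
                 dimnames = list(samp, colnames(praw)))
    for (j in seq_along(praw)) {
        v <- praw[[j]]
        empty <- v == "" | is.na(v)
        num <- suppressWarnings(as.numeric(v))
        broken <- !empty & is.na(num)
        if (any(broken))
            bad[[colnames(praw)[j]]] <- which(broken) + 1L  # header line
        pm[, j] <- num
    }
    if (length(bad)) {
        msg <- vapply(names(bad), function(nm)
            paste0(nm, " (line ", paste(bad[[nm]], collapse = ","), ")"),
            character(1))
        stop("non-numeric abundance cell(s): ", paste(msg, collapse = "; "))
    }
    if (!identical(rownames(cd), rownames(pm)))
        pm <- pm[match(rownames(cd), rownames(pm)), , drop = FALSE]
    ProteoCohort(abundance = t(pm), colData = cd,
                 metadata = list(tscore_ref_mean = tscore_ref_mean,
                                 tscore_ref_sd = tscore_ref_sd))
}

.pipeline_stages <- c("simulate", "preprocess", "select", "assoc", "meta",
                      "prs", "trajectory", "survival", "bioage", "mr")

#' Default pipeline configuration
#'
#' Nested configuration driving [runPipeline()]. Defaults are desk-scale
#' (800 participants, 60 proteins) so the full pipeline runs in minutes;
#' full-scale analyses pass a larger `synth` block.
#'
#' @param n_participants,n_proteins synthetic cohort scale.
#' @param seed master seed; per-stage seeds derive from it.
#' @return nested list of class `PipelineConfig`.
#' @export
defaultPipelineConfig <- function(n_participants = 800L, n_proteins = 60L,
                                  seed = 1L) {
    cfg <- list(
        seed = as.integer(seed),
        stages = .pipeline_stages,
        synth = list(n_participants = n_participants,
                     n_proteins = n_proteins),
        select = list(train_frac = 0.7, n_folds = 10L,
                      nrounds = 150L, max_depth = 3L, eta = 0.05),
        assoc = list(covariate_tier = "model3"),
        meta = list(),
        prs = list(),
        trajectory = list(k_max = 5L, appa_threshold = 0.7,
                          n_restarts = 10L),
        survival = list(n_knots = 4L),
        bioage = list(min_abs_r = 0.1, max_pairwise_r = 0.7),
        mr = list(n_snps = 50L, theta_true = 0.5, pleiotropy_sd = 0))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Loads a nested YAML file and merges it over the defaults; unknown keys
#' (top-level or within a block) are rejected.
#'
#' @param path YAML file path.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    user <- yaml::read_yaml(path)
    base <- defaultPipelineConfig()
    unknown <- setdiff(names(user), names(base))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    for (k in names(user)) {
        if (is.list(base[[k]]) && is.list(user[[k]])) {
            bad <- setdiff(names(user[[k]]),
                           c(names(base[[k]]), names(formals(synthConfig))))
            if (length(bad))
                stop("unknown key(s) in '", k, "': ",
                     paste(bad, collapse = ", "))
            base[[k]][names(user[[k]])] <- user[[k]]
        } else base[[k]] <- user[[k]]
    }
    class(base) <- "PipelineConfig"
    base
}

#' Run the full analysis pipeline
#'
#' Executes simulate, preprocess, select, assoc, meta, prs, trajectory,
#' survival, bioage and mr in order (stages are individually skippable via
#' `config$stages`), writes per-stage TSV/JSON outputs under `outdir`, and
#' records seeds and parameters in a JSON run manifest. A stage whose
#' upstream artifact is missing raises an error naming it.
#'
#' @param config a `PipelineConfig` (see [defaultPipelineConfig()]).
#' @param outdir output directory; `NULL` keeps everything in memory.
#' @return invisibly, a list of per-stage results plus the manifest.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outdir = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    if (!is.null(outdir))
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    st <- list()
    run_stages <- intersect(.pipeline_stages, config$stages)
    need <- function(what, stage) {
        if (is.null(st[[what]]))
            stop("stage '", stage, "' requires upstream artifact '", what,
                 "'; enable its producing stage")
        st[[what]]
    }
    emit <- function(name, obj) {
        if (is.null(outdir)) return(invisible(NULL))
        path <- file.path(outdir, name)
        if (grepl("\\.json$", name))
            jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE)
        else .writeTsv(obj, path)
    }
    tiers <- covariateTiers()

    for (stage in run_stages) {
        switch(stage,
        simulate = {
            sargs <- config$synth
            sargs$seed <- config$seed
            st$cohort <- simulateCohort(do.call(synthConfig, sargs))
            if (!is.null(outdir))
                writeCohort(st$cohort, file.path(outdir, "cohort"))
        },
        preprocess = {
            coh <- need("cohort", "preprocess")
            coh <- imputeHalfMin(coh)
            st$imputed_matrix <- proteinMatrix(coh)
            coh <- standardizeProteins(coh)
            st$cohort_std <- coh
            cd <- cohortData(coh)
            st$statuses <- lapply(c(ls = "ls", fn = "fn"), function(s)
                cohortStatuses(coh, s))
            # ever-osteoporosis labels per participant and site
            st$labels <- lapply(st$statuses, function(ss) {
                ev <- tapply(ss$status == "osteoporosis", ss$participant,
                             any)
                setNames(as.integer(ev), names(ev))
            })
            base <- cd$visit == min(cd$visit)
            st$pca <- pcaBatchCheck(proteinMatrix(coh)[base, , drop = FALSE],
                                    cd$batch[base])
            # fold change per visit, OP-ever cases vs controls (LS)
            lab <- st$labels$ls[as.character(cd$participant)]
            fc <- lapply(sort(unique(cd$visit)), function(v) {
                rows <- which(cd$visit == v)
                data.frame(visit = v,
                           foldChange(st$imputed_matrix[rows, , drop = FALSE],
                                      which(lab[rows] == 1),
                                      which(lab[rows] == 0)))
            })
            st$fold_change <- do.call(rbind, fc)
            emit("fold_change.tsv", st$fold_change)
        },
        select = {
            coh <- need("cohort_std", "select")
            cd <- cohortData(coh)
            z <- proteinMatrix(coh)
            base <- cd$visit == min(cd$visit)
            st$selection <- list()
            for (site in c("ls", "fn")) {
                lab_all <- st$labels[[site]]
                rows <- which(base & cd$batch == "discovery")
                ids <- as.character(cd$participant[rows])
                y <- lab_all[ids]
                sp <- splitDiscovery(seq_along(rows),
                                     config$select$train_frac,
                                     seed = config$seed + 11L)
                Xtr <- z[rows[sp$train], , drop = FALSE]
                Xte <- z[rows[sp$test], , drop = FALSE]
                shap <- selectByShap(Xtr, y[sp$train],
                                     params = list(
                                         nrounds = config$select$nrounds,
                                         max_depth = config$select$max_depth,
                                         eta = config$select$eta,
                                         min_child_weight = 5,
                                         subsample = 1,
                                         colsample_bytree = 1),
                                     seed = config$seed + 13L)
                lasso <- selectByLasso(Xtr, y[sp$train],
                                       n_folds = config$select$n_folds,
                                       seed = config$seed + 17L)
                vrows <- which(base & cd$batch == "validation")
                vy <- lab_all[as.character(cd$participant[vrows])]
                Xv <- z[vrows, , drop = FALSE]
                st$selection[[site]] <- list(
                    shap = shap, lasso = lasso,
                    auc = list(
                        shap_test = evaluateSelection(shap, Xte,
                                                      y[sp$test])$auc,
                        shap_validation = evaluateSelection(shap, Xv,
                                                            vy)$auc,
                        lasso_test = evaluateSelection(lasso, Xte,
                                                       y[sp$test])$auc,
                        lasso_validation = evaluateSelection(lasso, Xv,
                                                             vy)$auc))
                emit(paste0("selection_", site, ".tsv"), data.frame(
                    protein = names(shap$importance),
                    shap_importance = unname(shap$importance),
                    shap_retained = names(shap$importance) %in%
                        shap$retained,
                    lasso_importance = unname(
                        lasso$importance[names(shap$importance)]),
                    lasso_retained = names(shap$importance) %in%
                        lasso$retained))
            }
            emit("selection_auc.json",
                 lapply(st$selection, `[[`, "auc"))
        },
        assoc = {
            coh <- need("cohort_std", "assoc")
            cvs <- tiers[[config$assoc$covariate_tier]]
            st$assoc <- list()
            for (site in c("ls", "fn")) {
                est <- rbind(
                    runAssociation(coh, site, "discovery", cvs),
                    runAssociation(coh, site, "validation", cvs))
                st$assoc[[site]] <- est
                emit(paste0("assoc_", site, ".tsv"), est)
            }
        },
        meta = {
            if (is.null(st$assoc)) need("assoc", "meta")
            st$meta <- lapply(st$assoc, metaAnalyze)
            for (site in names(st$meta))
                emit(paste0("meta_", site, ".tsv"), st$meta[[site]])
        },
        prs = {
            if (is.null(st$meta)) need("meta", "prs")
            coh <- need("cohort_std", "prs")
            cd <- cohortData(coh)
            z <- proteinMatrix(coh)
            cvs <- tiers[[config$assoc$covariate_tier]]
            st$prs <- list()
            for (site in names(st$meta)) {
                mm <- st$meta[[site]]
                fl <- mm[mm$flagged, , drop = FALSE]
                if (!nrow(fl)) {
                    st$prs[[site]] <- NULL
                    next
                }
                base <- cd$visit == min(cd$visit)
                prs_b <- buildPrs(fl, z[base, , drop = FALSE])
                cross <- lapply(sort(unique(cd$visit)), function(v) {
                    rows <- which(cd$visit == v)
                    pv <- buildPrs(fl, z[rows, , drop = FALSE])
                    bmdz <- as.vector(scale(cd[[paste0("bmd_", site)]][rows]))
                    lin <- fitGlmCross(bmdz, pv$score,
                                       cd[rows, cvs, drop = FALSE],
                                       "linear")
                    opv <- as.integer(
                        st$statuses[[site]]$status[rows] == "osteoporosis")
                    logi <- if (length(unique(opv)) > 1)
                        fitGlmCross(opv, pv$score,
                                    cd[rows, cvs, drop = FALSE],
                                    "logistic") else NULL
                    list(visit = v, linear = lin, logistic = logi)
                })
                st$prs[[site]] <- list(weights = attr(prs_b, "weights"),
                                       baseline = prs_b, cross = cross)
                emit(paste0("prs_weights_", site, ".tsv"), data.frame(
                    protein = names(attr(prs_b, "weights")),
                    weight = unname(attr(prs_b, "weights"))))
                emit(paste0("prs_scores_", site, ".tsv"), data.frame(
                    prs_b, quartile = as.character(prsQuartiles(prs_b$score))))
            }
        },
        trajectory = {
            coh <- need("cohort_std", "trajectory")
            cd <- cohortData(coh)
            st$traj <- list()
            for (site in c("ls", "fn")) {
                bmdz <- as.vector(scale(cd[[paste0("bmd_", site)]]))
                dat <- data.frame(participant = cd$participant,
                                  time = cd$time_years, y = bmdz)
                fits <- lapply(seq_len(config$trajectory$k_max), function(k)
                    fitLctm(dat, k, seed = config$seed + 19L + k,
                            n_restarts = config$trajectory$n_restarts))
                best <- selectClasses(fits,
                                      config$trajectory$appa_threshold)
                anova_res <- NULL
                if (!is.null(st$meta) && best$K >= 2L) {
                    fl <- st$meta[[site]]
                    fl <- fl$protein[fl$flagged]
                    if (length(fl) && all(table(best$assignment) >= 2)) {
                        z <- proteinMatrix(coh)
                        base <- which(cd$visit == min(cd$visit))
                        names(base) <- cd$participant[base]
                        asg <- best$assignment
                        rows <- base[names(asg)]
                        anova_res <- do.call(rbind, lapply(fl, function(pr) {
                            a <- anovaAcrossClasses(z[rows, pr], asg)
                            data.frame(protein = pr, F = a$F, df1 = a$df1,
                                       df2 = a$df2, p = a$p)
                        }))
                    }
                }
                st$traj[[site]] <- list(fits = fits, best = best,
                                        anova = anova_res)
                emit(paste0("trajectory_", site, ".json"), list(
                    bic = vapply(fits, `[[`, numeric(1), "bic"),
                    appa = vapply(fits, `[[`, numeric(1), "appa_min"),
                    K_selected = best$K,
                    intercept = best$intercept, slope = best$slope,
                    pi = best$pi, sigma = best$sigma))
            }
        },
        survival = {
            coh <- need("cohort_std", "survival")
            cd <- cohortData(coh)
            base <- cd$visit == min(cd$visit)
            basecd <- cd[base, , drop = FALSE]
            rownames(basecd) <- basecd$participant
            cvs <- tiers[[config$assoc$covariate_tier]]
            st$records <- lapply(st$statuses, makeSurvivalRecords)
            st$surv <- list()
            for (site in names(st$records)) {
                rec <- st$records[[site]]
                out <- list()
                if (!is.null(st$prs[[site]])) {
                    prs_b <- st$prs[[site]]$baseline
                    prs_map <- setNames(prs_b$score,
                                        cd$participant[match(prs_b$sample,
                                                             rownames(cd))])
                    expo <- prs_map[rec$participant]
                    cov_df <- basecd[rec$participant, cvs, drop = FALSE]
                    out$cox_prs <- fitCoxModel(rec, expo, cov_df)
                    # quartile and spline summaries need events spread
                    # across the exposure range; record why when the
                    # cohort is too small to support them
                    out$quartile <- tryCatch(
                        quartileHr(rec, prsQuartiles(expo), cov_df),
                        error = function(e)
                            list(error = conditionMessage(e)))
                    out$rcs <- tryCatch(
                        rcsDoseResponse(rec, expo, cov_df,
                                        config$survival$n_knots),
                        error = function(e)
                            list(error = conditionMessage(e)))
                    if (is.data.frame(out$rcs))
                        emit(paste0("rcs_", site, ".tsv"), out$rcs)
                }
                st$surv[[site]] <- out
                emit(paste0("survival_records_", site, ".tsv"), rec)
            }
        },
        bioage = {
            coh <- need("cohort_std", "bioage")
            cd <- cohortData(coh)
            z <- proteinMatrix(coh)
            base <- which(cd$visit == min(cd$visit))
            zb <- z[base, , drop = FALSE]
            ca <- cd$age[base]
            sel <- selectAgeProteins(zb, ca,
                                     config$bioage$max_pairwise_r,
                                     config$bioage$min_abs_r)
            model <- fitKdm(zb[, sel, drop = FALSE], ca)
            ba <- predictBioage(model, zb[, sel, drop = FALSE], ca)
            ba$participant <- cd$participant[base]
            basecd <- cd[base, , drop = FALSE]
            rownames(basecd) <- basecd$participant
            st$bioage <- list(selected = sel, model = model, bioage = ba,
                              cor_ca = cor(ba$ba_ec, ca))
            if (!is.null(st$records)) {
                st$bioage$cox <- lapply(st$records, function(rec) {
                    list(kdm = bioageSurvival(ba, rec, basecd, "ba_ec"),
                         accel = bioageSurvival(ba, rec, basecd, "accel"))
                })
            }
            emit("bioage.tsv", ba)
            emit("kdm_model.json", list(
                proteins = model@proteins, s_ba = model@sBA,
                r_char = model@rChar, ca_range = model@caRange))
        },
        mr = {
            sim <- simulateMrSummary(config$mr$n_snps,
                                     config$mr$theta_true,
                                     config$mr$pleiotropy_sd,
                                     seed = config$seed + 29L)
            inst <- filterInstruments(sim$instruments)
            st$mr <- list(truth = sim$truth,
                          estimates = mrAll(inst,
                                            seed = config$seed + 31L))
            emit("mr_estimates.tsv", st$mr$estimates)
        })
    }
    manifest <- list(stages = run_stages, seed = config$seed,
                     parameters = unclass(config),
                     package_version =
                         as.character(utils::packageVersion("ProteoBoneAge")),
                     n_stage = length(run_stages))
    if (!is.null(outdir))
        jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    st$manifest <- manifest
    invisible(st)
}
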