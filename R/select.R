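#' Random train/test split of the discovery cohort
#'
#' Disjoint, exhaustive split with `round(n * train_frac)` training rows,
#' deterministic given the seed. At the reference cohort size of 1746 and
#' a 0.7 fraction this yields the canonical 1222/524 split.
#'
#' @param ids vector of row identifiers (or a single integer n, expanded to
#'   `seq_len(n)`).
#' @param train_frac training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
splitDiscovery <- function(ids, train_frac = 0.7, seed = 1L) {
    if (length(ids) == 1L && is.numeric(ids)) ids <- seq_len(ids)
    n <- length(ids)
    if (n < 2L) stop("need at least 2 rows to split")
    if (train_frac <= 0 || train_frac >= 1)
        stop("train_frac must lie strictly in (0, 1)")
    set.seed(seed)
    n_train <- round(n * train_frac)
    tr <- sample.int(n, n_train)
    list(train = ids[sort(tr)], test = ids[sort(setdiff(seq_len(n), tr))])
}

#' Protein selection by gradient boosting with SHAP attributions
#'
#' Fits a gradient-boosted decision-tree classifier (binary logistic
#' objective, single thread for determinism) on the training rows and
#' computes exact TreeSHAP attributions there. Features whose mean absolute
#' SHAP value exceeds a small numerical tolerance are retained; constant
#' features can never split and receive attribution 0.
#'
#' @param features numeric matrix (samples x proteins).
#' @param labels binary 0/1 vector; both classes must be present.
#' @param params list of boosting hyperparameters: `nrounds`, `max_depth`,
#'   `eta`, `min_child_weight`, `subsample`, `colsample_bytree`.
#' @param seed integer seed.
#' @param tol retention tolerance on mean |SHAP| (absorbs floating-point
#'   attribution noise).
#' @return list of class `SelectionResult`: `method`, `importance` (named,
#'   mean |SHAP| per feature), `retained` (character), `model`, `params`.
#' @export
selectByShap <- function(features, labels,
                         params = list(nrounds = 200L, max_depth = 3L,
                                       eta = 0.05, min_child_weight = 5,
                                       subsample = 1, colsample_bytree = 1),
                         seed = 1L, tol = 1e-12) {
    .checkBinary(labels, features)
    set.seed(seed)
    dm <- xgboost::xgb.DMatrix(features, label = labels, nthread = 1)
    bst <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      min_child_weight = params$min_child_weight,
                      subsample = params$subsample,
                      colsample_bytree = params$colsample_bytree,
                      nthread = 1, seed = seed),
        data = dm, nrounds = params$nrounds, verbose = 0)
    contrib <- predict(bst, dm, predcontrib = TRUE)
    phi <- colMeans(abs(contrib))
    phi <- phi[setdiff(names(phi), c("BIAS", "(Intercept)"))]
    names(phi) <- colnames(features)
    structure(list(method = "gbm_shap", importance = phi,
                   retained = names(phi)[phi > tol],
                   model = bst, params = params),
              class = "SelectionResult")
}

#' Protein selection by L1-penalized logistic regression
#'
#' LASSO over a lambda grid with lambda chosen by n-fold cross-validated
#' binomial deviance; retained proteins are those with nonzero coefficients
#' at the selected lambda.
#'
#' @param features numeric matrix (samples x proteins).
#' @param labels binary 0/1 vector.
#' @param n_folds number of CV folds.
#' @param seed integer seed (drives fold assignment).
#' @param lambda_choice `"min"` (deviance-minimizing, default) or `"1se"`.
#' @return a `SelectionResult` (importance = |coefficient| at lambda*).
#' @export
selectByLasso <- function(features, labels, n_folds = 10L, seed = 1L,
                          lambda_choice = c("min", "1se")) {
    .checkBinary(labels, features)
    lambda_choice <- match.arg(lambda_choice)
    n <- nrow(features)
    if (n_folds > n) stop("n_folds exceeds the number of samples")
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(n_folds), n))
    cv <- glmnet::cv.glmnet(features, labels, family = "binomial",
                            foldid = foldid, type.measure = "deviance")
    s <- if (lambda_choice == "min") cv$lambda.min else cv$lambda.1se
    beta <- as.matrix(coef(cv, s = s))[-1, 1]
    structure(list(method = "lasso", importance = abs(beta),
                   retained = names(beta)[beta != 0],
                   model = cv, params = list(n_folds = n_folds, lambda = s)),
              class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
    cat("SelectionResult (", x$method, "): ", length(x$retained), " of ",
        length(x$importance), " features retained\n", sep = "")
    top <- sort(x$importance, decreasing = TRUE)
    print(round(head(top, 5), 4))
    invisible(x)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' AUC = P(score_case > score_control) + 0.5 P(tie), computed from the
#' rank-sum statistic.
#'
#' @param labels binary 0/1 vector (1 = case).
#' @param scores numeric predictions.
#' @return AUC in [0, 1].
#' @export
aucMW <- function(labels, scores) {
    labels <- as.integer(labels)
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    if (n1 == 0 || n0 == 0) stop("both classes must be present")
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.checkBinary <- function(labels, features) {
    if (length(unique(labels)) < 2L)
        stop("labels must contain both classes")
    if (!all(labels %in% c(0, 1)))
        stop("labels must be coded 0/1")
    if (ncol(features) < 2L) stop("need at least 2 features")
    if (nrow(features) != length(labels))
        stop("features and labels disagree in length")
    invisible(TRUE)
}

#' Evaluate a trained selection model on new data
#'
#' Scores samples with the fitted boosting or LASSO model and returns the
#' Mann-Whitney AUC, mirroring the two-step design in which features are
#' selected in the discovery cohort and re-evaluated on held-out and
#' validation samples.
#'
#' @param result a `SelectionResult`.
#' @param features numeric matrix with the same columns used at fit time.
#' @param labels binary 0/1 vector.
#' @return list with `auc` and `scores`.
#' @export
evaluateSelection <- function(result, features, labels) {
    scores <- if (result$method == "gbm_shap") {
        predict(result$model,
                xgboost::xgb.DMatrix(features, nthread = 1))
    } else {
        as.vector(predict(result$model, newx = features, s = "lambda.min",
                          type = "response"))
    }
    list(auc = aucMW(labels, scores), scores = scores)
}
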