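#' Train the lasso logistic fragmentation model
#'
#' Fits an L1-penalized logistic regression of case status on per-bin
#' short-fragment proportions. Features are standardized internally by the
#' fitter; the penalty is chosen by repeated stratified k-fold
#' cross-validation: the cross-validated binomial deviance curve is averaged
#' over \code{nRepeats} independent fold assignments and the lambda
#' minimizing the mean curve is selected (ties go to the larger, sparser
#' lambda). Samples are put in a canonical order (sorted by id) before fold
#' assignment, so the fit is invariant to input row order given the seed.
#'
#' @param x samples x bins matrix of proportions (no missing values), or a
#'   \code{\link{FragProfileSet}} (missing bins imputed with the sample
#'   mean).
#' @param labels per-sample class vector; the positive class is
#'   \code{"case"} (or the last factor level when no \code{"case"} value is
#'   present).
#' @param nFolds folds per cross-validation round (default 5).
#' @param nRepeats independent fold assignments averaged (default 5).
#' @param seed RNG seed for fold assignment.
#' @param cutoff score threshold stored on the model. \code{NULL} (default)
#'   selects the training-set Youden-optimal threshold; pass an external
#'   reference value (e.g. a previously published 0.494) to reproduce a
#'   fixed operating point.
#' @param centered model row-centered rather than raw proportions.
#' @return a \code{\link{FragModel}}.
#' @export
trainFragModel <- function(x, labels, nFolds = 5, nRepeats = 5, seed = 1,
                           cutoff = NULL, centered = FALSE) {
    m <- if (is(x, "FragProfileSet"))
        proportionMatrix(x, imputeMissing = TRUE) else as.matrix(x)
    if (centered) m <- centerRows(m)
    labels <- as.character(labels)
    if (length(labels) != nrow(m)) stop("labels length != number of samples")
    if (anyNA(m)) stop("missing values in feature matrix; impute first")
    cls <- sort(unique(labels))
    if (length(cls) != 2)
        stop("exactly two classes required, got: ",
             paste(cls, collapse = ", "))
    pos <- if ("case" %in% cls) "case" else cls[2]
    y <- as.integer(labels == pos)
    if (nrow(m) < nFolds) stop("fewer samples than folds")
    if (min(table(y)) < nFolds)
        stop("each class needs at least nFolds samples for stratified CV")

    if (is.null(rownames(m)))
        rownames(m) <- sprintf("s%05d", seq_len(nrow(m)))
    ord <- order(rownames(m))
    m <- m[ord, , drop = FALSE]; y <- y[ord]

    g0 <- glmnet::glmnet(m, y, family = "binomial", alpha = 1,
                         standardize = TRUE, nlambda = 100)
    lambdas <- g0$lambda

    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    cvSum <- setNames(numeric(length(lambdas)), signif(lambdas, 10))
    cvN <- cvSum
    for (r in seq_len(nRepeats)) {
        set.seed(seed + r - 1L)
        foldid <- stratifiedFolds(y, nFolds)
        cv <- glmnet::cv.glmnet(m, y, family = "binomial", alpha = 1,
                                standardize = TRUE, lambda = lambdas,
                                foldid = foldid, type.measure = "deviance")
        idx <- match(signif(cv$lambda, 10), names(cvSum))
        cvSum[idx] <- cvSum[idx] + cv$cvm
        cvN[idx] <- cvN[idx] + 1
    }
    used <- cvN > 0
    cvMean <- cvSum[used] / cvN[used]
    lamUsed <- lambdas[used]
    # lambdas are in decreasing order: which.min returns the largest
    # (sparsest) lambda among ties
    lambdaStar <- lamUsed[which.min(cvMean)]

    cf <- as.matrix(stats::coef(g0, s = lambdaStar))[, 1]
    intercept <- cf[1]
    beta <- cf[-1]
    nz <- beta[beta != 0]
    featureSd <- apply(m, 2, stats::sd)
    featureMean <- colMeans(m)

    model <- new("FragModel",
        featureNames = colnames(m),
        coefficients = nz,
        intercept = unname(intercept),
        lambda = lambdaStar,
        cutoff = 0.5,
        featureSd = featureSd,
        featureMean = featureMean,
        seed = as.integer(seed),
        nFolds = as.integer(nFolds),
        nRepeats = as.integer(nRepeats),
        cvCurve = data.frame(lambda = lamUsed, deviance = unname(cvMean)))
    model@cutoff <- if (is.null(cutoff))
        youdenCutoff(scoreSamples(model, m), y) else cutoff
    validObject(model)
    model
}

stratifiedFolds <- function(y, nFolds) {
    foldid <- integer(length(y))
    for (cl in unique(y)) {
        idx <- which(y == cl)
        foldid[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    foldid
}

# candidate thresholds are midpoints between consecutive observed scores,
# so a cutoff inside a wide class gap lands mid-gap
youdenCutoff <- function(scores, y) {
    u <- sort(unique(scores))
    cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
    best <- cand[1]; bestJ <- -Inf
    for (c in cand) {
        sens <- mean(scores[y == 1] >= c)
        spec <- mean(scores[y == 0] < c)
        j <- sens + spec - 1
        if (j > bestJ) { bestJ <- j; best <- c }
    }
    best
}

#' Score samples with a fragmentation model
#'
#' The score is the model's predicted case probability,
#' \code{plogis(intercept + x . beta)}, always in [0, 1].
#'
#' @param model a \code{\link{FragModel}}.
#' @param x samples x bins matrix or \code{\link{FragProfileSet}}; must
#'   contain every bin the model uses.
#' @return named numeric vector of scores.
#' @export
scoreSamples <- function(model, x) {
    stopifnot(is(model, "FragModel"))
    m <- if (is(x, "FragProfileSet"))
        proportionMatrix(x, imputeMissing = TRUE) else as.matrix(x)
    need <- names(model@coefficients)
    miss <- setdiff(need, colnames(m))
    if (length(miss))
        stop("feature bin(s) missing from input: ",
             paste(miss, collapse = ", "))
    eta <- model@intercept +
        as.numeric(m[, need, drop = FALSE] %*% model@coefficients)
    setNames(stats::plogis(eta), rownames(m))
}

#' Relative importance of the model's bins
#'
#' Importance of bin i is its absolute standardized coefficient
#' \code{|beta_i * sd_i|} as a percentage of the sum over all selected bins;
#' percentages sum to 100.
#'
#' @param model a \code{\link{FragModel}} with at least one nonzero
#'   coefficient.
#' @return named numeric percentages, sorted decreasing.
#' @export
featureImportance <- function(model) {
    stopifnot(is(model, "FragModel"))
    if (!length(model@coefficients))
        stop("model has no nonzero coefficients")
    std <- abs(model@coefficients *
               model@featureSd[names(model@coefficients)])
    sort(100 * std / sum(std), decreasing = TRUE)
}

#' Classify scores at a cutoff
#'
#' @param scores numeric scores in [0, 1].
#' @param cutoff threshold; a score equal to the cutoff is called positive.
#' @return factor with levels \code{negative}, \code{positive}.
#' @export
classifyScores <- function(scores, cutoff = 0.494) {
    factor(ifelse(scores >= cutoff, "positive", "negative"),
           levels = c("negative", "positive"))
}

#' Aggregate sample scores per subject and time window
#'
#' Subjects with several samples in the same time-to-diagnosis window get
#' the arithmetic mean of their sample scores; classification is applied
#' after averaging.
#'
#' @param scored data.frame with columns \code{subject_id}, \code{window}
#'   and \code{score} (extra columns ignored).
#' @return data.frame with one row per (subject, window): \code{subject_id},
#'   \code{window}, \code{score} (mean), \code{n_samples}.
#' @export
aggregateSubjectWindow <- function(scored) {
    need <- c("subject_id", "window", "score")
    miss <- setdiff(need, colnames(scored))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    key <- interaction(scored$subject_id, scored$window, drop = TRUE,
                       lex.order = TRUE)
    agg <- data.frame(
        subject_id = tapply(as.character(scored$subject_id), key, `[`, 1),
        window = tapply(as.character(scored$window), key, `[`, 1),
        score = as.numeric(tapply(scored$score, key, mean)),
        n_samples = as.integer(tapply(scored$score, key, length)))
    rownames(agg) <- NULL
    agg[order(agg$subject_id, agg$window), , drop = FALSE]
}

#' Serialize / deserialize a FragModel as JSON
#'
#' The JSON records feature names, nonzero coefficients, intercept, lambda,
#' cutoff, standardization parameters, seed and CV layout — enough to score
#' new samples exactly and to audit training.
#'
#' @param model a \code{\link{FragModel}}.
#' @param path JSON file path.
#' @return \code{writeFragModel} returns \code{path} invisibly;
#'   \code{readFragModel} returns the \code{FragModel}.
#' @export
writeFragModel <- function(model, path) {
    stopifnot(is(model, "FragModel"))
    obj <- list(
        feature_names = model@featureNames,
        coefficients = as.list(model@coefficients),
        intercept = model@intercept,
        lambda = model@lambda,
        cutoff = model@cutoff,
        feature_sd = as.list(model@featureSd),
        feature_mean = as.list(model@featureMean),
        seed = model@seed,
        n_folds = model@nFolds,
        n_repeats = model@nRepeats)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeFragModel
#' @export
readFragModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    co <- unlist(obj$coefficients)
    if (is.null(co)) co <- stats::setNames(numeric(0), character(0))
    new("FragModel",
        featureNames = obj$feature_names,
        coefficients = co,
        intercept = obj$intercept,
        lambda = obj$lambda,
        cutoff = obj$cutoff,
        featureSd = unlist(obj$feature_sd),
        featureMean = unlist(obj$feature_mean),
        seed = as.integer(obj$seed),
        nFolds = as.integer(obj$n_folds),
        nRepeats = as.integer(obj$n_repeats),
        cvCurve = data.frame())
}
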