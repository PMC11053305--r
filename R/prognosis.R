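#' Compare scores between two clinical groups
#'
#' Two-sided Wilcoxon rank-sum test, exact when both groups have at most 20
#' observations and no ties, normal approximation with continuity and tie
#' correction otherwise.
#'
#' @param scores numeric scores.
#' @param group two-level grouping vector.
#' @return list with \code{statistic} (W), \code{p.value},
#'   \code{group_means} (named).
#' @export
groupCompare <- function(scores, group) {
    group <- as.factor(droplevels(as.factor(group)))
    if (nlevels(group) != 2)
        stop("exactly two non-empty groups required")
    a <- scores[group == levels(group)[1]]
    b <- scores[group == levels(group)[2]]
    if (!length(a) || !length(b)) stop("a group is empty")
    exact <- length(a) <= 20 && length(b) <= 20 &&
        !any(duplicated(c(a, b)))
    wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                             correct = TRUE)
    list(statistic = unname(wt$statistic), p.value = wt$p.value,
         group_means = stats::setNames(c(mean(a), mean(b)), levels(group)))
}

#' Dichotomize scores at the case median
#'
#' Labels a score "high" when it is at or above the median of all provided
#' scores (so an odd cohort whose median is attained once splits
#' (n+1)/2 high vs (n-1)/2 low).
#'
#' @param scores numeric scores for the case subjects.
#' @param threshold override the threshold instead of using the median.
#' @return list with \code{labels} (factor \code{low}/\code{high}) and
#'   \code{threshold}.
#' @export
dichotomizeScores <- function(scores, threshold = NULL) {
    if (length(scores) < 2) stop("need at least 2 subjects")
    if (is.null(threshold)) threshold <- stats::median(scores)
    list(labels = factor(ifelse(scores >= threshold, "high", "low"),
                         levels = c("low", "high")),
         threshold = threshold)
}

#' Administrative censoring at a follow-up cap
#'
#' @param time follow-up time in months.
#' @param event event indicator (1 = death).
#' @param capMonths administrative cap (default 36).
#' @return data.frame \code{time}, \code{event} with times beyond the cap
#'   censored at the cap.
#' @export
capFollowup <- function(time, event, capMonths = 36) {
    over <- time > capMonths
    data.frame(time = pmin(time, capMonths),
               event = ifelse(over, 0L, as.integer(event)))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator; the median survival is the earliest time at
#' which the survival curve drops to 0.5 or below, missing when never
#' reached.
#'
#' @param time follow-up time (months).
#' @param event event indicator (1 = death, 0 = censored).
#' @return list with \code{steps} (data.frame \code{time}, \code{n_risk},
#'   \code{n_event}, \code{surv}) and \code{median}.
#' @export
kmEstimate <- function(time, event) {
    if (!length(time)) stop("no survival records")
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, surv = fit$surv)
    med <- if (any(steps$surv <= 0.5))
        min(steps$time[steps$surv <= 0.5]) else NA_real_
    list(steps = steps, median = med)
}

#' Two-group log-rank test
#'
#' @param time,event survival outcome.
#' @param group two-level grouping (e.g. high/low score).
#' @param strata optional stratification factor (e.g. BCLC stage) for a
#'   stratified log-rank test.
#' @return list with \code{chisq}, \code{df}, \code{p.value}.
#' @export
logrankTest <- function(time, event, group, strata = NULL) {
    if (sum(event) < 1) stop("log-rank test needs at least one event")
    group <- droplevels(as.factor(group))
    if (nlevels(group) != 2) stop("exactly two groups required")
    df <- data.frame(time = time, event = event, group = group)
    if (is.null(strata)) {
        sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                                 data = df)
    } else {
        df$str <- as.factor(strata)
        sd <- survival::survdiff(
            survival::Surv(time, event) ~ group + survival::strata(str),
            data = df)
    }
    deg <- nlevels(group) - 1
    list(chisq = unname(sd$chisq), df = deg,
         p.value = stats::pchisq(sd$chisq, deg, lower.tail = FALSE))
}

#' Adjusted Cox proportional-hazards fit
#'
#' Partial-likelihood fit with the Efron tie correction; returns per-term
#' hazard ratios with Wald confidence intervals. Intended use: the
#' dichotomized fragmentation score group adjusted for age group, sex, BCLC
#' stage and AFP status.
#'
#' @param time,event survival outcome.
#' @param covariates data.frame of covariates (factors or numerics); the
#'   fitted model is \code{Surv(time, event) ~ .} over its columns.
#' @param conf confidence level for the Wald intervals.
#' @return data.frame with one row per coefficient: \code{term}, \code{hr},
#'   \code{lo}, \code{hi}, \code{p.value}; attribute \code{fit} carries the
#'   underlying \code{coxph} object.
#' @export
coxFit <- function(time, event, covariates, conf = 0.95) {
    stopifnot(is.data.frame(covariates))
    if (sum(event) < ncol(covariates))
        warning("fewer events (", sum(event), ") than covariates (",
                ncol(covariates), "): estimates may be unstable")
    dat <- cbind(data.frame(.time = time, .event = event), covariates)
    fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                           ties = "efron")
    if (any(is.na(stats::coef(fit))) || !all(is.finite(stats::coef(fit))))
        stop("Cox model did not converge cleanly; check covariates")
    z <- stats::qnorm(1 - (1 - conf) / 2)
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    out <- data.frame(term = names(co),
                      hr = exp(co),
                      lo = exp(co - z * se),
                      hi = exp(co + z * se),
                      p.value = 2 * stats::pnorm(-abs(co / se)))
    rownames(out) <- NULL
    attr(out, "fit") <- fit
    out
}
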