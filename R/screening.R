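#' Confusion-matrix metrics
#'
#' Sensitivity is TP/(TP+FN) over true cases, specificity TN/(TN+FP) over
#' true controls; a metric whose class is absent from \code{truth} is
#' \code{NA}.
#'
#' @param truth per-sample truth: \code{"case"}/\code{"control"}, or logical
#'   (TRUE = case).
#' @param predicted per-sample call: \code{"positive"}/\code{"negative"},
#'   or logical (TRUE = positive).
#' @return list with \code{sensitivity}, \code{specificity} and the counts
#'   \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @export
confusionMetrics <- function(truth, predicted) {
    if (length(truth) != length(predicted))
        stop("truth and predicted have different lengths")
    isCase <- if (is.logical(truth)) truth else as.character(truth) == "case"
    isPos <- if (is.logical(predicted)) predicted
             else as.character(predicted) == "positive"
    tp <- sum(isCase & isPos); fn <- sum(isCase & !isPos)
    fp <- sum(!isCase & isPos); tn <- sum(!isCase & !isPos)
    list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The Clopper-Pearson interval inverts the binomial tail probabilities: the
#' lower bound is the p with P(X >= x | p) = alpha/2 and the upper the p
#' with P(X <= x | p) = alpha/2, computed in closed form from beta
#' quantiles. Bounds are 0 when \code{x == 0} and 1 when \code{x == n}. A
#' Wilson score interval is available as an alternative.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @param method \code{"clopper-pearson"} (default) or \code{"wilson"}.
#' @return numeric \code{c(lower, upper)}.
#' @export
exactBinomialCI <- function(x, n, conf = 0.95,
                            method = c("clopper-pearson", "wilson")) {
    method <- match.arg(method)
    if (n < 1 || x < 0 || x > n) stop("need 0 <= x <= n, n >= 1")
    alpha <- 1 - conf
    if (method == "clopper-pearson") {
        lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
        hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
    } else {
        z <- stats::qnorm(1 - alpha / 2)
        p <- x / n
        den <- 1 + z^2 / n
        ctr <- (p + z^2 / (2 * n)) / den
        hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
        lo <- max(0, ctr - hw); hi <- min(1, ctr + hw)
    }
    c(lower = lo, upper = hi)
}

#' ROC AUC with a DeLong-style confidence interval
#'
#' AUC is the Mann-Whitney concordance probability (ties counted 1/2),
#' computed from ranks. The confidence interval uses the asymptotic variance
#' of the placement values (DeLong), truncated to [0, 1].
#'
#' @param scores numeric scores.
#' @param truth \code{"case"}/\code{"control"} or logical (TRUE = case).
#' @param conf confidence level.
#' @return list with \code{auc}, \code{ci} = \code{c(lower, upper)} and
#'   \code{se}.
#' @export
rocAuc <- function(scores, truth, conf = 0.95) {
    isCase <- if (is.logical(truth)) truth else as.character(truth) == "case"
    n1 <- sum(isCase); n0 <- sum(!isCase)
    if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
    r <- rank(scores)
    auc <- (sum(r[isCase]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    # placement values: V10_i = P(control < case_i) + P(tie)/2
    cs <- scores[isCase]; ct <- scores[!isCase]
    v10 <- vapply(cs, function(s) (sum(ct < s) + 0.5 * sum(ct == s)) / n0,
                  0.0)
    v01 <- vapply(ct, function(s) (sum(cs > s) + 0.5 * sum(cs == s)) / n1,
                  0.0)
    se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- c(lower = max(0, auc - z * se), upper = min(1, auc + z * se))
    list(auc = auc, ci = ci, se = se)
}

#' Standard pre-diagnosis time windows
#'
#' Intervals in years before diagnosis, \code{(lower, upper]}: a sample
#' exactly at a boundary belongs to the narrower, closer-to-diagnosis
#' window; a sample drawn on the day of diagnosis (0 years) counts as
#' "0-1y".
#'
#' @return data.frame with \code{label}, \code{lower}, \code{upper}.
#' @export
hccTimeWindows <- function() {
    data.frame(label = c("0-1y", "1-2y", "2-3y", "3-4y", ">4y"),
               lower = c(0, 1, 2, 3, 4),
               upper = c(1, 2, 3, 4, Inf))
}

#' Assign samples to time-to-diagnosis windows
#'
#' @param yearsBeforeDx numeric, years between sample collection and
#'   diagnosis (0 = at diagnosis).
#' @param windows window table as from \code{\link{hccTimeWindows}}.
#' @return character window labels (\code{NA} for negative times).
#' @export
assignTimeWindow <- function(yearsBeforeDx, windows = hccTimeWindows()) {
    out <- rep(NA_character_, length(yearsBeforeDx))
    for (i in seq_len(nrow(windows))) {
        inWin <- !is.na(yearsBeforeDx) &
            ((yearsBeforeDx > windows$lower[i] &
              yearsBeforeDx <= windows$upper[i]) |
             (yearsBeforeDx == 0 & windows$lower[i] == 0))
        out[inWin & is.na(out)] <- windows$label[i]
    }
    out
}

#' Per-window sensitivity with exact confidence intervals
#'
#' Sensitivity in each time-to-diagnosis window is computed over the case
#' subjects that have an aggregated score in that window (one score per
#' subject per window; see \code{\link{aggregateSubjectWindow}}).
#'
#' @param subjectWindowScores data.frame with \code{subject_id},
#'   \code{window}, \code{score} for case subjects.
#' @param cutoff score threshold (a score equal to the cutoff is positive).
#' @param windows window table (order of the output rows).
#' @param conf confidence level for the Clopper-Pearson interval.
#' @return data.frame: \code{window}, \code{n} (eligible case subjects),
#'   \code{detected}, \code{sensitivity}, \code{ci_lo}, \code{ci_hi}.
#'   Windows with no eligible subjects get \code{NA} and a warning.
#' @export
windowSensitivity <- function(subjectWindowScores, cutoff = 0.494,
                              windows = hccTimeWindows(), conf = 0.95) {
    out <- data.frame(window = windows$label, n = 0L, detected = 0L,
                      sensitivity = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_)
    for (i in seq_len(nrow(out))) {
        sel <- subjectWindowScores$window == out$window[i]
        n <- sum(sel)
        out$n[i] <- n
        if (n == 0) {
            warning("no eligible subjects in window ", out$window[i])
            next
        }
        det <- sum(subjectWindowScores$score[sel] >= cutoff)
        ci <- exactBinomialCI(det, n, conf)
        out$detected[i] <- det
        out$sensitivity[i] <- det / n
        out$ci_lo[i] <- ci[1]; out$ci_hi[i] <- ci[2]
    }
    out
}

#' Incidence rate per 100,000 person-years
#'
#' @param nEvents incident cases observed.
#' @param personYears accumulated follow-up time in years.
#' @return events per 100,000 person-years (unrounded).
#' @export
incidenceRate <- function(nEvents, personYears) {
    if (personYears <= 0) stop("person-years must be positive")
    nEvents / personYears * 1e5
}

#' Predictive values at a given prevalence
#'
#' Bayes' rule applied to a screening test:
#' \code{PPV = sens * p / (sens * p + (1 - spec) * (1 - p))} and
#' \code{NPV = spec * (1 - p) / (spec * (1 - p) + (1 - sens) * p)}. For a
#' rare outcome the annual incidence rate approximates the 1-year risk used
#' as \code{prevalence}.
#'
#' @param sensitivity,specificity,prevalence probabilities in [0, 1].
#' @return list with \code{ppv} and \code{npv}; a zero denominator yields
#'   \code{NA} with a warning.
#' @export
ppvNpv <- function(sensitivity, specificity, prevalence) {
    args <- c(sensitivity, specificity, prevalence)
    if (any(is.na(args)) || any(args < 0 | args > 1))
        stop("all arguments must lie in [0, 1]")
    pd <- sensitivity * prevalence +
        (1 - specificity) * (1 - prevalence)
    nd <- specificity * (1 - prevalence) +
        (1 - sensitivity) * prevalence
    ppv <- if (pd > 0) sensitivity * prevalence / pd else {
        warning("no positive calls at these parameters: PPV undefined")
        NA_real_
    }
    npv <- if (nd > 0) specificity * (1 - prevalence) / nd else {
        warning("no negative calls at these parameters: NPV undefined")
        NA_real_
    }
    list(ppv = ppv, npv = npv)
}

#' Per-window predictive values
#'
#' Applies \code{\link{ppvNpv}} to each window's sensitivity at a common
#' specificity and prevalence. When the sensitivity table carries
#' Clopper-Pearson bounds, PPV/NPV intervals are derived by transforming the
#' sensitivity CI endpoints through the same formula (the specificity and
#' prevalence are held fixed; the interval is labelled as
#' sensitivity-propagated).
#'
#' @param windowSens data.frame from \code{\link{windowSensitivity}}.
#' @param specificity,prevalence common operating parameters.
#' @return \code{windowSens} with added columns \code{ppv}, \code{npv} and,
#'   when CI columns are present, \code{ppv_lo}, \code{ppv_hi},
#'   \code{npv_lo}, \code{npv_hi}.
#' @export
ppvNpvByWindow <- function(windowSens, specificity, prevalence) {
    out <- windowSens
    out$ppv <- out$npv <- NA_real_
    hasCI <- all(c("ci_lo", "ci_hi") %in% colnames(windowSens))
    if (hasCI) out$ppv_lo <- out$ppv_hi <- out$npv_lo <- out$npv_hi <-
        NA_real_
    for (i in seq_len(nrow(out))) {
        s <- out$sensitivity[i]
        if (is.na(s)) next
        pv <- ppvNpv(s, specificity, prevalence)
        out$ppv[i] <- pv$ppv; out$npv[i] <- pv$npv
        if (hasCI && !is.na(out$ci_lo[i])) {
            lo <- ppvNpv(out$ci_lo[i], specificity, prevalence)
            hi <- ppvNpv(out$ci_hi[i], specificity, prevalence)
            out$ppv_lo[i] <- lo$ppv; out$ppv_hi[i] <- hi$ppv
            # NPV decreases as sensitivity decreases
            out$npv_lo[i] <- lo$npv; out$npv_hi[i] <- hi$npv
        }
    }
    out
}

#' Assemble a screening report
#'
#' Combines the control-side operating point, per-window case sensitivity
#' and incidence-based predictive values into one report list.
#'
#' @param caseWindowScores aggregated case subject-window scores
#'   (\code{subject_id}, \code{window}, \code{score}).
#' @param controlScores one aggregated score per control subject.
#' @param cutoff score threshold.
#' @param incidencePer100k annual incidence per 100,000 person-years, used
#'   as the (rare-disease) 1-year prevalence.
#' @param windows window table.
#' @param conf confidence level.
#' @return list of class \code{ScreeningReport}: \code{specificity} (with
#'   counts and CI), \code{windows} (sensitivity + PPV/NPV table),
#'   \code{cutoff}, \code{prevalence}.
#' @export
screeningReport <- function(caseWindowScores, controlScores, cutoff = 0.494,
                            incidencePer100k = 382,
                            windows = hccTimeWindows(), conf = 0.95) {
    fp <- sum(controlScores >= cutoff)
    nC <- length(controlScores)
    spec <- (nC - fp) / nC
    specCI <- exactBinomialCI(nC - fp, nC, conf)
    prev <- incidencePer100k / 1e5
    ws <- windowSensitivity(caseWindowScores, cutoff, windows, conf)
    tab <- ppvNpvByWindow(ws, spec, prev)
    structure(list(
        specificity = list(value = spec, n = nC, misclassified = fp,
                           ci = specCI),
        windows = tab, cutoff = cutoff, prevalence = prev),
        class = "ScreeningReport")
}

#' @export
print.ScreeningReport <- function(x, ...) {
    cat(sprintf("Screening report (cutoff %.3f, prevalence %.5f)\n",
                x$cutoff, x$prevalence))
    cat(sprintf("Specificity: %.1f%% (%d/%d controls negative; 95%% CI %.1f-%.1f%%)\n",
                100 * x$specificity$value,
                x$specificity$n - x$specificity$misclassified,
                x$specificity$n, 100 * x$specificity$ci[1],
                100 * x$specificity$ci[2]))
    print(x$windows, row.names = FALSE)
    invisible(x)
}
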