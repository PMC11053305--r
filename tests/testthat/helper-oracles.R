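# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# AUC as exhaustive pairwise concordance (ties count 1/2)
bruteAuc <- function(scores, isCase) {
  cs <- scores[isCase]; ct <- scores[!isCase]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Clopper-Pearson bounds from the defining binomial tail conditions:
# coarse grid scan to bracket, then bisection on the tail probability.
bruteExactCI <- function(x, n, conf = 0.95) {
  alpha <- 1 - conf
  lowerTail <- function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE)
  upperTail <- function(p) stats::pbinom(x, n, p)
  solveFor <- function(f, target) {
    ps <- seq(0, 1, by = 1e-4)
    v <- f(ps)
    i <- max(which(v <= target))
    lo <- ps[i]; hi <- ps[min(i + 1, length(ps))]
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) <= target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lo <- if (x == 0) 0 else solveFor(lowerTail, alpha / 2)
  hi <- if (x == n) 1 else 1 - solveFor(function(p) upperTail(1 - p),
                                        alpha / 2)
  c(lo, hi)
}

# Kaplan-Meier as a direct product over risk sets
bruteKm <- function(time, event) {
  tt <- sort(unique(time))
  s <- 1
  out <- data.frame(time = tt, surv = NA_real_)
  for (i in seq_along(tt)) {
    atRisk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / atRisk)
    out$surv[i] <- s
  }
  out
}

# per-bin short/total counting as a naive double loop
naiveProfileCounts <- function(fragments, binsDf, sizeLo = 100,
                               sizeHi = 167, lengthCap = 1000) {
  nb <- nrow(binsDf)
  short <- total <- integer(nb)
  for (i in seq_len(nrow(fragments))) {
    len <- fragments$end[i] - fragments$start[i]
    if (len < 1 || len > lengthCap) next
    mid <- fragments$start[i] + floor(len / 2)
    for (b in seq_len(nb)) {
      if (fragments$chrom[i] == binsDf$chrom[b] &&
          mid >= binsDf$start[b] && mid < binsDf$end[b]) {
        total[b] <- total[b] + 1L
        if (len >= sizeLo && len <= sizeHi) short[b] <- short[b] + 1L
        break
      }
    }
  }
  list(short = short, total = total)
}

# Cox partial likelihood for untied data, maximized numerically
brutePartialLogLik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

binsAsDf <- function(binset) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(binset)),
             start = GenomicRanges::start(binset) - 1,
             end = GenomicRanges::end(binset),
             label = binLabels(binset))
}

# best two-group label agreement over the two possible matchings
twoGroupAgreement <- function(pred, truth) {
  pred <- as.integer(as.factor(pred)); truth <- as.integer(as.factor(truth))
  max(mean(pred == truth), mean(pred == 3 - truth))
}
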