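#' Configuration for a synthetic cfDNA screening cohort
#'
#' Bundles every latent parameter of the generator. The defaults describe a
#' compact but realistic shallow-WGS screening study: a 504-window genome,
#' ~1e5 fragments per sample, a per-bin baseline short-fragment proportion
#' around 0.2, five tumour-affected windows with case/control enrichment
#' drawn from the empirically observed 1.50-2.38 range, a tumour signal that
#' doubles every 4.6 months as diagnosis approaches, and survival linked to
#' the latent tumour burden with a high-vs-low hazard ratio of 2.41.
#'
#' @param seed integer RNG seed; identical seed + config give byte-identical
#'   cohorts.
#' @param nCases,nControls subjects per class.
#' @param nBins number of analysis windows (504 genome-wide; use ~50 for
#'   quick simulations).
#' @param nArms synthetic chromosome arms the bins are spread over.
#' @param binSpan window span in bases.
#' @param fragmentsPerSample mean fragments per sample;
#'   \code{fragmentsCv} is its coefficient of variation (Gamma-Poisson).
#' @param fragmentsCv see above.
#' @param p0Mean,p0Sd baseline short-fragment proportion: per-bin values are
#'   drawn once per cohort from N(p0Mean, p0Sd), truncated to [0.01, 0.9].
#' @param nAffected number of tumour-affected bins.
#' @param affectedBins explicit affected bin indices (overrides
#'   \code{nAffected}).
#' @param enrichment per-affected-bin case/control enrichment ratio r >= 1;
#'   scalar recycled, or \code{NULL} to draw each from U(1.50, 2.38).
#' @param tumorFraction tumour fraction tau in [0, 1] at diagnosis.
#' @param tumorFractionSdLog between-subject log-normal spread of tau.
#' @param doublingTimeMonths tumour volume doubling time; the effective
#'   tumour fraction of a sample drawn t months before diagnosis is
#'   \code{tau * 2^(-t / doublingTimeMonths)}.
#' @param samplingTimesYears case sampling times in years before diagnosis
#'   (0 = at diagnosis, the clinical-cohort condition; a vector gives
#'   longitudinal pre-diagnosis samples).
#' @param controlTimesYears control sampling times (default: matched to
#'   cases).
#' @param survBaselineMedianMonths median survival of the low-burden group.
#' @param survHR hazard ratio of the high- vs low-burden group.
#' @param capMonths administrative censoring cap.
#' @param qcFailFraction fraction of samples given sub-threshold fragment
#'   counts to exercise the depth QC filter.
#' @param minFragments QC depth threshold accompanying the cohort.
#' @return validated list of class \code{CohortConfig}.
#' @export
cohortConfig <- function(seed = 1L, nCases = 30, nControls = 30,
                         nBins = 504, nArms = 5, binSpan = 5e6,
                         fragmentsPerSample = 1e5, fragmentsCv = 0.05,
                         p0Mean = 0.2, p0Sd = 0.02,
                         nAffected = 5, affectedBins = NULL,
                         enrichment = NULL,
                         tumorFraction = 0.5, tumorFractionSdLog = 0.2,
                         doublingTimeMonths = 4.6,
                         samplingTimesYears = 0, controlTimesYears = NULL,
                         survBaselineMedianMonths = 30, survHR = 2.41,
                         capMonths = 36, qcFailFraction = 0,
                         minFragments = 5e4) {
    cfg <- list(seed = as.integer(seed), nCases = nCases,
                nControls = nControls, nBins = nBins, nArms = nArms,
                binSpan = binSpan, fragmentsPerSample = fragmentsPerSample,
                fragmentsCv = fragmentsCv, p0Mean = p0Mean, p0Sd = p0Sd,
                nAffected = nAffected, affectedBins = affectedBins,
                enrichment = enrichment, tumorFraction = tumorFraction,
                tumorFractionSdLog = tumorFractionSdLog,
                doublingTimeMonths = doublingTimeMonths,
                samplingTimesYears = samplingTimesYears,
                controlTimesYears = if (is.null(controlTimesYears))
                    samplingTimesYears else controlTimesYears,
                survBaselineMedianMonths = survBaselineMedianMonths,
                survHR = survHR, capMonths = capMonths,
                qcFailFraction = qcFailFraction,
                minFragments = minFragments)
    with(cfg, {
        stopifnot(nBins >= 1, nArms >= 1, nCases >= 0, nControls >= 0,
                  tumorFraction >= 0, tumorFraction <= 1,
                  p0Mean > 0, p0Mean < 1,
                  qcFailFraction >= 0, qcFailFraction <= 1,
                  doublingTimeMonths > 0, survHR > 0,
                  all(samplingTimesYears >= 0))
        if (!is.null(enrichment) && any(enrichment < 1))
            stop("enrichment ratios must be >= 1")
    })
    if (!is.null(cfg$affectedBins))
        cfg$nAffected <- length(cfg$affectedBins)
    structure(cfg, class = "CohortConfig")
}

#' Build the synthetic genome's bin set
#'
#' \code{nBins} consecutive windows of \code{binSpan} bases, distributed as
#' evenly as possible over \code{nArms} single-arm chromosomes, with global
#' sequential labels (\code{1q_1 ... }).
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return a \code{\link{BinSet}}.
#' @export
makeBinSet <- function(config) {
    n <- config$nBins; a <- min(config$nArms, n)
    perArm <- rep(n %/% a, a) + c(rep(1, n %% a), rep(0, a - n %% a))
    chrom <- rep(paste0("chr", seq_len(a)), perArm)
    arm <- rep(paste0(seq_len(a), "q"), perArm)
    off <- unlist(lapply(perArm, seq_len)) - 1
    gr <- GRanges(chrom,
                  IRanges(start = off * config$binSpan + 1,
                          width = config$binSpan),
                  arm = arm,
                  n_source_bins = as.integer(config$binSpan / 1e5))
    gr <- sortSeqlevels(gr)
    gr <- gr[order(as.integer(seqnames(gr)), start(gr))]
    mcols(gr)$label <- paste0(mcols(gr)$arm, "_", seq_along(gr))
    BinSet(gr, genomeBuild = "synthetic")
}

#' Synthetic 100-kb source bins (fixture for the binning readers)
#'
#' @param nArms arms; \code{binsPerArm} consecutive 100-kb bins each.
#' @param binsPerArm bins per arm.
#' @param binWidth source bin width (default 1e5).
#' @param path optional BED4 file to write (tab-separated, 0-based).
#' @return data.frame \code{chrom}, \code{start}, \code{end}, \code{arm}.
#' @export
makeSourceBins <- function(nArms = 3, binsPerArm = 50, binWidth = 1e5,
                           path = NULL) {
    df <- do.call(rbind, lapply(seq_len(nArms), function(a) {
        data.frame(chrom = paste0("chr", a),
                   start = (seq_len(binsPerArm) - 1) * binWidth,
                   end = seq_len(binsPerArm) * binWidth,
                   arm = paste0(a, "q"))
    }))
    if (!is.null(path))
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    df
}

#' Draw the cohort-level latent parameters
#'
#' Per-bin baseline proportions p0, the affected-bin set and per-bin
#' enrichment ratios, drawn deterministically from \code{config$seed} (the
#' draw happens inside \code{\link{makeCohort}}; call this directly only for
#' stand-alone use of \code{\link{sampleProfileCounts}}).
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return list with \code{p0} (length nBins), \code{affected} (indices) and
#'   \code{r} (length nBins; 1 outside affected bins).
#' @export
cohortLatents <- function(config) {
    p0 <- pmin(pmax(stats::rnorm(config$nBins, config$p0Mean, config$p0Sd),
                    0.01), 0.9)
    affected <- if (!is.null(config$affectedBins))
        sort(config$affectedBins)
    else sort(sample.int(config$nBins, min(config$nAffected, config$nBins)))
    r <- rep(1, config$nBins)
    r[affected] <- if (is.null(config$enrichment))
        stats::runif(length(affected), 1.50, 2.38)
    else rep_len(config$enrichment, length(affected))
    list(p0 = p0, affected = affected, r = r)
}

#' Simulate one sample's per-bin fragment counts
#'
#' The effective tumour fraction decays exponentially with time before
#' diagnosis, \code{tauEff = tau * 2^(-months / doublingTimeMonths)}. The
#' per-bin short-fragment probability is
#' \code{p0 * (1 + (r - 1) * tauEff)} in affected bins (clipped to [0, 1])
#' and \code{p0} elsewhere, so at \code{tauEff = 1} the expected
#' case/control proportion ratio equals r. Total counts are multinomial
#' over bins (uniform spans); short counts are binomial.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param latents from \code{\link{cohortLatents}}.
#' @param isCase logical; controls have \code{tauEff = 0}.
#' @param timeBeforeDxYears sample collection time before diagnosis.
#' @param tau subject-level tumour fraction (default
#'   \code{config$tumorFraction}).
#' @param nFragments override the drawn fragment total.
#' @return list with \code{short}, \code{total} (integer vectors),
#'   \code{tauEff} and \code{p} (per-bin short probability used).
#' @export
sampleProfileCounts <- function(config, latents, isCase,
                                timeBeforeDxYears = 0,
                                tau = config$tumorFraction,
                                nFragments = NULL) {
    if (is.na(tau) || tau < 0 || tau > 1)
        stop("tumour fraction must lie in [0, 1]")
    tauEff <- if (isCase)
        tau * 2^(-(timeBeforeDxYears * 12) / config$doublingTimeMonths)
    else 0
    p <- latents$p0 * (1 + (latents$r - 1) * tauEff)
    p <- pmin(pmax(p, 0), 1)
    if (is.null(nFragments)) {
        size <- 1 / config$fragmentsCv^2
        nFragments <- stats::rnbinom(1, size = size,
                                     mu = config$fragmentsPerSample)
    }
    total <- as.integer(stats::rmultinom(1, nFragments,
                                         rep(1, config$nBins))[, 1])
    short <- stats::rbinom(config$nBins, total, p)
    list(short = short, total = total, tauEff = tauEff, p = p)
}

#' Write a sample's fragments as a BED file
#'
#' Materializes per-bin (short, total) counts as individual fragments:
#' short-class lengths uniform on [100, 167]; the remainder drawn from the
#' upper shoulder of the mononucleosome peak (normal, mean 167, sd 10,
#' truncated to >= 168 so that programmed short counts are exactly
#' recoverable); positions uniform within the bin. A configurable fraction
#' of decoy fragments with out-of-class lengths and sub-threshold mapping
#' quality is appended to exercise the MAPQ filter. Output columns:
#' chrom, start, end, name, mapq (BED5, 0-based half-open).
#'
#' @param short,total per-bin counts (as from
#'   \code{\link{sampleProfileCounts}}).
#' @param binset the \code{\link{BinSet}}.
#' @param path output BED path; \code{NULL} returns the data.frame instead.
#' @param decoyFraction decoys as a fraction of real fragments.
#' @param decoyMapq mapping quality assigned to decoys (default 10).
#' @param mapq mapping quality of real fragments (default 60).
#' @return the path (invisibly), or the fragment data.frame when
#'   \code{path = NULL}.
#' @export
emitFragments <- function(short, total, binset, path = NULL,
                          decoyFraction = 0, decoyMapq = 10, mapq = 60) {
    stopifnot(is(binset, "BinSet"), length(short) == length(binset),
              length(total) == length(binset), all(short <= total))
    bStart0 <- start(binset) - 1L
    bEnd <- end(binset)
    chroms <- as.character(seqnames(binset))
    pieces <- vector("list", length(binset))
    for (b in seq_along(binset)) {
        nS <- short[b]; nL <- total[b] - short[b]
        if (nS + nL == 0) next
        lenS <- if (nS > 0) sample(100:167, nS, replace = TRUE) else integer(0)
        lenL <- if (nL > 0) truncNormLengths(nL, 167, 10, 168) else integer(0)
        len <- c(lenS, lenL)
        st <- bStart0[b] +
            floor(stats::runif(nS + nL, 0, bEnd[b] - bStart0[b] - len))
        pieces[[b]] <- data.frame(chrom = chroms[b], start = st,
                                  end = st + len, mapq = mapq)
    }
    frags <- do.call(rbind, pieces)
    if (is.null(frags))
        frags <- data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0), mapq = numeric(0))
    nDecoy <- round(decoyFraction * nrow(frags))
    if (nDecoy > 0) {
        b <- sample.int(length(binset), nDecoy, replace = TRUE)
        len <- sample(c(60, 80, 250, 300), nDecoy, replace = TRUE)
        st <- bStart0[b] + floor(stats::runif(nDecoy, 0,
                                              bEnd[b] - bStart0[b] - len))
        frags <- rbind(frags, data.frame(chrom = chroms[b], start = st,
                                         end = st + len, mapq = decoyMapq))
    }
    frags <- frags[order(frags$chrom, frags$start), , drop = FALSE]
    rownames(frags) <- NULL
    frags$name <- sprintf("frag%07d", seq_len(nrow(frags)))
    frags <- frags[, c("chrom", "start", "end", "name", "mapq")]
    if (is.null(path)) return(frags)
    data.table::fwrite(frags, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

truncNormLengths <- function(n, mean, sd, lo) {
    out <- integer(0)
    while (length(out) < n) {
        cand <- round(stats::rnorm(2 * (n - length(out)) + 10, mean, sd))
        out <- c(out, cand[cand >= lo])
    }
    out[seq_len(n)]
}

#' Generate a complete synthetic screening cohort
#'
#' Cases get one sample per configured pre-diagnosis time with tumour
#' signal growing toward diagnosis (exponential growth at the configured
#' doubling time); controls are sampled at matched times with no tumour
#' signal. A configurable fraction of samples is given sub-threshold depth.
#' Case subjects receive exponential survival times whose hazard is
#' multiplied by \code{survHR} for the high tumour-burden half, then
#' administratively censored at \code{capMonths}. Every latent parameter is
#' recorded in \code{$truth}.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param dir optional output directory; when given, writes
#'   \code{bins.tsv}, \code{profile_matrix.tsv}, \code{metadata.csv},
#'   \code{survival.csv}, \code{truth.json} (and \code{config.yaml} when the
#'   yaml package is available).
#' @param writeFragments also write one fragment BED per sample under
#'   \code{dir/fragments/} (requires \code{dir}).
#' @param decoyFraction decoy fraction passed to
#'   \code{\link{emitFragments}}.
#' @return list of class \code{SyntheticCohort}: \code{binset},
#'   \code{profiles} (a \code{\link{FragProfileSet}}), \code{metadata},
#'   \code{survival}, \code{truth}, \code{config}.
#' @export
makeCohort <- function(config, dir = NULL, writeFragments = FALSE,
                       decoyFraction = 0) {
    stopifnot(inherits(config, "CohortConfig"))
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(config$seed)

    binset <- makeBinSet(config)
    lat <- cohortLatents(config)

    subj <- data.frame(
        subject_id = c(sprintf("case%03d", seq_len(config$nCases)),
                       sprintf("ctrl%03d", seq_len(config$nControls))),
        label = rep(c("case", "control"),
                    c(config$nCases, config$nControls)))
    subj$tau <- ifelse(subj$label == "case",
        pmin(1, config$tumorFraction *
                 exp(stats::rnorm(nrow(subj), 0,
                                  config$tumorFractionSdLog))), 0)
    subj$age <- round(stats::rnorm(nrow(subj), 55, 8))
    subj$sex <- sample(c("M", "F"), nrow(subj), replace = TRUE,
                       prob = c(0.85, 0.15))
    subj$bclc <- ifelse(subj$label == "case",
                        sample(c("0/A", "B/C"), nrow(subj), replace = TRUE),
                        NA)
    subj$afp <- ifelse(subj$label == "case",
                       sample(c("positive", "negative"), nrow(subj),
                              replace = TRUE, prob = c(0.4, 0.6)),
                       "negative")

    times <- lapply(seq_len(nrow(subj)), function(i)
        if (subj$label[i] == "case") config$samplingTimesYears
        else config$controlTimesYears)
    meta <- do.call(rbind, lapply(seq_len(nrow(subj)), function(i) {
        tt <- times[[i]]
        data.frame(sample_id = paste0(subj$subject_id[i], "_t",
                                      seq_along(tt)),
                   subject_id = subj$subject_id[i],
                   label = subj$label[i],
                   time_before_dx_years = tt,
                   age = subj$age[i], sex = subj$sex[i],
                   bclc = subj$bclc[i], afp = subj$afp[i])
    }))
    meta$window <- assignTimeWindow(meta$time_before_dx_years)

    nS <- nrow(meta)
    qcFail <- rep(FALSE, nS)
    if (config$qcFailFraction > 0)
        qcFail[sample.int(nS, round(config$qcFailFraction * nS))] <- TRUE
    shortM <- totalM <- matrix(0L, config$nBins, nS)
    tauEff <- numeric(nS)
    for (i in seq_len(nS)) {
        subjTau <- subj$tau[match(meta$subject_id[i], subj$subject_id)]
        nf <- NULL
        if (qcFail[i])
            nf <- round(stats::runif(1, 0.2, 0.8) * config$minFragments)
        sc <- sampleProfileCounts(config, lat,
                                  isCase = meta$label[i] == "case",
                                  timeBeforeDxYears =
                                      meta$time_before_dx_years[i],
                                  tau = subjTau, nFragments = nf)
        shortM[, i] <- sc$short; totalM[, i] <- sc$total
        tauEff[i] <- sc$tauEff
    }
    profiles <- profileSetFromCounts(shortM, totalM, binset,
                                     sampleIds = meta$sample_id)
    profiles <- qcFilter(profiles, config$minFragments)

    cases <- subj[subj$label == "case", , drop = FALSE]
    surv <- NULL
    if (nrow(cases) >= 2) {
        highGroup <- cases$tau >= stats::median(cases$tau)
        lam0 <- log(2) / config$survBaselineMedianMonths
        rate <- lam0 * ifelse(highGroup, config$survHR, 1)
        t <- stats::rexp(nrow(cases), rate)
        cs <- capFollowup(t, rep(1L, nrow(cases)), config$capMonths)
        surv <- data.frame(subject_id = cases$subject_id,
                           time_months = cs$time, event = cs$event,
                           burden_group = ifelse(highGroup, "high", "low"),
                           age = cases$age, sex = cases$sex,
                           bclc = cases$bclc, afp = cases$afp)
    }

    truth <- list(p0 = lat$p0,
                  affected_bins = binLabels(binset)[lat$affected],
                  affected_idx = lat$affected,
                  enrichment = lat$r[lat$affected],
                  subject_tau = stats::setNames(subj$tau, subj$subject_id),
                  sample_tau_eff = stats::setNames(tauEff, meta$sample_id),
                  qc_fail = stats::setNames(qcFail, meta$sample_id),
                  seed = config$seed)

    out <- structure(list(binset = binset, profiles = profiles,
                          metadata = meta, survival = surv, truth = truth,
                          config = config), class = "SyntheticCohort")
    if (!is.null(dir)) writeCohort(out, dir, writeFragments, decoyFraction)
    out
}

writeCohort <- function(cohort, dir, writeFragments = FALSE,
                        decoyFraction = 0) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeBinManifest(cohort$binset, file.path(dir, "bins.tsv"))
    m <- proportionMatrix(cohort$profiles)
    utils::write.table(
        data.frame(sample_id = rownames(m), m, check.names = FALSE),
        file.path(dir, "profile_matrix.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                     row.names = FALSE)
    if (!is.null(cohort$survival))
        utils::write.csv(cohort$survival, file.path(dir, "survival.csv"),
                         row.names = FALSE)
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (requireNamespace("yaml", quietly = TRUE))
        yaml::write_yaml(unclass(cohort$config)[
            !vapply(unclass(cohort$config), is.null, TRUE)],
            file.path(dir, "config.yaml"))
    if (writeFragments) {
        fd <- file.path(dir, "fragments")
        dir.create(fd, showWarnings = FALSE)
        sh <- shortCounts(cohort$profiles)
        tot <- totalCounts(cohort$profiles)
        for (s in colnames(sh))
            emitFragments(sh[, s], tot[, s], cohort$binset,
                          file.path(fd, paste0(s, ".bed")),
                          decoyFraction = decoyFraction)
    }
    invisible(dir)
}
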