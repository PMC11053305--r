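#' Read cfDNA fragments from a fragment BED or a paired-end BAM
#'
#' One record per sequenced fragment. For a BAM, fragments are taken from
#' properly paired primary alignments via the pair's outer coordinates (the
#' leftmost mate's position plus the template length); for a BED, one
#' fragment per line (columns \code{chrom}, \code{start}, \code{end}
#' 0-based half-open, optional 4th name and 5th mapping-quality column).
#' Records with mapping quality below \code{mapqMin} are dropped; records
#' with non-positive length are skipped with a warning counter. BED records
#' without a quality column are treated as passing.
#'
#' @param path fragment BED (".bed", optionally gzipped) or coordinate-sorted
#'   indexed BAM (".bam").
#' @param mapqMin minimum mapping quality retained (default 30).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{length}, \code{mapq}; attributes
#'   \code{n_dropped_mapq} and \code{n_skipped} record filter counts.
#' @export
readFragments <- function(path, mapqMin = 30) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (grepl("\\.bam$", path, ignore.case = TRUE)) {
        frags <- readFragmentsBam(path)
    } else {
        dt <- data.table::fread(path, header = FALSE, sep = "\t",
                                data.table = FALSE)
        if (ncol(dt) < 3) stop("fragment BED needs >= 3 columns: ", path)
        frags <- data.frame(chrom = as.character(dt[[1]]),
                            start = as.numeric(dt[[2]]),
                            end = as.numeric(dt[[3]]))
        frags$mapq <- if (ncol(dt) >= 5 && is.numeric(dt[[5]]))
            as.numeric(dt[[5]]) else NA_real_
    }
    frags$length <- frags$end - frags$start
    nSkip <- sum(frags$length < 1)
    if (nSkip > 0) {
        warning(nSkip, " fragment(s) with non-positive length skipped")
        frags <- frags[frags$length >= 1, , drop = FALSE]
    }
    keep <- is.na(frags$mapq) | frags$mapq >= mapqMin
    nDrop <- sum(!keep)
    frags <- frags[keep, , drop = FALSE]
    rownames(frags) <- NULL
    attr(frags, "n_dropped_mapq") <- nDrop
    attr(frags, "n_skipped") <- nSkip
    frags
}

readFragmentsBam <- function(path) {
    flag <- Rsamtools::scanBamFlag(isProperPair = TRUE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag,
        what = c("rname", "pos", "isize", "mapq"))
    b <- Rsamtools::scanBam(path, param = param)[[1]]
    keep <- !is.na(b$isize) & b$isize > 0   # leftmost mate only
    data.frame(chrom = as.character(b$rname)[keep],
               start = b$pos[keep] - 1,
               end = b$pos[keep] - 1 + b$isize[keep],
               mapq = as.numeric(b$mapq[keep]))
}

#' Compute a sample's per-bin short-fragment proportion profile
#'
#' For each analysis window, the feature is the number of fragments with
#' length in the inclusive short window \code{[sizeLo, sizeHi]} (default
#' 100-167 nt) divided by the total number of fragments of all retained
#' sizes in that window. Fragments longer than \code{lengthCap} are treated
#' as artifacts and excluded from both counts. Bins with no fragments get a
#' missing proportion. Coverage fluctuation is absorbed by the within-bin
#' ratio; no GC correction is applied.
#'
#' @param fragments data.frame from \code{\link{readFragments}} (needs
#'   \code{chrom}, \code{start}, \code{end}; \code{length} derived if
#'   absent).
#' @param binset a \code{\link{BinSet}}.
#' @param sampleId sample identifier stored in \code{colData}.
#' @param sizeLo,sizeHi inclusive short-fragment window in nucleotides.
#' @param lengthCap fragments longer than this are dropped (default 1000).
#' @return a one-sample \code{\link{FragProfileSet}}. With no usable
#'   fragments the profile has all-missing proportions and
#'   \code{qc_pass = FALSE}.
#' @export
computeProfile <- function(fragments, binset, sampleId = "sample",
                           sizeLo = 100, sizeHi = 167, lengthCap = 1000) {
    stopifnot(is(binset, "BinSet"))
    if (length(binset) == 0) stop("empty bin set")
    if (is.null(fragments$length))
        fragments$length <- fragments$end - fragments$start
    fragments <- fragments[fragments$length >= 1 &
                           fragments$length <= lengthCap, , drop = FALSE]
    labs <- binLabels(binset)
    shortv <- totalv <- setNames(integer(length(labs)), labs)
    if (nrow(fragments) > 0) {
        hit <- assignBin(fragments, binset)
        ok <- !is.na(hit)
        if (any(ok)) {
            tt <- table(factor(hit[ok], levels = labs))
            totalv[] <- as.integer(tt)
            isShort <- ok & fragments$length >= sizeLo &
                fragments$length <= sizeHi
            ts <- table(factor(hit[isShort], levels = labs))
            shortv[] <- as.integer(ts)
        }
    }
    profileSetFromCounts(matrix(shortv, ncol = 1),
                         matrix(totalv, ncol = 1),
                         binset, sampleIds = sampleId)
}

#' Assemble a FragProfileSet from count matrices
#'
#' @param short,total bins x samples integer matrices of short-fragment and
#'   all-fragment counts.
#' @param binset the \code{\link{BinSet}} describing the rows.
#' @param sampleIds sample identifiers (columns).
#' @return a \code{\link{FragProfileSet}}; proportions are \code{NA} where
#'   \code{total == 0}, and samples with zero fragments get
#'   \code{qc_pass = FALSE} up front.
#' @export
profileSetFromCounts <- function(short, total, binset, sampleIds = NULL) {
    stopifnot(is(binset, "BinSet"))
    short <- as.matrix(short); total <- as.matrix(total)
    if (!all(dim(short) == dim(total)))
        stop("short and total dimensions differ")
    if (nrow(short) != length(binset))
        stop("count rows (", nrow(short), ") != bins (", length(binset), ")")
    if (is.null(sampleIds))
        sampleIds <- colnames(short)
    if (is.null(sampleIds))
        sampleIds <- paste0("sample", seq_len(ncol(short)))
    prop <- ifelse(total > 0, short / total, NA_real_)
    dimnames(short) <- dimnames(total) <- dimnames(prop) <-
        list(binLabels(binset), sampleIds)
    nTot <- colSums(total)
    cd <- DataFrame(sample_id = sampleIds,
                    n_fragments_total = nTot,
                    qc_pass = ifelse(nTot == 0, FALSE, NA),
                    row.names = sampleIds)
    se <- SummarizedExperiment(
        assays = list(short = short, total = total, proportion = prop),
        rowRanges = as(binset, "GRanges"), colData = cd)
    new("FragProfileSet", se)
}

#' Apply the sequencing-depth QC filter
#'
#' A sample passes QC when its total retained fragment count is at least
#' \code{minFragments} (default 5e6, the usual shallow-WGS threshold; scale
#' it down for small simulated cohorts).
#'
#' @param x a \code{\link{FragProfileSet}}.
#' @param minFragments minimum fragments per sample; \code{0} disables the
#'   filter.
#' @return \code{x} with \code{colData(x)$qc_pass} filled in.
#' @export
qcFilter <- function(x, minFragments = 5e6) {
    stopifnot(is(x, "FragProfileSet"))
    colData(x)$qc_pass <- colData(x)$n_fragments_total >= minFragments
    x
}

#' @rdname qcFilter
#' @return \code{qcPass} returns the named logical QC vector.
#' @export
qcPass <- function(x) setNames(colData(x)$qc_pass, colnames(x))

#' Extract the samples x bins proportion matrix
#'
#' @param x a \code{\link{FragProfileSet}}.
#' @param imputeMissing replace a sample's missing (zero-coverage) bins with
#'   that sample's mean observed proportion — neutral under row-centering
#'   and required before modeling.
#' @return numeric matrix, samples in rows, bins in columns.
#' @export
proportionMatrix <- function(x, imputeMissing = FALSE) {
    stopifnot(is(x, "FragProfileSet"))
    m <- t(assay(x, "proportion"))
    if (imputeMissing && anyNA(m)) {
        rm <- rowMeans(m, na.rm = TRUE)
        idx <- which(is.na(m), arr.ind = TRUE)
        m[idx] <- rm[idx[, 1]]
    }
    m
}

#' @rdname proportionMatrix
#' @export
shortCounts <- function(x) assay(x, "short")

#' @rdname proportionMatrix
#' @export
totalCounts <- function(x) assay(x, "total")

#' Row-center a profile matrix
#'
#' Subtracts each sample's mean proportion from its bins, the normalization
#' used to display fragmentation profiles on a common scale. For a
#' \code{FragProfileSet} the result is stored as a \code{centered} assay and
#' flagged in \code{metadata}.
#'
#' @param x samples x bins matrix, or a \code{\link{FragProfileSet}}.
#' @return same type as the input, centered (matrix rows sum to zero).
#' @export
setGeneric("centerRows", function(x) standardGeneric("centerRows"))

#' @rdname centerRows
#' @export
setMethod("centerRows", "matrix", function(x) {
    allNA <- rowSums(!is.na(x)) == 0
    if (any(allNA))
        stop("sample(s) with all-missing proportions: ",
             paste(rownames(x)[allNA], collapse = ", "))
    out <- sweep(x, 1, rowMeans(x, na.rm = TRUE))
    attr(out, "centered") <- TRUE
    out
})

#' @rdname centerRows
#' @export
setMethod("centerRows", "FragProfileSet", function(x) {
    m <- centerRows(proportionMatrix(x, imputeMissing = TRUE))
    attr(m, "centered") <- NULL
    assay(x, "centered", withDimnames = TRUE) <- t(m)
    metadata(x)$centered <- TRUE
    x
})

#' Per-bin case/control proportion ratio
#'
#' Ratio of the mean uncentered short-fragment proportion among cases to
#' that among controls, per bin — in diseased cohorts the hallmark is a
#' ratio above 1 in tumour-affected windows.
#'
#' @param x samples x bins matrix or \code{\link{FragProfileSet}}.
#' @param labels per-sample class vector with values \code{"case"} /
#'   \code{"control"}.
#' @return named numeric of length \code{n_bins}; \code{NA} (with a warning)
#'   where the control mean is zero.
#' @export
caseControlRatio <- function(x, labels) {
    m <- if (is(x, "FragProfileSet")) proportionMatrix(x) else as.matrix(x)
    labels <- as.character(labels)
    if (length(labels) != nrow(m))
        stop("labels length != number of samples")
    if (!any(labels == "case") || !any(labels == "control"))
        stop("both 'case' and 'control' samples are required")
    mc <- colMeans(m[labels == "case", , drop = FALSE], na.rm = TRUE)
    m0 <- colMeans(m[labels == "control", , drop = FALSE], na.rm = TRUE)
    zero <- !is.na(m0) & m0 == 0
    if (any(zero))
        warning(sum(zero), " bin(s) with zero control mean: ratio set to NA")
    r <- mc / m0
    r[zero] <- NA_real_
    r
}

#' Hierarchical clustering of fragmentation profiles
#'
#' Agglomerative clustering of row-centered profiles (Euclidean distance,
#' Ward linkage by default) with a two-group cut, used to assess whether
#' fragmentation alone separates cases from controls.
#'
#' @param x samples x bins matrix or \code{\link{FragProfileSet}}.
#' @param method linkage passed to \code{\link[stats]{hclust}}.
#' @param center row-center before clustering (default TRUE).
#' @return list with \code{hclust} (the tree), \code{order} (leaf order) and
#'   \code{groups} (two-group cut labels, named by sample).
#' @export
clusterSamples <- function(x, method = "ward.D2", center = TRUE) {
    m <- if (is(x, "FragProfileSet"))
        proportionMatrix(x, imputeMissing = TRUE) else as.matrix(x)
    if (nrow(m) < 2) stop("clustering needs at least 2 samples")
    if (center) m <- centerRows(m)
    hc <- stats::hclust(stats::dist(m), method = method)
    list(hclust = hc, order = hc$order,
         groups = stats::cutree(hc, k = 2))
}
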