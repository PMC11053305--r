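#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom GenomeInfoDb sortSeqlevels seqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- rowRanges colData colData<-
#' @importFrom stats setNames
NULL

#' BinSet: genome-wide analysis windows
#'
#' A \code{BinSet} is a \link[GenomicRanges]{GRanges} of non-overlapping,
#' coordinate-sorted genomic windows (typically ~5 Mb, merged from 100-kb
#' source bins on non-acrocentric autosome arms). Metadata columns:
#' \describe{
#'   \item{\code{arm}}{chromosome arm, e.g. \code{"12q"}; no window crosses
#'     an arm boundary}
#'   \item{\code{label}}{arm plus a single global sequential index over the
#'     sorted genome, e.g. \code{"12q_370"}; unique within the set}
#'   \item{\code{n_source_bins}}{number of constituent source bins}
#' }
#'
#' @slot genomeBuild genome build identifier, e.g. \code{"hg19"}.
#' @seealso \code{\link{mergeToWindows}}, \code{\link{assignBin}}
#' @export
setClass("BinSet",
    contains = "GRanges",
    representation(genomeBuild = "character"),
    prototype(genomeBuild = "custom"))

setValidity("BinSet", function(object) {
    msg <- character()
    mc <- mcols(object)
    need <- c("arm", "label", "n_source_bins")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
    if (anyDuplicated(mc$label))
        msg <- c(msg, "bin labels are not unique")
    if (length(object) > 1) {
        if (is.unsorted(order(as.integer(seqnames(object)), start(object))) ||
            !identical(order(as.integer(seqnames(object)), start(object)),
                       seq_along(object)))
            msg <- c(msg, "bins are not sorted by genomic coordinate")
        ov <- findOverlaps(object, drop.self = TRUE, drop.redundant = TRUE)
        if (length(ov) > 0)
            msg <- c(msg, "bins overlap")
    }
    if (any(width(object) < 1))
        msg <- c(msg, "zero- or negative-width bin")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a BinSet
#'
#' @param gr a \code{GRanges} with metadata columns \code{arm}, \code{label}
#'   and \code{n_source_bins} (\code{label}/\code{n_source_bins} are filled
#'   in when absent).
#' @param genomeBuild genome build string recorded on the object.
#' @return a \code{BinSet}.
#' @export
BinSet <- function(gr, genomeBuild = "custom") {
    stopifnot(is(gr, "GRanges"))
    gr <- sortSeqlevels(gr)
    gr <- gr[order(as.integer(seqnames(gr)), start(gr))]
    if (is.null(mcols(gr)$arm))
        stop("GRanges must carry an 'arm' metadata column")
    if (is.null(mcols(gr)$label))
        mcols(gr)$label <- paste0(mcols(gr)$arm, "_", seq_along(gr))
    if (is.null(mcols(gr)$n_source_bins))
        mcols(gr)$n_source_bins <- rep(1L, length(gr))
    new("BinSet", gr, genomeBuild = genomeBuild)
}

#' @describeIn BinSet-class bin labels in genomic order
#' @param x a \code{BinSet}
#' @export
binLabels <- function(x) mcols(x)$label

#' @describeIn BinSet-class genome build string
#' @export
genomeBuild <- function(x) x@genomeBuild

setMethod("show", "BinSet", function(object) {
    cat("BinSet with", length(object), "windows on",
        length(unique(mcols(object)$arm)), "arm(s); genome:",
        object@genomeBuild, "\n")
    callNextMethod()
})

#' FragProfileSet: per-sample per-bin fragmentation profiles
#'
#' Container for cfDNA fragmentation profiles, extending
#' \link[SummarizedExperiment]{RangedSummarizedExperiment}: rows are genomic
#' windows (the \code{\link{BinSet}} in \code{rowRanges}), columns are
#' samples. Assays:
#' \describe{
#'   \item{\code{short}}{count of fragments with length in the short window
#'     (default 100-167 nt) per bin}
#'   \item{\code{total}}{count of fragments of all retained sizes per bin}
#'   \item{\code{proportion}}{\code{short/total}; \code{NA} where
#'     \code{total == 0}}
#' }
#' \code{colData} carries \code{sample_id}, \code{n_fragments_total} and
#' \code{qc_pass}.
#'
#' @export
setClass("FragProfileSet", contains = "RangedSummarizedExperiment")

setValidity("FragProfileSet", function(object) {
    an <- names(assays(object))
    need <- c("short", "total", "proportion")
    if (!all(need %in% an))
        return(paste("assays must include:", paste(need, collapse = ", ")))
    s <- assay(object, "short"); t <- assay(object, "total")
    if (any(s > t, na.rm = TRUE))
        return("short counts exceed total counts")
    p <- assay(object, "proportion")
    if (any(p < 0 | p > 1, na.rm = TRUE))
        return("proportions outside [0, 1]")
    cd <- colData(object)
    if (!all(c("sample_id", "n_fragments_total", "qc_pass") %in% colnames(cd)))
        return("colData must have sample_id, n_fragments_total, qc_pass")
    TRUE
})

setMethod("show", "FragProfileSet", function(object) {
    cat("FragProfileSet:", ncol(object), "sample(s) x", nrow(object),
        "bin(s)")
    if (isTRUE(metadata(object)$centered)) cat(" [row-centered assay present]")
    cat("\n")
    callNextMethod()
})

#' FragModel: penalized logistic fragmentation model
#'
#' Trained L1-penalized (lasso) logistic model mapping a sample's per-bin
#' short-fragment proportions to a probability-scale score in [0, 1].
#' Coefficients are stored on the original proportion scale; the per-feature
#' training standard deviations are kept so that standardized-scale
#' importances can be derived.
#'
#' @slot featureNames all feature (bin) labels seen at training.
#' @slot coefficients named numeric, the nonzero coefficients (original scale).
#' @slot intercept scalar intercept.
#' @slot lambda selected penalty.
#' @slot cutoff score threshold for calling a sample positive.
#' @slot featureSd named numeric, per-feature training standard deviation.
#' @slot featureMean named numeric, per-feature training mean.
#' @slot seed integer training seed.
#' @slot nFolds,nRepeats cross-validation layout.
#' @slot cvCurve data.frame with columns \code{lambda}, \code{deviance}
#'   (mean cross-validated binomial deviance).
#' @export
setClass("FragModel", representation(
    featureNames = "character",
    coefficients = "numeric",
    intercept    = "numeric",
    lambda       = "numeric",
    cutoff       = "numeric",
    featureSd    = "numeric",
    featureMean  = "numeric",
    seed         = "integer",
    nFolds       = "integer",
    nRepeats     = "integer",
    cvCurve      = "data.frame"))

setValidity("FragModel", function(object) {
    if (length(object@coefficients) &&
        is.null(names(object@coefficients)))
        return("coefficients must be named by bin label")
    if (!all(names(object@coefficients) %in% object@featureNames))
        return("coefficient names must be a subset of featureNames")
    if (length(object@cutoff) == 1 &&
        (object@cutoff < 0 || object@cutoff > 1))
        return("cutoff must lie in [0, 1]")
    TRUE
})

setMethod("show", "FragModel", function(object) {
    cat("FragModel: lasso logistic,", length(object@coefficients),
        "of", length(object@featureNames), "bins selected\n")
    cat("  lambda =", signif(object@lambda, 4),
        " cutoff =", signif(object@cutoff, 4), "\n")
    if (length(object@coefficients)) {
        imp <- featureImportance(object)
        cat("  top bins:", paste(utils::head(names(imp), 5), collapse = ", "),
            "\n")
    }
})

#' @describeIn FragModel-class nonzero coefficients, original scale
#' @param object a \code{FragModel}
#' @export
modelCoefficients <- function(object) object@coefficients

#' @describeIn FragModel-class the score cutoff shipped with the model
#' @export
modelCutoff <- function(object) object@cutoff
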