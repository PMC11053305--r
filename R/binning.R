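#' Load 100-kb source bins from an arm-annotated BED file
#'
#' Reads a BED4+ file (\code{chrom}, \code{start}, \code{end}, \code{arm};
#' 0-based half-open coordinates) describing the non-overlapping source bins
#' from which analysis windows are merged. Mappability / blacklist filtering
#' is assumed already applied upstream; an optional exclusion BED drops any
#' source bin overlapping an excluded region by more than
#' \code{excludeFraction} of its width.
#'
#' @param path BED4+ file of source bins.
#' @param excludePath optional BED3 file of regions to exclude.
#' @param excludeFraction overlap fraction above which a source bin is
#'   dropped (default 0.5).
#' @param verbose print a summary of counts per arm.
#' @return a coordinate-sorted \code{GRanges} with an \code{arm} metadata
#'   column.
#' @export
loadSourceBins <- function(path, excludePath = NULL, excludeFraction = 0.5,
                           verbose = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
    if (!length(lines)) stop("empty BED file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < 4)
    if (length(bad))
        stop("malformed BED line ", bad[1], ": expected >= 4 tab-separated ",
             "fields, got ", nf[bad[1]])
    chrom <- vapply(fields, `[[`, "", 1)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
    end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
    arm   <- vapply(fields, `[[`, "", 4)
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
        stop("malformed BED line ", bad[1], ": non-numeric start/end")
    bad <- which(start >= end)
    if (length(bad))
        stop("malformed BED line ", bad[1], ": start >= end")
    gr <- GRanges(chrom, IRanges(start + 1, end), arm = arm)
    gr <- sortSeqlevels(gr)
    gr <- gr[order(as.integer(seqnames(gr)), start(gr))]
    ov <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov))
        stop("source bins overlap (e.g. records ",
             S4Vectors::queryHits(ov)[1], " and ",
             S4Vectors::subjectHits(ov)[1], " after sorting)")
    if (!is.null(excludePath)) {
        ex <- loadExclusionBed(excludePath)
        hit <- findOverlaps(gr, ex)
        if (length(hit)) {
            w <- width(GenomicRanges::pintersect(
                gr[S4Vectors::queryHits(hit)], ex[S4Vectors::subjectHits(hit)]))
            ovw <- rep(0, length(gr))
            agg <- tapply(w, S4Vectors::queryHits(hit), sum)
            ovw[as.integer(names(agg))] <- agg
            drop <- which(ovw / width(gr) > excludeFraction)
            if (length(drop)) {
                if (verbose)
                    message("dropping ", length(drop),
                            " source bin(s) overlapping exclusion regions")
                gr <- gr[-drop]
            }
        }
    }
    if (verbose) {
        message(length(gr), " source bins on ",
                length(unique(mcols(gr)$arm)), " arms")
        tb <- table(mcols(gr)$arm)
        message(paste(names(tb), tb, sep = ":", collapse = " "))
    }
    gr
}

loadExclusionBed <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end"),
                            colClasses = c("character", "numeric", "numeric"))
    GRanges(df$chrom, IRanges(df$start + 1, df$end))
}

#' Merge source bins into ~5-Mb analysis windows
#'
#' Within each chromosome arm, consecutive source bins are grouped greedily
#' into windows of \code{floor(targetSpan / sourceSpan)} source bins (50 for
#' 100-kb bins and a 5-Mb target). A trailing group with at least half that
#' many source bins becomes its own window; a smaller trailing group is
#' absorbed into the previous window (or kept as the arm's only window when
#' the arm is short). Windows never cross an arm boundary. Labels are
#' \code{<arm>_<k>} with \code{k} a single global sequential index over the
#' sorted genome.
#'
#' @param sourceBins \code{GRanges} from \code{\link{loadSourceBins}} (or any
#'   arm-annotated, sorted, non-overlapping bin set).
#' @param targetSpan target window span in bases (default 5e6).
#' @param genomeBuild genome build string recorded on the result.
#' @return a \code{\link{BinSet}}.
#' @export
mergeToWindows <- function(sourceBins, targetSpan = 5e6,
                           genomeBuild = "custom") {
    if (length(sourceBins) == 0) stop("no source bins to merge")
    if (is.null(mcols(sourceBins)$arm)) stop("source bins lack 'arm' column")
    sourceBins <- sortSeqlevels(sourceBins)
    sourceBins <- sourceBins[order(as.integer(seqnames(sourceBins)),
                                   start(sourceBins))]
    sourceSpan <- stats::median(width(sourceBins))
    k <- max(1L, as.integer(floor(targetSpan / sourceSpan)))
    minTrail <- ceiling(k / 2)

    arm <- mcols(sourceBins)$arm
    armRle <- rle(arm)
    out <- list()
    offset <- 0L
    for (a in seq_along(armRle$lengths)) {
        n <- armRle$lengths[a]
        idx <- offset + seq_len(n)
        offset <- offset + n
        grp <- ceiling(seq_len(n) / k)
        nGrp <- max(grp)
        if (nGrp > 1 && sum(grp == nGrp) < minTrail)
            grp[grp == nGrp] <- nGrp - 1L
        armBins <- sourceBins[idx]
        for (g in seq_len(max(grp))) {
            sel <- which(grp == g)
            out[[length(out) + 1L]] <- data.frame(
                chrom = as.character(seqnames(armBins))[sel[1]],
                start = min(start(armBins[sel])),
                end = max(end(armBins[sel])),
                arm = armRle$values[a],
                n_source_bins = length(sel),
                source_span = sum(width(armBins[sel])))
        }
    }
    df <- do.call(rbind, out)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                  arm = df$arm, n_source_bins = df$n_source_bins,
                  source_span = df$source_span)
    gr <- sortSeqlevels(gr)
    gr <- gr[order(as.integer(seqnames(gr)), start(gr))]
    mcols(gr)$label <- paste0(mcols(gr)$arm, "_", seq_along(gr))
    BinSet(gr, genomeBuild = genomeBuild)
}

#' Assign fragments to analysis windows by midpoint
#'
#' A fragment belongs to the window containing its midpoint,
#' \code{start + floor(length / 2)} in 0-based coordinates, under the
#' half-open \code{[start, end)} convention: a midpoint exactly at a window
#' start is assigned to that window. Fragments whose midpoint falls outside
#' every window (including fragments on chromosomes absent from the bin set)
#' get \code{NA}.
#'
#' @param fragments data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), e.g. from \code{\link{readFragments}}.
#' @param binset a \code{\link{BinSet}}.
#' @return character vector of bin labels (\code{NA} = unassigned), one per
#'   fragment.
#' @export
assignBin <- function(fragments, binset) {
    stopifnot(is(binset, "BinSet"))
    if (nrow(fragments) == 0) return(character(0))
    mid0 <- fragments$start + floor((fragments$end - fragments$start) / 2)
    known <- fragments$chrom %in% seqlevels(binset)
    lab <- rep(NA_character_, nrow(fragments))
    if (any(known)) {
        pts <- GRanges(fragments$chrom[known], IRanges(mid0[known] + 1,
                                                       width = 1))
        hit <- findOverlaps(pts, binset, select = "first")
        lab[known] <- binLabels(binset)[hit]
    }
    lab
}

#' Write / read the bin manifest
#'
#' The manifest is a TSV with columns \code{label}, \code{chrom},
#' \code{start} (0-based), \code{end}, \code{arm}, \code{n_source_bins} —
#' the interchange format between the binning and profiling steps.
#'
#' @param binset a \code{\link{BinSet}}.
#' @param path file to write / read.
#' @return \code{writeBinManifest} returns \code{path} invisibly;
#'   \code{readBinManifest} returns a \code{BinSet}.
#' @export
writeBinManifest <- function(binset, path) {
    stopifnot(is(binset, "BinSet"))
    df <- data.frame(label = binLabels(binset),
                     chrom = as.character(seqnames(binset)),
                     start = start(binset) - 1L,
                     end = end(binset),
                     arm = mcols(binset)$arm,
                     n_source_bins = mcols(binset)$n_source_bins)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeBinManifest
#' @param genomeBuild genome build recorded on the re-read \code{BinSet}.
#' @export
readBinManifest <- function(path, genomeBuild = "custom") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "character",
                                           "numeric", "numeric", "character",
                                           "integer"))
    gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end),
                  arm = df$arm, label = df$label,
                  n_source_bins = df$n_source_bins)
    BinSet(gr, genomeBuild = genomeBuild)
}
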