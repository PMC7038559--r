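#' @include AllClasses.R
NULL

## Coordinates: user-facing files are BED (0-based half-open); GRanges is
## 1-based closed, so start is shifted by +1 on import and -1 on export.

.skipLine <- function(x) {
    grepl("^(#|track\\b|browser\\b)", x) | !nzchar(trimws(x))
}

#' Read a BED or narrowPeak file into a PeakSet
#'
#' Accepts 3+-column BED and 10-column narrowPeak. Only chrom/start/end
#' (and the name column, when present) are used; narrowPeak summit,
#' signal and p/q-value columns are ignored so that all formats are
#' treated uniformly. Intervals are sorted by (chrom, start). Peak sets
#' smaller than `minPeaks` are rejected: sparse peak sets give unstable
#' cobinding columns, and the shipped default (1000) is the quality gate
#' applied to the HMR itself.
#'
#' @param path path to a BED3/BED6/narrowPeak file. Lines starting with
#'   `#`, `track` or `browser` are skipped.
#' @param factorName label for the factor; defaults to the file base name.
#' @param minPeaks minimum number of peaks required (default 1000); a
#'   smaller file raises a QC error.
#' @return a [PeakSet].
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t300", "chr1\t500\t900"), f)
#' readPeaks(f, minPeaks = 1)
#' @export
readPeaks <- function(path, factorName = NULL, minPeaks = 1000L) {
    stopifnot(is.numeric(minPeaks), minPeaks >= 0)
    if (!file.exists(path))
        stop("peak file not found: ", path)
    lines <- readLines(path)
    keep <- !.skipLine(lines)
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines))
        stop("no data lines in ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("line ", lineNo[which(nf < 3L)[1L]], " of ", path,
             ": fewer than 3 tab-separated columns")
    chrom <- vapply(fields, `[[`, "", 1L)
    startChr <- vapply(fields, `[[`, "", 2L)
    endChr <- vapply(fields, `[[`, "", 3L)
    start <- suppressWarnings(as.integer(startChr))
    end <- suppressWarnings(as.integer(endChr))
    bad <- is.na(start) | is.na(end) | startChr != as.character(start) |
        endChr != as.character(end)
    if (any(bad))
        stop("line ", lineNo[which(bad)[1L]], " of ", path,
             ": non-integer coordinates")
    bad <- start < 0L | start >= end
    if (any(bad))
        stop("line ", lineNo[which(bad)[1L]], " of ", path,
             ": requires 0 <= start < end")
    if (!any(nzchar(chrom)))
        stop("empty chromosome name in ", path)
    name <- ifelse(nf >= 4L, vapply(fields, function(f)
        if (length(f) >= 4L) f[[4L]] else NA_character_, ""), NA_character_)
    if (length(chrom) < minPeaks)
        stop("QC rejection: ", path, " has ", length(chrom),
             " peaks, fewer than the required ", minPeaks)
    gr <- GRanges(factor(chrom, levels = sort(unique(chrom))),
                  IRanges(start + 1L, end))
    if (any(!is.na(name)))
        mcols(gr)$name <- name
    gr <- gr[order(as.character(seqnames(gr)), start(gr))]
    if (is.null(factorName))
        factorName <- sub("\\.(bed|narrowPeak|broadPeak)$", "",
                          basename(path), ignore.case = TRUE)
    new("PeakSet", factorName = factorName, ranges = gr)
}

#' Construct a PeakSet from a GRanges
#'
#' @param factorName factor label.
#' @param gr a `GRanges`; it is sorted by (chrom, start).
#' @return a [PeakSet].
#' @export
peakSet <- function(factorName, gr) {
    chrom <- as.character(seqnames(gr))
    gr2 <- GRanges(factor(chrom, levels = sort(unique(chrom))),
                   IRanges(start(gr), end(gr)))
    mcols(gr2) <- mcols(gr)
    gr2 <- gr2[order(chrom, start(gr2))]
    new("PeakSet", factorName = factorName, ranges = gr2)
}

#' Write a PeakSet to a BED file
#'
#' Emits BED3 (plus a name column when the intervals carry one) in
#' (chrom, start) order; coordinates are written back in the 0-based
#' half-open convention, so `readPeaks()` after `writeIntervals()` is the
#' identity on (chrom, start, end, name).
#'
#' @param peaks a [PeakSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeIntervals <- function(peaks, path) {
    stopifnot(is(peaks, "PeakSet"))
    validObject(peaks)
    gr <- peaks@ranges
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    nm <- mcols(gr)$name
    if (!is.null(nm) && any(!is.na(nm)))
        df$name <- ifelse(is.na(nm), ".", nm)
    ok <- tryCatch({
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        TRUE
    }, error = function(e) stop("cannot write ", path, ": ",
                                conditionMessage(e)))
    invisible(path)
}

#' Read a signal track (bigWig or bedGraph)
#'
#' Loads a normalized read-density track into a per-chromosome
#' run-length-encoded coverage representation supporting windowed mean
#' queries. bedGraph records must be non-overlapping; values must be
#' non-negative. Format is chosen by file extension (`.bw`/`.bigwig` vs
#' `.bedgraph`/`.bdg`/`.bg`).
#'
#' @param path path to a bigWig or bedGraph file.
#' @param name track label; defaults to the file base name.
#' @return a [SignalTrack].
#' @export
readSignalTrack <- function(path, name = NULL) {
    if (!file.exists(path))
        stop("signal track not found: ", path)
    ext <- tolower(sub(".*\\.", "", path))
    gr <- if (ext %in% c("bw", "bigwig")) {
        rtracklayer::import.bw(path)
    } else if (ext %in% c("bedgraph", "bdg", "bg")) {
        rtracklayer::import(path, format = "bedGraph")
    } else {
        stop("unsupported signal track format '.", ext,
             "' (expected bigWig or bedGraph)")
    }
    if (is.null(gr$score))
        stop("track ", path, " has no score column")
    if (any(gr$score < 0))
        stop("track ", path, " contains negative values")
    cnt <- coverage(gr)
    if (any(vapply(cnt, function(x) any(runValue(x) > 1L), TRUE)))
        stop("track ", path, " contains overlapping records")
    cov <- coverage(gr, weight = "score")
    if (is.null(name))
        name <- sub("\\.[^.]*$", "", basename(path))
    new("SignalTrack", name = name, coverage = cov)
}

#' Construct a SignalTrack from a scored GRanges
#'
#' @param gr disjoint `GRanges` with a numeric `score` column.
#' @param name track label.
#' @return a [SignalTrack].
#' @export
signalTrack <- function(gr, name = "track") {
    stopifnot(!is.null(gr$score), all(gr$score >= 0))
    cnt <- coverage(gr)
    if (any(vapply(cnt, function(x) any(runValue(x) > 1L), TRUE)))
        stop("overlapping records in signal GRanges")
    new("SignalTrack", name = name, coverage = coverage(gr, weight = "score"))
}

#' Mean signal over a window around a position
#'
#' Arithmetic mean of the per-base signal over the half-open window
#' `[max(0, center - halfwidth), center + halfwidth)` in 0-based
#' coordinates. Bases beyond the track's recorded extent (or on
#' chromosomes absent from the track) contribute 0; windows reaching
#' below position 0 are clipped there and the mean is taken over the
#' clipped length.
#'
#' @param track a [SignalTrack].
#' @param chrom chromosome name.
#' @param center window center, 0-based bp.
#' @param halfwidth window half-width in bp (> 0).
#' @return mean signal (numeric scalar, >= 0).
#' @export
meanSignalInWindow <- function(track, chrom, center, halfwidth) {
    stopifnot(is(track, "SignalTrack"), halfwidth > 0)
    s <- max(0, center - halfwidth)
    e <- center + halfwidth
    len <- e - s
    if (len <= 0) return(0)
    cov <- track@coverage
    if (!chrom %in% names(cov)) return(0)
    x <- cov[[chrom]]
    from <- s + 1          # 1-based inclusive
    to <- min(e, length(x))
    if (to < from) return(0)
    sum(window(x, from, to)) / len
}

## Vectorized windowed means over many centers on arbitrary chromosomes;
## internal workhorse behind buildResponse()/buildQuantitativeMatrix().
.meanSignalWindows <- function(track, chrom, starts0, ends0) {
    n <- length(starts0)
    out <- numeric(n)
    cov <- track@coverage
    lens <- ends0 - starts0
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        if (!ch %in% names(cov)) next
        x <- cov[[ch]]
        from <- pmax(starts0[idx], 0) + 1
        to <- pmin(ends0[idx], length(x))
        ok <- to >= from
        if (!any(ok)) next
        v <- IRanges::Views(x, start = from[ok], end = to[ok])
        out[idx[ok]] <- IRanges::viewSums(v) / lens[idx][ok]
    }
    out
}

#' Peak centers of a PeakSet
#'
#' Midpoint `floor((start + end) / 2)` of each interval in the 0-based
#' convention. narrowPeak summit offsets are deliberately not used, so
#' every input format yields the same definition of a peak center.
#'
#' @param peaks a [PeakSet].
#' @return integer vector of 0-based center positions.
#' @export
peakCenters <- function(peaks) {
    gr <- peaks@ranges
    as.integer(floor(((start(gr) - 1L) + end(gr)) / 2))
}
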