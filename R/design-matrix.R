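#' @include AllClasses.R genomic-io.R
NULL

#' Signal-window half-width for a histone mark
#'
#' Broad marks (H3K9me3, H3K27me3, H3K36me3 by default) are averaged over
#' +/- 5 kb around each peak center; all other marks over +/- 1 kb.
#'
#' @param hmName histone mark name.
#' @param broadList character vector of marks treated as broad.
#' @return half-width in bp (5000 or 1000).
#' @examples
#' chooseHalfwidth("H3K27me3")  # 5000
#' chooseHalfwidth("H3K4me3")   # 1000
#' @export
chooseHalfwidth <- function(hmName,
                            broadList = c("H3K9me3", "H3K27me3",
                                          "H3K36me3")) {
    stopifnot(is.character(hmName), length(hmName) == 1L, nzchar(hmName))
    if (hmName %in% broadList) 5000L else 1000L
}

#' Build the response vector Y of windowed histone-mark signal
#'
#' For each HMR peak, averages each substrate/product track over the
#' window of +/- `halfwidth` bp around the peak center, then combines
#' multiple tracks element-wise. The default combination is `max`, so a
#' site only counts as mark-depleted (low Y) when *every* classical
#' substrate/product is absent there; `mean` is available for sensitivity
#' analysis.
#'
#' @param hmrPeaks the HMR [PeakSet].
#' @param hmTracks list of [SignalTrack]s, one per classical mark.
#' @param hmNames optional mark names (defaults to the tracks' names).
#' @param halfwidth window half-width in bp; by default derived from the
#'   first mark name via [chooseHalfwidth()].
#' @param combine `"max"` (default) or `"mean"` across tracks.
#' @param broadList passed to [chooseHalfwidth()].
#' @return a [ResponseVector] aligned with `hmrPeaks`.
#' @export
buildResponse <- function(hmrPeaks, hmTracks, hmNames = NULL,
                          halfwidth = NULL, combine = c("max", "mean"),
                          broadList = c("H3K9me3", "H3K27me3",
                                        "H3K36me3")) {
    combine <- match.arg(combine)
    stopifnot(is(hmrPeaks, "PeakSet"))
    if (is(hmTracks, "SignalTrack"))
        hmTracks <- list(hmTracks)
    if (!length(hmTracks))
        stop("at least one histone-mark signal track is required")
    if (is.null(hmNames))
        hmNames <- vapply(hmTracks, function(t) t@name, "")
    if (is.null(halfwidth))
        halfwidth <- chooseHalfwidth(hmNames[[1L]], broadList)
    centers <- peakCenters(hmrPeaks)
    chrom <- as.character(seqnames(hmrPeaks@ranges))
    s0 <- pmax(centers - halfwidth, 0)
    e0 <- centers + halfwidth
    per <- vapply(hmTracks, .meanSignalWindows, numeric(length(centers)),
                  chrom = chrom, starts0 = s0, ends0 = e0)
    per <- matrix(per, nrow = length(centers))
    y <- if (combine == "max") apply(per, 1L, max) else rowMeans(per)
    new("ResponseVector", values = as.numeric(y),
        hmName = paste(hmNames, collapse = "+"),
        halfwidth = as.numeric(halfwidth))
}

#' Build the binary cobinding design matrix X
#'
#' `X[i, j] = 1` iff factor j has at least one peak overlapping HMR peak
#' i by >= 1 bp. Overlap is computed against the peak interval itself
#' (not the signal window): using the window would inflate cobinding for
#' broad marks. Pass `overlapWindow` to widen each HMR peak symmetrically
#' for sensitivity analysis.
#'
#' @param hmrPeaks the HMR [PeakSet].
#' @param factors list of factor [PeakSet]s with unique names.
#' @param overlapWindow optional half-width in bp by which each HMR peak
#'   is extended on both sides before the overlap test (default 0).
#' @return a binary [CobindingMatrix] with one column per factor.
#' @export
buildCobindingMatrix <- function(hmrPeaks, factors, overlapWindow = 0L) {
    stopifnot(is(hmrPeaks, "PeakSet"))
    if (is(factors, "PeakSet"))
        factors <- list(factors)
    if (!length(factors))
        stop("at least one factor peak set is required")
    nms <- vapply(factors, factorName, "")
    if (anyDuplicated(nms))
        stop("duplicate factor names: ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "),
             "; supply pre-deduplicated inputs (one peak set per factor)")
    q <- hmrPeaks@ranges
    if (overlapWindow > 0) {
        q <- GRanges(seqnames(q),
                     IRanges(pmax(start(q) - overlapWindow, 1L),
                             end(q) + overlapWindow))
    }
    X <- matrix(0, nrow = length(q), ncol = length(factors),
                dimnames = list(NULL, nms))
    for (j in seq_along(factors)) {
        hits <- countOverlaps(q, factors[[j]]@ranges, minoverlap = 1L)
        X[hits > 0L, j] <- 1
    }
    new("CobindingMatrix", matrix = X, mode = "binary")
}

#' Build a quantitative design matrix from factor signal tracks
#'
#' The `signal` running mode: `X[i, j]` is factor j's mean signal over
#' HMR peak i's own interval.
#'
#' @param hmrPeaks the HMR [PeakSet].
#' @param factorTracks named list of [SignalTrack]s, one per factor.
#' @return a quantitative [CobindingMatrix].
#' @export
buildQuantitativeMatrix <- function(hmrPeaks, factorTracks) {
    stopifnot(is(hmrPeaks, "PeakSet"))
    if (is(factorTracks, "SignalTrack"))
        factorTracks <- list(factorTracks)
    if (!length(factorTracks))
        stop("at least one factor signal track is required")
    nms <- names(factorTracks)
    if (is.null(nms))
        nms <- vapply(factorTracks, function(t) t@name, "")
    if (anyDuplicated(nms))
        stop("duplicate factor names: ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
    gr <- hmrPeaks@ranges
    chrom <- as.character(seqnames(gr))
    s0 <- start(gr) - 1L
    e0 <- end(gr)
    X <- vapply(factorTracks, .meanSignalWindows, numeric(length(gr)),
                chrom = chrom, starts0 = s0, ends0 = e0)
    X <- matrix(X, nrow = length(gr), dimnames = list(NULL, nms))
    new("CobindingMatrix", matrix = X, mode = "quantitative")
}

#' Export Y and X as TSV for inspection
#'
#' `writeResponse()` writes (chrom, start, end, Y); `writeCobinding()`
#' writes the peaks-by-factors matrix with a header row of factor names.
#'
#' @param hmrPeaks the HMR [PeakSet] the objects are aligned with.
#' @param response a [ResponseVector].
#' @param cobinding a [CobindingMatrix].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeResponse <- function(hmrPeaks, response, path) {
    gr <- hmrPeaks@ranges
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     Y = response@values)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeResponse
#' @export
writeCobinding <- function(cobinding, path) {
    utils::write.table(cobinding@matrix, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
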