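#' @include AllClasses.R
#' @importFrom stats cov
NULL

#' Otsu threshold of a signal distribution
#'
#' Histograms the values into `nBins` equal-width bins over
#' `[min, max]` and returns the internal bin edge that minimizes the
#' weighted intra-class variance of the two resulting classes
#' (equivalently, maximizes the between-class variance). Ties are broken
#' toward the lower edge. 256 bins mirror the algorithm's 8-bit
#' image-processing origin.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param nBins number of histogram bins (default 256).
#' @return the threshold (a bin edge strictly inside the value range).
#' @export
otsuThreshold <- function(values, nBins = 256L) {
    stopifnot(nBins >= 2L)
    values <- values[is.finite(values)]
    if (length(values) < 2L || diff(range(values)) == 0)
        stop("degenerate input: need at least 2 distinct values")
    lo <- min(values)
    hi <- max(values)
    edges <- seq(lo, hi, length.out = nBins + 1L)
    ## right-closed bins, lowest bin closed on both sides (hist default)
    counts <- tabulate(findInterval(values, edges, rightmost.closed = TRUE,
                                    left.open = TRUE, all.inside = TRUE),
                       nbins = nBins)
    mids <- (edges[-1L] + edges[-(nBins + 1L)]) / 2
    w <- counts / sum(counts)
    ## cumulative weight and mean below each internal edge
    cw <- cumsum(w)[-nBins]
    cm <- cumsum(w * mids)[-nBins]
    mu <- sum(w * mids)
    between <- ifelse(cw > 0 & cw < 1,
                      (mu * cw - cm)^2 / (cw * (1 - cw)), -Inf)
    k <- which.max(between)          # first max = lower edge on ties
    edges[k + 1L]
}

#' Classify HMR peaks into classical and non-classical sites
#'
#' Peaks whose response value is strictly below the threshold are
#' labelled `non_classical` (mark-depleted); boundary values fall in the
#' classical (high-signal) class. Pass `threshold = NA` (e.g. when
#' [otsuThreshold()] was degenerate) to label every peak classical.
#'
#' @param Y a [ResponseVector] or numeric vector.
#' @param threshold signal threshold, typically from [otsuThreshold()].
#' @return a [SiteClassification] with empty cofactor subsets.
#' @export
classifySites <- function(Y, threshold) {
    y <- .asResponse(Y)
    labels <- if (is.na(threshold)) rep("classical", length(y))
              else ifelse(y < threshold, "non_classical", "classical")
    new("SiteClassification", threshold = as.numeric(threshold),
        labels = labels, subsets = list())
}

#' Per-cofactor subsets of non-classical sites
#'
#' For each surviving cofactor, records which non-classical HMR peaks
#' are overlapped (>= 1 bp) by that cofactor's peaks. Subsets of
#' different cofactors may intersect; each is a subset of the
#' non-classical index set.
#'
#' @param classification a [SiteClassification] aligned with `hmrPeaks`.
#' @param hmrPeaks the HMR [PeakSet].
#' @param cofactors list of cofactor [PeakSet]s (typically the survivors
#'   of [predictCofactors()]).
#' @return the [SiteClassification] with `subsets` filled.
#' @export
cofactorSiteSubsets <- function(classification, hmrPeaks, cofactors) {
    stopifnot(is(classification, "SiteClassification"),
              is(hmrPeaks, "PeakSet"))
    if (is(cofactors, "PeakSet"))
        cofactors <- list(cofactors)
    stopifnot(length(classification@labels) == nPeaks(hmrPeaks))
    nc <- which(classification@labels == "non_classical")
    subsets <- lapply(cofactors, function(cf) {
        hits <- countOverlaps(hmrPeaks@ranges, cf@ranges,
                              minoverlap = 1L)
        intersect(which(hits > 0L), nc)
    })
    names(subsets) <- vapply(cofactors, factorName, "")
    initialize(classification, subsets = subsets)
}
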