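#' @import methods
#' @importFrom S4Vectors mcols mcols<- isSorted
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   countOverlaps coverage granges sort
#' @importFrom IRanges IRanges RleList
NULL

#' PeakSet: the binding sites of one factor
#'
#' A named, coordinate-sorted collection of ChIP-seq peak intervals for a
#' single factor (the HMR under study, or a candidate cofactor). Intervals
#' are held as a [GenomicRanges::GRanges]; all user-facing coordinates
#' follow the BED convention (0-based half-open), converted on import.
#'
#' @slot factorName single string naming the factor the peaks belong to.
#' @slot ranges `GRanges` of peak intervals, sorted by (chrom, start).
#'
#' @seealso [readPeaks()], [writeIntervals()], [buildCobindingMatrix()]
#' @export
setClass("PeakSet",
    representation(factorName = "character", ranges = "GRanges"))

setValidity("PeakSet", function(object) {
    msg <- NULL
    if (length(object@factorName) != 1L || is.na(object@factorName) ||
        !nzchar(object@factorName))
        msg <- c(msg, "'factorName' must be a single non-empty string")
    if (length(object@ranges) < 1L)
        msg <- c(msg, "a PeakSet must contain at least one interval")
    if (any(width(object@ranges) < 1L))
        msg <- c(msg, "all intervals must satisfy start < end")
    o <- order(as.character(seqnames(object@ranges)), start(object@ranges))
    if (!identical(o, seq_along(object@ranges)))
        msg <- c(msg, "intervals must be sorted by (chrom, start)")
    if (is.null(msg)) TRUE else msg
})

#' SignalTrack: piecewise-constant genome-wide signal
#'
#' Read-density style coverage (e.g. a normalized histone-modification
#' signal) held per chromosome as run-length encoded vectors. Positions
#' not covered by the source file, including whole chromosomes absent from
#' it, contribute 0 to any windowed mean.
#'
#' @slot name track label (e.g. the histone mark).
#' @slot coverage an [IRanges::RleList], one numeric Rle per chromosome.
#'
#' @seealso [readSignalTrack()], [meanSignalInWindow()]
#' @export
setClass("SignalTrack",
    representation(name = "character", coverage = "RleList"))

setValidity("SignalTrack", function(object) {
    if (length(object@name) != 1L)
        return("'name' must be a single string")
    TRUE
})

#' ResponseVector: per-peak histone-mark signal Y
#'
#' The response of the cobinding regression: one windowed mean signal
#' value per HMR peak, aligned with the HMR [PeakSet] it was built from.
#'
#' @slot values numeric vector Y, one value per HMR peak, all >= 0.
#' @slot hmName name of the histone mark (or combination rule label).
#' @slot halfwidth half-width in bp of the window around each peak center
#'   over which the signal was averaged.
#'
#' @seealso [buildResponse()], [chooseHalfwidth()]
#' @export
setClass("ResponseVector",
    representation(values = "numeric", hmName = "character",
                   halfwidth = "numeric"))

setValidity("ResponseVector", function(object) {
    msg <- NULL
    if (length(object@values) < 1L)
        msg <- c(msg, "'values' must be non-empty")
    if (any(!is.finite(object@values)) || any(object@values < 0))
        msg <- c(msg, "'values' must be finite and non-negative")
    if (length(object@halfwidth) != 1L || object@halfwidth <= 0)
        msg <- c(msg, "'halfwidth' must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' CobindingMatrix: peaks x factors design matrix X
#'
#' Design matrix of the cobinding regression: rows are the HMR's peaks,
#' columns are candidate factors. In `binary` mode `X[i, j]` is 1 when
#' factor j has at least one peak overlapping HMR peak i by >= 1 bp; in
#' `quantitative` mode it is factor j's mean signal over peak i.
#'
#' @slot matrix numeric matrix with factor names as column names.
#' @slot mode `"binary"` or `"quantitative"`.
#'
#' @seealso [buildCobindingMatrix()], [buildQuantitativeMatrix()]
#' @export
setClass("CobindingMatrix",
    representation(matrix = "matrix", mode = "character"))

setValidity("CobindingMatrix", function(object) {
    msg <- NULL
    m <- object@matrix
    if (!is.numeric(m))
        msg <- c(msg, "'matrix' must be numeric")
    if (ncol(m) > 0L && is.null(colnames(m)))
        msg <- c(msg, "'matrix' must have factor column names")
    if (anyDuplicated(colnames(m)))
        msg <- c(msg, "duplicate factor names in columns")
    if (!object@mode %in% c("binary", "quantitative"))
        msg <- c(msg, "'mode' must be 'binary' or 'quantitative'")
    else if (object@mode == "binary" && length(m) && !all(m %in% c(0, 1)))
        msg <- c(msg, "binary mode requires all entries in {0, 1}")
    else if (object@mode == "quantitative" && length(m) && any(m < 0))
        msg <- c(msg, "quantitative mode requires non-negative entries")
    if (is.null(msg)) TRUE else msg
})

#' RegressionConfig: tuning parameters of the cofactor inference step
#'
#' @slot alpha penalty mixing weight on the quadratic term, in `[0, 1]`:
#'   the penalty is `lambda * sum(alpha * beta^2 + (1 - alpha) * |beta|)`,
#'   so `alpha = 0` is the Lasso and `alpha = 1` pure ridge. Default 0.5.
#' @slot lambdaRule `"lambda.1se"` (default) or `"lambda.min"`; how the
#'   cross-validated penalty strength is picked.
#' @slot cvFolds number of cross-validation folds (default 10).
#' @slot seed integer seed controlling fold assignment and permutations.
#' @slot r2Cutoff adjusted-R2 threshold a refit factor must exceed
#'   (default 0.1).
#' @slot nPerm number of permutations for the significance test
#'   (default 1000).
#' @slot permPCutoff permutation p-value threshold (default 0.001).
#'
#' @seealso [regressionConfig()], [predictCofactors()]
#' @export
setClass("RegressionConfig",
    representation(alpha = "numeric", lambdaRule = "character",
                   cvFolds = "integer", seed = "integer",
                   r2Cutoff = "numeric", nPerm = "integer",
                   permPCutoff = "numeric"))

setValidity("RegressionConfig", function(object) {
    msg <- NULL
    if (object@alpha < 0 || object@alpha > 1)
        msg <- c(msg, "'alpha' must lie in [0, 1]")
    if (!object@lambdaRule %in% c("lambda.1se", "lambda.min"))
        msg <- c(msg, "'lambdaRule' must be 'lambda.1se' or 'lambda.min'")
    if (object@cvFolds < 2L)
        msg <- c(msg, "'cvFolds' must be >= 2")
    if (object@nPerm < 1L)
        msg <- c(msg, "'nPerm' must be >= 1")
    if (object@r2Cutoff <= 0 || object@r2Cutoff >= 1)
        msg <- c(msg, "'r2Cutoff' must lie in (0, 1)")
    if (object@permPCutoff <= 0 || object@permPCutoff > 1)
        msg <- c(msg, "'permPCutoff' must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' CofactorReport: ranked cofactor candidates and the overall verdict
#'
#' Result of [predictCofactors()]. The `results` table holds one row per
#' surviving cofactor candidate with its penalized selection coefficient,
#' univariate refit slope, R2, Wherry-adjusted R2, permutation p value and
#' rank (descending adjusted R2, ties broken by factor name). The verdict
#' is `TRUE` when at least one factor survives all gates, i.e. the HMR is
#' predicted to have a non-classical function.
#'
#' @slot results data.frame of surviving candidates (possibly 0 rows).
#' @slot allFactors data.frame of diagnostics for every column submitted
#'   to feature selection (selection coefficient, refit statistics where
#'   computed, gate flags).
#' @slot verdict logical scalar.
#' @slot method feature-selection method used.
#' @slot config the [RegressionConfig] the run used.
#'
#' @export
setClass("CofactorReport",
    representation(results = "data.frame", allFactors = "data.frame",
                   verdict = "logical", method = "character",
                   config = "RegressionConfig"))

#' SiteClassification: classical / non-classical partition of HMR peaks
#'
#' @slot threshold the Otsu threshold on the response values (NA when the
#'   response was degenerate and no split was possible).
#' @slot labels character vector, one of `"classical"`/`"non_classical"`
#'   per peak; peaks with `Y < threshold` are non-classical.
#' @slot subsets named list: for each cofactor, the integer indices of
#'   non-classical peaks overlapped by that cofactor's peaks.
#'
#' @seealso [otsuThreshold()], [classifySites()], [cofactorSiteSubsets()]
#' @export
setClass("SiteClassification",
    representation(threshold = "numeric", labels = "character",
                   subsets = "list"))

setValidity("SiteClassification", function(object) {
    msg <- NULL
    if (!all(object@labels %in% c("classical", "non_classical")))
        msg <- c(msg, "labels must be 'classical' or 'non_classical'")
    nc <- which(object@labels == "non_classical")
    for (s in object@subsets)
        if (!all(s %in% nc)) {
            msg <- c(msg, "subsets may only contain non-classical indices")
            break
        }
    if (is.null(msg)) TRUE else msg
})

#' SimulatedDataset: synthetic HMR dataset with planted ground truth
#'
#' A synthetic counterpart of a real (HMR peaks, HM signal, factor peaks)
#' bundle: a bimodal per-peak response drawn from a two-component
#' truncated-normal mixture, per-peak ground-truth site labels, and a
#' binary cobinding matrix whose columns belong to four planted groups
#' (strong/weak x negative/positive association with the response).
#'
#' @slot peaks synthetic HMR [PeakSet] laid out on one synthetic
#'   chromosome.
#' @slot response the clean (or noise-perturbed) [ResponseVector].
#' @slot labels ground-truth per-peak labels, `"classical"` or
#'   `"non_classical"`.
#' @slot cobinding the planted [CobindingMatrix] (may have 0 columns
#'   before [simulateCobinding()] is called).
#' @slot groupOf named character vector mapping each factor to its group:
#'   `strong_negative`, `weak_negative`, `weak_positive`,
#'   `strong_positive`.
#' @slot params list of generator parameters (mixture means/SDs, fraction
#'   of non-classical sites, genome-wide mean signal, group sizes).
#' @slot noise character vector recording the noise operations applied,
#'   in order.
#' @slot seed integer seed the dataset was generated from.
#'
#' @seealso [simulateHmrDataset()], [simulateCobinding()], [addHmNoise()],
#'   [dropNonclassicalSites()], [flipCobinding()]
#' @export
setClass("SimulatedDataset",
    representation(peaks = "PeakSet", response = "ResponseVector",
                   labels = "character", cobinding = "CobindingMatrix",
                   groupOf = "character", params = "list",
                   noise = "character", seed = "integer"))

setValidity("SimulatedDataset", function(object) {
    msg <- NULL
    n <- length(object@response@values)
    if (length(object@labels) != n)
        msg <- c(msg, "labels and response lengths differ")
    if (length(object@peaks@ranges) != n)
        msg <- c(msg, "peaks and response lengths differ")
    if (ncol(object@cobinding@matrix) > 0L &&
        nrow(object@cobinding@matrix) != n)
        msg <- c(msg, "cobinding rows and response length differ")
    if (!all(object@labels %in% c("classical", "non_classical")))
        msg <- c(msg, "labels must be 'classical' or 'non_classical'")
    if (is.null(msg)) TRUE else msg
})
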