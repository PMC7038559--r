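#' @include AllClasses.R
NULL

#' Accessors for epiCofactor classes
#'
#' Small accessor generics: `factorName()` returns the factor label of a
#' [PeakSet]; `nPeaks()` its interval count; `peakRanges()` the underlying
#' `GRanges`; `responseValues()` the numeric Y of a [ResponseVector] or
#' [SimulatedDataset]; `cobindingMatrix()` the numeric X of a
#' [CobindingMatrix] or [SimulatedDataset]; `siteLabels()` the per-peak
#' labels of a [SiteClassification] or the ground truth of a
#' [SimulatedDataset]; `cofactorTable()` the ranked candidate table of a
#' [CofactorReport] and `verdict()` its non-classical-function call.
#'
#' @param x an object of the documented class.
#' @return the slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("factorName", function(x) standardGeneric("factorName"))

#' @rdname accessors
#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))

#' @rdname accessors
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))

#' @rdname accessors
#' @export
setGeneric("responseValues", function(x) standardGeneric("responseValues"))

#' @rdname accessors
#' @export
setGeneric("cobindingMatrix", function(x) standardGeneric("cobindingMatrix"))

#' @rdname accessors
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname accessors
#' @export
setGeneric("cofactorTable", function(x) standardGeneric("cofactorTable"))

#' @rdname accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setMethod("factorName", "PeakSet", function(x) x@factorName)

#' @rdname accessors
#' @export
setMethod("nPeaks", "PeakSet", function(x) length(x@ranges))

#' @rdname accessors
#' @export
setMethod("peakRanges", "PeakSet", function(x) x@ranges)

#' @rdname accessors
#' @export
setMethod("nPeaks", "SimulatedDataset", function(x) length(x@response@values))

#' @rdname accessors
#' @export
setMethod("peakRanges", "SimulatedDataset", function(x) x@peaks@ranges)

#' @rdname accessors
#' @export
setMethod("responseValues", "ResponseVector", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("responseValues", "SimulatedDataset", function(x) x@response@values)

#' @rdname accessors
#' @export
setMethod("cobindingMatrix", "CobindingMatrix", function(x) x@matrix)

#' @rdname accessors
#' @export
setMethod("cobindingMatrix", "SimulatedDataset", function(x) x@cobinding@matrix)

#' @rdname accessors
#' @export
setMethod("siteLabels", "SiteClassification", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("siteLabels", "SimulatedDataset", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("cofactorTable", "CofactorReport", function(x) x@results)

#' @rdname accessors
#' @export
setMethod("verdict", "CofactorReport", function(x) x@verdict)

setMethod("show", "PeakSet", function(object) {
    r <- object@ranges
    cat("PeakSet for", object@factorName, "with", length(r), "peaks on",
        length(unique(as.character(seqnames(r)))), "chromosome(s)\n")
})

setMethod("show", "SignalTrack", function(object) {
    cov <- object@coverage
    cat("SignalTrack '", object@name, "': ", length(cov),
        " chromosome(s), ", sum(as.numeric(lengths(cov))),
        " bp covered extent\n", sep = "")
})

setMethod("show", "ResponseVector", function(object) {
    cat("ResponseVector for", object@hmName, "over",
        length(object@values), "peaks (halfwidth",
        object@halfwidth, "bp); mean =",
        format(mean(object@values), digits = 4), "\n")
})

setMethod("show", "CobindingMatrix", function(object) {
    cat("CobindingMatrix (", object@mode, "): ",
        nrow(object@matrix), " peaks x ", ncol(object@matrix),
        " factors\n", sep = "")
})

setMethod("show", "CofactorReport", function(object) {
    cat("CofactorReport (", object@method, ")\n", sep = "")
    cat("  non-classical function predicted:",
        if (object@verdict) "YES" else "no", "\n")
    cat("  surviving cofactor candidates:", nrow(object@results), "\n")
    if (nrow(object@results))
        print(utils::head(object@results, 5L), row.names = FALSE)
})

setMethod("show", "SiteClassification", function(object) {
    tab <- table(factor(object@labels,
                        levels = c("classical", "non_classical")))
    cat("SiteClassification: threshold =",
        format(object@threshold, digits = 4), "\n  classical:",
        tab[["classical"]], " non-classical:", tab[["non_classical"]],
        "\n")
    if (length(object@subsets))
        cat("  cofactor subsets:",
            paste(sprintf("%s(%d)", names(object@subsets),
                          lengths(object@subsets)), collapse = ", "),
            "\n")
})

setMethod("show", "SimulatedDataset", function(object) {
    cat("SimulatedDataset:", length(object@labels), "peaks,",
        ncol(object@cobinding@matrix), "factors, seed", object@seed, "\n")
    cat("  non-classical fraction:",
        format(mean(object@labels == "non_classical"), digits = 3), "\n")
    if (length(object@noise))
        cat("  noise applied:", paste(object@noise, collapse = "; "), "\n")
})
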