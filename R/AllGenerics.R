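#' Number of telomeric ends in a set of calls
#'
#' @param x A [TelomereCalls-class] object.
#' @return Integer count of ends with `isTelomere == TRUE`.
#' @export
setGeneric("telomereCount", function(x) standardGeneric("telomereCount"))

#' @rdname telomereCount
#' @export
setMethod("telomereCount", "TelomereCalls",
          function(x) sum(x$isTelomere))

#' Selected centromere intervals
#'
#' @param x A [CentromereCalls-class] object.
#' @return A [GenomicRanges::GRanges] with one range per chromosome that
#'   received an unambiguous call.
#' @export
setGeneric("selectedCentromeres",
           function(x) standardGeneric("selectedCentromeres"))

#' @rdname selectedCentromeres
#' @export
setMethod("selectedCentromeres", "CentromereCalls", function(x) {
    cl <- x@calls
    ok <- !is.na(cl$start)
    GenomicRanges::GRanges(cl$chrom[ok],
                           IRanges::IRanges(cl$start[ok], cl$end[ok]))
})

#' Phred-scaled consensus quality value from a k-mer survey
#'
#' Per-base error probability is estimated as
#' `E = 1 - (1 - X/Y)^(1/k)` and reported as `QV = -10 log10(E)`; when no
#' assembly k-mer is unsupported (`X = 0`) the configured cap is returned.
#'
#' @param x A [KmerSurvey-class] object.
#' @param cap QV reported when `X = 0` (default 99).
#' @return A single numeric QV.
#' @export
setGeneric("estimateQV", function(x, cap = 99)
    standardGeneric("estimateQV"))

#' @rdname estimateQV
#' @export
setMethod("estimateQV", "KmerSurvey", function(x, cap = 99) {
    Y <- x@assemblyTotal
    X <- x@assemblyMissing
    if (Y <= 0)
        stop("no assembly k-mers surveyed (Y = 0); QV undefined")
    if (X == 0)
        return(cap)
    E <- 1 - (1 - X / Y)^(1 / x@k)
    -10 * log10(E)
})
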