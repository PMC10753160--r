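#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Per-end telomere calls
#'
#' A [S4Vectors::DataFrame()] subclass holding one row per chromosome end
#' with the motif-repeat evidence and the telomere verdict. Columns:
#' `chrom`, `end` (`"5prime"`/`"3prime"`), `repeatCount`, `scannedWindow`
#' (bp actually scanned, clipped to the sequence), `motif`, and
#' `isTelomere`. The calling parameters are kept in `metadata()`.
#'
#' @seealso [callTelomeres()], [telomereCount()]
#' @exportClass TelomereCalls
setClass("TelomereCalls", contains = "DFrame")

setValidity("TelomereCalls", function(object) {
    need <- c("chrom", "end", "repeatCount", "scannedWindow", "motif",
              "isTelomere")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(paste("missing columns:", paste(miss, collapse = ", ")))
    if (nrow(object)) {
        if (!all(object$end %in% c("5prime", "3prime")))
            return("end must be '5prime' or '3prime'")
        if (any(object$repeatCount < 0))
            return("repeatCount must be >= 0")
    }
    TRUE
})

#' Centromere candidate calls
#'
#' Holds, per chromosome, the ranked centromere candidate intervals and the
#' selected call (or none, when the evidence is ambiguous or absent).
#'
#' @slot calls A `DFrame` with one row per chromosome: `chrom`, `start`,
#'   `end`, `length` (NA when no call), `nCandidates`, `ambiguous`.
#' @slot candidates A [GenomicRanges::GRanges] of all candidate intervals
#'   with metadata columns `score` (summed tandem coverage in bp) and
#'   `rank` (1 = best per chromosome).
#' @seealso [callCentromeres()], [selectedCentromeres()]
#' @exportClass CentromereCalls
setClass("CentromereCalls",
    representation(calls = "DFrame", candidates = "GRanges"))

setValidity("CentromereCalls", function(object) {
    need <- c("chrom", "start", "end", "length", "nCandidates", "ambiguous")
    miss <- setdiff(need, colnames(object@calls))
    if (length(miss))
        return(paste("calls missing columns:", paste(miss, collapse = ", ")))
    TRUE
})

#' k-mer survey of an assembly against a read set
#'
#' Counts of assembly k-mer positions (`assemblyTotal`, the estimator's Y)
#' and of those whose canonical k-mer is unsupported by the read k-mer set
#' (`assemblyMissing`, X). Read k-mers seen fewer than `readKmerMinCount`
#' times are treated as absent (sequencing-error filtering).
#'
#' @slot k Odd k-mer size (>= 11).
#' @slot assemblyTotal Number of counted assembly k-mer positions.
#' @slot assemblyMissing Number of those unsupported by reads.
#' @slot readKmerMinCount Minimum read-side count for a k-mer to exist.
#' @seealso [assemblyKmerSurvey()], [estimateQV()]
#' @exportClass KmerSurvey
setClass("KmerSurvey",
    representation(k = "integer", assemblyTotal = "numeric",
                   assemblyMissing = "numeric", readKmerMinCount = "integer"))

setValidity("KmerSurvey", function(object) {
    if (length(object@k) != 1L || object@k < 11L || object@k %% 2L == 0L)
        return("k must be a single odd integer >= 11")
    if (object@assemblyMissing < 0 ||
        object@assemblyMissing > object@assemblyTotal)
        return("need 0 <= assemblyMissing <= assemblyTotal")
    TRUE
})

#' @describeIn TelomereCalls-class Compact display.
#' @param object A `TelomereCalls` object.
#' @export
setMethod("show", "TelomereCalls", function(object) {
    cat(sprintf("TelomereCalls: %d ends, %d telomeric (motifs %s)\n",
                nrow(object), sum(object$isTelomere),
                paste(unique(object$motif), collapse = "/")))
    callNextMethod()
})

#' @describeIn CentromereCalls-class Compact display.
#' @param object A `CentromereCalls` object.
#' @export
setMethod("show", "CentromereCalls", function(object) {
    ok <- !is.na(object@calls$start)
    cat(sprintf(
        "CentromereCalls: %d chromosomes, %d selected, %d ambiguous\n",
        nrow(object@calls), sum(ok), sum(object@calls$ambiguous)))
    show(object@calls)
})

#' @describeIn KmerSurvey-class Compact display.
#' @param object A `KmerSurvey` object.
#' @export
setMethod("show", "KmerSurvey", function(object) {
    cat(sprintf(
        "KmerSurvey: k=%d, Y=%.0f assembly k-mers, X=%.0f missing (minCount=%d)\n",
        object@k, object@assemblyTotal, object@assemblyMissing,
        object@readKmerMinCount))
})
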