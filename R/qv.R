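## k-mer-spectrum consensus quality value (QV).
##
## Canonical k-mers are encoded as base-4 integers held exactly in
## doubles (4^21 < 2^53), so no external k-mer counter is needed; read
## k-mer counts are aggregated with data.table.

## canonical (min of forward / reverse complement) k-mer codes for one
## sequence; NA where the window contains a non-ACGT base
.canonicalCodes <- function(seq, k) {
    b <- .baseCodes(seq)
    fw <- .kmerCodes(b, k)
    rc <- .rcKmerCodes(b, k)
    pmin(fw, rc)
}

#' Survey assembly k-mers against a read k-mer set
#'
#' Counts every assembly k-mer position (`Y`, with multiplicity,
#' matching the estimator's per-base error interpretation) and how many
#' of those positions carry a canonical k-mer seen fewer than
#' `readKmerMinCount` times in the reads (`X`). k-mers containing N are
#' skipped on both sides and excluded from `Y`.
#'
#' @param assembly DNAStringSet of the assembly.
#' @param reads DNAStringSet of the read set (FASTA/FASTQ via
#'   [readFasta()]; qualities are ignored).
#' @param k Odd k-mer size (default 21).
#' @param readKmerMinCount Minimum read-side count for a k-mer to be
#'   considered present (default 2; sequencing-error filtering).
#' @return A [KmerSurvey-class] object.
#' @export
assemblyKmerSurvey <- function(assembly, reads, k = 21L,
                               readKmerMinCount = 2L) {
    k <- as.integer(k)
    if (any(Biostrings::width(assembly) < k))
        stop("k exceeds the length of at least one assembly sequence")
    readCodes <- unlist(lapply(seq_along(reads), function(i)
        .canonicalCodes(reads[[i]], k)), use.names = FALSE)
    readCodes <- readCodes[!is.na(readCodes)]
    if (length(readCodes)) {
        dt <- data.table::data.table(code = readCodes)
        cnt <- dt[, .N, by = "code"]
        present <- cnt$code[cnt$N >= readKmerMinCount]
    } else present <- numeric(0)
    Y <- 0; X <- 0
    for (i in seq_along(assembly)) {
        ac <- .canonicalCodes(assembly[[i]], k)
        ac <- ac[!is.na(ac)]
        Y <- Y + length(ac)
        if (length(ac))
            X <- X + sum(!(ac %in% present))
    }
    methods::new("KmerSurvey", k = k, assemblyTotal = Y,
                 assemblyMissing = X,
                 readKmerMinCount = as.integer(readKmerMinCount))
}
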