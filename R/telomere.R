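#' Count non-overlapping telomere-motif repeats
#'
#' Counts exact, non-overlapping occurrences of `motif` in `seq`,
#' scanning left to right (greedy). Matching is strand-specific: the
#' reverse complement is never searched. The 7-bp plant telomere motifs
#' cannot overlap themselves, so greedy counting equals the number of
#' occurrences.
#'
#' @param seq A DNA string (character or [Biostrings::DNAString]).
#' @param motif Non-empty motif string, e.g. `"TTTAGGG"`.
#' @return Integer repeat count.
#' @export
countMotifRepeats <- function(seq, motif) {
    seq <- as.character(seq)
    motif <- as.character(motif)
    if (!nzchar(motif)) stop("motif must be non-empty")
    if (!nzchar(seq)) return(0L)
    m <- gregexpr(motif, seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
}

#' Motif-repeat counts in the two terminal windows of a sequence
#'
#' Counts `motif5` in the first `terminalWindow` bp and `motif3` in the
#' last `terminalWindow` bp; windows are clipped to the sequence length,
#' so short sequences are scanned whole.
#'
#' @param record A DNA sequence (character or `DNAString`).
#' @param motif5,motif3 Motifs searched at the 5' and 3' terminus.
#' @param terminalWindow Window size in bp (default 150000).
#' @return Named integer vector `c(c5 = ..., c3 = ...)`.
#' @export
terminalRepeatCounts <- function(record, motif5 = "CCCATTT",
                                 motif3 = "TTTAGGG",
                                 terminalWindow = 150000L) {
    s <- as.character(record)
    L <- nchar(s)
    w <- min(terminalWindow, L)
    c5 <- countMotifRepeats(substr(s, 1L, w), motif5)
    c3 <- countMotifRepeats(substr(s, L - w + 1L, L), motif3)
    c(c5 = c5, c3 = c3)
}

#' Default telomere-calling parameters
#'
#' The motifs are the plant-type repeats searched at each end (`CCCATTT`
#' upstream, `TTTAGGG` downstream). `minRepeats` (default 100) is the
#' acceptance threshold: an end is a telomere iff its repeat count
#' reaches it. `terminalWindow` (default 150 kb) bounds the scan.
#'
#' @param motif5,motif3 Terminal motifs.
#' @param terminalWindow Scan window in bp.
#' @param minRepeats Minimum repeat count for a telomere verdict.
#' @param screenWindow Maximum distance (bp) from a chromosome terminus
#'   for a read alignment to count as terminal (default 50).
#' @return A named list of parameters.
#' @export
telomereParams <- function(motif5 = "CCCATTT", motif3 = "TTTAGGG",
                           terminalWindow = 150000L, minRepeats = 100L,
                           screenWindow = 50L) {
    stopifnot(nzchar(motif5), nzchar(motif3),
              terminalWindow >= max(nchar(motif5), nchar(motif3)),
              minRepeats >= 1L, screenWindow >= 0L)
    list(motif5 = motif5, motif3 = motif3,
         terminalWindow = as.integer(terminalWindow),
         minRepeats = as.integer(minRepeats),
         screenWindow = as.integer(screenWindow))
}

#' Call telomeres at both ends of every chromosome
#'
#' Produces two calls per sequence (5' and 3'); an end is telomeric iff
#' its repeat count is at least `params$minRepeats`. This reproduces the
#' accept/reject logic by which an end carrying only a couple of motif
#' copies is not considered a telomere.
#'
#' @param records A [Biostrings::DNAStringSet].
#' @param params See [telomereParams()].
#' @return A [TelomereCalls-class] object (one row per end); the
#'   parameters used are stored in `metadata()`.
#' @export
callTelomeres <- function(records, params = telomereParams()) {
    n <- length(records)
    chrom <- rep(names(records), each = 2L)
    end <- rep(c("5prime", "3prime"), n)
    cnt <- integer(2L * n)
    win <- integer(2L * n)
    for (i in seq_len(n)) {
        cc <- terminalRepeatCounts(records[[i]], params$motif5,
                                   params$motif3, params$terminalWindow)
        cnt[2L * i - 1L] <- cc[["c5"]]
        cnt[2L * i] <- cc[["c3"]]
        win[(2L * i - 1L):(2L * i)] <-
            min(params$terminalWindow, Biostrings::width(records)[i])
    }
    df <- DataFrame(chrom = chrom, end = end, repeatCount = cnt,
                    scannedWindow = win,
                    motif = rep(c(params$motif5, params$motif3), n),
                    isTelomere = cnt >= params$minRepeats)
    out <- methods::new("TelomereCalls", df)
    metadata(out) <- list(params = params)
    out
}

#' Collect reads aligned to chromosome termini
#'
#' A read is assigned to a chromosome's 5' end iff its alignment starts
#' within `screenWindow` bp of the chromosome start, and to the 3' end
#' iff it ends within `screenWindow` bp of the chromosome end (a short
#' chromosome can satisfy both).
#'
#' @param alignments GRanges from [readPaf()].
#' @param chromLengths Named integer vector of chromosome lengths.
#' @param screenWindow Screening window in bp (default 50).
#' @return Named list mapping `"<chrom>:<5prime|3prime>"` to a character
#'   vector of read ids; ends with no reads are absent.
#' @export
collectTerminalReads <- function(alignments, chromLengths,
                                 screenWindow = 50L) {
    out <- list()
    if (!length(alignments)) return(out)
    chrom <- as.character(GenomeInfoDb::seqnames(alignments))
    unknown <- setdiff(unique(chrom), names(chromLengths))
    if (length(unknown))
        stop("PAF references unknown chromosome(s): ",
             paste(unknown, collapse = ", "))
    tstart0 <- GenomicRanges::start(alignments) - 1L  # PAF convention
    tend <- GenomicRanges::end(alignments)
    L <- unname(chromLengths[chrom])
    is5 <- tstart0 <= screenWindow
    is3 <- (L - tend) <= screenWindow
    ids <- mcols(alignments)$read_id
    addAll <- function(sel, endlab) {
        for (ch in unique(chrom[sel])) {
            key <- paste0(ch, ":", endlab)
            out[[key]] <<- unique(c(out[[key]], ids[sel & chrom == ch]))
        }
    }
    addAll(is5, "5prime")
    addAll(is3, "3prime")
    out
}

#' Select the reference read for an end by telomere-repeat count
#'
#' The read with the most motif repeats is the reference; the others are
#' queries. Ties break to the longest read, then the lexicographically
#' smallest id. A reference with zero repeats is still returned — the
#' caller decides whether patching is worthwhile.
#'
#' @param reads A [Biostrings::DNAStringSet] of candidate reads.
#' @param motif The end's telomere motif.
#' @return List with `referenceRead`, `queryReads`,
#'   `referenceRepeatCount`, and the per-read `counts`.
#' @export
selectReferenceRead <- function(reads, motif) {
    if (!length(reads)) stop("no reads to select from (no_reads)")
    cnt <- vapply(seq_along(reads),
                  function(i) countMotifRepeats(reads[[i]], motif),
                  integer(1))
    names(cnt) <- names(reads)
    o <- order(-cnt, -Biostrings::width(reads), names(reads))
    list(referenceRead = names(reads)[o[1]],
         queryReads = names(reads)[o[-1]],
         referenceRepeatCount = unname(cnt[o[1]]),
         counts = cnt)
}

#' Patch one chromosome terminus with the selected reference read
#'
#' The terminal span covered by the reference read's alignment is
#' replaced by the read sequence (reverse-complemented for minus-strand
#' alignments), extending the chromosome when the read runs past the
#' assembled end. If the end already carries at least as many repeats as
#' the reference read, the sequence is left untouched
#' (`already_complete`).
#'
#' @param record DNA sequence of the chromosome (character/`DNAString`).
#' @param selection Output of [selectReferenceRead()].
#' @param anchor One-row GRanges (from [readPaf()]) for the reference
#'   read on this chromosome.
#' @param reads DNAStringSet holding at least the reference read.
#' @param end `"5prime"` or `"3prime"`.
#' @param params See [telomereParams()].
#' @return List `seq` (patched character sequence) and `report` (one-row
#'   `DFrame`: chrom, end, preCount, postCount, replacedSpan, status).
#' @export
patchTerminus <- function(record, selection, anchor, reads,
                          end = c("5prime", "3prime"),
                          params = telomereParams()) {
    end <- match.arg(end)
    s <- as.character(record)
    L <- nchar(s)
    chrom <- as.character(GenomeInfoDb::seqnames(anchor))
    motif <- if (end == "5prime") params$motif5 else params$motif3
    pre <- unname(terminalRepeatCounts(
        s, params$motif5, params$motif3,
        params$terminalWindow)[if (end == "5prime") "c5" else "c3"])
    if (mcols(anchor)$read_id != selection$referenceRead)
        stop("anchor does not belong to the reference read")
    report <- function(post, span, status)
        DataFrame(chrom = chrom, end = end, preCount = pre,
                  postCount = post, replacedSpan = span, status = status)
    if (selection$referenceRepeatCount <= pre)
        return(list(seq = s,
                    report = report(pre, 0L, "already_complete")))
    rseq <- as.character(reads[[selection$referenceRead]])
    if (as.character(GenomicRanges::strand(anchor)) == "-")
        rseq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(rseq)))
    tstart0 <- GenomicRanges::start(anchor) - 1L
    tend <- GenomicRanges::end(anchor)
    if (end == "5prime") {
        patched <- paste0(rseq, substr(s, tend + 1L, L))
        span <- tend
    } else {
        patched <- paste0(substr(s, 1L, tstart0), rseq)
        span <- L - tstart0
    }
    post <- unname(terminalRepeatCounts(
        patched, params$motif5, params$motif3,
        params$terminalWindow)[if (end == "5prime") "c5" else "c3"])
    list(seq = patched, report = report(post, as.integer(span), "patched"))
}

#' Patch every incomplete terminus of a genome from terminal reads
#'
#' Orchestrates the terminal-repair procedure: collect terminal reads per
#' end (50-bp screening window by default), pick the read with the most
#' motif repeats as reference, and splice it over the terminus. The 3'
#' end is patched before the 5' end so stored alignment coordinates stay
#' valid. Ends with no terminal reads are reported as `no_reads`.
#'
#' @param genome DNAStringSet of chromosomes.
#' @param alignments GRanges from [readPaf()].
#' @param reads DNAStringSet of the terminal reads.
#' @param params See [telomereParams()].
#' @return List `genome` (patched DNAStringSet) and `report` (`DFrame`,
#'   one row per chromosome end).
#' @export
patchTelomeres <- function(genome, alignments, reads,
                           params = telomereParams()) {
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    byEnd <- collectTerminalReads(alignments, lens, params$screenWindow)
    seqs <- as.character(genome)
    reports <- list()
    for (ch in names(genome)) {
        for (e in c("3prime", "5prime")) {  # 3' first: keeps 5' coords valid
            key <- paste0(ch, ":", e)
            motif <- if (e == "5prime") params$motif5 else params$motif3
            ids <- byEnd[[key]]
            if (is.null(ids) || !length(ids)) {
                pre <- unname(terminalRepeatCounts(
                    seqs[[ch]], params$motif5, params$motif3,
                    params$terminalWindow)[if (e == "5prime") "c5" else "c3"])
                reports[[key]] <- DataFrame(
                    chrom = ch, end = e, preCount = pre, postCount = pre,
                    replacedSpan = 0L, status = "no_reads")
                next
            }
            sel <- selectReferenceRead(reads[ids], motif)
            cand <- alignments[
                mcols(alignments)$read_id == sel$referenceRead &
                as.character(GenomeInfoDb::seqnames(alignments)) == ch]
            if (e == "5prime") {
                cand <- cand[GenomicRanges::start(cand) - 1L <=
                             params$screenWindow]
            } else {
                cand <- cand[lens[[ch]] - GenomicRanges::end(cand) <=
                             params$screenWindow]
            }
            anchor <- cand[which.max(GenomicRanges::width(cand))]
            res <- patchTerminus(seqs[[ch]], sel, anchor, reads, e, params)
            seqs[[ch]] <- res$seq
            reports[[key]] <- res$report
        }
    }
    rep <- do.call(rbind, unname(reports))
    list(genome = Biostrings::DNAStringSet(seqs), report = rep)
}
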