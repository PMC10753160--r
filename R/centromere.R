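## Tandem-repeat array detection and multi-evidence centromere calling.
##
## The detector is a functional stand-in for an alignment-based tandem
## repeat finder, built for centromere-scale arrays: candidate regions
## are seeded by k-mer recurrence distances (in a tandem array of period
## p, the k-mer starting at i reappears at i + p), the period is taken as
## the smallest offset whose exact self-match fraction reaches the purity
## threshold, and boundaries are refined to the maximal extent supported
## by a sliding purity window.

.BASE4 <- {
    v <- rep(NA_real_, 256)
    v[utf8ToInt("A")] <- 0; v[utf8ToInt("C")] <- 1
    v[utf8ToInt("G")] <- 2; v[utf8ToInt("T")] <- 3
    v
}

## numeric base codes 0..3 (NA for N) for one sequence
.baseCodes <- function(seq) .BASE4[utf8ToInt(as.character(seq))]

## k-mer codes at every start position (length n-k+1); NA where any base N
.kmerCodes <- function(b, k) {
    n <- length(b)
    if (n < k) return(numeric(0))
    m <- n - k + 1L
    code <- numeric(m)
    for (j in 0:(k - 1L))
        code <- code + b[(1L + j):(m + j)] * 4^(k - 1L - j)
    code
}

## reverse-complement k-mer codes for the same windows
.rcKmerCodes <- function(b, k) {
    n <- length(b)
    if (n < k) return(numeric(0))
    m <- n - k + 1L
    rb <- 3 - b
    code <- numeric(m)
    for (j in 0:(k - 1L))
        code <- code + rb[(1L + j):(m + j)] * 4^j
    code
}

## left-aligned rolling mean over window w via cumsum
.rollMean <- function(x, w) {
    n <- length(x)
    if (n < w) return(numeric(0))
    cs <- cumsum(c(0, x))
    (cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]) / w
}

## runs of TRUE, merging gaps <= gap; matrix with columns start,end
.trueRuns <- function(x, gap = 0L) {
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(cbind(start = integer(0), end = integer(0)))
    s <- starts[keep]; e <- ends[keep]
    if (gap > 0L && length(s) > 1L) {
        ms <- s[1]; me <- e[1]; outS <- integer(0); outE <- integer(0)
        for (i in 2:length(s)) {
            if (s[i] - me - 1L <= gap) me <- e[i]
            else { outS <- c(outS, ms); outE <- c(outE, me)
                   ms <- s[i]; me <- e[i] }
        }
        s <- c(outS, ms); e <- c(outE, me)
    }
    cbind(start = s, end = e)
}

#' Detect tandem-repeat arrays in one sequence
#'
#' Finds maximal, non-overlapping tandem arrays with period between
#' `minPeriod` and `maxPeriod`, at least `minArrayLen` bp long (and at
#' least two periods), whose self-match purity — the fraction of
#' positions `i` in the array with `s[i] == s[i + period]` — reaches
#' `minPurity`. The reported period is the smallest one achieving the
#' purity threshold, so a perfect dimer of the monomer is never reported
#' in place of the monomer. Deterministic for fixed input.
#'
#' @param seq DNA sequence (character or `DNAString`).
#' @param minPeriod,maxPeriod Period search range in bp (defaults 20 and
#'   2000).
#' @param minArrayLen Minimum array length in bp (default 10000).
#' @param minPurity Minimum self-match purity (default 0.7).
#' @param seedK k-mer size used for seeding (default 11).
#' @param seedDensity Minimum seed fraction for a candidate region
#'   (default 0.15).
#' @return `data.frame` with columns `start`, `end` (1-based inclusive),
#'   `period`, `copies`, `purity`, sorted by `start`; zero rows when
#'   nothing qualifies.
#' @export
findTandemArrays <- function(seq, minPeriod = 20L, maxPeriod = 2000L,
                             minArrayLen = 10000L, minPurity = 0.7,
                             seedK = 11L, seedDensity = 0.15) {
    stopifnot(minPeriod >= 1L, minPeriod <= maxPeriod)
    s <- as.character(seq)
    n <- nchar(s)
    empty <- data.frame(start = integer(0), end = integer(0),
                        period = integer(0), copies = numeric(0),
                        purity = numeric(0))
    if (n < max(minArrayLen, 2L * minPeriod)) return(empty)
    b <- .baseCodes(s)
    codes <- .kmerCodes(b, seedK)
    pos <- which(!is.na(codes))
    if (!length(pos)) return(empty)
    dt <- data.table::data.table(code = codes[pos], pos = pos)
    data.table::setorder(dt, code, pos)
    dt[, d := pos - data.table::shift(pos), by = "code"]
    dist <- rep(NA_real_, n)
    dist[dt$pos] <- dt$d
    seed <- !is.na(dist) & dist >= minPeriod & dist <= maxPeriod
    w <- max(30L, min(as.integer(minArrayLen), 5000L))
    dens <- .rollMean(as.numeric(seed), w)
    if (!length(dens)) return(empty)
    regions <- .trueRuns(dens >= seedDensity, gap = w)
    if (!nrow(regions)) return(empty)
    out <- list()
    for (r in seq_len(nrow(regions))) {
        a <- regions[r, "start"]
        bnd <- min(n, regions[r, "end"] + w - 1L)
        sp <- which(seed[a:bnd]) + a - 1L
        if (length(sp) < 3L) next
        a <- sp[1]; bnd <- sp[length(sp)]
        dmode <- as.integer(names(sort(table(dist[sp]),
                                       decreasing = TRUE))[1])
        arr <- .refineArray(b, n, a, bnd, dmode, minPeriod, minPurity,
                            minArrayLen)
        if (!is.null(arr)) out[[length(out) + 1L]] <- arr
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    ## enforce non-overlap: keep the strongest (purity * length) first
    res <- res[order(-(res$end - res$start + 1L) * res$purity), ,
               drop = FALSE]
    keep <- rep(TRUE, nrow(res))
    for (i in seq_len(nrow(res))) {
        if (!keep[i]) next
        if (i < nrow(res)) for (j in (i + 1L):nrow(res)) {
            if (keep[j] && res$start[j] <= res$end[i] &&
                res$end[j] >= res$start[i]) keep[j] <- FALSE
        }
    }
    res <- res[keep, , drop = FALSE]
    res[order(res$start), , drop = FALSE]
}

## choose smallest qualifying period and refine boundaries around [a, bnd]
.refineArray <- function(b, n, a, bnd, dmode, minPeriod, minPurity,
                         minArrayLen) {
    if (bnd - a + 1L < 2L * minPeriod) return(NULL)
    eqFrac <- function(p, i1, i2) {
        i2p <- min(i2, n - p)
        if (i2p - i1 + 1L < max(2L, p)) return(0)
        mean(b[i1:i2p] == b[(i1 + p):(i2p + p)], na.rm = TRUE)
    }
    pmax_try <- min(dmode, bnd - a)
    period <- NA_integer_
    for (p in minPeriod:pmax_try) {
        if (eqFrac(p, a, bnd) >= minPurity) { period <- p; break }
    }
    if (is.na(period)) {
        if (eqFrac(dmode, a, bnd) >= minPurity) period <- dmode
        else return(NULL)
    }
    p <- period
    pad <- max(2L * p, 100L)
    a2 <- max(1L, a - pad)
    b2 <- min(n - p, bnd + pad)
    if (b2 <= a2) return(NULL)
    eq <- b[a2:b2] == b[(a2 + p):(b2 + p)]
    eq[is.na(eq)] <- FALSE
    rw <- max(10L, min(2L * p, as.integer(floor(length(eq) / 2))))
    rm_ <- .rollMean(as.numeric(eq), rw)
    if (!length(rm_)) return(NULL)
    runs <- .trueRuns(rm_ >= minPurity, gap = rw)
    if (!nrow(runs)) return(NULL)
    ## pick the run overlapping the seed region
    mid <- (a + bnd) / 2 - a2 + 1L
    sel <- which(runs[, "start"] <= mid + rw & runs[, "end"] + rw >= mid)
    if (!length(sel))
        sel <- which.max(runs[, "end"] - runs[, "start"])
    run <- runs[sel[1], ]
    lo <- run[["start"]]
    hi <- min(length(eq), run[["end"]] + rw - 1L)
    ## anchor both boundaries on a short all-match run so chance matches
    ## in the flanks cannot drag the array past its true extent
    t <- min(p, 10L)
    runOk <- function(i) i >= 1L && i + t - 1L <= length(eq) &&
        all(eq[i:(i + t - 1L)])
    while (lo <= hi && !runOk(lo)) lo <- lo + 1L
    while (hi >= lo && !runOk(hi - t + 1L)) hi <- hi - 1L
    if (hi <= lo) return(NULL)
    start <- a2 + lo - 1L
    end <- a2 + hi - 1L + p
    len <- end - start + 1L
    if (len < max(minArrayLen, 2L * p)) return(NULL)
    purity <- mean(b[start:(end - p)] == b[(start + p):end], na.rm = TRUE)
    if (is.na(purity) || purity < minPurity) return(NULL)
    data.frame(start = start, end = end, period = p,
               copies = len / p, purity = purity)
}

#' Detect tandem arrays genome-wide
#'
#' @param genome DNAStringSet.
#' @param ... Passed to [findTandemArrays()].
#' @return GRanges with metadata columns `period`, `copies`, `purity`.
#' @export
findGenomeTandemArrays <- function(genome, ...) {
    per <- lapply(names(genome), function(ch) {
        df <- findTandemArrays(genome[[ch]], ...)
        if (nrow(df)) df$chrom <- ch
        df
    })
    df <- do.call(rbind, per)
    if (is.null(df) || !nrow(df)) {
        gr <- GenomicRanges::GRanges()
        mcols(gr) <- S4Vectors::DataFrame(period = integer(0),
            copies = numeric(0), purity = numeric(0))
        return(gr)
    }
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(df$start, df$end))
    mcols(gr) <- S4Vectors::DataFrame(period = df$period,
        copies = df$copies, purity = df$purity)
    gr
}

## bp of each tile covered by the reduced interval set
.coveredBp <- function(tiles, gr) {
    out <- numeric(length(tiles))
    if (!length(gr)) return(out)
    red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
    ov <- GenomicRanges::findOverlaps(tiles, red, ignore.strand = TRUE)
    if (!length(ov)) return(out)
    pi <- GenomicRanges::pintersect(tiles[S4Vectors::queryHits(ov)],
                                    red[S4Vectors::subjectHits(ov)],
                                    ignore.strand = TRUE)
    tapplyed <- tapply(GenomicRanges::width(pi),
                       S4Vectors::queryHits(ov), sum)
    out[as.integer(names(tapplyed))] <- as.numeric(tapplyed)
    out
}

#' Per-window centromere evidence features
#'
#' Tiles every chromosome into fixed windows (the final window per
#' chromosome may be shorter) and computes, per window, the fraction
#' covered by tandem arrays, the number of overlapping genes, the
#' fraction covered by Gypsy-LTR intervals, and whether the window
#' midpoint falls inside a Hi-C blank region (NA when no blank mask is
#' supplied).
#'
#' @param genome DNAStringSet (chromosome lengths are taken from it).
#' @param arrays GRanges of tandem arrays ([findGenomeTandemArrays()]).
#' @param genes GRanges of gene models.
#' @param gypsy GRanges of Gypsy-LTR intervals.
#' @param hicBlank Optional GRanges of Hi-C blank regions.
#' @param window Window size in bp (default 60000, the screening window
#'   the centromere prediction operates at).
#' @return `DFrame` with columns `chrom`, `start`, `end`,
#'   `tandemFraction`, `geneCount`, `gypsyFraction`, `hicBlank`.
#' @export
windowFeatures <- function(genome, arrays, genes, gypsy,
                           hicBlank = NULL, window = 60000L) {
    sl <- stats::setNames(Biostrings::width(genome), names(genome))
    tiles <- GenomicRanges::tileGenome(sl, tilewidth = window,
                                       cut.last.tile.in.chrom = TRUE)
    wlen <- GenomicRanges::width(tiles)
    tf <- .coveredBp(tiles, arrays) / wlen
    gf <- .coveredBp(tiles, gypsy) / wlen
    gc <- GenomicRanges::countOverlaps(tiles, genes, ignore.strand = TRUE)
    if (is.null(hicBlank) || !length(hicBlank)) {
        hb <- rep(NA, length(tiles))
    } else {
        mids <- GenomicRanges::resize(tiles, width = 1L, fix = "center")
        hb <- GenomicRanges::countOverlaps(mids, hicBlank,
                                           ignore.strand = TRUE) > 0L
    }
    DataFrame(chrom = as.character(GenomeInfoDb::seqnames(tiles)),
              start = GenomicRanges::start(tiles),
              end = GenomicRanges::end(tiles),
              tandemFraction = tf, geneCount = as.integer(gc),
              gypsyFraction = gf, hicBlank = hb)
}

#' Default centromere-calling parameters
#'
#' Thresholds for the multi-evidence rule: a window is centromere-like
#' iff its tandem coverage is at least `minTandem`, it overlaps at most
#' `maxGeneCount` genes, its Gypsy coverage is at least `minGypsy`, and —
#' when a Hi-C blank mask was supplied — it lies in a blank region.
#' Passing windows are merged across gaps of up to `mergeGapWindows`
#' windows; per chromosome the top candidate by summed tandem coverage is
#' selected unless the runner-up is within `ambiguityMargin` (relative),
#' in which case the call is withheld as ambiguous.
#'
#' @param minTandem Minimum per-window tandem coverage fraction.
#' @param maxGeneCount Maximum genes per window.
#' @param minGypsy Minimum Gypsy coverage fraction.
#' @param mergeGapWindows Merge gap, in windows.
#' @param ambiguityMargin Relative score margin below which two top
#'   candidates are considered indistinguishable.
#' @param window Window size in bp.
#' @return Named parameter list.
#' @export
centromereParams <- function(minTandem = 0.3, maxGeneCount = 1L,
                             minGypsy = 0.1, mergeGapWindows = 2L,
                             ambiguityMargin = 0.2, window = 60000L) {
    list(minTandem = minTandem, maxGeneCount = as.integer(maxGeneCount),
         minGypsy = minGypsy,
         mergeGapWindows = as.integer(mergeGapWindows),
         ambiguityMargin = ambiguityMargin, window = as.integer(window))
}

#' Call centromere candidates from window features
#'
#' Applies the multi-evidence window rule (see [centromereParams()]),
#' merges passing windows into candidate intervals, ranks candidates by
#' summed tandem coverage and selects one per chromosome — or withholds
#' the call as ambiguous when two candidates score within the ambiguity
#' margin, mirroring the situation where two regions on one chromosome
#' cannot be told apart. When `arrays` is supplied, the selected interval
#' is trimmed to the extent of the tandem arrays it contains, which
#' sharpens boundaries beyond window resolution.
#'
#' @param features `DFrame` from [windowFeatures()].
#' @param arrays Optional GRanges of tandem arrays used for boundary
#'   trimming.
#' @param params See [centromereParams()].
#' @return A [CentromereCalls-class] object.
#' @export
callCentromeres <- function(features, arrays = NULL,
                            params = centromereParams()) {
    useHic <- !all(is.na(features$hicBlank))
    pass <- features$tandemFraction >= params$minTandem &
        features$geneCount <= params$maxGeneCount &
        features$gypsyFraction >= params$minGypsy
    if (useHic) pass <- pass & !is.na(features$hicBlank) &
        features$hicBlank
    chroms <- unique(features$chrom)
    callRows <- list()
    candList <- list()
    for (ch in chroms) {
        sel <- features$chrom == ch
        f <- features[sel, , drop = FALSE]
        p <- pass[sel]
        if (!any(p)) {
            callRows[[ch]] <- DataFrame(chrom = ch, start = NA_integer_,
                end = NA_integer_, length = NA_integer_,
                nCandidates = 0L, ambiguous = FALSE)
            next
        }
        wgr <- GenomicRanges::GRanges(ch,
            IRanges::IRanges(f$start[p], f$end[p]))
        score_w <- f$tandemFraction[p] *
            (f$end[p] - f$start[p] + 1)
        cand <- GenomicRanges::reduce(wgr,
            min.gapwidth = params$mergeGapWindows * params$window +
                params$window)
        ov <- GenomicRanges::findOverlaps(wgr, cand)
        sc <- tapply(score_w[S4Vectors::queryHits(ov)],
                     S4Vectors::subjectHits(ov), sum)
        score <- numeric(length(cand))
        score[as.integer(names(sc))] <- as.numeric(sc)
        o <- order(-score)
        cand <- cand[o]; score <- score[o]
        mcols(cand)$score <- score
        mcols(cand)$rank <- seq_along(cand)
        candList[[ch]] <- cand
        ambiguous <- length(cand) >= 2L &&
            (score[1] - score[2]) < params$ambiguityMargin * score[1]
        if (ambiguous) {
            callRows[[ch]] <- DataFrame(chrom = ch, start = NA_integer_,
                end = NA_integer_, length = NA_integer_,
                nCandidates = length(cand), ambiguous = TRUE)
        } else {
            top <- cand[1]
            if (!is.null(arrays) && length(arrays)) {
                inArr <- arrays[as.character(
                    GenomeInfoDb::seqnames(arrays)) == ch]
                hit <- inArr[GenomicRanges::start(inArr) <=
                                 GenomicRanges::end(top) &
                             GenomicRanges::end(inArr) >=
                                 GenomicRanges::start(top)]
                if (length(hit)) {
                    ## the arrays are the physical feature; windows only
                    ## locate them — report the array extent
                    top <- GenomicRanges::GRanges(ch, IRanges::IRanges(
                        min(GenomicRanges::start(hit)),
                        max(GenomicRanges::end(hit))))
                }
            }
            callRows[[ch]] <- DataFrame(chrom = ch,
                start = GenomicRanges::start(top),
                end = GenomicRanges::end(top),
                length = GenomicRanges::width(top),
                nCandidates = length(cand), ambiguous = FALSE)
        }
    }
    calls <- do.call(rbind, unname(callRows))
    candidates <- if (length(candList)) {
        suppressWarnings(do.call(c, unname(candList)))
    } else GenomicRanges::GRanges()
    methods::new("CentromereCalls", calls = calls,
                 candidates = candidates)
}
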