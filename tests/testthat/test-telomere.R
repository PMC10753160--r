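test_that("motif counting is exact, greedy and strand-specific", {
    expect_identical(countMotifRepeats("", "CCCATTT"), 0L)
    set.seed(1)
    arr <- strrep("CCCATTT", 5)
    flank <- function(n) gsub("CCCATTT", "ACCATTT", randDna(n),
                              fixed = TRUE)
    s <- paste0(flank(200), arr, flank(200))
    expect_identical(countMotifRepeats(s, "CCCATTT"), 5L)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(arr)))
    expect_identical(countMotifRepeats(rc, "CCCATTT"), 0L)
    expect_error(countMotifRepeats("ACGT", ""), "non-empty")
})

test_that("motif counting agrees with a sliding-scan oracle", {
    set.seed(99)
    for (i in 1:25) {
        motif <- randDna(sample(3:8, 1))
        s <- randDna(sample(c(500, 2000, 10000), 1))
        ## salt with planted copies so counts are non-trivial
        pos <- sample(nchar(s) - 100, 3)
        for (p in pos)
            substr(s, p, p + 2 * nchar(motif) - 1) <- strrep(motif, 2)
        expect_identical(countMotifRepeats(s, motif),
                         oracleMotifCount(s, motif))
    }
})

test_that("terminal windows clip to short sequences", {
    s <- paste0(strrep("CCCATTT", 3), "ACGTACGT", strrep("TTTAGGG", 4))
    cc <- terminalRepeatCounts(s, terminalWindow = 1e6)
    expect_identical(unname(cc), c(3L, 4L))
})

test_that("telomere verdicts follow the repeat threshold", {
    set.seed(2)
    clean <- function(n) gsub("CCCATTT", "ACCATTT",
        gsub("TTTAGGG", "TTTAGGC", randDna(n), fixed = TRUE),
        fixed = TRUE)
    g <- Biostrings::DNAStringSet(c(
        ok = paste0(strrep("CCCATTT", 120), clean(5000),
                    strrep("TTTAGGG", 111)),
        barely = paste0(strrep("CCCATTT", 2), clean(5000),
                        strrep("TTTAGGG", 100))))
    calls <- callTelomeres(g)
    df <- as.data.frame(calls)
    expect_identical(df$isTelomere, c(TRUE, TRUE, FALSE, TRUE))
    expect_identical(telomereCount(calls), 3L)
    expect_identical(df$repeatCount[3], 2L)   # rejected end, counted anyway

    bare <- Biostrings::DNAStringSet(c(b1 = randDna(3000)))
    expect_identical(telomereCount(callTelomeres(bare)), 0L)
})

test_that("terminal read collection honours the screening window", {
    L <- 100000L
    mk <- function(id, tstart, tend) {
        gr <- GenomicRanges::GRanges("Chr1",
            IRanges::IRanges(tstart + 1, tend), strand = "+")
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            read_id = id, read_len = 1000L, read_start = 0L,
            read_end = 1000L, nmatch = 1000L, alen = 1000L,
            mapq = 60L, tlen = L)
        gr
    }
    aln <- c(mk("in3", L - 1010, L - 10), mk("out3", L - 1100, L - 100),
             mk("in5", 40, 1040))
    got <- collectTerminalReads(aln, c(Chr1 = L), screenWindow = 50)
    expect_identical(got[["Chr1:3prime"]], "in3")
    expect_identical(got[["Chr1:5prime"]], "in5")
    expect_identical(collectTerminalReads(aln[0], c(Chr1 = L)), list())
    expect_error(collectTerminalReads(aln, c(ChrX = L)), "unknown")
})

test_that("reference-read selection follows count then length then id", {
    reads <- Biostrings::DNAStringSet(c(
        r1 = paste0(strrep("TTTAGGG", 5), randDna(100)),
        r2 = paste0(strrep("TTTAGGG", 9), randDna(300)),
        r3 = paste0(strrep("TTTAGGG", 9), randDna(100))))
    sel <- selectReferenceRead(reads, "TTTAGGG")
    expect_identical(sel$referenceRead, "r2")       # tie broken by length
    expect_identical(sel$referenceRepeatCount, 9L)
    expect_setequal(sel$queryReads, c("r1", "r3"))

    one <- selectReferenceRead(reads[1], "TTTAGGG")
    expect_identical(one$referenceRead, "r1")
    expect_length(one$queryReads, 0L)

    none <- Biostrings::DNAStringSet(c(a = randDna(50), b = randDna(80)))
    sel0 <- selectReferenceRead(none, "TTTAGGG")
    expect_identical(sel0$referenceRepeatCount, 0L)
    expect_identical(sel0$referenceRead, "b")        # 0-tie: longest
    expect_error(selectReferenceRead(none[0], "TTTAGGG"), "no_reads")
})

test_that("patching restores truncated termini and never loses repeats", {
    cfg <- genomeConfig(nChrom = 1L, chromLength = 5e4,
        telomereCounts = matrix(c(80L, 20L), 1, 2),
        centromeres = list(list()))
    b <- simulateGenome(cfg, seed = 21)
    rd <- simulateTerminalReads(b, "Chr1", "3prime", nReads = 4,
                                extensionRepeats = 130, seed = 3)
    pt <- patchTelomeres(b$genome, rd$alignments, rd$reads)
    rep3 <- pt$report[pt$report$end == "3prime", ]
    expect_identical(as.character(rep3$status), "patched")
    expect_identical(rep3$preCount, 20L)
    expect_identical(rep3$postCount,
                     max(rd$manifest$trueRepeatCount))
    expect_true(all(pt$report$postCount >= pt$report$preCount))
    rep5 <- pt$report[pt$report$end == "5prime", ]
    expect_identical(as.character(rep5$status), "no_reads")

    ## an end already at least as complete as the best read is untouched
    sel <- selectReferenceRead(rd$reads, "TTTAGGG")
    sel$referenceRepeatCount <- 10L
    anchor <- rd$alignments[
        S4Vectors::mcols(rd$alignments)$read_id == sel$referenceRead]
    res <- patchTerminus(b$genome[["Chr1"]], sel, anchor, rd$reads,
                         "3prime")
    expect_identical(as.character(res$report$status), "already_complete")
    expect_identical(res$seq, as.character(b$genome[["Chr1"]]))
})
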