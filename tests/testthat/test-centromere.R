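test_that("random sequence yields no tandem arrays", {
    for (seed in 1:5) {
        set.seed(seed)
        arr <- findTandemArrays(randDna(1e5), minArrayLen = 5000,
                                minPurity = 0.8)
        expect_identical(nrow(arr), 0L)
    }
})

test_that("an exact small array is recovered with perfect purity", {
    set.seed(12)
    monomer <- randDna(10)
    flank <- function(n) randDna(n)
    s <- paste0(flank(300), strrep(monomer, 4), flank(300))
    arr <- findTandemArrays(s, minPeriod = 5, maxPeriod = 50,
                            minArrayLen = 40)
    expect_identical(nrow(arr), 1L)
    expect_identical(arr$period, 10L)
    expect_equal(arr$purity, 1.0)
    expect_equal(arr$copies, 4.0)
    expect_identical(arr$start, 301L)
    expect_identical(arr$end, 340L)
})

test_that("a diverged monomer array is localised with the right period", {
    cfg <- genomeConfig(nChrom = 1L, chromLength = 2e5,
        telomereCounts = matrix(c(0L, 0L), 1, 2),
        centromeres = list(list(list(lengthBp = 171 * 300,
            monomerLength = 171L, divergence = 0.02,
            centerFrac = 0.5))))
    b <- simulateGenome(cfg, seed = 31)
    tr <- b$manifest$chromosomes$Chr1$centromeres[[1]]
    arr <- findTandemArrays(b$genome[[1]])
    expect_identical(nrow(arr), 1L)
    expect_true(arr$period >= 169 && arr$period <= 173)
    expect_gte(jaccardIv(arr$start, arr$end, tr$start, tr$end), 0.9)

    ## reported purity equals an independent recomputation
    s <- strsplit(as.character(b$genome[[1]]), "")[[1]]
    i <- arr$start:(arr$end - arr$period)
    expect_equal(arr$purity, mean(s[i] == s[i + arr$period]))
})

test_that("window features compute coverage fractions and gene counts", {
    g <- Biostrings::DNAStringSet(c(Chr1 = randDna(180000)))
    arrays <- GenomicRanges::GRanges("Chr1",
        IRanges::IRanges(60001, 120000))
    S4Vectors::mcols(arrays) <- S4Vectors::DataFrame(
        period = 171L, copies = 350, purity = 0.95)
    gypsy <- GenomicRanges::GRanges("Chr1",
        IRanges::IRanges(c(1, 15001), c(10000, 35000)))
    genes <- GenomicRanges::GRanges()
    S4Vectors::mcols(genes)$gene_id <- character(0)
    S4Vectors::mcols(genes)$rank <- integer(0)
    f <- windowFeatures(g, arrays, genes, gypsy)
    expect_identical(nrow(f), 3L)
    expect_equal(f$tandemFraction, c(0, 1, 0))
    expect_equal(f$gypsyFraction[1], 0.5)    # 30 kb covered of 60 kb
    expect_identical(f$geneCount, rep(0L, 3))
    expect_true(all(is.na(f$hicBlank)))
})

test_that("centromere calling withholds when nothing passes and is
           invariant under chromosome renaming", {
    cfg <- genomeConfig(nChrom = 2L, chromLength = 1e6)
    b <- simulateGenome(cfg, seed = 41)
    arr <- findGenomeTandemArrays(b$genome)
    f <- windowFeatures(b$genome, arr, b$genes, b$gypsy)
    cc <- callCentromeres(f, arr)
    expect_identical(sum(!is.na(cc@calls$start)), 2L)

    ## renaming chromosomes must not change the intervals
    ren <- c(Chr1 = "pseudoA", Chr2 = "pseudoB")
    g2 <- b$genome; names(g2) <- unname(ren[names(b$genome)])
    rn <- function(gr) {
        GenomeInfoDb::seqlevels(gr) <-
            unname(ren[GenomeInfoDb::seqlevels(gr)])
        gr
    }
    f2 <- windowFeatures(g2, rn(arr), rn(b$genes), rn(b$gypsy))
    cc2 <- callCentromeres(f2, rn(arr))
    expect_identical(cc2@calls$start, cc@calls$start)
    expect_identical(cc2@calls$end, cc@calls$end)

    ## thresholds that nothing meets -> no candidates, call withheld
    hard <- centromereParams(minTandem = 0.999, minGypsy = 0.999)
    cc3 <- callCentromeres(f, arr, hard)
    expect_true(all(is.na(cc3@calls$start)))
    expect_identical(sum(cc3@calls$nCandidates), 0L)
    expect_length(selectedCentromeres(cc3), 0L)
})

test_that("hi-c blank evidence gates calls when provided", {
    cfg <- genomeConfig(nChrom = 1L, chromLength = 1e6)
    b <- simulateGenome(cfg, seed = 51)
    arr <- findGenomeTandemArrays(b$genome)
    tr <- b$manifest$chromosomes$Chr1$centromeres[[1]]
    blank <- GenomicRanges::GRanges("Chr1",
        IRanges::IRanges(tr$start, tr$end))
    f <- windowFeatures(b$genome, arr, b$genes, b$gypsy,
                        hicBlank = blank)
    cc <- callCentromeres(f, arr)
    expect_false(is.na(cc@calls$start[1]))
    ## a blank mask far from the array suppresses the call
    off <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(1, 60000))
    f2 <- windowFeatures(b$genome, arr, b$genes, b$gypsy,
                         hicBlank = off)
    cc2 <- callCentromeres(f2, arr)
    expect_true(is.na(cc2@calls$start[1]))
})
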