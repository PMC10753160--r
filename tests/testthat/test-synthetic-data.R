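smallCfg <- function() genomeConfig(
    nChrom = 2L, chromLength = 6e4,
    telomereCounts = matrix(c(120L, 50L, 0L, 300L), 2, 2),
    centromeres = list(list(), list()))

test_that("genome simulation is deterministic and places telomeres exactly", {
    b1 <- simulateGenome(smallCfg(), seed = 5)
    b2 <- simulateGenome(smallCfg(), seed = 5)
    expect_identical(as.character(b1$genome), as.character(b2$genome))

    s1 <- as.character(b1$genome[["Chr1"]])
    ## direct string count over the planted 5' array span
    expect_identical(oracleMotifCount(substr(s1, 1, 120 * 7), "CCCATTT"),
                     120L)
    cc <- terminalRepeatCounts(b1$genome[["Chr2"]])
    expect_identical(unname(cc), c(50L, 300L))
    expect_identical(b1$manifest$chromosomes$Chr2$telomere5, 50L)
})

test_that("zero-divergence centromere is an exact tandem array", {
    cfg <- genomeConfig(nChrom = 1L, chromLength = 1e5,
        telomereCounts = matrix(c(0L, 0L), 1, 2),
        centromeres = list(list(list(lengthBp = 17100,
            monomerLength = 171L, divergence = 0, centerFrac = 0.5))))
    b <- simulateGenome(cfg, seed = 3)
    tr <- b$manifest$chromosomes$Chr1$centromeres[[1]]
    s <- strsplit(as.character(b$genome[[1]]), "")[[1]]
    i <- tr$start:(tr$end - 171)
    expect_true(all(s[i] == s[i + 171]))
})

test_that("generator rejects invalid configurations", {
    expect_error(simulateGenome(genomeConfig(nChrom = 1L,
        chromLength = 1000,
        telomereCounts = matrix(c(100L, 100L), 1, 2),
        centromeres = list(list()))), "longer than chromosome")
    expect_error(genomeConfig(nChrom = 1L,
        centromeres = list(list(list(lengthBp = 100,
            monomerLength = 10L, divergence = 0.6,
            centerFrac = 0.5)))), "divergence")
})

test_that("terminal reads carry the configured telomere extensions", {
    cfg <- genomeConfig(nChrom = 1L, chromLength = 5e4,
        telomereCounts = matrix(c(0L, 20L), 1, 2),
        centromeres = list(list()))
    b <- simulateGenome(cfg, seed = 8)

    r0 <- simulateTerminalReads(b, "Chr1", "3prime", nReads = 0)
    expect_length(r0$reads, 0L)
    expect_length(r0$alignments, 0L)

    r1 <- simulateTerminalReads(b, "Chr1", "3prime", nReads = 1,
                                extensionRepeats = 30, seed = 2)
    expect_identical(r1$manifest$trueRepeatCount, 50L)  # 20 planted + 30
    expect_identical(
        countMotifRepeats(as.character(r1$reads[[1]]), "TTTAGGG"), 50L)

    ra <- simulateTerminalReads(b, "Chr1", "3prime", nReads = 4,
                                extensionRepeats = 25, seed = 7)
    rb <- simulateTerminalReads(b, "Chr1", "3prime", nReads = 4,
                                extensionRepeats = 25, seed = 7)
    expect_identical(as.character(ra$reads), as.character(rb$reads))
    expect_error(simulateTerminalReads(b, "Chr1", "3prime",
        extensionRepeats = -1), ">= 0")
})

test_that("assembly corruption plants the promised substitution load", {
    b <- simulateGenome(smallCfg(), seed = 5)
    c0 <- corruptAssembly(b$genome, 0, seed = 1)
    expect_identical(as.character(c0$genome), as.character(b$genome))
    expect_identical(c0$errorCount, 0L)

    big <- Biostrings::DNAStringSet(c(chr = randDna(1e6)))
    c1 <- corruptAssembly(big, 1e-3, seed = 4)
    ## binomial: 1000 +/- 4 sd (sd ~ 31.6)
    expect_lt(abs(c1$errorCount - 1000), 4 * sqrt(1e6 * 1e-3 * 0.999))
    c2 <- corruptAssembly(big, 1e-3, seed = 4)
    expect_identical(as.character(c1$genome), as.character(c2$genome))
    expect_error(corruptAssembly(big, 0.5), "subRate")
})

test_that("family generator plants residues, lengths and clusters", {
    fam <- simulateFamily(seed = 11)
    diagPos <- fam$anchor$srs6Start + fam$anchor$diagnosticPosition - 1L
    for (id in names(fam$truth$srs6Residue)) {
        expect_identical(substr(as.character(fam$proteins[[id]]),
                                diagPos, diagPos),
                         unname(fam$truth$srs6Residue[[id]]))
    }
    expect_setequal(fam$truth$filterExcluded, c("decoyShort", "decoyLong"))

    ## members placed at ranks 10 and 18 are marked same-cluster
    cfg <- familyConfig(members = data.frame(
        id = c("m1", "m2"), length = c(505L, 505L),
        srs6Residue = c("T", "A"), identity = c(0.8, 0.8),
        deriveFrom = "anchor", chrom = "Chr1", rank = c(10L, 18L)))
    f2 <- simulateFamily(cfg, seed = 1)
    expect_length(f2$truth$expectedClusters, 1L)
    expect_setequal(f2$truth$expectedClusters[[1]], c("m1", "m2"))
    expect_error(familyConfig(anchorLength = 100L, srs6Start = 90L,
                              srs6End = 120L), "SRS6")
})

test_that("FPKM simulation reproduces planted tissue means exactly", {
    means <- matrix(c(221.6, 10, 5, 5), 2, 2,
                    dimnames = list(c("gA", "gB"), c("FB", "L")))
    m <- simulateFpkm(means)
    expect_identical(dim(m), c(2L, 6L))
    expect_equal(mean(m["gA", startsWith(colnames(m), "FB")]), 221.6)
    expect_equal(mean(m["gB", startsWith(colnames(m), "FB")]), 10)
})

test_that("genome bundles round-trip through their on-disk formats", {
    b <- simulateGenome(genomeConfig(nChrom = 1L, chromLength = 8e4,
        telomereCounts = matrix(c(50L, 60L), 1, 2)), seed = 9)
    dir <- withr::local_tempdir()
    writeGenomeBundle(b, dir)
    g <- readFasta(file.path(dir, "genome.fa"))
    expect_identical(as.character(g), as.character(b$genome))
    genes <- readGffGenes(file.path(dir, "genes.gff3"))
    expect_identical(genes$gene_id, b$genes$gene_id)
    expect_identical(genes$rank, b$genes$rank)
    gy <- readBed(file.path(dir, "gypsy.bed"))
    expect_identical(GenomicRanges::start(gy),
                     GenomicRanges::start(b$gypsy))
    man <- jsonlite::read_json(file.path(dir, "manifest.json"))
    expect_equal(man$chromosomes$Chr1$telomere5, 50)
})
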