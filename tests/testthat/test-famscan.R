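randAa <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
    "")[[1]], n, replace = TRUE), collapse = "")

test_that("length filter keeps the inclusive 400-600 aa window", {
    set.seed(3)
    prot <- Biostrings::AAStringSet(c(p399 = randAa(399),
        p400 = randAa(400), p600 = randAa(600), p601 = randAa(601)))
    hits <- data.frame(target = names(prot), query = "prof",
                       evalue = 1e-30, score = 100)
    res <- filterFamilyCandidates(hits, prot)
    expect_setequal(res$members$geneId, c("p400", "p600"))
    expect_setequal(res$dropped$geneId, c("p399", "p601"))
    expect_match(res$dropped$reason[res$dropped$geneId == "p399"], "<")

    empty <- filterFamilyCandidates(hits[0, ], prot)
    expect_identical(nrow(empty$members), 0L)
    hits2 <- rbind(hits, data.frame(target = "ghost", query = "prof",
                                    evalue = 1, score = 1))
    expect_error(filterFamilyCandidates(hits2, prot), "ghost")
})

test_that("domain-table round-trip preserves hits", {
    hits <- data.frame(target = c("a", "b"), query = "prof",
                       evalue = c(1e-50, 1e-10), score = c(300, 120))
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeDomtbl(hits, tmp)
    back <- readDomtbl(tmp, cols = list(target = 1, query = 4,
                                        evalue = 7, score = 8))
    expect_identical(back$target, hits$target)
    expect_equal(back$evalue, hits$evalue)
})

mkGenes <- function(ranks, chrom = "Chr1", ids = NULL) {
    n <- max(ranks) + 2L
    perChrom <- lapply(unique(chrom), function(ch) {
        starts <- seq_len(n) * 1000L
        gid <- sprintf("%s_f%03d", ch, seq_len(n))
        sel <- chrom == ch
        gid[ranks[sel]] <- ids[sel]
        gr <- GenomicRanges::GRanges(ch,
            IRanges::IRanges(starts, starts + 500L))
        S4Vectors::mcols(gr)$gene_id <- gid
        gr
    })
    gr <- suppressWarnings(do.call(c, perChrom))
    T2Tqc:::.rankGenes(gr)
}

test_that("cluster rule links at rank gap 8 but not 9 and chains", {
    g <- mkGenes(c(10L, 18L), ids = c("m1", "m2"), chrom = c("Chr1", "Chr1"))
    cl <- detectGeneClusters(c("m1", "m2"), g)
    expect_identical(cl$nClusters, 1L)

    g2 <- mkGenes(c(10L, 19L), ids = c("m1", "m2"),
                  chrom = c("Chr1", "Chr1"))
    cl2 <- detectGeneClusters(c("m1", "m2"), g2)
    expect_identical(cl2$nClusters, 0L)

    g3 <- mkGenes(c(10L, 11L, 18L, 26L), ids = c("a", "b", "c", "d"),
                  chrom = rep("Chr1", 4))
    cl3 <- detectGeneClusters(c("a", "b", "c", "d"), g3)
    expect_identical(cl3$nClusters, 1L)          # chained transitively
    expect_identical(cl3$nClusteredGenes, 4L)
    expect_identical(cl3$tandemPairs$geneId1, "a")
    expect_identical(cl3$tandemPairs$geneId2, "b")

    expect_error(detectGeneClusters("nope", g3), "missing")
})

test_that("clustering matches the all-pairs connected-components oracle", {
    skip_if_not_installed("igraph")
    set.seed(17)
    for (i in 1:40) {
        nGenes <- sample(10:50, 1)
        nChrom <- sample(1:3, 1)
        chrom <- sprintf("Chr%d", sample(nChrom, nGenes, replace = TRUE))
        nMem <- sample(2:min(8, nGenes), 1)
        pick <- sample(nGenes, nMem)
        ## build an annotation with one gene per (chrom, slot)
        rows <- data.frame(chrom = chrom, slot = stats::ave(
            seq_len(nGenes), chrom, FUN = seq_along))
        ids <- sprintf("g%02d", seq_len(nGenes))
        gr <- GenomicRanges::GRanges(rows$chrom,
            IRanges::IRanges(rows$slot * 1000L, rows$slot * 1000L + 500L))
        S4Vectors::mcols(gr)$gene_id <- ids
        gr <- T2Tqc:::.rankGenes(gr)
        memberIds <- ids[pick]
        got <- detectGeneClusters(memberIds, gr)
        idx <- match(memberIds, gr$gene_id)
        want <- oracleClusters(as.character(
            GenomeInfoDb::seqnames(gr))[idx], gr$rank[idx])
        gotPart <- lapply(split(got$clusters$geneId,
                                got$clusters$clusterId), sort)
        wantPart <- lapply(want, function(ix) sort(memberIds[ix]))
        expect_setequal(unname(gotPart), unname(wantPart))
        ## invariance under member input order
        got2 <- detectGeneClusters(rev(memberIds), gr)
        expect_identical(got2$nClusters, got$nClusters)
        expect_identical(got2$nClusteredGenes, got$nClusteredGenes)
    }
})

test_that("global alignment matches the enumeration oracle", {
    mat <- acgtMatrix()
    al <- globalAlign("ACGTACGT", "ACGTACGT", substitutionMatrix = mat,
                      gapOpening = 6, gapExtension = 2)
    expect_identical(al$pattern, "ACGTACGT")
    expect_equal(percentIdentity(al), 100)

    set.seed(23)
    for (i in 1:60) {
        a <- randDna(sample(1:8, 1))
        b <- randDna(sample(1:8, 1))
        got <- globalAlign(a, b, substitutionMatrix = mat,
                           gapOpening = 6, gapExtension = 2)$score
        expect_equal(got, oracleAlignScore(a, b), info = paste(a, b))
    }
    expect_error(globalAlign("", "ACD"), "empty")
    expect_error(globalAlign("ACD", "AC1"), "non-amino-acid")
})

test_that("percent identity counts matching columns over all columns", {
    expect_equal(percentIdentity(list(pattern = "ACDEFGHIKL",
                                      subject = "ACDEFGHIKV")), 90)
    expect_equal(percentIdentity(list(pattern = "AC-D",
                                      subject = "ACED")), 75)
    expect_error(percentIdentity(list(pattern = "AC", subject = "A")),
                 "length")
})

test_that("SRS6 projection recovers the window across indels", {
    set.seed(29)
    anchorSeq <- randAa(120)
    anchor <- list(seq = anchorSeq, srs6Start = 80L, srs6End = 89L,
                   diagnosticPosition = 8L)
    self <- extractSrs6(anchorSeq, anchor)
    expect_identical(self$window, substr(anchorSeq, 80, 89))
    expect_identical(self$diagnosticResidue, substr(anchorSeq, 87, 87))

    ## a 5-aa insertion upstream of SRS6 must not shift the projection
    ins <- paste0(substr(anchorSeq, 1, 40), "WWWWW",
                  substr(anchorSeq, 41, 120))
    shifted <- extractSrs6(ins, anchor)
    expect_identical(shifted$window, substr(anchorSeq, 80, 89))

    ## planted diagnostic residue is read out
    mut <- anchorSeq
    substr(mut, 87, 87) <- "A"
    expect_identical(extractSrs6(mut, anchor)$diagnosticResidue, "A")
    expect_error(extractSrs6(anchorSeq, list(seq = anchorSeq,
        srs6Start = 115L, srs6End = 130L)), "outside anchor")
})

test_that("the SRS6 position-8 rule assigns hydroxylase classes", {
    lab <- function(r) classifyFbh(list(diagnosticResidue = r))$label
    expect_identical(lab("T"), "F3pH_like")
    expect_identical(lab("S"), "F3pH_like")
    expect_identical(lab("A"), "F3p5pH_like")
    expect_identical(lab("G"), "unclassified")
    expect_identical(lab("-"), "unclassified")
})

test_that("expression summaries log-normalise and ratio on raw means", {
    means <- rbind(gA = c(FB = 221.6, L = 7), gB = c(FB = 10, L = 7),
                   gC = c(FB = 0, L = 4))
    fpkm <- simulateFpkm(means)
    res <- tissueExpressionSummary(fpkm, c("gA", "gB", "gC"),
        ratioPairs = data.frame(geneA = c("gA", "gB"),
                                geneB = c("gB", "gB"),
                                tissue = c("FB", "FB")))
    expect_equal(res$ratios$ratio, c(22.16, 1.00))
    expect_equal(res$tissueMeans["gA", "FB"], 221.6)
    expect_equal(res$log10["gC", "FB_2"], 0)        # FPKM 0, pseudo 1
    expect_error(tissueExpressionSummary(fpkm, "missing"), "missing")
})
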