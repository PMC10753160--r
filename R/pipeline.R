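#' Assembly summary statistics
#'
#' Sequence count, total length, N count, GC percent and contig N50.
#' GC% is (G+C)/(A+C+G+T), i.e. Ns are excluded from the denominator,
#' reported to one decimal. N50 is the standard cumulative-length
#' definition: the length of the shortest sequence in the smallest set
#' of longest sequences covering half the total.
#'
#' @param genome Non-empty DNAStringSet.
#' @return List `nSeqs`, `totalBp`, `nCount`, `gcPercent`, `lengths`
#'   (named), `n50`.
#' @export
assemblySummary <- function(genome) {
    if (!length(genome)) stop("empty genome")
    af <- Biostrings::alphabetFrequency(genome, collapse = TRUE)
    acgt <- af[c("A", "C", "G", "T")]
    gc <- round(100 * sum(acgt[c("C", "G")]) / sum(acgt), 1)
    lens <- sort(Biostrings::width(genome), decreasing = TRUE)
    n50 <- lens[which(cumsum(as.numeric(lens)) >=
                      sum(as.numeric(lens)) / 2)[1]]
    list(nSeqs = length(genome),
         totalBp = sum(as.numeric(Biostrings::width(genome))),
         nCount = unname(af["N"]), gcPercent = unname(gc),
         lengths = stats::setNames(Biostrings::width(genome),
                                   names(genome)),
         n50 = n50)
}

#' Default end-to-end pipeline configuration
#'
#' One document with per-module parameter blocks and the single seed
#' every stochastic step derives from. The defaults are the package's
#' standard synthetic study conditions (see [genomeConfig()],
#' [familyConfig()]); QV is assessed on a copy of the genome corrupted
#' at `qv$subRate` against the uncorrupted sequences as the read set.
#'
#' @param seed Integer seed.
#' @param genome [genomeConfig()] block.
#' @param telomere [telomereParams()] block.
#' @param centromere [centromereParams()] block.
#' @param qv List `k`, `readKmerMinCount`, `subRate`, `cap`.
#' @param family [familyConfig()] block.
#' @param patch List `nReads`, `extensionRepeats`, `errorRate`.
#' @return Config list for [runPipeline()].
#' @export
pipelineConfig <- function(seed = 1L, genome = genomeConfig(),
                           telomere = telomereParams(),
                           centromere = centromereParams(),
                           qv = list(k = 21L, readKmerMinCount = 1L,
                                     subRate = 1e-4, cap = 99),
                           family = familyConfig(),
                           patch = list(nReads = 5L,
                                        extensionRepeats = 130L,
                                        errorRate = 0)) {
    list(seed = as.integer(seed), genome = genome, telomere = telomere,
         centromere = centromere, qv = qv, family = family,
         patch = patch)
}

#' Run the whole synthetic QC pipeline
#'
#' Executes simulate, telomere calling, terminal patching of a
#' truncated end, telomere rescan, centromere prediction, QV estimation
#' on a corrupted copy of the genome, and family mining, and returns a
#' consolidated report next to the generator's truth manifest. Rerunning
#' with the same config yields an identical report.
#'
#' @param config See [pipelineConfig()].
#' @param outDir Optional directory; when given, the report is written
#'   there as `report.json`.
#' @return List with elements `summary`, `telomeres`, `patch`,
#'   `centromeres`, `qv`, `family`, `truth`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
    seed <- config$seed
    bundle <- simulateGenome(config$genome, seed = seed)
    summ <- assemblySummary(bundle$genome)
    tel <- callTelomeres(bundle$genome, config$telomere)

    ## patch exercise: truncate the least-repetitive telomeric 3' end,
    ## then restore it from simulated terminal reads
    c3 <- config$genome$telomereCounts[, 2]
    tchr <- names(bundle$genome)[which.min(replace(c3, c3 == 0, NA))]
    truncated <- bundle
    keepRepeats <- 20L
    info <- bundle$manifest$chromosomes[[tchr]]
    drop <- (info$telomere3 - keepRepeats) * nchar(config$genome$motif3)
    seqs <- as.character(bundle$genome)
    s <- seqs[[tchr]]
    seqs[[tchr]] <- substr(s, 1, nchar(s) - drop)
    truncated$genome <- Biostrings::DNAStringSet(seqs)
    truncated$manifest$chromosomes[[tchr]]$telomere3 <- keepRepeats
    truncated$manifest$chromosomes[[tchr]]$length <- nchar(s) - drop
    rd <- simulateTerminalReads(truncated, tchr, "3prime",
        nReads = config$patch$nReads,
        extensionRepeats = config$patch$extensionRepeats,
        errorRate = config$patch$errorRate, seed = seed + 1L)
    pt <- patchTelomeres(truncated$genome[tchr], rd$alignments,
                         rd$reads, config$telomere)
    rescan <- callTelomeres(pt$genome, config$telomere)

    arrays <- findGenomeTandemArrays(bundle$genome)
    feats <- windowFeatures(bundle$genome, arrays, bundle$genes,
                            bundle$gypsy,
                            window = config$centromere$window)
    cen <- callCentromeres(feats, arrays, config$centromere)

    corrupted <- corruptAssembly(bundle$genome, config$qv$subRate,
                                 seed = seed + 2L)
    survey <- assemblyKmerSurvey(corrupted$genome, bundle$genome,
        k = config$qv$k, readKmerMinCount = config$qv$readKmerMinCount)
    qv <- estimateQV(survey, cap = config$qv$cap)

    fam <- simulateFamily(config$family, seed = seed + 3L)
    filt <- filterFamilyCandidates(fam$hits, fam$proteins)
    clus <- detectGeneClusters(filt$members$geneId, fam$genes)
    cls <- lapply(filt$members$geneId, function(id)
        classifyFbh(extractSrs6(fam$proteins[[id]], fam$anchor)))
    classifications <- data.frame(
        geneId = filt$members$geneId,
        label = vapply(cls, `[[`, character(1), "label"),
        residue = vapply(cls, `[[`, character(1), "evidence"))

    report <- list(
        summary = summ,
        telomeres = list(count = telomereCount(tel), calls = tel),
        patch = list(chrom = tchr, report = pt$report,
                     rescanCount = telomereCount(rescan)),
        centromeres = cen,
        qv = list(survey = survey, qv = qv,
                  plantedErrors = corrupted$errorCount),
        family = list(members = filt$members, dropped = filt$dropped,
                      clusters = clus, classifications = classifications),
        truth = list(genome = bundle$manifest, family = fam$truth,
                     patchReads = rd$manifest))
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(.reportJson(report),
                             file.path(outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    report
}

## flatten the report into plain JSON-serialisable pieces
.reportJson <- function(report) {
    list(
        summary = report$summary[c("nSeqs", "totalBp", "nCount",
                                   "gcPercent", "n50")],
        telomereCount = report$telomeres$count,
        telomereRepeatCounts = as.list(stats::setNames(
            report$telomeres$calls$repeatCount,
            paste0(report$telomeres$calls$chrom, ":",
                   report$telomeres$calls$end))),
        patch = list(chrom = report$patch$chrom,
                     status = as.character(report$patch$report$status),
                     postCount = report$patch$report$postCount),
        centromeres = as.data.frame(report$centromeres@calls),
        qv = list(k = report$qv$survey@k,
                  Y = report$qv$survey@assemblyTotal,
                  X = report$qv$survey@assemblyMissing,
                  qv = report$qv$qv,
                  plantedErrors = report$qv$plantedErrors),
        family = list(
            nMembers = nrow(report$family$members),
            nClusters = report$family$clusters$nClusters,
            nClusteredGenes = report$family$clusters$nClusteredGenes,
            classifications = report$family$classifications))
}
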