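## Gene-family mining: length filter on profile-HMM hits, tandem
## gene-cluster detection in annotated gene order, global protein
## alignment / percent identity, SRS6 extraction and flavonoid B-ring
## hydroxylase classification, tissue expression summaries.

#' Read a domain-table (domtblout-style) hits file
#'
#' Parses the whitespace-delimited per-domain output of profile-HMM
#' search tools; lines starting with `#` are skipped. Column indices are
#' configurable because downstream tools disagree on layout; defaults
#' match hmmsearch domtblout (target name 1, query name 4, full-sequence
#' E-value 7, score 8). No R parser for this trivial format ships with
#' the supported stack.
#'
#' @param path Path to the hits file.
#' @param cols Named list of 1-based column indices: `target`, `query`,
#'   `evalue`, `score`.
#' @return data.frame with columns `target`, `query`, `evalue`, `score`.
#' @export
readDomtbl <- function(path,
                       cols = list(target = 1L, query = 4L,
                                   evalue = 7L, score = 8L)) {
    stopifnot(file.exists(path))
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    if (!length(ln))
        return(data.frame(target = character(0), query = character(0),
                          evalue = numeric(0), score = numeric(0)))
    f <- strsplit(trimws(ln), "[ \t]+")
    pick <- function(i) vapply(f, `[[`, character(1), i)
    data.frame(target = pick(cols$target), query = pick(cols$query),
               evalue = as.numeric(pick(cols$evalue)),
               score = as.numeric(pick(cols$score)))
}

#' Write hits as a domtblout-style TSV
#'
#' @param hits data.frame with columns `target`, `query`, `evalue`,
#'   `score`.
#' @param path Output path.
#' @export
writeDomtbl <- function(hits, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# target\t-\t-\tquery\t-\t-\tevalue\tscore"), con)
    writeLines(sprintf("%s\t-\t-\t%s\t-\t-\t%g\t%g", hits$target,
                       hits$query, hits$evalue, hits$score), con)
    invisible(path)
}

#' Filter family candidates by protein length
#'
#' Keeps hits whose protein length lies in `[minAA, maxAA]` — the
#' boundaries are inclusive, i.e. candidates shorter than `minAA` or
#' longer than `maxAA` are filtered out. Dropped ids are reported with
#' the reason.
#'
#' @param hits data.frame from [readDomtbl()] (or equivalent).
#' @param proteins AAStringSet resolving every hit target.
#' @param minAA,maxAA Inclusive length bounds (defaults 400 and 600).
#' @return List `members` (`DFrame`: `geneId`, `lengthAA`, `evalue`,
#'   `score`) and `dropped` (`DFrame`: `geneId`, `lengthAA`, `reason`).
#' @export
filterFamilyCandidates <- function(hits, proteins, minAA = 400L,
                                   maxAA = 600L) {
    ids <- unique(hits$target)
    absent <- setdiff(ids, names(proteins))
    if (length(absent))
        stop("hit id(s) absent from protein FASTA: ",
             paste(absent, collapse = ", "))
    h <- hits[!duplicated(hits$target), , drop = FALSE]
    len <- Biostrings::width(proteins)[match(h$target, names(proteins))]
    keep <- len >= minAA & len <= maxAA
    members <- DataFrame(geneId = h$target[keep], lengthAA = len[keep],
                         evalue = h$evalue[keep], score = h$score[keep])
    reason <- ifelse(len < minAA, sprintf("length %d < %d", len, minAA),
                     sprintf("length %d > %d", len, maxAA))
    dropped <- DataFrame(geneId = h$target[!keep],
                         lengthAA = len[!keep], reason = reason[!keep])
    list(members = members, dropped = dropped)
}

#' Detect tandem gene clusters in chromosome gene order
#'
#' Two family members are linked iff they lie on the same chromosome
#' within `maxGap` open reading frames of each other — operationalised
#' as a gene-rank difference of at most `maxGap` in the chromosome's
#' annotated gene order — and clusters are the connected components of
#' that link relation (transitive chaining). Singletons are excluded.
#' Member pairs at adjacent ranks (difference 1) are flagged as tandem
#' pairs.
#'
#' @param memberIds Character vector of family gene ids.
#' @param genes GRanges of all gene models with `gene_id` and `rank`
#'   (see [readGffGenes()]).
#' @param maxGap Maximum rank difference that links two members
#'   (default 8).
#' @return List `clusters` (`DFrame`: `clusterId`, `chrom`, `geneId`,
#'   `rank`, `start`, `end`), `tandemPairs` (`DFrame`: `geneId1`,
#'   `geneId2`, `chrom`), `nClusters`, `nClusteredGenes`.
#' @export
detectGeneClusters <- function(memberIds, genes, maxGap = 8L) {
    idx <- match(memberIds, genes$gene_id)
    if (anyNA(idx))
        stop("member gene(s) missing from annotation: ",
             paste(memberIds[is.na(idx)], collapse = ", "))
    df <- data.frame(geneId = memberIds,
                     chrom = as.character(GenomeInfoDb::seqnames(genes))[idx],
                     rank = genes$rank[idx],
                     start = GenomicRanges::start(genes)[idx],
                     end = GenomicRanges::end(genes)[idx])
    df <- df[order(df$chrom, df$rank), , drop = FALSE]
    clRows <- list(); tpRows <- list(); cid <- 0L
    for (ch in unique(df$chrom)) {
        d <- df[df$chrom == ch, , drop = FALSE]
        grp <- cumsum(c(1L, diff(d$rank) > maxGap))
        for (g in unique(grp)) {
            sub <- d[grp == g, , drop = FALSE]
            if (nrow(sub) < 2L) next
            cid <- cid + 1L
            clRows[[cid]] <- DataFrame(
                clusterId = sprintf("cluster_%03d", cid),
                chrom = ch, geneId = sub$geneId, rank = sub$rank,
                start = sub$start, end = sub$end)
            adj <- which(diff(sub$rank) == 1L)
            if (length(adj))
                tpRows[[length(tpRows) + 1L]] <- DataFrame(
                    geneId1 = sub$geneId[adj],
                    geneId2 = sub$geneId[adj + 1L], chrom = ch)
        }
    }
    clusters <- if (length(clRows)) do.call(rbind, clRows)
        else DataFrame(clusterId = character(0), chrom = character(0),
                       geneId = character(0), rank = integer(0),
                       start = integer(0), end = integer(0))
    tandemPairs <- if (length(tpRows)) do.call(rbind, tpRows)
        else DataFrame(geneId1 = character(0), geneId2 = character(0),
                       chrom = character(0))
    list(clusters = clusters, tandemPairs = tandemPairs,
         nClusters = length(unique(clusters$clusterId)),
         nClusteredGenes = nrow(clusters))
}

#' Global protein alignment with affine gaps
#'
#' Needleman–Wunsch global alignment via
#' [Biostrings::pairwiseAlignment()] with an affine gap model (a gap of
#' length L costs `gapOpening + L * gapExtension`). Deterministic for
#' fixed inputs.
#'
#' @param a,b Protein sequences (character or `AAString`); must be
#'   non-empty and use the 20 amino-acid letters (plus X).
#' @param substitutionMatrix Matrix name (e.g. `"BLOSUM62"`) or an
#'   explicit numeric matrix.
#' @param gapOpening,gapExtension Nonnegative gap penalties.
#' @return List `pattern`, `subject` (aligned strings with `-` gaps)
#'   and `score`.
#' @export
globalAlign <- function(a, b, substitutionMatrix = "BLOSUM62",
                        gapOpening = 10, gapExtension = 0.5) {
    a <- as.character(a); b <- as.character(b)
    if (!nzchar(a) || !nzchar(b))
        stop("cannot align empty sequences")
    ok <- paste0(paste(.AA20, collapse = ""), "X")
    if (grepl(sprintf("[^%s]", ok), a) ||
        grepl(sprintf("[^%s]", ok), b))
        stop("non-amino-acid symbols in input")
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        type = "global", substitutionMatrix = substitutionMatrix,
        gapOpening = gapOpening, gapExtension = gapExtension)
    list(pattern = as.character(Biostrings::alignedPattern(pa)),
         subject = as.character(Biostrings::alignedSubject(pa)),
         score = Biostrings::score(pa))
}

#' Percent identity of a global alignment
#'
#' Identity = identical residue columns divided by all alignment
#' columns, gap columns included in the denominator; reported to two
#' decimals.
#'
#' @param alignment List with `pattern` and `subject` (from
#'   [globalAlign()]) or any two equal-length aligned strings.
#' @return Numeric percent, rounded to 2 decimals.
#' @export
percentIdentity <- function(alignment) {
    p <- strsplit(alignment$pattern, "")[[1]]
    s <- strsplit(alignment$subject, "")[[1]]
    if (length(p) != length(s))
        stop("aligned strings differ in length")
    round(100 * sum(p == s & p != "-") / length(p), 2)
}

#' Extract the SRS6 window of a candidate by alignment projection
#'
#' Globally aligns the candidate to an annotated anchor protein and
#' projects the anchor's SRS6 columns onto the candidate: the window is
#' the candidate's residues (gaps preserved) in those columns, and the
#' diagnostic residue is the candidate symbol in the column of anchor
#' SRS6 position `diagnosticPosition`.
#'
#' @param candidate Candidate protein (character or `AAString`).
#' @param anchor List with `seq`, `srs6Start`, `srs6End` (1-based
#'   inclusive anchor coordinates) and optionally `diagnosticPosition`
#'   (default 8).
#' @param ... Passed to [globalAlign()].
#' @return List `window` (aligned window string), `diagnosticResidue`
#'   (single letter, `-` when the candidate is gapped there),
#'   `diagnosticPosition`.
#' @export
extractSrs6 <- function(candidate, anchor, ...) {
    dpos <- if (!is.null(anchor$diagnosticPosition))
        anchor$diagnosticPosition else 8L
    aLen <- nchar(anchor$seq)
    if (anchor$srs6Start < 1L || anchor$srs6End > aLen ||
        anchor$srs6Start > anchor$srs6End)
        stop("SRS6 coordinates outside anchor length")
    aln <- globalAlign(candidate, anchor$seq, ...)
    cand <- strsplit(aln$pattern, "")[[1]]
    anch <- strsplit(aln$subject, "")[[1]]
    anchorPos <- cumsum(anch != "-")
    anchorPos[anch == "-"] <- NA_integer_
    inWin <- !is.na(anchorPos) & anchorPos >= anchor$srs6Start &
        anchorPos <= anchor$srs6End
    window <- paste(cand[inWin], collapse = "")
    diagCol <- which(!is.na(anchorPos) &
                     anchorPos == anchor$srs6Start + dpos - 1L)
    diag <- if (length(diagCol)) cand[diagCol[1]] else "-"
    list(window = window, diagnosticResidue = diag,
         diagnosticPosition = dpos)
}

#' Classify a flavonoid B-ring hydroxylase from its SRS6 residue
#'
#' The position-8 residue of SRS6 discriminates the two CYP75
#' hydroxylase types: threonine or serine marks an F3'H-like (CYP75B)
#' enzyme, alanine an F3'5'H-like (CYP75A) enzyme; anything else
#' (including a gap) is left unclassified.
#'
#' @param window List from [extractSrs6()] (or anything with a
#'   `diagnosticResidue` element).
#' @return List `label` (`"F3pH_like"`, `"F3p5pH_like"` or
#'   `"unclassified"`) and `evidence` (the residue).
#' @export
classifyFbh <- function(window) {
    r <- window$diagnosticResidue
    label <- if (r %in% c("T", "S")) "F3pH_like"
             else if (identical(r, "A")) "F3p5pH_like"
             else "unclassified"
    list(label = label, evidence = r)
}

#' Tissue expression summary of selected genes
#'
#' Heatmap-style normalisation `log10(FPKM + pseudo)`, per-tissue mean
#' FPKM (raw scale), and fold ratios between named gene pairs computed
#' on the raw tissue means (not the logged values), reported to two
#' decimals. Tissue of each sample is the sample name up to the last
#' underscore (e.g. `"FB_2"` is replicate 2 of tissue `"FB"`).
#'
#' @param fpkm Numeric matrix genes x samples, FPKM >= 0.
#' @param genes Gene ids to summarise (all must be present).
#' @param pseudo Pseudocount for the log transform (default 1).
#' @param ratioPairs Optional data.frame with columns `geneA`, `geneB`,
#'   `tissue`; each row requests `mean(geneA)/mean(geneB)` in that
#'   tissue.
#' @return List `log10` (matrix), `tissueMeans` (genes x tissues),
#'   `ratios` (data.frame with a `ratio` column, 2 decimals).
#' @export
tissueExpressionSummary <- function(fpkm, genes, pseudo = 1,
                                    ratioPairs = NULL) {
    missing <- setdiff(genes, rownames(fpkm))
    if (length(missing))
        stop("gene id(s) missing from FPKM matrix: ",
             paste(missing, collapse = ", "))
    m <- fpkm[genes, , drop = FALSE]
    if (any(m < 0)) stop("FPKM values must be >= 0")
    lg <- log10(m + pseudo)
    tissue <- sub("_[^_]*$", "", colnames(m))
    tissues <- unique(tissue)
    tm <- vapply(tissues, function(t)
        rowMeans(m[, tissue == t, drop = FALSE]), numeric(nrow(m)))
    tm <- matrix(tm, nrow = nrow(m),
                 dimnames = list(rownames(m), tissues))
    ratios <- NULL
    if (!is.null(ratioPairs)) {
        ratios <- ratioPairs
        ratios$ratio <- round(
            tm[cbind(ratioPairs$geneA, ratioPairs$tissue)] /
            tm[cbind(ratioPairs$geneB, ratioPairs$tissue)], 2)
    }
    list(log10 = lg, tissueMeans = tm, ratios = ratios)
}
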