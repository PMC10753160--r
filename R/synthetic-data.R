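## Deterministic synthetic-data generator with truth manifests.
##
## The generator emulates the structure of a nine-chromosome T2T plant
## genome at desk scale: terminal telomere arrays of configured repeat
## counts, centromeric tandem arrays sitting in gene-poor / Gypsy-rich
## windows, background genes at realistic density, and (separately) a
## planted protein family with tandem clusters, SRS6 diagnostic residues
## and an FPKM matrix. Everything is a pure function of (config, seed).

.DNA <- c("A", "C", "G", "T")
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Remove chance occurrences of the telomere motifs outside the planted
## arrays (one base of each occurrence, chosen outside any protected
## range, is resampled; repeated until clean). This keeps the truth
## manifest exact: a motif occurs in a chromosome only where planted.
.scrubMotifs <- function(s, motifs, protect) {
    inProtect <- function(p) nrow(protect) &&
        any(p >= protect[, 1] & p <= protect[, 2])
    repeat {
        str <- paste(s, collapse = "")
        bad <- integer(0)
        for (m in motifs) {
            hits <- gregexpr(m, str, fixed = TRUE)[[1]]
            if (hits[1] == -1L) next
            w <- nchar(m)
            for (h in hits) {
                span <- h:(h + w - 1L)
                free <- span[!vapply(span, inProtect, logical(1))]
                if (length(free))
                    bad <- c(bad, free[ceiling(length(free) / 2)])
            }
        }
        if (!length(bad)) return(s)
        for (p in unique(bad))
            s[p] <- sample(setdiff(.DNA, s[p]), 1L)
    }
}

#' Genome generator configuration
#'
#' Defaults describe the package's standard synthetic study conditions:
#' nine 1-Mb chromosomes whose 17 telomeric ends carry repeat counts
#' evenly spanning 111 to 2673 while the upstream end of chromosome 5
#' carries only 2 copies (below any sensible calling threshold); one
#' centromeric array per chromosome (171-bp monomer, 2% divergence,
#' one-tenth of the chromosome) placed mid-chromosome; background genes
#' every 13 kb of length 4 kb (about 73 genes/Mb, with centromeres
#' nearly gene-free); Gypsy annotation covering ~6% of the background
#' and ~45% of centromeres.
#'
#' @param nChrom Number of chromosomes.
#' @param chromLength Length in bp (scalar or per-chromosome vector).
#' @param motif5,motif3 Telomere motifs planted at the 5' and 3' ends.
#' @param telomereCounts `nChrom x 2` matrix of per-end repeat counts
#'   (0 allowed); NULL for the default pattern described above.
#' @param centromeres Per-chromosome list; each element is a list of
#'   array specs `list(lengthBp, monomerLength, divergence, centerFrac)`
#'   (several arrays per chromosome allowed, `NULL` element for none).
#'   NULL for the default single mid-chromosome array.
#' @param centromereLengthFrac Fraction of the chromosome occupied by
#'   the default centromeric array.
#' @param monomerLength,divergence Defaults for centromere arrays.
#' @param geneSpacing,geneLength,centromereGeneSpacing Gene placement.
#' @param gypsyBackgroundFraction,gypsyCentromereFraction Gypsy coverage.
#' @return Config list for [simulateGenome()].
#' @export
genomeConfig <- function(nChrom = 9L, chromLength = 1e6,
                         motif5 = "CCCATTT", motif3 = "TTTAGGG",
                         telomereCounts = NULL, centromeres = NULL,
                         centromereLengthFrac = 0.1,
                         monomerLength = 171L, divergence = 0.02,
                         geneSpacing = 13000L, geneLength = 4000L,
                         centromereGeneSpacing = 250000L,
                         gypsyBackgroundFraction = 0.06,
                         gypsyCentromereFraction = 0.45) {
    nChrom <- as.integer(nChrom)
    chromLength <- rep_len(as.numeric(chromLength), nChrom)
    if (is.null(telomereCounts)) {
        nTel <- 2L * nChrom - (nChrom >= 5L)
        ends <- round(seq(111, 2673, length.out = nTel))
        telomereCounts <- matrix(0L, nChrom, 2L)
        slot <- 1L
        for (i in seq_len(nChrom)) for (j in 1:2) {
            if (i == 5L && j == 1L && nChrom >= 5L) {
                telomereCounts[i, j] <- 2L  # bare end, sub-threshold
            } else {
                telomereCounts[i, j] <- as.integer(ends[slot])
                slot <- slot + 1L
            }
        }
    }
    stopifnot(is.matrix(telomereCounts),
              nrow(telomereCounts) == nChrom, ncol(telomereCounts) == 2L,
              all(telomereCounts >= 0))
    if (is.null(centromeres)) {
        centromeres <- lapply(seq_len(nChrom), function(i)
            list(list(lengthBp = round(centromereLengthFrac *
                                       chromLength[i]),
                      monomerLength = monomerLength,
                      divergence = divergence, centerFrac = 0.5)))
    }
    for (cl in centromeres) for (a in cl)
        if (!is.null(a) && (a$divergence < 0 || a$divergence > 0.5))
            stop("monomer divergence must lie in [0, 0.5]")
    list(nChrom = nChrom, chromLength = chromLength, motif5 = motif5,
         motif3 = motif3, telomereCounts = telomereCounts,
         centromeres = centromeres, geneSpacing = as.integer(geneSpacing),
         geneLength = as.integer(geneLength),
         centromereGeneSpacing = as.integer(centromereGeneSpacing),
         gypsyBackgroundFraction = gypsyBackgroundFraction,
         gypsyCentromereFraction = gypsyCentromereFraction)
}

## regular interval tiling covering `frac` of [from, to]
.tileIntervals <- function(from, to, frac, pieceLen) {
    if (frac <= 0 || to <= from)
        return(cbind(start = numeric(0), end = numeric(0)))
    pieceLen <- min(pieceLen, to - from + 1)
    spacing <- max(pieceLen + 1, round(pieceLen / frac))
    starts <- seq(from, to - pieceLen + 1, by = spacing)
    cbind(start = starts, end = pmin(starts + pieceLen - 1, to))
}

#' Simulate a genome bundle with truth manifest
#'
#' Builds chromosomes as i.i.d. uniform ACGT background with telomere
#' arrays placed exactly at the sequence termini, centromeric tandem
#' arrays spliced in at their configured positions, gene models dense
#' outside and sparse inside centromeres, and Gypsy intervals the other
#' way around. Identical `(cfg, seed)` give byte-identical output.
#'
#' @param cfg See [genomeConfig()].
#' @param seed Integer seed; the single source of randomness.
#' @return List with `genome` (DNAStringSet), `genes` (GRanges with
#'   `gene_id`, `rank`), `gypsy` (GRanges), `manifest` (list), `cfg`.
#' @export
simulateGenome <- function(cfg = genomeConfig(), seed = 1L) {
    set.seed(as.integer(seed))
    chromNames <- sprintf("Chr%d", seq_len(cfg$nChrom))
    seqs <- character(cfg$nChrom)
    manifestChrom <- list()
    geneRows <- list()
    gypsyRows <- list()
    for (i in seq_len(cfg$nChrom)) {
        L <- cfg$chromLength[i]
        ch <- chromNames[i]
        c5 <- cfg$telomereCounts[i, 1]
        c3 <- cfg$telomereCounts[i, 2]
        m5 <- strsplit(cfg$motif5, "")[[1]]
        m3 <- strsplit(cfg$motif3, "")[[1]]
        telLen <- c5 * length(m5) + c3 * length(m3)
        if (telLen >= L)
            stop("telomere arrays longer than chromosome ", ch)
        s <- sample(.DNA, L, replace = TRUE)
        cenTruth <- list()
        for (a in cfg$centromeres[[i]]) {
            if (is.null(a)) next
            m <- a$monomerLength
            copies <- max(2L, round(a$lengthBp / m))
            monomer <- sample(.DNA, m, replace = TRUE)
            block <- rep(monomer, copies)
            if (a$divergence > 0) {
                mut <- which(stats::runif(length(block)) < a$divergence)
                if (length(mut))
                    block[mut] <- vapply(block[mut], function(x)
                        sample(setdiff(.DNA, x), 1L), character(1))
            }
            len <- length(block)
            start <- max(telLen + 1,
                         round(a$centerFrac * L - len / 2))
            if (start + len - 1 > L - c3 * length(m3))
                stop("centromere array does not fit in chromosome ", ch)
            s[start:(start + len - 1)] <- block
            cenTruth[[length(cenTruth) + 1L]] <-
                list(start = start, end = start + len - 1,
                     period = m, copies = copies,
                     divergence = a$divergence)
        }
        if (c5 > 0) s[seq_len(c5 * length(m5))] <- rep(m5, c5)
        if (c3 > 0) s[(L - c3 * length(m3) + 1):L] <- rep(m3, c3)
        protect <- rbind(
            if (c5 > 0) c(1, c5 * length(m5)),
            if (c3 > 0) c(L - c3 * length(m3) + 1, L))
        if (is.null(protect)) protect <- cbind(numeric(0), numeric(0))
        s <- .scrubMotifs(s, unique(c(cfg$motif5, cfg$motif3)), protect)
        seqs[i] <- paste(s, collapse = "")
        ## gene placement: dense background, sparse centromere
        cen <- if (length(cenTruth))
            cbind(vapply(cenTruth, `[[`, numeric(1), "start"),
                  vapply(cenTruth, `[[`, numeric(1), "end"))
        else cbind(numeric(0), numeric(0))
        inCen <- function(p)
            length(cen) && any(p >= cen[, 1] & p <= cen[, 2])
        starts <- seq(cfg$geneSpacing, L - cfg$geneLength,
                      by = cfg$geneSpacing)
        keep <- logical(length(starts))
        lastCenGene <- -Inf
        for (gi in seq_along(starts)) {
            p <- starts[gi]
            if (inCen(p) || inCen(p + cfg$geneLength)) {
                if (p - lastCenGene >= cfg$centromereGeneSpacing) {
                    keep[gi] <- TRUE
                    lastCenGene <- p
                }
            } else keep[gi] <- TRUE
        }
        starts <- starts[keep]
        if (length(starts))
            geneRows[[ch]] <- data.frame(
                chrom = ch, start = starts,
                end = starts + cfg$geneLength - 1,
                strand = rep_len(c("+", "-"), length(starts)),
                gene_id = sprintf("%s_g%04d", ch, seq_along(starts)))
        ## gypsy annotation
        gy <- .tileIntervals(1, L, cfg$gypsyBackgroundFraction, 2000)
        if (length(cen)) {
            if (nrow(gy)) {
                keepBg <- !vapply(seq_len(nrow(gy)), function(r)
                    inCen(gy[r, 1]) || inCen(gy[r, 2]), logical(1))
                gy <- gy[keepBg, , drop = FALSE]
            }
            for (k in seq_len(nrow(cen))) {
                gy <- rbind(gy, .tileIntervals(
                    cen[k, 1], cen[k, 2],
                    cfg$gypsyCentromereFraction, 9000))
            }
        }
        if (nrow(gy))
            gypsyRows[[ch]] <- data.frame(chrom = ch, start = gy[, 1],
                                          end = gy[, 2])
        manifestChrom[[ch]] <- list(
            length = L, telomere5 = c5, telomere3 = c3,
            centromeres = cenTruth)
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chromNames
    gdf <- do.call(rbind, unname(geneRows))
    if (is.null(gdf)) {
        genes <- GenomicRanges::GRanges()
        mcols(genes)$gene_id <- character(0)
        mcols(genes)$rank <- integer(0)
    } else {
        genes <- GenomicRanges::GRanges(gdf$chrom,
            IRanges::IRanges(gdf$start, gdf$end), strand = gdf$strand)
        mcols(genes)$gene_id <- gdf$gene_id
        genes <- .rankGenes(genes)
    }
    ydf <- do.call(rbind, unname(gypsyRows))
    if (is.null(ydf)) {
        gypsy <- GenomicRanges::GRanges()
        mcols(gypsy)$label <- character(0)
    } else {
        gypsy <- GenomicRanges::GRanges(ydf$chrom,
            IRanges::IRanges(ydf$start, ydf$end))
        mcols(gypsy)$label <- "Gypsy"
    }
    manifest <- list(seed = as.integer(seed),
                     motif5 = cfg$motif5, motif3 = cfg$motif3,
                     chromosomes = manifestChrom)
    list(genome = genome, genes = genes, gypsy = gypsy,
         manifest = manifest, cfg = cfg)
}

#' Simulate ultra-long reads spanning a chromosome terminus
#'
#' Each read covers the terminal `anchorLen` bp of the chromosome
#' (chosen to contain the whole existing telomere array) and carries a
#' per-read number of additional telomere motif copies beyond the
#' assembled end, up to `extensionRepeats`; one read always carries the
#' full extension so the best-read target is well defined. The truthful
#' alignment of each read's genomic portion is returned in PAF
#' convention, and the manifest records each read's true total repeat
#' count.
#'
#' @param bundle Genome bundle from [simulateGenome()].
#' @param chrom Chromosome name.
#' @param end `"5prime"` or `"3prime"`.
#' @param nReads Number of reads (0 allowed).
#' @param extensionRepeats Maximum extra motif copies per read (>= 0).
#' @param errorRate Per-base substitution rate in `[0, 0.3)`.
#' @param seed Integer seed.
#' @param anchorLen Genomic anchor length in bp; NULL to auto-size to
#'   the telomere array plus 3 kb.
#' @return List `reads` (DNAStringSet), `alignments` (GRanges in
#'   [readPaf()] layout) and `manifest` (data.frame with `read_id`,
#'   `extraRepeats`, `trueRepeatCount`).
#' @export
simulateTerminalReads <- function(bundle, chrom,
                                  end = c("5prime", "3prime"),
                                  nReads = 5L, extensionRepeats = 0L,
                                  errorRate = 0, seed = 1L,
                                  anchorLen = NULL) {
    end <- match.arg(end)
    if (extensionRepeats < 0) stop("extension must be >= 0")
    if (errorRate < 0 || errorRate >= 0.3)
        stop("errorRate must lie in [0, 0.3)")
    set.seed(as.integer(seed))
    s <- as.character(bundle$genome[[chrom]])
    L <- nchar(s)
    info <- bundle$manifest$chromosomes[[chrom]]
    motif <- if (end == "5prime") bundle$manifest$motif5
             else bundle$manifest$motif3
    planted <- if (end == "5prime") info$telomere5 else info$telomere3
    mlen <- nchar(motif)
    if (is.null(anchorLen))
        anchorLen <- planted * mlen + 3000L
    anchorLen <- min(anchorLen, L)
    if (nReads == 0L)
        return(list(reads = Biostrings::DNAStringSet(),
                    alignments = readPafEmpty(),
                    manifest = data.frame(read_id = character(0),
                                          extraRepeats = integer(0),
                                          trueRepeatCount = integer(0))))
    extras <- if (nReads == 1L) as.integer(extensionRepeats)
              else as.integer(sample.int(extensionRepeats + 1L, nReads,
                                         replace = TRUE) - 1L)
    extras[1] <- as.integer(extensionRepeats)
    ids <- sprintf("read_%s_%s_%02d", chrom, end, seq_len(nReads))
    seqs <- character(nReads)
    paf <- vector("list", nReads)
    for (r in seq_len(nReads)) {
        ext <- paste(rep(motif, extras[r]), collapse = "")
        if (end == "5prime") {
            genomic <- substr(s, 1L, anchorLen)
            read <- paste0(ext, genomic)
            qstart <- nchar(ext); qend <- nchar(read)
            tstart <- 0L; tend <- anchorLen
        } else {
            genomic <- substr(s, L - anchorLen + 1L, L)
            read <- paste0(genomic, ext)
            qstart <- 0L; qend <- anchorLen
            tstart <- L - anchorLen; tend <- L
        }
        if (errorRate > 0) {
            rv <- strsplit(read, "")[[1]]
            mut <- which(stats::runif(length(rv)) < errorRate)
            if (length(mut))
                rv[mut] <- vapply(rv[mut], function(x)
                    sample(setdiff(.DNA, x), 1L), character(1))
            read <- paste(rv, collapse = "")
        }
        seqs[r] <- read
        paf[[r]] <- data.frame(read_id = ids[r],
            read_len = nchar(read), read_start = qstart,
            read_end = qend, tstart = tstart, tend = tend)
    }
    pafdf <- do.call(rbind, paf)
    aln <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(pafdf$tstart + 1, pafdf$tend), strand = "+")
    mcols(aln) <- S4Vectors::DataFrame(
        read_id = pafdf$read_id, read_len = pafdf$read_len,
        read_start = pafdf$read_start, read_end = pafdf$read_end,
        nmatch = pafdf$tend - pafdf$tstart,
        alen = pafdf$tend - pafdf$tstart, mapq = 60L,
        tlen = as.integer(L))
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- ids
    list(reads = reads, alignments = aln,
         manifest = data.frame(read_id = ids, extraRepeats = extras,
                               trueRepeatCount = planted + extras))
}

## empty GRanges in the readPaf layout
readPafEmpty <- function() {
    out <- GenomicRanges::GRanges()
    mcols(out) <- S4Vectors::DataFrame(
        read_id = character(0), read_len = integer(0),
        read_start = integer(0), read_end = integer(0),
        nmatch = integer(0), alen = integer(0), mapq = integer(0),
        tlen = integer(0))
    out
}

#' Plant substitution errors into an assembly
#'
#' Draws independent per-base substitutions (to a different nucleotide)
#' at rate `subRate` and returns the corrupted sequences together with
#' the exact number and positions of the introduced errors — the ground
#' truth for QV estimation.
#'
#' @param genome DNAStringSet.
#' @param subRate Per-base substitution probability in `[0, 0.01]`.
#' @param seed Integer seed.
#' @return List `genome` (corrupted DNAStringSet), `errorCount`,
#'   `positions` (list per chromosome).
#' @export
corruptAssembly <- function(genome, subRate, seed = 1L) {
    if (subRate < 0 || subRate > 0.01)
        stop("subRate must lie in [0, 0.01]")
    set.seed(as.integer(seed))
    seqs <- as.character(genome)
    positions <- list()
    total <- 0L
    if (subRate > 0) for (ch in names(seqs)) {
        v <- strsplit(seqs[[ch]], "")[[1]]
        mut <- which(stats::runif(length(v)) < subRate & v != "N")
        if (length(mut)) {
            v[mut] <- vapply(v[mut], function(x)
                sample(setdiff(.DNA, x), 1L), character(1))
            seqs[[ch]] <- paste(v, collapse = "")
        }
        positions[[ch]] <- mut
        total <- total + length(mut)
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(genome)
    list(genome = out, errorCount = total, positions = positions)
}

#' Protein-family generator configuration
#'
#' Defaults emulate a seven-member flavonoid B-ring hydroxylase family:
#' members 1–6 carry Thr or Ser at SRS6 position 8 (F3'H-like) and
#' member 7 carries Ala (F3'5'H-like); members 1 and 2 are adjacent in
#' gene order (a tandem pair) and derived from each other at ~91%
#' identity; two decoys fall outside the 400–600 aa length window.
#'
#' @param anchorLength Anchor protein length (aa).
#' @param srs6Start,srs6End SRS6 coordinates on the anchor (1-based
#'   inclusive).
#' @param diagnosticPosition Diagnostic position within SRS6 (default 8).
#' @param members data.frame with columns `id`, `length`, `srs6Residue`,
#'   `identity` (target vs `deriveFrom`), `deriveFrom` (`"anchor"` or an
#'   earlier member id), `chrom`, `rank`.
#' @param decoys data.frame with columns `id`, `length` (no SRS6).
#' @param geneSpacing,geneLength,fillerPerChrom Gene-order scaffold.
#' @return Config list for [simulateFamily()].
#' @export
familyConfig <- function(anchorLength = 505L, srs6Start = 460L,
                         srs6End = 469L, diagnosticPosition = 8L,
                         members = NULL, decoys = NULL,
                         geneSpacing = 10000L, geneLength = 3000L,
                         fillerPerChrom = 40L) {
    if (srs6Start < 1L || srs6End > anchorLength || srs6Start > srs6End)
        stop("SRS6 coordinates outside anchor length")
    if (is.null(members))
        members <- data.frame(
            id = sprintf("fam%d", 1:7),
            length = c(505L, 505L, 500L, 510L, 505L, 498L, 505L),
            srs6Residue = c("T", "S", "T", "S", "T", "S", "A"),
            identity = c(0.75, 0.9136, 0.75, 0.75, 0.70, 0.75, 0.62),
            deriveFrom = c("anchor", "fam1", "anchor", "anchor",
                           "anchor", "anchor", "anchor"),
            chrom = c("Chr1", "Chr1", "Chr2", "Chr2", "Chr3", "Chr3",
                      "Chr4"),
            rank = c(10L, 11L, 5L, 14L, 8L, 16L, 3L))
    if (is.null(decoys))
        decoys <- data.frame(id = c("decoyShort", "decoyLong"),
                             length = c(399L, 601L))
    list(anchorLength = as.integer(anchorLength),
         srs6Start = as.integer(srs6Start), srs6End = as.integer(srs6End),
         diagnosticPosition = as.integer(diagnosticPosition),
         members = members, decoys = decoys,
         geneSpacing = as.integer(geneSpacing),
         geneLength = as.integer(geneLength),
         fillerPerChrom = as.integer(fillerPerChrom))
}

#' Simulate a protein family with planted SRS6 residues and clusters
#'
#' Generates an anchor protein with known SRS6 coordinates, derives each
#' member from its source at the configured identity, plants the
#' diagnostic residue at SRS6 position `diagnosticPosition`, places the
#' member genes at configured ranks in a filler gene scaffold, and
#' fabricates a domain-table of profile-HMM hits listing every member
#' plus the decoys. The truth manifest records the planted label, the
#' expected filter verdict and the expected cluster partition.
#'
#' @param cfg See [familyConfig()].
#' @param seed Integer seed.
#' @return List `proteins` (AAStringSet of members + decoys), `anchor`
#'   (list `seq`, `srs6Start`, `srs6End`, `diagnosticPosition`), `hits`
#'   (data.frame `target`, `query`, `evalue`, `score`), `genes`
#'   (GRanges with ranks), `truth` (list).
#' @export
simulateFamily <- function(cfg = familyConfig(), seed = 1L) {
    set.seed(as.integer(seed))
    anchor <- paste(sample(.AA20, cfg$anchorLength, replace = TRUE),
                    collapse = "")
    diagPos <- cfg$srs6Start + cfg$diagnosticPosition - 1L
    mem <- cfg$members
    seqs <- list()
    for (i in seq_len(nrow(mem))) {
        src <- if (mem$deriveFrom[i] == "anchor") anchor
               else seqs[[mem$deriveFrom[i]]]
        v <- strsplit(src, "")[[1]]
        nmut <- round((1 - mem$identity[i]) * length(v))
        if (nmut > 0) {
            mut <- sample(length(v), nmut)
            v[mut] <- vapply(v[mut], function(x)
                sample(setdiff(.AA20, x), 1L), character(1))
        }
        targetLen <- mem$length[i]
        if (targetLen < cfg$srs6End + 1L)
            stop("member ", mem$id[i],
                 " too short to contain the SRS6 window")
        if (length(v) > targetLen) v <- v[seq_len(targetLen)]
        if (length(v) < targetLen)
            v <- c(v, sample(.AA20, targetLen - length(v),
                             replace = TRUE))
        v[diagPos] <- mem$srs6Residue[i]
        seqs[[mem$id[i]]] <- paste(v, collapse = "")
    }
    for (i in seq_len(nrow(cfg$decoys)))
        seqs[[cfg$decoys$id[i]]] <- paste(
            sample(.AA20, cfg$decoys$length[i], replace = TRUE),
            collapse = "")
    proteins <- Biostrings::AAStringSet(unlist(seqs))
    hits <- data.frame(
        target = c(mem$id, cfg$decoys$id), query = "CYP450_profile",
        evalue = 1e-50, score = 300)
    ## gene scaffold: filler genes at every rank, members at theirs
    chroms <- unique(mem$chrom)
    rows <- list()
    for (ch in chroms) {
        ids <- sprintf("%s_f%03d", ch, seq_len(cfg$fillerPerChrom))
        mi <- mem$chrom == ch
        ids[mem$rank[mi]] <- mem$id[mi]
        starts <- seq_len(cfg$fillerPerChrom) * cfg$geneSpacing
        rows[[ch]] <- data.frame(chrom = ch, start = starts,
            end = starts + cfg$geneLength - 1, gene_id = ids)
    }
    gdf <- do.call(rbind, unname(rows))
    genes <- GenomicRanges::GRanges(gdf$chrom,
        IRanges::IRanges(gdf$start, gdf$end), strand = "+")
    mcols(genes)$gene_id <- gdf$gene_id
    genes <- .rankGenes(genes)
    ## expected cluster partition by the generator's own chaining
    expected <- list()
    for (ch in chroms) {
        mm <- mem[mem$chrom == ch, , drop = FALSE]
        mm <- mm[order(mm$rank), , drop = FALSE]
        if (nrow(mm) < 2L) next
        grp <- cumsum(c(1L, diff(mm$rank) > 8L))
        for (g in unique(grp))
            if (sum(grp == g) >= 2L)
                expected[[length(expected) + 1L]] <- mm$id[grp == g]
    }
    labels <- ifelse(mem$srs6Residue %in% c("T", "S"), "F3pH_like",
                     ifelse(mem$srs6Residue == "A", "F3p5pH_like",
                            "unclassified"))
    truth <- list(
        labels = stats::setNames(labels, mem$id),
        srs6Residue = stats::setNames(mem$srs6Residue, mem$id),
        filterExcluded = cfg$decoys$id[cfg$decoys$length < 400 |
                                       cfg$decoys$length > 600],
        expectedClusters = expected,
        identityTargets = mem[, c("id", "deriveFrom", "identity")])
    list(proteins = proteins,
         anchor = list(seq = anchor, srs6Start = cfg$srs6Start,
                       srs6End = cfg$srs6End,
                       diagnosticPosition = cfg$diagnosticPosition),
         hits = hits, genes = genes, truth = truth)
}

#' Simulate a tissue FPKM matrix with planted fold ratios
#'
#' Three replicates per tissue; each gene's per-tissue replicate values
#' are symmetric around the planted mean, so tissue means (and therefore
#' fold ratios between genes) are reproduced exactly.
#'
#' @param means Matrix of planted per-tissue mean FPKM (genes x
#'   tissues, dimnames required).
#' @param reps Replicates per tissue (default 3).
#' @param spreadFrac Half-spread of replicate values as a fraction of
#'   the mean (default 0.1).
#' @return Numeric matrix genes x (tissues * reps) with names like
#'   `"FB_1"`.
#' @export
simulateFpkm <- function(means, reps = 3L, spreadFrac = 0.1) {
    tissues <- colnames(means)
    out <- matrix(0, nrow(means), length(tissues) * reps,
        dimnames = list(rownames(means),
            paste(rep(tissues, each = reps), seq_len(reps), sep = "_")))
    offs <- seq(-spreadFrac, spreadFrac, length.out = reps)
    for (t in seq_along(tissues)) for (r in seq_len(reps))
        out[, (t - 1L) * reps + r] <- means[, t] * (1 + offs[r])
    out
}

#' Write a genome bundle to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `gypsy.bed` and `manifest.json`.
#'
#' @param bundle From [simulateGenome()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeGenomeBundle <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeFasta(bundle$genome, file.path(dir, "genome.fa"))
    writeGffGenes(bundle$genes, file.path(dir, "genes.gff3"))
    writeBed(bundle$gypsy, file.path(dir, "gypsy.bed"))
    jsonlite::write_json(bundle$manifest,
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
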